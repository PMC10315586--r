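#' Score predicted against designed proportions
#'
#' Per cell type, computes the Pearson correlation (and its square), the
#' root-mean-squared error and the mean absolute error between predicted
#' and true proportions across samples, plus unweighted averages over cell
#' types. An `unknown` column in the prediction is excluded (designed
#' mixtures carry no unknown mass). A cell type whose true proportions are
#' constant has no defined correlation; it is excluded from the average r
#' squared with a warning while its RMSE/MAE are still computed.
#'
#' @param pred samples x cell-types proportion matrix (e.g. from
#'   [hibed_deconvolve()]).
#' @param truth a `hibed_mixture_truth` or a samples x cell-types matrix.
#' @return object of class `hibed_eval`: list with `per_type` (data.frame:
#'   `cell_type`, `pearson_r`, `r_squared`, `rmse`, `mae`) and aggregates
#'   `average_r_squared`, `average_rmse`, `average_mae`. RMSE/MAE are in
#'   proportion units; multiply by 100 to report percentage points.
#' @export
evaluate_proportions <- function(pred, truth) {
  truth_m <- if (inherits(truth, "hibed_mixture_truth")) truth$proportions else truth
  pred <- as.matrix(pred)
  pred <- pred[, setdiff(colnames(pred), "unknown"), drop = FALSE]
  types <- intersect(colnames(truth_m), colnames(pred))
  if (length(types) == 0) stop("no shared cell types between pred and truth", call. = FALSE)
  common <- intersect(rownames(truth_m), rownames(pred))
  if (length(common) < 3) stop("need >= 3 matched samples", call. = FALSE)
  pred <- pred[common, types, drop = FALSE]
  truth_m <- truth_m[common, types, drop = FALSE]

  per <- lapply(types, function(t) {
    p <- pred[, t]; q <- truth_m[, t]
    r <- if (sd(q) == 0) {
      warning("constant true proportions for ", t, "; correlation undefined")
      NA_real_
    } else cor(p, q)
    data.frame(cell_type = t, pearson_r = r, r_squared = r^2,
               rmse = sqrt(mean((p - q)^2)), mae = mean(abs(p - q)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_type = per,
                 average_r_squared = mean(per$r_squared, na.rm = TRUE),
                 average_rmse = mean(per$rmse),
                 average_mae = mean(per$mae)),
            class = "hibed_eval")
}

#' @export
print.hibed_eval <- function(x, ...) {
  cat("deconvolution performance (", nrow(x$per_type), " cell types)\n", sep = "")
  print(transform(x$per_type,
                  r_squared = round(r_squared, 4),
                  rmse_pct = round(100 * rmse, 3),
                  mae_pct = round(100 * mae, 3))[
                    , c("cell_type", "pearson_r", "r_squared", "rmse_pct", "mae_pct")],
        row.names = FALSE)
  cat(sprintf("average R^2 = %.4f, average RMSE = %.3f%%, average MAE = %.3f%%\n",
              x$average_r_squared, 100 * x$average_rmse, 100 * x$average_mae))
  invisible(x)
}

.require_leaves <- function(props, leaves) {
  missing <- setdiff(leaves, colnames(props))
  if (length(missing) > 0) {
    stop("requires layer-2 proportions (missing: ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  }
}

#' Glia-to-neuron ratio per sample
#'
#' GNR = (astrocyte + microglia + oligodendrocyte) / (GABA + GLU). A zero
#' neuronal sum yields `NaN` with a warning.
#'
#' @param props layer-2 proportion matrix with the seven leaf types.
#' @return named numeric vector, one ratio per sample.
#' @export
glia_neuron_ratio <- function(props) {
  .require_leaves(props, c("Astrocyte", "Microglia", "Oligodendrocyte", "GABA", "GLU"))
  glial <- rowSums(props[, c("Astrocyte", "Microglia", "Oligodendrocyte"), drop = FALSE])
  neuronal <- rowSums(props[, c("GABA", "GLU"), drop = FALSE])
  if (any(neuronal == 0)) warning("zero neuronal proportion; GNR undefined for some samples")
  setNames(ifelse(neuronal == 0, NaN, glial / neuronal), rownames(props))
}

#' GABAergic-to-glutamatergic neuron ratio per sample
#'
#' @param props layer-2 proportion matrix.
#' @return named numeric vector; `NaN` with a warning where GLU = 0.
#' @export
gaba_glu_ratio <- function(props) {
  .require_leaves(props, c("GABA", "GLU"))
  glu <- props[, "GLU"]
  if (any(glu == 0)) warning("zero GLU proportion; ratio undefined for some samples")
  setNames(ifelse(glu == 0, NaN, props[, "GABA"] / glu), rownames(props))
}

#' Composition of the glial compartment
#'
#' Each glial leaf proportion divided by the glial sum, so rows sum to 1
#' when any glial signal is present; a zero glial sum yields `NaN`s with a
#' warning.
#'
#' @param props layer-2 proportion matrix.
#' @return samples x 3 matrix (Astrocyte, Microglia, Oligodendrocyte
#'   fractions of the glial compartment).
#' @export
glial_composition <- function(props) {
  glial_types <- c("Astrocyte", "Microglia", "Oligodendrocyte")
  .require_leaves(props, glial_types)
  g <- props[, glial_types, drop = FALSE]
  tot <- rowSums(g)
  if (any(tot == 0)) warning("zero glial proportion; composition undefined for some samples")
  out <- g / ifelse(tot == 0, NaN, tot)
  rownames(out) <- rownames(props)
  out
}
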