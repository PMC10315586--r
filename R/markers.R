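#' One-vs-rest moderated differential methylation statistics
#'
#' For each probe and each class, computes the mean beta difference between
#' the class and all remaining samples, a pooled two-group residual
#' variance, and a moderated t-statistic in which per-probe variances are
#' shrunk toward a common prior by empirical Bayes (a scaled
#' inverse-chi-square prior fitted to the observed variances;
#' `limma::squeezeVar`). Moderation stabilises the ranking when each class
#' holds only a handful of purified samples. A probe whose moderated
#' variance is zero gets t = 0 when its effect is zero, and +/-Inf (perfect
#' separation) otherwise.
#'
#' @param beta probes x samples matrix without missing values.
#' @param ann annotation with `sample_id`, `cell_type`; `cell_type` levels
#'   must cover `classes`.
#' @param classes ordered character vector of class labels to contrast.
#' @return object of class `hibed_modt`: list with `probe_ids`, `classes`,
#'   matrices `effect` and `t` (probes x classes), and per-class counts
#'   `n_target`, `n_rest`.
#' @export
moderated_one_vs_rest <- function(beta, ann, classes) {
  validate_beta_matrix(beta)
  validate_annotation(ann, beta)
  if (nrow(beta) == 0) stop("zero probes", call. = FALSE)
  ann <- ann[ann$cell_type %in% classes, , drop = FALSE]
  beta <- beta[, ann$sample_id, drop = FALSE]
  if (anyNA(beta)) stop("missing values among used probes/samples", call. = FALSE)
  counts <- table(factor(ann$cell_type, levels = classes))
  if (any(counts < 2)) {
    stop("every class needs >= 2 samples; short: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }

  p <- nrow(beta)
  effect <- tmat <- matrix(NA_real_, p, length(classes),
                           dimnames = list(rownames(beta), classes))
  n_target <- n_rest <- setNames(integer(length(classes)), classes)

  row_var <- function(x) {
    n <- ncol(x)
    mu <- rowMeans(x)
    pmax(0, (rowSums(x * x) - n * mu * mu) / (n - 1))
  }

  for (cl in classes) {
    in_c <- ann$cell_type == cl
    x1 <- beta[, in_c, drop = FALSE]
    x0 <- beta[, !in_c, drop = FALSE]
    n1 <- ncol(x1); n0 <- ncol(x0)
    eff <- rowMeans(x1) - rowMeans(x0)
    df <- n1 + n0 - 2
    s2 <- ((n1 - 1) * row_var(x1) + (n0 - 1) * row_var(x0)) / df
    sq <- tryCatch(suppressWarnings(limma::squeezeVar(s2, df = df)),
                   error = function(e) list(var.post = s2))
    v <- sq$var.post * (1 / n1 + 1 / n0)
    t_c <- ifelse(v > 0, eff / sqrt(v), ifelse(eff == 0, 0, sign(eff) * Inf))
    effect[, cl] <- eff
    tmat[, cl] <- t_c
    n_target[cl] <- n1
    n_rest[cl] <- n0
  }
  structure(list(probe_ids = rownames(beta), classes = classes,
                 effect = effect, t = tmat,
                 n_target = n_target, n_rest = n_rest),
            class = "hibed_modt")
}

#' Select top-ranked cell-type-specific CpGs
#'
#' Ranks probes by moderated t per class and keeps, per class, the
#' `n_per_type` most hypermethylated (`mode = "hyper"`: largest t), most
#' hypomethylated (`"hypo"`: most negative t), or the union of both
#' (`"hybrid"`). Ranking uses a stable sort with probe-ID lexicographic
#' tie-break so that selection is fully deterministic. The pooled set is
#' the deduplicated union across classes, ordered by probe ID.
#'
#' @param res a `hibed_modt` result.
#' @param n_per_type probes to keep per class per direction.
#' @param mode `"hyper"`, `"hypo"` or `"hybrid"`.
#' @return list with `per_class` (named list of probe-ID vectors) and
#'   `pooled` (sorted unique union).
#' @export
select_top_cpgs <- function(res, n_per_type, mode = c("hybrid", "hyper", "hypo")) {
  stopifnot(inherits(res, "hibed_modt"))
  mode <- match.arg(mode)
  p <- length(res$probe_ids)
  if (n_per_type < 1 || n_per_type > p) {
    stop("n_per_type must be between 1 and the number of probes (", p, ")",
         call. = FALSE)
  }
  top <- function(tvals, n, direction) {
    key <- if (direction == "hyper") -tvals else tvals
    ord <- order(key, res$probe_ids)
    res$probe_ids[ord[seq_len(n)]]
  }
  per_class <- lapply(res$classes, function(cl) {
    tv <- res$t[, cl]
    switch(mode,
           hyper  = top(tv, n_per_type, "hyper"),
           hypo   = top(tv, n_per_type, "hypo"),
           hybrid = union(top(tv, n_per_type, "hyper"),
                          top(tv, n_per_type, "hypo")))
  })
  names(per_class) <- res$classes
  list(per_class = per_class,
       pooled = sort(unique(unlist(per_class, use.names = FALSE))))
}
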