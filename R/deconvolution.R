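#' Constrained-projection estimate of mixing proportions
#'
#' Solves the Houseman-style constrained projection for one bulk profile:
#' \deqn{\min_{\pi} \|y - X\pi\|^2 \quad s.t.\ \pi \ge 0,\ \sum_i \pi_i
#' \{\le,=\} 1} where `X` holds the reference mean profiles (probes x cell
#' types) and `y` the bulk betas over the same probes. The solution is
#' found by exact enumeration of KKT active sets: every subset of the
#' non-negativity constraints, with and without the sum constraint bound,
#' is solved as an equality-constrained least-squares system and the
#' feasible candidate with the smallest objective is returned. With at most
#' seven cell types this is at most 256 tiny linear solves, exact to solver
#' precision and fully deterministic (ties resolved by fixed enumeration
#' order; singular systems by the minimum-norm solution).
#'
#' @param y numeric vector of bulk beta values over the node probes.
#' @param X probes x cell-types matrix of reference means.
#' @param sum_mode `"le_one"` (proportions may leave an unexplained
#'   remainder) or `"eq_one"` (proportions forced onto the simplex).
#' @return named proportion vector (length `ncol(X)`), non-negative, with
#'   attribute `objective` (residual sum of squares).
#' @export
cp_qp <- function(y, X, sum_mode = c("le_one", "eq_one")) {
  sum_mode <- match.arg(sum_mode)
  if (!is.matrix(X) || ncol(X) < 2) stop("X must be a matrix with >= 2 cell types", call. = FALSE)
  if (length(y) != nrow(X)) stop("dimension mismatch between y and X", call. = FALSE)
  if (nrow(X) < ncol(X)) stop("need at least as many probes as cell types", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  k <- ncol(X)
  if (qr(X)$rank < k) {
    warning("rank-deficient reference matrix; ties broken by minimum-norm convention")
  }
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  eps <- 1e-9

  solve_safely <- function(A, b) {
    tryCatch(solve(A, b), error = function(e) drop(MASS::ginv(A) %*% b))
  }

  best <- rep(0, k)
  best_obj <- if (sum_mode == "le_one") 0 else Inf  # pi = 0 feasible only for le_one

  for (mask in seq_len(2^k) - 1L) {
    free <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    nf <- length(free)
    for (sum_active in c(FALSE, TRUE)) {
      if (sum_mode == "eq_one" && !sum_active) next
      if (nf == 0) next  # pi = 0 handled above; sum constraint unsatisfiable
      if (!sum_active) {
        pf <- solve_safely(XtX[free, free, drop = FALSE], Xty[free])
      } else {
        A <- rbind(cbind(2 * XtX[free, free, drop = FALSE], 1),
                   c(rep(1, nf), 0))
        sol <- solve_safely(A, c(2 * Xty[free], 1))
        pf <- sol[seq_len(nf)]
      }
      if (any(!is.finite(pf)) || any(pf < -eps)) next
      s <- sum(pf)
      if (!sum_active && sum_mode == "le_one" && s > 1 + eps) next
      if (sum_active && abs(s - 1) > 1e-6) next
      obj <- drop(pf %*% XtX[free, free, drop = FALSE] %*% pf) - 2 * sum(Xty[free] * pf)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- rep(0, k)
        best[free] <- pf
      }
    }
  }
  pi_hat <- pmax(best, 0)
  names(pi_hat) <- colnames(X)
  attr(pi_hat, "objective") <- best_obj + sum(y * y)
  pi_hat
}

#' Deconvolve bulk samples against one reference sub-library
#'
#' Restricts the bulk matrix to the sub-library's probes and runs [cp_qp()]
#' per sample. Probes missing for a given sample are dropped from that
#' sample's fit only. Coverage below 80% of the library probes triggers a
#' warning; below 50% an error. When the sub-library carries context
#' columns (pooled mean profiles of the other hierarchy groups, attached
#' by [build_hibed_library()] to Layer-2 nodes), they enter the projection
#' as nuisance components under the same sum constraint and are discarded
#' from the returned proportions: bulk mass from other cell groups lands
#' on them instead of biasing the node's cell-type estimates.
#'
#' @param bulk probes x samples beta matrix.
#' @param sub a `hibed_sublibrary`.
#' @param sum_mode passed to [cp_qp()].
#' @return samples x cell-types proportion matrix with attributes `node`
#'   and `n_probes_used` (per-sample count).
#' @export
deconvolve_node <- function(bulk, sub, sum_mode = c("le_one", "eq_one")) {
  sum_mode <- match.arg(sum_mode)
  validate_beta_matrix(bulk)
  stopifnot(inherits(sub, "hibed_sublibrary"))
  n_lib <- length(sub$probe_ids)
  common <- intersect(sub$probe_ids, rownames(bulk))
  cov <- length(common) / n_lib
  if (cov < 0.5) {
    stop(sprintf("insufficient library coverage at node %s: %.0f%% of %d probes",
                 sub$node, 100 * cov, n_lib), call. = FALSE)
  }
  if (cov < 0.8) {
    warning(sprintf("node %s: only %.0f%% of library probes present in bulk",
                    sub$node, 100 * cov))
  }
  samples <- colnames(bulk)
  out <- matrix(NA_real_, length(samples), length(sub$cell_types),
                dimnames = list(samples, sub$cell_types))
  used <- setNames(integer(length(samples)), samples)
  low_cov_samples <- character(0)
  for (s in samples) {
    y <- bulk[common, s]
    ok <- !is.na(y)
    cov_s <- sum(ok) / n_lib
    if (cov_s < 0.5) {
      stop(sprintf("insufficient library coverage at node %s for sample %s",
                   sub$node, s), call. = FALSE)
    }
    if (cov_s < 0.8) low_cov_samples <- c(low_cov_samples, s)
    X <- sub$means[common[ok], , drop = FALSE]
    if (!is.null(sub$context_means)) {
      X <- cbind(X, sub$context_means[common[ok], , drop = FALSE])
    }
    fit <- cp_qp(y[ok], X, sum_mode)
    out[s, ] <- fit[sub$cell_types]
    used[s] <- sum(ok)
  }
  if (length(low_cov_samples) > 0) {
    warning(sprintf("node %s: < 80%% probe coverage for sample(s) %s",
                    sub$node, paste(low_cov_samples, collapse = ", ")))
  }
  structure(out, node = sub$node, n_probes_used = used)
}

#' Hierarchical deconvolution of bulk brain methylation profiles
#'
#' Three-step procedure: (1) the Layer-1 sub-library estimates the
#' neuronal, glial and endothelial/stromal group proportions (with an
#' `unknown` remainder when `sum_mode = "le_one"`); (2) each multi-leaf
#' Layer-2 sub-library estimates proportions among its group's cell types,
#' renormalised to conditional proportions summing to one; (3) leaf
#' proportions are the conditional Layer-2 estimates weighted by the
#' Layer-1 group proportion, so leaves within a group always sum to the
#' group total. Single-leaf groups pass the group proportion through. A
#' degenerate all-zero Layer-2 solution falls back to uniform conditional
#' proportions with a warning.
#'
#' @param bulk probes x samples beta matrix.
#' @param lib a `hibed_library`.
#' @param layer `1` for group proportions, `2` for the seven leaf types.
#' @param sum_mode Layer-1 sum constraint; default `"le_one"` so that mass
#'   not explained by the reference appears as `unknown`.
#' @return samples x cell-types matrix (groups + `unknown` at layer 1;
#'   leaves + `unknown` at layer 2) with attributes `layer` and
#'   `sum_mode`.
#' @export
hibed_deconvolve <- function(bulk, lib, layer = 2,
                             sum_mode = c("le_one", "eq_one")) {
  sum_mode <- match.arg(sum_mode)
  stopifnot(inherits(lib, "hibed_library"))
  if (!layer %in% c(1, 2)) stop("layer must be 1 or 2", call. = FALSE)
  hier <- lib$hierarchy
  l1 <- deconvolve_node(bulk, lib$sub_libraries$Layer1, sum_mode)
  unknown <- pmax(0, 1 - rowSums(l1))
  if (layer == 1) {
    out <- cbind(l1, unknown = unknown)
    return(structure(out, layer = 1L, sum_mode = sum_mode))
  }
  samples <- rownames(l1)
  leaves <- leaf_order(hier)
  out <- matrix(0, length(samples), length(leaves),
                dimnames = list(samples, leaves))
  for (g in names(hier$groups)) {
    g_leaves <- hier$groups[[g]]
    if (length(g_leaves) == 1) {
      out[, g_leaves] <- l1[, g]
      next
    }
    node <- lib$sub_libraries[[hier$layer2_nodes[[g]]]]
    cond <- deconvolve_node(bulk, node, "le_one")
    tot <- rowSums(cond)
    zero <- tot <= 1e-12
    if (any(zero)) {
      warning(sprintf("node %s: all-zero solution for sample(s) %s; using uniform conditional proportions",
                      node$node, paste(samples[zero], collapse = ", ")))
      cond[zero, ] <- 1 / length(g_leaves)
      tot[zero] <- 1
    }
    cond <- cond / tot
    out[, g_leaves] <- cond[, g_leaves, drop = FALSE] * l1[, g]
  }
  out <- cbind(out, unknown = unknown)
  structure(out, layer = 2L, sum_mode = sum_mode, layer1 = l1)
}

#' Write / read a proportions table
#'
#' CSV with samples as rows (first column `sample_id`) and cell types as
#' columns, values in `[0, 1]`.
#'
#' @param props samples x cell-types matrix.
#' @param path file path.
#' @return the path (write) or the proportions matrix (read).
#' @export
write_proportions <- function(props, path) {
  df <- data.frame(sample_id = rownames(props), props, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
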