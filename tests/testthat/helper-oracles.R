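# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the grid search enumerates the constraint set,
# the Pearson/RMSE formulas are written out longhand, and the exact-bulk
# builder works from the library object's raw matrices.

# Brute-force constrained least squares on a proportion grid.
# sum_mode "eq_one" walks the unit simplex; "le_one" the sub-simplex sum<=1.
grid_search_qp <- function(y, X, step, sum_mode = "eq_one") {
  k <- ncol(X)
  levels <- round(1 / step)
  pts <- switch(as.character(k),
    "2" = {
      i <- 0:levels
      if (sum_mode == "eq_one") cbind(i, levels - i)
      else do.call(rbind, lapply(i, function(a) cbind(a, 0:(levels - a))))
    },
    "3" = {
      out <- list()
      for (a in 0:levels) for (b in 0:(levels - a)) {
        out[[length(out) + 1]] <-
          if (sum_mode == "eq_one") c(a, b, levels - a - b) else NULL
      }
      if (sum_mode == "eq_one") do.call(rbind, out)
      else {
        out <- list()
        for (a in 0:levels) for (b in 0:(levels - a)) {
          cc <- 0:(levels - a - b)
          out[[length(out) + 1]] <- cbind(a, b, cc)
        }
        do.call(rbind, out)
      }
    },
    stop("grid oracle supports 2 or 3 cell types"))
  P <- pts * step
  resid <- matrix(y, nrow(X), nrow(P)) - X %*% t(P)
  obj <- colSums(resid^2)
  P[which.min(obj), ]
}

# Pearson r, RMSE, MAE written from the textbook definitions.
pearson_by_formula <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
rmse_by_formula <- function(x, y) sqrt(sum((x - y)^2) / length(x))
mae_by_formula <- function(x, y) sum(abs(x - y)) / length(x)

# Plain (unmoderated) two-sample pooled-variance t statistic per probe.
plain_t <- function(beta, in_group) {
  x1 <- beta[, in_group, drop = FALSE]
  x0 <- beta[, !in_group, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  v <- function(x) apply(x, 1, stats::var)
  s2 <- ((n1 - 1) * v(x1) + (n0 - 1) * v(x0)) / (n1 + n0 - 2)
  (rowMeans(x1) - rowMeans(x0)) / sqrt(s2 * (1 / n1 + 1 / n0))
}

# Bulk profiles that are exact linear combinations of a library's mean
# matrices: Layer-1 probes carry X_L1 %*% (group totals) and each Layer-2
# node's probes carry X_node %*% (absolute leaf proportions). Probes
# appearing in more than one sub-library are dropped so every node sees an
# exactly consistent signal.
exact_block_bulk <- function(lib, leaf_props) {
  hier <- lib$hierarchy
  map <- leaf_to_group(hier)
  group_tot <- vapply(names(hier$groups), function(g) {
    rowSums(leaf_props[, names(map)[map == g], drop = FALSE])
  }, numeric(nrow(leaf_props)))
  all_probes <- unlist(lapply(lib$sub_libraries, `[[`, "probe_ids"))
  dup <- unique(all_probes[duplicated(all_probes)])
  bulk <- matrix(NA_real_, 0, nrow(leaf_props))
  for (s in lib$sub_libraries) {
    keep <- setdiff(s$probe_ids, dup)
    if (s$node == "Layer1") {
      block <- s$means[keep, colnames(group_tot), drop = FALSE] %*% t(group_tot)
    } else {
      block <- s$means[keep, , drop = FALSE] %*%
        t(leaf_props[, s$cell_types, drop = FALSE])
    }
    bulk <- rbind(bulk, block)
  }
  colnames(bulk) <- rownames(leaf_props)
  bulk
}

# Random leaf-proportion rows on the simplex (oracle-side generator).
random_simplex <- function(n, labels, seed) {
  withr::with_seed(seed, {
    u <- matrix(runif(n * length(labels)), n)
    p <- u / rowSums(u)
    dimnames(p) <- list(sprintf("s%03d", seq_len(n)), labels)
    p
  })
}

# Small shared fixtures (built once per test run).
fixture_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_synthetic_reference(synthetic_reference_config(seed = 42))
    }
    cache
  }
})

fixture_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- fixture_reference()
      cache <<- build_hibed_library(ref$betas, ref$annotation)
    }
    cache
  }
})

# At n_per_type = 10 the hybrid selection lands exactly on the planted
# marker blocks, so the four sub-libraries are pairwise disjoint; used for
# the exactness constructions, which need every node's probes uncontested.
fixture_library_sparse <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- fixture_reference()
      cache <<- build_hibed_library(ref$betas, ref$annotation, n_per_type = 10)
    }
    cache
  }
})
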