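#' Build one reference sub-library
#'
#' A sub-library is the reference matrix for one hierarchy node: for each
#' child class, the arithmetic mean beta profile over that class's samples,
#' restricted to the node's marker probes. At the Layer-1 node a "class" is
#' a group and its samples are all samples of its leaf types pooled.
#'
#' @param beta probes x samples matrix.
#' @param ann annotation with `sample_id`, `cell_type` (class labels for
#'   this node).
#' @param classes ordered child classes of the node.
#' @param probes marker probe IDs (must be rows of `beta`).
#' @param node_label label such as `"Layer1"` or `"Layer2B"`.
#' @return list with `node`, `cell_types`, `probe_ids`, `means`
#'   (probes x classes matrix), class `hibed_sublibrary`.
#' @export
build_sub_library <- function(beta, ann, classes, probes, node_label = "node") {
  validate_beta_matrix(beta)
  validate_annotation(ann, beta)
  missing <- setdiff(probes, rownames(beta))
  if (length(missing) > 0) {
    stop("probes absent from beta matrix: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(probes)) stop("duplicate probes in sub-library", call. = FALSE)
  if (length(probes) < length(classes)) {
    stop("need at least as many probes as cell types for identifiability",
         call. = FALSE)
  }
  means <- sapply(classes, function(cl) {
    ids <- ann$sample_id[ann$cell_type == cl]
    if (length(ids) == 0) stop("class with zero samples: ", cl, call. = FALSE)
    rowMeans(beta[probes, ids, drop = FALSE])
  })
  means <- matrix(means, nrow = length(probes),
                  dimnames = list(probes, classes))
  structure(list(node = node_label, cell_types = classes,
                 probe_ids = probes, means = means),
            class = "hibed_sublibrary")
}

#' Build the full hierarchical reference library
#'
#' Runs one-vs-rest moderated selection and mean-profile construction once
#' for the Layer-1 node (classes = groups, over all reference samples) and
#' once per multi-leaf Layer-2 node (classes = that group's leaves, using
#' only that group's samples). Probes with any missing value in the
#' reference cohort are dropped before selection.
#'
#' @param beta purified reference beta matrix (probes x samples).
#' @param ann annotation mapping samples to leaf cell types.
#' @param hierarchy a [cell_hierarchy()]; default [brain_hierarchy()].
#' @param n_per_type marker CpGs per cell type per direction (default 50).
#' @param mode selection direction, default `"hybrid"` (hyper and hypo
#'   markers combined).
#' @return object of class `hibed_library`: list with `format_version`,
#'   `hierarchy`, `sub_libraries` (named by node label) and `provenance`.
#' @export
build_hibed_library <- function(beta, ann, hierarchy = brain_hierarchy(),
                                n_per_type = 50, mode = "hybrid") {
  validate_beta_matrix(beta)
  validate_annotation(ann, beta, labels = hierarchy$leaves)
  counts <- table(factor(ann$cell_type, levels = hierarchy$leaves))
  if (any(counts < 2)) {
    stop("every leaf cell type needs >= 2 reference samples; short: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  ann <- ann[ann$cell_type %in% hierarchy$leaves, , drop = FALSE]
  beta <- beta[, ann$sample_id, drop = FALSE]
  complete <- rowSums(is.na(beta)) == 0
  beta <- beta[complete, , drop = FALSE]
  if (nrow(beta) == 0) stop("no probes without missing values", call. = FALSE)

  run_node <- function(node_beta, node_ann, classes, label) {
    res <- tryCatch({
      m <- moderated_one_vs_rest(node_beta, node_ann, classes)
      sel <- select_top_cpgs(m, n_per_type, mode)
      build_sub_library(node_beta, node_ann, classes, sel$pooled, label)
    }, error = function(e) {
      stop("node ", label, ": ", conditionMessage(e), call. = FALSE)
    })
    res
  }

  map <- leaf_to_group(hierarchy)
  ann_groups <- ann
  ann_groups$cell_type <- unname(map[ann$cell_type])
  subs <- list(Layer1 = run_node(beta, ann_groups, names(hierarchy$groups), "Layer1"))

  for (g in names(hierarchy$layer2_nodes)) {
    label <- hierarchy$layer2_nodes[[g]]
    leaves <- hierarchy$groups[[g]]
    sub_ann <- ann[ann$cell_type %in% leaves, , drop = FALSE]
    sub_beta <- beta[, sub_ann$sample_id, drop = FALSE]
    sub <- run_node(sub_beta, sub_ann, leaves, label)
    # Pooled mean profiles of the remaining groups over this node's probes.
    # These ride along as nuisance columns in the node's projection so that
    # bulk mass from other cell groups is not forced onto this group's
    # cell types (which would bias the conditional proportions).
    others <- setdiff(names(hierarchy$groups), g)
    sub$context_means <- vapply(others, function(h) {
      ids <- ann$sample_id[ann_groups$cell_type == h]
      rowMeans(beta[sub$probe_ids, ids, drop = FALSE])
    }, numeric(length(sub$probe_ids)))
    dimnames(sub$context_means) <- list(sub$probe_ids, others)
    subs[[label]] <- sub
  }

  structure(list(format_version = "1.0", hierarchy = hierarchy,
                 sub_libraries = subs,
                 provenance = list(n_per_type = n_per_type, mode = mode,
                                   n_reference_samples = nrow(ann))),
            class = "hibed_library")
}

#' @export
print.hibed_library <- function(x, ...) {
  cat("hibed reference library (format", x$format_version, ")\n")
  for (s in x$sub_libraries) {
    cat(sprintf("  %-8s %4d probes: %s\n", s$node, length(s$probe_ids),
                paste(s$cell_types, collapse = ", ")))
  }
  invisible(x)
}

#' Dispersion separability criterion (DSC)
#'
#' Ratio of between-class to within-class dispersion over a probe subset:
#' with class centroids \eqn{c_k}, global centroid \eqn{c} and \eqn{N}
#' samples, between = \eqn{\sqrt{(1/N)\sum_k n_k \|c_k - c\|^2}} and
#' within = \eqn{\sqrt{(1/N)\sum_k \sum_{i \in k} \|x_i - c_k\|^2}}.
#' Higher values mean better class separation; used to compare candidate
#' marker libraries.
#'
#' @param beta probes x samples matrix.
#' @param ann annotation with `sample_id`, `cell_type`.
#' @param probes probe subset to score.
#' @return list with `value`, `between_dispersion`, `within_dispersion`;
#'   `value = Inf` when classes are internally identical but separated.
#' @export
compute_dsc <- function(beta, ann, probes) {
  validate_beta_matrix(beta)
  validate_annotation(ann, beta)
  missing <- setdiff(probes, rownames(beta))
  if (length(missing) > 0) stop("probes absent from beta matrix", call. = FALSE)
  x <- beta[probes, ann$sample_id, drop = FALSE]
  if (anyNA(x)) stop("missing values in scored probes", call. = FALSE)
  classes <- unique(ann$cell_type)
  if (length(classes) < 2) stop("DSC needs >= 2 classes", call. = FALSE)
  n_total <- ncol(x)
  global <- rowMeans(x)
  between_ss <- 0
  within_ss <- 0
  for (cl in classes) {
    xc <- x[, ann$sample_id[ann$cell_type == cl], drop = FALSE]
    centroid <- rowMeans(xc)
    between_ss <- between_ss + ncol(xc) * sum((centroid - global)^2)
    within_ss <- within_ss + sum((xc - centroid)^2)
  }
  between <- sqrt(between_ss / n_total)
  within <- sqrt(within_ss / n_total)
  if (between == 0 && within == 0) {
    stop("degenerate: all samples identical over the probe set", call. = FALSE)
  }
  value <- if (within == 0) Inf else between / within
  list(value = value, between_dispersion = between, within_dispersion = within)
}
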