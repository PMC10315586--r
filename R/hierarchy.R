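#' Construct a two-layer cell hierarchy
#'
#' A hierarchy maps group labels (Layer 1) to ordered leaf cell types
#' (Layer 2). Leaves must partition across groups. Each group with at least
#' two leaves gets its own Layer-2 reference node, labelled `Layer2A`,
#' `Layer2B`, ... in group order; the group level itself is the single
#' `Layer1` node.
#'
#' @param groups named list, group label -> character vector of leaf types.
#' @return object of class `cell_hierarchy` with elements `groups`,
#'   `leaves`, and `layer2_nodes` (named map group -> node label for groups
#'   with >= 2 leaves).
#' @examples
#' brain_hierarchy()
#' @export
cell_hierarchy <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list", call. = FALSE)
  }
  if (length(groups) < 2) stop("hierarchy needs at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("every group must be nonempty", call. = FALSE)
  leaves <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(leaves)) {
    stop("each leaf cell type must belong to exactly one group", call. = FALSE)
  }
  multi <- names(groups)[lengths(groups) >= 2]
  layer2 <- setNames(paste0("Layer2", LETTERS[seq_along(multi)]), multi)
  structure(list(groups = groups, leaves = leaves, layer2_nodes = layer2),
            class = "cell_hierarchy")
}

#' Default brain cell hierarchy
#'
#' Seven brain cell types in three Layer-1 groups: endothelial and stromal
#' cells (`Layer2A`), the glial types astrocyte, microglia and
#' oligodendrocyte (`Layer2B`), and the GABAergic/glutamatergic neuronal
#' types (`Layer2C`).
#'
#' @return a `cell_hierarchy`.
#' @export
brain_hierarchy <- function() {
  cell_hierarchy(list(
    EndoStromal = c("Endothelial", "Stromal"),
    Glial       = c("Astrocyte", "Microglia", "Oligodendrocyte"),
    Neuronal    = c("GABA", "GLU")
  ))
}

#' Map leaf cell types to their Layer-1 group
#'
#' @param hierarchy a `cell_hierarchy`.
#' @return named character vector, leaf -> group label.
#' @export
leaf_to_group <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "cell_hierarchy"))
  unlist(lapply(names(hierarchy$groups), function(g) {
    setNames(rep(g, length(hierarchy$groups[[g]])), hierarchy$groups[[g]])
  }))
}

#' Canonical reporting order for leaf cell types
#'
#' Neuronal types first (GABA, GLU), then glial, then endothelial/stromal,
#' matching the conventional column order of proportion outputs. Leaves not
#' in the conventional set keep hierarchy order after the known ones.
#'
#' @param hierarchy a `cell_hierarchy`.
#' @return character vector of leaf labels.
#' @export
leaf_order <- function(hierarchy) {
  canonical <- c("GABA", "GLU", "Astrocyte", "Microglia", "Oligodendrocyte",
                 "Endothelial", "Stromal")
  known <- canonical[canonical %in% hierarchy$leaves]
  c(known, setdiff(hierarchy$leaves, known))
}

#' @export
print.cell_hierarchy <- function(x, ...) {
  cat("cell hierarchy:", length(x$groups), "groups,", length(x$leaves), "leaves\n")
  for (g in names(x$groups)) {
    node <- if (g %in% names(x$layer2_nodes)) paste0(" [", x$layer2_nodes[[g]], "]") else ""
    cat("  ", g, node, ": ", paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
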