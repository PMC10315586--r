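LIBRARY_FORMAT_VERSION <- "1.0"

#' Save a reference library to a versioned JSON file
#'
#' The on-disk format is plain JSON with fields `format_version`,
#' `hierarchy` (`groups`, `layer2_nodes`), `provenance`, and
#' `sub_libraries` as a list of `{node, cell_types, probe_ids, means}`
#' blocks, `means` stored row-per-probe at full double precision.
#'
#' @param lib a `hibed_library`.
#' @param path output path.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "hibed_library"))
  payload <- list(
    format_version = lib$format_version,
    hierarchy = list(groups = lib$hierarchy$groups,
                     layer2_nodes = as.list(lib$hierarchy$layer2_nodes)),
    provenance = lib$provenance,
    sub_libraries = lapply(unname(lib$sub_libraries), function(s) {
      block <- list(node = s$node, cell_types = s$cell_types,
                    probe_ids = s$probe_ids,
                    means = apply(s$means, 1, function(r) unname(r), simplify = FALSE))
      if (!is.null(s$context_means)) {
        block$context_types <- colnames(s$context_means)
        block$context_means <- apply(s$context_means, 1, function(r) unname(r),
                                     simplify = FALSE)
      }
      block
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a reference library from JSON
#'
#' Validates the format version and that the Layer-1 node and every
#' Layer-2 node declared by the hierarchy are present.
#'
#' @param path path written by [save_library()].
#' @return a `hibed_library`.
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$format_version) ||
      !identical(as.character(payload$format_version), LIBRARY_FORMAT_VERSION)) {
    stop("unsupported library format version: ",
         payload$format_version %||% "<missing>",
         " (expected ", LIBRARY_FORMAT_VERSION, ")", call. = FALSE)
  }
  groups <- lapply(payload$hierarchy$groups, function(g) unlist(g, use.names = FALSE))
  hierarchy <- cell_hierarchy(groups)
  subs <- list()
  for (s in payload$sub_libraries) {
    probes <- unlist(s$probe_ids, use.names = FALSE)
    types <- unlist(s$cell_types, use.names = FALSE)
    means <- do.call(rbind, lapply(s$means, function(r) unlist(r, use.names = FALSE)))
    if (is.null(means) || nrow(means) != length(probes) || ncol(means) != length(types)) {
      stop("sub-library '", s$node, "': means shape does not match probes x cell types",
           call. = FALSE)
    }
    dimnames(means) <- list(probes, types)
    sub <- list(node = s$node, cell_types = types, probe_ids = probes,
                means = means)
    if (!is.null(s$context_means)) {
      ctypes <- unlist(s$context_types, use.names = FALSE)
      cm <- do.call(rbind, lapply(s$context_means,
                                  function(r) unlist(r, use.names = FALSE)))
      if (nrow(cm) != length(probes) || ncol(cm) != length(ctypes)) {
        stop("sub-library '", s$node, "': context means shape mismatch",
             call. = FALSE)
      }
      dimnames(cm) <- list(probes, ctypes)
      sub$context_means <- cm
    }
    subs[[s$node]] <- structure(sub, class = "hibed_sublibrary")
  }
  needed <- c("Layer1", unname(hierarchy$layer2_nodes))
  absent <- setdiff(needed, names(subs))
  if (length(absent) > 0) {
    stop("library file is missing sub-libraries: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  structure(list(format_version = LIBRARY_FORMAT_VERSION, hierarchy = hierarchy,
                 sub_libraries = subs,
                 provenance = lapply(payload$provenance, function(x) x)),
            class = "hibed_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
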