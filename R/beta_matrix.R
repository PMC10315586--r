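#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with CpG probes as rows (unique
#' rownames, Illumina-style `cg...` IDs) and samples as columns (unique
#' colnames). All non-missing values must lie in `[0, 1]`; `NA`s are
#' permitted and flag missing measurements.
#'
#' @param beta numeric matrix, probes x samples.
#' @return `beta`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix must have probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(beta))) {
    stop("duplicate probe IDs: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(beta))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  invisible(beta)
}

#' Read a beta-value matrix from CSV/TSV
#'
#' Expects column 1 = probe IDs and a header row of sample IDs. Empty cells
#' and `NA` become missing values. Values are validated to `[0, 1]`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`; default guessed from the extension.
#' @param transpose set when the file stores samples as rows.
#' @return probes x samples numeric matrix.
#' @export
read_beta_matrix <- function(path, dialect = c("auto", "csv", "tsv"),
                             transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header: expected probe ID column plus samples",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    nonnum <- is.na(m) & !is.na(as.matrix(df[, -1, drop = FALSE])) &
      trimws(as.matrix(df[, -1, drop = FALSE])) != ""
    if (any(nonnum)) {
      w <- which(nonnum, arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                   ids[w[1]], colnames(m)[w[2]]), call. = FALSE)
    }
  }
  rownames(m) <- ids
  if (transpose) m <- t(m)
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix to CSV/TSV
#'
#' @param beta probes x samples matrix.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_beta_matrix <- function(beta, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_beta_matrix(beta)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
              row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a probe exclusion list
#'
#' Plain text, one probe ID per line; `#` starts a comment; blank lines
#' ignored. Typical lists: cross-reactive probes, SNP-related probes,
#' sex-chromosome probes.
#'
#' @param path file path.
#' @return character vector of probe IDs.
#' @export
read_probe_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Remove excluded and non-CpG probes from a beta matrix
#'
#' Drops the union of the supplied exclusion lists and, when
#' `drop_non_cpg_prefixes` is set, probes whose IDs mark non-CpG (`ch.`) or
#' SNP (`rs`) assays by the Illumina manifest naming convention.
#' Sex-chromosome and cross-reactive membership must come from
#' user-supplied lists. Values and samples are untouched; the operation is
#' idempotent.
#'
#' @param beta probes x samples matrix.
#' @param exclusions character vector, or list of character vectors, of
#'   probe IDs to remove (union is removed).
#' @param drop_non_cpg_prefixes drop `ch.`/`rs`-prefixed probes.
#' @return the filtered beta matrix.
#' @export
filter_probes <- function(beta, exclusions = list(),
                          drop_non_cpg_prefixes = TRUE) {
  validate_beta_matrix(beta)
  drop <- unique(unlist(exclusions, use.names = FALSE))
  keep <- !(rownames(beta) %in% drop)
  if (drop_non_cpg_prefixes) {
    keep <- keep & !grepl("^(ch\\.|rs)", rownames(beta))
  }
  if (!any(keep)) stop("empty matrix after filtering", call. = FALSE)
  beta[keep, , drop = FALSE]
}

#' Validate a sample annotation table
#'
#' @param ann data frame with columns `sample_id` and `cell_type` (optional
#'   covariates such as `age`, `sex` are carried along).
#' @param beta companion beta matrix; every `sample_id` must be a column.
#' @param labels optional allowed set of cell-type labels.
#' @return `ann`, invisibly.
#' @export
validate_annotation <- function(ann, beta = NULL, labels = NULL) {
  if (!is.data.frame(ann) || !all(c("sample_id", "cell_type") %in% names(ann))) {
    stop("annotation must be a data.frame with sample_id and cell_type columns",
         call. = FALSE)
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample_id in annotation", call. = FALSE)
  }
  if (!is.null(beta)) {
    missing <- setdiff(ann$sample_id, colnames(beta))
    if (length(missing) > 0) {
      stop("annotation samples absent from beta matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(labels)) {
    bad <- setdiff(unique(ann$cell_type), labels)
    if (length(bad) > 0) {
      stop("unknown cell-type labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(ann)
}
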