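#' Configuration for the synthetic purified reference generator
#'
#' The generator emulates a purified-cell discovery panel: every probe gets
#' a baseline beta drawn uniformly from `baseline_beta_range`; disjoint
#' probe blocks are reserved per hierarchy group and per leaf cell type,
#' and within each block half the probes are shifted up and half down by
#' the group- or leaf-level signal for that class's samples
#' (hypermethylated and hypomethylated markers); i.i.d. Gaussian noise of
#' sd `noise_sd` is added and values are clipped to `[0, 1]`.
#'
#' @param n_probes total probes (default 2000).
#' @param n_samples_per_type purified samples per leaf type (default 5).
#' @param delta_beta_group group-level methylation difference (default 0.5).
#' @param delta_beta_leaf leaf-level methylation difference (default 0.4).
#' @param n_signal_probes_per_class planted marker probes per class
#'   (default 20, half per direction).
#' @param noise_sd within-cell-type beta noise sd (default 0.02).
#' @param baseline_beta_range baseline beta range (default `c(0.15, 0.85)`).
#' @param seed RNG seed.
#' @return a `synthetic_reference_config` list.
#' @export
synthetic_reference_config <- function(n_probes = 2000, n_samples_per_type = 5,
                                       delta_beta_group = 0.5,
                                       delta_beta_leaf = 0.4,
                                       n_signal_probes_per_class = 20,
                                       noise_sd = 0.02,
                                       baseline_beta_range = c(0.15, 0.85),
                                       seed = 1) {
  fracs <- c(delta_beta_group, delta_beta_leaf, noise_sd, baseline_beta_range)
  if (any(fracs < 0) || any(c(delta_beta_group, delta_beta_leaf,
                              baseline_beta_range) > 1)) {
    stop("signal sizes and baseline range must lie in [0, 1]", call. = FALSE)
  }
  if (baseline_beta_range[1] > baseline_beta_range[2]) {
    stop("baseline_beta_range must be increasing", call. = FALSE)
  }
  structure(list(n_probes = n_probes, n_samples_per_type = n_samples_per_type,
                 delta_beta_group = delta_beta_group,
                 delta_beta_leaf = delta_beta_leaf,
                 n_signal_probes_per_class = n_signal_probes_per_class,
                 noise_sd = noise_sd,
                 baseline_beta_range = baseline_beta_range, seed = seed),
            class = "synthetic_reference_config")
}

#' Generate a synthetic purified-cell reference panel
#'
#' Produces a beta matrix of purified profiles for the seven brain cell
#' types (or any hierarchy's leaves) with planted hierarchical structure:
#' group-level differentially methylated probes separate the Layer-1
#' groups and leaf-level probes separate cell types within a group. Signal
#' blocks for distinct classes are disjoint, so the probes a selection
#' procedure should recover are known exactly.
#'
#' @param cfg a [synthetic_reference_config()].
#' @param hierarchy a [cell_hierarchy()]; default [brain_hierarchy()].
#' @return list with `betas` (probes x samples), `annotation`
#'   (`sample_id`, `cell_type`), `signal_probes` (named list: per class, a
#'   data.frame of `probe_id` and `direction`), and `config`.
#' @export
make_synthetic_reference <- function(cfg = synthetic_reference_config(),
                                     hierarchy = brain_hierarchy()) {
  stopifnot(inherits(cfg, "synthetic_reference_config"))
  groups <- names(hierarchy$groups)
  leaves <- hierarchy$leaves
  classes <- c(groups, leaves)
  n_sig <- cfg$n_signal_probes_per_class
  if (length(classes) * n_sig > cfg$n_probes) {
    stop("signal probes exceed n_probes", call. = FALSE)
  }
  probes <- sprintf("cg%08d", seq_len(cfg$n_probes))
  samples <- unlist(lapply(leaves, function(l) {
    paste(l, seq_len(cfg$n_samples_per_type), sep = "_")
  }))
  sample_type <- rep(leaves, each = cfg$n_samples_per_type)
  map <- leaf_to_group(hierarchy)

  withr::with_seed(cfg$seed, {
    baseline <- runif(cfg$n_probes, cfg$baseline_beta_range[1],
                      cfg$baseline_beta_range[2])
    betas <- matrix(baseline, cfg$n_probes, length(samples),
                    dimnames = list(probes, samples))
    signal_probes <- list()
    lo <- cfg$baseline_beta_range[1]; hi <- cfg$baseline_beta_range[2]
    for (i in seq_along(classes)) {
      cl <- classes[i]
      block <- ((i - 1) * n_sig + 1):(i * n_sig)
      dir <- rep_len(c(1, -1), n_sig)
      delta <- if (cl %in% groups) cfg$delta_beta_group else cfg$delta_beta_leaf
      # marker probes get baselines rescaled into the sub-range where the
      # planted shift cannot saturate at 0 or 1 (hypermethylating markers
      # start low, hypomethylating markers start high) so the designed
      # delta-beta is realised undistorted
      up <- dir > 0
      new_hi <- min(hi, 1 - delta); new_lo <- max(lo, delta)
      frac <- (betas[block, 1] - lo) / (hi - lo)
      shifted_base <- ifelse(up, lo + frac * (new_hi - lo),
                             new_lo + frac * (hi - new_lo))
      betas[block, ] <- matrix(shifted_base, n_sig, ncol(betas))
      in_class <- if (cl %in% groups) map[sample_type] == cl else sample_type == cl
      betas[block, in_class] <- betas[block, in_class] + dir * delta
      signal_probes[[cl]] <- data.frame(
        probe_id = probes[block],
        direction = ifelse(dir > 0, "hyper", "hypo"),
        stringsAsFactors = FALSE)
    }
    if (cfg$noise_sd > 0) {
      betas <- betas + matrix(rnorm(length(betas), sd = cfg$noise_sd),
                              nrow(betas), ncol(betas))
    }
    betas <- pmin(pmax(betas, 0), 1)
  })

  list(betas = betas,
       annotation = data.frame(sample_id = samples, cell_type = sample_type,
                               stringsAsFactors = FALSE),
       signal_probes = signal_probes,
       config = cfg)
}

#' Draw designed mixture proportions on the unit simplex
#'
#' For each mixture, `length(cell_types)` i.i.d. Uniform(0,1) numbers are
#' drawn and normalised by their sum, yielding a proportion vector on the
#' simplex with a gradient of proportions per cell type across mixtures.
#'
#' @param n_mixtures number of in-silico bulk samples.
#' @param cell_types character vector of cell-type labels.
#' @param seed RNG seed.
#' @return object of class `hibed_mixture_truth`: list with `sample_ids`,
#'   `cell_types`, `proportions` (mixtures x cell types, rows sum to 1) and
#'   `seed`.
#' @export
sample_mixture_proportions <- function(n_mixtures, cell_types, seed = 1) {
  if (n_mixtures < 1) stop("n_mixtures must be >= 1", call. = FALSE)
  if (length(cell_types) == 0) stop("cell_types must be nonempty", call. = FALSE)
  ids <- sprintf("mix_%03d", seq_len(n_mixtures))
  props <- withr::with_seed(seed, {
    u <- matrix(runif(n_mixtures * length(cell_types)), n_mixtures)
    u / rowSums(u)
  })
  dimnames(props) <- list(ids, cell_types)
  structure(list(sample_ids = ids, cell_types = cell_types,
                 proportions = props, seed = seed),
            class = "hibed_mixture_truth")
}

#' Build in-silico bulk mixtures from purified profiles
#'
#' For each mixture, `samples_per_type_draw` purified samples are drawn
#' without replacement per cell type and averaged per probe into a
#' mean-profile matrix M; the mixture's bulk profile is the matrix product
#' M times the designed proportion vector. Per-type, per-probe standard
#' deviations across the drawn samples are returned as metadata. Optional
#' i.i.d. Gaussian noise of sd `noise_sd` is added and values clipped to
#' `[0, 1]`.
#'
#' @param purified probes x samples purified beta matrix.
#' @param ann annotation mapping purified samples to cell types.
#' @param truth a [sample_mixture_proportions()] result.
#' @param samples_per_type_draw purified samples drawn per type per
#'   mixture.
#' @param noise_sd added beta noise sd (default 0: noiseless mixtures).
#' @param seed RNG seed for draws and noise.
#' @return list with `betas` (probes x mixtures), `truth`, `drawn_samples`
#'   (per mixture: named list of drawn sample IDs per type) and `type_sds`
#'   (per mixture: probes x types sd matrix).
#' @export
build_mixture_matrix <- function(purified, ann, truth, samples_per_type_draw,
                                 noise_sd = 0, seed = 1) {
  validate_beta_matrix(purified)
  validate_annotation(ann, purified)
  stopifnot(inherits(truth, "hibed_mixture_truth"))
  types <- truth$cell_types
  avail <- split(ann$sample_id, ann$cell_type)
  absent <- setdiff(types, names(avail))
  if (length(absent) > 0) {
    stop("cell types absent from purified panel: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  short <- types[vapply(avail[types], length, 1L) < samples_per_type_draw]
  if (length(short) > 0) {
    stop("insufficient purified samples for: ", paste(short, collapse = ", "),
         call. = FALSE)
  }
  n_mix <- length(truth$sample_ids)
  betas <- matrix(NA_real_, nrow(purified), n_mix,
                  dimnames = list(rownames(purified), truth$sample_ids))
  drawn <- vector("list", n_mix)
  sds <- vector("list", n_mix)
  names(drawn) <- names(sds) <- truth$sample_ids
  withr::with_seed(seed, {
    for (i in seq_len(n_mix)) {
      picks <- lapply(avail[types], function(ids) {
        ids[sample.int(length(ids), samples_per_type_draw)]
      })
      M <- vapply(picks, function(ids) {
        rowMeans(purified[, ids, drop = FALSE])
      }, numeric(nrow(purified)))
      sds[[i]] <- vapply(picks, function(ids) {
        apply(purified[, ids, drop = FALSE], 1, sd)
      }, numeric(nrow(purified)))
      drawn[[i]] <- picks
      betas[, i] <- M %*% truth$proportions[i, types]
    }
    if (noise_sd > 0) {
      betas <- betas + matrix(rnorm(length(betas), sd = noise_sd),
                              nrow(betas), ncol(betas))
    }
    betas <- pmin(pmax(betas, 0), 1)
  })
  list(betas = betas, truth = truth, drawn_samples = drawn, type_sds = sds)
}
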