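make_two_class <- function(values, n_per_class = 2) {
  # one probe per row of `values`: list(class1 = ..., class2 = ...)
  beta <- do.call(rbind, lapply(values, function(v) rep(v, each = n_per_class)))
  rownames(beta) <- sprintf("cg%03d", seq_along(values))
  colnames(beta) <- paste0("s", seq_len(ncol(beta)))
  ann <- data.frame(sample_id = colnames(beta),
                    cell_type = rep(c("A", "B"), each = n_per_class))
  list(beta = beta, ann = ann)
}

test_that("one-vs-rest effects are antisymmetric and null for flat probes", {
  d <- make_two_class(list(c(0.9, 0.1), c(0.5, 0.5)))
  res <- moderated_one_vs_rest(d$beta, d$ann, c("A", "B"))
  expect_equal(unname(res$effect["cg001", ]), c(0.8, -0.8), tolerance = 1e-12)
  expect_equal(unname(res$effect["cg002", ]), c(0, 0))
  expect_equal(unname(res$t["cg002", ]), c(0, 0))
  expect_equal(res$effect[, "A"], -res$effect[, "B"], tolerance = 1e-12)
  expect_error(moderated_one_vs_rest(d$beta, d$ann[-1, ], c("A", "B")), ">= 2 samples")
})

test_that("moderated ranking recovers planted signals like a plain t oracle", {
  classes <- c("C1", "C2", "C3")
  withr::with_seed(7, {
    beta <- matrix(runif(200, 0.2, 0.4), 200, 15,
                   dimnames = list(sprintf("cg%04d", 1:200),
                                   sprintf("s%02d", 1:15)))
    ann <- data.frame(sample_id = colnames(beta),
                      cell_type = rep(classes, each = 5))
    planted <- split(sprintf("cg%04d", 1:30), rep(classes, each = 10))
    for (cl in classes) {
      idx <- ann$cell_type == cl
      beta[planted[[cl]], idx] <- beta[planted[[cl]], idx] + 0.6
    }
    beta <- pmin(pmax(beta + rnorm(length(beta), sd = 0.02), 0), 1)
  })
  res <- moderated_one_vs_rest(beta, ann, classes)
  hits <- 0
  for (cl in classes) {
    top10 <- rownames(beta)[order(-abs(res$t[, cl]))][1:10]
    hits <- hits + sum(top10 %in% planted[[cl]])
    # independent oracle: plain two-sample t ranks the same planted probes
    pt <- plain_t(beta, ann$cell_type == cl)
    expect_gte(sum(rownames(beta)[order(-abs(pt))][1:10] %in% planted[[cl]]), 9)
  }
  expect_gte(hits, 28)
})

test_that("top-CpG selection is exact, symmetric and composable", {
  d <- make_two_class(list(c(0.9, 0.1), c(0.2, 0.8), c(0.55, 0.45),
                           c(0.4, 0.6), c(0.5, 0.5)))
  res <- moderated_one_vs_rest(d$beta, d$ann, c("A", "B"))
  # two-class mirror: A's hyper picks equal B's hypo picks
  selA <- select_top_cpgs(res, 2, "hyper")
  selB <- select_top_cpgs(res, 2, "hypo")
  expect_identical(selA$per_class$A, selB$per_class$B)
  # hyper n=3 takes exactly the 3 largest t for the class
  sel3 <- select_top_cpgs(res, 3, "hyper")
  expect_identical(sel3$per_class$A,
                   rownames(d$beta)[order(-res$t[, "A"])][1:3])
  # hybrid pooled set contains both direction-specific top sets
  hyb <- select_top_cpgs(res, 2, "hybrid")
  expect_true(all(selA$per_class$A %in% hyb$pooled))
  expect_true(all(select_top_cpgs(res, 2, "hypo")$per_class$A %in% hyb$pooled))
  expect_lte(length(hyb$pooled), 2 * 2 * 2)
  expect_error(select_top_cpgs(res, 99, "hyper"), "n_per_type")
})

test_that("hybrid selection recovers planted markers per hierarchy node", {
  ref <- fixture_reference()
  hier <- brain_hierarchy()
  map <- leaf_to_group(hier)
  ann_groups <- transform(ref$annotation, cell_type = unname(map[cell_type]))
  select_node <- function(beta, ann, classes) {
    res <- moderated_one_vs_rest(beta, ann, classes)
    select_top_cpgs(res, 10, "hybrid")
  }
  check <- function(beta, ann, classes) {
    sel <- select_node(beta, ann, classes)
    planted <- unlist(lapply(ref$signal_probes[classes], `[[`, "probe_id"))
    if (length(classes) >= 3) {
      # enough independent contrasts to rank every planted block on top
      expect_gte(mean(planted %in% sel$pooled), 0.9)
    } else {
      # two-class nodes: the one-vs-rest contrast is antisymmetric, so the
      # four top-10 lists collapse to at most 20 distinct probes; all of
      # them must be planted markers, at that structural cap
      expect_true(all(sel$pooled %in% planted))
      expect_equal(length(sel$pooled), 20)
      expect_setequal(sel$per_class[[1]], sel$per_class[[2]])
    }
  }
  check(ref$betas, ann_groups, names(hier$groups))
  for (g in names(hier$layer2_nodes)) {
    ann_g <- ref$annotation[ref$annotation$cell_type %in% hier$groups[[g]], ]
    check(ref$betas[, ann_g$sample_id], ann_g, hier$groups[[g]])
  }
})

test_that("sub-library means are pooled arithmetic means", {
  beta <- matrix(c(0.2, 0.1, 0.4, 0.3, 0.6, 0.8), 2, 3,
                 dimnames = list(c("cg1", "cg2"), c("a", "b", "c")))
  ann <- data.frame(sample_id = c("a", "b", "c"),
                    cell_type = c("X", "X", "Y"))
  sub <- build_sub_library(beta, ann, c("X", "Y"), c("cg1", "cg2"), "toy")
  expect_equal(unname(sub$means["cg1", ]), c(0.3, 0.6))
  expect_equal(unname(sub$means["cg2", ]), c(0.2, 0.8))
  # pooled group mean over unequal leaf sizes differs from mean of leaf means
  beta2 <- matrix(rep(c(0.1, 0.2, 0.3, 0.9), each = 2), 2, 4,
                  dimnames = list(c("cg1", "cg2"), paste0("s", 1:4)))
  ann_leaf <- data.frame(sample_id = paste0("s", 1:4),
                         cell_type = c("L1", "L1", "L1", "L2"))
  ann_grp <- transform(ann_leaf, cell_type = "G")
  pooled <- build_sub_library(beta2, ann_grp, "G", c("cg1", "cg2"), "l1")$means["cg1", "G"]
  expect_equal(unname(pooled), mean(c(0.1, 0.2, 0.3, 0.9)))
  leaf_means <- build_sub_library(beta2, ann_leaf, c("L1", "L2"),
                                  c("cg1", "cg2"), "l2")$means["cg1", ]
  expect_false(isTRUE(all.equal(unname(pooled), mean(leaf_means))))
  # constant input gives that constant for every class
  const <- matrix(0.42, 2, 4, dimnames = list(c("cg1", "cg2"), paste0("s", 1:4)))
  expect_true(all(build_sub_library(const, ann_leaf, c("L1", "L2"),
                                    c("cg1", "cg2"), "c")$means == 0.42))
  expect_error(build_sub_library(beta, ann, c("X", "Z"), c("cg1", "cg2"), "t"),
               "zero samples")
})

test_that("the full library has four nodes with identifiable, distinct probes", {
  lib <- fixture_library()
  expect_named(lib$sub_libraries, c("Layer1", "Layer2A", "Layer2B", "Layer2C"))
  for (s in lib$sub_libraries) {
    expect_gte(length(s$probe_ids), length(s$cell_types))
    expect_true(all(s$means >= 0 & s$means <= 1))
    expect_false(anyDuplicated(s$probe_ids) > 0)
  }
  expect_identical(lib$sub_libraries$Layer1$cell_types,
                   names(lib$hierarchy$groups))
  # group-level and leaf-level signals live on distinct probe blocks; when
  # selection depth matches the planted design, Layer-1 probes avoid the
  # Layer-2 selections outright
  sparse <- fixture_library_sparse()
  l1 <- sparse$sub_libraries$Layer1$probe_ids
  l2 <- unique(unlist(lapply(sparse$sub_libraries[-1], `[[`, "probe_ids")))
  expect_lt(mean(l1 %in% l2), 0.5)
})

test_that("DSC matches its defining formula and degenerates correctly", {
  beta <- matrix(c(0.1, 0.3, 0.7, 0.9), 1, 4,
                 dimnames = list("cg1", paste0("s", 1:4)))
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    cell_type = c("A", "A", "B", "B"))
  d <- compute_dsc(beta, ann, "cg1")
  expect_equal(d$between_dispersion, 0.3)
  expect_equal(d$within_dispersion, 0.1)
  expect_equal(d$value, 3.0)
  # permuting samples leaves the value unchanged
  perm <- c(3, 1, 4, 2)
  d2 <- compute_dsc(beta[, perm, drop = FALSE], ann[perm, ], "cg1")
  expect_equal(d2$value, d$value)
  # within-class duplicates with distinct centroids hit the +Inf sentinel
  beta_dup <- matrix(c(0.2, 0.2, 0.8, 0.8), 1, 4,
                     dimnames = list("cg1", paste0("s", 1:4)))
  expect_equal(compute_dsc(beta_dup, ann, "cg1")$value, Inf)
  expect_error(compute_dsc(matrix(0.5, 1, 4,
    dimnames = list("cg1", paste0("s", 1:4))), ann, "cg1"), "degenerate")
  expect_error(compute_dsc(beta, transform(ann, cell_type = "A"), "cg1"),
               ">= 2 classes")
})
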