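test_that("profile matches an independent brute-force oracle", {
  catal <- generate_gene_catalog(2, 30, seed = 4)
  counts <- random_counts(60, 20, seed = 5, lambda = 3)
  rownames(counts) <- catal$gene_id
  cells <- make_cells(counts)
  ref <- colnames(counts)[1:8]
  for (w in c(1, 7, 10)) {
    got <- compute_cnv_profile(cells, catal, ref, window_size = w)
    want <- oracle_cnv_profile(counts, catal, ref, w)
    expect_lt(max(abs(got$matrix - want)), 1e-10)
  }
})

test_that("window_size one gives centered expression with no smoothing", {
  catal <- generate_gene_catalog(1, 25, seed = 2)
  counts <- random_counts(25, 12, seed = 3, lambda = 4)
  rownames(counts) <- catal$gene_id
  prof <- compute_cnv_profile(make_cells(counts), catal,
                              colnames(counts)[1:5], window_size = 1)
  nz <- rownames(counts)[rowSums(counts) > 0]
  expect_equal(ncol(prof$matrix), length(nz))
  expect_true(all(prof$windows$n_genes == 1))
  # columns are the (centered, unsmoothed) per-gene values
  want <- oracle_cnv_profile(counts, catal, colnames(counts)[1:5], 1)
  expect_lt(max(abs(prof$matrix - want)), 1e-12)
})

test_that("a constant expression matrix yields an all-zero profile", {
  catal <- generate_gene_catalog(1, 20, seed = 1)
  counts <- matrix(5, nrow = 20, ncol = 10,
                   dimnames = list(catal$gene_id, sprintf("c%02d", 1:10)))
  prof <- compute_cnv_profile(make_cells(counts), catal,
                              colnames(counts)[1:4], window_size = 5)
  expect_lt(max(abs(prof$matrix)), 1e-12)
})

test_that("profiles are invariant to per-cell library scaling", {
  catal <- generate_gene_catalog(2, 20, seed = 6)
  counts <- random_counts(40, 15, seed = 7, lambda = 3)
  rownames(counts) <- catal$gene_id
  ref <- colnames(counts)[1:6]
  p1 <- compute_cnv_profile(make_cells(counts), catal, ref, window_size = 8)
  scaled <- sweep(counts, 2, seq(1, 4, length.out = 15), "*")
  p2 <- compute_cnv_profile(make_cells(scaled), catal, ref, window_size = 8)
  expect_lt(max(abs(p1$matrix - p2$matrix)), 1e-10)
})

test_that("windows respect chromosome locality", {
  catal <- generate_gene_catalog(2, 12, seed = 8)
  counts <- random_counts(24, 10, seed = 9, lambda = 3)
  rownames(counts) <- catal$gene_id
  ref <- colnames(counts)[1:4]
  # window wider than a chromosome: one whole-chromosome window each
  prof <- compute_cnv_profile(make_cells(counts), catal, ref, window_size = 30)
  expect_equal(nrow(prof$windows), 2)
  expect_false(any(table(prof$windows$chromosome) > 1))
  # permuting gene order inside one chromosome leaves whole-chrom windows alone
  cat_perm <- catal
  chr1 <- which(catal$chromosome == "chr1")
  set.seed(1)
  cat_perm$gene_id[chr1] <- sample(catal$gene_id[chr1])
  prof_perm <- compute_cnv_profile(make_cells(counts), cat_perm, ref,
                                   window_size = 30)
  expect_lt(max(abs(prof$matrix - prof_perm$matrix)), 1e-12)
  # moving a high-expression gene across chromosomes changes the profile
  cat_swap <- catal
  cat_swap$gene_id[c(1, 13)] <- cat_swap$gene_id[c(13, 1)]
  prof_swap <- compute_cnv_profile(make_cells(counts), cat_swap, ref,
                                   window_size = 30)
  expect_gt(max(abs(prof$matrix - prof_swap$matrix)), 1e-6)
})

test_that("a 2x dosage block produces a log2-unit plateau with linear ramps", {
  catal <- generate_gene_catalog(2, 400, seed = 1)
  n_ref <- 30
  counts <- matrix(100, nrow = 800, ncol = n_ref + 1)
  block <- 101:250  # 150 genes on chr1
  counts[block, n_ref + 1] <- counts[block, n_ref + 1] * 2
  dimnames(counts) <- list(catal$gene_id, sprintf("c%02d", 1:(n_ref + 1)))
  prof <- compute_cnv_profile(make_cells(counts), catal,
                              colnames(counts)[1:n_ref], window_size = 100)
  v <- prof$matrix[n_ref + 1, ]
  wm <- prof$windows
  interior <- which(wm$chromosome == "chr1" &
                      wm$first_index >= 100 & wm$last_index <= 249)
  expect_gt(length(interior), 10)
  # library renormalization shifts the plateau slightly below log2(2)
  plateau <- mean(v[interior])
  expect_lt(abs(plateau - log2(2)), 0.15)
  expect_lt(diff(range(v[interior])), 0.02)
  # ramp across the 99-gene overlap at the block edge is linear in coverage
  ramp <- which(wm$chromosome == "chr1" &
                  wm$first_index < 100 & wm$last_index >= 100)
  cover <- (wm$last_index[ramp] - 99) / wm$n_genes[ramp]
  fit <- stats::lm(v[ramp] ~ cover)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # fit can be exact
  expect_gt(r2, 0.999)
})

test_that("malignancy calls follow the burden threshold rule", {
  set.seed(10)
  M <- matrix(rnorm(50 * 40, sd = 0.1), nrow = 50,
              dimnames = list(sprintf("c%02d", 1:50), sprintf("w%02d", 1:40)))
  M[50, ] <- 0  # a cell identical to the reference mean
  prof <- structure(list(matrix = M, windows = NULL,
                         reference_cells = rownames(M)[1:30],
                         window_size = 10L, clamp = 3),
                    class = "cnv_profile")
  call <- call_malignancy(prof, denoise_sd = 0)
  expect_equal(call$calls$burden[50], 0)
  expect_equal(call$calls$label[50], "non_malignant")
  expect_true(all(call$calls$label[call$calls$burden > call$threshold] ==
                    "malignant"))
  # degenerate reference: zero variance
  M0 <- M; M0[1:30, ] <- 1
  prof0 <- structure(list(matrix = M0, reference_cells = rownames(M)[1:30]),
                     class = "cnv_profile")
  expect_error(call_malignancy(prof0), "reference")
})

test_that("subclone clustering is deterministic and respects k", {
  set.seed(3)
  M <- rbind(matrix(rnorm(20 * 10, mean = 2), nrow = 20),
             matrix(rnorm(20 * 10, mean = -2), nrow = 20))
  rownames(M) <- sprintf("c%02d", 1:40)
  prof <- structure(list(matrix = M, reference_cells = character(0)),
                    class = "cnv_profile")
  one <- cluster_subclones(prof, rownames(M), k = 1)
  expect_true(all(one$subclone == 1))
  two <- cluster_subclones(prof, rownames(M), k = "auto", k_max = 5)
  expect_equal(two$k, 2)
  expect_equal(ari(two$subclone, rep(1:2, each = 20)), 1)
  expect_error(cluster_subclones(prof, rownames(M)[1:3], k = 5), "exceeds")
  # duplicating every cell preserves co-membership
  M2 <- rbind(M, M)
  rownames(M2) <- c(rownames(M), sprintf("d%02d", 1:40))
  prof2 <- structure(list(matrix = M2, reference_cells = character(0)),
                     class = "cnv_profile")
  dup <- cluster_subclones(prof2, rownames(M2), k = 2)
  expect_equal(unname(dup$subclone[sprintf("c%02d", 1:40)]),
               unname(dup$subclone[sprintf("d%02d", 1:40)]))
  expect_equal(ari(dup$subclone[sprintf("c%02d", 1:40)], two$subclone), 1)
})

test_that("driver-gene scores reduce to window means and flag missing genes", {
  catal <- generate_gene_catalog(1, 10, seed = 1)
  M <- matrix(c(1, 1, 2, 2, 0, 0), nrow = 6, ncol = 2,
              dimnames = list(sprintf("c%d", 1:6), c("w1", "w2")))
  wm <- data.frame(chromosome = "chr1", first_index = c(0, 5),
                   last_index = c(4, 9), n_genes = 5, window = 1:2)
  prof <- structure(list(matrix = M, windows = wm,
                         reference_cells = character(0)),
                    class = "cnv_profile")
  asg <- structure(list(subclone = stats::setNames(c(1, 1, 2, 2, 3, 3),
                                                   rownames(M)), k = 3),
                   class = "subclone_assignment")
  g_first <- catal$gene_id[catal$order_index == 2]
  expect_warning(sc <- score_driver_genes(prof, asg, c(g_first, "nope"), catal),
                 "nope")
  expect_equal(attr(sc, "missing_genes"), "nope")
  expect_equal(unname(sc[, g_first]), c(1, 2, 0))
  # all-zero profile gives all-zero scores
  prof$matrix[] <- 0
  sc0 <- suppressWarnings(score_driver_genes(prof, asg, g_first, catal))
  expect_true(all(sc0 == 0))
})

test_that("malignant ratio applies the continuity correction only at zero", {
  calls <- structure(list(calls = data.frame(
    cell_id = sprintf("c%02d", 1:19),
    burden = 0,
    label = c(rep("malignant", 10), rep("non_malignant", 5),
              rep("malignant", 4))),
    threshold = 1), class = "malignancy_call")
  types <- c(rep("A", 15), rep("B", 4))
  out <- malignant_ratio(calls, types)
  expect_equal(out$ratio[out$cell_type == "A"], 2.0)
  expect_false(out$corrected[out$cell_type == "A"])
  expect_equal(out$ratio[out$cell_type == "B"], 9.0)
  expect_true(out$corrected[out$cell_type == "B"])
})

test_that("burden is window-permutation invariant and monotone in dosage", {
  set.seed(12)
  M <- matrix(rnorm(30 * 20, sd = 0.2), nrow = 30,
              dimnames = list(sprintf("c%02d", 1:30), NULL))
  prof <- structure(list(matrix = M, reference_cells = rownames(M)[1:15]),
                    class = "cnv_profile")
  b1 <- call_malignancy(prof, denoise_sd = 0)$calls$burden
  perm <- sample(ncol(M))
  prof$matrix <- M[, perm]
  b2 <- call_malignancy(prof, denoise_sd = 0)$calls$burden
  expect_equal(b1, b2)
  # monotone in |log2 multiplier| on expected-value inputs
  burdens <- sapply(c(1, 1.5, 2, 3), function(mult) {
    catal <- generate_gene_catalog(1, 100, seed = 1)
    counts <- matrix(100, nrow = 100, ncol = 11,
                     dimnames = list(catal$gene_id, sprintf("c%02d", 1:11)))
    counts[20:60, 11] <- counts[20:60, 11] * mult
    p <- compute_cnv_profile(make_cells(counts), catal,
                             colnames(counts)[1:10], window_size = 20)
    mean(p$matrix[11, ]^2)  # burden of the dosage-carrying cell
  })
  expect_true(all(diff(burdens) > -1e-12))
})
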