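test_that("gene catalog has the requested shape and is seed-deterministic", {
  cat1 <- generate_gene_catalog(5, 400, seed = 1)
  expect_equal(nrow(cat1), 2000)
  expect_equal(length(unique(cat1$chromosome)), 5)
  expect_equal(range(cat1$order_index), c(0, 399))
  expect_false(anyDuplicated(cat1$gene_id) > 0)
  for (ch in unique(cat1$chromosome)) {
    sub <- cat1[cat1$chromosome == ch, ]
    expect_true(all(diff(sub$start[order(sub$order_index)]) > 0))
  }
  expect_identical(generate_gene_catalog(3, 100, seed = 7),
                   generate_gene_catalog(3, 100, seed = 7))
  single <- generate_gene_catalog(1, 1, seed = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$order_index, 0L)
  expect_error(generate_gene_catalog(0, 10), "must be >= 1")
})

test_that("Poisson limit with unit marker fold makes genes exchangeable", {
  catal <- generate_gene_catalog(2, 50, seed = 2)
  des <- two_type_design(n_cells = 50, n_markers = 10, marker_fold = 1,
                         seed = 3, dispersion = Inf)
  sim <- simulate_single_cells(catal, des)
  marker_means <- rowMeans(sim$cells$counts[sim$truth$markers$A, ])
  set.seed(11)
  rand_genes <- sample(setdiff(rownames(sim$cells$counts),
                               unlist(sim$truth$markers)), 10)
  rand_means <- rowMeans(sim$cells$counts[rand_genes, ])
  diff <- mean(marker_means) - mean(rand_means)
  se <- sqrt(var(marker_means) / 10 + var(rand_means) / 10)
  expect_lt(abs(diff), 3 * se)
})

test_that("a multiplier-2 event doubles mean counts in the carrying subclone", {
  catal <- generate_gene_catalog(1, 300, seed = 1)
  des <- cohort_design(
    cell_types = "T", immune_types = character(0),
    n_markers_per_type = 5, marker_fold = 1, cells_per_type = 500,
    samples = data.frame(sample = "s1", condition = "LUAD", stage = "I"),
    malignant = list(list(
      type = "T", conditions = "LUAD", fraction = 0.5,
      subclones = list(list(proportion = 1, events = data.frame(
        chromosome = "chr1", first_gene_index = 100L, last_gene_index = 249L,
        multiplier = 2.0))))),
    seed = 5)
  sim <- simulate_single_cells(catal, des)
  ev_genes <- catal$gene_id[catal$order_index >= 100 & catal$order_index <= 249]
  mal <- sim$cells$meta$malignant
  ratio <- mean(sim$cells$counts[ev_genes, mal]) /
    mean(sim$cells$counts[ev_genes, !mal])
  expect_gt(sum(mal), 200)
  expect_lt(abs(ratio - 2), 0.2)
  # dosage acts only inside the event range
  out_genes <- catal$gene_id[catal$order_index < 100]
  ratio_out <- mean(sim$cells$counts[out_genes, mal]) /
    mean(sim$cells$counts[out_genes, !mal])
  expect_lt(abs(ratio_out - 1), 0.1)
})

test_that("zero cells requested for a type leaves it out of the metadata", {
  catal <- generate_gene_catalog(1, 60, seed = 1)
  des <- cohort_design(
    cell_types = c("A", "B"), immune_types = character(0),
    n_markers_per_type = 5, cells_per_type = c(A = 40, B = 0),
    samples = data.frame(sample = "s1", condition = "LUAD", stage = "I"),
    malignant = list(), seed = 1)
  sim <- simulate_single_cells(catal, des)
  expect_false("B" %in% sim$cells$meta$cell_type)
})

test_that("overlapping marker sets and out-of-range events are rejected", {
  catal <- generate_gene_catalog(1, 60, seed = 1)
  des <- two_type_design(n_cells = 20, n_markers = 5)
  expect_error(
    simulate_single_cells(catal, des,
                          markers = list(A = catal$gene_id[1:5],
                                         B = catal$gene_id[5:9])),
    "disjoint")
  des_bad <- cohort_design(
    cell_types = "T", immune_types = character(0),
    n_markers_per_type = 5, cells_per_type = 20,
    samples = data.frame(sample = "s1", condition = "LUAD", stage = "I"),
    malignant = list(list(type = "T", conditions = "LUAD", fraction = 1,
                          subclones = list(list(proportion = 1, events = data.frame(
                            chromosome = "chr1", first_gene_index = 10L,
                            last_gene_index = 100L, multiplier = 2))))),
    seed = 1)
  expect_error(simulate_single_cells(catal, des_bad), "out of chromosome bounds")
})

test_that("simulation is a pure function of (design, seed)", {
  catal <- generate_gene_catalog(1, 50, seed = 1)
  des <- two_type_design(n_cells = 30, seed = 9)
  s1 <- simulate_single_cells(catal, des)
  s2 <- simulate_single_cells(catal, des)
  expect_identical(s1$cells$counts, s2$cells$counts)
  expect_identical(s1$truth$markers, s2$truth$markers)
})

test_that("noiseless bulk mixtures are exact and compositions sum to one", {
  catal <- generate_gene_catalog(1, 40, seed = 1)
  profiles <- matrix(rlnorm(40 * 3, 1, 1), nrow = 40,
                     dimnames = list(catal$gene_id, c("A", "B", "C")))
  des <- cohort_design(cell_types = c("A", "B", "C"),
                       immune_types = character(0),
                       cells_per_type = 10, malignant = list(),
                       samples = data.frame(sample = "s1", condition = "LUAD",
                                            stage = "I"),
                       bulk_sigma = 0, seed = 1)
  comp <- rbind(c(0, 1, 0), c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25))
  res <- simulate_bulk(catal, profiles, des, compositions = comp)
  expect_equal(unname(res$bulk[, 1]), unname(profiles[, "B"]))
  expect_equal(res$bulk[, 2], res$bulk[, 3], ignore_attr = TRUE)
  res2 <- simulate_bulk(catal, profiles, des)
  expect_true(all(abs(rowSums(res2$truth$composition) - 1) < 1e-9))
  expect_true(all(res2$truth$composition >= 0))
})

test_that("Dirichlet archetype means match alpha_i / sum(alpha)", {
  catal <- generate_gene_catalog(1, 30, seed = 1)
  types <- paste0("T", 1:16)
  types[1] <- "Fib"
  profiles <- matrix(rlnorm(30 * 17, 1, 1), nrow = 30,
                     dimnames = list(catal$gene_id, c(types, "T17")))
  alpha <- stats::setNames(rep(1, 17), colnames(profiles))
  alpha["Fib"] <- 50
  des <- cohort_design(cell_types = colnames(profiles),
                       immune_types = character(0), cells_per_type = 5,
                       malignant = list(),
                       samples = data.frame(sample = "s1", condition = "LUAD",
                                            stage = "I"),
                       archetypes = list(fib_dom = alpha),
                       hazards = c(fib_dom = 1),
                       n_bulk_per_group = 100, bulk_sigma = 0, seed = 4)
  res <- simulate_bulk(catal, profiles, des)
  w_fib <- res$truth$composition[, "Fib"]
  expected <- 50 / (50 + 16)
  se <- sd(w_fib) / sqrt(length(w_fib))
  expect_lt(abs(mean(w_fib) - expected), 3 * se)
})

test_that("survival times follow group hazards with independent censoring", {
  s <- simulate_survival(rep("g", 2000), c(g = 1), censoring_rate = 0, seed = 2)
  expect_true(all(s$event == 1))
  expect_lt(abs(mean(s$time) - 1), 3 / sqrt(2000))
  s2 <- simulate_survival(rep(c("a", "b"), 500), c(a = 1, b = 2),
                          censoring_rate = 0.3, seed = 3)
  expect_lt(abs(mean(s2$event == 0) - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  expect_error(simulate_survival(c("a", "zzz"), c(a = 1), 0, 1), "zzz")
  expect_error(simulate_survival("a", c(a = -1), 0, 1), "positive")
})

test_that("cohort round-trips through MTX/TSV/BED on disk", {
  catal <- generate_gene_catalog(2, 20, seed = 1)
  des <- two_type_design(n_cells = 10, n_markers = 3)
  sim <- simulate_single_cells(catal, des)
  dir <- tempfile("cohort")
  write_cohort(sim$cells, catal, dir, truth = list(note = "synthetic"))
  back <- read_cohort(dir)
  expect_equal(back$counts, sim$cells$counts, ignore_attr = TRUE)
  expect_equal(back$meta$cell_type, sim$cells$meta$cell_type)
  cat_back <- read_gene_catalog(file.path(dir, "genes.bed"))
  expect_setequal(cat_back$gene_id, catal$gene_id)
  m <- merge(cat_back, catal, by = "gene_id")
  expect_equal(m$order_index.x, m$order_index.y)
  unlink(dir, recursive = TRUE)
})
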