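#' Generate an ordered gene catalog
#'
#' Builds a synthetic gene catalog of `n_chromosomes x genes_per_chromosome`
#' genes. Within each chromosome, start coordinates are strictly increasing
#' (cumulative random gaps, 0-based) and `order_index` ranks genes 0-based in
#' coordinate order. The catalog defines the chromosome-wise gene order used
#' by sliding-window CNV inference.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param genes_per_chromosome genes on each chromosome (>= 1).
#' @param seed integer RNG seed; output is a pure function of the arguments.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `order_index`.
#' @export
generate_gene_catalog <- function(n_chromosomes, genes_per_chromosome, seed = 1L) {
  if (n_chromosomes < 1 || genes_per_chromosome < 1)
    stop("n_chromosomes and genes_per_chromosome must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- n_chromosomes * genes_per_chromosome
  gaps <- matrix(sample(1e3:1e5, n, replace = TRUE),
                 nrow = genes_per_chromosome)
  starts <- apply(gaps, 2, cumsum)
  out <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chromosome = rep(paste0("chr", seq_len(n_chromosomes)),
                     each = genes_per_chromosome),
    start = as.integer(starts),
    order_index = rep(seq_len(genes_per_chromosome) - 1L, n_chromosomes)
  )
  validate_catalog(out)
  out
}

validate_catalog <- function(catalog) {
  stopifnot(all(c("gene_id", "chromosome", "start", "order_index") %in% names(catalog)))
  if (anyDuplicated(catalog$gene_id)) stop("duplicate gene ids", call. = FALSE)
  for (ch in unique(catalog$chromosome)) {
    sub <- catalog[catalog$chromosome == ch, ]
    sub <- sub[order(sub$order_index), ]
    if (any(diff(sub$start) <= 0))
      stop("start not strictly increasing with order_index on ", ch, call. = FALSE)
  }
  invisible(catalog)
}

#' Cohort design for the synthetic generator
#'
#' Collects every tunable of the synthetic single-cell + bulk cohort:
#' cell types, per-type marker counts and fold, negative-binomial parameters,
#' malignant subclone structure (contiguous dosage events), bulk composition
#' archetypes (Dirichlet concentrations), group hazards and censoring.
#' Defaults describe a desk-scale lung-tumor-like cohort: 8 non-immune and 4
#' immune cell types, AT2 carrying subclonal events under LUAD and basal
#' under LUSC, and four bulk archetypes (Fib-high, AT2-high, NE-high,
#' hybrid) of which Fib-high carries an elevated hazard.
#'
#' @param cell_types character vector of cell-type names.
#' @param immune_types subset of `cell_types` treated as immune.
#' @param n_markers_per_type marker genes sampled per type (disjoint blocks).
#' @param marker_fold multiplicative elevation of a type's markers (default 8).
#' @param cells_per_type total cells simulated per type (split over samples).
#' @param samples data.frame with columns `sample`, `condition`
#'   (LUAD/LUSC/adjacent/normal) and `stage` (I-IV).
#' @param malignant list of per-type malignancy specs: each a list with
#'   `type`, `conditions` (conditions whose samples carry malignant cells),
#'   `fraction` (malignant fraction among that type's cells in those samples)
#'   and `subclones`, a list of subclones each holding `proportion` and
#'   `events` (data.frame chromosome / first_gene_index / last_gene_index /
#'   multiplier, indices in 0-based `order_index` units, inclusive).
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   mu^2); `Inf` gives the Poisson limit.
#' @param library_sigma log-normal sigma of per-cell library-size factors.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of per-gene
#'   baseline means.
#' @param archetypes named list of Dirichlet concentration vectors over
#'   `cell_types`, one per bulk group.
#' @param n_bulk_per_group bulk samples drawn per group.
#' @param bulk_sigma log-normal sigma of multiplicative bulk noise.
#' @param hazards named per-group exponential event rates.
#' @param censoring_rate fraction of subjects censored (in [0, 1)).
#' @param seed integer seed; every simulator output is a pure function of
#'   (design, seed).
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(
    cell_types = c("AT1", "AT2", "Basal", "Club", "Cilia", "NE", "Fib", "Endo",
                   "Tcell", "Bcell", "Mph", "Mast"),
    immune_types = c("Tcell", "Bcell", "Mph", "Mast"),
    n_markers_per_type = 40L,
    marker_fold = 8,
    cells_per_type = 250L,
    samples = data.frame(
      sample = c("LUAD_1", "LUAD_2", "LUSC_1", "LUSC_2", "ADJ_1", "ADJ_2"),
      condition = c("LUAD", "LUAD", "LUSC", "LUSC", "adjacent", "adjacent"),
      stage = c("I", "III", "II", "IV", "I", "II")),
    malignant = list(
      list(type = "AT2", conditions = c("LUAD"), fraction = 0.5,
           subclones = list(
             list(proportion = 0.5, events = data.frame(
               chromosome = "chr1", first_gene_index = 50L,
               last_gene_index = 249L, multiplier = 2.0)),
             list(proportion = 0.5, events = data.frame(
               chromosome = c("chr2", "chr3"),
               first_gene_index = c(100L, 0L),
               last_gene_index = c(299L, 149L),
               multiplier = c(0.5, 2.0))))),
      list(type = "Basal", conditions = c("LUSC"), fraction = 0.5,
           subclones = list(
             list(proportion = 1, events = data.frame(
               chromosome = c("chr4", "chr5"),
               first_gene_index = c(100L, 200L),
               last_gene_index = c(299L, 349L),
               multiplier = c(2.0, 0.5)))))),
    dispersion = 0.5,
    library_sigma = 0.2,
    base_mean_meanlog = -1,
    base_mean_sdlog = 1,
    archetypes = NULL,
    n_bulk_per_group = 30L,
    bulk_sigma = 0.2,
    hazards = NULL,
    censoring_rate = 0.2,
    seed = 1L) {
  if (is.null(archetypes)) {
    base <- stats::setNames(rep(1, length(cell_types)), cell_types)
    dominant <- intersect(c("Fib", "AT2", "NE"), cell_types)
    archetypes <- lapply(dominant, function(d) { a <- base; a[d] <- 50; a })
    names(archetypes) <- vapply(dominant, function(d) paste0(d, "-high"), "")
    archetypes$hybrid <- base * 5
  }
  if (is.null(hazards)) {
    hazards <- stats::setNames(rep(0.35, length(archetypes)), names(archetypes))
    # poor-prognosis archetype: fibroblast-dominated when present, else first
    hazards[[if ("Fib-high" %in% names(hazards)) "Fib-high" else 1L]] <- 1.0
  }
  if (length(cells_per_type) > 1 && is.null(names(cells_per_type)))
    stop("per-type cells_per_type must be named", call. = FALSE)
  stopifnot(all(cells_per_type >= 0), n_markers_per_type > 0, marker_fold > 0,
            dispersion > 0, library_sigma >= 0, bulk_sigma >= 0,
            n_bulk_per_group > 0)
  if (any(unlist(archetypes) <= 0)) stop("Dirichlet concentrations must be positive", call. = FALSE)
  if (any(hazards <= 0)) stop("hazards must be positive", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)", call. = FALSE)
  if (!all(immune_types %in% cell_types)) stop("immune_types must be cell_types", call. = FALSE)
  if (!setequal(names(hazards), names(archetypes)))
    stop("hazards must name every archetype group", call. = FALSE)
  structure(list(
    cell_types = cell_types, immune_types = immune_types,
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_fold = marker_fold,
    cells_per_type = stats::setNames(as.integer(cells_per_type),
                                     names(cells_per_type)),
    samples = samples, malignant = malignant, dispersion = dispersion,
    library_sigma = library_sigma, base_mean_meanlog = base_mean_meanlog,
    base_mean_sdlog = base_mean_sdlog, archetypes = archetypes,
    n_bulk_per_group = as.integer(n_bulk_per_group), bulk_sigma = bulk_sigma,
    hazards = hazards, censoring_rate = censoring_rate,
    seed = as.integer(seed)), class = "cohort_design")
}

# Validate CNV events against a catalog; returns events with gene row indices.
check_events <- function(events, catalog) {
  per_chrom <- table(catalog$chromosome)
  for (i in seq_len(nrow(events))) {
    ch <- events$chromosome[i]
    if (!ch %in% names(per_chrom))
      stop("CnvEvent references unknown chromosome ", ch, call. = FALSE)
    if (events$first_gene_index[i] < 0 ||
        events$last_gene_index[i] < events$first_gene_index[i] ||
        events$last_gene_index[i] >= per_chrom[[ch]])
      stop("CnvEvent range out of chromosome bounds on ", ch, call. = FALSE)
    if (events$multiplier[i] <= 0)
      stop("CnvEvent multiplier must be positive", call. = FALSE)
  }
  invisible(events)
}

# Gene row indices covered by an event data.frame.
event_gene_rows <- function(events, catalog) {
  unlist(lapply(seq_len(nrow(events)), function(i) {
    which(catalog$chromosome == events$chromosome[i] &
            catalog$order_index >= events$first_gene_index[i] &
            catalog$order_index <= events$last_gene_index[i])
  }))
}

#' Simulate a single-cell cohort with ground truth
#'
#' Draws counts from a negative-binomial model: per-gene baseline means are
#' log-normal; each cell type's marker genes have mean elevated by
#' `marker_fold`; malignant cells have expected expression multiplied
#' gene-wise by their subclone's dosage events (expression linear in copy
#' number); per-cell library factors are log-normal. Non-malignant cells
#' carry no dosage effect.
#'
#' @param catalog gene catalog from [generate_gene_catalog].
#' @param design a [cohort_design].
#' @param markers optional named list (type -> gene ids) overriding the seeded
#'   random marker assignment; sets must be disjoint.
#' @return list with `cells` (a [cell_matrix] whose metadata carries the truth
#'   columns `malignant` and `subclone`) and `truth` (markers, per-cell flags,
#'   events, per-gene expected means per population).
#' @export
simulate_single_cells <- function(catalog, design, markers = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n_genes <- nrow(catalog)
  types <- design$cell_types

  if (is.null(markers)) {
    need <- length(types) * design$n_markers_per_type
    if (need > n_genes) stop("not enough genes for requested markers", call. = FALSE)
    pool <- sample(catalog$gene_id, need)
    markers <- split(pool, rep(types, each = design$n_markers_per_type))
  } else {
    all_m <- unlist(markers)
    if (anyDuplicated(all_m) > 0)
      stop("marker sets must be disjoint across cell types", call. = FALSE)
    if (!all(all_m %in% catalog$gene_id))
      stop("markers must be catalog genes", call. = FALSE)
  }

  base_mean <- rlnorm(n_genes, design$base_mean_meanlog, design$base_mean_sdlog)
  names(base_mean) <- catalog$gene_id

  type_mean <- sapply(types, function(t) {
    mu <- base_mean
    if (!is.null(markers[[t]])) mu[markers[[t]]] <- mu[markers[[t]]] * design$marker_fold
    mu
  })  # genes x types

  mal_specs <- design$malignant
  for (sp in mal_specs) check_events(do.call(rbind, lapply(sp$subclones, `[[`, "events")), catalog)

  samples <- design$samples
  cpt <- design$cells_per_type
  if (length(cpt) == 1L) cpt <- stats::setNames(rep(cpt, length(types)), types)
  cpt[is.na(cpt[types])] <- 0L
  n_per_type <- pmax(0L, as.integer(round(cpt[types] / nrow(samples))))
  n_per_type[cpt[types] > 0 & n_per_type == 0] <- 1L
  names(n_per_type) <- types

  meta_list <- list()
  count_list <- list()
  cell_counter <- 0L
  for (si in seq_len(nrow(samples))) {
    for (t in types) {
      n_cells <- n_per_type[[t]]
      if (n_cells == 0L) next
      spec <- Filter(function(sp) sp$type == t &&
                       samples$condition[si] %in% sp$conditions, mal_specs)
      spec <- if (length(spec)) spec[[1]] else NULL
      malignant <- if (is.null(spec)) rep(FALSE, n_cells) else
        stats::runif(n_cells) < spec$fraction
      subclone <- rep(NA_integer_, n_cells)
      if (!is.null(spec) && any(malignant)) {
        props <- vapply(spec$subclones, `[[`, numeric(1), "proportion")
        subclone[malignant] <- sample(seq_along(spec$subclones), sum(malignant),
                                      replace = TRUE, prob = props)
      }
      mu_base <- type_mean[, t]
      mu <- matrix(mu_base, nrow = n_genes, ncol = n_cells)
      if (!is.null(spec)) {
        for (k in seq_along(spec$subclones)) {
          cols <- which(!is.na(subclone) & subclone == k)
          if (!length(cols)) next
          ev <- spec$subclones[[k]]$events
          for (e in seq_len(nrow(ev))) {
            rows <- event_gene_rows(ev[e, ], catalog)
            mu[rows, cols] <- mu[rows, cols] * ev$multiplier[e]
          }
        }
      }
      libf <- rlnorm(n_cells, 0, design$library_sigma)
      mu <- sweep(mu, 2, libf, "*")
      counts <- if (is.finite(design$dispersion)) {
        matrix(rnbinom(length(mu), mu = mu, size = 1 / design$dispersion),
               nrow = n_genes)
      } else {
        matrix(rpois(length(mu), lambda = mu), nrow = n_genes)
      }
      ids <- sprintf("cell%06d", cell_counter + seq_len(n_cells))
      cell_counter <- cell_counter + n_cells
      colnames(counts) <- ids
      rownames(counts) <- catalog$gene_id
      count_list[[length(count_list) + 1L]] <- counts
      meta_list[[length(meta_list) + 1L]] <- data.frame(
        cell_id = ids, sample = samples$sample[si], cell_type = t,
        condition = samples$condition[si], stage = samples$stage[si],
        malignant = malignant, subclone = subclone)
    }
  }
  counts <- do.call(cbind, count_list)
  meta <- do.call(rbind, meta_list)
  cells <- cell_matrix(counts, meta)
  events <- do.call(rbind, lapply(mal_specs, function(sp) {
    do.call(rbind, lapply(seq_along(sp$subclones), function(k) {
      ev <- sp$subclones[[k]]$events
      ev$subclone_id <- k
      ev$type <- sp$type
      ev
    }))
  }))
  marker_of <- rep(NA_character_, n_genes)
  names(marker_of) <- catalog$gene_id
  for (t in names(markers)) marker_of[markers[[t]]] <- t
  truth <- list(markers = markers, marker_of = marker_of,
                malignant = stats::setNames(meta$malignant, meta$cell_id),
                subclone = stats::setNames(meta$subclone, meta$cell_id),
                events = events, type_mean = type_mean)
  list(cells = cells, truth = truth)
}

#' Mean expression profile per cell type
#'
#' Mean linear relative expression (library-normalized, `scale_factor`) per
#' cell type; the reference profiles mixed by [simulate_bulk] and the entries
#' of deconvolution signatures.
#'
#' @param cells a [cell_matrix] with `cell_type` metadata.
#' @param scale_factor normalization scale (default 1e4).
#' @return genes x cell-types matrix.
#' @export
cell_type_profiles <- function(cells, scale_factor = 1e4) {
  ls <- relative_expression(cells$counts, scale_factor)
  types <- sort(unique(cells$meta$cell_type))
  sapply(types, function(t) rowMeans(ls[, cells$meta$cell_type == t, drop = FALSE]))
}

#' Simulate bulk samples as noisy mixtures of cell-type profiles
#'
#' Each sample's true composition is drawn from its group's Dirichlet
#' archetype; the expected bulk profile is `profiles %*% composition` with
#' multiplicative log-normal noise (`bulk_sigma = 0` gives exact mixtures).
#'
#' @param catalog gene catalog (for gene-id checks).
#' @param profiles genes x cell-types matrix of mean expression per type.
#' @param design a [cohort_design] (archetypes, n per group, noise sigma).
#' @param seed RNG seed (default `design$seed`).
#' @param compositions optional samples x cell-types matrix of fixed true
#'   compositions (rows summing to 1) overriding the Dirichlet draw; rownames
#'   are then used as group labels if named, else "fixed".
#' @return list with `bulk` (genes x samples), `truth` (list with
#'   `composition` samples x types and `group` labels).
#' @export
simulate_bulk <- function(catalog, profiles, design, seed = design$seed,
                          compositions = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$bulk_sigma < 0) stop("bulk noise sigma must be >= 0", call. = FALSE)
  if (any(profiles < 0)) stop("profiles must be non-negative", call. = FALSE)
  types <- colnames(profiles)
  set.seed(seed)
  if (is.null(compositions)) {
    for (a in design$archetypes)
      if (!all(types %in% names(a)))
        stop("archetype vectors must cover all cell types", call. = FALSE)
    groups <- rep(names(design$archetypes), each = design$n_bulk_per_group)
    W <- do.call(rbind, lapply(names(design$archetypes), function(g)
      rdirichlet(design$n_bulk_per_group, design$archetypes[[g]][types])))
  } else {
    W <- as.matrix(compositions)
    if (!isTRUE(all.equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-9)))
      stop("fixed compositions must sum to 1 per row", call. = FALSE)
    groups <- if (!is.null(rownames(W))) rownames(W) else rep("fixed", nrow(W))
  }
  colnames(W) <- types
  n_samp <- nrow(W)
  expected <- profiles %*% t(W)  # genes x samples
  noise <- if (design$bulk_sigma > 0)
    matrix(rlnorm(length(expected), 0, design$bulk_sigma), nrow = nrow(expected))
  else 1
  bulk <- expected * noise
  colnames(bulk) <- sprintf("bulk%03d", seq_len(n_samp))
  rownames(bulk) <- rownames(profiles)
  rownames(W) <- colnames(bulk)
  list(bulk = bulk,
       truth = list(composition = W,
                    group = stats::setNames(groups, colnames(bulk))))
}

#' Simulate survival times with group-dependent hazards
#'
#' Event times are exponential with the subject's group hazard; censoring is
#' independent (a competing exponential whose rate is chosen so the marginal
#' probability of censoring equals `censoring_rate`). `event = 1` marks an
#' observed death.
#'
#' @param group_labels character vector of per-sample group names.
#' @param hazards named positive rates, one per group present in the labels.
#' @param censoring_rate fraction censored, in [0, 1).
#' @param seed RNG seed.
#' @return data.frame with `time` and `event` (0/1) per sample.
#' @export
simulate_survival <- function(group_labels, hazards, censoring_rate = 0,
                              seed = 1L) {
  if (any(hazards <= 0)) stop("hazards must be positive", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)", call. = FALSE)
  unknown <- setdiff(unique(group_labels), names(hazards))
  if (length(unknown))
    stop("unknown group(s) in labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  n <- length(group_labels)
  lambda <- hazards[group_labels]
  t_event <- rexp(n, rate = lambda)
  if (censoring_rate > 0) {
    mu <- lambda * censoring_rate / (1 - censoring_rate)
    t_cens <- rexp(n, rate = mu)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  } else {
    data.frame(time = t_event, event = rep(1L, n))
  }
}
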