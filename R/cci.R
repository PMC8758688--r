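#' Ligand-receptor interaction score
#'
#' The score of a (ligand, receptor) pair for a (sender, receiver) cell-type
#' pair is the mean of two means: mean ligand expression over sender cells and
#' mean receptor expression over receiver cells (normalized linear scale by
#' default).
#'
#' @param cells a [cell_matrix].
#' @param ligand,receptor gene ids (must be present in the matrix).
#' @param sender,receiver cell-type labels (must be present in the metadata).
#' @param normalize use linear relative expression (`counts/libsize * 1e4`);
#'   `FALSE` scores raw values.
#' @return numeric score.
#' @export
interaction_score <- function(cells, ligand, receptor, sender, receiver,
                              normalize = TRUE) {
  stopifnot(inherits(cells, "cell_matrix"))
  for (g in c(ligand, receptor))
    if (!g %in% rownames(cells$counts))
      stop("gene '", g, "' not in expression matrix", call. = FALSE)
  types <- cells$meta$cell_type
  for (t in c(sender, receiver))
    if (!t %in% types) stop("cell type '", t, "' not present", call. = FALSE)
  x <- if (normalize) relative_expression(cells$counts) else cells$counts
  mean(c(mean(x[ligand, types == sender]),
         mean(x[receptor, types == receiver])))
}

#' Permutation p-value for a ligand-receptor interaction
#'
#' One-sided (enrichment) permutation test: the null distribution of the
#' interaction score is generated by shuffling cell-type labels across all
#' cells (equivalently, drawing random disjoint sender/receiver cell sets of
#' the observed sizes); `p = (# null >= observed + 1) / (B + 1)`. Pairs where
#' either type has fewer than 3 cells are flagged and returned with p = 1.
#'
#' @inheritParams interaction_score
#' @param n_permutations number of label permutations (>= 100, default 1000).
#' @param seed integer seed.
#' @return one-row data.frame: ligand, receptor, sender, receiver, score,
#'   p_value, n_permutations, flag ("" or "insufficient_cells").
#' @export
permutation_pvalue <- function(cells, ligand, receptor, sender, receiver,
                               n_permutations = 1000L, seed = 1L,
                               normalize = TRUE) {
  if (n_permutations < 100) stop("n_permutations must be >= 100", call. = FALSE)
  obs <- interaction_score(cells, ligand, receptor, sender, receiver, normalize)
  types <- cells$meta$cell_type
  n_s <- sum(types == sender)
  n_r <- sum(types == receiver)
  if (n_s < 3 || n_r < 3)
    return(data.frame(ligand = ligand, receptor = receptor, sender = sender,
                      receiver = receiver, score = obs, p_value = 1,
                      n_permutations = as.integer(n_permutations),
                      flag = "insufficient_cells"))
  x <- if (normalize) relative_expression(cells$counts) else cells$counts
  lig <- x[ligand, ]
  rec <- x[receptor, ]
  n <- length(lig)
  set.seed(seed)
  null_scores <- vapply(seq_len(n_permutations), function(b) {
    idx <- sample.int(n, n_s + n_r)
    (mean(lig[idx[seq_len(n_s)]]) + mean(rec[idx[n_s + seq_len(n_r)]])) / 2
  }, numeric(1))
  p <- (sum(null_scores >= obs) + 1) / (n_permutations + 1)
  data.frame(ligand = ligand, receptor = receptor, sender = sender,
             receiver = receiver, score = obs, p_value = p,
             n_permutations = as.integer(n_permutations), flag = "")
}

#' Score a ligand-receptor pair list over cell-type pairs
#'
#' Evaluates [permutation_pvalue] for every pair in `pairs` and every ordered
#' (sender, receiver) cell-type combination, gated on detection: a pair is
#' tested only when the ligand is detected (count > 0) in at least
#' `min_expressed_frac` of sender cells and the receptor in at least that
#' fraction of receiver cells.
#'
#' @param cells a [cell_matrix].
#' @param pairs data.frame with columns `ligand`, `receptor`.
#' @param types cell types to cross (default: all types in the metadata).
#' @param min_expressed_frac detection gate (default 0.1).
#' @param n_permutations,seed,normalize passed to [permutation_pvalue].
#' @return long data.frame of interaction results (gated-out combinations are
#'   omitted).
#' @export
score_lr_pairs <- function(cells, pairs, types = NULL,
                           min_expressed_frac = 0.1, n_permutations = 1000L,
                           seed = 1L, normalize = TRUE) {
  stopifnot(inherits(cells, "cell_matrix"),
            all(c("ligand", "receptor") %in% names(pairs)))
  if (is.null(types)) types <- sort(unique(cells$meta$cell_type))
  detected <- cells$counts > 0
  frac <- sapply(types, function(t)
    rowMeans(detected[, cells$meta$cell_type == t, drop = FALSE]))
  res <- list()
  i <- 0L
  for (p in seq_len(nrow(pairs))) {
    lg <- pairs$ligand[p]; rc <- pairs$receptor[p]
    if (!lg %in% rownames(cells$counts) || !rc %in% rownames(cells$counts))
      next
    for (s in types) for (r in types) {
      if (frac[lg, s] < min_expressed_frac || frac[rc, r] < min_expressed_frac)
        next
      i <- i + 1L
      res[[i]] <- permutation_pvalue(cells, lg, rc, s, r, n_permutations,
                                     seed = seed + i, normalize = normalize)
    }
  }
  if (!length(res))
    return(data.frame(ligand = character(0), receptor = character(0),
                      sender = character(0), receiver = character(0),
                      score = numeric(0), p_value = numeric(0),
                      n_permutations = integer(0), flag = character(0)))
  do.call(rbind, res)
}

#' Count significant interactions per cell-type pair and per cell type
#'
#' @param results long data.frame of interaction results (from
#'   [permutation_pvalue] / [score_lr_pairs]).
#' @param alpha nominal significance level (default 0.05; no multiplicity
#'   correction, matching the counting convention of permutation-based
#'   interaction tools).
#' @return list: `per_pair` (sender, receiver, n_significant, n_tested) and
#'   `per_type` (type, n_as_sender, n_as_receiver, total).
#' @export
count_interactions <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0) {
    return(list(per_pair = data.frame(sender = character(0),
                                      receiver = character(0),
                                      n_significant = integer(0),
                                      n_tested = integer(0)),
                per_type = data.frame(type = character(0),
                                      n_as_sender = integer(0),
                                      n_as_receiver = integer(0),
                                      total = integer(0))))
  }
  sig <- results$p_value < alpha
  key <- interaction(results$sender, results$receiver, drop = TRUE)
  per_pair <- do.call(rbind, lapply(levels(key), function(kk) {
    idx <- key == kk
    data.frame(sender = results$sender[idx][1],
               receiver = results$receiver[idx][1],
               n_significant = sum(sig[idx]), n_tested = sum(idx))
  }))
  types <- sort(unique(c(results$sender, results$receiver)))
  per_type <- do.call(rbind, lapply(types, function(t) {
    ns <- sum(per_pair$n_significant[per_pair$sender == t])
    nr <- sum(per_pair$n_significant[per_pair$receiver == t])
    data.frame(type = t, n_as_sender = ns, n_as_receiver = nr,
               total = ns + nr)
  }))
  list(per_pair = per_pair, per_type = per_type)
}
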