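#' Sample-by-sample Pearson correlation of compositions
#'
#' @param comp a `composition_matrix` or samples x types matrix.
#' @return symmetric samples x samples correlation matrix (unit diagonal);
#'   attribute `constant_samples` lists flagged constant rows (their
#'   correlations are NA).
#' @export
composition_correlation <- function(comp) {
  W <- if (inherits(comp, "composition_matrix")) comp$weights else as.matrix(comp)
  if (nrow(W) < 2) stop("need at least 2 samples", call. = FALSE)
  constant <- rownames(W)[apply(W, 1, sd) == 0]
  if (length(constant))
    warning("constant composition row(s): ", paste(constant, collapse = ", "),
            call. = FALSE)
  R <- suppressWarnings(cor(t(W)))
  diag(R) <- 1
  attr(R, "constant_samples") <- constant
  R
}

#' Discover recurrent cellular-composition groups
#'
#' Hierarchically clusters samples on correlation distance (1 - Pearson) with
#' average linkage. Correlations are computed on column-standardized
#' (z-scored) weights: standardization expresses each sample relative to the
#' cohort, so archetypes without a single dominant type (flat "hybrid"
#' compositions) still share a pattern and cohere, instead of being swamped
#' by the dominant-type coordinates. With `k = "auto"` the
#' group count is chosen in `2..k_max` by mean silhouette width. Each group is
#' named from the mean z-scored weights of its samples: the top type T gives
#' "T-high" when its mean z exceeds `z_dominant` and no other type comes
#' within `z_hybrid_gap` of it; exactly one runner-up within the gap gives
#' "T1-T2 hybrid"; more ties, or no type reaching `z_dominant`, give
#' "hybrid".
#'
#' @param comp a `composition_matrix` or samples x types matrix.
#' @param k number of groups, or "auto".
#' @param k_max upper bound for automatic selection (default 8).
#' @param z_dominant z threshold for a dominant type (default 1).
#' @param z_hybrid_gap z gap under which two dominant types tie (default 0.25).
#' @return a `group_assignment`: list with `groups` (data.frame sample,
#'   group_id, group_name), `k`, `linkage`, `group_names`.
#' @export
discover_groups <- function(comp, k = "auto", k_max = 8L, z_dominant = 1,
                            z_hybrid_gap = 0.25) {
  W <- if (inherits(comp, "composition_matrix")) comp$weights else as.matrix(comp)
  n <- nrow(W)
  if (!identical(k, "auto") && k > n)
    stop("k exceeds the number of samples", call. = FALSE)
  ord <- order(rownames(W))
  W <- W[ord, , drop = FALSE]
  Z <- scale(W)
  Z[, attr(Z, "scaled:scale") == 0] <- 0

  if (identical(k, "auto") || k > 1) {
    R <- suppressWarnings(cor(t(Z)))
    R[is.na(R)] <- 0
    d <- stats::as.dist(1 - R)
    hc <- hclust(d, method = "average")
    kk <- if (identical(k, "auto")) select_k_silhouette(d, hc, k_max)
          else as.integer(k)
    raw <- cutree(hc, k = kk)
  } else {
    kk <- 1L
    raw <- rep(1L, n)
  }
  gid <- as.integer(factor(raw, levels = unique(raw)))

  group_names <- character(kk)
  for (g in seq_len(kk)) {
    mz <- colMeans(Z[gid == g, , drop = FALSE])
    o <- order(mz, decreasing = TRUE)
    n_near <- sum(mz >= mz[o[1]] - z_hybrid_gap)  # types tied with the top
    group_names[g] <- if (mz[o[1]] <= z_dominant || n_near > 2) "hybrid"
    else if (n_near == 2)
      paste0(colnames(W)[o[1]], "-", colnames(W)[o[2]], " hybrid")
    else paste0(colnames(W)[o[1]], "-high")
  }
  groups <- data.frame(sample = rownames(W), group_id = gid,
                       group_name = group_names[gid])
  structure(list(groups = groups, k = kk, linkage = "average",
                 group_names = group_names),
            class = "group_assignment")
}

#' SVM classification of sample classes from compositions
#'
#' Linear-kernel support vector machine on composition weights, evaluated by
#' stratified k-fold cross-validation repeated `n_repeats` times with distinct
#' derived seeds. AUC is computed one-vs-one for every class pair from pooled
#' held-out decision values and macro-averaged per repeat; the report carries
#' the mean and SD over repeats.
#'
#' @param comp a `composition_matrix` or samples x types matrix.
#' @param labels per-sample class labels.
#' @param n_folds folds per repeat (default 5); every class needs >= n_folds
#'   samples.
#' @param n_repeats cross-validation repeats (default 20).
#' @param seed integer seed; identical seeds give identical reports.
#' @return a `classifier_report`: list with `mean_auc`, `sd_auc`,
#'   `auc_per_repeat`, `per_pair` (mean AUC per class pair), `n_folds`,
#'   `n_repeats`, `seed`.
#' @export
classify_subtypes <- function(comp, labels, n_folds = 5L, n_repeats = 20L,
                              seed = 1L) {
  W <- if (inherits(comp, "composition_matrix")) comp$weights else as.matrix(comp)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(W))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < n_folds))
    stop("every class needs at least n_folds samples", call. = FALSE)
  classes <- sort(names(tab))
  pairs <- utils::combn(classes, 2, simplify = FALSE)

  auc_rep <- matrix(NA_real_, nrow = n_repeats, ncol = length(pairs))
  for (r in seq_len(n_repeats)) {
    set.seed(seed * 1000L + r)
    for (pi in seq_along(pairs)) {
      pr <- pairs[[pi]]
      idx <- which(labels %in% pr)
      y <- factor(labels[idx], levels = pr)
      X <- W[idx, , drop = FALSE]
      folds <- stratified_folds(as.character(y), n_folds)
      dv <- numeric(length(idx))
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                          scale = FALSE)
        pred <- stats::predict(fit, X[!tr, , drop = FALSE],
                               decision.values = TRUE)
        d <- drop(attr(pred, "decision.values"))
        # orient decision values toward the second level
        if (startsWith(colnames(attr(pred, "decision.values"))[1],
                       paste0(pr[1], "/")))
          d <- -d
        dv[!tr] <- d
      }
      auc_rep[r, pi] <- auc_score(dv, y == pr[2])
    }
  }
  per_repeat <- rowMeans(auc_rep)
  per_pair <- colMeans(auc_rep)
  names(per_pair) <- vapply(pairs, paste, character(1), collapse = " vs ")
  structure(list(mean_auc = mean(per_repeat), sd_auc = sd(per_repeat),
                 auc_per_repeat = per_repeat, per_pair = per_pair,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: mean AUC %.3f (SD %.3f over %d repeats of %d-fold CV)\n",
              x$mean_auc, x$sd_auc, x$n_repeats, x$n_folds))
  invisible(x)
}

#' Augur-style prioritization of condition-responsive cell types
#'
#' For each cell type, repeatedly subsamples an equal number of cells per
#' condition, trains a cross-validated ridge-regularized logistic classifier
#' on the log-normalized expression of the most variable genes, and records
#' the held-out AUC. Cell types are ranked by mean AUC (higher = more
#' perturbed by the condition). With more than two conditions, AUC is
#' macro-averaged over condition pairs. Types lacking
#' `cells_per_subsample` cells in some condition are excluded with a warning.
#'
#' @param cells a [cell_matrix].
#' @param condition per-cell condition labels (>= 2 levels).
#' @param n_subsamples subsampling repeats per type (default 20).
#' @param cells_per_subsample cells drawn per condition per repeat
#'   (default 50).
#' @param seed integer seed.
#' @param n_hvg highly-variable genes used as features (default 100).
#' @param n_folds cross-validation folds (default 3).
#' @param lambda ridge penalty (default 0.1).
#' @return data.frame sorted by decreasing `mean_auc`: cell_type, mean_auc,
#'   sd_auc, n_subsamples.
#' @export
prioritize_cell_types <- function(cells, condition, n_subsamples = 20L,
                                  cells_per_subsample = 50L, seed = 1L,
                                  n_hvg = 100L, n_folds = 3L, lambda = 0.1) {
  stopifnot(inherits(cells, "cell_matrix"))
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(cells$counts))
  conds <- sort(unique(condition))
  if (length(conds) < 2) stop("need at least 2 conditions", call. = FALSE)
  cond_pairs <- utils::combn(conds, 2, simplify = FALSE)
  types <- sort(unique(cells$meta$cell_type))
  ok <- vapply(types, function(t) {
    all(vapply(conds, function(cc)
      sum(cells$meta$cell_type == t & condition == cc), integer(1)) >=
        cells_per_subsample)
  }, logical(1))
  if (any(!ok))
    warning("excluding type(s) lacking cells: ",
            paste(types[!ok], collapse = ", "), call. = FALSE)
  types <- types[ok]
  if (!length(types)) stop("no evaluable cell types", call. = FALSE)

  x_all <- log_normalize(cells$counts)
  res <- lapply(types, function(t) {
    aucs <- numeric(n_subsamples)
    for (s in seq_len(n_subsamples)) {
      set.seed(seed * 10000L + s * 100L + match(t, types))
      pair_auc <- vapply(cond_pairs, function(pr) {
        idx <- unlist(lapply(pr, function(cc)
          sample(which(cells$meta$cell_type == t & condition == cc),
                 cells_per_subsample)))
        y <- factor(condition[idx], levels = pr)
        X <- x_all[, idx, drop = FALSE]
        v <- apply(X, 1, var)
        X <- t(X[order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(X)))], ,
                 drop = FALSE])
        folds <- stratified_folds(as.character(y), n_folds)
        prob <- numeric(length(idx))
        for (f in seq_len(n_folds)) {
          tr <- folds != f
          fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                                family = "binomial", alpha = 0,
                                lambda = lambda, standardize = TRUE)
          prob[!tr] <- stats::predict(fit, X[!tr, , drop = FALSE],
                                      type = "response")[, 1]
        }
        auc_score(prob, y == pr[2])
      }, numeric(1))
      aucs[s] <- mean(pair_auc)
    }
    data.frame(cell_type = t, mean_auc = mean(aucs), sd_auc = sd(aucs),
               n_subsamples = n_subsamples)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$mean_auc, decreasing = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit] returning the step curve as a
#' data.frame (with the S(0) = 1 anchor). Censored times reduce the risk set
#' without introducing steps.
#'
#' @param times non-negative observed times.
#' @param events 0/1 event flags (1 = death observed).
#' @return data.frame: time, n_risk, n_event, survival.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events must have equal length", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(times), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square over pooled event times via
#' [survival::survdiff], with per-group Kaplan-Meier curves attached. With no
#' events at all the test is degenerate: chi-square 0, p = 1, with a warning.
#'
#' @param times,events as in [km_estimate].
#' @param groups per-subject group labels (>= 2 non-empty groups).
#' @return a `survival_result`: list with `chisq`, `df`, `p_value`, `n` (per
#'   group), `curves` (named list of [km_estimate] frames).
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  curves <- lapply(split(seq_along(times), groups), function(i)
    km_estimate(times[i], events[i]))
  if (sum(events) == 0) {
    warning("no events observed; log-rank test degenerate", call. = FALSE)
    return(structure(list(chisq = 0, df = length(tab) - 1L, p_value = 1,
                          n = tab, curves = curves),
                     class = "survival_result"))
  }
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- pchisq(sd_fit$chisq, df = length(tab) - 1L, lower.tail = FALSE)
  structure(list(chisq = unname(sd_fit$chisq), df = length(tab) - 1L,
                 p_value = p, n = tab, curves = curves),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}
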