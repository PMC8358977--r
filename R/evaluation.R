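#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted one half. Computed
#' from mid-ranks, which is exactly equivalent to trapezoidal integration
#' of the ROC curve.
#'
#' @param labels binary vector (0/1, logical, or factor whose second level
#'   is the positive class)
#' @param scores numeric classifier scores, higher = more positive
#' @return AUC in `[0, 1]`
#' @export
auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  assert_that(length(y) == length(scores), "labels and scores must align")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    as.integer(labels == levels(labels)[length(levels(labels))])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else if (is.character(labels)) {
    as_binary_labels(factor(labels, levels = c("drum", "syllable")))
  } else {
    assert_that(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    as.integer(labels)
  }
}

#' Shuffled k-fold partition
#'
#' Randomly shuffles `n_items` indices and divides them into `k` groups of
#' as-equal-as-possible size (sizes differ by at most one), following the
#' shuffle-then-split cross-validation procedure.
#'
#' @param n_items number of items to partition
#' @param k number of folds (default 5)
#' @param seed integer seed; the partition is deterministic per seed
#' @return list of `k` integer index vectors, disjoint, covering `1:n_items`
#' @export
kfold_split <- function(n_items, k = 5, seed = 1) {
  assert_that(n_items >= k, sprintf("need at least k = %d items", k))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n_items)
  sizes <- rep(n_items %/% k, k)
  extra <- n_items %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  split(idx, rep(seq_len(k), times = sizes))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Binomial significance threshold for binary decoding accuracy
#'
#' For `n` trials and chance level 1/2, finds the smallest correct-response
#' count `c*` whose exact binomial upper-tail probability is below `alpha`,
#' and reports the accuracy percentage strictly above which a score is
#' significant: `100 * (c* - 1) / n`. No normal approximation is used.
#'
#' @param n trial count
#' @param alpha significance level in (0, 1)
#' @return list with `n`, `alpha`, `threshold_pct`, and `min_count`
#'   (the smallest significant correct count `c*`)
#' @export
significance_threshold <- function(n, alpha) {
  assert_that(n >= 1, "n must be at least 1")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  counts <- 0:n
  # upper tail P(X >= c) under Binomial(n, 1/2)
  tail <- pbinom(counts - 1, n, 0.5, lower.tail = FALSE)
  sig <- counts[tail < alpha]
  assert_that(length(sig) > 0, "no attainable significant count")
  cstar <- min(sig)
  list(n = n, alpha = alpha,
       threshold_pct = 100 * (cstar - 1) / n,
       min_count = cstar)
}

#' Rank-sum (Mann-Whitney) test for two independent groups
#'
#' Compares two unpaired groups of scores. `W` is the rank sum of the
#' smaller group (the first group if sizes are equal). For small samples
#' (min group size < 8) without ties the two-sided p-value is exact;
#' otherwise a normal approximation with tie correction is used and `Z`
#' is the standardised statistic.
#'
#' @param group_a,group_b numeric score vectors
#' @return list with `W`, `Z`, `p` (two-sided), and group sizes
#' @export
rank_sum_test <- function(group_a, group_b) {
  assert_that(length(group_a) >= 1 && length(group_b) >= 1,
              "both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b)
  # W is reported for the smaller group
  if (nb < na) { tmp <- group_a; group_a <- group_b; group_b <- tmp
                 tmp <- na; na <- nb; nb <- tmp }
  pooled <- c(group_a, group_b)
  r <- rank(pooled, ties.method = "average")
  W <- sum(r[seq_len(na)])
  N <- na + nb
  mu <- na * (N + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sig2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  Z <- if (sig2 <= 0) 0 else (W - mu) / sqrt(sig2)
  if (min(na, nb) < 8 && tie_term == 0) {
    # exact: U statistic for the smaller group, symmetric two-sided tail
    U <- W - na * (na + 1) / 2
    lo <- pwilcox(U, na, nb)
    hi <- pwilcox(U - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
  } else {
    p <- if (sig2 <= 0) 1 else min(1, 2 * pnorm(-abs(Z)))
  }
  list(W = W, Z = Z, p = p, n_a = na, n_b = nb)
}

#' Cross-validated evaluation of a per-subject decoder
#'
#' Runs shuffled k-fold cross-validation of the chosen model on one
#' subject's epoch set: a fresh model is trained on the k-1 training groups
#' of each fold and scored (ROC-AUC) on the held-out group. The `condition`
#' selects whether improbable epochs are excluded (`"clean"`) or retained
#' (`"all_epochs"`). If a fold's test labels are single-class the partition
#' is re-drawn with a perturbed seed (logged via a message).
#'
#' @param epochs an `epoch_set` with both classes; for `condition = "clean"`
#'   its `reject_mask` must be filled
#' @param model `"cnn"`, `"svm"`, or `"dummy"` (a constant-score reference
#'   model, useful to verify the ties-at-chance convention)
#' @param k number of folds
#' @param seed integer seed controlling the shuffle and all model randomness
#' @param condition `"clean"` or `"all_epochs"`
#' @param subject_id identifier copied into the summary
#' @param cnn_config a [cnn_train_config()] (CNN path only)
#' @param svm_config a [svm_config()] (SVM path only)
#' @return a `cv_summary`: per-fold AUCs, their mean and sample SD,
#'   plus bookkeeping fields
#' @export
run_cv <- function(epochs, model = c("svm", "cnn", "dummy"), k = 5,
                   seed = 1, condition = c("clean", "all_epochs"),
                   subject_id = "s01",
                   cnn_config = cnn_train_config(),
                   svm_config = default_svm_config()) {
  model <- match.arg(model)
  condition <- match.arg(condition)
  if (condition == "clean") {
    assert_that(!is.null(epochs$reject_mask),
                "clean condition requires a filled reject_mask")
    epochs <- epochs[!epochs$reject_mask]
  }
  n <- n_epochs(epochs)
  y <- as_binary_labels(epochs$labels)
  assert_that(length(unique(y)) == 2, "both classes must be present")

  folds <- kfold_split(n, k, seed)
  for (attempt in 1:20) {
    degenerate <- vapply(folds, function(te) length(unique(y[te])) < 2, logical(1))
    if (!any(degenerate)) break
    message("re-drawing k-fold partition: fold with single-class test labels")
    folds <- kfold_split(n, k, derive_seed(seed, "redraw", attempt))
  }

  fold_auc <- numeric(k)
  for (j in seq_len(k)) {
    te <- folds[[j]]
    tr <- setdiff(seq_len(n), te)
    scores <- fit_and_score(model, epochs, tr, te,
                            seed = derive_seed(seed, subject_id, condition, "fold", j),
                            cnn_config = cnn_config, svm_config = svm_config)
    fold_auc[j] <- auc(y[te], scores)
  }
  cv_summary(fold_auc, subject_id = subject_id, model = model,
             condition = condition, seed = seed,
             site = attr(epochs, "site_label") %||% "A")
}

# Train on epochs[tr], return decoder scores for epochs[te].
fit_and_score <- function(model, epochs, tr, te, seed, cnn_config, svm_config) {
  switch(model,
    dummy = rep(0, length(te)),
    svm = {
      fit <- svm_pipeline_fit(epochs[tr], config = svm_config)
      svm_pipeline_score(fit, epochs[te])
    },
    cnn = {
      norm <- minmax_transform(epochs$data[tr, , , drop = FALSE])
      xtr <- apply_minmax(norm, epochs$data[tr, , , drop = FALSE])
      xte <- apply_minmax(norm, epochs$data[te, , , drop = FALSE])
      ytr <- as_binary_labels(epochs$labels[tr])
      cfg <- cnn_config
      cfg$rng_seed <- seed
      fit <- train_cnn(xtr, ytr, config = cfg)
      predict_proba(fit, xte)
    })
}

#' Per-subject cross-validation summary
#'
#' @param fold_auc numeric vector of per-fold AUC scores
#' @param subject_id,model,condition,seed,site bookkeeping fields
#' @return a `cv_summary` object
#' @export
cv_summary <- function(fold_auc, subject_id = "s01", model = "svm",
                       condition = "clean", seed = NA, site = "A") {
  structure(list(fold_auc = fold_auc,
                 mean_auc = mean(fold_auc),
                 sd_auc = sd(fold_auc),
                 k = length(fold_auc),
                 subject_id = subject_id, model = model,
                 condition = condition, seed = seed, site = site),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %s / %s / %s: mean AUC %.3f (SD %.3f) over %d folds\n",
              x$subject_id, x$model, x$condition, x$mean_auc, x$sd_auc, x$k))
  invisible(x)
}

#' Clean-versus-noisy robustness experiment for one subject
#'
#' Runs the identical cross-validation protocol twice on one subject's
#' data — once on the clean view (improbable epochs excluded) and once on
#' all epochs — and reports both summaries plus the AUC difference
#' (clean minus all-epochs; positive = performance degrades when noisy
#' epochs are retained).
#'
#' @inheritParams run_cv
#' @return list with elements `clean`, `all_epochs` (both `cv_summary`)
#'   and `degradation` (mean clean AUC minus mean all-epochs AUC)
#' @export
robustness_experiment <- function(epochs, model = c("svm", "cnn"), k = 5,
                                  seed = 1, subject_id = "s01",
                                  cnn_config = cnn_train_config(),
                                  svm_config = default_svm_config()) {
  model <- match.arg(model)
  assert_that(!is.null(epochs$reject_mask),
              "robustness experiment requires a filled reject_mask")
  assert_that(any(!epochs$reject_mask), "clean epoch set is empty")
  clean <- run_cv(epochs, model, k, seed, "clean", subject_id,
                  cnn_config, svm_config)
  noisy <- run_cv(epochs, model, k, seed, "all_epochs", subject_id,
                  cnn_config, svm_config)
  list(clean = clean, all_epochs = noisy,
       degradation = clean$mean_auc - noisy$mean_auc)
}

#' Tabulate a cohort of cross-validation summaries
#'
#' Builds the cohort-level report: one row per subject x model x condition
#' with fold AUCs, mean and SD; cohort mean/SD per model and condition;
#' binomial significance thresholds; and, when two recording sites are
#' present, a rank-sum comparison of per-subject mean AUCs between sites.
#'
#' @param summaries list of `cv_summary` objects
#' @param n_trials trial count used for the binomial thresholds
#'   (default 100)
#' @param alphas significance levels to annotate
#' @return list with `table` (data.frame), `cohort` (data.frame of
#'   per-model/condition means), `thresholds`, and `site_test` (or `NULL`
#'   when only one site is present)
#' @export
cohort_report <- function(summaries, n_trials = 100, alphas = c(0.05, 1e-4)) {
  assert_that(length(summaries) >= 1, "at least one summary required")
  rows <- lapply(summaries, function(s) {
    data.frame(subject_id = s$subject_id, model = s$model,
               condition = s$condition, site = s$site,
               mean_auc = s$mean_auc, sd_auc = s$sd_auc, k = s$k,
               fold_auc = paste(sprintf("%.4f", s$fold_auc), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cohort <- aggregate(mean_auc ~ model + condition, data = tab,
                      FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  cohort <- do.call(data.frame, cohort)
  names(cohort) <- c("model", "condition", "mean_auc", "sd_auc", "n_subjects")
  thresholds <- lapply(alphas, function(a) significance_threshold(n_trials, a))
  site_test <- NULL
  sites <- unique(tab$site)
  if (length(sites) == 2) {
    a <- tab$mean_auc[tab$site == sites[1]]
    b <- tab$mean_auc[tab$site == sites[2]]
    site_test <- rank_sum_test(a, b)
    site_test$sites <- sites
  }
  list(table = tab, cohort = cohort, thresholds = thresholds,
       site_test = site_test)
}
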