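test_that("AUC matches pair enumeration, symmetry and the ROC-integration oracle", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  set.seed(10)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- round(rnorm(n), sample(0:2, 1))   # induce ties
    a <- auc(y, s)
    expect_equal(a, auc_trapezoid(y, s), tolerance = 1e-12)
    expect_equal(a + auc(y, -s), 1, tolerance = 1e-12)
  }
  expect_error(auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("k-fold partitions are balanced, exhaustive and seed-stable", {
  f <- kfold_split(800, 5, seed = 1)
  expect_equal(lengths(f), rep(160, 5), ignore_attr = TRUE)
  expect_setequal(unlist(f), 1:800)
  f7 <- kfold_split(7, 5, seed = 2)
  expect_equal(sort(lengths(f7), decreasing = TRUE), c(2, 2, 1, 1, 1),
               ignore_attr = TRUE)
  expect_identical(kfold_split(100, 5, seed = 3), kfold_split(100, 5, seed = 3))
  expect_false(identical(kfold_split(100, 5, seed = 3), kfold_split(100, 5, seed = 4)))
  expect_error(kfold_split(4, 5), "at least k")
})

test_that("binomial significance thresholds match exact enumeration", {
  expect_equal(significance_threshold(100, 0.05)$threshold_pct, 58)
  expect_equal(significance_threshold(100, 1e-4)$threshold_pct, 68)
  expect_equal(significance_threshold(10, 0.05)$threshold_pct, 80)
  # brute-force oracle over a range of trial counts; when even a perfect
  # score cannot reach significance (2^-n >= alpha) both must refuse
  for (n in c(1:40, 64, 100, 250, 1000)) {
    for (a in c(0.05, 0.01, 1e-4)) {
      bf <- threshold_bruteforce(n, a)
      if (is.na(bf)) {
        expect_error(significance_threshold(n, a), "no attainable")
      } else {
        th <- significance_threshold(n, a)$threshold_pct
        expect_equal(th, bf, info = sprintf("n=%d alpha=%g", n, a))
      }
    }
  }
  # thresholds live in [50, 100) for alpha < 0.5
  expect_gte(significance_threshold(20, 0.4)$threshold_pct, 50)
  expect_lt(significance_threshold(20, 1e-5)$threshold_pct, 100)
})

test_that("the rank-sum test reproduces exact small-sample and approximate behaviour", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$W, 3)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  # identical groups: Z = 0, p ~ 1
  r0 <- rank_sum_test(rep(2, 10), rep(2, 10))
  expect_equal(r0$Z, 0)
  expect_gte(r0$p, 0.99)
  # normal-approximation branch agrees with the reference implementation
  set.seed(11)
  a <- rnorm(30); b <- rnorm(25, 0.3)
  mine <- rank_sum_test(a, b)
  ref <- wilcox.test(b, a, exact = FALSE, correct = FALSE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  # null calibration: same-distribution groups rarely reach significance
  ps <- vapply(1:20, function(i) {
    set.seed(100 + i)
    rank_sum_test(rnorm(50), rnorm(50))$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  expect_lt(abs(mean(vapply(1:20, function(i) {
    set.seed(200 + i); rank_sum_test(rnorm(50), rnorm(50))$Z
  }, numeric(1)))), 0.75)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("cross-validation returns k fold scores and honours the ties convention", {
  ep <- tiny_epochs(n = 40, nch = 8, ns = 200, seed = 12, signal = 1)
  ep$reject_mask <- rep(FALSE, 40)
  s <- run_cv(ep, "dummy", k = 5, seed = 1, condition = "all_epochs")
  expect_length(s$fold_auc, 5)
  # constant scores tie every pair: AUC exactly 0.5 in every fold
  expect_true(all(s$fold_auc == 0.5))
  expect_equal(s$mean_auc, 0.5)
  expect_equal(s$sd_auc, 0)
  # clean condition needs a mask
  ep2 <- tiny_epochs(n = 20, nch = 8, ns = 200, seed = 13)
  expect_error(run_cv(ep2, "dummy", condition = "clean"), "reject_mask")
})

test_that("the SVM cross-validation pipeline decodes structured epochs", {
  # class signal in the spectral domain: syllable epochs carry a 3 Hz tone
  set.seed(14)
  n <- 60
  x <- array(rnorm(n * 8 * 200), c(n, 8, 200))
  tone <- sin(2 * pi * 3 * seq(0, 2 - 0.01, by = 0.01))
  labs <- rep(c("drum", "syllable"), each = n / 2)
  for (e in which(labs == "syllable")) x[e, , ] <- x[e, , ] + rep(tone, each = 8)
  ep <- epoch_set(x, labs, 100, 2)
  ep$reject_mask <- rep(FALSE, 60)
  s <- run_cv(ep, "svm", k = 5, seed = 2, condition = "clean")
  expect_length(s$fold_auc, 5)
  expect_gte(s$mean_auc, 0.9)
  expect_equal(s$mean_auc, mean(s$fold_auc))
  expect_equal(s$sd_auc, sd(s$fold_auc))
})

test_that("the robustness experiment pairs identical fold policies across conditions", {
  cfg <- small_config(n_repetitions = 120, seed = 15,
                      artifact_channel_count = 0, artifact_transient_rate = 0,
                      evoked_amp_sd = 0, evoked_jitter_ms = 0)
  pp <- preprocess_subject(generate_cohort(1, cfg)[[1]], keep_channels = 12)
  rb <- robustness_experiment(pp$epochs, "svm", seed = 3)
  expect_s3_class(rb$clean, "cv_summary")
  expect_s3_class(rb$all_epochs, "cv_summary")
  expect_equal(rb$degradation, rb$clean$mean_auc - rb$all_epochs$mean_auc)
  # without artifacts the two conditions differ only by masking noise
  expect_lt(abs(rb$degradation), 0.05)
})

test_that("cohort reports count rows, aggregate and compare sites correctly", {
  mk <- function(i, model, cond, site, mu) {
    cv_summary(pmin(pmax(rnorm(5, mu, 0.05), 0), 1),
               subject_id = sprintf("s%02d", i), model = model,
               condition = cond, site = site)
  }
  set.seed(16)
  sums <- list()
  for (i in 1:95) for (m in c("cnn", "svm")) for (cond in c("clean", "all_epochs")) {
    sums[[length(sums) + 1]] <- mk(i, m, cond, if (i > 87) "B" else "A", 0.85)
  }
  rep_ <- cohort_report(sums)
  expect_equal(nrow(rep_$table), 380)               # 95 x 2 x 2
  expect_equal(nrow(rep_$cohort), 4)
  # cohort mean equals the mean of per-subject means
  m_cnn_clean <- rep_$cohort$mean_auc[rep_$cohort$model == "cnn" &
                                      rep_$cohort$condition == "clean"]
  expect_equal(m_cnn_clean,
               mean(rep_$table$mean_auc[rep_$table$model == "cnn" &
                                        rep_$table$condition == "clean"]))
  expect_equal(vapply(rep_$thresholds, `[[`, numeric(1), "threshold_pct"),
               c(58, 68))
  # identical site distributions: the rank-sum comparison is usually null
  pvals <- vapply(1:20, function(r) {
    set.seed(300 + r)
    ss <- list()
    for (i in 1:30) {
      ss[[i]] <- mk(i, "cnn", "clean", if (i > 22) "B" else "A", 0.85)
    }
    cohort_report(ss)$site_test$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})
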