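#' Full experiment configuration
#'
#' One object that fully determines a simulated study: cohort generation,
#' preprocessing thresholds, both model configurations, and the evaluation
#' protocol. A single master seed fans out into every subject- and
#' stage-level random stream, so a config reproduces an experiment
#' exactly.
#'
#' @param n_subjects cohort size (the study cohort was 95)
#' @param seed master seed
#' @param generator a [generator_config()]
#' @param preprocessing list of [preprocess_session()] threshold overrides
#' @param cnn a [cnn_train_config()]
#' @param svm a [svm_config()]
#' @param evaluation list with `k` (folds), `n_trials` and `alphas` for the
#'   significance thresholds
#' @param models character subset of `c("cnn", "svm")`
#' @param conditions character subset of `c("clean", "all_epochs")`
#' @return an `experiment_config`
#' @export
experiment_config <- function(n_subjects = 95, seed = 1,
                              generator = generator_config(rng_seed = seed),
                              preprocessing = list(),
                              cnn = cnn_train_config(),
                              svm = svm_config(),
                              evaluation = list(k = 5, n_trials = 100,
                                                alphas = c(0.05, 1e-4)),
                              models = c("cnn", "svm"),
                              conditions = c("clean", "all_epochs")) {
  structure(list(n_subjects = n_subjects, seed = seed, generator = generator,
                 preprocessing = preprocessing, cnn = cnn, svm = svm,
                 evaluation = evaluation, models = models,
                 conditions = conditions),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' The round trip is lossless: reading a written config reconstructs an
#' identical `experiment_config`.
#'
#' @param config an [experiment_config()]
#' @param path file path
#' @return `read_experiment_config` returns the reconstructed config
#' @export
write_experiment_config <- function(config, path) {
  plain <- list(n_subjects = config$n_subjects, seed = config$seed,
                generator = unclass(config$generator),
                preprocessing = config$preprocessing,
                cnn = unclass(config$cnn),
                svm = c(unclass(config$svm)[c("k_pca", "cost", "log_transform")],
                        list(bands = as.list(config$svm$bands))),
                evaluation = config$evaluation,
                models = as.list(config$models),
                conditions = as.list(config$conditions))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  p <- yaml::read_yaml(path)
  bands <- do.call(data.frame, c(p$svm$bands, stringsAsFactors = FALSE))
  experiment_config(
    n_subjects = p$n_subjects, seed = p$seed,
    generator = do.call(generator_config, p$generator),
    preprocessing = p$preprocessing,
    cnn = do.call(cnn_train_config, p$cnn),
    svm = svm_config(k_pca = p$svm$k_pca, cost = p$svm$cost,
                     log_transform = p$svm$log_transform, bands = bands),
    evaluation = list(k = p$evaluation$k, n_trials = p$evaluation$n_trials,
                      alphas = unlist(p$evaluation$alphas)),
    models = unlist(p$models), conditions = unlist(p$conditions))
}

#' Run the full simulated experiment
#'
#' Generates the synthetic cohort, preprocesses every subject's two
#' sessions, runs the cross-validated CNN and/or SVM decoders in the
#' requested conditions (one independent model per subject per fold —
#' nothing is shared across subjects), and assembles the cohort report. A
#' subject whose processing fails is excluded from the report with the
#' recorded reason, mirroring participant dropout handling.
#'
#' @param config an [experiment_config()]
#' @param progress print per-subject progress messages (default `FALSE`)
#' @return an `experiment_result`: list with `report` (from
#'   [cohort_report()]), `summaries` (all `cv_summary` objects),
#'   `reject_rates` (per subject/session improbable-epoch fractions),
#'   `excluded` (named reasons) and the `config`
#' @export
run_experiment <- function(config = experiment_config(), progress = FALSE) {
  gen <- config$generator
  gen$rng_seed <- config$seed
  cohort <- generate_cohort(config$n_subjects, gen)
  summaries <- list()
  reject_rates <- list()
  excluded <- list()
  for (subj in cohort) {
    if (progress) message("subject ", subj$subject_id)
    res <- tryCatch({
      pp <- do.call(preprocess_subject, c(list(subj), config$preprocessing))
      reject_rates[[subj$subject_id]] <- pp$reject_rates
      for (model in config$models) {
        for (cond in config$conditions) {
          s <- run_cv(pp$epochs, model = model, k = config$evaluation$k,
                      seed = derive_seed(config$seed, subj$subject_id, model),
                      condition = cond, subject_id = subj$subject_id,
                      cnn_config = config$cnn, svm_config = config$svm)
          s$site <- subj$site
          summaries[[length(summaries) + 1]] <- s
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) excluded[[subj$subject_id]] <- res
  }
  report <- if (length(summaries) > 0) {
    cohort_report(summaries, n_trials = config$evaluation$n_trials,
                  alphas = config$evaluation$alphas)
  } else NULL
  structure(list(report = report, summaries = summaries,
                 reject_rates = reject_rates, excluded = excluded,
                 config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d subjects, %d summaries, %d excluded\n",
              x$config$n_subjects, length(x$summaries), length(x$excluded)))
  if (!is.null(x$report)) print(x$report$cohort, row.names = FALSE)
  invisible(x)
}

#' Write an experiment report to CSV and JSON
#'
#' @param result an `experiment_result`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "per_subject.csv")
  write.csv(result$report$table, csv, row.names = FALSE)
  js <- file.path(dir, "cohort.json")
  jsonlite::write_json(
    list(cohort = result$report$cohort,
         thresholds = lapply(result$report$thresholds, function(t)
           t[c("n", "alpha", "threshold_pct")]),
         site_test = result$report$site_test,
         reject_rates = result$reject_rates,
         excluded = result$excluded,
         seed = result$config$seed),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

#' Model-development workflow: early-stopping training histories
#'
#' Runs the CNN in its exploratory configuration (validation split with
#' early stopping on validation AUC) on a small development subset of
#' subjects and returns the per-pass training histories, the material
#' from which training/validation curves are drawn and a fixed training
#' budget is chosen. The main protocol then uses the fixed number of
#' passes (see [cnn_train_config()]).
#'
#' @param cohort list of subjects from [generate_cohort()]
#' @param config a [cnn_train_config()]; early stopping is switched on
#' @param seed master seed
#' @param preprocessing list of [preprocess_subject()] overrides
#' @param out_dir optional directory; if given, one
#'   `history_<subject>.csv` per subject is written
#' @return named list of history data.frames (epoch, loss, val_loss,
#'   val_auc) with an attribute `stopped_at` per subject
#' @export
training_history_experiment <- function(cohort, config = cnn_train_config(
                                          n_epochs = 50, early_stopping = TRUE),
                                        seed = 1, preprocessing = list(),
                                        out_dir = NULL) {
  config$early_stopping <- TRUE
  histories <- list()
  for (subj in cohort) {
    pp <- do.call(preprocess_subject, c(list(subj), preprocessing))
    ep <- pp$epochs[!pp$epochs$reject_mask]
    norm <- minmax_transform(ep$data)
    cfg <- config
    cfg$rng_seed <- derive_seed(seed, subj$subject_id, "dev")
    fit <- train_cnn(apply_minmax(norm, ep$data), ep$labels, cfg)
    h <- fit$history
    attr(h, "stopped_at") <- fit$stopped_at
    histories[[subj$subject_id]] <- h
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(h, file.path(out_dir,
                             sprintf("history_%s.csv", subj$subject_id)),
                row.names = FALSE)
    }
  }
  histories
}
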