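# End-to-end orchestration: synthetic cohort -> spectrogram tensors ->
# leave-one-subject-out training -> evaluation, with a YAML experiment
# configuration and JSON artifacts.

.known_cfg_keys <- list(
  cohort = c("n_subjects", "epochs_per_subject", "stage_dist", "fs",
             "shift_magnitude", "data_dir"),
  model = c("input_size", "widths", "gru_hidden", "head_hidden", "lambda",
            "lambda_schedule", "use_se", "use_discriminator", "profile"),
  training = c("epochs", "batch_size", "lr", "optimizer"),
  evaluation = c("bootstrap_B", "bootstrap_level"),
  top = c("cohort", "model", "training", "evaluation", "seed", "out_dir")
)

#' Read and validate an experiment configuration
#'
#' YAML with sections `cohort`, `model`, `training`, `evaluation` plus a top
#' level `seed`. Unknown keys are errors (typos surface immediately).
#'
#' @param path YAML file path.
#' @return Nested configuration list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
}

#' @rdname read_experiment_config
#' @param cfg A configuration list (as from [yaml::read_yaml()]).
#' @export
validate_experiment_config <- function(cfg) {
  check <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  check(names(cfg), .known_cfg_keys$top, "top level")
  for (sec in c("cohort", "model", "training", "evaluation"))
    if (!is.null(cfg[[sec]]))
      check(names(cfg[[sec]]), .known_cfg_keys[[sec]], sec)
  opt <- cfg$training$optimizer
  if (!is.null(opt) && !identical(tolower(opt), "adam"))
    stop("only the adam optimizer is supported")
  structure(cfg, class = "experiment_config")
}

resolve_model_config <- function(mcfg, seed) {
  mcfg <- mcfg %||% list()
  profile <- mcfg$profile %||% "desk"
  base <- if (identical(profile, "reference")) model_config
          else model_config_desk
  args <- mcfg[setdiff(names(mcfg), "profile")]
  args$seed <- seed
  do.call(base, args)
}

#' Run a full experiment
#'
#' Generates (or reads) the cohort, preprocesses every subject, trains each
#' leave-one-subject-out fold, evaluates on the held-out subject and writes
#' all artifacts (per-fold reports, aggregate summary, training histories,
#' resolved configuration, seed manifest) to the output directory.
#'
#' @param cfg An `experiment_config` (see [read_experiment_config()]), or a
#'   plain list with the same structure.
#' @param out_dir Output directory; overrides `cfg$out_dir`.
#' @param seed Master seed; overrides `cfg$seed`.
#' @param verbose Print progress.
#' @return The aggregate summary (invisibly also written as JSON).
#' @export
run_experiment <- function(cfg, out_dir = NULL, seed = NULL,
                           verbose = FALSE) {
  if (!inherits(cfg, "experiment_config")) cfg <- validate_experiment_config(cfg)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_line <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = file.path(out_dir, "run.log.jsonl"), append = TRUE)
    if (verbose) message("[", stage, "] ", paste(..., collapse = " "))
  }

  ccfg_args <- cfg$cohort[setdiff(names(cfg$cohort), "data_dir")]
  if (!is.null(cfg$cohort$data_dir)) {
    cohort <- read_cohort(cfg$cohort$data_dir)
    log_line("cohort", source = cfg$cohort$data_dir,
             n_subjects = length(cohort))
  } else {
    ccfg_args$seed <- derive_seed(seed, 101L)
    ccfg <- do.call(cohort_config, ccfg_args)
    cohort <- generate_cohort(ccfg)
    log_line("cohort", source = "synthetic", n_subjects = length(cohort))
  }

  epochs <- unlist(lapply(cohort, preprocess_recording), recursive = FALSE)
  log_line("preprocess", n_epochs = length(epochs))

  mcfg <- resolve_model_config(cfg$model, derive_seed(seed, 102L))
  tr <- cfg$training %||% list()
  tcfg <- train_config(epochs = tr$epochs %||% 5L,
                       batch_size = tr$batch_size %||% 16L,
                       lr = tr$lr %||% 2e-5)
  B <- cfg$evaluation$bootstrap_B %||% 200L
  lvl <- cfg$evaluation$bootstrap_level %||% 0.95

  sids <- vapply(cohort, `[[`, integer(1), "subject_id")
  folds <- loso_folds(sids, seed = derive_seed(seed, 103L))
  reports <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    ds <- build_domain_dataset(epochs, fold)
    fit <- train_fold(ds, mcfg, tcfg, seed = fold$seed)
    truth <- vapply(ds$test, `[[`, integer(1), "stage_label")
    pred <- predict_stages(ds$test, fit$params, fit$config)
    rep <- evaluate_predictions(truth, pred, K = mcfg$n_classes,
                                B = B, level = lvl,
                                seed = derive_seed(seed, 104L, f))
    reports[[f]] <- rep
    tag <- sprintf("fold_%02d", f)
    write_eval_report(rep, file.path(out_dir, paste0(tag, "_report.json")))
    data.table::fwrite(fit$history,
                       file.path(out_dir, paste0(tag, "_history.csv")))
    save_checkpoint(fit$params, fit$config,
                    file.path(out_dir, paste0(tag, "_model.rds")))
    log_line("fold", fold = f, test_subject = fold$test_subject,
             accuracy = rep$accuracy)
  }

  summary <- aggregate_folds(reports)
  summary$seed <- seed
  jsonlite::write_json(summary_to_json(summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  resolved <- list(cohort = ccfg_args[setdiff(names(ccfg_args), "signatures")],
                   model = unclass(mcfg), training = unclass(tcfg),
                   evaluation = list(bootstrap_B = B, bootstrap_level = lvl),
                   seed = seed)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  log_line("summary", mean_accuracy = summary$mean_accuracy,
           mean_kappa = summary$mean_kappa)
  invisible(summary)
}

summary_to_json <- function(s) {
  list(mean_accuracy = s$mean_accuracy, mean_macro_f1 = s$mean_macro_f1,
       mean_kappa = s$mean_kappa, fold_accuracy = s$fold_accuracy,
       pooled = list(accuracy = s$pooled$accuracy,
                     macro_f1 = s$pooled$macro_f1,
                     kappa = s$pooled$kappa,
                     confusion = s$pooled$confusion),
       n_folds = s$n_folds, seed = s$seed)
}

#' Write an evaluation report as JSON (+ CSV confusion matrix)
#' @param rep An `eval_report`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(rep, path) {
  out <- list(accuracy = rep$accuracy, macro_f1 = rep$macro_f1,
              kappa = rep$kappa, n = rep$n,
              per_class = rep$per_class, confusion = rep$confusion)
  if (!is.null(rep$ci)) out$ci <- rep$ci[c("lower", "upper", "level", "B")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  data.table::fwrite(data.table::as.data.table(rep$confusion),
                     sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}

#' Domain-generalization efficacy experiment
#'
#' Directional comparison of held-out-subject accuracy with and without the
#' adversarial domain branch, on a synthetic cohort with the default domain
#' shift. For each seed a cohort is generated, one leave-one-subject-out
#' fold is trained twice from the identical initialization -- once with the
#' discriminator + gradient reversal, once without -- and evaluated on the
#' held-out subject.
#'
#' @param n_subjects Cohort size (default 6).
#' @param epochs_per_subject 30-s epochs per subject (default 20).
#' @param train_epochs Training epochs per run (default 30).
#' @param seeds Integer vector of seeds (default 1:5).
#' @param lr Learning rate (desk-scale Adam default 1e-3).
#' @param lambda Adversarial weight (default 1).
#' @param verbose Print per-seed results.
#' @return Data frame with one row per seed: `seed`, `acc_adversarial`,
#'   `acc_plain`.
#' @export
dg_efficacy_experiment <- function(n_subjects = 6L, epochs_per_subject = 20L,
                                   train_epochs = 30L, seeds = 1:5,
                                   lr = 1e-3, lambda = 1.0,
                                   verbose = FALSE) {
  res <- lapply(seeds, function(sd) {
    cc <- cohort_config(n_subjects, epochs_per_subject,
                        seed = derive_seed(sd, 201L))
    cohort <- generate_cohort(cc)
    eps <- unlist(lapply(cohort, preprocess_recording), recursive = FALSE)
    folds <- loso_folds(vapply(cohort, `[[`, integer(1), "subject_id"),
                        seed = sd)
    fold <- folds[[(sd - 1L) %% n_subjects + 1L]]
    ds <- build_domain_dataset(eps, fold)
    truth <- vapply(ds$test, `[[`, integer(1), "stage_label")
    tcfg <- train_config(epochs = train_epochs, lr = lr)
    accs <- vapply(c(TRUE, FALSE), function(use_d) {
      mcfg <- model_config_desk(lambda = lambda, use_discriminator = use_d,
                                seed = sd)
      fit <- train_fold(ds, mcfg, tcfg, seed = sd)
      mean(predict_stages(ds$test, fit$params, fit$config) == truth)
    }, numeric(1))
    if (verbose)
      message(sprintf("seed %d: adversarial %.3f  plain %.3f", sd,
                      accs[1], accs[2]))
    data.frame(seed = sd, acc_adversarial = accs[1], acc_plain = accs[2])
  })
  do.call(rbind, res)
}
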