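#' Run configuration for the reporting commands
#'
#' Bundles the options shared by the `cmd_*` reporting entry points. The
#' full configuration (plus the package version and fixture checksums) is
#' embedded in every report for provenance.
#'
#' @param data `"fixtures"` for the embedded study tables, or a path to a
#'   compound-record CSV (see [read_compound_csv()]).
#' @param model One of `"mlr"`, `"mnlr"`, `"ann"` (refits) or `"reported"`
#'   (the published linear coefficients; no refit).
#' @param terms Descriptor labels. Default [qsar_terms()].
#' @param seed Seed recorded in reports and used by commands with random
#'   components. Default 1.
#' @param out Optional output path; commands write JSON there when set.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data = "fixtures", model = c("mlr", "mnlr", "ann", "reported"),
                       terms = qsar_terms(), seed = 1L, out = NULL) {
  model <- match.arg(model)
  structure(list(data = data, model = model, terms = terms,
                 seed = as.integer(seed), out = out,
                 package_version = as.character(utils::packageVersion("mcf7qsar"))),
            class = "run_config")
}

config_records <- function(config) {
  if (identical(config$data, "fixtures")) {
    ds <- load_study_dataset()
    list(modeling = ds$modeling, dataset = ds)
  } else {
    df <- read_compound_csv(config$data)
    list(modeling = df, dataset = NULL)
  }
}

config_model <- function(config, train) {
  switch(config$model,
    mlr = fit_mlr(train, terms = config$terms),
    mnlr = fit_mnlr(train, terms = config$terms),
    ann = train_ann(train, ann_spec(n_inputs = length(config$terms),
                                    seed = config$seed),
                    terms = config$terms),
    reported = reported_mlr_model())
}

config_predictor <- function(config) {
  switch(config$model, mnlr = predict_mnlr, ann = predict_ann, predict_mlr)
}

finish_report <- function(report, config) {
  report$config <- unclass(config)
  if (!is.null(config$out)) {
    jsonlite::write_json(prune_report(report), config$out,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# drop unserializable closures/lm fits before JSON export
prune_report <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, c("lm", "nnet"))) return(NULL)
  if (is.list(x)) {
    x <- lapply(unclass(x), prune_report)
    x[!vapply(x, is.null, logical(1))]
  } else x
}

#' Fit an activity model and report its statistics
#'
#' Fits the configured model on the training rows of the configured data
#' and returns (optionally writes) a model + statistics report.
#'
#' @param config A [run_config()].
#' @return A list with `model` (the fitted object) and `stats`.
#' @export
cmd_fit <- function(config) {
  rec <- config_records(config)
  train <- rec$modeling[rec$modeling$split == "train", , drop = FALSE]
  model <- config_model(config, train)
  finish_report(list(command = "fit", model = model, stats = model$stats),
                config)
}

#' Cross-validate and externally validate the configured model
#'
#' Runs leave-one-out cross-validation on the training rows, then refits on
#' the full training set, predicts the test rows and applies the
#' Golbraikh-Tropsha battery to the observed/predicted test pairs.
#'
#' @param config A [run_config()]; `model = "reported"` is not refittable
#'   and is rejected.
#' @return A list with `crossval` ([loo_q2()] report) and `external`
#'   ([golbraikh_tropsha()] report).
#' @export
cmd_validate <- function(config) {
  if (config$model == "reported") {
    stop("validation needs a refittable model, not fixed coefficients",
         call. = FALSE)
  }
  rec <- config_records(config)
  m <- rec$modeling
  train <- m[m$split == "train", , drop = FALSE]
  test <- m[m$split == "test", , drop = FALSE]
  if (nrow(test) == 0L) stop("no test rows for external validation", call. = FALSE)

  fit_fun <- function(d) config_model(config, d)
  pred_fun <- config_predictor(config)
  cv <- loo_q2(train, fit_fun, pred_fun)
  model <- fit_fun(train)
  gt <- golbraikh_tropsha(test$pIC50_obs, pred_fun(model, test))
  finish_report(list(command = "validate", crossval = cv, external = gt),
                config)
}

#' Applicability-domain report and Williams-plot data
#'
#' Computes leverages with all modeling compounds as the reference design
#' (the study convention behind h* = 3(p+1)/31), standardizes the residuals
#' of an MLR refit on the training rows by its training RMSE, and returns
#' the Williams-plot data.
#'
#' @param config A [run_config()].
#' @param williams_csv Optional path for a `id,leverage,std_residual,set`
#'   CSV export.
#' @return A list with `leverage` ([leverages()] report) and `williams`
#'   ([williams_data()]).
#' @export
cmd_ad <- function(config, williams_csv = NULL) {
  rec <- config_records(config)
  m <- rec$modeling
  train <- m[m$split == "train", , drop = FALSE]
  fit <- fit_mlr(train, terms = config$terms)
  resid_all <- stats::setNames(m$pIC50_obs - predict_mlr(fit, m),
                               record_ids(m))
  lev <- leverages(m, terms = config$terms)
  wd <- williams_data(lev, resid_all, fit$stats$rmse)
  if (!is.null(williams_csv)) write_williams_csv(wd, williams_csv)
  finish_report(list(command = "ad", leverage = lev, williams = wd), config)
}

#' Predict designed candidates and screen their drug-likeness
#'
#' Applies the configured model (default: the reported linear coefficients)
#' to candidate descriptor rows, flags applicability-domain membership
#' against the modeling design, and, when property rows are available, runs
#' the drug-likeness rule battery.
#'
#' @param config A [run_config()]; with `model = "reported"` the published
#'   coefficients are used directly, otherwise the model is refitted on the
#'   training rows first.
#' @param candidates Candidate records; default the fixture candidates.
#' @param properties Candidate property rows for rule screening; default
#'   the fixture properties when running from fixtures.
#' @return A list with `predictions` ([predict_candidates()]) and
#'   `druglikeness` ([apply_druglikeness_rules()] or `NULL`).
#' @export
cmd_predict <- function(config, candidates = NULL, properties = NULL) {
  rec <- config_records(config)
  if (is.null(candidates)) {
    if (is.null(rec$dataset)) stop("no candidates supplied", call. = FALSE)
    candidates <- rec$dataset$candidates
  }
  if (is.null(properties) && !is.null(rec$dataset)) {
    properties <- rec$dataset$candidate_properties
  }
  train <- rec$modeling[rec$modeling$split == "train", , drop = FALSE]
  model <- if (config$model == "reported") reported_mlr_model()
           else config_model(config, train)
  if (!inherits(model, "qsar_mlr")) {
    stop("candidate prediction uses a linear model ('mlr' or 'reported')",
         call. = FALSE)
  }
  preds <- predict_candidates(model, candidates, rec$modeling)
  rules <- if (!is.null(properties)) apply_druglikeness_rules(properties)
  finish_report(list(command = "predict", predictions = preds,
                     druglikeness = rules), config)
}

#' Generate a synthetic dataset and run a recovery experiment
#'
#' @param config A [run_config()]; its seed overrides the synthetic seed.
#' @param synth A [synthetic_config()].
#' @param n_replicates Replicates for [recovery_experiment()]. Default 25.
#' @return A list with `dataset` and `recovery`.
#' @export
cmd_simulate <- function(config, synth = synthetic_config(),
                         n_replicates = 25L) {
  synth$seed <- config$seed
  dat <- generate_dataset(synth)
  rec <- recovery_experiment(synth, n_replicates)
  finish_report(list(command = "simulate", dataset = dat, recovery = rec),
                config)
}
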