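#' @title File-level pipeline commands
#' @description Thin orchestration layer over the package functions:
#'   featurize structures to a descriptor CSV, train and serialize a
#'   consensus model with its validation reports, predict with
#'   applicability-domain flags, and analyze kinetic measurements from
#'   CSV. Every command is deterministic given (inputs, config, seed).
#'   These functions, together with the `inst/scripts/aoqsar` wrapper,
#'   are the command-line surface of the package.
#' @name pipeline
NULL

#' Read structures from a SMILES or SDF file
#'
#' Dispatches on the file extension: `.sdf` goes through [read_sdf()],
#' anything else is treated as a SMILES file (one structure per line,
#' optional tab-separated id).
#'
#' @param path Input file.
#' @return List of `ao_molecule`.
#' @export
read_structures <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) read_sdf(path)
  else read_smiles_file(path)
}

#' Featurize a structure file to a descriptor CSV
#'
#' Fits a featurizer on the input structures and writes the normalized
#' descriptor matrix (one row per compound, header = feature names, first
#' column `id`). Feature counts by kind are reported via `message()`.
#'
#' @param input SMILES or SDF file.
#' @param output Output CSV path.
#' @param config An [ao_config()].
#' @return The featurizer, invisibly.
#' @export
ao_featurize_file <- function(input, output, config = ao_config()) {
  mols <- read_structures(input)
  if (length(mols) == 0) stop("no structures found in ", input)
  fz <- fit_featurizer(mols, config = config)
  X <- descriptor_matrix(fz, mols)
  message("featurized ", nrow(X), " structures: ",
          paste(sprintf("%s=%d", names(table(attr(X, "kinds"))),
                        table(attr(X, "kinds"))), collapse = ", "))
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, output, row.names = FALSE)
  invisible(fz)
}

#' Train a consensus model from structure and activity files
#'
#' Reads structures and an activity table (CSV with columns `id`,
#' `lgk7`), performs the ranked k:1 split, builds the consensus on the
#' training part, evaluates it on the held-out part, cross-validates by
#' leave-many-out, and writes `model.json` (the ensemble manifest),
#' `test_metrics.json`, `cv_metrics.json` and `config.json` into
#' `out_dir`.
#'
#' @param structures SMILES or SDF file.
#' @param activities CSV with columns `id` and `lgk7`.
#' @param out_dir Output directory (created if missing).
#' @param descriptor_type `"qna"`, `"mna"` or `"combined"`.
#' @param seed Integer seed.
#' @param config An [ao_config()].
#' @param cross_validate Run the leave-many-out CV (default TRUE).
#' @return List with the model and the reports, invisibly.
#' @export
ao_train <- function(structures, activities, out_dir,
                     descriptor_type = "qna", seed = 1L,
                     config = ao_config(), cross_validate = TRUE) {
  mols <- read_structures(structures)
  act <- utils::read.csv(activities, stringsAsFactors = FALSE)
  if (!all(c("id", "lgk7") %in% names(act))) {
    stop("activity table must have columns 'id' and 'lgk7'")
  }
  ids <- vapply(mols, `[[`, "", "id")
  hit <- match(ids, act$id)
  if (any(is.na(hit))) {
    stop("no activity for structure id(s): ",
         paste(utils::head(ids[is.na(hit)], 5), collapse = ", "))
  }
  ds <- activity_dataset(ids, mols, act$lgk7[hit])
  if (length(ds) < 10) stop("insufficient data: need at least 10 compounds")
  sp <- rank_and_split(ds, config$split_ratio)
  model <- build_consensus(sp$train, descriptor_type, seed = seed,
                           config = config)
  pred <- predict_consensus(model, sp$test$molecules)
  test_rep <- compute_metrics(sp$test$lgk7, pred$lgk7_pred,
                              mean(sp$train$lgk7))
  verdict <- classify_predictivity(
    test_rep, diff(range(sp$train$lgk7)))
  cv <- NULL
  if (cross_validate) {
    cv <- cross_validate_lmo(
      sp$train,
      build = function(tr) {
        m <- build_consensus(tr, descriptor_type, seed = seed, config = config)
        function(te) predict_consensus(m, te$molecules)$lgk7_pred
      },
      n_folds = config$cv_folds, holdout_frac = config$cv_holdout,
      seed = seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_model_json(model, file.path(out_dir, "model.json"))
  report_json <- function(rep, path) {
    jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = NA)
  }
  report_json(test_rep, file.path(out_dir, "test_metrics.json"))
  if (!is.null(cv)) report_json(cv$pooled, file.path(out_dir, "cv_metrics.json"))
  jsonlite::write_json(c(unclass(config),
                         list(descriptor_type = descriptor_type, seed = seed)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, test_metrics = test_rep,
                 predictivity = verdict, cv = cv, split = sp))
}

#' Predict activities for a structure file
#'
#' @param model_json Path to a consensus `model.json`.
#' @param structures SMILES or SDF file.
#' @param output Output CSV path (id, lgk7_pred, spread and the
#'   applicability-domain flags).
#' @return The prediction data.frame, invisibly.
#' @export
ao_predict_file <- function(model_json, structures, output) {
  model <- read_model_json(model_json)
  mols <- read_structures(structures)
  if (length(mols) == 0) stop("no structures found in ", structures)
  out <- ao_predict(model, mols)
  utils::write.csv(out, output, row.names = FALSE)
  invisible(out)
}

#' Analyze kinetic measurements from CSV files
#'
#' Reads an initial-rate table (columns `inh_conc`, `rate`) and,
#' optionally, an induction-period table (columns `inh_conc`, `tau`),
#' fits the inhibition model and writes the fit report as JSON. When the
#' tau file is missing the report contains fk7 only (with a warning).
#'
#' @param rates_csv CSV of inhibitor concentration vs initial rate.
#' @param tau_csv Optional CSV of concentration vs induction period.
#' @param output Output JSON path.
#' @param v0,vi,k6 Experiment constants (see [inhibition_experiment()]).
#' @return The `ao_inhibition_fit`, invisibly.
#' @export
ao_kinetics_file <- function(rates_csv, tau_csv = NULL, output,
                             v0, vi, k6) {
  rates <- utils::read.csv(rates_csv, stringsAsFactors = FALSE)
  if (!all(c("inh_conc", "rate") %in% names(rates))) {
    stop("rate table must have columns 'inh_conc' and 'rate' (file ",
         rates_csv, ")")
  }
  taus <- NULL
  if (!is.null(tau_csv)) {
    if (file.exists(tau_csv)) {
      taus <- utils::read.csv(tau_csv, stringsAsFactors = FALSE)
      if (!all(c("inh_conc", "tau") %in% names(taus))) {
        stop("tau table must have columns 'inh_conc' and 'tau' (file ",
             tau_csv, ")")
      }
    } else {
      warning("tau file not found (", tau_csv, "); reporting fk7 only")
    }
  }
  exp <- inhibition_experiment(
    v0 = v0, vi = vi, k6 = k6,
    points = data.frame(inh_conc = rates$inh_conc, v = rates$rate),
    tau_points = if (!is.null(taus)) {
      data.frame(inh_conc = taus$inh_conc, tau = taus$tau)
    })
  fit <- fit_inhibition(exp)
  jsonlite::write_json(unclass(fit), output, auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
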