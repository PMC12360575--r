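#' Resolve a named feature set
#'
#' Feature sets operate at raw-variable granularity; encoded columns are
#' resolved through the catalog. Available sets mirror the model variants of
#' the subgroup evaluation: all variables, the task's seven core variables,
#' the marker alone, everything except the marker, non-laboratory variables,
#' the top-k of a driver ranking, or a custom list.
#'
#' @param catalog A feature catalog.
#' @param name One of `"all"`, `"core7"`, `"marker_only"`,
#'   `"all_minus_marker"`, `"nonlab"`, `"top_k"`, `"custom"`.
#' @param task `"cvd"` or `"diabetes"` (needed for `"core7"`).
#' @param marker Marker variable for the marker-based sets (default
#'   `"HbA1c"`).
#' @param order Character vector of raw variable names in rank order (for
#'   `"top_k"`).
#' @param k Number of top variables to keep (for `"top_k"`).
#' @param vars Custom raw variable list (for `"custom"`).
#' @return An object of class `feature_set` with fields `name`, `vars`
#'   (raw variables) and `columns` (encoded columns).
#' @export
feature_set <- function(catalog,
                        name = c("all", "core7", "marker_only",
                                 "all_minus_marker", "nonlab", "top_k",
                                 "custom"),
                        task = NULL, marker = "HbA1c", order = NULL, k = NULL,
                        vars = NULL) {
  name <- match.arg(name)
  sel <- switch(name,
    all = catalog$name,
    core7 = {
      stopifnot(!is.null(task))
      catalog$name[catalog[[paste0("core7_", task)]]]
    },
    marker_only = marker,
    all_minus_marker = setdiff(catalog$name, marker),
    nonlab = catalog$name[!catalog$is_lab],
    top_k = {
      stopifnot(!is.null(order), !is.null(k))
      utils::head(order, k)
    },
    custom = {
      stopifnot(!is.null(vars))
      vars
    }
  )
  unknown <- setdiff(sel, catalog$name)
  if (length(unknown) > 0)
    abort_elf(paste0("feature set refers to unknown variable(s): ",
                     paste(unknown, collapse = ", ")), "elf_unknown_variable")
  structure(list(name = name, vars = sel,
                 columns = encoded_columns(catalog, sel)),
            class = "feature_set")
}

default_xgb_params <- function() {
  list(max_depth = 3, eta = 0.1, nrounds = 150, subsample = 0.9)
}

sample_xgb_params <- function(seed) {
  set.seed(seed)
  list(max_depth = sample(2:8, 1),
       eta = exp(stats::runif(1, log(0.01), log(0.3))),
       nrounds = sample(50:500, 1),
       subsample = stats::runif(1, 0.5, 1))
}

fit_booster <- function(X, y, params, seed, nthread = 1) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = nthread)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = params$max_depth,
                  eta = params$eta, subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree %||% 1,
                  nthread = nthread, seed = seed,
                  eval_metric = "logloss"),
    data = dtrain, nrounds = params$nrounds, verbose = 0
  )
}

predict_booster <- function(booster, X, type = c("prob", "margin",
                                                 "contrib")) {
  type <- match.arg(type)
  d <- xgboost::xgb.DMatrix(X, nthread = 1)
  switch(type,
         prob = stats::predict(booster, d),
         margin = stats::predict(booster, d, outputmargin = TRUE),
         contrib = stats::predict(booster, d, predcontrib = TRUE))
}

#' Fit the unified gradient-boosted risk model under cross-validation
#'
#' One gradient-boosted tree ensemble per fold, trained on that fold's
#' training rows only. With `budget >= 2`, hyperparameters are tuned by
#' random search over depth 2--8, learning rate 0.01--0.3 (log scale),
#' 50--500 rounds and subsample 0.5--1.0, scored by AUC on an inner
#' stratified 80/20 split of the training rows; trial 1 is always a fixed
#' default configuration (depth 3, eta 0.1, 150 rounds, subsample 0.9) so a
#' budget of 1 skips the search deterministically. A single unified model
#' serves both subgroups; it is never refit per subgroup.
#'
#' @param cohort An encoded `elf_cohort` with `$outcome`.
#' @param fset A [feature_set()] (default: all variables).
#' @param folds Fold assignment from [make_folds()].
#' @param budget Number of hyperparameter trials (>= 1).
#' @param seed Master seed; per-fold and per-trial seeds are derived from it.
#' @param model_name Label carried into metric tables.
#' @return An object of class `elf_risk_fit`: per-fold boosters, chosen
#'   hyperparameters, and out-of-fold probabilities.
#' @export
fit_unified_model <- function(cohort, fset = NULL, folds, budget = 1,
                              seed = 1, model_name = NULL) {
  stopifnot(!is.null(cohort$encoded), !is.null(cohort$outcome), budget >= 1)
  fset <- fset %||% feature_set(cohort$catalog, "all")
  model_name <- model_name %||% fset$name
  X <- cohort$encoded[, fset$columns, drop = FALSE]
  y <- cohort$outcome
  n_folds <- max(folds)
  fits <- vector("list", n_folds)
  chosen <- vector("list", n_folds)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[tr])) < 2)
      abort_elf(sprintf("training split for fold %d has a single class", f),
                "elf_single_class_fold")
    params <- default_xgb_params()
    if (budget >= 2) {
      inner <- make_folds(y[tr], n_folds = 5,
                          seed = derive_seed(seed, "inner", f))
      itr <- tr[inner != 1]; iva <- tr[inner == 1]
      best_auc <- -Inf
      for (trial in seq_len(budget)) {
        cand <- if (trial == 1) default_xgb_params() else
          sample_xgb_params(derive_seed(seed, "trial", f, trial))
        b <- fit_booster(X[itr, , drop = FALSE], y[itr], cand,
                         seed = derive_seed(seed, "fit", f, trial))
        a <- auc_rank(y[iva], predict_booster(b, X[iva, , drop = FALSE]))
        if (!is.na(a) && a > best_auc) { best_auc <- a; params <- cand }
      }
    }
    fits[[f]] <- fit_booster(X[tr, , drop = FALSE], y[tr], params,
                             seed = derive_seed(seed, "final", f))
    chosen[[f]] <- params
    oof[te] <- predict_booster(fits[[f]], X[te, , drop = FALSE])
  }
  structure(list(model_name = model_name, fset = fset, folds = folds,
                 fits = fits, hyperparams = chosen, oof = oof, outcome = y,
                 task = cohort$task, seed = seed,
                 feature_names = fset$columns),
            class = "elf_risk_fit")
}

#' @export
print.elf_risk_fit <- function(x, ...) {
  cat("<elf_risk_fit> model '", x$model_name, "', ", length(x$fits),
      " folds, ", length(x$feature_names), " encoded features\n", sep = "")
  invisible(x)
}

#' Predict risk probabilities from a fitted model
#'
#' Uses the booster of the fold each row was held out from, i.e. every row is
#' scored by a model that did not train on it. Rows outside the cohort raise
#' an error; an empty row set returns an empty vector.
#'
#' @param object An `elf_risk_fit`.
#' @param cohort The cohort the model was fitted on (feature columns must
#'   match).
#' @param rows Integer row indices (default: all rows).
#' @return Probabilities in \[0, 1\], one per requested row.
#' @export
predict_risk <- function(object, cohort, rows = seq_len(n_samples(cohort))) {
  if (length(rows) == 0) return(numeric(0))
  missing_cols <- setdiff(object$feature_names, colnames(cohort$encoded))
  if (length(missing_cols) > 0)
    abort_elf(paste0("cohort lacks model feature(s): ",
                     paste(utils::head(missing_cols, 5), collapse = ", ")),
              "elf_feature_mismatch")
  if (any(rows < 1 | rows > n_samples(cohort)))
    abort_elf("row index outside cohort", "elf_feature_mismatch")
  object$oof[rows]
}

#' Single-variable risk models
#'
#' Fits one gradient-boosted model per raw catalog variable (using the
#' variable's encoded column or columns) with the fixed default
#' configuration, and evaluates AUC-ROC separately on the comorbid and
#' non-comorbid rows of each test fold, averaged over folds. A variable
#' that is constant yields AUC 0.5 with a warning.
#'
#' @param cohort An encoded, subgroup-labelled `elf_cohort`.
#' @param folds Fold assignment from [make_folds()].
#' @param seed Master seed.
#' @param vars Raw variables to score (default: all in the catalog).
#' @return A driver tibble with one row per variable x subgroup:
#'   `feature`, `category`, `subgroup`, `score` (mean AUC), `rank`.
#' @export
single_variable_models <- function(cohort, folds, seed = 1,
                                   vars = cohort$catalog$name) {
  stopifnot(!is.null(cohort$encoded), !is.null(cohort$comorbid))
  catalog <- cohort$catalog
  y <- cohort$outcome
  n_folds <- max(folds)
  params <- list(max_depth = 2, eta = 0.1, nrounds = 60, subsample = 1)
  res <- purrr::map_dfr(vars, function(nm) {
    cols <- encoded_columns(catalog, nm)
    X <- cohort$encoded[, cols, drop = FALSE]
    if (all(apply(X, 2, function(col) length(unique(col)) == 1))) {
      warning("variable ", nm, " is constant; AUC fixed at 0.5")
      return(tibble::tibble(feature = nm,
                            category = catalog$category[catalog$name == nm],
                            subgroup = c("comorbid", "non_comorbid"),
                            score = 0.5))
    }
    aucs <- matrix(NA_real_, n_folds, 2,
                   dimnames = list(NULL, c("comorbid", "non_comorbid")))
    for (f in seq_len(n_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      b <- fit_booster(X[tr, , drop = FALSE], y[tr], params,
                       seed = derive_seed(seed, "sv", nm, f))
      p <- predict_booster(b, X[te, , drop = FALSE])
      for (sg in c(TRUE, FALSE)) {
        keep <- cohort$comorbid[te] == sg
        aucs[f, if (sg) "comorbid" else "non_comorbid"] <-
          auc_rank(y[te][keep], p[keep])
      }
    }
    tibble::tibble(feature = nm,
                   category = catalog$category[catalog$name == nm],
                   subgroup = c("comorbid", "non_comorbid"),
                   score = c(mean(aucs[, "comorbid"], na.rm = TRUE),
                             mean(aucs[, "non_comorbid"], na.rm = TRUE)))
  })
  res |>
    dplyr::group_by(.data$subgroup) |>
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(), metric = "single_var_auc") |>
    dplyr::ungroup()
}

#' Score a cohort with an external coefficient-based risk score
#'
#' Pluggable stand-in for published clinical scores: a named coefficient
#' vector, an intercept and a link applied to the encoded features.
#'
#' @param cohort An encoded `elf_cohort`.
#' @param score_spec List with `coefficients` (named numeric over encoded
#'   columns), `intercept`, and `link` (`"logistic"` default or
#'   `"identity"`).
#' @return Per-sample risk values (probabilities under the logistic link).
#' @export
external_score <- function(cohort, score_spec) {
  stopifnot(!is.null(cohort$encoded))
  coefs <- score_spec$coefficients %||% numeric()
  missing_vars <- setdiff(names(coefs), colnames(cohort$encoded))
  if (length(missing_vars) > 0)
    abort_elf(paste0("score variable(s) absent from cohort: ",
                     paste(missing_vars, collapse = ", ")),
              "elf_missing_score_variable")
  lp <- rep(score_spec$intercept %||% 0, n_samples(cohort))
  if (length(coefs) > 0)
    lp <- lp + as.numeric(cohort$encoded[, names(coefs), drop = FALSE] %*%
                            coefs)
  switch(score_spec$link %||% "logistic",
         logistic = sigmoid(lp),
         identity = lp,
         abort_elf("unknown link", "elf_missing_score_variable"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-fold summary of a fitted risk model
#'
#' @param x An `elf_risk_fit`.
#' @param ... Unused.
#' @return One row per fold: chosen hyperparameters and out-of-fold AUC and
#'   Brier score.
#' @export
tidy.elf_risk_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$fits), function(f) {
    te <- which(x$folds == f)
    hp <- x$hyperparams[[f]]
    tibble::tibble(fold = f, max_depth = hp$max_depth, eta = hp$eta,
                   nrounds = hp$nrounds, subsample = hp$subsample,
                   auc = auc_rank(x$outcome[te], x$oof[te]),
                   brier = brier_score(x$outcome[te], x$oof[te]))
  })
}

#' One-line summary of a fitted risk model
#'
#' @param x An `elf_risk_fit`.
#' @param ... Unused.
#' @export
glance.elf_risk_fit <- function(x, ...) {
  out <- tibble::tibble(model = x$model_name, n_folds = length(x$fits),
                        n_features = length(x$feature_names))
  out$auc <- auc_rank(x$outcome, x$oof)
  out$brier <- brier_score(x$outcome, x$oof)
  out
}
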