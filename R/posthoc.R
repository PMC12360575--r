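#' Stratify a cohort at a marker's population mean
#'
#' Splits samples into a low-normal stratum (marker strictly below the
#' whole-cohort mean) and a high-normal stratum (at or above the mean; a
#' value exactly at the mean goes to the high stratum). The threshold is the
#' mean over the entire cohort, not per fold or per subgroup.
#'
#' @param cohort An `elf_cohort`.
#' @param marker A continuous, complete raw variable name (default
#'   `"HbA1c"`).
#' @return A list with `low` and `high` (`elf_cohort` subsets) and
#'   `threshold`.
#' @export
stratify_by_marker <- function(cohort, marker = "HbA1c") {
  x <- as.numeric(cohort$raw[[marker]])
  stopifnot(!anyNA(x))
  if (stats::sd(x) == 0)
    abort_elf("marker is constant; stratification undefined",
              "elf_constant_marker")
  thr <- mean(x)
  list(low = subset_cohort(cohort, x < thr),
       high = subset_cohort(cohort, x >= thr),
       threshold = thr)
}

#' Marker-stratified model comparison in the comorbid subgroup
#'
#' Restricts the cohort to its comorbid rows, stratifies at the marker's
#' whole-cohort mean, and evaluates each model variant within each stratum
#' under its own stratified cross-validation (AUC mean +/- sd across folds).
#'
#' @param cohort An encoded, subgroup-labelled `elf_cohort`.
#' @param variants Named list of [feature_set()] specifications given as
#'   either `feature_set` objects or set names (resolved against the cohort's
#'   catalog and task); external probability vectors over all cohort rows are
#'   also accepted (evaluated, not refitted, within each stratum's folds).
#' @param marker Stratifying marker (default `"HbA1c"`).
#' @param n_folds Cross-validation folds per stratum (default 5).
#' @param budget Hyperparameter trials per fit (default 1).
#' @param seed Master seed.
#' @return A tibble: `variant`, `stratum`, `auc_mean`, `auc_sd`, `n`.
#' @export
stratified_model_comparison <- function(cohort, variants, marker = "HbA1c",
                                        n_folds = 5, budget = 1, seed = 1) {
  stopifnot(!is.null(cohort$comorbid))
  strata <- stratify_by_marker(cohort, marker)
  sub <- list(low = subset_cohort(strata$low, strata$low$comorbid),
              high = subset_cohort(strata$high, strata$high$comorbid))
  purrr::imap_dfr(variants, function(v, nm) {
    purrr::imap_dfr(sub, function(s, stratum) {
      folds <- make_folds(s, n_folds = n_folds,
                          seed = derive_seed(seed, "strat", stratum))
      if (is.numeric(v)) {
        p <- v[match(s$sample_ids, cohort$sample_ids)]
        aucs <- vapply(seq_len(n_folds), function(f) {
          te <- folds == f
          auc_rank(s$outcome[te], p[te])
        }, 0.0)
      } else {
        fs <- if (inherits(v, "feature_set")) v else
          feature_set(s$catalog, v, task = s$task, marker = marker)
        fit <- fit_unified_model(s, fs, folds, budget = budget,
                                 seed = derive_seed(seed, "fit", nm, stratum))
        aucs <- vapply(seq_len(n_folds), function(f) {
          te <- folds == f
          auc_rank(s$outcome[te], fit$oof[te])
        }, 0.0)
      }
      tibble::tibble(variant = nm, stratum = stratum,
                     auc_mean = mean(aucs, na.rm = TRUE),
                     auc_sd = stats::sd(aucs, na.rm = TRUE),
                     n = n_samples(s))
    })
  })
}

#' Incremental feature curve
#'
#' Starting from a base feature set, adds raw variables one at a time in the
#' given ranking order (base variables are excluded from the queue), refits
#' the cross-validated model after each addition, and records per-subgroup
#' AUC. The plateau point is the first position where `window` consecutive
#' marginal gains (on the comorbid curve) fall below `eps`.
#'
#' @param cohort An encoded, subgroup-labelled `elf_cohort`.
#' @param base A [feature_set()] or raw-variable character vector to start
#'   from.
#' @param order Character vector of raw variables in ranking order (e.g. a
#'   PFI table's `feature` column), or a driver tibble with `feature`.
#' @param folds Fold assignment from [make_folds()].
#' @param seed Master seed.
#' @param budget Hyperparameter trials per fit (default 1).
#' @param eps Marginal-gain threshold for the plateau rule (default 0.002).
#' @param window Consecutive sub-threshold gains required (default 3).
#' @param max_add Cap on the number of additions (default: all).
#' @return A tibble with one row per step x subgroup: `step`,
#'   `added`, `n_vars`, `subgroup`, `auc`; attribute `"plateau"` holds the
#'   plateau step (NA if never reached).
#' @export
incremental_feature_curve <- function(cohort, base, order, folds, seed = 1,
                                      budget = 1, eps = 0.002, window = 3,
                                      max_add = Inf) {
  base_vars <- if (inherits(base, "feature_set")) base$vars else base
  if (is.data.frame(order)) order <- order$feature
  queue <- setdiff(order, base_vars)
  if (is.finite(max_add)) queue <- utils::head(queue, max_add)
  steps <- c(list(base_vars),
             lapply(seq_along(queue), function(i) c(base_vars,
                                                    queue[seq_len(i)])))
  res <- purrr::map_dfr(seq_along(steps), function(i) {
    fs <- feature_set(cohort$catalog, "custom", vars = steps[[i]])
    fit <- fit_unified_model(cohort, fs, folds, budget = budget,
                             seed = derive_seed(seed, "incr", i))
    ev <- evaluate_subgroups(list(step = fit), cohort, folds)
    tibble::tibble(step = i - 1L,
                   added = if (i == 1) NA_character_ else queue[i - 1L],
                   n_vars = length(steps[[i]]),
                   subgroup = ev$subgroup, auc = ev$auc_mean)
  })
  gains <- res |>
    dplyr::filter(.data$subgroup == "comorbid") |>
    dplyr::arrange(.data$step) |>
    dplyr::mutate(gain = .data$auc - dplyr::lag(.data$auc))
  plateau <- NA_integer_
  g <- gains$gain[-1]
  if (length(g) >= window) {
    run <- stats::filter(abs(g) < eps, rep(1, window), sides = 1)
    hit <- which(run == window)
    if (length(hit) > 0) plateau <- gains$step[hit[1] + 1L]
  }
  attr(res, "plateau") <- plateau
  res
}

#' ELF contribution shares per model variant
#'
#' For each driver table (one per model variant x metric, computed on the
#' comorbid subgroup), the ELF share is 100 x the summed scores of
#' ELF-category variables over the summed scores of all variables, with
#' negative PFI scores clipped to 0 before summation so shares stay in
#' \[0, 100\]. Gains are reported against the all-variables baseline in
#' percentage points and as percent of the baseline value.
#'
#' @param tables A named list of driver tibbles; names are variant labels
#'   (must include `baseline`).
#' @param baseline Name of the baseline variant (default `"all_vars"`).
#' @return A tibble: `variant`, `metric`, `elf_share`, `gain_abs`,
#'   `gain_rel`.
#' @export
elf_contribution_shares <- function(tables, baseline = "all_vars") {
  stopifnot(baseline %in% names(tables))
  shares <- purrr::imap_dfr(tables, function(tab, nm) {
    s <- pmax(tab$score, 0)
    s[is.na(s)] <- 0
    total <- sum(s)
    if (total == 0)
      abort_elf(paste0("all driver scores zero for variant ", nm),
                "elf_zero_total")
    tibble::tibble(variant = nm,
                   metric = tab$metric[1],
                   elf_share = 100 * sum(s[tab$category == "ELF"]) / total)
  })
  base <- shares$elf_share[shares$variant == baseline]
  shares |>
    dplyr::mutate(gain_abs = .data$elf_share - base,
                  gain_rel = 100 * (.data$elf_share - base) / base)
}

#' Run the full subgroup evaluation pipeline
#'
#' Generates (or accepts) a cohort, fits the all-variables and core-7 risk
#' models under stratified cross-validation, and assembles the table
#' families of the analysis: subgroup metrics, decision curves, Bayes-error
#' bounds, driver tables (single-variable AUC, PFI, Shapley importance,
#' effect size), the marker-stratified comparison, the incremental feature
#' curve, and ELF contribution shares. Every table is written as tidy CSV
#' under `out_dir`, alongside a JSON manifest recording the configuration,
#' seeds and package version. Identical configs produce identical outputs.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param cohort Optionally a pre-built encoded, labelled cohort (skips
#'   generation).
#' @param components Character vector of optional stages to run; any of
#'   `"bounds"`, `"drivers"`, `"posthoc"`, `"decision_curve"`,
#'   `"incremental"` (the capped incremental feature curve; requires
#'   `"posthoc"`).
#' @param budget Hyperparameter trials per fit.
#' @param pfi_repeats Permutation repeats for PFI tables.
#' @param knn_set Variable set for the k-NN bounds (default `"core7"`).
#' @param top_k Variables in the reduced top-k variant (default 25).
#' @return A named list of result tibbles plus the manifest, invisibly
#'   written to `out_dir` when given.
#' @export
run_full_analysis <- function(config, out_dir = NULL, cohort = NULL,
                              components = c("bounds", "drivers", "posthoc",
                                             "decision_curve"),
                              budget = 1, pfi_repeats = 10,
                              knn_set = "core7", top_k = 25) {
  seed <- config$seed
  cohort <- cohort %||% generate_cohort(config)
  folds <- make_folds(cohort, n_folds = 5, seed = derive_seed(seed, "folds"))
  catalog <- cohort$catalog

  fit_all <- fit_unified_model(cohort, feature_set(catalog, "all"), folds,
                               budget = budget,
                               seed = derive_seed(seed, "all"),
                               model_name = "all_vars")
  fit_core7 <- fit_unified_model(cohort,
                                 feature_set(catalog, "core7",
                                             task = cohort$task),
                                 folds, budget = budget,
                                 seed = derive_seed(seed, "core7"),
                                 model_name = "core7")
  models <- list(all_vars = fit_all, core7 = fit_core7)
  out <- list(metrics = evaluate_subgroups(models, cohort, folds))

  if ("decision_curve" %in% components)
    out$decision_curves <- decision_curve(cohort, models)

  if ("bounds" %in% components)
    out$bounds <- bounds_report(cohort, sets = c(knn_set),
                                seed = derive_seed(seed, "bounds"))

  if ("drivers" %in% components) {
    out$drivers_singlevar <- single_variable_models(
      cohort, folds, seed = derive_seed(seed, "sv"))
    out$drivers_pfi <- dplyr::bind_rows(
      permutation_importance(fit_all, cohort, "comorbid",
                             repeats = pfi_repeats,
                             seed = derive_seed(seed, "pfi_c")),
      permutation_importance(fit_all, cohort, "non_comorbid",
                             repeats = pfi_repeats,
                             seed = derive_seed(seed, "pfi_nc")))
    out$drivers_shap <- dplyr::bind_rows(
      shap_importance(fit_all, cohort, "comorbid"),
      shap_importance(fit_all, cohort, "non_comorbid"))
    out$drivers_effectsize <- dplyr::bind_rows(
      effect_size_drivers(fit_all, cohort, "comorbid"),
      effect_size_drivers(fit_all, cohort, "non_comorbid"))
  }

  if ("posthoc" %in% components) {
    stopifnot("drivers" %in% components)
    out$posthoc_stratified <- stratified_model_comparison(
      cohort,
      variants = list(core7 = "core7", marker_only = "marker_only",
                      all_minus_marker = "all_minus_marker",
                      all_vars = "all"),
      budget = budget, seed = derive_seed(seed, "posthoc"))
    pfi_c <- out$drivers_pfi |> dplyr::filter(.data$subgroup == "comorbid")
    fs_topk <- feature_set(catalog, "top_k", order = pfi_c$feature, k = top_k)
    fit_topk <- fit_unified_model(cohort, fs_topk, folds, budget = budget,
                                  seed = derive_seed(seed, "topk"),
                                  model_name = "top_k")
    fit_nonlab <- fit_unified_model(cohort, feature_set(catalog, "nonlab"),
                                    folds, budget = budget,
                                    seed = derive_seed(seed, "nonlab"),
                                    model_name = "nonlab")
    out$metrics <- dplyr::bind_rows(
      out$metrics,
      evaluate_subgroups(list(top_k = fit_topk, nonlab = fit_nonlab),
                         cohort, folds))
    variant_fits <- list(all_vars = fit_all, top_k = fit_topk,
                         nonlab = fit_nonlab)
    shares <- purrr::map_dfr(
      c(pfi = "pfi", shap = "shap", effect_size = "effect_size"),
      function(metric) {
        tabs <- purrr::map(variant_fits, function(ft) switch(
          metric,
          pfi = permutation_importance(ft, cohort, "comorbid",
                                       repeats = pfi_repeats,
                                       seed = derive_seed(seed, "share")),
          shap = shap_importance(ft, cohort, "comorbid"),
          effect_size = effect_size_drivers(ft, cohort, "comorbid")))
        elf_contribution_shares(tabs)
      })
    out$elf_shares <- shares
    if ("incremental" %in% components) {
      base <- feature_set(catalog, "custom",
                          vars = c(catalog$name[catalog[[paste0(
                                     "core7_", cohort$task)]]],
                                   catalog$name[catalog$category == "ELF"]))
      out$incremental_curve <- incremental_feature_curve(
        cohort, base, pfi_c$feature, folds,
        seed = derive_seed(seed, "incr"), budget = budget, max_add = 15)
    }
  }

  out$manifest <- list(
    package = "elfrisk",
    version = as.character(utils::packageVersion("elfrisk")),
    config = unclass(config),
    components = components,
    budget = budget, pfi_repeats = pfi_repeats, top_k = top_k
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(out), "manifest"))
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
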