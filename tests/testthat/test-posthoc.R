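test_that("marker stratification splits at the population mean", {
  catalog <- tiny_catalog()
  raw <- tibble::tibble(age = c(1, 2, 3, 4), sex = c(0, 1, 0, 1),
                        colour = c("red", "red", "blue", "green"),
                        flag = c(0, 1, 0, 1))
  co <- cohort_from_raw(raw, catalog)
  s <- stratify_by_marker(co, "age")
  expect_equal(s$threshold, 2.5)
  expect_equal(s$low$raw$age, c(1, 2))
  expect_equal(s$high$raw$age, c(3, 4))
  expect_equal(n_samples(s$low) + n_samples(s$high), 4)
  # a value exactly at the mean joins the high stratum
  raw2 <- raw
  raw2$age <- c(1, 2, 3, 2)  # mean 2: sample 2 and 4 sit exactly at it
  co2 <- cohort_from_raw(raw2, catalog)
  s2 <- stratify_by_marker(co2, "age")
  expect_equal(s2$low$raw$age, 1)
  expect_equal(sort(s2$high$raw$age), c(2, 2, 3))
  co3 <- co
  co3$raw$age <- rep(1, 4)
  expect_error(stratify_by_marker(co3, "age"), class = "elf_constant_marker")
})

test_that("piecewise marker coupling is recovered by stratified comparison", {
  # marker-only model: near-chance AUC in the low stratum (flat coupling
  # below the mean), clearly predictive in the high stratum
  cfg <- generator_config(n_samples = 16000, seed = 17)
  co <- generate_cohort(cfg)
  res <- stratified_model_comparison(
    co, variants = list(marker_only = "marker_only", core7 = "core7",
                        all_vars = "all"),
    seed = 2)
  m_low <- res$auc_mean[res$variant == "marker_only" & res$stratum == "low"]
  m_high <- res$auc_mean[res$variant == "marker_only" & res$stratum == "high"]
  expect_lt(abs(m_low - 0.5), 0.06)
  expect_gt(m_high, m_low + 0.05)
  # all-variables model keeps performing in the low stratum without the
  # marker's help
  a_low <- res$auc_mean[res$variant == "all_vars" & res$stratum == "low"]
  expect_gt(a_low, m_low + 0.05)
})

test_that("removing a signal-free marker leaves the model unchanged", {
  cfg <- generator_config(n_samples = 8000, seed = 23, marker_coupling = 0)
  co <- generate_cohort(cfg)
  folds <- make_folds(co, seed = 1)
  fit_all <- fit_unified_model(co, NULL, folds, seed = 3)
  fit_minus <- fit_unified_model(co, feature_set(co$catalog,
                                                 "all_minus_marker"),
                                 folds, seed = 3)
  a <- auc_rank(co$outcome, fit_all$oof)
  b <- auc_rank(co$outcome, fit_minus$oof)
  expect_lt(abs(a - b), 0.01)
})

test_that("incremental curve detects the designed plateau", {
  # 4 informative + many null variables: adding nulls after the signal
  # variables moves AUC by less than the plateau threshold
  catalog <- default_catalog()
  cfg <- generator_config(n_samples = 6000, seed = 29)
  co <- generate_cohort(cfg)
  co$comorbid[] <- TRUE  # evaluate the curve on the whole cohort
  folds <- make_folds(co, n_folds = 3, seed = 1)
  base <- c("Age", "Glucose", "WaistCircumference", "HbA1c")
  nulls <- c("Height", "PulseRate", "VitaminD", "Creatinine", "CerealIntake",
             "WaterIntake")
  # eps sits above the cross-validated refit jitter at this cohort size so
  # that only genuine signal would defer the plateau
  curve <- incremental_feature_curve(co, base, nulls, folds, seed = 2,
                                     eps = 0.02)
  expect_equal(attr(curve, "plateau"), 3)
  com <- curve[curve$subgroup == "comorbid", ]
  expect_equal(nrow(com), length(nulls) + 1)
  # null additions never move AUC much
  gains <- diff(com$auc[order(com$step)])
  expect_true(all(abs(gains) < 0.02))
})

test_that("incremental curve endpoint matches the same-universe model", {
  cfg <- generator_config(n_samples = 6000, seed = 37)
  co <- generate_cohort(cfg)
  co$comorbid[] <- TRUE  # whole-cohort curve: endpoint comparison is stable
  folds <- make_folds(co, n_folds = 3, seed = 2)
  catalog <- co$catalog
  vars <- catalog$name
  base <- vars[1:60]
  curve <- incremental_feature_curve(co, base, vars, folds, seed = 3)
  fit_all <- fit_unified_model(co, NULL, folds, seed = 3)
  ev <- evaluate_subgroups(list(all = fit_all), co, folds)
  endpoint <- curve$auc[curve$subgroup == "comorbid" &
                          curve$step == max(curve$step)]
  expect_lt(abs(endpoint - ev$auc_mean[ev$subgroup == "comorbid"]), 0.01)
})

test_that("ELF share arithmetic and gains are exact", {
  mk <- function(metric, scores, elf_idx) {
    tibble::tibble(feature = paste0("v", seq_along(scores)),
                   category = ifelse(seq_along(scores) %in% elf_idx,
                                     "ELF", "lifestyle"),
                   subgroup = "comorbid", score = scores, metric = metric)
  }
  # equal scores over 10 variables, 2 of them ELFs -> share 20%
  tabs <- list(all_vars = mk("pfi", rep(1, 10), 1:2),
               top_k = mk("pfi", c(rep(1, 4), rep(0, 6)), 1:2))
  sh <- elf_contribution_shares(tabs)
  expect_equal(sh$elf_share[sh$variant == "all_vars"], 20)
  expect_equal(sh$elf_share[sh$variant == "top_k"], 50)
  expect_equal(sh$gain_abs, c(0, 30))
  expect_equal(sh$gain_rel, c(0, 150))
  # negative scores are clipped before the share is formed
  neg <- list(all_vars = mk("pfi", c(2, 2, -5, 6), 1:2))
  expect_equal(elf_contribution_shares(neg)$elf_share, 40)
  zero <- list(all_vars = mk("pfi", rep(0, 4), 1))
  expect_error(elf_contribution_shares(zero), class = "elf_zero_total")
})

test_that("null ELF effects produce a small SHAP ELF share", {
  cfg <- generator_config(n_samples = 8000, seed = 41,
                          elf_main_effect = 0, elf_comorbid_interaction = 0)
  co <- generate_cohort(cfg)
  folds <- make_folds(co, seed = 1)
  fit <- fit_unified_model(co, NULL, folds, seed = 1)
  tab <- shap_importance(fit, co, "comorbid")
  sh <- elf_contribution_shares(list(all_vars = tab))
  expect_lt(sh$elf_share, 5)
})

test_that("full pipeline is deterministic and modular", {
  cfg <- generator_config(n_samples = 2000, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_full_analysis(cfg, out_dir = d1, components = "decision_curve",
                          budget = 1)
  r2 <- run_full_analysis(cfg, out_dir = d2, components = "decision_curve",
                          budget = 1)
  expect_identical(readLines(file.path(d1, "metrics.csv")),
                   readLines(file.path(d2, "metrics.csv")))
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # disabling a component removes its table family and nothing else
  expect_false(file.exists(file.path(d1, "bounds.csv")))
  expect_true(file.exists(file.path(d1, "decision_curves.csv")))
  r3 <- run_full_analysis(cfg, components = c("decision_curve", "bounds"),
                          budget = 1)
  expect_true("bounds" %in% names(r3))
  expect_identical(r1$metrics, r3$metrics)
})
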