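# Shared fixture: a labelled, encoded cohort with a strong, a weak, and a
# constant variable, plus a fitted cross-validated model.
driver_fixture <- function(n = 1000, seed = 5) {
  catalog <- tiny_catalog()
  set.seed(seed)
  raw <- tibble::tibble(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                        colour = sample(c("red", "green", "blue"), n, TRUE),
                        flag = rep(1, n))  # constant: never used by any tree
  y <- as.integer(raw$age + 0.5 * raw$sex + rnorm(n, sd = 0.3) > 0)
  co <- encode_features(cohort_from_raw(raw, catalog, outcome = y,
                                        comorbid = rep(c(TRUE, FALSE),
                                                       n / 2)))
  folds <- make_folds(co, n_folds = 3, seed = seed)
  fit <- fit_unified_model(co, NULL, folds, seed = seed)
  list(co = co, folds = folds, fit = fit)
}

test_that("PFI is exactly zero for features no tree uses", {
  fx <- driver_fixture()
  tab <- permutation_importance(fx$fit, fx$co, "all", repeats = 3, seed = 1)
  expect_equal(tab$score[tab$feature == "flag"], 0)
  expect_gt(tab$score[tab$feature == "age"], 0)
  expect_equal(sort(tab$rank), seq_len(nrow(tab)))
})

test_that("PFI of a label-defining feature matches the direct loss gap", {
  # outcome equals a binary feature; the model uses it alone. The expected
  # loss after permutation is the exact double mean over all (i, j) pairings,
  # computed directly from the model's own predictions.
  catalog <- tiny_catalog()
  set.seed(3)
  n <- 5000
  raw <- tibble::tibble(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                        colour = sample(c("red", "green", "blue"), n, TRUE),
                        flag = rbinom(n, 1, 0.4))
  y <- raw$flag
  co <- encode_features(cohort_from_raw(raw, catalog, outcome = y,
                                        comorbid = rep(FALSE, n)))
  folds <- make_folds(co, n_folds = 2, seed = 1)
  fs <- feature_set(catalog, "custom", vars = c("age", "flag"))
  fit <- fit_unified_model(co, fs, folds, seed = 1)
  tab <- permutation_importance(fit, co, "all", repeats = 10, seed = 2,
                                vars = "flag")
  # direct oracle: loss where flag column is replaced by an independent draw
  # from its marginal = mean over i of mean over j of L(y_i, f(x_i; flag_j))
  gap <- mean(vapply(1:2, function(f) {
    rows <- which(fit$folds == f)
    Xe <- co$encoded[rows, fit$feature_names, drop = FALSE]
    p <- elfrisk:::predict_booster(fit$fits[[f]], Xe)
    base <- elfrisk:::log_loss(y[rows], p)
    # flag is binary: expected permuted loss mixes the two counterfactuals
    X1 <- Xe; X1[, "flag"] <- 1
    X0 <- Xe; X0[, "flag"] <- 0
    p1 <- elfrisk:::predict_booster(fit$fits[[f]], X1)
    p0 <- elfrisk:::predict_booster(fit$fits[[f]], X0)
    w <- mean(Xe[, "flag"])
    eps <- 1e-7
    ll <- function(pp) -(y[rows] * log(pmax(pp, eps)) +
                           (1 - y[rows]) * log(pmax(1 - pp, eps)))
    mean(w * ll(p1) + (1 - w) * ll(p0)) - base
  }, 0.0))
  expect_gt(tab$score[tab$feature == "flag"], 0)
  expect_equal(tab$score[tab$feature == "flag"], gap, tolerance = 0.05 * gap)
})

test_that("a null feature's PFI stays within 3 standard errors of zero", {
  fx <- driver_fixture(n = 2000, seed = 11)
  # 'colour' is independent of the outcome by construction
  tab <- permutation_importance(fx$fit, fx$co, "all", repeats = 10, seed = 4)
  row <- tab[tab$feature == "colour", ]
  expect_lt(abs(row$score), 3 * row$se + 1e-9)
})

test_that("duplicating a feature dilutes its per-copy PFI", {
  # a model that must spread its splits over two identical copies
  # (column subsampling forces both to be used) scores each copy below the
  # importance of the lone copy in a single-copy model
  catalog <- tiny_catalog()
  set.seed(6)
  n <- 1500
  age <- rnorm(n)
  raw1 <- tibble::tibble(age = age, sex = rbinom(n, 1, 0.5),
                         colour = sample(c("red", "green", "blue"), n, TRUE),
                         flag = rbinom(n, 1, 0.5))
  y <- as.integer(age + rnorm(n, sd = 0.5) > 0)
  co1 <- encode_features(cohort_from_raw(raw1, catalog, outcome = y,
                                         comorbid = rep(FALSE, n)))
  folds <- make_folds(co1, n_folds = 2, seed = 2)
  manual_fit <- function(co, vars, colsample = 1) {
    fs <- feature_set(co$catalog, "custom", vars = vars)
    fits <- lapply(1:2, function(f) {
      tr <- folds != f
      elfrisk:::fit_booster(co$encoded[tr, fs$columns, drop = FALSE], y[tr],
                            list(max_depth = 3, eta = 0.2, nrounds = 40,
                                 subsample = 1,
                                 colsample_bytree = colsample),
                            seed = 2)
    })
    structure(list(model_name = "manual", fset = fs, folds = folds,
                   fits = fits, oof = rep(NA_real_, n), outcome = y,
                   feature_names = fs$columns, seed = 2),
              class = "elf_risk_fit")
  }
  fit1 <- manual_fit(co1, c("age", "sex"))
  single <- permutation_importance(fit1, co1, "all", repeats = 5, seed = 3,
                                   vars = "age")$score
  cat2 <- catalog
  cat2$dtype[cat2$name == "flag"] <- "continuous"
  raw2 <- raw1
  raw2$flag <- age  # identical copy of age in another continuous slot
  co2 <- encode_features(cohort_from_raw(raw2, cat2, outcome = y,
                                         comorbid = rep(FALSE, n)))
  fit2 <- manual_fit(co2, c("age", "sex", "flag"), colsample = 0.5)
  dup <- permutation_importance(fit2, co2, "all", repeats = 5, seed = 3,
                                vars = c("age", "flag"))
  expect_lt(max(dup$score), single)
})

test_that("Spearman screen flags monotone duplicates and clears null pairs", {
  set.seed(2)
  x <- rnorm(1000)
  X <- cbind(x = x, ex = exp(x), u1 = runif(1000), u2 = runif(1000))
  rep <- spearman_screen(X)
  pair <- rep[rep$feature_1 == "x" & rep$feature_2 == "ex", ]
  expect_equal(pair$rho, 1)
  expect_true(pair$fully_correlated)
  null_pair <- rep[rep$feature_1 == "u1" & rep$feature_2 == "u2", ]
  expect_lt(abs(null_pair$rho), 0.15)
  # generated cohorts contain no fully correlated variable pair
  co <- generate_cohort(generator_config(n_samples = 1000, seed = 13))
  scr <- spearman_screen(co$encoded[, 1:40])
  one_hot_pairs <- scr$feature_1 %in% colnames(co$encoded)[3:20] &
    startsWith(scr$feature_2, substr(scr$feature_1, 1, 6))
  expect_false(any(scr$fully_correlated[!one_hot_pairs]))
})

test_that("tree attributions match the exhaustive Shapley oracle", {
  set.seed(42)
  n <- 300; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] * X[, 3] + rnorm(n, sd = 0.3) > 0)
  bst <- fit_toy_booster(X, y, nrounds = 15, max_depth = 3)
  contrib <- elfrisk:::predict_booster(bst, X, type = "contrib")
  trees <- oracle_tree_tables(bst)
  feats <- colnames(X)
  # the intercept column is the oracle's empty-coalition value shifted by
  # the ensemble's constant base margin; that shift is instance-independent
  base_shift <- contrib[1, "(Intercept)"] -
    oracle_shap(trees, as.list(X[1, ]), feats)$baseline
  for (i in c(1, 7, 50, 200)) {
    oracle <- oracle_shap(trees, as.list(X[i, ]), feats)
    expect_equal(unname(contrib[i, feats]), unname(oracle$phi),
                 tolerance = 1e-6)
    expect_equal(unname(contrib[i, "(Intercept)"]),
                 unname(oracle$baseline + base_shift), tolerance = 1e-6)
  }
  # local accuracy on every instance: baseline + sum(phi) = margin
  marg <- elfrisk:::predict_booster(bst, X, type = "margin")
  expect_lt(max(abs(rowSums(contrib) - marg)), 1e-5)
})

test_that("Shapley symmetry: interchangeable features get equal credit", {
  # hand-built two-tree ensemble in which features a and b play perfectly
  # symmetric roles: tree 0 splits on a, tree 1 on b, same structure, same
  # covers, same leaves. For any x with x_a = x_b the induced game is
  # symmetric, so the exact Shapley values must coincide.
  mk_tree <- function(tree_id, feat) {
    ids <- paste0(tree_id, "-", 0:2)
    data.frame(Tree = tree_id, Node = 0:2, ID = ids,
               Feature = c(feat, "Leaf", "Leaf"),
               Split = c(0, NA, NA),
               Yes = c(ids[2], NA, NA), No = c(ids[3], NA, NA),
               Missing = c(ids[3], NA, NA),
               Gain = c(1, -0.4, 0.7), Cover = c(10, 6, 4),
               row.names = ids)
  }
  trees <- list(mk_tree(0, "a"), mk_tree(1, "b"))
  for (v in c(-1.3, 0.2)) {
    oracle <- oracle_shap(trees, list(a = v, b = v, c = 99), c("a", "b", "c"))
    expect_equal(oracle$phi[["a"]], oracle$phi[["b"]], tolerance = 1e-12)
    expect_equal(oracle$phi[["c"]], 0)
  }
})

test_that("single-feature models attribute everything to that feature", {
  set.seed(4)
  n <- 500
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- as.integer(X[, "x1"] > 0)
  # model fit on x1 only, then scored in a 2-feature matrix
  bst <- fit_toy_booster(X[, "x1", drop = FALSE], y, nrounds = 10)
  contrib <- elfrisk:::predict_booster(bst, X[, "x1", drop = FALSE],
                                       type = "contrib")
  marg <- elfrisk:::predict_booster(bst, X[, "x1", drop = FALSE],
                                    type = "margin")
  # phi_x1 = f(x) - E[f(x)] (cover-weighted baseline), all others zero
  expect_equal(unname(contrib[, "x1"]),
               unname(marg - contrib[, "(Intercept)"]), tolerance = 1e-5)
})

test_that("shap_importance aggregates one-hot blocks and ranks drivers", {
  fx <- driver_fixture()
  tab <- shap_importance(fx$fit, fx$co, "all")
  expect_setequal(tab$feature, c("age", "sex", "colour", "flag"))
  expect_equal(tab$score[tab$feature == "flag"], 0)
  expect_equal(tab$feature[1], "age")
  enc <- shap_importance(fx$fit, fx$co, "all", level = "encoded")
  expect_true(all(c("colour_red", "colour_green", "colour_blue") %in%
                    enc$feature))
})

test_that("dual-group effect size reproduces the printed pooled formula", {
  # constructed example: high-risk values {2, 4}, low-risk {0, 2};
  # means 3 and 1, sample variances 2 and 2, pooled sd sqrt(2), D = sqrt(2)
  X <- matrix(c(2, 4, 0, 2), ncol = 1, dimnames = list(NULL, "x"))
  p <- c(0.9, 0.8, 0.2, 0.1)
  tab <- dual_group_effect_size(p, X, t = 0.5)
  expect_equal(tab$score, sqrt(2), tolerance = 1e-12)
  # affine invariance: c * x and x + const give the same D
  expect_equal(dual_group_effect_size(p, X * 3.7, t = 0.5)$score, sqrt(2),
               tolerance = 1e-12)
  expect_equal(dual_group_effect_size(p, X + 11, t = 0.5)$score, sqrt(2),
               tolerance = 1e-12)
})

test_that("effect size handles middle bands and degenerate groups", {
  X <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "x"))
  p <- c(0.95, 0.9, 0.85, 0.7, 0.55, 0.45, 0.3, 0.2, 0.1, 0.05)
  tab <- dual_group_effect_size(p, X, t = 0.6)
  # t = 0.6: {0.55, 0.45} fall in the excluded middle band
  expect_equal(tab$n_high, 4)
  expect_equal(tab$n_low, 4)
  # identical distributions in both groups: D = 0
  Xc <- matrix(rep(c(1, 2), 5), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(dual_group_effect_size(c(.9, .9, .9, .9, .1, .1, .1, .1),
                                      matrix(c(1, 2, 1, 2, 1, 2, 1, 2),
                                             ncol = 1,
                                             dimnames = list(NULL, "x")))$score,
               0)
  # constant feature: undefined, not zero
  expect_true(is.na(dual_group_effect_size(p, matrix(1, 10, 1,
                                                     dimnames = list(NULL,
                                                                     "c")),
                                           t = 0.5)$score))
  expect_error(dual_group_effect_size(rep(0.9, 10), X, t = 0.5),
               class = "elf_degenerate_groups")
})

test_that("driver summaries report overlap and ELF counts", {
  t1 <- tibble::tibble(feature = paste0("v", 1:10), category = "lifestyle",
                       subgroup = "comorbid", score = 10:1)
  t2 <- t1
  t2$subgroup <- "non_comorbid"
  identical_sum <- driver_summary(dplyr::bind_rows(t1, t2), top_k = 10)
  expect_equal(identical_sum$overlap_fraction, 1)
  t3 <- t2
  t3$feature <- paste0("w", 1:10)
  disjoint_sum <- driver_summary(dplyr::bind_rows(t1, t3), top_k = 10)
  expect_equal(disjoint_sum$overlap_fraction, 0)
  t1$category[1:3] <- "ELF"
  counted <- driver_summary(dplyr::bind_rows(t1, t3), top_k = 10)
  expect_equal(unname(counted$elf_counts["comorbid"]), 3L)
})
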