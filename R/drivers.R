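#' Permutation feature importance (PFI)
#'
#' For each raw variable, its encoded column block is shuffled as a unit on
#' the evaluated rows and the loss recomputed; PFI is the mean increase,
#' shuffled minus original, over `repeats` shuffles, averaged across folds
#' (test rows only, restricted to the requested subgroup). Positive scores
#' mark variables the model's performance depends on. Shuffling a block
#' keeps within-variable level structure intact, so a 64-variable ranking is
#' reported even though the model consumes 83 encoded columns.
#'
#' The sign convention makes important features positive: the loss after
#' shuffling minus the loss before. Default loss is the log loss
#' (instance-decomposable); `"one_minus_auc"` is selectable.
#'
#' @param fit An `elf_risk_fit`.
#' @param cohort The cohort it was fitted on.
#' @param subgroup `"comorbid"`, `"non_comorbid"`, or `"all"`.
#' @param loss `"logloss"` (default) or `"one_minus_auc"`.
#' @param repeats Shuffles per variable (default 10).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @param vars Raw variables to score (default all model variables).
#' @return A driver tibble: `feature`, `category`, `subgroup`, `score`,
#'   `se` (standard error over repeats), `rank`, `metric`.
#' @export
permutation_importance <- function(fit, cohort,
                                   subgroup = c("comorbid", "non_comorbid",
                                                "all"),
                                   loss = c("logloss", "one_minus_auc"),
                                   repeats = 10, seed = 1,
                                   vars = fit$fset$vars) {
  subgroup <- match.arg(subgroup)
  loss <- match.arg(loss)
  catalog <- cohort$catalog
  loss_fn <- switch(loss,
                    logloss = log_loss,
                    one_minus_auc = function(y, p) 1 - auc_rank(y, p))
  in_sg <- switch(subgroup, all = rep(TRUE, n_samples(cohort)),
                  comorbid = cohort$comorbid, non_comorbid = !cohort$comorbid)
  y <- cohort$outcome
  n_folds <- max(fit$folds)
  # per fold, per variable, per repeat loss deltas
  deltas <- array(NA_real_, c(n_folds, length(vars), repeats),
                  dimnames = list(NULL, vars, NULL))
  for (f in seq_len(n_folds)) {
    rows <- which(fit$folds == f & in_sg)
    if (length(rows) < 2 || length(unique(y[rows])) < 2) next
    Xe <- cohort$encoded[rows, fit$feature_names, drop = FALSE]
    base <- loss_fn(y[rows], predict_booster(fit$fits[[f]], Xe))
    for (v in seq_along(vars)) {
      cols <- intersect(encoded_columns(catalog, vars[v]), colnames(Xe))
      if (length(cols) == 0) next
      for (r in seq_len(repeats)) {
        set.seed(derive_seed(seed, "pfi", f, v, r))
        perm <- sample(nrow(Xe))
        Xp <- Xe
        Xp[, cols] <- Xe[perm, cols, drop = FALSE]
        deltas[f, v, r] <-
          loss_fn(y[rows], predict_booster(fit$fits[[f]], Xp)) - base
      }
    }
  }
  per_var <- apply(deltas, 2, function(m) mean(m, na.rm = TRUE))
  se <- apply(deltas, 2, function(m) {
    reps <- colMeans(m, na.rm = TRUE)  # mean over folds, per repeat
    stats::sd(reps, na.rm = TRUE) / sqrt(sum(!is.na(reps)))
  })
  tibble::tibble(feature = vars,
                 category = catalog$category[match(vars, catalog$name)],
                 subgroup = subgroup, score = unname(per_var),
                 se = unname(se),
                 metric = "pfi", repeats = repeats) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Spearman rank-correlation screen
#'
#' Pairwise Spearman correlations of the encoded features on the training
#' data; pairs at |rho| = 1 are flagged as fully correlated. The screen feeds
#' a warning about PFI underestimation for correlated features -- it never
#' drops variables automatically.
#'
#' @param X Numeric matrix or data frame (samples x features), >= 3 rows.
#' @param flag_at Absolute correlation treated as complete (default 1, with
#'   a small numerical tolerance).
#' @return A tibble of feature pairs: `feature_1`, `feature_2`, `rho`,
#'   `fully_correlated`, sorted by |rho| descending.
#' @export
spearman_screen <- function(X, flag_at = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  R <- stats::cor(X[, keep, drop = FALSE], method = "spearman")
  idx <- which(upper.tri(R), arr.ind = TRUE)
  tibble::tibble(feature_1 = colnames(R)[idx[, 1]],
                 feature_2 = colnames(R)[idx[, 2]],
                 rho = R[idx]) |>
    dplyr::mutate(fully_correlated = abs(.data$rho) >= flag_at - 1e-12) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho)))
}

#' Shapley-attribution variable importance
#'
#' Per-instance additive attributions of the gradient-boosted model (exact
#' tree-path Shapley values on the margin scale; the baseline plus the sum of
#' attributions reproduces each prediction to numerical precision).
#' Importance I_j is the mean absolute attribution over the evaluated rows;
#' encoded columns of one raw variable are aggregated by summing their
#' attributions per instance before taking the absolute value. Computed on
#' each fold's test rows and averaged across folds.
#'
#' @inheritParams permutation_importance
#' @param level `"raw"` (default; one row per raw variable) or `"encoded"`.
#' @return A driver tibble: `feature`, `category`, `subgroup`, `score`
#'   (mean |phi|), `rank`, `metric`.
#' @export
shap_importance <- function(fit, cohort,
                            subgroup = c("comorbid", "non_comorbid", "all"),
                            level = c("raw", "encoded")) {
  subgroup <- match.arg(subgroup)
  level <- match.arg(level)
  catalog <- cohort$catalog
  in_sg <- switch(subgroup, all = rep(TRUE, n_samples(cohort)),
                  comorbid = cohort$comorbid, non_comorbid = !cohort$comorbid)
  n_folds <- max(fit$folds)
  col2raw <- encoded_to_raw(catalog)
  per_fold <- purrr::map(seq_len(n_folds), function(f) {
    rows <- which(fit$folds == f & in_sg)
    if (length(rows) == 0) return(NULL)
    Xe <- cohort$encoded[rows, fit$feature_names, drop = FALSE]
    contrib <- predict_booster(fit$fits[[f]], Xe, type = "contrib")
    phi <- contrib[, fit$feature_names, drop = FALSE]
    if (level == "raw") {
      groups <- col2raw[fit$feature_names]
      agg <- vapply(unique(groups), function(g)
        rowSums(phi[, groups == g, drop = FALSE]), numeric(nrow(phi)))
      colMeans(abs(agg))
    } else {
      colMeans(abs(phi))
    }
  })
  per_fold <- purrr::compact(per_fold)
  scores <- colMeans(do.call(rbind, per_fold))
  tibble::tibble(feature = names(scores),
                 category = catalog$category[match(
                   if (level == "raw") names(scores) else
                     col2raw[names(scores)], catalog$name)],
                 subgroup = subgroup, score = unname(scores),
                 metric = "shap_importance") |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Dual-group risk effect size (Cohen's D)
#'
#' Splits samples into a predicted high-risk group (probability > t) and a
#' predicted low-risk group (probability <= 1 - t); with the default t = 0.5
#' the two groups cover all samples, while t > 0.5 excludes a middle band.
#' For each feature, Cohen's D between the groups is
#' |mean_high - mean_low| / s_pooled with the (n-1)-weighted pooled standard
#' deviation. Features are returned sorted by descending D. A feature with
#' zero pooled variance, or groups with fewer than 2 members, yield `NA`
#' (undefined), never 0.
#'
#' @param probabilities Predicted risk per sample.
#' @param X Numeric matrix or data frame of feature values (samples x
#'   features).
#' @param t Risk threshold in \[0.5, 1) (default 0.5).
#' @return A tibble: `feature`, `score` (Cohen's D), `n_high`, `n_low`,
#'   `rank`, `metric`.
#' @export
#' @examples
#' # high-risk values {2, 4}, low-risk values {0, 2}: D = 2 / sqrt(2)
#' dual_group_effect_size(c(0.9, 0.9, 0.1, 0.1),
#'                        matrix(c(2, 4, 0, 2), ncol = 1,
#'                               dimnames = list(NULL, "x")))
dual_group_effect_size <- function(probabilities, X, t = 0.5) {
  X <- as.matrix(X)
  high <- probabilities > t
  low <- probabilities <= 1 - t
  if (sum(high) < 2 || sum(low) < 2)
    abort_elf("need at least 2 samples in each risk group",
              "elf_degenerate_groups")
  nh <- sum(high); nl <- sum(low)
  d <- vapply(colnames(X), function(j) {
    xh <- X[high, j]; xl <- X[low, j]
    sp <- sqrt(((nh - 1) * stats::var(xh) + (nl - 1) * stats::var(xl)) /
                 (nh + nl - 2))
    if (sp == 0) return(NA_real_)
    abs(mean(xh) - mean(xl)) / sp
  }, 0.0)
  tibble::tibble(feature = colnames(X), score = unname(d),
                 n_high = nh, n_low = nl, metric = "cohens_d") |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Dual-group effect sizes from a fitted model, per subgroup
#'
#' Convenience wrapper applying [dual_group_effect_size()] to a subgroup's
#' out-of-fold probabilities over the model's encoded features, with catalog
#' categories attached.
#'
#' @inheritParams permutation_importance
#' @param t Risk threshold (default 0.5).
#' @return A driver tibble with `feature`, `category`, `subgroup`, `score`,
#'   `rank`, `metric`.
#' @export
effect_size_drivers <- function(fit, cohort,
                                subgroup = c("comorbid", "non_comorbid",
                                             "all"),
                                t = 0.5) {
  subgroup <- match.arg(subgroup)
  in_sg <- switch(subgroup, all = rep(TRUE, n_samples(cohort)),
                  comorbid = cohort$comorbid, non_comorbid = !cohort$comorbid)
  rows <- which(in_sg)
  col2raw <- encoded_to_raw(cohort$catalog)
  out <- dual_group_effect_size(fit$oof[rows],
                                cohort$encoded[rows, fit$feature_names,
                                               drop = FALSE], t = t)
  out$category <- cohort$catalog$category[match(col2raw[out$feature],
                                                cohort$catalog$name)]
  out$subgroup <- subgroup
  out
}

#' Compare driver rankings between subgroups
#'
#' Top-k lists per subgroup from a pair of driver tables sharing a feature
#' universe, with the overlap fraction, the number of ELF-category features
#' in each top-k, and per-feature marking of variables shared by both
#' subgroups' top-k lists.
#'
#' @param tables A driver tibble (or bind of two) containing both subgroups,
#'   with `feature`, `subgroup`, `score` and `category` columns.
#' @param top_k List length (default 30).
#' @return A list with `top` (tibble of top-k rows per subgroup, with
#'   `shared` marking), `overlap_fraction`, and `elf_counts` (named by
#'   subgroup).
#' @export
driver_summary <- function(tables, top_k = 30) {
  subgroups <- unique(tables$subgroup)
  stopifnot(length(subgroups) == 2)
  tops <- lapply(subgroups, function(sg) {
    tables |>
      dplyr::filter(.data$subgroup == sg) |>
      dplyr::arrange(dplyr::desc(.data$score)) |>
      utils::head(top_k)
  })
  names(tops) <- subgroups
  shared <- intersect(tops[[1]]$feature, tops[[2]]$feature)
  top <- dplyr::bind_rows(tops) |>
    dplyr::mutate(shared = .data$feature %in% shared)
  list(top = top,
       overlap_fraction = length(shared) / top_k,
       elf_counts = vapply(tops, function(t)
         sum(t$category == "ELF", na.rm = TRUE), 0L))
}
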