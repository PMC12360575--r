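#' Subgroup-stratified performance metrics
#'
#' AUC-ROC and Brier score of one or more fitted (or external) models,
#' computed on each fold's held-out rows restricted to the comorbid and
#' non-comorbid subgroups, then summarised as mean +/- sd across folds.
#' A fold whose subgroup slice has fewer than 2 samples or a single class
#' contributes `NA` for that cell and is dropped from the summary.
#'
#' @param models A named list of `elf_risk_fit` objects and/or numeric
#'   probability vectors (external scores, one probability per cohort row).
#'   A bare `elf_risk_fit` is also accepted.
#' @param cohort The subgroup-labelled `elf_cohort` the models were
#'   evaluated on.
#' @param folds Fold assignment from [make_folds()]; defaults to the folds
#'   of the first fitted model.
#' @return A tibble with one row per model x subgroup: `task`, `model`,
#'   `subgroup`, `auc_mean`, `auc_sd`, `brier_mean`, `brier_sd`, `n_folds`.
#' @export
evaluate_subgroups <- function(models, cohort, folds = NULL) {
  stopifnot(!is.null(cohort$comorbid), !is.null(cohort$outcome))
  if (inherits(models, "elf_risk_fit")) models <- list(models)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(seq_along(models), function(i) {
      m <- models[[i]]
      if (inherits(m, "elf_risk_fit")) m$model_name else paste0("model_", i)
    }, "")
  folds <- folds %||% {
    fitted <- purrr::detect(models, inherits, "elf_risk_fit")
    stopifnot(!is.null(fitted))
    fitted$folds
  }
  y <- cohort$outcome
  purrr::imap_dfr(models, function(m, nm) {
    p <- if (inherits(m, "elf_risk_fit")) m$oof else as.numeric(m)
    stopifnot(length(p) == length(y))
    purrr::map_dfr(c("comorbid", "non_comorbid"), function(sg) {
      in_sg <- cohort$comorbid == (sg == "comorbid")
      per_fold <- purrr::map_dfr(seq_len(max(folds)), function(f) {
        rows <- which(folds == f & in_sg)
        if (length(rows) < 2 || length(unique(y[rows])) < 2)
          return(tibble::tibble(auc = NA_real_, brier = NA_real_))
        tibble::tibble(auc = auc_rank(y[rows], p[rows]),
                       brier = brier_score(y[rows], p[rows]))
      })
      ok <- !is.na(per_fold$auc)
      tibble::tibble(task = cohort$task %||% NA_character_, model = nm,
                     subgroup = sg,
                     auc_mean = mean(per_fold$auc[ok]),
                     auc_sd = stats::sd(per_fold$auc[ok]),
                     brier_mean = mean(per_fold$brier[ok]),
                     brier_sd = stats::sd(per_fold$brier[ok]),
                     n_folds = sum(ok))
    })
  })
}

#' Net benefit at a decision threshold
#'
#' b(t) = TP/n - (FP/n) * t/(1-t), where a prediction is positive iff the
#' predicted probability strictly exceeds t (ties at the threshold count as
#' negative). The 'none' strategy (all probabilities 0) scores 0 at every
#' threshold; a perfect classifier scores the prevalence at every threshold.
#'
#' @param labels Binary 0/1 outcomes.
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param t Decision threshold strictly inside (0, 1).
#' @return The net benefit (a scalar).
#' @export
#' @examples
#' # 10 samples, 3 true positives, 2 false positives at t = 0.2:
#' y <- c(1, 1, 1, 0, 0, rep(0, 4), 1)
#' p <- c(0.9, 0.8, 0.7, 0.6, 0.5, rep(0.1, 4), 0.1)
#' net_benefit(y, p, 0.2)  # 3/10 - (2/10)*(0.2/0.8) = 0.25
net_benefit <- function(labels, probabilities, t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t >= 1)
    abort_elf("threshold must lie strictly inside (0, 1)",
              "elf_invalid_threshold")
  y <- as.integer(labels)
  pos <- probabilities > t
  n <- length(y)
  tp <- sum(pos & y == 1L)
  fp <- sum(pos & y == 0L)
  tp / n - (fp / n) * (t / (1 - t))
}

#' Decision-curve analysis for a subgroup
#'
#' Net benefit of each model across a threshold grid on the rows of the
#' requested subgroup (comorbid by default, matching the evaluation protocol
#' for clinical utility in the harder population), together with the two
#' reference strategies: treat-'all', with closed form
#' pi - (1 - pi) t/(1 - t) at prevalence pi, and treat-'none', identically 0.
#'
#' @param cohort A subgroup-labelled `elf_cohort`.
#' @param models Named list of `elf_risk_fit` objects and/or probability
#'   vectors over all cohort rows (out-of-fold probabilities are used for
#'   fitted models).
#' @param t_grid Threshold grid (default 0.01 ... 0.99 in steps of 0.01).
#' @param subgroup `"comorbid"` (default), `"non_comorbid"`, or `"all"`.
#' @return A `nb_curve` tibble: `threshold`, `strategy`, `net_benefit`,
#'   `subgroup`, `n`.
#' @export
decision_curve <- function(cohort, models, t_grid = seq(0.01, 0.99, by = 0.01),
                           subgroup = c("comorbid", "non_comorbid", "all")) {
  subgroup <- match.arg(subgroup)
  rows <- switch(subgroup,
                 all = seq_len(n_samples(cohort)),
                 comorbid = which(cohort$comorbid),
                 non_comorbid = which(!cohort$comorbid))
  y <- cohort$outcome[rows]
  pi_hat <- mean(y)
  if (inherits(models, "elf_risk_fit")) models <- list(models)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- vapply(seq_along(models), function(i) {
      m <- models[[i]]
      if (inherits(m, "elf_risk_fit")) m$model_name else paste0("model_", i)
    }, "")
  curves <- purrr::imap_dfr(models, function(m, nm) {
    p <- if (inherits(m, "elf_risk_fit")) m$oof[rows] else as.numeric(m)[rows]
    tibble::tibble(threshold = t_grid, strategy = nm,
                   net_benefit = vapply(t_grid, function(t)
                     net_benefit(y, p, t), 0.0))
  })
  refs <- dplyr::bind_rows(
    tibble::tibble(threshold = t_grid, strategy = "all",
                   net_benefit = pi_hat - (1 - pi_hat) * t_grid / (1 - t_grid)),
    tibble::tibble(threshold = t_grid, strategy = "none", net_benefit = 0)
  )
  out <- dplyr::bind_rows(curves, refs)
  out$subgroup <- subgroup
  out$n <- length(y)
  class(out) <- c("nb_curve", class(out))
  out
}
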