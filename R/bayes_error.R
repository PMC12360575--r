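#' Group-specific Bayes error bounds
#'
#' The Bayes error is the smallest expected misclassification rate any
#' classifier can reach on a task; it quantifies the irreducible noise of a
#' subgroup's prediction problem. Three classical estimators bound it from
#' data: a Mahalanobis-distance bound (upper bound only), the Gaussian
#' Bhattacharyya bound pair, and a cross-validated k-nearest-neighbour
#' estimate inverted through the two-class Cover-Hart relation.
#'
#' All bounds live in \[0, 0.5\] and satisfy E_low <= E_up whenever both are
#' defined. Covariance singularity (condition number above 1e12) is reported
#' as a `singular_covariance` status rather than an exception, matching the
#' known failure mode of the Bhattacharyya estimator on rank-deficient
#' one-hot encoded feature sets.
#'
#' @name bayes_error
NULL

bound_estimate <- function(method, E_low = NA_real_, E_up = NA_real_,
                           status = "ok", subgroup = NA_character_,
                           variable_set = NA_character_, k = NA_integer_,
                           n_folds = NA_integer_) {
  tibble::tibble(method = method, subgroup = subgroup,
                 variable_set = variable_set, E_low = E_low, E_up = E_up,
                 k = k, n_folds = n_folds, status = status)
}

cov_singular <- function(S, cond_max = 1e12) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) <= 0 || max(ev) / min(ev) > cond_max
}

#' Mahalanobis-distance Bayes error upper bound
#'
#' E_up = 2 p1 p2 / (1 + p1 p2 Delta), where p1, p2 are the class priors and
#' Delta the squared Mahalanobis distance between the class means under the
#' pooled covariance. No lower bound is available from this statistic.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels.
#' @return A one-row bound tibble (see [bayes_error]).
#' @export
mahalanobis_bound <- function(X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(length(unique(y)) == 2)
  p1 <- mean(y == 1); p2 <- 1 - p1
  X1 <- X[y == 1, , drop = FALSE]; X0 <- X[y == 0, , drop = FALSE]
  S <- ((nrow(X1) - 1) * stats::cov(X1) + (nrow(X0) - 1) * stats::cov(X0)) /
    (nrow(X) - 2)
  if (cov_singular(S))
    return(bound_estimate("mahalanobis", status = "singular_covariance"))
  d <- colMeans(X1) - colMeans(X0)
  delta <- as.numeric(t(d) %*% solve(S, d))
  bound_estimate("mahalanobis", E_up = 2 * p1 * p2 / (1 + p1 * p2 * delta))
}

#' Bhattacharyya Bayes error bound pair
#'
#' Under per-class Gaussian models N(mu_i, Sigma_i), the Bhattacharyya
#' distance is
#' B = 1/8 (mu1-mu2)' Sbar^{-1} (mu1-mu2) + 1/2 ln(|Sbar| / sqrt(|S1||S2|)),
#' Sbar = (S1+S2)/2, and with rho = exp(-B):
#' E_up = sqrt(p1 p2) rho,  E_low = (1 - sqrt(1 - 4 p1 p2 rho^2)) / 2.
#'
#' @inheritParams mahalanobis_bound
#' @return A one-row bound tibble; status `singular_covariance` when any of
#'   S1, S2 or their average is numerically singular.
#' @export
bhattacharyya_bounds <- function(X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(length(unique(y)) == 2)
  p1 <- mean(y == 1); p2 <- 1 - p1
  X1 <- X[y == 1, , drop = FALSE]; X0 <- X[y == 0, , drop = FALSE]
  S1 <- stats::cov(X1); S0 <- stats::cov(X0); Sb <- (S1 + S0) / 2
  if (cov_singular(S1) || cov_singular(S0) || cov_singular(Sb))
    return(bound_estimate("bhattacharyya", status = "singular_covariance"))
  d <- colMeans(X1) - colMeans(X0)
  ld <- function(S) determinant(S, logarithm = TRUE)$modulus
  B <- as.numeric(t(d) %*% solve(Sb, d)) / 8 +
    0.5 * as.numeric(ld(Sb) - 0.5 * (ld(S1) + ld(S0)))
  rho <- exp(-B)
  E_up <- sqrt(p1 * p2) * rho
  E_low <- 0.5 * (1 - sqrt(pmax(1 - 4 * p1 * p2 * rho^2, 0)))
  bound_estimate("bhattacharyya", E_low = E_low, E_up = E_up)
}

#' k-nearest-neighbour Bayes error bounds
#'
#' Estimates the k-NN misclassification rate by cross-validation (default
#' k = 5, 5 folds), clips it to \[0, 0.5\], and inverts the two-class
#' Cover-Hart asymptotic relation: E_up = eps_hat and
#' E_low = (1 - sqrt(1 - 2 eps_hat)) / 2. Continuous features are
#' standardised with training-fold statistics before the Euclidean-metric
#' neighbour search (k-NN is scale-sensitive, so the convention is explicit).
#'
#' @inheritParams mahalanobis_bound
#' @param k Neighbourhood size (default 5).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @return A one-row bound tibble.
#' @export
knn_bounds <- function(X, y, k = 5, folds = 5, seed = 1) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(length(unique(y)) == 2)
  if (min(table(y)) < 10 * k)
    abort_elf("need at least 10*k samples per class for the k-NN bound",
              "elf_too_few_samples")
  fold <- make_folds(y, n_folds = folds, seed = seed)
  err <- vapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    pred <- class::knn(Ztr, Zte, factor(y[tr]), k = k)
    mean(pred != factor(y[te], levels = levels(pred)))
  }, 0.0)
  eps <- clip(mean(err), 0, 0.5)
  bound_estimate("knn", E_low = 0.5 * (1 - sqrt(1 - 2 * eps)), E_up = eps,
                 k = as.integer(k), n_folds = as.integer(folds))
}

#' Bayes-error bound report across subgroups and variable sets
#'
#' Runs the requested methods on each subgroup x variable-set combination and
#' flags whether the comorbid and non-comorbid k-NN intervals overlap;
#' non-overlap indicates a genuinely different irreducible difficulty.
#'
#' @param cohort An encoded, subgroup-labelled `elf_cohort`.
#' @param sets Character vector of [feature_set()] names (default core-7 and
#'   all variables).
#' @param methods Methods to run.
#' @param k,n_folds k-NN settings.
#' @param seed Integer seed.
#' @return A tibble of bound estimates, one row per
#'   method x subgroup x variable set, with attribute
#'   `"knn_nonoverlap"` (named logical per variable set).
#' @export
bounds_report <- function(cohort, sets = c("core7", "all"),
                          methods = c("mahalanobis", "bhattacharyya", "knn"),
                          k = 5, n_folds = 5, seed = 1) {
  stopifnot(!is.null(cohort$encoded), !is.null(cohort$comorbid))
  out <- purrr::map_dfr(sets, function(set_name) {
    fs <- feature_set(cohort$catalog, set_name, task = cohort$task)
    purrr::map_dfr(c("comorbid", "non_comorbid"), function(sg) {
      rows <- which(cohort$comorbid == (sg == "comorbid"))
      X <- cohort$encoded[rows, fs$columns, drop = FALSE]
      y <- cohort$outcome[rows]
      purrr::map_dfr(methods, function(m) {
        est <- switch(m,
                      mahalanobis = mahalanobis_bound(X, y),
                      bhattacharyya = bhattacharyya_bounds(X, y),
                      knn = knn_bounds(X, y, k = k, folds = n_folds,
                                       seed = derive_seed(seed, set_name, sg)))
        est$subgroup <- sg
        est$variable_set <- set_name
        est
      })
    })
  })
  knn_rows <- out[out$method == "knn", ]
  nonoverlap <- vapply(sets, function(s) {
    co <- knn_rows[knn_rows$variable_set == s &
                     knn_rows$subgroup == "comorbid", ]
    nc <- knn_rows[knn_rows$variable_set == s &
                     knn_rows$subgroup == "non_comorbid", ]
    if (nrow(co) == 0 || nrow(nc) == 0) return(NA)
    co$E_low > nc$E_up || nc$E_low > co$E_up
  }, NA)
  attr(out, "knn_nonoverlap") <- nonoverlap
  out
}
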