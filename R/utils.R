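# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic seed derivation so that every stage of a run (per fold, per
#' tuning trial, per permutation repeat) draws from an independent stream while
#' remaining reproducible from a single master seed. Values stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param ... One or more integers or strings identifying the sub-stream.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.integer(x)
  })))
  h <- 0
  for (p in parts) h <- (h * 31 + (as.double(p) %% 2147483647)) %% 2147483629
  as.integer(h %% 2147483647L)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Area under the ROC curve by the Mann-Whitney rank statistic
#'
#' Midrank tie handling: AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0), where R1 is
#' the rank sum of the positive-class scores.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, larger meaning more positive.
#' @return AUC in \[0, 1\]; `NA` if either class is absent.
#' @export
#' @examples
#' auc_rank(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
auc_rank <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; lower is better calibrated.
#'
#' @inheritParams auc_rank
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @return Mean squared error of the probabilities.
#' @export
brier_score <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  mean((as.numeric(labels) - probabilities)^2)
}

# Per-sample log loss with clipping for numerical safety.
log_loss <- function(labels, probabilities, eps = 1e-7) {
  p <- clip(probabilities, eps, 1 - eps)
  y <- as.numeric(labels)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

abort_elf <- function(message, class) {
  rlang::abort(message, class = c(class, "elfrisk_error"))
}
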