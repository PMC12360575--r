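#' Impute missing values in a cohort
#'
#' Default method is iterative chained-equation imputation: after a mean/mode
#' initialisation, each incomplete variable is regressed in turn on all other
#' variables (linear model for continuous variables, a classification tree
#' for binary and categorical variables) and its missing cells replaced by
#' the fitted values, cycling until values stabilise. Imputed continuous
#' values are clamped to the observed \[min, max\] of the variable. The whole
#' procedure is deterministic given `seed` (the seed fixes the variable visit
#' order and any tree tie-breaks).
#'
#' Variables whose missing fraction exceeds `ceiling` signal an error,
#' mirroring the screening rule that variables with more than 25% missingness
#' should be dropped rather than imputed. With `stratum` supplied the ceiling
#' is checked within that stratum (e.g. positive-outcome participants) instead
#' of the whole cohort.
#'
#' @param cohort An `elf_cohort`.
#' @param method `"chained"` (default) or `"mean"` (mean/mode fill).
#' @param seed Integer seed.
#' @param ceiling Maximum tolerated missing fraction per variable (default
#'   0.25).
#' @param max_iter Chained-equation sweeps (default 3).
#' @param stratum Optional logical vector marking the rows over which the
#'   ceiling is checked.
#' @return The cohort with all missing cells filled and the mask cleared
#'   (the pre-imputation mask is kept as attribute `"imputed_mask"`).
#' @export
impute_missing <- function(cohort, method = c("chained", "mean"), seed = 1,
                           ceiling = 0.25, max_iter = 3, stratum = NULL) {
  method <- match.arg(method)
  mask <- cohort$mask
  if (!any(mask)) return(cohort)
  check_rows <- if (is.null(stratum)) rep(TRUE, nrow(mask)) else stratum
  frac <- colMeans(mask[check_rows, , drop = FALSE])
  if (any(frac > ceiling))
    abort_elf(paste0("missing fraction above ceiling for: ",
                     paste(names(frac)[frac > ceiling], collapse = ", ")),
              "elf_excess_missingness")

  catalog <- cohort$catalog[match(names(cohort$raw), cohort$catalog$name), ]
  raw <- cohort$raw
  obs_range <- lapply(names(raw), function(nm) {
    if (catalog$dtype[catalog$name == nm] == "continuous")
      range(raw[[nm]][!mask[, nm]]) else NULL
  })
  names(obs_range) <- names(raw)

  mode_of <- function(x) names(which.max(table(x)))
  # initial mean/mode fill
  for (nm in names(raw)) {
    miss <- mask[, nm]
    if (!any(miss)) next
    row <- catalog[catalog$name == nm, ]
    if (row$dtype == "continuous") {
      raw[[nm]][miss] <- mean(raw[[nm]][!miss])
    } else if (row$dtype == "binary") {
      raw[[nm]][miss] <- as.numeric(mode_of(raw[[nm]][!miss]))
    } else {
      raw[[nm]][miss] <- mode_of(raw[[nm]][!miss])
    }
  }

  if (method == "chained") {
    set.seed(seed)
    incomplete <- sample(names(raw)[colSums(mask) > 0])
    for (iter in seq_len(max_iter)) {
      for (nm in incomplete) {
        miss <- mask[, nm]
        row <- catalog[catalog$name == nm, ]
        df <- as.data.frame(raw)
        for (cn in names(df)) if (is.character(df[[cn]]))
          df[[cn]] <- factor(df[[cn]],
                             levels = catalog$levels[[match(cn, catalog$name)]])
        fml <- stats::as.formula(paste0("`", nm, "` ~ ."))
        if (row$dtype == "continuous") {
          fit <- stats::lm(fml, data = df[!miss, , drop = FALSE])
          pred <- stats::predict(fit, newdata = df[miss, , drop = FALSE])
          pred[is.na(pred)] <- mean(df[[nm]][!miss])
          raw[[nm]][miss] <- clip(pred, obs_range[[nm]][1], obs_range[[nm]][2])
        } else {
          df[[nm]] <- factor(df[[nm]])
          fit <- rpart::rpart(fml, data = df[!miss, , drop = FALSE],
                              method = "class",
                              control = rpart::rpart.control(cp = 0.01,
                                                             xval = 0))
          pred <- as.character(stats::predict(fit,
                                              newdata = df[miss, , drop = FALSE],
                                              type = "class"))
          if (row$dtype == "binary") {
            raw[[nm]][miss] <- as.numeric(pred)
          } else {
            raw[[nm]][miss] <- pred
          }
        }
      }
    }
  }

  cohort$raw <- raw
  attr(cohort, "imputed_mask") <- mask
  cohort$mask <- matrix(FALSE, nrow(mask), ncol(mask),
                        dimnames = dimnames(mask))
  cohort
}
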