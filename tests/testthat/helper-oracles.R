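# Independent oracles used by the test suite. These re-derive expected
# values by brute force or closed form and never call the code paths they
# check.

# --- exhaustive Shapley oracle over xgboost tree dumps ----------------------
# Value function: expected ensemble margin when the features in coalition S
# are fixed to x and the rest are marginalised recursively by cover weights
# (the tree-path conditional convention). Shapley values computed by full
# 2^|F| coalition enumeration.

oracle_tree_tables <- function(booster) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  lapply(split(dt, dt$Tree), function(tr) {
    rownames(tr) <- tr$ID
    tr
  })
}

# xgboost stores features and thresholds as float32 and compares at that
# precision; both the instance values and the (decimal-printed) dumped
# thresholds must be rounded back to float32 or boundary instances take a
# different branch.
f32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          size = 4L, n = length(v))
}

oracle_tree_value <- function(tr, x, S) {
  rec <- function(id) {
    nd <- tr[id, ]
    if (nd$Feature == "Leaf") return(nd$Gain)
    if (nd$Feature %in% S) {
      if (f32(x[[nd$Feature]]) < f32(nd$Split)) rec(nd$Yes) else rec(nd$No)
    } else {
      cy <- tr[nd$Yes, "Cover"]; cn <- tr[nd$No, "Cover"]
      (cy * rec(nd$Yes) + cn * rec(nd$No)) / (cy + cn)
    }
  }
  rec(tr$ID[tr$Node == 0][1])
}

# Vectorised exhaustive oracle: exact Shapley attributions for every row of
# X at once. Shapley additivity over trees lets each tree be enumerated over
# its own feature set only (absent features are dummy players).
oracle_shap_matrix <- function(booster, X) {
  trees <- oracle_tree_tables(booster)
  feats <- colnames(X)
  n <- nrow(X)
  phi <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  baseline <- numeric(n)
  X32 <- apply(X, 2, f32)
  for (tr in trees) {
    used <- intersect(feats, unique(tr$Feature))
    m <- length(used)
    tree_value <- function(S) {
      rec <- function(id) {
        nd <- tr[id, ]
        if (nd$Feature == "Leaf") return(rep(nd$Gain, n))
        vy <- rec(nd$Yes); vn <- rec(nd$No)
        if (nd$Feature %in% S) {
          ifelse(X32[, nd$Feature] < f32(nd$Split), vy, vn)
        } else {
          cy <- tr[nd$Yes, "Cover"]; cn <- tr[nd$No, "Cover"]
          (cy * vy + cn * vn) / (cy + cn)
        }
      }
      rec(tr$ID[tr$Node == 0][1])
    }
    if (m == 0) { baseline <- baseline + tree_value(character()); next }
    vals <- lapply(0:(2^m - 1), function(mask)
      tree_value(used[bitwAnd(mask, 2^(0:(m - 1))) > 0]))
    baseline <- baseline + vals[[1]]
    for (jx in seq_len(m)) {
      j_bit <- 2^(jx - 1)
      for (mask in 0:(2^m - 1)) {
        if (bitwAnd(mask, j_bit) > 0) next
        sz <- sum(bitwAnd(mask, 2^(0:(m - 1))) > 0)
        w <- factorial(sz) * factorial(m - sz - 1) / factorial(m)
        phi[, used[jx]] <- phi[, used[jx]] +
          w * (vals[[mask + j_bit + 1]] - vals[[mask + 1]])
      }
    }
  }
  list(phi = phi, baseline = baseline)
}

oracle_margin <- function(trees, x, S) {
  sum(vapply(trees, oracle_tree_value, 0.0, x = x, S = S))
}

# Exact Shapley attribution of every feature for one instance; returns the
# named phi vector plus the empty-coalition baseline.
oracle_shap <- function(trees, x, feats) {
  nf <- length(feats)
  vals <- vapply(0:(2^nf - 1), function(m) {
    S <- feats[bitwAnd(m, 2^(0:(nf - 1))) > 0]
    oracle_margin(trees, x, S)
  }, 0.0)
  key <- function(S) sum(2^(match(S, feats) - 1)) + 1
  phi <- stats::setNames(numeric(nf), feats)
  for (j in feats) {
    others <- setdiff(feats, j)
    for (m in 0:(2^(nf - 1) - 1)) {
      V <- others[bitwAnd(m, 2^(0:(nf - 2))) > 0]
      w <- factorial(length(V)) * factorial(nf - length(V) - 1) / factorial(nf)
      phi[j] <- phi[j] + w * (vals[key(c(V, j))] - vals[key(V)])
    }
  }
  list(phi = phi, baseline = vals[1])
}

# --- Gaussian Bayes error by numeric overlap integral -----------------------
# Two-class Bayes error for 1-D class-conditionals N(mu_i, sd_i) with priors
# p1, p0: integral of min(p1 f1, p0 f0).
gaussian_bayes_error_1d <- function(mu1, sd1, mu0, sd0, p1 = 0.5) {
  f <- function(x) pmin(p1 * stats::dnorm(x, mu1, sd1),
                        (1 - p1) * stats::dnorm(x, mu0, sd0))
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

# 2-D spherical case: Bayes error depends only on the Mahalanobis separation,
# reduce to the 1-D projection along the mean difference.
gaussian_bayes_error_spherical <- function(mu1, mu0, sd = 1, p1 = 0.5) {
  delta <- sqrt(sum((mu1 - mu0)^2))
  gaussian_bayes_error_1d(0, sd, delta, sd, p1)
}

# --- small fixtures ---------------------------------------------------------

# Minimal 4-variable catalog for I/O and encoding tests.
tiny_catalog <- function() {
  df <- tibble::tibble(
    name = c("age", "sex", "colour", "flag"),
    category = c("sociodemographic", "sociodemographic", "lifestyle",
                 "medical_history"),
    dtype = c("continuous", "binary", "categorical", "binary"),
    levels = list(character(), character(), c("red", "green", "blue"),
                  character()),
    is_lab = FALSE,
    core7_cvd = FALSE, core7_diabetes = FALSE
  )
  validate_catalog(elfrisk:::new_catalog(df), check_core7 = FALSE)
}

# Build an elf_cohort directly from a complete raw tibble.
cohort_from_raw <- function(raw, catalog, outcome = NULL, comorbid = NULL) {
  mask <- matrix(FALSE, nrow(raw), ncol(raw),
                 dimnames = list(NULL, names(raw)))
  elfrisk:::new_cohort(raw, mask, catalog,
                       sprintf("S%04d", seq_len(nrow(raw))),
                       outcome = outcome, comorbid = comorbid)
}

# Quick booster on a plain matrix, default small configuration.
fit_toy_booster <- function(X, y, nrounds = 20, max_depth = 3, eta = 0.3,
                            seed = 1) {
  elfrisk:::fit_booster(X, y,
                        list(max_depth = max_depth, eta = eta,
                             nrounds = nrounds, subsample = 1),
                        seed = seed)
}
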