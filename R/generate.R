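#' Synthetic cohort generator configuration
#'
#' Defaults encode the study conditions every downstream recovery test
#' assumes: early-life factors (ELFs) that are nearly uninformative on their
#' own (`elf_main_effect` close to 0) but substantially more informative in
#' the comorbid subgroup (`elf_comorbid_interaction` > 0), a designated
#' HbA1c-like laboratory marker coupled to the outcome only above its mean
#' (`marker_coupling`), and label noise that is higher in the comorbid
#' subgroup than the non-comorbid subgroup, making the comorbid prediction
#' task intrinsically harder.
#'
#' @param n_samples Cohort size (>= 100).
#' @param seed Integer seed (mandatory; the generator is fully deterministic
#'   given the config).
#' @param task `"cvd"` or `"diabetes"`; fixes which baseline condition flag
#'   defines comorbidity.
#' @param prevalence Target marginal outcome rate in (0, 1).
#' @param comorbid_fraction Target comorbid-subgroup fraction in (0, 1).
#' @param elf_main_effect Log-odds per active ELF in everyone.
#' @param elf_comorbid_interaction Extra log-odds per active ELF in the
#'   comorbid subgroup.
#' @param proximal_effects Named list of per-category log-odds scales for the
#'   proximal signal variables.
#' @param marker_coupling Log-odds per standard deviation of the HbA1c-like
#'   marker above its mean (flat below the mean).
#' @param noise_rate_comorbid,noise_rate_noncomorbid Label-flip probabilities
#'   in \[0, 0.5).
#' @param missing_rates Named per-category missing-cell rates in \[0, 0.25\],
#'   used by [inject_missingness()].
#' @param elf_prevalence Bernoulli rate of each ELF.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 20000,
                             seed = 1,
                             task = c("diabetes", "cvd"),
                             prevalence = 0.12,
                             comorbid_fraction = 0.15,
                             elf_main_effect = 0.02,
                             elf_comorbid_interaction = 1.2,
                             proximal_effects = NULL,
                             marker_coupling = 1.0,
                             noise_rate_comorbid = 0.15,
                             noise_rate_noncomorbid = 0.03,
                             missing_rates = NULL,
                             elf_prevalence = 0.18) {
  task <- match.arg(task)
  proximal_effects <- proximal_effects %||% list(
    sociodemographic = 0.45, blood_assay = 0.5, physical = 0.45,
    lifestyle = 0.12, psychosocial = 0.1, family_history = 0.25,
    medical_history = 0.4, mental_health = 0.1
  )
  missing_rates <- missing_rates %||% list(
    sociodemographic = 0.02, ELF = 0.08, blood_assay = 0.10,
    physical = 0.02, lifestyle = 0.05, psychosocial = 0.05,
    family_history = 0.05, medical_history = 0, mental_health = 0
  )
  stopifnot(n_samples >= 100,
            prevalence > 0, prevalence < 1,
            comorbid_fraction > 0, comorbid_fraction < 1,
            noise_rate_comorbid >= 0, noise_rate_comorbid < 0.5,
            noise_rate_noncomorbid >= 0, noise_rate_noncomorbid < 0.5,
            all(unlist(missing_rates) >= 0), all(unlist(missing_rates) <= 0.25))
  structure(list(n_samples = n_samples, seed = seed, task = task,
                 prevalence = prevalence, comorbid_fraction = comorbid_fraction,
                 elf_main_effect = elf_main_effect,
                 elf_comorbid_interaction = elf_comorbid_interaction,
                 proximal_effects = proximal_effects,
                 marker_coupling = marker_coupling,
                 noise_rate_comorbid = noise_rate_comorbid,
                 noise_rate_noncomorbid = noise_rate_noncomorbid,
                 missing_rates = missing_rates,
                 elf_prevalence = elf_prevalence),
            class = "generator_config")
}

# Variables that carry proximal signal, per category, with unit direction.
# The remainder of each category is pure noise, giving the feature-selection
# analyses a designed plateau.
proximal_signal_vars <- function() {
  list(
    sociodemographic = c(Age = 1),
    blood_assay = c(Glucose = 0.8, Triglycerides = 0.3, HDLCholesterol = -0.3,
                    CReactiveProtein = 0.25),
    physical = c(WaistCircumference = 0.8, BMI = 0.5,
                 SystolicBloodPressure = 0.4, BodyFatPercentage = 0.25),
    lifestyle = c(SmokingStatus = 1, PhysicalActivity = -0.5),
    psychosocial = c(OverallHealthRating = -1),
    family_history = c(IllnessesOfMother = 1, IllnessesOfSiblings = 0.5),
    medical_history = c(Hypertension = 1),
    mental_health = c(Depression = 1)
  )
}

#' Generate a synthetic cohort
#'
#' Latent chain: independent Bernoulli ELFs raise the probability of the
#' mental-health flags and of the baseline complementary condition; the
#' comorbidity flag follows from those flags exactly as in
#' [assign_subgroups()]; the outcome is drawn from a logistic model whose
#' linear predictor combines proximal effects, a piecewise HbA1c-like marker
#' term (flat below the marker's mean, linear above), ELF main effects and
#' ELF-by-comorbid interaction terms; finally labels are flipped at
#' subgroup-specific noise rates. Both the outcome prevalence and the
#' comorbid fraction are calibrated by bisection on their intercepts
#' (tolerance 0.001, at most 50 iterations), so targets hold in expectation
#' by construction.
#'
#' @param config A [generator_config()].
#' @param catalog A feature catalog (default [default_catalog()]).
#' @return An encoded, subgroup-labelled `elf_cohort` with no missing cells
#'   (use [inject_missingness()] to blank cells afterwards).
#' @export
generate_cohort <- function(config, catalog = default_catalog()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  set.seed(derive_seed(config$seed, "cohort"))
  cols <- purrr::pmap(catalog, function(name, category, dtype, levels, ...) {
    if (dtype == "continuous") stats::rnorm(n)
    else if (dtype == "binary") stats::rbinom(n, 1, 0.25)
    else sample(levels, n, replace = TRUE,
                prob = seq(length(levels), 1) / sum(seq_len(length(levels))))
  })
  names(cols) <- catalog$name
  raw <- tibble::as_tibble(cols)

  # ELFs: independent Bernoulli at the configured prevalence
  elf_vars <- catalog$name[catalog$category == "ELF"]
  for (nm in elf_vars) raw[[nm]] <- stats::rbinom(n, 1, config$elf_prevalence)
  elf_sum <- rowSums(raw[elf_vars])

  # mental-health flags raised by ELFs
  p_dep <- sigmoid(-2.1 + 0.35 * elf_sum)
  p_anx <- sigmoid(-2.5 + 0.25 * elf_sum)
  raw$Depression <- stats::rbinom(n, 1, p_dep)
  raw$Anxiety <- stats::rbinom(n, 1, p_anx)
  p_mental <- 1 - (1 - p_dep) * (1 - p_anx)

  # ELFs leave a small footprint on the metabolic axis
  raw$BMI <- raw$BMI + 0.12 * elf_sum
  raw$WaistCircumference <- raw$WaistCircumference + 0.12 * elf_sum

  # baseline complementary condition, calibrated so the comorbid fraction
  # (mental flag AND complementary flag) hits its target in expectation
  complement <- if (config$task == "cvd") "Diabetes" else "CVD"
  lp_flag <- 0.3 * raw$BMI + 0.25 * elf_sum +
    0.3 * (raw$Hypertension == 1)
  c_flag <- calibrate_intercept(function(c0) {
    mean(p_mental * sigmoid(c0 + lp_flag))
  }, target = config$comorbid_fraction)
  raw[[complement]] <- stats::rbinom(n, 1, sigmoid(c_flag + lp_flag))

  mask <- matrix(FALSE, n, ncol(raw), dimnames = list(NULL, names(raw)))
  cohort <- new_cohort(raw, mask, catalog, sprintf("S%06d", seq_len(n)))
  cohort <- assign_subgroups(cohort, config$task)
  comorbid <- cohort$comorbid

  # proximal linear predictor
  sig <- proximal_signal_vars()
  lp <- numeric(n)
  for (category in names(sig)) {
    scale <- config$proximal_effects[[category]] %||% 0
    if (scale == 0) next
    for (nm in names(sig[[category]])) {
      w <- sig[[category]][[nm]]
      row <- catalog[catalog$name == nm, ]
      x <- if (row$dtype == "categorical") {
        # illness histories: either condition counts, own condition doubly
        as.numeric(raw[[nm]] != "None") +
          as.numeric(raw[[nm]] == if (config$task == "cvd") "CVD" else "Diabetes")
      } else as.numeric(raw[[nm]])
      lp <- lp + scale * w * x
    }
  }
  # piecewise marker coupling: flat below the marker mean, linear above
  marker <- raw$HbA1c
  lp <- lp + config$marker_coupling * pmax(marker - mean(marker), 0)
  # ELF effects: weak main effect, strong comorbid interaction
  lp <- lp + config$elf_main_effect * elf_sum +
    config$elf_comorbid_interaction * elf_sum * comorbid

  noise <- ifelse(comorbid, config$noise_rate_comorbid,
                  config$noise_rate_noncomorbid)
  a <- calibrate_intercept(function(a0) {
    p <- sigmoid(a0 + lp)
    mean((1 - noise) * p + noise * (1 - p))
  }, target = config$prevalence)
  if (is.na(a))
    abort_elf("requested prevalence unreachable under the configured effects",
              "elf_degenerate_config")
  y_true <- stats::rbinom(n, 1, sigmoid(a + lp))
  flip <- stats::rbinom(n, 1, noise)
  cohort$outcome <- as.integer(ifelse(flip == 1, 1L - y_true, y_true))

  encode_features(cohort)
}

# Bisection on an intercept until fn(c) == target (tolerance 0.001 absolute,
# i.e. 0.1 percentage points), at most `max_iter` iterations.
calibrate_intercept <- function(fn, target, lower = -30, upper = 30,
                                tol = 0.001, max_iter = 50) {
  f_lo <- fn(lower) - target
  f_hi <- fn(upper) - target
  if (f_lo > 0 || f_hi < 0) return(NA_real_)
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    f_mid <- fn(mid) - target
    if (abs(f_mid) < tol / 10) break
    if (f_mid > 0) upper <- mid else lower <- mid
  }
  mid
}

#' Blank cells missing-at-random by category
#'
#' Cells of each variable are set missing independently at the category's
#' configured rate. The positive-outcome stratum never exceeds a 25% missing
#' rate by construction (rates are capped at 0.25).
#'
#' @param cohort A generated `elf_cohort`.
#' @param config The [generator_config()] whose `missing_rates` apply.
#' @return The cohort with mask set and masked raw cells set to `NA`
#'   (categoricals) -- the encoded matrix is dropped until re-imputation.
#' @export
inject_missingness <- function(cohort, config) {
  set.seed(derive_seed(config$seed, "missing"))
  catalog <- cohort$catalog
  n <- n_samples(cohort)
  for (nm in names(cohort$raw)) {
    category <- catalog$category[catalog$name == nm]
    rate <- config$missing_rates[[category]] %||% 0
    if (rate <= 0) next
    miss <- stats::runif(n) < rate
    cohort$mask[, nm] <- miss
    cohort$raw[[nm]][miss] <- NA
  }
  cohort$encoded <- NULL
  cohort
}
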