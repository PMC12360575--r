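#' Feature catalogs
#'
#' A feature catalog declares, for every raw variable in a cohort table, its
#' domain category (early-life factor, sociodemographic, blood assay, ...),
#' its type (binary, categorical, continuous), the declared levels of
#' categorical variables, whether it is a laboratory measurement, and whether
#' it belongs to the seven core variables of the published clinical scores
#' for each prediction task. Every downstream subset -- "ELF", "core-7",
#' "non-laboratory" -- is computed from this taxonomy rather than hard-coded.
#'
#' @name catalog
NULL

catalog_categories <- c(
  "ELF", "sociodemographic", "blood_assay", "physical", "lifestyle",
  "psychosocial", "family_history", "medical_history", "mental_health"
)

new_catalog <- function(df) {
  stopifnot(all(c("name", "category", "dtype", "levels", "is_lab",
                  "core7_cvd", "core7_diabetes") %in% names(df)))
  structure(tibble::as_tibble(df), class = c("elf_catalog", class(tibble::tibble())))
}

#' Validate a feature catalog
#'
#' Checks name uniqueness, category and dtype membership, that every
#' categorical variable declares at least two levels, and that exactly seven
#' variables are flagged as core for each task when `check_core7 = TRUE`.
#'
#' @param catalog A catalog tibble (see [default_catalog()]).
#' @param check_core7 Require exactly 7 core variables per task (the default
#'   catalog contract; custom catalogs may relax this).
#' @return The catalog, invisibly, if valid; otherwise an error.
#' @export
validate_catalog <- function(catalog, check_core7 = TRUE) {
  if (anyDuplicated(catalog$name))
    abort_elf("catalog variable names must be unique", "elf_invalid_catalog")
  if (!all(catalog$category %in% catalog_categories))
    abort_elf("unknown catalog category", "elf_invalid_catalog")
  if (!all(catalog$dtype %in% c("binary", "categorical", "continuous")))
    abort_elf("unknown catalog dtype", "elf_invalid_catalog")
  bad <- catalog$dtype == "categorical" &
    vapply(catalog$levels, length, 0L) < 2L
  if (any(bad))
    abort_elf("every categorical variable needs >= 2 declared levels",
              "elf_invalid_catalog")
  if (check_core7) {
    for (task in c("cvd", "diabetes")) {
      n7 <- sum(catalog[[paste0("core7_", task)]])
      if (n7 != 7L)
        abort_elf(sprintf("expected exactly 7 core variables for %s, found %d",
                          task, n7), "elf_invalid_catalog")
    }
  }
  invisible(catalog)
}

#' The default 64-variable feature catalog
#'
#' Mirrors the variable families of a UK-Biobank-style multimorbidity study:
#' 8 early-life factors (ELFs), sociodemographics, blood assays, physical
#' measures, lifestyle, psychosocial indicators, family history, medical
#' history (including baseline CVD, diabetes and hypertension flags) and
#' mental-health history (depression, anxiety). One-hot encoding of the seven
#' multi-level categorical variables expands the 64 raw variables to 83
#' encoded features.
#'
#' Core-7 membership follows the published scores: Framingham for CVD
#' (sex, age, systolic blood pressure, hypertension treatment, smoking,
#' baseline diabetes, BMI) and UKDiabetes for diabetes (sex, age, ethnicity,
#' maternal illness history, waist circumference, BMI, hypertension).
#'
#' @return A catalog tibble with columns `name`, `category`, `dtype`,
#'   `levels` (list column), `is_lab`, `core7_cvd`, `core7_diabetes`.
#' @export
#' @examples
#' cat64 <- default_catalog()
#' nrow(cat64)                     # 64 raw variables
#' sum(cat64$category == "ELF")    # 8 early-life factors
default_catalog <- function() {
  v <- function(name, category, dtype, levels = character(),
                is_lab = FALSE, core7_cvd = FALSE, core7_diabetes = FALSE) {
    tibble::tibble(name = name, category = category, dtype = dtype,
                   levels = list(levels), is_lab = is_lab,
                   core7_cvd = core7_cvd, core7_diabetes = core7_diabetes)
  }
  cat64 <- dplyr::bind_rows(
    # sociodemographic (6)
    v("Age", "sociodemographic", "continuous", core7_cvd = TRUE, core7_diabetes = TRUE),
    v("Sex", "sociodemographic", "binary", core7_cvd = TRUE, core7_diabetes = TRUE),
    v("Ethnicity", "sociodemographic", "categorical",
      c("White", "Asian", "Black", "Other"), core7_diabetes = TRUE),
    v("Qualifications", "sociodemographic", "categorical",
      c("UnivDegree", "ALevels", "GCSE", "ProfQual", "NoneAbove")),
    v("CurrentEmploymentStatus", "sociodemographic", "categorical",
      c("Paid", "Retired", "Homemaker", "SickDisabled", "Unemployed")),
    v("AvgHouseholdIncome", "sociodemographic", "categorical",
      c("Low", "Middle", "High")),
    # early-life factors (8)
    v("MaternalSmokingAroundBirth", "ELF", "binary"),
    v("BreastfedAsABaby", "ELF", "binary"),
    v("PhysicallyAbusedByFamilyAsAChild", "ELF", "binary"),
    v("SexuallyMolestedAsAChild", "ELF", "binary"),
    v("FeltHatedByFamilyMemberAsAChild", "ELF", "binary"),
    v("FeltLovedAsAChild", "ELF", "binary"),
    v("SomeoneToTakeToDoctorWhenNeededAsAChild", "ELF", "binary"),
    v("AdoptedAsAChild", "ELF", "binary"),
    # blood assays (12)
    v("HbA1c", "blood_assay", "continuous", is_lab = TRUE),
    v("Glucose", "blood_assay", "continuous", is_lab = TRUE),
    v("Cholesterol", "blood_assay", "continuous", is_lab = TRUE),
    v("HDLCholesterol", "blood_assay", "continuous", is_lab = TRUE),
    v("LDLDirect", "blood_assay", "continuous", is_lab = TRUE),
    v("Triglycerides", "blood_assay", "continuous", is_lab = TRUE),
    v("ApolipoproteinA", "blood_assay", "continuous", is_lab = TRUE),
    v("ApolipoproteinB", "blood_assay", "continuous", is_lab = TRUE),
    v("CReactiveProtein", "blood_assay", "continuous", is_lab = TRUE),
    v("Urate", "blood_assay", "continuous", is_lab = TRUE),
    v("VitaminD", "blood_assay", "continuous", is_lab = TRUE),
    v("Creatinine", "blood_assay", "continuous", is_lab = TRUE),
    # physical measures (10)
    v("BMI", "physical", "continuous", core7_cvd = TRUE, core7_diabetes = TRUE),
    v("Height", "physical", "continuous"),
    v("Weight", "physical", "continuous"),
    v("WaistCircumference", "physical", "continuous", core7_diabetes = TRUE),
    v("HipCircumference", "physical", "continuous"),
    v("BodyFatPercentage", "physical", "continuous"),
    v("SystolicBloodPressure", "physical", "continuous", core7_cvd = TRUE),
    v("DiastolicBloodPressure", "physical", "continuous"),
    v("PulseRate", "physical", "continuous"),
    v("HandGripStrength", "physical", "continuous"),
    # lifestyle (14)
    v("SmokingStatus", "lifestyle", "binary", core7_cvd = TRUE),
    v("AlcoholIntakeFrequency", "lifestyle", "continuous"),
    v("PhysicalActivity", "lifestyle", "continuous"),
    v("SleepDuration", "lifestyle", "continuous"),
    v("FreshFruitIntake", "lifestyle", "continuous"),
    v("CookedVegetableIntake", "lifestyle", "continuous"),
    v("RawVegetableIntake", "lifestyle", "continuous"),
    v("ProcessedMeatIntake", "lifestyle", "continuous"),
    v("PorkIntake", "lifestyle", "continuous"),
    v("PoultryIntake", "lifestyle", "continuous"),
    v("BeefIntake", "lifestyle", "continuous"),
    v("CerealIntake", "lifestyle", "continuous"),
    v("WaterIntake", "lifestyle", "continuous"),
    v("SaltAddedToFood", "lifestyle", "binary"),
    # psychosocial (6)
    v("MoodSwings", "psychosocial", "binary"),
    v("Irritability", "psychosocial", "binary"),
    v("Loneliness", "psychosocial", "binary"),
    v("OverallHealthRating", "psychosocial", "continuous"),
    v("LeisureSocialActivities", "psychosocial", "binary"),
    v("RiskTaking", "psychosocial", "binary"),
    # family history (3)
    v("IllnessesOfMother", "family_history", "categorical",
      c("None", "CVD", "Diabetes"), core7_diabetes = TRUE),
    v("IllnessesOfFather", "family_history", "categorical",
      c("None", "CVD", "Diabetes")),
    v("IllnessesOfSiblings", "family_history", "categorical",
      c("None", "CVD", "Diabetes")),
    # medical history (3)
    v("Hypertension", "medical_history", "binary",
      core7_cvd = TRUE, core7_diabetes = TRUE),
    v("Diabetes", "medical_history", "binary", core7_cvd = TRUE),
    v("CVD", "medical_history", "binary"),
    # mental health (2)
    v("Depression", "mental_health", "binary"),
    v("Anxiety", "mental_health", "binary")
  )
  validate_catalog(new_catalog(cat64))
}

#' Encoded column names for catalog variables
#'
#' Binary and continuous variables contribute one column named after the
#' variable; a k-level categorical contributes k indicator columns named
#' `<var>_<level>` (full one-hot, no reference level dropped).
#'
#' @param catalog A catalog tibble.
#' @param vars Raw variable names (default: all).
#' @return Character vector of encoded column names, in catalog order.
#' @export
encoded_columns <- function(catalog, vars = catalog$name) {
  rows <- catalog[match(vars, catalog$name), ]
  unlist(purrr::pmap(rows, function(name, dtype, levels, ...) {
    if (dtype == "categorical") paste(name, levels, sep = "_") else name
  }), use.names = FALSE)
}

# Map each encoded column back to its raw variable.
encoded_to_raw <- function(catalog) {
  cols <- encoded_columns(catalog)
  raw <- unlist(purrr::pmap(catalog, function(name, dtype, levels, ...) {
    rep(name, if (dtype == "categorical") length(levels) else 1L)
  }), use.names = FALSE)
  stats::setNames(raw, cols)
}

#' Read / write a feature catalog as JSON
#'
#' @param path Path to a JSON catalog file.
#' @return `read_catalog()` returns a validated catalog tibble.
#' @export
read_catalog <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  df <- dplyr::bind_rows(lapply(raw$variables, function(e) {
    tibble::tibble(
      name = e$name, category = e$category, dtype = e$dtype,
      levels = list(as.character(unlist(e$levels %||% character()))),
      is_lab = isTRUE(e$is_lab),
      core7_cvd = "cvd" %in% unlist(e$core7_for %||% character()),
      core7_diabetes = "diabetes" %in% unlist(e$core7_for %||% character())
    )
  }))
  validate_catalog(new_catalog(df), check_core7 = isTRUE(raw$check_core7))
}

#' @rdname read_catalog
#' @param catalog A catalog tibble.
#' @param check_core7 Recorded in the JSON so the 7-core contract survives the
#'   round trip.
#' @export
write_catalog <- function(catalog, path, check_core7 = TRUE) {
  vars <- purrr::pmap(catalog, function(name, category, dtype, levels, is_lab,
                                        core7_cvd, core7_diabetes) {
    list(name = name, category = category, dtype = dtype,
         levels = as.list(levels), is_lab = is_lab,
         core7_for = as.list(c(if (core7_cvd) "cvd",
                               if (core7_diabetes) "diabetes")))
  })
  jsonlite::write_json(list(check_core7 = check_core7, variables = vars),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
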