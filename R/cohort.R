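#' Cohort objects
#'
#' An `elf_cohort` bundles one prediction task's data: the raw samples-by-
#' variables table, the missingness mask, the catalog it was read against,
#' and (once computed) the encoded feature matrix, the binary outcome and the
#' comorbidity subgroup flag. Raw categorical values are stored as character
#' levels, binary variables as 0/1, continuous variables as doubles.
#'
#' @name cohort
NULL

new_cohort <- function(raw, mask, catalog, sample_ids,
                       encoded = NULL, outcome = NULL, comorbid = NULL,
                       task = NULL) {
  structure(list(raw = raw, mask = mask, catalog = catalog,
                 sample_ids = sample_ids, encoded = encoded,
                 outcome = outcome, comorbid = comorbid, task = task),
            class = "elf_cohort")
}

#' @export
print.elf_cohort <- function(x, ...) {
  cat("<elf_cohort> ", nrow(x$raw), " samples x ", ncol(x$raw),
      " raw variables\n", sep = "")
  cat("  encoded: ", if (is.null(x$encoded)) "no" else
    paste0(ncol(x$encoded), " features"), "\n", sep = "")
  cat("  missing cells: ", sum(x$mask), "\n", sep = "")
  if (!is.null(x$task))
    cat("  task: ", x$task, "; outcome prevalence ",
        round(mean(x$outcome), 4), "\n", sep = "")
  if (!is.null(x$comorbid))
    cat("  comorbid fraction: ", round(mean(x$comorbid), 4), "\n", sep = "")
  invisible(x)
}

#' Number of samples in a cohort
#' @param x An `elf_cohort`.
#' @export
n_samples <- function(x) nrow(x$raw)

#' Subset a cohort by row
#'
#' Keeps raw table, mask, encoded matrix, outcome and subgroup labels in
#' lockstep.
#'
#' @param cohort An `elf_cohort`.
#' @param rows Integer or logical row index.
#' @return The subset cohort.
#' @export
subset_cohort <- function(cohort, rows) {
  new_cohort(
    raw = cohort$raw[rows, , drop = FALSE],
    mask = cohort$mask[rows, , drop = FALSE],
    catalog = cohort$catalog,
    sample_ids = cohort$sample_ids[rows],
    encoded = if (!is.null(cohort$encoded)) cohort$encoded[rows, , drop = FALSE],
    outcome = cohort$outcome[rows],
    comorbid = cohort$comorbid[rows],
    task = cohort$task
  )
}

#' Load a cohort table against a catalog
#'
#' Reads a delimited text table (CSV by default; empty string = missing) whose
#' header must match catalog variable names, parses values according to the
#' declared types, and records missing cells in the mask. No encoding or
#' imputation is performed here.
#'
#' Columns named `sample_id`, `outcome` and `comorbid` are treated as
#' metadata, not catalog variables.
#'
#' @param table_path Path to the delimited table.
#' @param catalog A catalog tibble or a path to a JSON catalog.
#' @param sep Field separator (`","` default, `"\t"` for TSV).
#' @return An `elf_cohort`.
#' @export
load_cohort <- function(table_path, catalog, sep = ",") {
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  df <- utils::read.table(table_path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"",
                          stringsAsFactors = FALSE)
  meta_cols <- intersect(c("sample_id", "outcome", "comorbid"), names(df))
  vars <- setdiff(names(df), meta_cols)
  unknown <- setdiff(vars, catalog$name)
  if (length(unknown) > 0)
    abort_elf(paste0("column(s) not in catalog: ",
                     paste(unknown, collapse = ", ")), "elf_unknown_variable")
  raw <- tibble::as_tibble(df[vars])
  mask <- as.matrix(raw == "" | is.na(raw))
  dimnames(mask) <- list(NULL, vars)
  for (i in seq_along(vars)) {
    nm <- vars[i]
    row <- catalog[catalog$name == nm, ]
    vals <- raw[[nm]]
    vals[mask[, nm]] <- NA
    if (row$dtype == "categorical") {
      bad <- !is.na(vals) & !(vals %in% row$levels[[1]])
      if (any(bad))
        abort_elf(sprintf("value(s) outside declared levels for %s: %s", nm,
                          paste(unique(vals[bad]), collapse = ", ")),
                  "elf_level_mismatch")
      raw[[nm]] <- vals
    } else {
      raw[[nm]] <- as.numeric(vals)
    }
  }
  sample_ids <- if ("sample_id" %in% meta_cols) df$sample_id else
    sprintf("S%06d", seq_len(nrow(df)))
  outcome <- if ("outcome" %in% meta_cols) as.integer(df$outcome)
  comorbid <- if ("comorbid" %in% meta_cols) as.logical(as.integer(df$comorbid))
  new_cohort(raw, mask, catalog, sample_ids,
             outcome = outcome, comorbid = comorbid)
}

#' Write a cohort's raw table to delimited text
#'
#' Inverse of [load_cohort()]: missing cells become empty strings; outcome and
#' subgroup labels are written alongside when present.
#'
#' @param cohort An `elf_cohort`.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  out <- cohort$raw
  for (nm in names(out)) {
    v <- as.character(out[[nm]])
    v[cohort$mask[, nm]] <- ""
    v[is.na(v)] <- ""
    out[[nm]] <- v
  }
  out <- cbind(sample_id = cohort$sample_ids, out)
  if (!is.null(cohort$outcome)) out$outcome <- cohort$outcome
  if (!is.null(cohort$comorbid)) out$comorbid <- as.integer(cohort$comorbid)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-hot encode a cohort's raw table
#'
#' Binary and continuous variables map to a single column; a k-level
#' categorical maps to k indicator columns `<var>_<level>` (no reference
#' level is dropped). With the default 64-variable catalog this yields 83
#' encoded features. Requires a complete table (impute first).
#'
#' @param cohort An `elf_cohort` with no remaining missing values.
#' @return The cohort with `$encoded` set (samples x features numeric matrix).
#' @export
encode_features <- function(cohort) {
  if (any(cohort$mask))
    abort_elf("cohort still has missing values; run impute_missing() first",
              "elf_missing_values")
  catalog <- cohort$catalog[cohort$catalog$name %in% names(cohort$raw), ]
  cols <- purrr::pmap(catalog, function(name, dtype, levels, ...) {
    v <- cohort$raw[[name]]
    if (dtype == "categorical") {
      m <- vapply(levels, function(l) as.numeric(v == l),
                  numeric(length(v)))
      colnames(m) <- paste(name, levels, sep = "_")
      m
    } else {
      matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, name))
    }
  })
  cohort$encoded <- do.call(cbind, cols)
  cohort
}

#' Recover raw values from an encoded matrix
#'
#' Round-trip inverse of [encode_features()] on complete data; used to verify
#' that one-hot encoding is lossless.
#'
#' @param encoded Encoded matrix from [encode_features()].
#' @param catalog The catalog used to encode.
#' @return A raw-format tibble.
#' @export
decode_features <- function(encoded, catalog) {
  present <- vapply(catalog$name, function(nm)
    all(encoded_columns(catalog, nm) %in% colnames(encoded)), NA)
  catalog <- catalog[present, ]
  out <- purrr::pmap(catalog, function(name, dtype, levels, ...) {
    if (dtype == "categorical") {
      cols <- paste(name, levels, sep = "_")
      idx <- max.col(encoded[, cols, drop = FALSE])
      levels[idx]
    } else {
      as.numeric(encoded[, name])
    }
  })
  names(out) <- catalog$name
  tibble::as_tibble(out)
}

#' Assign comorbidity subgroup labels
#'
#' A sample is comorbid when a mental disorder (depression or anxiety) co-
#' occurs at baseline with the condition complementary to the prediction
#' task: baseline diabetes when predicting CVD, baseline CVD when predicting
#' diabetes. The partition is exhaustive and disjoint.
#'
#' @param cohort An `elf_cohort` whose raw table contains `Depression`,
#'   `Anxiety` and the complementary condition flag.
#' @param task `"cvd"` or `"diabetes"`.
#' @return The cohort with `$comorbid` and `$task` set.
#' @export
assign_subgroups <- function(cohort, task = c("cvd", "diabetes")) {
  task <- match.arg(task)
  complement <- if (task == "cvd") "Diabetes" else "CVD"
  need <- c("Depression", "Anxiety", complement)
  missing_flags <- setdiff(need, names(cohort$raw))
  if (length(missing_flags) > 0)
    abort_elf(paste0("required diagnosis flag(s) absent: ",
                     paste(missing_flags, collapse = ", ")),
              "elf_missing_flag")
  mental <- cohort$raw$Depression == 1 | cohort$raw$Anxiety == 1
  cohort$comorbid <- as.logical(mental & cohort$raw[[complement]] == 1)
  cohort$task <- task
  cohort
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `n_folds` folds so that per-fold positive
#' counts differ by at most one from perfect proportionality (outcome-
#' stratified assignment).
#'
#' @param cohort An `elf_cohort` with `$outcome` set, or a binary vector.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
make_folds <- function(cohort, n_folds = 5, seed = 1) {
  y <- if (inherits(cohort, "elf_cohort")) cohort$outcome else as.integer(cohort)
  stopifnot(!is.null(y))
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}
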