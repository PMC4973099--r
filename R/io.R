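# Cohort CSV and configuration I/O. Missing values are empty cells, never
# sentinel numbers; units are fixed by column name.

COHORT_COLS <- c(
  "id", "age_years", "sex", "htn", "dm", "ihd", "apache2", "sofa_adm",
  "sofa_72h", "vasopressor", "mech_vent", "ivf_pre6h_ml", "ivf_post6h_ml",
  "E_cm_s", "A_cm_s", "e_prime_cm_s", "DT_ms", "LAVI_ml_m2", "EF_pct",
  "TAPSE_mm", "s_prime_cm_s", "died_28d", "icu_free_days", "latent_grade"
)
COHORT_NUMERIC <- setdiff(COHORT_COLS, c("id", "sex", "latent_grade"))

empty_cohort <- function() {
  cols <- stats::setNames(
    lapply(COHORT_COLS, function(cl) {
      if (cl %in% COHORT_NUMERIC) numeric(0) else character(0)
    }), COHORT_COLS)
  tibble::as_tibble(cols)
}

#' Read a cohort CSV
#'
#' Reads and validates a per-patient cohort table. The first 23 schema
#' columns are required in order (`latent_grade` is optional and synthetic
#' only); extra trailing columns -- e.g. grading verdicts -- are preserved.
#' Empty cells become `NA`. Malformed cells are reported with row and
#' column; negative measurements are rejected.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  required <- setdiff(COHORT_COLS, "latent_grade")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!identical(names(df)[seq_along(required)], required) &&
      !identical(names(df)[seq_len(length(COHORT_COLS))][
        seq_along(required)], required)) {
    stop("cohort columns out of order; expected leading columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  for (cl in intersect(COHORT_NUMERIC, names(df))) {
    x <- df[[cl]]
    if (!is.numeric(x)) {
      raw <- as.character(x)
      conv <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(conv))
      if (length(bad) > 0) {
        problems <- c(problems, sprintf("row %d, column %s: '%s' is not numeric",
                                        bad, cl, raw[bad]))
      }
      df[[cl]] <- conv
    }
  }
  for (cl in intersect(MEASUREMENT_COLS, names(df))) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("row %d, column %s: non-positive value %s",
                                      bad, cl, format(df[[cl]][bad])))
    }
  }
  if (length(problems) > 0) {
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a cohort CSV
#'
#' Writes the table with empty cells for missing values. Written files
#' round-trip through [read_cohort()] losslessly.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}

# Config serialization. The copula matrix travels as a list of rows.
config_to_list <- function(cfg) {
  cfg <- validate_generator_config(cfg)
  out <- unclass(cfg)
  out$copula <- apply(cfg$copula, 1, as.numeric, simplify = FALSE)
  out$grade_weights <- as.list(cfg$grade_weights)
  out$missingness <- as.list(cfg$missingness)
  out$outcome$coef <- as.list(cfg$outcome$coef)
  out
}

list_to_config <- function(x) {
  x$grade_weights <- unlist(x$grade_weights)
  x$missingness <- unlist(x$missingness)
  x$outcome$coef <- unlist(x$outcome$coef)
  if (!is.null(x$copula)) {
    R <- do.call(rbind, lapply(x$copula, as.numeric))
    dimnames(R) <- list(ECHO_PARAMS, ECHO_PARAMS)
    x$copula <- R
  }
  for (p in names(x$params)) x$params[[p]] <- lapply(x$params[[p]], unlist)
  validate_generator_config(x)
}

#' Write a generator configuration to JSON or YAML
#'
#' @param cfg Generator config.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(cfg, path) {
  x <- config_to_list(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    stop("config path must end in .json, .yaml or .yml", call. = FALSE)
  }
  invisible(path)
}

#' Read and validate a generator configuration
#'
#' @param path JSON or YAML config path.
#' @return A validated `dd_generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  list_to_config(x)
}
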