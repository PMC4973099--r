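# Echocardiographic measurement panels: construction, validation,
# cycle averaging and ratio derivation.

# Canonical measurement columns of a cohort table, with units fixed by name.
MEASUREMENT_COLS <- c(
  "E_cm_s", "A_cm_s", "e_prime_cm_s", "DT_ms", "LAVI_ml_m2",
  "EF_pct", "TAPSE_mm", "s_prime_cm_s"
)
RATIO_COLS <- c("E_over_A", "E_over_e_prime")

#' Build a table of echocardiographic measurement panels
#'
#' Assembles per-patient averaged Doppler / 2-D parameters into a tibble with
#' the package's canonical column names, validates positivity constraints and
#' derives the `E/A` and `E/e'` ratios. A missing measurement is `NA`; ratios
#' are only defined where both operands are present.
#'
#' @param E,A Peak early / late diastolic mitral inflow velocity, cm/s.
#' @param e_prime Peak early diastolic velocity of the septal mitral annulus
#'   (tissue Doppler), cm/s.
#' @param DT Deceleration time of early diastolic filling, ms.
#' @param LAVI Left atrial volume index, ml/m^2.
#' @param EF Left ventricular ejection fraction, percent.
#' @param TAPSE Tricuspid annular plane systolic excursion, mm (carried
#'   through only; not used in grading).
#' @param s_prime Systolic septal annular velocity, cm/s (carried only).
#'
#' @return A tibble with one row per patient, columns `E_cm_s`, `A_cm_s`,
#'   `e_prime_cm_s`, `DT_ms`, `LAVI_ml_m2`, `EF_pct`, `TAPSE_mm`,
#'   `s_prime_cm_s`, `E_over_A`, `E_over_e_prime`.
#' @examples
#' echo_measurements(E = 90, e_prime = 9)           # E/e' = 10
#' echo_measurements(E = 90, A = NA, e_prime = 5.8) # E/A stays NA
#' @export
echo_measurements <- function(E = NA_real_, A = NA_real_, e_prime = NA_real_,
                              DT = NA_real_, LAVI = NA_real_, EF = NA_real_,
                              TAPSE = NA_real_, s_prime = NA_real_) {
  m <- tibble::tibble(
    E_cm_s = as.numeric(E), A_cm_s = as.numeric(A),
    e_prime_cm_s = as.numeric(e_prime), DT_ms = as.numeric(DT),
    LAVI_ml_m2 = as.numeric(LAVI), EF_pct = as.numeric(EF),
    TAPSE_mm = as.numeric(TAPSE), s_prime_cm_s = as.numeric(s_prime)
  )
  validate_measurements(m)
  derive_ratios(m)
}

#' Validate measurement positivity invariants
#'
#' Velocities, times and volumes must be strictly positive where present and
#' EF must lie in (0, 100]. Violations are reported with row and column.
#'
#' @param m A data frame containing (a subset of) the canonical measurement
#'   columns.
#' @return `m`, invisibly, if valid; otherwise an error listing offenders.
#' @export
validate_measurements <- function(m) {
  offenders <- character(0)
  for (col in intersect(MEASUREMENT_COLS, names(m))) {
    x <- m[[col]]
    bad <- which(!is.na(x) & (!is.finite(x) | x <= 0))
    if (col == "EF_pct") bad <- union(bad, which(!is.na(x) & x > 100))
    if (length(bad) > 0) {
      offenders <- c(offenders, sprintf("row %d, column %s (value %s)",
                                        bad, col, format(x[bad])))
    }
  }
  if (length(offenders) > 0) {
    stop("invalid measurement value(s): ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  invisible(m)
}

#' Average a series of per-beat measurements
#'
#' Each reported echocardiographic parameter is the arithmetic mean of
#' measurements from consecutive cardiac cycles -- three when image quality
#' allows, two as a fallback. The number of beats used is recorded on the
#' result as attribute `n_beats`.
#'
#' @param values Numeric vector of per-beat raw values (length >= 1), all
#'   finite and positive.
#' @return The mean, with attribute `n_beats`.
#' @examples
#' average_cycles(c(80, 90, 100)) # 90, n_beats = 3
#' @export
average_cycles <- function(values) {
  if (length(values) == 0) {
    stop("cycle series is empty: at least one beat is required", call. = FALSE)
  }
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0)) {
    stop("cycle series must contain finite positive values", call. = FALSE)
  }
  structure(mean(values), n_beats = length(values))
}

#' Derive the E/A and E/e' ratios
#'
#' Adds (or recomputes) `E_over_A` and `E_over_e_prime` on a measurement
#' table. A ratio is present iff both operands are; an absent operand leaves
#' the ratio `NA`, never zero. Ratios are computed from the cycle-averaged
#' parameters, not per beat.
#'
#' @param m Data frame with columns `E_cm_s`, `A_cm_s`, `e_prime_cm_s`
#'   (any may be `NA`).
#' @return `m` with `E_over_A` and `E_over_e_prime` columns set.
#' @export
derive_ratios <- function(m) {
  for (col in c("E_cm_s", "A_cm_s", "e_prime_cm_s")) {
    if (!col %in% names(m)) m[[col]] <- NA_real_
    denom_bad <- !is.na(m[[col]]) & m[[col]] <= 0
    if (any(denom_bad)) {
      stop("non-positive value in ", col, " at row(s) ",
           paste(which(denom_bad), collapse = ", "), call. = FALSE)
    }
  }
  m$E_over_A <- ifelse(!is.na(m$E_cm_s) & !is.na(m$A_cm_s),
                       m$E_cm_s / m$A_cm_s, NA_real_)
  m$E_over_e_prime <- ifelse(!is.na(m$E_cm_s) & !is.na(m$e_prime_cm_s),
                             m$E_cm_s / m$e_prime_cm_s, NA_real_)
  m
}
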