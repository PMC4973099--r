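# Diastolic function grading engines.
#
# Two categorization schemes over the same measurement panel:
#   * ASE 2009: a two-stage vote-intersection scheme. Stage 1 decides
#     normal vs dysfunction from septal e' and LAVI; stage 2 grades the
#     dysfunction from E/A, DT and E/e'. Available parameters each vote a
#     set of grades; the verdict is the intersection.
#   * Simplified: a two-parameter decision tree on septal e' and E/e' whose
#     bins partition the whole plane, so a complete panel always grades and
#     discordance is structurally impossible.
#
# Verdict semantics: "categorized" (exactly one grade), "discordant"
# (available parameters support no common grade), "insufficient" (too little
# information to pin a single grade).

GRADE_LEVELS <- c("0", "I", "II", "III")
STATUS_LEVELS <- c("categorized", "discordant", "insufficient")

#' Numeric value of a diastolic dysfunction grade
#'
#' Maps the grade labels `"0", "I", "II", "III"` to 0:3 (useful for grade
#' differences). `NA` maps to `NA`.
#' @param grade Character vector of grade labels.
#' @return Integer vector.
#' @export
grade_number <- function(grade) {
  match(grade, GRADE_LEVELS) - 1L
}

# e' threshold: >= 8 cm/s is normal relaxation. LAVI threshold: >= 34 ml/m2
# is enlarged (votes dysfunction).
E_PRIME_NORMAL <- 8
LAVI_ENLARGED <- 34

#' Stage-1 ASE votes: presence of diastolic dysfunction
#'
#' Septal e' and LAVI each vote `"normal"` or `"dysfunction"`:
#' e' >= 8 cm/s votes normal, e' < 8 dysfunction; LAVI < 34 ml/m^2 votes
#' normal, LAVI >= 34 dysfunction. An absent parameter contributes no vote.
#'
#' @param m Measurement table (see [echo_measurements()]).
#' @return A list (one element per row) of named lists mapping `e_prime`
#'   and `LAVI` to their vote (character), absent parameters omitted.
#' @export
ase_stage1_votes <- function(m) {
  m <- ensure_ratios(m)
  n <- nrow(m)
  lapply(seq_len(n), function(i) {
    v <- list()
    if (!is.na(m$e_prime_cm_s[i])) {
      v$e_prime <- if (m$e_prime_cm_s[i] >= E_PRIME_NORMAL) "normal" else "dysfunction"
    }
    if (!is.na(m$LAVI_ml_m2[i])) {
      v$LAVI <- if (m$LAVI_ml_m2[i] < LAVI_ENLARGED) "normal" else "dysfunction"
    }
    v
  })
}

# Stage-2 vote tables. Grade-boundary conventions: the canonical thresholds
# leave gaps (E/e' in (8,9) and (12,13); E/A in (1.5,2)); values in a gap
# vote the union of the adjacent grades rather than abstaining, preserving
# the ambiguity such panels carry. DT 160 and 200 ms, and E/A 0.8 and 1.5,
# belong to the middle (grade II) bin.
vote_E_over_A <- function(x) {
  if (is.na(x)) return(NULL)
  if (x < 0.8) "I"
  else if (x <= 1.5) "II"
  else if (x < 2) c("II", "III")
  else "III"
}

vote_DT <- function(x) {
  if (is.na(x)) return(NULL)
  if (x > 200) "I"
  else if (x >= 160) "II"
  else "III"
}

vote_E_over_e_prime <- function(x) {
  if (is.na(x)) return(NULL)
  if (x <= 8) "I"
  else if (x < 9) c("I", "II")
  else if (x <= 12) "II"
  else if (x < 13) c("II", "III")
  else "III"
}

#' Stage-2 ASE votes: grade of dysfunction
#'
#' Given dysfunction, E/A, DT and E/e' each vote a set of grades in
#' \{I, II, III\}: E/A < 0.8 votes \{I\}, 0.8--1.5 \{II\}, (1.5, 2)
#' \{II, III\}, >= 2 \{III\}; DT > 200 ms votes \{I\}, 160--200 \{II\},
#' < 160 \{III\}; E/e' <= 8 votes \{I\}, (8, 9) \{I, II\}, 9--12 \{II\},
#' (12, 13) \{II, III\}, >= 13 \{III\}. LAVI contributes no stage-2
#' discrimination; absent parameters contribute no vote.
#'
#' @inheritParams ase_stage1_votes
#' @return A list (one element per row) of named lists mapping `E_over_A`,
#'   `DT` and `E_over_e_prime` to character vectors of supported grades.
#' @export
ase_stage2_votes <- function(m) {
  m <- ensure_ratios(m)
  lapply(seq_len(nrow(m)), function(i) {
    v <- list()
    ea <- vote_E_over_A(m$E_over_A[i])
    dt <- vote_DT(m$DT_ms[i])
    ee <- vote_E_over_e_prime(m$E_over_e_prime[i])
    if (!is.null(ea)) v$E_over_A <- ea
    if (!is.null(dt)) v$DT <- dt
    if (!is.null(ee)) v$E_over_e_prime <- ee
    v
  })
}

# Add ratio columns if the caller handed a raw measurement table.
ensure_ratios <- function(m) {
  for (col in MEASUREMENT_COLS) if (!col %in% names(m)) m[[col]] <- NA_real_
  if (!all(RATIO_COLS %in% names(m))) m <- derive_ratios(m)
  m
}

#' Grade a panel with the ASE 2009 scheme
#'
#' Stage 1 intersects the available presence votes (from e' and LAVI):
#' a conflict is `discordant`, no votes is `insufficient`, agreement on
#' normal is grade 0. On agreement on dysfunction, stage 2 intersects the
#' available grade votes (from E/A, DT, E/e'): a singleton is that grade,
#' an empty intersection is `discordant`, and several surviving grades --
#' or no stage-2 parameter at all -- is `insufficient`. A single available
#' parameter suffices when it pins one grade. All votes are retained for
#' audit.
#'
#' @param m Measurement table; ratios are derived if absent.
#' @return A tibble with one row per panel: `definition` (`"ase2009"`),
#'   `status` (`categorized` / `discordant` / `insufficient`), `grade`
#'   (`"0"`--`"III"`, `NA` unless categorized) and `votes` (list column of
#'   the per-parameter vote sets).
#' @examples
#' m <- echo_measurements(E = 113.6, A = 30.2, e_prime = 7.0,
#'                        DT = 142, LAVI = 34.7)
#' classify_ase2009(m)
#' @export
classify_ase2009 <- function(m) {
  m <- ensure_ratios(m)
  n <- nrow(m)
  s1 <- ase_stage1_votes(m)
  s2 <- ase_stage2_votes(m)
  status <- character(n)
  grade <- rep(NA_character_, n)
  votes <- vector("list", n)
  for (i in seq_len(n)) {
    votes[[i]] <- list(stage1 = s1[[i]], stage2 = s2[[i]])
    pres <- unique(unlist(s1[[i]], use.names = FALSE))
    if (length(pres) == 0) {
      status[i] <- "insufficient"
    } else if (length(pres) > 1) {
      status[i] <- "discordant"
    } else if (pres == "normal") {
      status[i] <- "categorized"
      grade[i] <- "0"
    } else {
      g <- s2[[i]]
      if (length(g) == 0) {
        status[i] <- "insufficient"
      } else {
        inter <- Reduce(intersect, g)
        if (length(inter) == 0) {
          status[i] <- "discordant"
        } else if (length(inter) == 1) {
          status[i] <- "categorized"
          grade[i] <- inter
        } else {
          status[i] <- "insufficient"
        }
      }
    }
  }
  tibble::tibble(definition = "ase2009", status = status, grade = grade,
                 votes = votes)
}

#' Grade a panel with the simplified two-parameter scheme
#'
#' Decision tree on septal e' and E/e' alone, with bins widened to cover
#' every value: e' >= 8 cm/s is grade 0 (E/e' is not consulted); otherwise
#' E/e' <= 8 is grade I, 8 < E/e' < 13 grade II, E/e' >= 13 grade III.
#' An absent e' -- or an absent E/e' when e' < 8 -- is `insufficient`.
#' Because the bins partition the plane, a complete panel always receives
#' exactly one grade and `discordant` is unreachable.
#'
#' @inheritParams classify_ase2009
#' @return A tibble with `definition` (`"simplified"`), `status`, `grade`.
#' @examples
#' classify_simplified(echo_measurements(E = 102.7, e_prime = 5.8)) # III
#' @export
classify_simplified <- function(m) {
  m <- ensure_ratios(m)
  e <- m$e_prime_cm_s
  ee <- m$E_over_e_prime
  grade <- rep(NA_character_, nrow(m))
  status <- rep("insufficient", nrow(m))
  normal <- !is.na(e) & e >= E_PRIME_NORMAL
  grade[normal] <- "0"
  low <- !is.na(e) & e < E_PRIME_NORMAL & !is.na(ee)
  grade[low & ee <= 8] <- "I"
  grade[low & ee > 8 & ee < 13] <- "II"
  grade[low & ee >= 13] <- "III"
  status[!is.na(grade)] <- "categorized"
  tibble::tibble(definition = "simplified", status = status, grade = grade)
}

#' Grade a whole cohort under one or both definitions
#'
#' Augments a cohort table (see [read_cohort()] for the schema) with the
#' verdicts of the requested engine(s). For a single definition the columns
#' `definition`, `status`, `grade` and (ASE only) `votes_json` are appended;
#' for `"both"` the prefixed columns `ase_status`, `ase_grade`,
#' `ase_votes_json`, `simp_status`, `simp_grade` are appended.
#'
#' @param cohort Cohort data frame containing the measurement columns.
#' @param definition `"ase2009"`, `"simplified"` or `"both"`.
#' @return The augmented tibble.
#' @export
grade_cohort <- function(cohort, definition = c("both", "ase2009", "simplified")) {
  definition <- match.arg(definition)
  m <- ensure_ratios(cohort)
  out <- tibble::as_tibble(m)
  if (definition == "ase2009" || definition == "both") {
    a <- classify_ase2009(m)
    vj <- vapply(a$votes, function(v) {
      as.character(jsonlite::toJSON(v, auto_unbox = FALSE))
    }, character(1))
    if (definition == "both") {
      out$ase_status <- a$status
      out$ase_grade <- a$grade
      out$ase_votes_json <- vj
    } else {
      out$definition <- a$definition
      out$status <- a$status
      out$grade <- a$grade
      out$votes_json <- vj
    }
  }
  if (definition == "simplified" || definition == "both") {
    s <- classify_simplified(m)
    if (definition == "both") {
      out$simp_status <- s$status
      out$simp_grade <- s$grade
    } else {
      out$definition <- s$definition
      out$status <- s$status
      out$grade <- s$grade
    }
  }
  out
}

#' Concordance between the two definitions
#'
#' Cross-tabulates categorization status under both engines and, among
#' patients categorized by both, the distribution of absolute grade
#' differences (0, 1, >= 2).
#'
#' @param graded A cohort graded with `grade_cohort(..., "both")`, i.e.
#'   carrying `ase_status`, `ase_grade`, `simp_status`, `simp_grade`.
#' @return An object of class `dd_concordance`: a list with `n`, a
#'   `status` tibble (counts categorized by both / ASE only / simplified
#'   only / neither) and a `grade_diff` tibble (counts at difference
#'   0 / 1 / >= 2 among both-categorized).
#' @export
compare_definitions <- function(graded) {
  stopifnot(all(c("ase_status", "ase_grade", "simp_status", "simp_grade")
                %in% names(graded)))
  a_cat <- graded$ase_status == "categorized"
  s_cat <- graded$simp_status == "categorized"
  status <- tibble::tibble(
    group = c("both", "ase_only", "simplified_only", "neither"),
    count = c(sum(a_cat & s_cat), sum(a_cat & !s_cat),
              sum(!a_cat & s_cat), sum(!a_cat & !s_cat))
  )
  both <- a_cat & s_cat
  d <- abs(grade_number(graded$ase_grade[both]) -
             grade_number(graded$simp_grade[both]))
  grade_diff <- tibble::tibble(
    abs_difference = c("0", "1", ">=2"),
    count = c(sum(d == 0), sum(d == 1), sum(d >= 2))
  )
  structure(list(n = nrow(graded), status = status, grade_diff = grade_diff),
            class = "dd_concordance")
}

#' @export
print.dd_concordance <- function(x, ...) {
  cat("Definition concordance over", x$n, "patients\n")
  cat("Categorization status:\n")
  print(as.data.frame(x$status), row.names = FALSE)
  cat("Absolute grade difference among both-categorized:\n")
  print(as.data.frame(x$grade_diff), row.names = FALSE)
  invisible(x)
}
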