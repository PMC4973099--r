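# Independent brute-force oracle for the ASE 2009 engine, written as
# interval containment over the full grade set rather than a decision tree:
# a grade survives iff every available parameter's value lies in that
# grade's supporting interval; the verdict applies the same
# singleton/empty/multiple rule.

oracle_supports <- function(param, x, g) {
  switch(param,
    EA = switch(g, I = x < 0.8, II = x >= 0.8 & x < 2, III = x > 1.5),
    DT = switch(g, I = x > 200, II = x >= 160 & x <= 200, III = x < 160),
    Ee = switch(g, I = x < 9, II = x > 8 & x < 13, III = x > 12)
  )
}

oracle_ase <- function(E = NA, A = NA, e = NA, DT = NA, LAVI = NA) {
  EA <- if (!is.na(E) && !is.na(A)) E / A else NA
  Ee <- if (!is.na(E) && !is.na(e)) E / e else NA
  pres <- character(0)
  if (!is.na(e)) pres <- c(pres, if (e >= 8) "normal" else "dysfunction")
  if (!is.na(LAVI)) pres <- c(pres, if (LAVI >= 34) "dysfunction" else "normal")
  u <- unique(pres)
  if (length(u) == 0) return(list(status = "insufficient", grade = NA_character_))
  if (length(u) > 1) return(list(status = "discordant", grade = NA_character_))
  if (u == "normal") return(list(status = "categorized", grade = "0"))
  avail <- list(EA = EA, DT = DT, Ee = Ee)
  avail <- avail[!vapply(avail, is.na, logical(1))]
  if (length(avail) == 0) return(list(status = "insufficient", grade = NA_character_))
  surviving <- Filter(function(g) {
    all(vapply(names(avail), function(p) oracle_supports(p, avail[[p]], g),
               logical(1)))
  }, c("I", "II", "III"))
  if (length(surviving) == 0) list(status = "discordant", grade = NA_character_)
  else if (length(surviving) == 1) list(status = "categorized", grade = surviving)
  else list(status = "insufficient", grade = NA_character_)
}

# Measurement panel with prescribed ratios: E is reconstructed from e' and
# E/e', and A from E and E/A. Vectorized with recycling.
panel_from <- function(e = NA, Ee = NA, EA = NA, DT = NA, LAVI = NA, E = NA) {
  n <- max(lengths(list(e, Ee, EA, DT, LAVI, E)))
  r <- function(x) rep_len(as.numeric(x), n)
  e <- r(e); Ee <- r(Ee); EA <- r(EA); DT <- r(DT); LAVI <- r(LAVI); E <- r(E)
  E <- ifelse(is.na(E) & !is.na(e) & !is.na(Ee), e * Ee, E)
  A <- ifelse(!is.na(E) & !is.na(EA), E / EA, NA_real_)
  echo_measurements(E = E, A = A, e_prime = e, DT = DT, LAVI = LAVI)
}

# Random raw panels with missingness, spanning all the grading bins.
random_panels <- function(n, p_present = 0.75) {
  draw <- function(lo, hi) {
    x <- stats::runif(n, lo, hi)
    x[stats::runif(n) > p_present] <- NA
    x
  }
  tibble::tibble(
    E_cm_s = draw(20, 150),
    A_cm_s = draw(15, 130),
    e_prime_cm_s = draw(2, 14),
    DT_ms = draw(80, 320),
    LAVI_ml_m2 = draw(10, 60)
  )
}
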