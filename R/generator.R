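# Synthetic septic-cohort generator.
#
# Model: a latent four-grade mixture of diastolic function. Within a grade,
# the six echo parameters (e', E/e', E/A, DT, LAVI, EF) are log-normal with
# per-grade medians/IQRs, joined by a Gaussian copula with one global
# correlation knob; e' and E/e' are truncated to the grade's defining bin
# under the simplified scheme (rejection sampling), so the latent truth IS
# the simplified grade while E/A, DT and LAVI are correlated but free
# satellites -- the source of discordance under the multi-parameter scheme.
# E and A are derived exactly: E = e' * (E/e'), A = E / (E/A).
#
# Missingness: a per-patient standard-normal image-quality factor Q; each of
# the five gradeable parameters (E, A, e', DT, LAVI) is masked when
# lambda*Q + sqrt(1-lambda^2)*eps falls below the quantile of its marginal
# rate. Marginal missingness is exact for any loading lambda; lambda > 0
# concentrates the masks in low-quality patients, raising the
# all-five-available fraction above the independence product.
#
# Outcomes: 28-day death is Bernoulli with a logit linear in E, E/A, e' and
# E/e' (DT and LAVI causally null); the intercept is calibrated so overall
# mortality is 24%. ICU-free days are 0 for deaths, else 28 minus a
# log-normal ICU stay, floored at 0.

ECHO_PARAMS <- c("e_prime", "E_over_e_prime", "E_over_A", "DT", "LAVI", "EF")
MISSABLE <- c("E", "A", "e_prime", "DT", "LAVI")

# Defaults fixed by the package's calibration (see the methods vignette):
# the copula correlation and image-quality loading are the two free knobs
# of the joint model; the mortality intercept centres the outcome model.
DEFAULT_COPULA_RHO <- 0.30
DEFAULT_QUALITY_LOADING <- 0.359
DEFAULT_MORTALITY_INTERCEPT <- -5.069

# median/IQR -> log-normal meanlog/sdlog via the normal quartile spacing.
lognormal_from_quartiles <- function(median, q1, q3) {
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

# Per-grade marginals. Grade I holds 3 of 146 categorized patients in the
# emulated cohort; its printed IQRs cannot identify a scale, so grade I
# borrows the grade II sdlog throughout (medians stay its own).
default_param_table <- function() {
  med <- list(
    e_prime        = c(9.5, 7.0, 6.7, 5.8),
    E_over_e_prime = c(9.3, 7.8, 10.0, 17.7),
    E_over_A       = c(1.2, 0.7, 0.8, 1.0),
    DT             = c(181, 229, 208, 189),
    LAVI           = c(23.7, 16.6, 21.0, 25.3),
    EF             = c(62, 67, 61, 60)
  )
  q1 <- list(
    e_prime        = c(8.6, NA, 6.0, 4.7),
    E_over_e_prime = c(7.9, NA, 9.6, 14.7),
    E_over_A       = c(1.0, NA, 0.7, 0.7),
    DT             = c(161, NA, 191, 149),
    LAVI           = c(16.2, NA, 16.6, 19.1),
    EF             = c(56, NA, 50, 45)
  )
  q3 <- list(
    e_prime        = c(10.7, NA, 7.3, 6.4),
    E_over_e_prime = c(11.4, NA, 11.6, 20.6),
    E_over_A       = c(1.4, NA, 1.0, 1.3),
    DT             = c(211, NA, 237, 218),
    LAVI           = c(30.9, NA, 25.1, 31.9),
    EF             = c(70, NA, 70, 70)
  )
  out <- list()
  for (p in ECHO_PARAMS) {
    meanlog <- log(med[[p]])
    sdlog <- (log(q3[[p]]) - log(q1[[p]])) / (2 * stats::qnorm(0.75))
    sdlog[2] <- sdlog[3] # grade I borrows grade II scale
    out[[p]] <- list(meanlog = meanlog, sdlog = sdlog)
  }
  out
}

#' Default generator configuration
#'
#' The packaged parameterization of the synthetic septic cohort: mixture
#' weights over latent grades 0/I/II/III, per-grade log-normal echo
#' marginals, an exchangeable Gaussian-copula correlation, the per-parameter
#' missingness rates (E 2\%, e' 11\%, LAVI 16\%, A 19\%, DT 27\%) with a
#' shared image-quality loading, per-grade comorbidity prevalences, the
#' 28-day mortality model and ICU-stay, severity-score and fluid-volume
#' distributions.
#'
#' @param n Cohort size (default 167).
#' @param seed Optional integer seed stored in the config.
#' @return A validated `dd_generator_config` list.
#' @export
default_generator_config <- function(n = 167, seed = NULL) {
  cfg <- list(
    n = n,
    seed = seed,
    grade_weights = c(`0` = 0.338, I = 0.021, II = 0.255, III = 0.386),
    params = default_param_table(),
    copula_rho = DEFAULT_COPULA_RHO,
    copula = NULL, # built from copula_rho unless supplied
    missingness = c(E = 0.02, A = 0.19, e_prime = 0.11, DT = 0.27, LAVI = 0.16),
    quality_loading = DEFAULT_QUALITY_LOADING,
    comorbidity = list(
      htn = c(0.380, 1.000, 0.595, 0.732),
      dm  = c(0.240, 1.000, 0.243, 0.571),
      ihd = c(0.100, 1.000, 0.135, 0.411)
    ),
    female = c(0.460, 0.667, 0.351, 0.643),
    age = list(meanlog = log(c(55, 86, 60, 72)),
               sdlog = c(0.379, 0.234, 0.234, 0.149)),
    outcome = list(
      coef = c(E = log(0.90), E_over_A = log(5.41),
               e_prime = log(2.11), E_over_e_prime = log(1.57),
               DT = 0, LAVI = 0),
      intercept = DEFAULT_MORTALITY_INTERCEPT,
      target_mortality = 0.24
    ),
    icu_stay = list(meanlog = log(2.7), sdlog = 0.55),
    severity = list(
      apache2 = list(meanlog = log(25), sdlog = 0.439),
      sofa_adm = list(meanlog = log(8), sdlog = 0.449),
      sofa_72h = list(meanlog = log(6), sdlog = 0.60)
    ),
    vasopressor = 0.678,
    mech_vent = 0.368,
    ivf = list(meanlog = log(1100), sdlog = 1.03),
    tapse = list(meanlog = log(20), sdlog = 0.224),
    s_prime = list(meanlog = log(8), sdlog = 0.281),
    max_reject_iter = 1000
  )
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#'
#' Checks mixture weights, rates, the copula correlation matrix (symmetric
#' positive definite) and distribution parameters; fills the copula matrix
#' from `copula_rho` when not supplied explicitly.
#'
#' @param cfg A generator config list.
#' @return The validated (and completed) config, classed
#'   `dd_generator_config`.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 0 ||
      cfg$n != round(cfg$n)) {
    stop("config: n must be a single non-negative integer", call. = FALSE)
  }
  w <- cfg$grade_weights
  if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-6) {
    stop("config: grade_weights must be a non-negative 4-vector summing to 1",
         call. = FALSE)
  }
  r <- cfg$missingness
  if (!all(MISSABLE %in% names(r)) || any(r < 0 | r > 1)) {
    stop("config: missingness must give rates in [0, 1] for ",
         paste(MISSABLE, collapse = ", "), call. = FALSE)
  }
  lam <- cfg$quality_loading
  if (!is.numeric(lam) || lam < 0 || lam >= 1) {
    stop("config: quality_loading must be in [0, 1)", call. = FALSE)
  }
  if (is.null(cfg[["copula"]])) {
    p <- length(ECHO_PARAMS)
    R <- matrix(cfg[["copula_rho"]], p, p)
    diag(R) <- 1
    dimnames(R) <- list(ECHO_PARAMS, ECHO_PARAMS)
    cfg[["copula"]] <- R
  }
  R <- cfg[["copula"]]
  if (!isSymmetric(unname(R)) || any(eigen(R, symmetric = TRUE,
                                           only.values = TRUE)$values <= 1e-10)) {
    stop("config: copula must be a symmetric positive-definite correlation matrix",
         call. = FALSE)
  }
  for (p in ECHO_PARAMS) {
    pr <- cfg$params[[p]]
    if (is.null(pr) || length(pr$meanlog) != 4 || length(pr$sdlog) != 4 ||
        any(!is.finite(pr$meanlog)) || any(pr$sdlog < 0)) {
      stop("config: params$", p, " needs finite meanlog and non-negative sdlog ",
           "for each of the four grades", call. = FALSE)
    }
  }
  for (cm in c("htn", "dm", "ihd")) {
    pv <- cfg$comorbidity[[cm]]
    if (length(pv) != 4 || any(pv < 0 | pv > 1)) {
      stop("config: comorbidity$", cm, " must be four prevalences in [0, 1]",
           call. = FALSE)
    }
  }
  class(cfg) <- "dd_generator_config"
  cfg
}

#' Draw latent diastolic-function grades
#'
#' Categorical draw from the mixture weights. With the default weights the
#' expected full-cohort composition, after categorizability losses from
#' missing e' or E, matches the categorized counts the default cohort is
#' calibrated to.
#'
#' @param n Number of draws.
#' @param cfg Generator config.
#' @return Character vector of grades `"0","I","II","III"`.
#' @export
sample_grade <- function(n, cfg = default_generator_config()) {
  cfg <- validate_generator_config(cfg)
  sample(GRADE_LEVELS, n, replace = TRUE, prob = cfg$grade_weights)
}

# Is (e', E/e') inside grade g's defining simplified bin?
in_grade_bin <- function(grade, e, ee) {
  switch(grade,
    "0" = e >= E_PRIME_NORMAL,
    "I" = e < E_PRIME_NORMAL & ee <= 8,
    "II" = e < E_PRIME_NORMAL & ee > 8 & ee < 13,
    "III" = e < E_PRIME_NORMAL & ee >= 13
  )
}

# Joint truncated copula draw of the echo panel for one grade. Values are
# reported at clinical resolution (velocities and volumes to 0.1, DT and EF
# to 1), and the grade-bin truncation is enforced on the reported values so
# a recorded panel always recovers its latent grade exactly.
sample_echo_grade <- function(n, grade, cfg) {
  g <- match(grade, GRADE_LEVELS)
  p <- length(ECHO_PARAMS)
  mu <- vapply(cfg$params, function(x) x$meanlog[g], numeric(1))[ECHO_PARAMS]
  sd <- vapply(cfg$params, function(x) x$sdlog[g], numeric(1))[ECHO_PARAMS]
  draw <- function(k) {
    z <- MASS::mvrnorm(k, mu = rep(0, p), Sigma = cfg$copula)
    z <- matrix(z, ncol = p)
    x <- exp(sweep(sweep(z, 2, sd, `*`), 2, mu, `+`))
    cbind(
      e_prime = round(x[, 1], 1),
      E = round(x[, 1] * x[, 2], 1),
      A = round(x[, 1] * x[, 2] / x[, 3], 1),
      DT = round(x[, 4]),
      LAVI = round(x[, 5], 1),
      EF = round(pmin(x[, 6], 100))
    )
  }
  cols <- c("e_prime", "E", "A", "DT", "LAVI", "EF")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  need <- seq_len(n)
  iter <- 0
  while (length(need) > 0) {
    iter <- iter + 1
    if (iter > cfg$max_reject_iter) {
      stop("rejection sampling failed to land in the grade ", grade,
           " bin within ", cfg$max_reject_iter, " rounds; the configured ",
           "distributions are inconsistent with the grade's defining bin",
           call. = FALSE)
    }
    x <- draw(length(need))
    ok <- in_grade_bin(grade, x[, "e_prime"], x[, "E"] / x[, "e_prime"]) &
      x[, "A"] > 0 & x[, "E"] > 0 & x[, "e_prime"] > 0
    out[need[ok], ] <- x[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

# Echo panels for a vector of grades, with the ratios re-derived from the
# reported values (exact arithmetic identity).
sample_echo <- function(grades, cfg) {
  n <- length(grades)
  cols <- c("e_prime", "E", "A", "DT", "LAVI", "EF")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (g in GRADE_LEVELS) {
    idx <- which(grades == g)
    if (length(idx) > 0) out[idx, ] <- sample_echo_grade(length(idx), g, cfg)
  }
  derive_ratios(tibble::tibble(
    e_prime_cm_s = out[, "e_prime"],
    E_cm_s = out[, "E"],
    A_cm_s = out[, "A"],
    DT_ms = out[, "DT"],
    LAVI_ml_m2 = out[, "LAVI"],
    EF_pct = out[, "EF"]
  ))
}

#' Sample the bin-defining hemodynamic parameters for given grades
#'
#' Draws (e', E/e', E/A) from the per-grade log-scale copula with e' and
#' E/e' truncated to the grade's defining bin, then derives
#' E = e' x (E/e') and A = E / (E/A).
#'
#' @param grades Character vector of latent grades.
#' @param cfg Generator config.
#' @return Tibble with `e_prime_cm_s`, `E_over_e_prime`, `E_over_A`,
#'   `E_cm_s`, `A_cm_s`.
#' @export
sample_hemodynamics <- function(grades, cfg = default_generator_config()) {
  cfg <- validate_generator_config(cfg)
  sample_echo(grades, cfg)[, c("e_prime_cm_s", "E_over_e_prime", "E_over_A",
                               "E_cm_s", "A_cm_s")]
}

#' Sample the satellite parameters for given grades
#'
#' Draws (DT, LAVI, EF) from the per-grade log-normal marginals. These are
#' not constrained by the simplified bins: they are free to disagree with
#' the bin-defining parameters, which is what generates discordance under
#' the multi-parameter scheme.
#'
#' @inheritParams sample_hemodynamics
#' @return Tibble with `DT_ms`, `LAVI_ml_m2`, `EF_pct`.
#' @export
sample_ancillary <- function(grades, cfg = default_generator_config()) {
  cfg <- validate_generator_config(cfg)
  sample_echo(grades, cfg)[, c("DT_ms", "LAVI_ml_m2", "EF_pct")]
}

#' Mask measurements with image-quality-correlated missingness
#'
#' Draws one standard-normal image-quality score per patient; parameter `j`
#' is masked when `lambda * Q + sqrt(1 - lambda^2) * eps_j` falls below
#' `qnorm(rate_j)`. Marginal missingness equals the configured rate exactly
#' for any loading; a positive loading makes masks co-occur in low-quality
#' studies, raising the all-five availability above the independence
#' product. Ratios are re-derived afterwards so a masked operand removes
#' its ratio.
#'
#' @param m Complete measurement table.
#' @param cfg Generator config (uses `missingness` and `quality_loading`).
#' @return `m` with masked entries set `NA` and ratios re-derived; the
#'   realized quality scores are attached as attribute `quality`.
#' @export
apply_missingness <- function(m, cfg = default_generator_config()) {
  cfg <- validate_generator_config(cfg)
  n <- nrow(m)
  lam <- cfg$quality_loading
  q <- stats::rnorm(n)
  cols <- c(E = "E_cm_s", A = "A_cm_s", e_prime = "e_prime_cm_s",
            DT = "DT_ms", LAVI = "LAVI_ml_m2")
  for (j in MISSABLE) {
    x <- lam * q + sqrt(1 - lam^2) * stats::rnorm(n)
    masked <- x < stats::qnorm(cfg$missingness[[j]])
    m[[cols[[j]]]][masked] <- NA_real_
  }
  m <- derive_ratios(m)
  attr(m, "quality") <- q
  m
}

#' Sample demographics, comorbidities, severity scores and outcomes
#'
#' Comorbidities are Bernoulli with per-grade prevalences. 28-day death is
#' Bernoulli with a logit linear in the complete (pre-masking) E, E/A, e'
#' and E/e'; DT and LAVI carry zero coefficients. ICU-free days follow the
#' standard convention: deaths score 0, survivors 28 minus a log-normal ICU
#' stay, floored at 0.
#'
#' @param grades Latent grades.
#' @param m Complete (pre-missingness) measurement table with ratios.
#' @param cfg Generator config.
#' @return Tibble of demographic, comorbidity, severity, fluid and outcome
#'   columns.
#' @export
sample_comorbidities_and_outcomes <- function(grades, m,
                                              cfg = default_generator_config()) {
  cfg <- validate_generator_config(cfg)
  n <- length(grades)
  g <- match(grades, GRADE_LEVELS)
  draw_flag <- function(pv) stats::rbinom(n, 1, pv[g])
  age <- round(pmax(18, stats::rlnorm(n, cfg$age$meanlog[g], cfg$age$sdlog[g])))
  sex <- ifelse(stats::rbinom(n, 1, cfg$female[g]) == 1, "F", "M")
  htn <- draw_flag(cfg$comorbidity$htn)
  dm <- draw_flag(cfg$comorbidity$dm)
  ihd <- draw_flag(cfg$comorbidity$ihd)
  b <- cfg$outcome$coef
  eta <- cfg$outcome$intercept +
    b[["E"]] * m$E_cm_s + b[["E_over_A"]] * m$E_over_A +
    b[["e_prime"]] * m$e_prime_cm_s +
    b[["E_over_e_prime"]] * m$E_over_e_prime +
    b[["DT"]] * m$DT_ms + b[["LAVI"]] * m$LAVI_ml_m2
  died <- stats::rbinom(n, 1, stats::plogis(eta))
  stay <- stats::rlnorm(n, cfg$icu_stay$meanlog, cfg$icu_stay$sdlog)
  ifd <- icu_free_days(died == 1, stay)
  sev <- cfg$severity
  tibble::tibble(
    age_years = age, sex = sex, htn = htn, dm = dm, ihd = ihd,
    apache2 = round(stats::rlnorm(n, sev$apache2$meanlog, sev$apache2$sdlog)),
    sofa_adm = pmin(24, round(stats::rlnorm(n, sev$sofa_adm$meanlog,
                                            sev$sofa_adm$sdlog))),
    sofa_72h = pmin(24, round(stats::rlnorm(n, sev$sofa_72h$meanlog,
                                            sev$sofa_72h$sdlog))),
    vasopressor = stats::rbinom(n, 1, cfg$vasopressor),
    mech_vent = stats::rbinom(n, 1, cfg$mech_vent),
    ivf_pre6h_ml = round(stats::rlnorm(n, cfg$ivf$meanlog, cfg$ivf$sdlog)),
    ivf_post6h_ml = round(stats::rlnorm(n, cfg$ivf$meanlog, cfg$ivf$sdlog)),
    died_28d = died,
    icu_free_days = round(ifd, 1)
  )
}

#' Generate a full synthetic cohort
#'
#' Composes the samplers per patient: latent grade, truncated-copula echo
#' parameters, demographics/comorbidities/outcomes (from the complete
#' measurements), then image-quality missingness. Fully reproducible from
#' `(cfg, seed)`.
#'
#' @param cfg Generator config.
#' @param seed Integer seed; defaults to `cfg$seed`. When neither is given
#'   the ambient RNG state is used.
#' @return A tibble in the cohort CSV schema (see [read_cohort()]), with
#'   `latent_grade` set and a `generation_log` attribute (per-grade counts
#'   and realized per-parameter missingness).
#' @examples
#' coh <- generate_cohort(default_generator_config(n = 50), seed = 1)
#' table(coh$latent_grade)
#' @export
generate_cohort <- function(cfg = default_generator_config(), seed = cfg$seed) {
  cfg <- validate_generator_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  if (n == 0) {
    empty <- empty_cohort()
    attr(empty, "generation_log") <- list(n = 0)
    return(empty)
  }
  grades <- sample_grade(n, cfg)
  echo <- sample_echo(grades, cfg)
  clin <- sample_comorbidities_and_outcomes(grades, echo, cfg)
  obs <- apply_missingness(echo, cfg)
  coh <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    clin[, c("age_years", "sex", "htn", "dm", "ihd", "apache2", "sofa_adm",
             "sofa_72h", "vasopressor", "mech_vent", "ivf_pre6h_ml",
             "ivf_post6h_ml")],
    E_cm_s = obs$E_cm_s, A_cm_s = obs$A_cm_s,
    e_prime_cm_s = obs$e_prime_cm_s, DT_ms = obs$DT_ms,
    LAVI_ml_m2 = obs$LAVI_ml_m2, EF_pct = obs$EF_pct,
    TAPSE_mm = round(stats::rlnorm(n, cfg$tapse$meanlog, cfg$tapse$sdlog), 1),
    s_prime_cm_s = round(stats::rlnorm(n, cfg$s_prime$meanlog,
                                       cfg$s_prime$sdlog), 1),
    died_28d = clin$died_28d, icu_free_days = clin$icu_free_days,
    latent_grade = grades
  )
  attr(coh, "generation_log") <- list(
    n = n,
    grade_counts = table(factor(grades, levels = GRADE_LEVELS)),
    missingness = vapply(
      c(E = "E_cm_s", A = "A_cm_s", e_prime = "e_prime_cm_s",
        DT = "DT_ms", LAVI = "LAVI_ml_m2"),
      function(cl) mean(is.na(coh[[cl]])), numeric(1))
  )
  coh
}

#' Calibrate the image-quality loading to a joint availability target
#'
#' Solves, by one-dimensional numerical integration over the latent quality
#' score, for the loading at which the probability that all five gradeable
#' parameters are simultaneously available equals `target`. With loading 0
#' the joint availability is the independence product of the marginal
#' availabilities.
#'
#' @param rates Named marginal missingness rates for `r paste(MISSABLE)`.
#' @param target Desired all-five availability.
#' @return The loading in [0, 1).
#' @export
calibrate_quality_loading <- function(rates, target = 0.47) {
  z <- stats::qnorm(rates[MISSABLE])
  p_all <- function(lam) {
    s <- sqrt(1 - lam^2)
    f <- function(q) {
      stats::dnorm(q) *
        apply(outer(q, z, function(qq, zz) stats::pnorm((lam * qq - zz) / s)),
              1, prod)
    }
    stats::integrate(f, -8, 8, rel.tol = 1e-9)$value
  }
  indep <- prod(1 - rates[MISSABLE])
  if (target <= indep) return(0)
  stats::uniroot(function(l) p_all(l) - target, c(1e-6, 0.98),
                 tol = 1e-7)$root
}

#' Calibrate the mortality-model intercept to a target death rate
#'
#' Monte-Carlo calibration: draws a large pre-missingness cohort from the
#' config, then solves for the intercept at which the mean of the modelled
#' death probabilities equals the target overall 28-day mortality.
#'
#' @param cfg Generator config.
#' @param target Overall mortality fraction (default the config's
#'   `outcome$target_mortality`).
#' @param n Monte-Carlo sample size.
#' @param seed Seed for the calibration draw.
#' @return The intercept (log-odds).
#' @export
calibrate_mortality_intercept <- function(cfg = default_generator_config(),
                                          target = cfg$outcome$target_mortality,
                                          n = 200000, seed = 1) {
  cfg <- validate_generator_config(cfg)
  set.seed(seed)
  grades <- sample_grade(n, cfg)
  m <- sample_echo(grades, cfg)
  b <- cfg$outcome$coef
  eta0 <- b[["E"]] * m$E_cm_s + b[["E_over_A"]] * m$E_over_A +
    b[["e_prime"]] * m$e_prime_cm_s + b[["E_over_e_prime"]] * m$E_over_e_prime
  stats::uniroot(function(a) mean(stats::plogis(a + eta0)) - target,
                 c(-30, 30), tol = 1e-6)$root
}
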