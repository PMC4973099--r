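# Outcome-association analysis: ICU-free days, multivariable logistic
# regression with collinearity diagnostics, random-forest permutation
# importance, and per-grade group comparison tables.

# Default covariate set for the mortality model, on native scales.
DEFAULT_COVARIATES <- c("E_cm_s", "E_over_A", "e_prime_cm_s",
                        "E_over_e_prime", "DT_ms", "LAVI_ml_m2")
DEFAULT_PREDICTORS <- c("E_cm_s", "A_cm_s", "E_over_A", "e_prime_cm_s",
                        "E_over_e_prime", "DT_ms", "LAVI_ml_m2")

#' ICU-free days to day 28
#'
#' Days alive and out of the ICU within 28 days of enrolment. Deaths before
#' day 28 score 0; survivors score `28 - icu_days`, floored at 0.
#'
#' @param died Logical (or 0/1): died by day 28.
#' @param icu_days Non-negative ICU length of stay, days.
#' @return Numeric vector in [0, 28].
#' @examples
#' icu_free_days(c(FALSE, TRUE, FALSE), c(3, 10, 30)) # 25, 0, 0
#' @export
icu_free_days <- function(died, icu_days) {
  if (any(icu_days < 0, na.rm = TRUE)) {
    stop("icu_days must be non-negative", call. = FALSE)
  }
  ifelse(as.logical(died), 0, pmax(0, 28 - icu_days))
}

#' Multivariable logistic regression for 28-day mortality
#'
#' Maximum-likelihood logistic fit of `died_28d` on the echo covariates,
#' complete-case over the covariate set, with odds ratios per unit of each
#' covariate on its native scale, Wald 95\% confidence intervals, and
#' variance inflation factors.
#'
#' @param cohort Cohort table (ratios derived if absent) with `died_28d`.
#' @param covariates Covariate columns; defaults to E, E/A, e', E/e', DT,
#'   LAVI.
#' @return A `dd_logit` object: list with `estimates` (tibble of term, OR,
#'   CI bounds, p), `vif` (tibble plus `mean_vif`), `n_used`, `n_dropped`,
#'   and the underlying `glm` fit.
#' @export
fit_mortality_model <- function(cohort, covariates = DEFAULT_COVARIATES) {
  cohort <- ensure_ratios(cohort)
  stopifnot("died_28d" %in% names(cohort))
  dat <- cohort[, c("died_28d", covariates)]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, ]
  if (nrow(dat) == 0) stop("no complete cases for the requested covariates",
                           call. = FALSE)
  events <- sum(dat$died_28d)
  if (events == 0 || events == nrow(dat)) {
    stop("degenerate outcome: ", events, " events among ", nrow(dat),
         " complete cases; the logistic model cannot be fit", call. = FALSE)
  }
  fml <- stats::reformulate(covariates, response = "died_28d")
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  if (!fit$converged) {
    stop("logistic fit did not converge (possible separation); ",
         "no estimates are reported", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  est <- sm[covariates, "Estimate"]
  se <- sm[covariates, "Std. Error"]
  z <- stats::qnorm(0.975)
  estimates <- tibble::tibble(
    term = covariates,
    log_or = unname(est),
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    p_value = unname(sm[covariates, "Pr(>|z|)"])
  )
  vif <- compute_vif(dat, covariates)
  structure(list(estimates = estimates, vif = vif,
                 n_used = nrow(dat), n_dropped = sum(!cc), fit = fit),
            class = "dd_logit")
}

#' @export
print.dd_logit <- function(x, ...) {
  cat("Logistic regression for 28-day mortality (n =", x$n_used,
      "complete cases,", x$n_dropped, "dropped)\n")
  print(as.data.frame(x$estimates), row.names = FALSE, digits = 3)
  cat("Mean VIF:", round(x$vif$mean_vif, 2), "\n")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the linear regression of covariate `j` on
#' the remaining covariates, over complete cases. Exact collinearity is
#' reported as an infinite VIF and flagged, not raised as an error.
#'
#' @param data Data frame containing the covariates.
#' @param covariates At least two covariate column names.
#' @return List with `vif` (tibble: term, vif, aliased flag) and
#'   `mean_vif` (mean over finite VIFs; `Inf` if any covariate is aliased).
#' @export
compute_vif <- function(data, covariates = DEFAULT_COVARIATES) {
  stopifnot(length(covariates) >= 2)
  data <- ensure_ratios(data)
  x <- data[stats::complete.cases(data[, covariates]), covariates]
  v <- vapply(covariates, function(j) {
    fit <- stats::lm(stats::reformulate(setdiff(covariates, j), response = j),
                     data = x)
    # aliased designs fit perfectly; reported as infinite VIF, so the
    # perfect-fit warning from summary.lm is expected noise here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tab <- tibble::tibble(term = covariates, vif = unname(v),
                        aliased = !is.finite(unname(v)))
  list(vif = tab,
       mean_vif = if (any(!is.finite(v))) Inf else mean(v))
}

#' Random-forest permutation variable importance
#'
#' Ensemble-of-trees permutation importance (mean decrease in accuracy for
#' 28-day mortality, mean decrease in MSE for ICU-free days), averaged over
#' seeded replicate forests on complete cases.
#'
#' @param cohort Cohort table (ratios derived if absent).
#' @param outcome `"died_28d"` or `"icu_free_days"`.
#' @param predictors Predictor columns; defaults to E, A, E/A, e', E/e',
#'   DT, LAVI.
#' @param num_trees Trees per forest (default 500).
#' @param replicates Number of seeded forests averaged (default 5).
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param mtry Features tried per split; default the square-root rule.
#' @return A `dd_importance` object: tibble of `predictor`, mean
#'   `importance`, `rank` (1 = most important), plus attributes `outcome`,
#'   `replicates`, `seed`, `n_used`.
#' @export
variable_importance <- function(cohort, outcome = c("died_28d", "icu_free_days"),
                                predictors = DEFAULT_PREDICTORS,
                                num_trees = 500, replicates = 5, seed = 1,
                                mtry = NULL) {
  outcome <- match.arg(outcome)
  cohort <- ensure_ratios(cohort)
  dat <- cohort[, c(outcome, predictors)]
  dat <- dat[stats::complete.cases(dat), ]
  y <- dat[[outcome]]
  if (length(unique(y)) < 2) {
    stop("outcome ", outcome, " is constant on the complete cases; ",
         "importance is undefined", call. = FALSE)
  }
  if (outcome == "died_28d") dat[[outcome]] <- factor(y)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(predictors))))
  fml <- stats::reformulate(predictors, response = outcome)
  imp <- vapply(seq_len(replicates), function(r) {
    fit <- ranger::ranger(fml, data = dat, num.trees = num_trees,
                          mtry = mtry, importance = "permutation",
                          seed = seed + r, num.threads = 1)
    fit$variable.importance[predictors]
  }, numeric(length(predictors)))
  mean_imp <- rowMeans(matrix(imp, nrow = length(predictors)))
  res <- tibble::tibble(
    predictor = predictors,
    importance = mean_imp,
    rank = rank(-mean_imp, ties.method = "first")
  )
  structure(res, class = c("dd_importance", class(res)),
            outcome = outcome, replicates = replicates, seed = seed,
            n_used = nrow(dat))
}

# Row set of the per-grade comparison table: label, column, type.
GROUP_TABLE_ROWS <- list(
  list("Age, years", "age_years", "continuous"),
  list("Female sex, %", "sex_female", "binary"),
  list("Hypertension, %", "htn", "binary"),
  list("Diabetes mellitus, %", "dm", "binary"),
  list("Ischemic heart disease, %", "ihd", "binary"),
  list("APACHE II score", "apache2", "continuous"),
  list("SOFA score on admission", "sofa_adm", "continuous"),
  list("On vasopressors, %", "vasopressor", "binary"),
  list("E, cm/s", "E_cm_s", "continuous"),
  list("A, cm/s", "A_cm_s", "continuous"),
  list("e', cm/s", "e_prime_cm_s", "continuous"),
  list("E/e'", "E_over_e_prime", "continuous"),
  list("DT, ms", "DT_ms", "continuous"),
  list("E/A", "E_over_A", "continuous"),
  list("LAVI, ml/m2", "LAVI_ml_m2", "continuous"),
  list("Ejection fraction, %", "EF_pct", "continuous"),
  list("ICU-free days", "icu_free_days", "continuous"),
  list("Mortality, %", "died_28d", "binary"),
  list("IVF 6 h pre-TTE, ml", "ivf_pre6h_ml", "continuous"),
  list("IVF 6 h post-TTE, ml", "ivf_post6h_ml", "continuous")
)

fmt_median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}

fmt_pct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("")
  sprintf("%.1f", 100 * mean(x))
}

#' Per-grade group comparison table
#'
#' Summarizes the categorized patients of a graded cohort by grade:
#' continuous rows as median (IQR) with a Kruskal-Wallis p value, binary
#' rows as percentages with a Fisher exact p value (exact up to a cell-count
#' cap, simulated beyond it under a fixed seed). Uncategorizable patients
#' are excluded; grades with zero members get empty cells and the test runs
#' over the non-empty grades. With fewer than two non-empty grades no test
#' is performed.
#'
#' @param cohort Cohort table.
#' @param definition `"ase2009"` or `"simplified"`; the cohort is graded
#'   with that engine first (existing verdict columns are ignored).
#' @param fisher_cap Largest total count for which the Fisher p is exact;
#'   beyond it the p value is simulated with B = 10000 at `seed`.
#' @param seed Seed for simulated Fisher p values.
#' @return A `dd_group_table` object: tibble with `variable`, `type`, one
#'   summary column per grade (`grade_0` ... `grade_III`), `p_value` and
#'   `test`; attribute `counts` holds the per-grade n.
#' @export
grade_group_table <- function(cohort, definition = c("simplified", "ase2009"),
                              fisher_cap = 400, seed = 1) {
  definition <- match.arg(definition)
  m <- ensure_ratios(cohort)
  verdict <- if (definition == "ase2009") classify_ase2009(m) else
    classify_simplified(m)
  keep <- verdict$status == "categorized"
  dat <- m[keep, , drop = FALSE]
  grade <- factor(verdict$grade[keep], levels = GRADE_LEVELS)
  if ("sex" %in% names(dat)) dat$sex_female <- as.integer(dat$sex == "F")
  counts <- table(grade)
  nonempty <- names(counts)[counts > 0]
  rows <- Filter(function(r) r[[2]] %in% names(dat), GROUP_TABLE_ROWS)
  out <- lapply(rows, function(r) {
    col <- r[[2]]; type <- r[[3]]
    x <- dat[[col]]
    cells <- vapply(GRADE_LEVELS, function(g) {
      xs <- x[grade == g]
      if (length(xs) == 0) "" else
        if (type == "continuous") fmt_median_iqr(xs) else fmt_pct(xs)
    }, character(1))
    p <- NA_real_; test <- NA_character_
    sub <- !is.na(x) & grade %in% nonempty
    if (length(nonempty) >= 2 && sum(sub) > 0 &&
        length(unique(grade[sub])) >= 2) {
      if (type == "continuous") {
        if (length(unique(x[sub])) > 1) {
          p <- stats::kruskal.test(x[sub], droplevels(grade[sub]))$p.value
          test <- "kruskal-wallis"
        }
      } else {
        tab <- table(x[sub], droplevels(grade[sub]))
        if (nrow(tab) >= 2) {
          if (sum(tab) <= fisher_cap) {
            p <- stats::fisher.test(tab, workspace = 2e7)$p.value
            test <- "fisher-exact"
          } else {
            set.seed(seed)
            p <- stats::fisher.test(tab, simulate.p.value = TRUE,
                                    B = 10000)$p.value
            test <- "fisher-simulated"
          }
        }
      }
    }
    tibble::tibble(variable = r[[1]], type = type,
                   grade_0 = cells[[1]], grade_I = cells[[2]],
                   grade_II = cells[[3]], grade_III = cells[[4]],
                   p_value = p, test = test)
  })
  res <- dplyr::bind_rows(out)
  structure(res, class = c("dd_group_table", class(res)),
            definition = definition, counts = counts)
}
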