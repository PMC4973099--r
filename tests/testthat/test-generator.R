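cfg <- default_generator_config()

test_that("latent grade sampling follows the mixture weights", {
  degenerate <- cfg
  degenerate$grade_weights <- c(`0` = 1, I = 0, II = 0, III = 0)
  expect_true(all(sample_grade(500, degenerate) == "0"))

  withr::with_seed(3, g <- sample_grade(1e5, cfg))
  freq <- table(factor(g, levels = c("0", "I", "II", "III"))) / 1e5
  se <- sqrt(cfg$grade_weights * (1 - cfg$grade_weights) / 1e5)
  expect_true(all(abs(freq - cfg$grade_weights) <= 3 * se))

  set.seed(42); a <- sample_grade(100, cfg)
  set.seed(42); b <- sample_grade(100, cfg)
  expect_identical(a, b)
})

test_that("hemodynamic draws respect the grade-defining bins and medians", {
  withr::with_seed(5, h3 <- sample_hemodynamics(rep("III", 2000), cfg))
  expect_true(all(h3$e_prime_cm_s < 8))
  expect_true(all(h3$E_over_e_prime >= 13))
  # E is the exact product of the sampled e' and E/e'
  expect_equal(h3$E_cm_s, h3$e_prime_cm_s * h3$E_over_e_prime)
  # implied grade III E median close to the product of the configured medians
  expect_lt(abs(median(h3$E_cm_s) / (5.8 * 17.7) - 1), 0.10)

  withr::with_seed(6, h0 <- sample_hemodynamics(rep("0", 1e4), cfg))
  expect_true(all(h0$e_prime_cm_s >= 8))
  expect_lt(abs(median(h0$e_prime_cm_s) / 9.5 - 1), 0.05)
})

test_that("ancillary draws are unconstrained log-normals around the medians", {
  withr::with_seed(8, a0 <- sample_ancillary(rep("0", 1e4), cfg))
  expect_lt(abs(median(a0$LAVI_ml_m2) / 23.7 - 1), 0.10)
  expect_lt(abs(median(a0$DT_ms) / 181 - 1), 0.10)

  flat <- cfg
  for (p in names(flat$params)) flat$params[[p]]$sdlog <- rep(0, 4)
  z <- sample_ancillary(rep("0", 5), flat)
  expect_equal(z$LAVI_ml_m2, rep(23.7, 5))
  expect_equal(z$DT_ms, rep(181, 5))
})

test_that("missingness marginals are exact and the quality loading couples them", {
  withr::with_seed(10, grades <- sample_grade(1e4, cfg))
  withr::with_seed(10, full <- sample_hemodynamics(grades, cfg))
  full$DT_ms <- 180; full$LAVI_ml_m2 <- 24 # complete panel

  withr::with_seed(11, obs <- apply_missingness(full, cfg))
  rates <- c(E = mean(is.na(obs$E_cm_s)), A = mean(is.na(obs$A_cm_s)),
             e_prime = mean(is.na(obs$e_prime_cm_s)),
             DT = mean(is.na(obs$DT_ms)), LAVI = mean(is.na(obs$LAVI_ml_m2)))
  expect_true(all(abs(rates - cfg$missingness[names(rates)]) < 0.02))
  # masked operands remove their ratios
  expect_true(all(is.na(obs$E_over_e_prime[is.na(obs$e_prime_cm_s)])))

  # zero loading: joint availability is the independence product
  indep <- cfg; indep$quality_loading <- 0
  withr::with_seed(12, obs0 <- apply_missingness(full, indep))
  all5 <- mean(stats::complete.cases(
    obs0[, c("E_cm_s", "A_cm_s", "e_prime_cm_s", "DT_ms", "LAVI_ml_m2")]))
  expect_lt(abs(all5 - prod(1 - cfg$missingness)), 0.02)

  # a certain mask empties its column
  certain <- cfg; certain$missingness[["DT"]] <- 1
  obs1 <- apply_missingness(full, certain)
  expect_true(all(is.na(obs1$DT_ms)))
})

test_that("quality-loading calibration solves the joint availability", {
  lam <- calibrate_quality_loading(cfg$missingness, target = 0.47)
  expect_gt(lam, 0)
  expect_equal(lam, cfg$quality_loading, tolerance = 0.01)
  expect_equal(calibrate_quality_loading(cfg$missingness,
                                         target = prod(1 - cfg$missingness)), 0)
})

test_that("outcome model hits its base rate and the ICU-free-days convention", {
  null_cfg <- cfg
  null_cfg$outcome$coef[] <- 0
  null_cfg$outcome$intercept <- stats::qlogis(0.3)
  withr::with_seed(20, grades <- sample_grade(2e4, null_cfg))
  withr::with_seed(20, m <- sample_hemodynamics(grades, null_cfg))
  m$DT_ms <- 180; m$LAVI_ml_m2 <- 24
  withr::with_seed(21, out <- sample_comorbidities_and_outcomes(grades, m, null_cfg))
  expect_lt(abs(mean(out$died_28d) - 0.3), 0.015)
  expect_true(all(out$icu_free_days[out$died_28d == 1] == 0))
  expect_true(all(out$icu_free_days >= 0 & out$icu_free_days <= 28))

  g3 <- which(grades == "III")
  expect_lt(abs(mean(out$htn[g3]) - 0.732), 0.03)
})

test_that("cohorts are reproducible, well-formed, and recover the latent grade", {
  expect_equal(nrow(generate_cohort(default_generator_config(n = 0))), 0)

  a <- generate_cohort(default_generator_config(n = 60), seed = 77)
  b <- generate_cohort(default_generator_config(n = 60), seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))

  coh <- generate_cohort(default_generator_config(n = 1000), seed = 13)
  log <- attr(coh, "generation_log")
  expect_equal(sum(log$grade_counts), 1000)
  validate_measurements(coh)

  # round-trip: wherever e' and E/e' survive masking, the simplified engine
  # returns the latent truth (guaranteed by bin truncation)
  s <- classify_simplified(derive_ratios(coh))
  seen <- s$status == "categorized" &
    !(is.na(coh$e_prime_cm_s) | (coh$e_prime_cm_s < 8 & is.na(coh$E_cm_s)))
  expect_true(all(s$grade[seen] == coh$latent_grade[seen]))
  # and no categorized verdict ever disagrees with the latent truth
  expect_true(all(s$grade[s$status == "categorized"] ==
                    coh$latent_grade[s$status == "categorized"]))
})

test_that("config validation rejects malformed configurations", {
  bad <- cfg; bad$grade_weights <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(validate_generator_config(bad), "grade_weights")
  bad <- cfg; bad$missingness[["DT"]] <- 1.4
  expect_error(validate_generator_config(bad), "missingness")
  bad <- cfg; bad$quality_loading <- 1.2
  expect_error(validate_generator_config(bad), "quality_loading")
  bad <- cfg; bad$copula <- matrix(1, 6, 6)
  expect_error(validate_generator_config(bad), "positive-definite")
  bad <- cfg; bad$comorbidity$htn <- c(2, 0, 0, 0)
  expect_error(validate_generator_config(bad), "comorbidity")
})

test_that("configs round-trip through YAML and JSON; packaged default matches", {
  for (ext in c("yaml", "json")) {
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_generator_config(cfg, p)
    back <- read_generator_config(p)
    expect_equal(back$grade_weights, cfg$grade_weights)
    expect_equal(unname(back$copula), unname(cfg$copula), tolerance = 1e-9)
    expect_equal(back$params$e_prime$meanlog, cfg$params$e_prime$meanlog,
                 tolerance = 1e-9)
    expect_equal(back$outcome$coef, cfg$outcome$coef, tolerance = 1e-9)
  }
  packaged <- system.file("extdata", "default_config.yaml",
                          package = "diastolr")
  expect_true(nzchar(packaged))
  pk <- read_generator_config(packaged)
  expect_equal(pk$grade_weights, cfg$grade_weights)
  expect_equal(pk$outcome$intercept, cfg$outcome$intercept, tolerance = 1e-9)
  expect_equal(pk$quality_loading, cfg$quality_loading, tolerance = 1e-9)
})

test_that("an impossible bin/distribution pairing raises a configuration error", {
  stuck <- cfg
  stuck$params$e_prime$meanlog[4] <- log(12) # grade III needs e' < 8
  stuck$params$e_prime$sdlog[4] <- 1e-6
  stuck$max_reject_iter <- 5
  expect_error(sample_hemodynamics(rep("III", 10), stuck), "rejection")
})
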