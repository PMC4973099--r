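# Worked grading examples use the per-grade median vectors of the emulated
# cohort's summary table; panels are reconstructed from (e', E/e', E/A).

test_that("simplified engine grades the per-grade median pairs and boundaries", {
  med <- panel_from(e = c(9.5, 7.0, 6.7, 5.8), Ee = c(9.3, 7.8, 10.0, 17.7))
  s <- classify_simplified(med)
  expect_equal(s$status, rep("categorized", 4))
  expect_equal(s$grade, c("0", "I", "II", "III"))

  # e' >= 8 forces grade 0 without consulting E/e'
  g0 <- classify_simplified(echo_measurements(e_prime = 9.5))
  expect_equal(g0$grade, "0")

  # boundary conventions: e' = 8 is normal; E/e' = 8 grade I, 13 grade III
  b <- panel_from(e = c(8, 7.9, 7.9, 7.9, 7.9),
                  Ee = c(20, 8, 8.0001, 12.9999, 13))
  expect_equal(classify_simplified(b)$grade, c("0", "I", "II", "II", "III"))

  # missing root parameter, or missing ratio below the root
  ins <- classify_simplified(tibble::tibble(
    e_prime_cm_s = c(NA, 6), E_cm_s = c(90, NA), A_cm_s = NA_real_))
  expect_equal(ins$status, rep("insufficient", 2))
})

test_that("simplified engine is total and never discordant on a complete grid", {
  grid <- expand.grid(e = seq(0.5, 20, by = 0.5), Ee = seq(0.5, 30, by = 0.5))
  m <- panel_from(e = grid$e, Ee = grid$Ee)
  s <- classify_simplified(m)
  expect_true(all(s$status == "categorized"))
  expect_false(any(s$status == "discordant"))
  expected <- ifelse(grid$e >= 8, "0",
                     ifelse(grid$Ee <= 8, "I",
                            ifelse(grid$Ee < 13, "II", "III")))
  expect_equal(s$grade, expected)
})

test_that("stage-1 presence votes follow the e' and LAVI thresholds", {
  v <- ase_stage1_votes(echo_measurements(e_prime = c(9.8, 7.0, 9.0),
                                          LAVI = c(23.7, 34.7, 40)))
  expect_equal(v[[1]], list(e_prime = "normal", LAVI = "normal"))
  expect_equal(v[[2]], list(e_prime = "dysfunction", LAVI = "dysfunction"))
  expect_equal(v[[3]], list(e_prime = "normal", LAVI = "dysfunction"))
  expect_equal(ase_stage1_votes(echo_measurements(E = 90))[[1]], list())
})

test_that("stage-2 grade votes match the bin tables including gap unions", {
  m <- panel_from(e = c(7, 7, 7), Ee = c(8.1, 9.7, 15.5),
                  EA = c(0.67, 0.91, 3.76), DT = c(238, 180, 142))
  v <- ase_stage2_votes(m)
  expect_equal(v[[1]], list(E_over_A = "I", DT = "I", E_over_e_prime = c("I", "II")))
  expect_equal(v[[2]], list(E_over_A = "II", DT = "II", E_over_e_prime = "II"))
  expect_equal(v[[3]], list(E_over_A = "III", DT = "III", E_over_e_prime = "III"))

  gaps <- panel_from(e = c(7, 7), Ee = c(12.5, 10), EA = c(1.7, 1.5),
                     DT = c(200, 160))
  vg <- ase_stage2_votes(gaps)
  expect_equal(vg[[1]]$E_over_e_prime, c("II", "III"))
  expect_equal(vg[[1]]$E_over_A, c("II", "III"))
  expect_equal(vg[[1]]$DT, "II")
  expect_equal(vg[[2]]$E_over_A, "II")
  expect_equal(vg[[2]]$DT, "II")
})

test_that("ASE engine categorizes the per-grade median vectors", {
  m <- panel_from(e = c(9.8, 7.0, 7.3, 7.0),
                  Ee = c(9.1, 8.1, 9.7, 15.5),
                  EA = c(1.21, 0.67, 0.91, 3.76),
                  DT = c(180, 238, 180, 142),
                  LAVI = c(23.7, 55.6, 35.2, 34.7))
  a <- classify_ase2009(m)
  expect_equal(a$status, rep("categorized", 4))
  expect_equal(a$grade, c("0", "I", "II", "III"))
  # grade 0 is decided at stage 1: its E/e' of 9.1 would vote grade II
  expect_equal(a$votes[[1]]$stage2$E_over_e_prime, "II")
})

test_that("ASE engine reports discordant and insufficient panels", {
  disc <- classify_ase2009(panel_from(e = 7.0, Ee = 7.0, EA = 0.6,
                                      DT = 150, LAVI = 40))
  expect_equal(disc$status, "discordant") # stage-2 votes {I},{III},{I}

  s1_conflict <- classify_ase2009(echo_measurements(e_prime = 9.0, LAVI = 40))
  expect_equal(s1_conflict$status, "discordant")

  nothing <- classify_ase2009(echo_measurements())
  expect_equal(nothing$status, "insufficient")

  # a single parameter pinning one category suffices
  only_e <- classify_ase2009(echo_measurements(e_prime = 9.5))
  expect_equal(only_e$status, "categorized")
  expect_equal(only_e$grade, "0")

  # dysfunction agreed but several grades survive
  multi <- classify_ase2009(panel_from(e = 7, Ee = 12.5, LAVI = 40))
  expect_equal(multi$status, "insufficient")
})

test_that("ASE engine agrees with the interval-enumeration oracle", {
  withr::with_seed(2024, {
    panels <- random_panels(4000)
  })
  got <- classify_ase2009(panels)
  for (i in seq_len(nrow(panels))) {
    want <- oracle_ase(panels$E_cm_s[i], panels$A_cm_s[i],
                       panels$e_prime_cm_s[i], panels$DT_ms[i],
                       panels$LAVI_ml_m2[i])
    expect_identical(got$status[i], want$status)
    expect_identical(got$grade[i], want$grade)
  }
})

test_that("removing a parameter never yields a grade outside the vote union", {
  cols <- c("E_cm_s", "A_cm_s", "e_prime_cm_s", "DT_ms", "LAVI_ml_m2")
  withr::with_seed(7, panels <- random_panels(600, p_present = 0.9))
  base <- classify_ase2009(panels)
  disc <- which(base$status == "discordant")
  for (i in disc) {
    union_votes <- unique(unlist(base$votes[[i]]$stage2, use.names = FALSE))
    for (cl in cols) {
      reduced <- panels[i, ]
      reduced[[cl]] <- NA_real_
      v <- classify_ase2009(reduced)
      if (v$status == "categorized" && v$grade != "0") {
        expect_true(v$grade %in% union_votes)
      }
    }
  }
})

test_that("grading is invariant to beat order fed to cycle averaging", {
  beats <- list(E = c(95, 88, 92), A = c(70, 75, 65), e = c(6.2, 6.0, 6.4))
  m1 <- echo_measurements(E = average_cycles(beats$E),
                          A = average_cycles(beats$A),
                          e_prime = average_cycles(beats$e))
  m2 <- echo_measurements(E = average_cycles(rev(beats$E)),
                          A = average_cycles(rev(beats$A)),
                          e_prime = average_cycles(sample(beats$e)))
  expect_equal(classify_simplified(m1)$grade, classify_simplified(m2)$grade)
  expect_equal(classify_ase2009(m1)$grade, classify_ase2009(m2)$grade)
})

test_that("concordance table matches a per-record tally", {
  # identity cohort: both engines agree everywhere
  ident <- panel_from(e = c(9.5, 5.8, 7, 7), Ee = c(9.3, 17.7, 7.8, 9.7),
                      EA = c(1.21, 3.76, 0.67, 0.91),
                      DT = c(180, 142, 238, 180),
                      LAVI = c(23.7, 34.7, 55.6, 35.2))
  g <- grade_cohort(ident, "both")
  cc <- compare_definitions(g)
  expect_equal(cc$status$count[cc$status$group == "both"], 4)
  expect_equal(cc$grade_diff$count, c(4, 0, 0))

  # single patient categorized only by the simplified engine
  # (ASE stage-2 votes {II} vs {I} conflict via DT)
  solo <- grade_cohort(panel_from(e = 6, Ee = 10, DT = 238), "both")
  cs <- compare_definitions(solo)
  expect_equal(cs$status$count[cs$status$group == "both"], 0)
  expect_equal(cs$status$count[cs$status$group == "simplified_only"], 1)
  expect_equal(sum(cs$grade_diff$count), 0)

  # randomized cohort: counts equal an independent per-record tally
  withr::with_seed(11, panels <- random_panels(400))
  gg <- grade_cohort(panels, "both")
  ct <- compare_definitions(gg)
  a_cat <- gg$ase_status == "categorized"
  s_cat <- gg$simp_status == "categorized"
  tally <- c(sum(a_cat & s_cat), sum(a_cat & !s_cat),
             sum(!a_cat & s_cat), sum(!(a_cat | s_cat)))
  expect_equal(ct$status$count, tally)
  expect_equal(sum(ct$status$count), 400)
  expect_equal(sum(ct$grade_diff$count), tally[1])
})
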