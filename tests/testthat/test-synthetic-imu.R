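test_that("step train embeds cadence with strict alternation", {
  tr <- simulate_step_train(160, 60, timing_jitter_cv = 0, seed = 1)
  expect_equal(nrow(tr), 160)
  expect_equal(diff(tr$time_s), rep(60 / 160, 159))
  expect_equal(tr$side, rep(c("L", "R"), 80))
  expect_equal(nrow(simulate_step_train(168, 300, 0, seed = 1)), 840)
  expect_error(simulate_step_train(0, 60), "positive")
  expect_error(simulate_step_train(160, -1), "positive")
})

test_that("jittered step trains keep the event count and are reproducible", {
  a <- simulate_step_train(160, 60, timing_jitter_cv = 0.05, seed = 99)
  b <- simulate_step_train(160, 60, timing_jitter_cv = 0.05, seed = 99)
  expect_identical(a, b)
  expect_lte(abs(nrow(a) - 160), 2)
  expect_true(all(diff(a$time_s) > 0))
})

test_that("impact transient peaks exactly at the programmed amplitude", {
  seg <- synth_impact_transient(12, 120)
  expect_equal(max(seg), 12)
  expect_lt(seg[length(seg)], 0.05 * 12)           # decayed by segment end
  expect_lte(length(seg) / 120, 0.5 * 60 / 240 + 1e-9)  # fits 240 spm spacing
  expect_error(synth_impact_transient(0), "positive")
})

test_that("superposed transients keep their individual peaks", {
  z <- transient_train(c(1.0, 1.375), 12, duration_s = 3)
  ev <- detect_impact_peaks(z, 120, "SACRUM")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$peak_magnitude_g, c(12, 12), tolerance = 0.01)
})

test_that("zero-noise bouts embed the programmed parameters exactly", {
  m <- analyse_bout(simulate_bout(clean_params(160, 10, la = 0, rsh = 0.5)))
  expect_equal(m$cad_spm, 160)
  expect_equal(m$pta_left_g, 10)
  expect_equal(m$pta_right_g, 10)
  expect_equal(m$ala, 0)
  expect_equal(m$rsh, 0.5)
  # asymmetry split: LA +0.20 at PTA 10 g puts 11 g left, 9 g right
  m2 <- analyse_bout(simulate_bout(clean_params(160, 10, la = 0.2)))
  expect_equal(m2$pta_left_g, 11)
  expect_equal(m2$pta_right_g, 9)
  expect_equal(m2$la, 0.2)
})

test_that("bout simulation is seed-deterministic and streams are synchronous", {
  p <- noisy_params(seed = 1234)
  r1 <- simulate_bout(p)
  r2 <- simulate_bout(p)
  expect_identical(r1$streams, r2$streams)
  lens <- vapply(r1$streams, function(s) length(s$t), 1L)
  expect_true(all(lens == lens[1]))
  expect_identical(r1$streams$L_TIBIA$t, r1$streams$SACRUM$t)
})

test_that("bout parameter invariants are enforced with the field named", {
  expect_error(bout_sim_params(-1, 10), "cadence_spm")
  expect_error(bout_sim_params(160, 0), "pta_target_g")
  expect_error(bout_sim_params(160, 10, la_target = 2.5), "la_target")
  expect_error(bout_sim_params(160, 10, rsh_target = -0.1), "rsh_target")
  expect_error(bout_sim_params(160, 10, duration_s = 25), "duration_s")
  # programmed amplitudes must clear the 1 g gravity baseline
  expect_error(simulate_bout(bout_sim_params(160, 10, rsh_target = 0.05)),
               "gravity baseline")
})

test_that("cohort generation yields 18 bouts per subject with exact cell means", {
  prof <- make_subject_profiles(4, seed = 11)
  sim <- simulate_cohort(prof, seed = 12, duration_s = 40,
                         handler = function(rec, row) NULL)
  expect_equal(nrow(sim$design), 4 * 18)
  expect_equal(as.vector(table(sim$design$subject)), rep(18L, 4))
  # standardised subject effects make programmed cell means exactly calibrated
  cal <- default_calibration()
  key <- function(d) paste(d$elevation_m, d$speed_level, d$surface)
  prog <- tapply(sim$design$pta_prog, key(sim$design), mean)
  expect_equal(as.numeric(prog[key(cal)]), cal$pta_mean)
  prog_cad <- tapply(sim$design$cad_prog, key(sim$design), mean)
  expect_equal(as.numeric(prog_cad[key(cal)]), cal$cad_mean)
  # per-subject asymmetry sign is a stable trait
  sgn <- tapply(sign(sim$design$la_prog), sim$design$subject,
                function(s) length(unique(s)))
  expect_true(all(sgn == 1))
})

test_that("cohort generation rejects degenerate cohorts and bad calibration", {
  expect_error(simulate_cohort(make_subject_profiles(2)[1, , drop = FALSE]),
               "2 subjects")
  expect_error(make_subject_profiles(0), "2 subjects")
  cal <- default_calibration()
  expect_error(simulate_cohort(make_subject_profiles(3, seed = 1),
                               calibration = cal[-c(1, 5), ]),
               "missing cells: .*50/v1/ROAD")
})

test_that("TRAIL bouts add variability, not a mean shift", {
  prof <- make_subject_profiles(3, seed = 2)
  sim <- simulate_cohort(prof, seed = 3, duration_s = 40,
                         handler = function(rec, row) NULL)
  d <- sim$design
  expect_equal(unique(d$amp_cv[d$surface == "TRAIL"]) /
                 unique(d$amp_cv[d$surface == "ROAD"]), 1.5)
  road <- d[d$surface == "ROAD", ]
  trail <- d[d$surface == "TRAIL", ]
  ord <- order(road$subject, road$elevation_m, road$speed_level)
  ord2 <- order(trail$subject, trail$elevation_m, trail$speed_level)
  expect_equal(road$pta_prog[ord], trail$pta_prog[ord2])
})
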