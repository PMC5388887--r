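rat <- species_config("rat")
mouse <- species_config("mouse")

test_that("simulation is reproducible under a seed and honors the config", {
  cc <- cohort_config("mouse", n = 50, seed = 99)
  expect_identical(simulate_cohort(cc), simulate_cohort(cc))
  cc2 <- cohort_config("mouse", n = 50, seed = 100)
  expect_false(identical(simulate_cohort(cc), simulate_cohort(cc2)))

  # degenerate lag: every first ovulation one day after VO
  cc <- cohort_config("rat", n = 30, lag_mean = 1, lag_sd = 0, seed = 5)
  traj <- simulate_cohort(cc)
  expect_true(all(traj$fo_age_pnd == traj$vo_age_pnd + 1L))
  expect_true(all(traj$sacrifice_age_pnd >= 25L))
  expect_true(all(traj$fo_age_pnd >= traj$vo_age_pnd))
})

test_that("large-cohort draws match the configured moments", {
  cc <- cohort_config("mouse", n = 1e4, seed = 12)
  traj <- simulate_cohort(cc)
  lag <- traj$fo_age_pnd - traj$vo_age_pnd
  # integer rounding adds ~1/12 to the variance; means are unbiased
  expect_lt(abs(mean(lag) - cc$lag_mean), 3 * cc$lag_sd / sqrt(cc$n))
  expect_lt(abs(sd(lag) - sqrt(cc$lag_sd^2 + 1 / 12)), 0.1)
  expect_lt(abs(mean(traj$vo_age_pnd) - cc$vo_mean),
            3 * cc$vo_sd / sqrt(cc$n))
})

test_that("impossible truncation is rejected", {
  cc <- cohort_config("mouse", n = 10, vo_mean = 5, vo_sd = 0.5, seed = 1)
  expect_error(simulate_cohort(cc), "no mass")
  expect_error(cohort_config("rat", p_long_cycle = 0.3), "mouse option")
})

test_that("rendering maps elapsed time to the species schedules", {
  traj <- data.frame(animal_id = "x", species = "rat", vo_age_pnd = 33L,
                     fo_age_pnd = 34L, sacrifice_age_pnd = 34L,
                     cycle_lengths = "4,4,4,4", stringsAsFactors = FALSE)
  # day of first ovulation: newly formed CL, COCs at the ampulla
  obs <- render_observation(traj, rat)
  expect_equal(length(obs$cl_generations), 1L)
  expect_equal(obs$oocyte_location, "ampulla_COC")
  expect_equal(obs$cl_generations[[1]]$luteinization, "none")
  expect_true(obs$cl_generations[[1]]$rupture_site)
  expect_equal(assign_pubscore(obs, rat)$score, 1L)

  # second estrus (elapsed 4 d): day-1 CL plus one regressing generation
  # with its apoptotic burst -> +5
  traj$sacrifice_age_pnd <- 38L
  obs <- render_observation(traj, rat)
  expect_equal(length(obs$cl_generations), 2L)
  expect_equal(obs$cl_generations[[2]]$apoptosis, "abundant")
  expect_equal(assign_pubscore(obs, rat)$score, 5L)

  # mouse diestrus picture: fibrous center, F3 companions, oocytes at the
  # utero-tubal junction
  tm <- data.frame(animal_id = "m", species = "mouse", vo_age_pnd = 32L,
                   fo_age_pnd = 39L, sacrifice_age_pnd = 41L,
                   cycle_lengths = "4,4,4", stringsAsFactors = FALSE)
  obs <- render_observation(tm, mouse)
  expect_true(obs$cl_generations[[1]]$fibrous_center)
  expect_equal(obs$follicle_class, "F3")
  expect_equal(obs$oocyte_location, "uterotubal_junction")
  expect_equal(assign_pubscore(obs, mouse)$score, 3L)

  # pre-ovulatory rendering walks the follicle ladder day by day
  for (k in 1:5) {
    tm$sacrifice_age_pnd <- tm$fo_age_pnd - k
    obs <- render_observation(tm, mouse)
    expect_equal(length(obs$cl_generations), 0L)
    expect_equal(assign_pubscore(obs, mouse)$score, -k)
  }
  tm$sacrifice_age_pnd <- tm$fo_age_pnd - 7L
  expect_warning(obs <- render_observation(tm, mouse), "before first")
  expect_equal(obs$follicle_class, "SF")
})

test_that("round trip: simulate, render, score, retrodate is exact", {
  for (sp in c("rat", "mouse")) {
    cfg <- species_config(sp)
    cc <- cohort_config(sp, n = 400, seed = 77,
                        sacrifice = list(rule = "fo_offset", min = -5,
                                         max = 4 * (cfg$max_regressing_generations + 1) - 1))
    traj <- simulate_cohort(cc)
    scored <- score_observations(render_cohort(traj, cfg), cfg)
    ovul <- scored$status == "ovulating"
    # every animal sacrificed in the dating window is dated exactly
    expect_true(all(scored$estimated_fo_age_pnd[ovul] ==
                      traj$fo_age_pnd[ovul]))
    # every animal sacrificed at or after its first ovulation but inside
    # the window must be dated (no silent misses)
    k <- traj$sacrifice_age_pnd - traj$fo_age_pnd
    expect_identical(ovul, k >= 0L)
    expect_false(any(scored$status == "inconsistent"))
  }
})

test_that("mice are censored beyond the 8-day window, never dated", {
  cc <- cohort_config("mouse", n = 300, seed = 31,
                      sacrifice = list(rule = "fo_offset", min = 6, max = 12))
  traj <- simulate_cohort(cc)
  scored <- score_observations(render_cohort(traj, mouse), mouse)
  k <- traj$sacrifice_age_pnd - traj$fo_age_pnd
  expect_identical(scored$status == "censored", k >= 8L)
  expect_true(all(is.na(scored$estimated_fo_age_pnd[scored$status ==
                                                      "censored"])))
  expect_true(all(scored$score[scored$status == "censored"] == 8L))
})

test_that("5-day mouse cycles give a lower bound on elapsed time", {
  # with extended diestrous phases the score underestimates elapsed time
  # by at most the accumulated extra days, and never overestimates it
  cc <- cohort_config("mouse", n = 300, seed = 53, p_long_cycle = 0.5,
                      sacrifice = list(rule = "fo_offset", min = 0, max = 7))
  traj <- simulate_cohort(cc)
  scored <- score_observations(render_cohort(traj, mouse), mouse)
  ovul <- which(scored$status == "ovulating")
  expect_true(length(ovul) > 50)
  for (i in ovul) {
    k <- traj$sacrifice_age_pnd[i] - traj$fo_age_pnd[i]
    est <- scored$estimated_fo_age_pnd[i]
    true_fo <- traj$fo_age_pnd[i]
    # estimated FO never earlier than the truth (score never overstates
    # elapsed time) ...
    expect_gte(est, true_fo)
    # ... and late by at most the extra diestrus days accumulated
    lens <- as.integer(strsplit(traj$cycle_lengths[i], ",")[[1]])
    cum <- cumsum(lens)
    n_complete <- sum(cum <= k)
    rem <- k - c(0L, cum)[n_complete + 1L]
    current_long <- n_complete < length(lens) &&
      lens[n_complete + 1L] == 5L
    extra <- sum(lens[seq_len(n_complete)] - 4L) +
      as.integer(current_long && rem >= 3L)
    expect_lte(est - true_fo, extra)
  }
})
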