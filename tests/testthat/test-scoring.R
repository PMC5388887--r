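rat <- species_config("rat")
mouse <- species_config("mouse")

test_that("worked examples score and retrodate correctly", {
  # rat at PND-40: two CL generations, current with metestrus features,
  # oocytes at the isthmus, F3 companions -> +6, first ovulation PND-35
  obs <- ovary_observation(
    "r1", "rat", 40, follicle_class = "F3",
    cl_generations = list(
      cl_features("current", luteinization = "partial", mitoses = "abundant",
                  vascular_pattern = TRUE),
      cl_features("R1", stromal_ratio_grade = 1L)),
    oocyte_location = "isthmus_nude")
  res <- assign_pubscore(obs, rat)
  expect_equal(res$score, 6L)
  expect_equal(res$status, "ovulating")
  expect_equal(res$estimated_fo_age_pnd, 35L)
  expect_true(length(res$evidence) > 0)

  # mouse at PND-42: single current CL with abundant apoptosis and F4
  # companions -> +4, first ovulation PND-39
  obs <- ovary_observation(
    "m1", "mouse", 42, follicle_class = "F4",
    cl_generations = list(
      cl_features("current", luteinization = "full",
                  apoptosis = "abundant")),
    oocyte_location = "none")
  res <- assign_pubscore(obs, mouse)
  expect_equal(res$score, 4L)
  expect_equal(res$estimated_fo_age_pnd, 39L)
})

test_that("non-ovulating animals score from the follicle ladder", {
  for (cls in c("SF", "F1", "F2", "F3", "F4")) {
    obs <- ovary_observation("m", "mouse", 30, follicle_class = cls)
    res <- assign_pubscore(obs, mouse)
    expect_equal(res$status, "prepubertal")
    expect_equal(res$score,
                 mouse$follicle_classes$score[
                   match(cls, mouse$follicle_classes$label)])
    expect_true(is.na(res$estimated_fo_age_pnd))
  }
  # rat SF carries the same floor score as F1, with a provenance note
  res <- assign_pubscore(
    ovary_observation("r", "rat", 28, follicle_class = "SF"), rat)
  expect_equal(res$score, -5L)
  expect_true("below_F1" %in% res$evidence)
})

test_that("score ceilings and censoring behave per species", {
  res <- assign_pubscore(schedule_observation(rat, g = 2L, d = 4L), rat)
  expect_equal(res$score, 12L)
  expect_equal(res$status, "ovulating")

  res <- assign_pubscore(schedule_observation(mouse, g = 1L, d = 4L), mouse)
  expect_equal(res$score, 8L)
  expect_equal(res$status, "ovulating")

  # a mouse past the window is censored at the ceiling, never dated
  res <- assign_pubscore(schedule_observation(mouse, g = 2L, d = 1L), mouse)
  expect_equal(res$status, "censored")
  expect_equal(res$score, 8L)
  expect_true(is.na(res$estimated_fo_age_pnd))
})

test_that("closed form matches exhaustive flowchart traversal", {
  for (cfg in list(rat, mouse)) {
    for (g in 0:cfg$max_regressing_generations) {
      for (d in 1:4) {
        obs <- schedule_observation(cfg, g = g, d = d)
        engine <- assign_pubscore(obs, cfg)
        oracle <- flowchart_score(obs, cfg)
        expect_equal(engine$score, 4L * g + d,
                     info = sprintf("%s g=%d d=%d", cfg$species, g, d))
        expect_equal(engine$score, oracle,
                     info = sprintf("%s g=%d d=%d", cfg$species, g, d))
        expect_equal(engine$status, "ovulating")
      }
    }
    # censored branch agrees too
    obs <- schedule_observation(cfg, g = cfg$max_regressing_generations + 1L,
                                d = 1L)
    engine <- assign_pubscore(obs, cfg)
    oracle <- flowchart_score(obs, cfg)
    expect_equal(engine$status, "censored")
    expect_true(oracle$censored)
    expect_equal(engine$score, oracle$score)
  }
  # prepubertal branch of the flowchart
  for (cls in c("SF", "F2", "F4")) {
    obs <- ovary_observation("m", "mouse", 30, follicle_class = cls)
    expect_equal(assign_pubscore(obs, mouse)$score,
                 flowchart_score(obs, mouse))
  }
})

test_that("scores stay within bounds and never take the value zero", {
  for (cfg in list(rat, mouse)) {
    scores <- integer(0)
    for (cls in follicle_labels(cfg)) {
      obs <- ovary_observation("a", cfg$species, 30, follicle_class = cls)
      scores <- c(scores, assign_pubscore(obs, cfg)$score)
    }
    for (g in 0:(cfg$max_regressing_generations + 1L)) {
      for (d in 1:4) {
        obs <- schedule_observation(cfg, g = g, d = d)
        scores <- c(scores, assign_pubscore(obs, cfg)$score)
      }
    }
    expect_true(all(scores >= -5L & scores <= cfg$max_score))
    expect_false(any(scores == 0L))
  }
})

test_that("score is non-decreasing in sacrifice age until censoring", {
  cc <- cohort_config("mouse", n = 1, lag_sd = 0, vo_sd = 0, seed = 3)
  traj <- simulate_cohort(cc)
  prev <- -6L
  for (sac in (traj$fo_age_pnd - 5L):(traj$fo_age_pnd + 7L)) {
    t2 <- traj
    t2$sacrifice_age_pnd <- sac
    res <- assign_pubscore(render_observation(t2, mouse), mouse)
    expect_gte(res$score, prev)
    prev <- res$score
  }
})

test_that("retrodating is consistent and refuses non-ovulating scores", {
  expect_equal(estimate_first_ovulation_age(40, 6), 35L)
  expect_equal(estimate_first_ovulation_age(42, 4), 39L)
  expect_equal(estimate_first_ovulation_age(33, 1), 33L)  # scored on the day
  for (score in 1:12) {
    est <- estimate_first_ovulation_age(50, score)
    expect_lte(est, 50)
    expect_equal(est == 50, score == 1L)
  }
  expect_error(estimate_first_ovulation_age(40, -3), "not yet ovulated")
  expect_error(estimate_first_ovulation_age(40, NA), "not yet ovulated")
})

test_that("species mismatch between observation and config is an error", {
  obs <- ovary_observation("x", "mouse", 30, follicle_class = "F2")
  expect_error(assign_pubscore(obs, rat), "mismatch")
})
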