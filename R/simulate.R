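#' Cohort simulation configuration
#'
#' Describes a synthetic peripubertal cohort: ages at vaginal opening (VO)
#' and VO-to-first-ovulation lags are drawn from truncated normal
#' distributions and rounded to integer postnatal days; estrous cycles are
#' 4 days long, with an optional per-cycle probability of a 5-day cycle
#' (the extra day extends diestrus, a mouse peculiarity). The sacrifice
#' rule is one of `"fixed"` (a fixed PND), `"vo_offset"` or `"fo_offset"`
#' (a uniform integer offset in `[min, max]` days after VO or after the
#' first ovulation).
#'
#' Defaults reproduce the validation cohort structure of each species:
#' rats (n = 20, VO 33.2 +/- 0.9 PND, lag 0.8 +/- 0.7 d, sacrifice at
#' PND-37) ovulate almost simultaneously with VO; mice (n = 17, VO
#' 31.8 +/- 1.8 PND, lag 6.8 +/- 2.3 d) ovulate about a week later and are
#' sacrificed 0-8 days after the first ovulation, inside the mouse dating
#' window.
#'
#' @param species `"rat"` or `"mouse"`.
#' @param n Number of animals.
#' @param vo_mean,vo_sd Mean and SD (PND) of the VO age, truncated at
#'   `vo_min`.
#' @param lag_mean,lag_sd Mean and SD (days) of the VO-to-first-ovulation
#'   lag, truncated at `lag_min` (>= 0).
#' @param vo_min,lag_min Truncation bounds.
#' @param cycle_length_days Baseline cycle length (4).
#' @param p_long_cycle Per-cycle probability of a 5-day cycle (0 for rat).
#' @param sacrifice List: `rule` plus `age_pnd` (fixed) or `min`/`max`
#'   (offsets).
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return A `pubscore_cohort_config` list.
#' @export
cohort_config <- function(species = c("rat", "mouse"),
                          n = NULL,
                          vo_mean = NULL, vo_sd = NULL,
                          lag_mean = NULL, lag_sd = NULL,
                          vo_min = 25, lag_min = 0,
                          cycle_length_days = 4L,
                          p_long_cycle = 0,
                          sacrifice = NULL,
                          seed = 1L) {
  species <- match.arg(species)
  defaults <- if (species == "rat") {
    list(n = 20L, vo_mean = 33.2, vo_sd = 0.9, lag_mean = 0.8, lag_sd = 0.7,
         sacrifice = list(rule = "fixed", age_pnd = 37L))
  } else {
    list(n = 17L, vo_mean = 31.8, vo_sd = 1.8, lag_mean = 6.8, lag_sd = 2.3,
         sacrifice = list(rule = "fo_offset", min = 0L, max = 8L))
  }
  cfg <- list(
    species = species,
    n = as.integer(if (is.null(n)) defaults$n else n),
    vo_mean = if (is.null(vo_mean)) defaults$vo_mean else vo_mean,
    vo_sd = if (is.null(vo_sd)) defaults$vo_sd else vo_sd,
    lag_mean = if (is.null(lag_mean)) defaults$lag_mean else lag_mean,
    lag_sd = if (is.null(lag_sd)) defaults$lag_sd else lag_sd,
    vo_min = vo_min, lag_min = lag_min,
    cycle_length_days = as.integer(cycle_length_days),
    p_long_cycle = p_long_cycle,
    sacrifice = if (is.null(sacrifice)) defaults$sacrifice else sacrifice,
    seed = as.integer(seed)
  )
  if (cfg$n < 1L) stop("n must be >= 1", call. = FALSE)
  if (cfg$vo_sd < 0 || cfg$lag_sd < 0) stop("sds must be >= 0", call. = FALSE)
  if (cfg$p_long_cycle < 0 || cfg$p_long_cycle > 1) {
    stop("p_long_cycle must be in [0, 1]", call. = FALSE)
  }
  if (species == "rat" && cfg$p_long_cycle > 0) {
    stop("p_long_cycle is a mouse option; rat cycles are 4 days",
         call. = FALSE)
  }
  if (!cfg$sacrifice$rule %in% c("fixed", "vo_offset", "fo_offset")) {
    stop("sacrifice$rule must be fixed, vo_offset or fo_offset",
         call. = FALSE)
  }
  class(cfg) <- "pubscore_cohort_config"
  cfg
}

#' Read a cohort configuration from YAML
#'
#' @param path Path to a YAML cohort configuration file (keys as in
#'   [cohort_config()], with `vo_age: {mean, sd, min}`,
#'   `lag_vo_to_fo: {mean, sd, min}` and `sacrifice: {rule, ...}` blocks).
#' @return A `pubscore_cohort_config`.
#' @export
load_cohort_config <- function(path) {
  if (!file.exists(path)) {
    stop("cohort config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  cohort_config(
    species = raw$species,
    n = raw$n,
    vo_mean = raw$vo_age$mean, vo_sd = raw$vo_age$sd,
    vo_min = if (is.null(raw$vo_age$min)) 25 else raw$vo_age$min,
    lag_mean = raw$lag_vo_to_fo$mean, lag_sd = raw$lag_vo_to_fo$sd,
    lag_min = if (is.null(raw$lag_vo_to_fo$min)) 0 else raw$lag_vo_to_fo$min,
    cycle_length_days = if (is.null(raw$cycle_length_days)) 4L
                        else raw$cycle_length_days,
    p_long_cycle = if (is.null(raw$p_long_cycle)) 0 else raw$p_long_cycle,
    sacrifice = raw$sacrifice,
    seed = if (is.null(raw$seed)) 1L else raw$seed
  )
}

# Truncated-normal sampler (lower truncation only), by rejection; errors
# out when essentially no mass lies above the bound.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (mean < lower) stop("truncation leaves no mass", call. = FALSE)
    return(rep(mean, n))
  }
  if (stats::pnorm(lower, mean, sd, lower.tail = FALSE) < 1e-8) {
    stop("truncation leaves no mass (lower bound ", lower,
         " vs mean ", mean, ", sd ", sd, ")", call. = FALSE)
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower])
  }
  out[seq_len(n)]
}

#' Simulate a peripubertal cohort
#'
#' Draws `n` ground-truth trajectories (VO age, first-ovulation age,
#' per-cycle lengths, sacrifice age) from a [cohort_config()].
#' Reproducible: the same config (including seed) always yields the same
#' cohort.
#'
#' @param config A `pubscore_cohort_config`.
#' @return A data frame of class `pubscore_trajectories` with columns
#'   `animal_id`, `species`, `vo_age_pnd`, `fo_age_pnd`,
#'   `sacrifice_age_pnd` and `cycle_lengths` (comma-separated days,
#'   covering the post-ovulation span up to sacrifice).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "pubscore_cohort_config"))
  set.seed(config$seed)
  n <- config$n
  vo <- round(rtruncnorm_lower(n, config$vo_mean, config$vo_sd,
                               config$vo_min))
  lag <- round(rtruncnorm_lower(n, config$lag_mean, config$lag_sd,
                                config$lag_min))
  fo <- vo + lag
  offsets <- function() {
    offs <- seq(as.integer(config$sacrifice$min),
                as.integer(config$sacrifice$max))
    offs[sample.int(length(offs), n, replace = TRUE)]
  }
  sac <- switch(config$sacrifice$rule,
    fixed = rep(as.integer(config$sacrifice$age_pnd), n),
    vo_offset = vo + offsets(),
    fo_offset = fo + offsets()
  )
  sac <- pmax(sac, 25L)
  # enough cycles to cover any sacrifice within the simulated span
  n_cycles <- max(3L, ceiling(max(sac - fo + 1L, 1L) / 4) + 1L)
  cycles <- vapply(seq_len(n), function(i) {
    lens <- config$cycle_length_days +
      stats::rbinom(n_cycles, 1L, config$p_long_cycle)
    paste(lens, collapse = ",")
  }, "")
  out <- data.frame(
    animal_id = sprintf("%s%04d", substr(config$species, 1, 1), seq_len(n)),
    species = config$species,
    vo_age_pnd = as.integer(vo),
    fo_age_pnd = as.integer(fo),
    sacrifice_age_pnd = as.integer(sac),
    cycle_lengths = cycles,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pubscore_trajectories", "data.frame")
  out
}

#' Render a trajectory into a histology observation
#'
#' Deterministically maps a ground-truth trajectory to the coded histology
#' that would be observed at sacrifice. For a pre-ovulatory animal
#' (sacrifice before first ovulation), day `-k` before ovulation carries
#' the follicle class mapped to score `-k` (the final preovulatory growth
#' days); earlier sacrifices yield baseline SF with a warning. For an
#' ovulating animal the elapsed days since first ovulation are walked
#' through the per-cycle lengths: the current-cycle CL day and companion
#' follicle class and oocyte location come from the species schedule (a
#' 5-day mouse cycle repeats the diestrus day, so the rendered CL age lags
#' the calendar), and each completed cycle contributes one regressing CL
#' generation with increasing stromal ratio grade, showing its apoptotic
#' burst on estrus days. Generations beyond the species identification
#' window are rendered as one extra unidentifiable remnant generation,
#' which the scorer reports as censored.
#'
#' @param traj One-row data frame (a row of [simulate_cohort()] output).
#' @param config Matching `pubscore_species_config`.
#' @return A [ovary_observation()].
#' @export
render_observation <- function(traj, config) {
  stopifnot(inherits(config, "pubscore_species_config"))
  if (is.data.frame(traj)) {
    stopifnot(nrow(traj) == 1L)
    traj <- as.list(traj)
  }
  k <- traj$sacrifice_age_pnd - traj$fo_age_pnd
  fc <- config$follicle_classes

  if (k < 0L) {
    if (k < -5L) {
      warning("sacrifice more than 5 days before first ovulation; ",
              "rendering baseline class SF")
      cls <- fc$label[1]
    } else {
      # most advanced class carrying score k (e.g. rat -5 -> F1, not SF)
      cls <- fc$label[max(which(fc$score == k))]
    }
    return(ovary_observation(traj$animal_id, traj$species,
                             age_pnd = traj$sacrifice_age_pnd,
                             follicle_class = cls,
                             cl_generations = list(),
                             oocyte_location = "none",
                             vo_age_pnd = traj$vo_age_pnd))
  }

  lens <- as.integer(strsplit(traj$cycle_lengths, ",")[[1]])
  if (sum(lens) <= k) {
    stop("cycle_lengths do not cover the elapsed time to sacrifice",
         call. = FALSE)
  }
  g_true <- 0L
  rem <- k
  while (rem >= lens[g_true + 1L]) {
    rem <- rem - lens[g_true + 1L]
    g_true <- g_true + 1L
  }
  j <- rem + 1L  # day within the current cycle
  cl_day <- if (lens[g_true + 1L] == 5L) c(1L, 2L, 3L, 3L, 4L)[j] else j

  sch <- config$cl_schedule[config$cl_schedule$day == cl_day, ]
  current <- cl_features(
    generation = "current",
    luteinization = sch$luteinization,
    mitoses = sch$mitoses,
    apoptosis = sch$apoptosis,
    vascular_pattern = sch$vascular_pattern,
    rupture_site = sch$rupture_site,
    fibrous_center = sch$fibrous_center,
    stromal_ratio_grade = 0L
  )
  g_vis <- min(g_true, config$max_regressing_generations + 1L)
  # a generation beyond the species window is an unidentifiable remnant,
  # coded only by its stromal ratio grade
  regressing <- lapply(seq_len(g_vis), function(i) {
    cl_features(
      generation = if (i <= config$max_regressing_generations)
        paste0("R", i) else NA_character_,
      luteinization = "full",
      mitoses = "absent",
      # regressing CL undergo an apoptotic burst at each estrus
      apoptosis = if (cl_day == 1L) "abundant" else "absent",
      stromal_ratio_grade = min(i, 2L)
    )
  })
  ovary_observation(traj$animal_id, traj$species,
                    age_pnd = traj$sacrifice_age_pnd,
                    follicle_class = sch$companion_class,
                    cl_generations = c(list(current), regressing),
                    oocyte_location = sch$oocyte_location,
                    vo_age_pnd = traj$vo_age_pnd)
}

#' Render a whole simulated cohort
#'
#' @param trajectories Output of [simulate_cohort()].
#' @inheritParams render_observation
#' @return A list of [ovary_observation()] objects.
#' @export
render_cohort <- function(trajectories, config) {
  lapply(seq_len(nrow(trajectories)), function(i) {
    render_observation(trajectories[i, ], config)
  })
}
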