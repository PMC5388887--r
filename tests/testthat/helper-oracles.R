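# Independent oracles and shared fixtures for the test suite.

# Literal traversal of the species staging flowcharts, written as the
# decision questions a histologist answers in order. Deliberately
# independent of the closed-form engine (assign_pubscore) it cross-checks.
flowchart_score <- function(obs, config) {
  fc <- config$follicle_classes
  if (length(obs$cl_generations) == 0L) {
    # follicle ladder for non-ovulating animals
    return(fc$score[match(obs$follicle_class, fc$label)])
  }
  gens <- vapply(obs$cl_generations, function(x) {
    if (!is.na(x$generation)) x$generation
    else c("current", "R1", "R2")[x$stromal_ratio_grade + 1L]
  }, "")
  n_regressing <- sum(gens != "current")
  if (n_regressing > config$max_regressing_generations) {
    return(list(score = config$max_score, censored = TRUE))
  }
  base <- 4L * n_regressing
  cur <- obs$cl_generations[[which(gens == "current")]]
  top <- fc$label[nrow(fc)]  # F5 in rat, F4 in mouse
  d <-
    if (obs$oocyte_location == "ampulla_COC") 1L
    else if (obs$oocyte_location == "isthmus_nude") 2L
    else if (obs$oocyte_location %in% c("uterotubal_junction", "uterine")) 3L
    else if (config$species == "mouse" && cur$apoptosis == "abundant") 4L
    else if (cur$luteinization == "none") 1L
    else if (cur$luteinization == "partial") 2L
    else if (config$species == "mouse" && cur$fibrous_center) 3L
    else if (obs$follicle_class == top) 4L
    else 3L
  base + d
}

# Render the typical observation for (species config, regressing
# generations g, current CL day d); mirrors the bundled feature schedules.
schedule_observation <- function(config, g, d, age_pnd = 60L) {
  sch <- config$cl_schedule[config$cl_schedule$day == d, ]
  current <- cl_features("current",
                         luteinization = sch$luteinization,
                         mitoses = sch$mitoses,
                         apoptosis = sch$apoptosis,
                         vascular_pattern = sch$vascular_pattern,
                         rupture_site = sch$rupture_site,
                         fibrous_center = sch$fibrous_center,
                         stromal_ratio_grade = 0L)
  regressing <- lapply(seq_len(g), function(i) {
    cl_features(generation = if (i <= config$max_regressing_generations)
                  paste0("R", i) else NA_character_,
                luteinization = "full",
                apoptosis = if (d == 1L) "abundant" else "absent",
                stromal_ratio_grade = min(i, 2L))
  })
  ovary_observation("sched", config$species, age_pnd,
                    follicle_class = sch$companion_class,
                    cl_generations = c(list(current), regressing),
                    oocyte_location = sch$oocyte_location)
}
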