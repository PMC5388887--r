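#' Classify an antral follicle by diameter
#'
#' Maps a follicle diameter to the species' discrete antral follicle class.
#' The class intervals are contiguous: everything below the first class
#' boundary is a small follicle (SF); each named class covers diameters up
#' to (and including) its upper bound; the top class is unbounded. For the
#' mouse this realizes SF < 250, F1 250-300, F2 301-350, F3 351-400 and
#' F4 > 400 micrometres.
#'
#' @param diameter_um Positive follicle diameter in micrometres.
#' @param config A `pubscore_species_config`.
#' @return A follicle class label (character).
#' @examples
#' cfg <- species_config("mouse")
#' classify_follicle(272.2, cfg)  # "F1"
#' classify_follicle(440.5, cfg)  # "F4"
#' @export
classify_follicle <- function(diameter_um, config) {
  stopifnot(inherits(config, "pubscore_species_config"))
  d <- as.numeric(diameter_um)
  if (length(d) != 1L || is.na(d) || d <= 0) {
    stop("diameter_um: must be a single positive diameter", call. = FALSE)
  }
  fc <- config$follicle_classes
  if (d < fc$upper_um[1]) {
    return(fc$label[1])
  }
  # smallest named class whose (inclusive) upper bound contains d
  fc$label[1L + which(d <= fc$upper_um[-1])[1]]
}

#' Most advanced healthy antral follicle class
#'
#' Classifies each measured follicle and returns the maximum class among the
#' healthy ones; atretic follicles are excluded from staging. If every
#' follicle is atretic, the baseline class SF is returned with a warning.
#'
#' @param diameters_um Numeric vector of follicle diameters (micrometres).
#' @param health Character vector (`"healthy"` / `"atretic"`), recycled to
#'   all-healthy when `NULL`.
#' @inheritParams classify_follicle
#' @return A follicle class label.
#' @export
most_advanced_class <- function(diameters_um, health = NULL, config) {
  stopifnot(inherits(config, "pubscore_species_config"))
  d <- as.numeric(diameters_um)
  if (length(d) == 0L) stop("diameters_um: empty", call. = FALSE)
  if (is.null(health)) health <- rep("healthy", length(d))
  health <- match.arg(as.character(health), c("healthy", "atretic"),
                      several.ok = TRUE)
  if (length(health) != length(d)) {
    stop("health: must match diameters_um in length", call. = FALSE)
  }
  keep <- d[health == "healthy"]
  if (length(keep) == 0L) {
    warning("all follicles atretic; returning baseline class SF")
    return(config$follicle_classes$label[1])
  }
  labels <- vapply(keep, classify_follicle, "", config = config)
  follicle_labels(config)[max(follicle_rank(labels, config))]
}

#' Date the current-cycle corpus luteum
#'
#' Assigns the age in days (1-4) since ovulation of the current-cycle CL
#' from its cytological features, the companion (most advanced healthy)
#' follicle class and the oviductal oocyte location. Discriminating signals
#' are applied in a fixed priority order so tie-breaking is deterministic:
#'
#' 1. oocyte location (cumulus-oocyte complexes in the dilated ampulla mark
#'    day 1; nude oocytes at the isthmus day 2; at the utero-tubal junction
#'    or uterus, day 3 in the mouse);
#' 2. the apoptosis landmark (abundant apoptotic cells in the current CL
#'    mark day 4 in the mouse; rat current-cycle CL show no apoptosis);
#' 3. luteinization grade (none = day 1, partial = day 2, full = days 3-4)
#'    refined by abundant mitoses (day 2) and a fibrous center (mouse day 3);
#' 4. the companion follicle class (in the rat, class F5 discriminates
#'    day 4 from day 3).
#'
#' Each informative signal narrows the candidate day set; a signal that
#' would empty the set is recorded as a conflict and the observation is
#' flagged inconsistent, keeping the best-supported day (the earliest
#' remaining candidate, i.e. the minimum elapsed time since ovulation).
#'
#' @param features [cl_features()] of the current-cycle CL
#'   (`generation == "current"` or `stromal_ratio_grade == 0`).
#' @param companion_class Most advanced healthy follicle class label.
#' @param oocytes Oviductal oocyte location token.
#' @inheritParams classify_follicle
#' @return A list with `day` (integer 1-4), `inconsistent` (logical),
#'   `evidence` (character, fired rules) and `conflicts` (character).
#' @export
date_current_cl <- function(features, companion_class, oocytes, config) {
  stopifnot(inherits(config, "pubscore_species_config"),
            inherits(features, "pubscore_cl_features"))
  gen_current <- identical(features$generation, "current") ||
    (is.na(features$generation) &&
       identical(features$stromal_ratio_grade, 0L))
  if (!gen_current) {
    stop("date_current_cl expects the current-cycle CL generation",
         call. = FALSE)
  }
  sch <- config$cl_schedule[order(config$cl_schedule$day), ]
  sets <- list()

  # priority 1: oocyte location ("none" is uninformative -- oocytes are
  # usually not found in the oviduct from diestrus onward)
  if (oocytes != "none") {
    sets[[length(sets) + 1L]] <- list(
      name = paste0("oocytes_", oocytes),
      days = sch$day[sch$oocyte_location == oocytes]
    )
  }

  # priority 2: apoptosis landmark
  if (features$apoptosis == "abundant") {
    sets[[length(sets) + 1L]] <- list(
      name = "apoptosis_abundant",
      days = sch$day[sch$apoptosis == "abundant"]
    )
  }

  # priority 3: luteinization grade, refined by abundant mitoses and the
  # fibrous center
  lut_days <- sch$day[sch$luteinization == features$luteinization]
  sets[[length(sets) + 1L]] <- list(
    name = paste0("luteinization_", features$luteinization),
    days = lut_days
  )
  if (features$mitoses == "abundant") {
    sets[[length(sets) + 1L]] <- list(
      name = "mitoses_abundant",
      days = sch$day[sch$mitoses == "abundant"]
    )
  }
  if (features$fibrous_center) {
    sets[[length(sets) + 1L]] <- list(
      name = "fibrous_center",
      days = sch$day[sch$fibrous_center]
    )
  }

  # priority 4: companion follicle class
  comp_days <- as.integer(names(config$companion_classes))[
    vapply(config$companion_classes, function(cl) companion_class %in% cl, NA)]
  if (length(comp_days)) {
    sets[[length(sets) + 1L]] <- list(
      name = paste0("companion_", companion_class),
      days = comp_days
    )
  } else {
    sets[[length(sets) + 1L]] <- list(
      name = paste0("companion_", companion_class, "_off_schedule"),
      days = integer(0)
    )
  }

  candidates <- sch$day
  evidence <- character(0)
  conflicts <- character(0)
  for (s in sets) {
    if (length(s$days) == 0L) {
      conflicts <- c(conflicts, s$name)
      next
    }
    narrowed <- intersect(candidates, s$days)
    if (length(narrowed) == 0L) {
      conflicts <- c(conflicts, s$name)
    } else {
      if (length(narrowed) < length(candidates)) {
        evidence <- c(evidence, s$name)
      }
      candidates <- narrowed
    }
  }
  list(day = as.integer(min(candidates)),
       inconsistent = length(conflicts) > 0L,
       evidence = evidence,
       conflicts = conflicts)
}

#' Count regressing corpus luteum generations
#'
#' Identifies the current-cycle CL and counts the regressing generations,
#' using the `generation` labels when present and otherwise ordering
#' generations by their stromal-to-steroidogenic ratio grade (the ratio
#' increases as CL regress). More than one CL generation places the animal
#' in at least its second estrous cycle. When more regressing generations
#' are recorded than the species can reliably identify (two in the rat,
#' one in the mouse), the count is capped and a censoring signal raised:
#' beyond that window the score is only a minimum elapsed time since
#' ovulation.
#'
#' @param cl_generations List of [cl_features()] objects.
#' @inheritParams classify_follicle
#' @return A list with `g` (regressing generations, capped), `censored`
#'   (logical), and `current_index` (position of the current-cycle CL, or
#'   `NA` if none).
#' @export
count_regressing_generations <- function(cl_generations, config) {
  stopifnot(inherits(config, "pubscore_species_config"))
  n <- length(cl_generations)
  if (n == 0L) {
    return(list(g = 0L, censored = FALSE, current_index = NA_integer_))
  }
  gens <- vapply(cl_generations, function(x) {
    if (!is.na(x$generation)) return(x$generation)
    c("current", "R1", "R2")[x$stromal_ratio_grade + 1L]
  }, "")
  cur <- which(gens == "current")
  if (length(cur) != 1L) {
    stop("cl_generations: exactly one current-cycle generation required (got ",
         length(cur), ")", call. = FALSE)
  }
  g_true <- n - 1L
  cap <- config$max_regressing_generations
  list(g = min(g_true, cap),
       censored = g_true > cap,
       current_index = cur)
}
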