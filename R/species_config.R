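#' @keywords internal
"_PACKAGE"

# Valid enum token sets, shared across the package.
.pub_enums <- list(
  species       = c("rat", "mouse"),
  luteinization = c("none", "partial", "full"),
  mitoses       = c("absent", "present", "abundant"),
  apoptosis     = c("absent", "abundant"),
  generation    = c("current", "R1", "R2"),
  oocyte        = c("none", "ampulla_COC", "isthmus_nude",
                    "uterotubal_junction", "uterine")
)

#' Load a species configuration
#'
#' Reads a YAML species parameter file describing the follicle class
#' boundaries, the class-to-score map for non-ovulating animals, the
#' current-cycle corpus luteum (CL) feature schedule, the oocyte transit
#' schedule and the species score ceiling, and validates it.
#'
#' The two bundled configurations (`species_config("rat")` and
#' `species_config("mouse")`) encode the published staging criteria:
#' the mouse carries five follicle classes (SF, F1-F4) mapped to scores
#' -5..-1 and a score ceiling of +8 (one identifiable generation of
#' regressing CL); the rat carries six classes (SF, F1-F5) and a ceiling
#' of +12 (two identifiable regressing generations).
#'
#' @param path Path to a YAML species configuration file.
#' @return A `pubscore_species_config` object (a validated list).
#' @examples
#' cfg <- species_config("mouse")
#' cfg$max_score
#' @export
load_species_config <- function(path) {
  if (!file.exists(path)) {
    stop("species config file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed species config '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  as_species_config(raw)
}

#' @rdname load_species_config
#' @param species `"rat"` or `"mouse"`; loads the bundled configuration.
#' @export
species_config <- function(species = c("rat", "mouse")) {
  species <- match.arg(species)
  load_species_config(system.file("extdata", paste0(species, ".yaml"),
                                  package = "pubscore", mustWork = TRUE))
}

# Build and validate a species config from a plain list (parsed YAML).
as_species_config <- function(raw) {
  required <- c("species", "cycle_length_days", "max_regressing_generations",
                "max_score", "follicle_classes", "cl_schedule")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("species config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    species = as.character(raw$species),
    cycle_length_days = as.integer(raw$cycle_length_days),
    max_regressing_generations = as.integer(raw$max_regressing_generations),
    max_score = as.integer(raw$max_score)
  )
  fc <- raw$follicle_classes
  cfg$follicle_classes <- data.frame(
    label = vapply(fc, function(x) as.character(x$label), ""),
    upper_um = vapply(fc, function(x) as.numeric(x$upper_um), 0),
    score = vapply(fc, function(x) as.integer(x$score), 0L),
    stringsAsFactors = FALSE
  )
  sch <- raw$cl_schedule
  cfg$cl_schedule <- data.frame(
    day = vapply(sch, function(x) as.integer(x$day), 0L),
    luteinization = vapply(sch, function(x) as.character(x$luteinization), ""),
    mitoses = vapply(sch, function(x) as.character(x$mitoses), ""),
    apoptosis = vapply(sch, function(x) as.character(x$apoptosis), ""),
    vascular_pattern = vapply(sch, function(x) isTRUE(x$vascular_pattern), NA),
    rupture_site = vapply(sch, function(x) isTRUE(x$rupture_site), NA),
    fibrous_center = vapply(sch, function(x) isTRUE(x$fibrous_center), NA),
    companion_class = vapply(sch, function(x) as.character(x$companion_class), ""),
    oocyte_location = vapply(sch, function(x) as.character(x$oocyte_location), ""),
    stringsAsFactors = FALSE
  )
  cfg$companion_classes <- lapply(sch, function(x) as.character(x$companion_classes))
  names(cfg$companion_classes) <- as.character(cfg$cl_schedule$day)
  class(cfg) <- "pubscore_species_config"
  validate_species_config(cfg)
  cfg
}

# Invariant checks; stop()s with the offending field name.
validate_species_config <- function(cfg) {
  if (!cfg$species %in% .pub_enums$species) {
    stop("species: must be one of ", paste(.pub_enums$species, collapse = ", "),
         call. = FALSE)
  }
  fc <- cfg$follicle_classes
  if (fc$label[1] != "SF") {
    stop("follicle_classes: first class must be SF", call. = FALSE)
  }
  if ("F5" %in% fc$label && cfg$species != "rat") {
    stop("follicle_classes: class F5 is valid only for rat", call. = FALSE)
  }
  # contiguous, non-overlapping intervals <=> strictly increasing uppers
  if (any(diff(fc$upper_um) <= 0) || !is.infinite(fc$upper_um[nrow(fc)])) {
    stop("follicle_classes: diameter bounds must be strictly increasing ",
         "and the top class unbounded", call. = FALSE)
  }
  if (any(fc$score < -5L) || any(fc$score > -1L)) {
    stop("follicle_classes: scores must lie in [-5, -1]", call. = FALSE)
  }
  # scores non-decreasing with class advancement, strictly increasing from
  # F1 upward (SF may share -5 with F1, as in the rat)
  if (any(diff(fc$score) < 0L) || any(diff(fc$score[-1]) <= 0L)) {
    stop("follicle_classes: scores must increase with class advancement",
         call. = FALSE)
  }
  if (cfg$max_score != 4L * cfg$max_regressing_generations + 4L) {
    stop("max_score: must equal 4 * max_regressing_generations + 4",
         call. = FALSE)
  }
  sch <- cfg$cl_schedule
  if (!identical(sort(sch$day), 1:4)) {
    stop("cl_schedule: must contain exactly days 1 to 4", call. = FALSE)
  }
  for (col in c("luteinization", "mitoses", "apoptosis")) {
    bad <- setdiff(sch[[col]], .pub_enums[[col]])
    if (length(bad)) {
      stop("cl_schedule$", col, ": unknown token '", bad[1], "'", call. = FALSE)
    }
  }
  bad <- setdiff(sch$oocyte_location, .pub_enums$oocyte)
  if (length(bad)) {
    stop("cl_schedule$oocyte_location: unknown token '", bad[1], "'",
         call. = FALSE)
  }
  if (!all(sch$companion_class %in% fc$label) ||
      !all(unlist(cfg$companion_classes) %in% fc$label)) {
    stop("cl_schedule$companion_class: class not declared in follicle_classes",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Write a species configuration to YAML
#'
#' Inverse of [load_species_config()]: writing then reloading reproduces an
#' identical configuration object.
#'
#' @param cfg A `pubscore_species_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pubscore_species_config"))
  fc <- cfg$follicle_classes
  sch <- cfg$cl_schedule
  out <- list(
    species = cfg$species,
    cycle_length_days = cfg$cycle_length_days,
    max_regressing_generations = cfg$max_regressing_generations,
    max_score = cfg$max_score,
    follicle_classes = lapply(seq_len(nrow(fc)), function(i) {
      list(label = fc$label[i], upper_um = fc$upper_um[i], score = fc$score[i])
    }),
    cl_schedule = lapply(seq_len(nrow(sch)), function(i) {
      list(day = sch$day[i],
           luteinization = sch$luteinization[i],
           mitoses = sch$mitoses[i],
           apoptosis = sch$apoptosis[i],
           vascular_pattern = sch$vascular_pattern[i],
           rupture_site = sch$rupture_site[i],
           fibrous_center = sch$fibrous_center[i],
           companion_class = sch$companion_class[i],
           companion_classes = cfg$companion_classes[[as.character(sch$day[i])]],
           oocyte_location = sch$oocyte_location[i])
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pubscore_species_config <- function(x, ...) {
  cat("Pub-score species configuration:", x$species, "\n")
  cat("  cycle length:", x$cycle_length_days, "days;",
      "max regressing CL generations:", x$max_regressing_generations, ";",
      "score ceiling: +", x$max_score, "\n", sep = " ")
  cat("  follicle classes:",
      paste(sprintf("%s(%d)", x$follicle_classes$label,
                    x$follicle_classes$score), collapse = " < "), "\n")
  invisible(x)
}

# ordered follicle class labels for a config
follicle_labels <- function(cfg) cfg$follicle_classes$label

# integer rank of a follicle class label (SF = 1)
follicle_rank <- function(label, cfg) {
  match(label, follicle_labels(cfg))
}
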