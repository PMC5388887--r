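#' Corpus luteum feature set
#'
#' Codes the cytological features of one corpus luteum (CL) generation as
#' recorded at sacrifice. `generation` identifies the generation directly
#' (`"current"`, `"R1"`, `"R2"`); when it is `NA` the generation is inferred
#' from `stromal_ratio_grade` (0 = current cycle, 1 = one-cycle-old,
#' 2 = two-cycle-old), reflecting the increasing ratio of stromal to
#' steroidogenic cells as CL regress.
#'
#' @param generation `"current"`, `"R1"`, `"R2"` or `NA`.
#' @param luteinization `"none"`, `"partial"` or `"full"`.
#' @param mitoses `"absent"`, `"present"` or `"abundant"`.
#' @param apoptosis `"absent"` or `"abundant"`.
#' @param vascular_pattern Logical; marked vascular pattern visible.
#' @param rupture_site Logical; rupture site visible at the ovarian surface.
#' @param fibrous_center Logical; fibrous center (a mouse diestrus hallmark).
#' @param stromal_ratio_grade Integer 0, 1, 2 or `NA`.
#' @return A `pubscore_cl_features` object.
#' @export
cl_features <- function(generation = NA_character_,
                        luteinization = "full",
                        mitoses = "absent",
                        apoptosis = "absent",
                        vascular_pattern = FALSE,
                        rupture_site = FALSE,
                        fibrous_center = FALSE,
                        stromal_ratio_grade = NA_integer_) {
  f <- list(
    generation = as.character(generation),
    luteinization = match.arg(luteinization, .pub_enums$luteinization),
    mitoses = match.arg(mitoses, .pub_enums$mitoses),
    apoptosis = match.arg(apoptosis, .pub_enums$apoptosis),
    vascular_pattern = isTRUE(vascular_pattern),
    rupture_site = isTRUE(rupture_site),
    fibrous_center = isTRUE(fibrous_center),
    stromal_ratio_grade = as.integer(stromal_ratio_grade)
  )
  if (!is.na(f$generation) && !f$generation %in% .pub_enums$generation) {
    stop("generation: unknown token '", f$generation, "'", call. = FALSE)
  }
  if (!is.na(f$stromal_ratio_grade) &&
      !f$stromal_ratio_grade %in% 0:2) {
    stop("stromal_ratio_grade: must be 0, 1 or 2", call. = FALSE)
  }
  if (is.na(f$generation) && is.na(f$stromal_ratio_grade)) {
    stop("a CL generation needs either 'generation' or 'stromal_ratio_grade'",
         call. = FALSE)
  }
  class(f) <- "pubscore_cl_features"
  f
}

#' One animal's coded ovarian histology
#'
#' Bundles the observations taken from serial ovarian sections of a single
#' animal at sacrifice: the most advanced healthy antral follicle class (or
#' raw follicle diameters with per-follicle health flags), the list of
#' corpus luteum generations with their cytological features, and the
#' location of ovulated oocytes in the oviduct. An empty `cl_generations`
#' list encodes a pre-ovulatory (non-ovulating) animal.
#'
#' @param animal_id Character identifier.
#' @param species `"rat"` or `"mouse"`.
#' @param age_pnd Age at sacrifice in postnatal days (day of birth = 1).
#' @param follicle_class Most advanced healthy antral follicle class label,
#'   or `NULL` when `diameters_um` is supplied.
#' @param cl_generations List of [cl_features()] objects (possibly empty).
#' @param oocyte_location Oviductal oocyte location token.
#' @param vo_age_pnd Optional recorded age at vaginal opening (PND).
#' @param diameters_um Optional numeric vector of raw follicle diameters.
#' @param health Optional character vector (`"healthy"`/`"atretic"`) matching
#'   `diameters_um`; defaults to all healthy.
#' @param config Species configuration, required to classify raw diameters.
#' @return A `pubscore_observation` object.
#' @examples
#' cfg <- species_config("mouse")
#' obs <- ovary_observation("m1", "mouse", age_pnd = 42, follicle_class = "F4",
#'                          cl_generations = list(cl_features("current",
#'                            luteinization = "full", apoptosis = "abundant")),
#'                          oocyte_location = "none")
#' assign_pubscore(obs, cfg)
#' @export
ovary_observation <- function(animal_id, species, age_pnd,
                              follicle_class = NULL,
                              cl_generations = list(),
                              oocyte_location = "none",
                              vo_age_pnd = NA_integer_,
                              diameters_um = NULL, health = NULL,
                              config = NULL) {
  species <- match.arg(species, .pub_enums$species)
  age_pnd <- as.integer(age_pnd)
  if (is.na(age_pnd) || age_pnd < 1L) {
    stop("age_pnd: must be a positive postnatal day", call. = FALSE)
  }
  if (is.null(follicle_class)) {
    if (is.null(diameters_um)) {
      stop("either follicle_class or diameters_um is required", call. = FALSE)
    }
    if (is.null(config)) config <- species_config(species)
    follicle_class <- most_advanced_class(diameters_um, health, config)
  }
  follicle_class <- as.character(follicle_class)
  if (follicle_class == "F5" && species != "rat") {
    stop("follicle_class: F5 is valid only for rat", call. = FALSE)
  }
  oocyte_location <- match.arg(oocyte_location, .pub_enums$oocyte)
  if (oocyte_location %in% c("uterotubal_junction", "uterine") &&
      species != "mouse") {
    stop("oocyte_location: '", oocyte_location,
         "' is expected only in mouse", call. = FALSE)
  }
  if (!all(vapply(cl_generations, inherits, NA, "pubscore_cl_features"))) {
    stop("cl_generations: must be a list of cl_features() objects",
         call. = FALSE)
  }
  if (any(vapply(cl_generations,
                 function(g) identical(g$generation, "R2"), NA)) &&
      species != "rat") {
    stop("cl_generations: generation R2 is valid only for rat", call. = FALSE)
  }
  obs <- list(
    animal_id = as.character(animal_id),
    species = species,
    age_pnd = age_pnd,
    follicle_class = follicle_class,
    cl_generations = cl_generations,
    oocyte_location = oocyte_location,
    vo_age_pnd = as.integer(vo_age_pnd)
  )
  class(obs) <- "pubscore_observation"
  obs
}

#' @export
print.pubscore_observation <- function(x, ...) {
  cat("Ovarian observation", x$animal_id, "(", x$species, ", PND-",
      x$age_pnd, ")\n", sep = "")
  cat("  most advanced healthy follicle class:", x$follicle_class, "\n")
  if (length(x$cl_generations) == 0L) {
    cat("  corpora lutea: none (pre-ovulatory)\n")
  } else {
    cat("  corpora lutea:", length(x$cl_generations), "generation(s)\n")
  }
  cat("  oocytes:", x$oocyte_location, "\n")
  invisible(x)
}
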