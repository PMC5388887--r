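# CSV surface. Observation tables are UTF-8, comma-separated, with a
# mandatory header:
#   animal_id, species, age_pnd, vo_age_pnd, follicle_class,
#   diameters_um, health, cl_generations, oocyte_location
# follicle_class may be empty when diameters_um ("260|320|410") and
# health ("healthy|healthy|atretic") are given. cl_generations packs the
# CL generations as semicolon-separated records of colon-separated fields
#   generation:luteinization:mitoses:apoptosis:vascular:rupture:fibrous:grade
# with logicals as 0/1 and missing generation/grade as "NA"; an empty
# string means no corpora lutea (pre-ovulatory animal).

.cl_field_order <- c("generation", "luteinization", "mitoses", "apoptosis",
                     "vascular_pattern", "rupture_site", "fibrous_center",
                     "stromal_ratio_grade")

serialize_cl <- function(cl_generations) {
  if (length(cl_generations) == 0L) return("")
  paste(vapply(cl_generations, function(g) {
    paste(c(if (is.na(g$generation)) "NA" else g$generation,
            g$luteinization, g$mitoses, g$apoptosis,
            as.integer(g$vascular_pattern), as.integer(g$rupture_site),
            as.integer(g$fibrous_center),
            if (is.na(g$stromal_ratio_grade)) "NA"
            else g$stromal_ratio_grade),
          collapse = ":")
  }, ""), collapse = ";")
}

parse_cl <- function(txt) {
  txt <- trimws(txt)
  if (is.na(txt) || txt == "") return(list())
  lapply(strsplit(txt, ";", fixed = TRUE)[[1]], function(rec) {
    f <- strsplit(rec, ":", fixed = TRUE)[[1]]
    if (length(f) != length(.cl_field_order)) {
      stop("cl_generations record '", rec, "' must have ",
           length(.cl_field_order), " colon-separated fields", call. = FALSE)
    }
    cl_features(
      generation = if (f[1] == "NA") NA_character_ else f[1],
      luteinization = f[2], mitoses = f[3], apoptosis = f[4],
      vascular_pattern = f[5] == "1", rupture_site = f[6] == "1",
      fibrous_center = f[7] == "1",
      stromal_ratio_grade = if (f[8] == "NA") NA_integer_
                            else as.integer(f[8])
    )
  })
}

#' Read an observation table
#'
#' Reads and validates a CSV of coded ovarian observations (schema in the
#' package README). Row-level problems are collected with their line
#' numbers and reported together; with `lenient = TRUE` offending rows are
#' dropped with a warning instead.
#'
#' @param path CSV file path.
#' @param config A `pubscore_species_config`; every row must match its
#'   species.
#' @param lenient Drop bad rows with a warning instead of erroring.
#' @return A list of [ovary_observation()] objects (empty, with a warning,
#'   for an empty file).
#' @export
read_observations <- function(path, config, lenient = FALSE) {
  stopifnot(inherits(config, "pubscore_species_config"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("animal_id", "species", "age_pnd", "oocyte_location")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("observation file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!("follicle_class" %in% names(df)) &&
      !("diameters_um" %in% names(df))) {
    stop("observation file needs a follicle_class or diameters_um column",
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty observation file: ", path)
    return(list())
  }
  getcol <- function(i, col) {
    if (!col %in% names(df)) return(NA_character_)
    v <- trimws(df[[col]][i])
    if (is.na(v) || v == "") NA_character_ else v
  }
  obs <- vector("list", nrow(df))
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    row_obs <- tryCatch({
      fcl <- getcol(i, "follicle_class")
      diam <- getcol(i, "diameters_um")
      if (is.na(fcl) && !is.na(diam)) {
        d <- as.numeric(strsplit(diam, "|", fixed = TRUE)[[1]])
        h <- getcol(i, "health")
        h <- if (is.na(h)) NULL else strsplit(h, "|", fixed = TRUE)[[1]]
        fcl <- most_advanced_class(d, h, config)
      }
      sp <- getcol(i, "species")
      if (!identical(sp, config$species)) {
        stop("species '", sp, "' does not match config species '",
             config$species, "'", call. = FALSE)
      }
      vo <- getcol(i, "vo_age_pnd")
      ovary_observation(
        animal_id = getcol(i, "animal_id"),
        species = sp,
        age_pnd = as.integer(getcol(i, "age_pnd")),
        follicle_class = fcl,
        cl_generations = parse_cl(getcol(i, "cl_generations")),
        oocyte_location = getcol(i, "oocyte_location"),
        vo_age_pnd = if (is.na(vo)) NA_integer_ else as.integer(vo)
      )
    }, error = function(e) {
      errors <<- c(errors,
                   sprintf("row %d: %s", i, conditionMessage(e)))
      NULL
    })
    obs[[i]] <- row_obs
  }
  if (length(errors)) {
    msg <- paste0("invalid observation row(s) in ", path, ":\n  ",
                  paste(errors, collapse = "\n  "))
    if (lenient) warning(msg) else stop(msg, call. = FALSE)
  }
  Filter(Negate(is.null), obs)
}

#' Write an observation table
#'
#' Inverse of [read_observations()]: writing then re-reading reproduces the
#' same observations.
#'
#' @param observations List of [ovary_observation()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  df <- do.call(rbind, lapply(observations, function(o) {
    data.frame(animal_id = o$animal_id, species = o$species,
               age_pnd = o$age_pnd,
               vo_age_pnd = o$vo_age_pnd,
               follicle_class = o$follicle_class,
               cl_generations = serialize_cl(o$cl_generations),
               oocyte_location = o$oocyte_location,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read scored result tables
#'
#' Scored tables (from [score_observations()]) round-trip through CSV with
#' the evidence trail preserved in the final column.
#'
#' @param scored Data frame from [score_observations()].
#' @param path CSV path.
#' @return `path` (write) or the scored data frame (read).
#' @export
write_scored <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scored
#' @export
read_scored <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("animal_id", "species", "age_pnd", "vo_age_pnd", "score",
              "status", "estimated_fo_age_pnd", "evidence")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("scored file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write simulated trajectories
#'
#' @param trajectories Output of [simulate_cohort()].
#' @param path CSV path.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(as.data.frame(trajectories), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
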