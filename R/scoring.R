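#' Assign a Pub-score to an ovarian observation
#'
#' The Pub-score stages peripubertal ovarian maturation on an integer scale
#' with no zero: negative scores (-5 to -1) grade pre-ovulatory antral
#' follicle development in animals without corpora lutea, and positive
#' scores count days elapsed since the first ovulation in ovulating ones.
#'
#' For an ovulating animal the score is `4 * g + d`, where `d` in 1..4 is
#' the age of the current-cycle CL (from [date_current_cl()]) and `g` is
#' the number of regressing CL generations (from
#' [count_regressing_generations()]); this closed form is equivalent to
#' traversing the species staging flowchart. The ceiling is +12 in the rat
#' (two identifiable regressing generations) and +8 in the mouse, whose
#' regressing CL are eliminated within one cycle. An animal past the
#' ceiling is reported `censored` at the ceiling score — the score then
#' represents the minimum elapsed time since ovulation — and is never
#' assigned a first-ovulation date. Conflicting CL features yield status
#' `inconsistent` with the best-supported day and a conflict report.
#'
#' @param obs A [ovary_observation()].
#' @param config Matching `pubscore_species_config`.
#' @return A `pubscore_result` with fields `score`, `status`
#'   (`"prepubertal"`, `"ovulating"`, `"censored"` or `"inconsistent"`),
#'   `estimated_fo_age_pnd` (PND of first ovulation; `NA` unless
#'   ovulating) and `evidence` (character vector of fired rules).
#' @examples
#' cfg <- species_config("rat")
#' obs <- ovary_observation(
#'   "r1", "rat", age_pnd = 40, follicle_class = "F3",
#'   cl_generations = list(
#'     cl_features("current", luteinization = "partial",
#'                 mitoses = "abundant", vascular_pattern = TRUE),
#'     cl_features("R1", stromal_ratio_grade = 1L)),
#'   oocyte_location = "isthmus_nude")
#' assign_pubscore(obs, cfg)  # +6, first ovulation PND-35
#' @export
assign_pubscore <- function(obs, config) {
  stopifnot(inherits(obs, "pubscore_observation"),
            inherits(config, "pubscore_species_config"))
  if (obs$species != config$species) {
    stop("species mismatch: observation is ", obs$species,
         ", config is ", config$species, call. = FALSE)
  }

  if (length(obs$cl_generations) == 0L) {
    fc <- config$follicle_classes
    score <- fc$score[match(obs$follicle_class, fc$label)]
    if (is.na(score)) {
      stop("follicle_class: unknown class '", obs$follicle_class, "'",
           call. = FALSE)
    }
    evidence <- paste0("no_cl;follicle_", obs$follicle_class)
    if (obs$follicle_class == "SF" && config$species == "rat") {
      evidence <- paste0(evidence, ";below_F1")
    }
    return(new_pubscore_result(obs, score, "prepubertal", NA_integer_,
                               strsplit(evidence, ";")[[1]]))
  }

  gen <- count_regressing_generations(obs$cl_generations, config)
  if (gen$censored) {
    return(new_pubscore_result(
      obs, config$max_score, "censored", NA_integer_,
      c(sprintf("regressing_generations_exceed_cap_%d",
                config$max_regressing_generations),
        "score_is_minimum_elapsed_time")))
  }

  current <- obs$cl_generations[[gen$current_index]]
  dated <- date_current_cl(current, obs$follicle_class,
                           obs$oocyte_location, config)
  score <- 4L * gen$g + dated$day
  evidence <- c(sprintf("regressing_generations_%d", gen$g),
                sprintf("current_cl_day_%d", dated$day),
                dated$evidence)
  if (dated$inconsistent) {
    return(new_pubscore_result(obs, score, "inconsistent", NA_integer_,
                               c(evidence,
                                 paste0("conflict:", dated$conflicts))))
  }
  fo <- estimate_first_ovulation_age(obs$age_pnd, score)
  new_pubscore_result(obs, score, "ovulating", fo, evidence)
}

new_pubscore_result <- function(obs, score, status, fo, evidence) {
  stopifnot(score != 0L)
  res <- list(
    animal_id = obs$animal_id,
    species = obs$species,
    age_pnd = obs$age_pnd,
    vo_age_pnd = obs$vo_age_pnd,
    score = as.integer(score),
    status = status,
    estimated_fo_age_pnd = as.integer(fo),
    evidence = evidence
  )
  class(res) <- "pubscore_result"
  res
}

#' Retrodate the first ovulation from a Pub-score
#'
#' For an ovulating animal, the day of the first ovulation is recovered as
#' `age_pnd - score + 1`: a score of +1 means the animal was sacrificed on
#' the day of its first ovulation.
#'
#' @param age_pnd Age at sacrifice (postnatal days).
#' @param score Positive Pub-score (>= +1) of a non-censored, ovulating
#'   animal.
#' @return Estimated age at first ovulation (PND, integer).
#' @examples
#' estimate_first_ovulation_age(40, 6)  # 35
#' estimate_first_ovulation_age(42, 4)  # 39
#' @export
estimate_first_ovulation_age <- function(age_pnd, score) {
  age_pnd <- as.integer(age_pnd)
  score <- as.integer(score)
  if (any(is.na(score)) || any(score < 1L)) {
    stop("score must be >= +1: animal has not yet ovulated or is outside ",
         "the dating window", call. = FALSE)
  }
  age_pnd - score + 1L
}

#' @export
print.pubscore_result <- function(x, ...) {
  cat("Pub-score for animal ", x$animal_id, " (", x$species, ", PND-",
      x$age_pnd, ")\n", sep = "")
  cat("  score: ", if (x$score > 0) "+" else "", x$score,
      "  status: ", x$status, "\n", sep = "")
  if (x$status == "ovulating") {
    cat("  estimated first ovulation: PND-", x$estimated_fo_age_pnd, "\n",
        sep = "")
  } else if (x$status == "censored") {
    cat("  >= ", x$score, " days since first ovulation (censored)\n",
        sep = "")
  }
  cat("  evidence:", paste(x$evidence, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pubscore_result <- function(x, ...) {
  data.frame(animal_id = x$animal_id, species = x$species,
             age_pnd = x$age_pnd, vo_age_pnd = x$vo_age_pnd,
             score = x$score, status = x$status,
             estimated_fo_age_pnd = x$estimated_fo_age_pnd,
             evidence = paste(x$evidence, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Score a list of observations into a table
#'
#' Applies [assign_pubscore()] to each observation and binds the results
#' into a data frame, one row per animal, with the evidence trail kept in
#' the final column for auditability.
#'
#' @param observations List of [ovary_observation()] objects.
#' @inheritParams assign_pubscore
#' @return A data frame with columns `animal_id`, `species`, `age_pnd`,
#'   `vo_age_pnd`, `score`, `status`, `estimated_fo_age_pnd`, `evidence`.
#' @export
score_observations <- function(observations, config) {
  rows <- lapply(observations, function(o) {
    as.data.frame(assign_pubscore(o, config))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
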