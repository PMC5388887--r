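#' Student-t confidence interval for a mean
#'
#' Two-sided confidence interval `mean +/- t(df = n-1, (1+level)/2) * sd /
#' sqrt(n)`, appropriate for the small group sizes (n < 30) typical of
#' peripubertal cohorts.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Sample size (>= 2).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric `c(lo, hi)`.
#' @examples
#' t_confidence_interval(440.5, 24.7, 18)  # lower bound 428.2
#' @export
t_confidence_interval <- function(mean, sd, n, level = 0.95) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  if (is.na(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  half <- stats::qt((1 + level) / 2, df = n - 1L) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' Squared Pearson correlation with p-value
#'
#' Coefficient of determination (R squared) between two paired samples and
#' the two-sided p-value from the t-transform of r, as used to relate the
#' recorded age at vaginal opening to the retrodated age at first
#' ovulation.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A list with `r2` and `p`.
#' @export
pearson_r2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r2 = unname(ct$estimate)^2, p = ct$p.value)
}

#' Summarize a scored cohort
#'
#' Builds the standard validation summary from a table of scored animals:
#' mean, SD and Student-t confidence intervals for the age at vaginal
#' opening (VO), the retrodated age at first ovulation (FO) and the time
#' elapsed between them, plus the coefficient of determination (R squared)
#' between VO and FO. Only ovulating animals with a recorded VO age enter
#' the FO statistics; censored, prepubertal and inconsistent animals are
#' excluded with a logged count and reported through the ovulating
#' proportion.
#'
#' @param scored Data frame as produced by [score_observations()] (columns
#'   `vo_age_pnd`, `score`, `status`, `estimated_fo_age_pnd`).
#' @param level Confidence level; default 0.95.
#' @return A `pubscore_cohort_summary` object.
#' @export
summarize_cohort <- function(scored, level = 0.95) {
  stopifnot(is.data.frame(scored))
  needed <- c("vo_age_pnd", "score", "status", "estimated_fo_age_pnd")
  missing <- setdiff(needed, names(scored))
  if (length(missing)) {
    stop("scored table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_total <- nrow(scored)
  excluded <- table(scored$status[scored$status != "ovulating"])
  use <- scored$status == "ovulating" & !is.na(scored$vo_age_pnd)
  n_no_vo <- sum(scored$status == "ovulating" & is.na(scored$vo_age_pnd))
  dat <- scored[use, , drop = FALSE]
  if (sum(use) < n_total) {
    message(sprintf(
      "summarize_cohort: excluded %d of %d animals (%s)",
      n_total - sum(use), n_total,
      paste(c(sprintf("%s: %d", names(excluded), as.integer(excluded)),
              if (n_no_vo) sprintf("no VO age: %d", n_no_vo)),
            collapse = ", ")))
  }
  n <- nrow(dat)
  if (n < 3L) {
    stop("fewer than 3 usable (ovulating, VO-recorded) animals", call. = FALSE)
  }
  vo <- dat$vo_age_pnd
  fo <- dat$estimated_fo_age_pnd
  elapsed <- fo - vo
  stat <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    list(mean = m, sd = s, ci = t_confidence_interval(m, s, n, level))
  }
  r2 <- pearson_r2(vo, fo)
  out <- list(
    species = if ("species" %in% names(scored)) scored$species[1] else NA,
    n = n,
    n_total = n_total,
    prop_ovulating = sum(scored$status %in% c("ovulating", "censored")) /
      n_total,
    excluded = as.list(excluded),
    level = level,
    vo = stat(vo), fo = stat(fo), elapsed = stat(elapsed),
    r2 = r2$r2, p_value = r2$p
  )
  class(out) <- "pubscore_cohort_summary"
  out
}

#' @export
print.pubscore_cohort_summary <- function(x, digits = 1, ...) {
  fmt <- function(s) {
    sprintf("%.*f ± %.*f (%.*f–%.*f)", digits, s$mean, digits, s$sd,
            digits, s$ci[1], digits, s$ci[2])
  }
  cat("Cohort summary (", x$n, " ovulating of ", x$n_total, " animals, ",
      round(100 * x$level), "% CI)\n", sep = "")
  cat("  VO age (PND):     ", fmt(x$vo), "\n")
  cat("  FO age (PND):     ", fmt(x$fo), "\n")
  cat("  elapsed (days):   ", fmt(x$elapsed), "\n")
  cat(sprintf("  R2 (VO vs FO):     %.2f (p = %.3g)\n", x$r2, x$p_value))
  cat(sprintf("  ovulating or censored proportion: %.2f\n",
              x$prop_ovulating))
  invisible(x)
}

#' @export
as.data.frame.pubscore_cohort_summary <- function(x, ...) {
  data.frame(
    species = x$species, n = x$n, n_total = x$n_total,
    prop_ovulating = x$prop_ovulating, ci_level = x$level,
    vo_mean = x$vo$mean, vo_sd = x$vo$sd,
    vo_ci_lo = x$vo$ci[1], vo_ci_hi = x$vo$ci[2],
    fo_mean = x$fo$mean, fo_sd = x$fo$sd,
    fo_ci_lo = x$fo$ci[1], fo_ci_hi = x$fo$ci[2],
    elapsed_mean = x$elapsed$mean, elapsed_sd = x$elapsed$sd,
    elapsed_ci_lo = x$elapsed$ci[1], elapsed_ci_hi = x$elapsed$ci[2],
    r2 = x$r2, p_value = x$p_value,
    stringsAsFactors = FALSE
  )
}
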