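# Effect-size harmonization: convert raw per-study statistics into
# small-sample-corrected standardized mean differences (Hedges' g).

#' Paradigms handled by the harmonizer
#'
#' Outcome paradigms fall into two families: chance-comparison paradigms,
#' scored as a one-sample difference from chance, and paired-contrast
#' paradigms, scored as a standardized difference between grammatical and
#' ungrammatical presentations.
#'
#' @format A data frame with one row per paradigm and columns:
#' \describe{
#'   \item{paradigm}{paradigm label used in coding sheets}
#'   \item{family}{"chance" or "paired"}
#'   \item{direction}{+1 if a larger grammatical-condition value indicates
#'     learning, -1 otherwise. For serial reaction time, learning means
#'     \emph{faster} (smaller RT) responses to the trained structure; for
#'     looking time, learning means \emph{longer} looking at the
#'     ungrammatical (novel) stimuli. Re-signing of familiarity-interpreted
#'     effects is handled separately by the \code{familiarity_resign} flag.}
#' }
#' @seealso [harmonize()]
#' @export
agl_paradigms <- data.frame(
  paradigm = c("accuracy_vs_chance", "go_nogo", "yes_no", "scale_judgement",
               "forced_choice", "head_turn", "frequency_estimation",
               "serial_reaction_time", "sequence_production", "looking_time"),
  family = c(rep("chance", 7), rep("paired", 3)),
  direction = c(rep(1, 7), -1, 1, -1),
  stringsAsFactors = FALSE
)

paradigm_family <- function(paradigm) {
  i <- match(paradigm, agl_paradigms$paradigm)
  if (is.na(i)) {
    stop("unsupported paradigm: '", paradigm, "'. Known paradigms: ",
         paste(agl_paradigms$paradigm, collapse = ", "), call. = FALSE)
  }
  agl_paradigms[i, ]
}

#' Small-sample correction factor J
#'
#' Hedges' correction for the positive bias of Cohen's d in small samples:
#' \eqn{J = 1 - 3 / (4\,df - 1)}.
#'
#' @param df Degrees of freedom (>= 1); `n - 1` for the one-sample and
#'   paired designs used here.
#' @return J in \[0, 1); exactly 0 at `df = 1`, approaching 1 as `df` grows.
#' @examples
#' correction_factor(19)  # 0.96
#' @export
correction_factor <- function(df) {
  if (!is.numeric(df) || any(!is.finite(df)) || any(df < 1)) {
    stop("df must be a finite number >= 1", call. = FALSE)
  }
  1 - 3 / (4 * df - 1)
}

#' Cohen's d for a one-sample comparison to chance
#'
#' @param mean Observed outcome mean (e.g. proportion correct).
#' @param chance Chance-level value on the same scale.
#' @param sd_within Within-group standard deviation (> 0).
#' @return Cohen's d = (mean - chance) / sd_within.
#' @export
one_sample_d <- function(mean, chance, sd_within) {
  if (!is.numeric(sd_within) || !is.finite(sd_within) || sd_within <= 0) {
    stop("sd_within must be a positive finite number", call. = FALSE)
  }
  (mean - chance) / sd_within
}

#' Cohen's d for a paired grammatical vs ungrammatical contrast
#'
#' Standardized mean difference between grammatical and ungrammatical
#' presentations, signed so that a positive d always means a
#' structure-conforming advantage: for reaction times, faster responses to
#' the trained structure; for looking time, longer looking at ungrammatical
#' (violating) stimuli; for sequence production, higher accuracy on
#' grammatical sequences.
#'
#' @param mean_grammatical,mean_ungrammatical Condition means (pooled across
#'   sessions where applicable).
#' @param sd_average Average SD across the contributing sessions
#'   (see [average_sd()]); must be > 0.
#' @param direction +1 if larger grammatical values indicate learning,
#'   -1 otherwise (see [agl_paradigms]).
#' @return Signed Cohen's d.
#' @export
paired_difference_d <- function(mean_grammatical, mean_ungrammatical,
                                sd_average, direction = 1) {
  if (!is.numeric(sd_average) || !is.finite(sd_average) || sd_average <= 0) {
    stop("sd_average must be a positive finite number", call. = FALSE)
  }
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1", call. = FALSE)
  direction * (mean_grammatical - mean_ungrammatical) / sd_average
}

#' Hedges' g from Cohen's d
#'
#' @param d Cohen's d.
#' @param df Degrees of freedom for the correction factor.
#' @return g = J(df) * d.
#' @export
hedges_g <- function(d, df) {
  correction_factor(df) * d
}

#' Sampling variance of Hedges' g
#'
#' Borenstein-convention variance of the corrected standardized mean
#' difference: \eqn{V_g = (1/n + d^2 / (2n)) \, J^2}. For paired designs the
#' same form is used with the participant count, a conservative treatment
#' equivalent to assuming a correlation of 1 between conditions.
#'
#' @param d Cohen's d (uncorrected).
#' @param n Total participants (>= 1).
#' @param df Degrees of freedom for J.
#' @return Sampling variance of g (>= 0).
#' @export
variance_g <- function(d, n, df) {
  if (!is.numeric(n) || !is.finite(n) || n < 1) {
    stop("n must be a finite number >= 1", call. = FALSE)
  }
  (1 / n + d^2 / (2 * n)) * correction_factor(df)^2
}

#' Participant-weighted pooled mean across test sessions
#'
#' @param means Session means.
#' @param ns Session participant counts.
#' @return Weighted mean, sum(n * mean) / sum(n).
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) == 0) stop("at least one session is required", call. = FALSE)
  if (length(means) != length(ns)) stop("means and ns differ in length", call. = FALSE)
  sum(ns * means) / sum(ns)
}

#' Average SD across test sessions
#'
#' Pools session standard deviations with degrees-of-freedom weights:
#' \eqn{\sqrt{\sum (n_i - 1) SD_i^2 / \sum (n_i - 1)}}, for any number of
#' sessions.
#'
#' @param sds Session standard deviations.
#' @param ns Session participant counts (each >= 2 unless several sessions
#'   share participants and at least one has n >= 2).
#' @return Pooled SD, lying between min(sds) and max(sds).
#' @export
average_sd <- function(sds, ns) {
  if (length(sds) == 0) stop("at least one session is required", call. = FALSE)
  if (length(sds) != length(ns)) stop("sds and ns differ in length", call. = FALSE)
  denom <- sum(ns - 1)
  if (denom <= 0) stop("all sessions have n = 1; pooled SD undefined", call. = FALSE)
  sqrt(sum((ns - 1) * sds^2) / denom)
}

#' Convert a reported confidence interval to a standard deviation
#'
#' Assumes the interval was built from the t distribution:
#' \eqn{SD = \sqrt{n} (upper - lower) / (2\, t_{crit})} with
#' \eqn{t_{crit}} the two-sided critical value on n - 1 df.
#'
#' @param n Sample size (>= 2).
#' @param upper,lower Interval limits, `upper > lower`.
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @return Implied standard deviation.
#' @export
ci_to_sd <- function(n, upper, lower, ci_level = 0.95) {
  if (!is.finite(n) || n < 2) stop("n must be >= 2 to invert a t interval", call. = FALSE)
  if (!(upper > lower)) stop("upper must exceed lower", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)", call. = FALSE)
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  sqrt(n) * (upper - lower) / (2 * tcrit)
}

#' Construct a raw study record
#'
#' One test outcome from one study, prior to harmonization. Chance-comparison
#' paradigms carry grammatical-condition sessions plus a chance level;
#' paired paradigms carry both grammatical and ungrammatical sessions.
#' Sessions reported as a mean with confidence-interval limits instead of an
#' SD are converted at ingest via [ci_to_sd()].
#'
#' @param paradigm One of `agl_paradigms$paradigm`.
#' @param grammatical Data frame of sessions with columns `mean`, `n`, and
#'   either `sd` or (`ci_lower`, `ci_upper`).
#' @param ungrammatical Same layout, required for paired paradigms.
#' @param chance Chance level, required for chance-comparison paradigms.
#' @param ci_level Confidence level of any reported intervals.
#' @param familiarity_resign Set when the original authors interpreted a
#'   grammatical-stimulus (familiarity) preference as learning; the
#'   harmonized effect is re-signed so that positive still means learning.
#' @param article_id,study_id Optional identifiers carried through.
#' @param moderators Optional named list of moderator codes carried through.
#' @return An object of class `raw_study`.
#' @export
raw_study <- function(paradigm, grammatical, ungrammatical = NULL,
                      chance = NULL, ci_level = 0.95,
                      familiarity_resign = FALSE,
                      article_id = NA_character_, study_id = NA_character_,
                      moderators = list()) {
  fam <- paradigm_family(paradigm)$family
  grammatical <- validate_sessions(grammatical, "grammatical", ci_level)
  if (fam == "chance") {
    if (is.null(chance) || !is.finite(chance)) {
      stop("paradigm '", paradigm, "' compares to chance; 'chance' is required",
           call. = FALSE)
    }
    if (!is.null(ungrammatical) && nrow(ungrammatical) > 0) {
      stop("chance-comparison paradigms take no ungrammatical sessions",
           call. = FALSE)
    }
    ungrammatical <- NULL
  } else {
    if (is.null(ungrammatical) || nrow(ungrammatical) == 0) {
      stop("paradigm '", paradigm, "' requires ungrammatical sessions",
           call. = FALSE)
    }
    ungrammatical <- validate_sessions(ungrammatical, "ungrammatical", ci_level)
    chance <- NULL
  }
  structure(
    list(paradigm = paradigm, grammatical = grammatical,
         ungrammatical = ungrammatical, chance = chance,
         ci_level = ci_level,
         familiarity_resign = isTRUE(familiarity_resign),
         article_id = article_id, study_id = study_id,
         moderators = moderators),
    class = "raw_study"
  )
}

# Checks session table consistency and fills missing SDs from CI limits.
validate_sessions <- function(sessions, label, ci_level) {
  sessions <- as.data.frame(sessions)
  missing <- setdiff(c("mean", "n"), names(sessions))
  if (length(missing) > 0) {
    stop(label, " sessions lack required fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"sd" %in% names(sessions)) sessions$sd <- NA_real_
  if (any(sessions$n < 1)) stop(label, " sessions must have n >= 1", call. = FALSE)
  need_ci <- is.na(sessions$sd)
  if (any(need_ci)) {
    if (!all(c("ci_lower", "ci_upper") %in% names(sessions))) {
      stop(label, " sessions missing SD must report ci_lower and ci_upper",
           call. = FALSE)
    }
    for (i in which(need_ci)) {
      sessions$sd[i] <- ci_to_sd(sessions$n[i], sessions$ci_upper[i],
                                 sessions$ci_lower[i], ci_level)
    }
  }
  if (any(sessions$sd < 0)) stop(label, " sessions must have sd >= 0", call. = FALSE)
  sessions
}

# Proportions occasionally arrive on the 0-100 scale; detect by the chance
# value and renormalize to 0-1. g is scale-invariant, so this only keeps the
# stored summaries on one scale.
normalize_scale <- function(record) {
  if (!is.null(record$chance) && record$chance > 1) {
    record$chance <- record$chance / 100
    record$grammatical$mean <- record$grammatical$mean / 100
    record$grammatical$sd <- record$grammatical$sd / 100
  }
  record
}

#' Harmonize one raw study record into a Hedges' g effect size
#'
#' Routes the record by paradigm: chance-comparison outcomes (accuracy,
#' endorsement, go/no-go, scale judgement, forced choice, head turn,
#' frequency estimation) are scored as the one-sample difference from chance
#' after participant-weighted pooling of sessions; paired outcomes (serial
#' reaction time, sequence production, looking time) as the standardized
#' grammatical-ungrammatical difference with the paradigm's sign convention.
#' The small-sample correction J and the sampling variance use df = n - 1.
#' Effects flagged `familiarity_resign` are negated so that a positive g
#' always indicates learning.
#'
#' @param record A [raw_study()] object.
#' @return A list of class `effect_size` with elements `d`, `g`, `v_g`,
#'   `df`, `n`, plus the record's identifiers and moderators.
#' @export
harmonize <- function(record) {
  if (!inherits(record, "raw_study")) {
    stop("record must be built with raw_study()", call. = FALSE)
  }
  record <- normalize_scale(record)
  fam <- paradigm_family(record$paradigm)
  gs <- record$grammatical
  if (fam$family == "chance") {
    m <- pooled_mean(gs$mean, gs$n)
    s <- average_sd(gs$sd, gs$n)
    d <- one_sample_d(m, record$chance, s)
    n <- sum(gs$n)
  } else {
    us <- record$ungrammatical
    m_g <- pooled_mean(gs$mean, gs$n)
    m_u <- pooled_mean(us$mean, us$n)
    s <- average_sd(c(gs$sd, us$sd), c(gs$n, us$n))
    d <- paired_difference_d(m_g, m_u, s, direction = fam$direction)
    # Same participants contribute to every session/block of a paired design.
    n <- max(c(gs$n, us$n))
  }
  df <- n - 1
  if (df < 1) stop("effect has n < 2; J and v_g are undefined", call. = FALSE)
  g <- hedges_g(d, df)
  v <- variance_g(d, n, df)
  if (record$familiarity_resign) g <- -g
  structure(
    list(d = d, g = g, v_g = v, df = df, n = n,
         paradigm = record$paradigm,
         article_id = record$article_id, study_id = record$study_id,
         moderators = record$moderators),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Harmonized effect (%s): g = %.4f, v_g = %.5f, n = %d\n",
              x$paradigm, x$g, x$v_g, as.integer(x$n)))
  invisible(x)
}

#' Harmonize a list of raw study records into an effect table
#'
#' @param records List of [raw_study()] objects.
#' @return A data frame with one row per effect: `article_id`, `study_id`,
#'   `paradigm`, `g`, `v_g`, `n`, plus one column per moderator present.
#' @export
harmonize_records <- function(records) {
  effects <- lapply(records, harmonize)
  base <- do.call(rbind, lapply(effects, function(e) {
    data.frame(article_id = e$article_id, study_id = e$study_id,
               paradigm = e$paradigm, g = e$g, v_g = e$v_g, n = e$n,
               stringsAsFactors = FALSE)
  }))
  mods <- unique(unlist(lapply(effects, function(e) names(e$moderators))))
  for (m in mods) {
    base[[m]] <- sapply(effects, function(e) {
      v <- e$moderators[[m]]
      if (is.null(v)) NA else v
    })
  }
  base
}
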