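# Synthetic coding-sheet generator. Emulates the statistical structure the
# analysis assumes -- effects nested in articles with two variance
# components, sampling variances derived from n, a realistic moderator
# layout, and paradigm-appropriate raw summary statistics -- so every
# pipeline stage is testable without external data.

#' Moderator columns of the standard coding sheet
#' @export
agl_moderators <- c(
  "animal_species", "animal_class", "human_vs_nonhuman", "stimulus_modality",
  "test_response", "test_type", "log_training_length",
  "categories_in_language", "vocabulary_size", "repetition_of_items",
  "adjacent_dependencies", "nonadjacent_dependencies"
)

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the scale of a typical comparative AGL literature:
#' about 66 articles contributing 1-4 effects each (~160 effects), a true
#' overall effect of 1 standard deviation, substantial heterogeneity at both
#' nesting levels, per-study sample sizes of 10-40 participants for humans
#' and 4-12 subjects for non-human animals, and an animal-class mix dominated
#' by human adults with a sizeable bird literature.
#'
#' @param n_articles Number of articles.
#' @param effects_per_article Either one integer (fixed) or a length-2 range
#'   sampled uniformly per article.
#' @param mu True overall effect (Hedges' g units).
#' @param tau2_article Between-article variance component.
#' @param tau2_study Within-article between-effect variance component.
#' @param moderator_effects Named list of true moderator coefficients. Names
#'   are either a continuous moderator column (e.g. `log_training_length`), a
#'   binary moderator column (coefficient applies when the level is
#'   "present"), or `"column=level"` for one level of a categorical moderator.
#' @param n_range_human,n_range_nonhuman Per-study participant-count ranges.
#' @param class_probs Named probabilities over animal classes
#'   (human_adult, human_child, nonhuman_mammal, bird); must sum to 1.
#' @param paradigm_mix Named probabilities over paradigms (see
#'   [agl_paradigms]); must sum to 1.
#' @param prop_multisession Fraction of chance-paradigm records reported as
#'   two pooled test sessions.
#' @param prop_ci_only Fraction of records reporting a 95% CI instead of an SD.
#' @param prop_resign Fraction of looking-time records with a
#'   familiarity-preference interpretation (re-signed at harmonization).
#' @param selection_bias Optional retention rule, a function of (g, se)
#'   returning a retention probability, applied by [apply_selection_bias()].
#' @param seed RNG seed used by the simulators.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_articles = 66,
                             effects_per_article = c(1, 4),
                             mu = 1.0,
                             tau2_article = 0.5,
                             tau2_study = 0.25,
                             moderator_effects = list(),
                             n_range_human = c(10, 40),
                             n_range_nonhuman = c(4, 12),
                             class_probs = c(human_adult = 0.64,
                                             human_child = 0.07,
                                             nonhuman_mammal = 0.05,
                                             bird = 0.24),
                             paradigm_mix = c(forced_choice = 0.40,
                                              yes_no = 0.15,
                                              go_nogo = 0.12,
                                              scale_judgement = 0.05,
                                              accuracy_vs_chance = 0.08,
                                              head_turn = 0.05,
                                              looking_time = 0.05,
                                              serial_reaction_time = 0.05,
                                              sequence_production = 0.03,
                                              frequency_estimation = 0.02),
                             prop_multisession = 0.3,
                             prop_ci_only = 0.2,
                             prop_resign = 0.5,
                             selection_bias = NULL,
                             seed = 1L) {
  stopifnot(n_articles >= 1,
            length(effects_per_article) %in% c(1, 2),
            tau2_article >= 0, tau2_study >= 0)
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1", call. = FALSE)
  if (abs(sum(paradigm_mix) - 1) > 1e-8) stop("paradigm_mix must sum to 1", call. = FALSE)
  if (!all(names(paradigm_mix) %in% agl_paradigms$paradigm)) {
    stop("paradigm_mix names unknown paradigms", call. = FALSE)
  }
  for (rng in list(n_range_human, n_range_nonhuman)) {
    if (length(rng) != 2 || rng[1] < 2 || rng[2] > 1e4 || rng[1] > rng[2]) {
      stop("participant-count ranges must lie within [2, 10000]", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "synthetic_config")
}

reflection_paradigms <- c("forced_choice", "yes_no", "go_nogo",
                          "scale_judgement", "frequency_estimation",
                          "accuracy_vs_chance")

species_pool <- list(
  human_adult = "human",
  human_child = "human",
  nonhuman_mammal = c("cotton_top_tamarin", "rat", "squirrel_monkey"),
  bird = c("zebra_finch", "budgerigar", "pigeon")
)

# True linear predictor contribution of the configured moderator effects.
moderator_contribution <- function(effects, row) {
  if (length(effects) == 0) return(0)
  total <- 0
  for (nm in names(effects)) {
    coef <- effects[[nm]]
    if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      total <- total + coef * as.numeric(identical(as.character(row[[parts[1]]]),
                                                   parts[2]))
    } else if (is.numeric(row[[nm]])) {
      total <- total + coef * row[[nm]]
    } else {
      total <- total + coef * as.numeric(identical(as.character(row[[nm]]),
                                                   "present"))
    }
  }
  total
}

#' Simulate a harmonized effect table from the nested generative model
#'
#' Draws article effects u_i ~ N(0, tau2_article), effect-level deviations
#' w_ij ~ N(0, tau2_study), and observed effects
#' g_ij = mu + x_ij' beta + u_i + w_ij + e_ij with sampling error variance
#' v_ij = 1/n_ij + theta_ij^2 / (2 n_ij). Deterministic under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return A [meta_dataset()] with the full moderator layout, plus columns
#'   `theta` (the true effect, for recovery checks) and `paradigm`.
#' @export
simulate_effects <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  epa <- config$effects_per_article
  rows <- list()
  for (i in seq_len(config$n_articles)) {
    k_i <- if (length(epa) == 1) epa else sample(epa[1]:epa[2], 1)
    class_i <- sample(names(config$class_probs), 1, prob = config$class_probs)
    species_i <- sample(species_pool[[class_i]], 1)
    u_i <- stats::rnorm(1, 0, sqrt(config$tau2_article))
    human <- class_i %in% c("human_adult", "human_child")
    for (j in seq_len(k_i)) {
      paradigm <- sample(names(config$paradigm_mix), 1,
                         prob = config$paradigm_mix)
      # Non-human animals are tested with operant / processing measures,
      # never questionnaire-style judgements.
      if (!human && paradigm %in% c("yes_no", "scale_judgement",
                                    "frequency_estimation",
                                    "sequence_production")) {
        paradigm <- "go_nogo"
      }
      training <- if (human) round(stats::rlnorm(1, log(200), 0.7))
                  else round(stats::rlnorm(1, log(3000), 0.8))
      row <- data.frame(
        article_id = sprintf("A%03d", i),
        study_id = sprintf("A%03d_s%d", i, j),
        paradigm = paradigm,
        animal_species = species_i,
        animal_class = class_i,
        human_vs_nonhuman = if (class_i == "human_adult") "human_adult"
                            else if (class_i == "human_child") "human_child"
                            else "nonhuman",
        stimulus_modality = if (!human) "auditory"
                            else sample(c("auditory", "visual", "audiovisual"),
                                        1, prob = c(0.55, 0.4, 0.05)),
        test_response = paradigm,
        test_type = if (paradigm %in% reflection_paradigms) "reflection"
                    else "processing",
        log_training_length = log(max(training, 1)),
        categories_in_language = sample(2:6, 1),
        vocabulary_size = sample(4:30, 1),
        repetition_of_items = sample(c("present", "absent"), 1,
                                     prob = c(0.3, 0.7)),
        adjacent_dependencies = sample(c("present", "absent"), 1,
                                       prob = c(0.8, 0.2)),
        nonadjacent_dependencies = sample(c("present", "absent"), 1,
                                          prob = c(0.3, 0.7)),
        stringsAsFactors = FALSE
      )
      rng <- if (human) config$n_range_human else config$n_range_nonhuman
      n <- sample(rng[1]:rng[2], 1)
      theta <- config$mu + moderator_contribution(config$moderator_effects, row) +
        u_i + stats::rnorm(1, 0, sqrt(config$tau2_study))
      v <- 1 / n + theta^2 / (2 * n)
      row$n <- n
      row$theta <- theta
      row$v_g <- v
      row$g <- theta + stats::rnorm(1, 0, sqrt(v))
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  meta_dataset(out, moderators = agl_moderators)
}

#' Simulate raw per-study summary statistics
#'
#' For each simulated effect, emits a [raw_study()] record whose
#' harmonization recovers the simulated g exactly: the generator chooses a
#' within-study SD and backs out the condition means from the target Cohen's
#' d, exercising multi-session pooling, CI-only reporting, paradigm sign
#' conventions and familiarity re-signing.
#'
#' @param config A [synthetic_config()].
#' @return List of [raw_study()] records. The target effect table is
#'   attached as attribute `effects`.
#' @export
simulate_raw_studies <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  effects <- simulate_effects(config)
  d <- as.data.frame(effects)
  records <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    records[[i]] <- invert_effect(d[i, ], config)
  }
  attr(records, "effects") <- effects
  records
}

# Builds a raw_study whose harmonize() output equals row$g (and v_g implied
# by the backed-out d). Randomness here only picks the reporting style.
invert_effect <- function(row, config) {
  fam <- paradigm_family(row$paradigm)
  n <- row$n
  resign <- fam$family == "paired" && row$paradigm == "looking_time" &&
    stats::runif(1) < config$prop_resign
  target_g <- if (resign) -row$g else row$g
  d <- target_g / correction_factor(n - 1)
  mods <- as.list(row[intersect(agl_moderators, names(row))])
  if (fam$family == "chance") {
    chance <- 0.5
    s <- 0.15
    m <- chance + d * s
    two_sessions <- n >= 4 && stats::runif(1) < config$prop_multisession
    if (two_sessions) {
      n1 <- ceiling(n / 2); n2 <- n - n1
      delta <- 0.02
      means <- c(m + delta, m - delta * n1 / n2)
      sessions <- data.frame(mean = means, sd = s, n = c(n1, n2))
    } else {
      sessions <- data.frame(mean = m, sd = s, n = n)
    }
    sessions <- maybe_ci_only(sessions, config$prop_ci_only)
    raw_study(row$paradigm, grammatical = sessions, chance = chance,
              article_id = row$article_id, study_id = row$study_id,
              moderators = mods)
  } else {
    base <- switch(row$paradigm,
                   serial_reaction_time = c(level = 600, s = 100),
                   looking_time = c(level = 10, s = 2),
                   sequence_production = c(level = 0.55, s = 0.15))
    s <- unname(base["s"])
    m_u <- unname(base["level"])
    m_g <- m_u + fam$direction * d * s
    gs <- data.frame(mean = m_g, sd = s, n = n)
    us <- data.frame(mean = m_u, sd = s, n = n)
    raw_study(row$paradigm, grammatical = gs, ungrammatical = us,
              familiarity_resign = resign,
              article_id = row$article_id, study_id = row$study_id,
              moderators = mods)
  }
}

# Replace the SD of single-session reports with an exact 95% t interval,
# which ci_to_sd() inverts at ingest.
maybe_ci_only <- function(sessions, prop_ci_only) {
  if (nrow(sessions) == 1 && sessions$n[1] >= 2 &&
      stats::runif(1) < prop_ci_only) {
    half <- stats::qt(0.975, sessions$n[1] - 1) * sessions$sd[1] /
      sqrt(sessions$n[1])
    sessions$ci_lower <- sessions$mean - half
    sessions$ci_upper <- sessions$mean + half
    sessions$sd <- NA_real_
  }
  sessions
}

#' Thin a dataset with a selection-bias rule
#'
#' Applies a retention rule mapping (g, se) to a retention probability and
#' keeps each effect independently with that probability, emulating
#' size-dependent publication selection.
#'
#' @param dataset A [meta_dataset()].
#' @param rule Function of (g, se) returning retention probabilities in
#'   \[0, 1\].
#' @param seed Optional seed for the thinning draws.
#' @return The thinned [meta_dataset()].
#' @export
apply_selection_bias <- function(dataset, rule, seed = NULL) {
  if (!inherits(dataset, "meta_dataset")) dataset <- meta_dataset(dataset)
  if (!is.null(seed)) set.seed(seed)
  d <- as.data.frame(dataset)
  pr <- rule(d$g, sqrt(d$v_g))
  if (any(!is.finite(pr) | pr < 0 | pr > 1)) {
    stop("rule must return retention probabilities in [0, 1]", call. = FALSE)
  }
  keep <- stats::runif(nrow(d)) < pr
  if (!any(keep)) stop("selection rule removed every effect", call. = FALSE)
  meta_dataset(d[keep, , drop = FALSE], moderators = moderator_names(dataset))
}
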