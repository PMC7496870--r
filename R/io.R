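# Coding-sheet I/O, validation and the end-to-end pipeline.
#
# Two sheet layouts are supported, auto-detected on read:
#  * precomputed: one row per effect with columns g, v_g, n, article_id,
#    study_id and moderator columns;
#  * raw: long format, one row per (effect, condition arm, test session)
#    with columns paradigm, arm, session, mean, sd, n, chance, ci_lower,
#    ci_upper, ci_level, familiarity_resign plus identifiers and moderators.

raw_sheet_cols <- c("article_id", "study_id", "paradigm", "arm", "session",
                    "mean", "sd", "n", "chance", "ci_lower", "ci_upper",
                    "ci_level", "familiarity_resign")

# Format numeric columns so that written sheets round-trip exactly
# (17 significant digits uniquely identify a double).
format_numeric_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.17g", df[[j]]))
    }
  }
  df
}

write_table_exact <- function(df, path, sep) {
  utils::write.table(format_numeric_cols(df), path, sep = sep,
                     row.names = FALSE, quote = TRUE, na = "")
}

#' Write a coding sheet or result table as CSV
#'
#' Numeric columns are written with enough digits to round-trip exactly, so
#' a write/read/write cycle is byte-identical.
#'
#' @param x A [meta_dataset()], an effect data frame, or a list of
#'   [raw_study()] records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coding_sheet <- function(x, path) {
  df <- if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, TRUE, "raw_study"))) {
    records_to_sheet(x)
  } else {
    as.data.frame(x)
  }
  write_table_exact(df, path, sep = ",")
  invisible(path)
}

# Long-format table for a list of raw_study records.
records_to_sheet <- function(records) {
  rows <- lapply(records, function(r) {
    arm_rows <- function(sessions, arm) {
      if (is.null(sessions)) return(NULL)
      has_ci <- if (all(c("ci_lower", "ci_upper") %in% names(sessions))) {
        is.finite(sessions$ci_lower) & is.finite(sessions$ci_upper)
      } else rep(FALSE, nrow(sessions))
      data.frame(
        article_id = r$article_id, study_id = r$study_id,
        paradigm = r$paradigm, arm = arm,
        session = seq_len(nrow(sessions)),
        mean = sessions$mean,
        # CI-only sessions are written as reported: limits without an SD
        # (the SD is re-derived at ingest)
        sd = ifelse(has_ci, NA_real_, sessions$sd),
        n = sessions$n,
        chance = if (is.null(r$chance)) NA_real_ else r$chance,
        ci_lower = if ("ci_lower" %in% names(sessions)) sessions$ci_lower else NA_real_,
        ci_upper = if ("ci_upper" %in% names(sessions)) sessions$ci_upper else NA_real_,
        ci_level = r$ci_level,
        familiarity_resign = r$familiarity_resign,
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(arm_rows(r$grammatical, "grammatical"),
                 arm_rows(r$ungrammatical, "ungrammatical"))
    for (m in names(r$moderators)) out[[m]] <- r$moderators[[m]]
    out
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(df) {
    for (m in setdiff(all_cols, names(df))) df[[m]] <- NA
    df[, all_cols, drop = FALSE]
  })
  do.call(rbind, rows)
}

# Rebuild raw_study records from a long-format sheet.
sheet_to_records <- function(df) {
  key <- paste(df$article_id, df$study_id, sep = "\r")
  mods_cols <- setdiff(names(df), raw_sheet_cols)
  lapply(split(df, factor(key, levels = unique(key))), function(grp) {
    grp <- grp[order(grp$arm, grp$session), , drop = FALSE]
    sess_cols <- c("mean", "sd", "n", "ci_lower", "ci_upper")
    gs <- grp[grp$arm == "grammatical", sess_cols, drop = FALSE]
    us <- grp[grp$arm == "ungrammatical", sess_cols, drop = FALSE]
    if (nrow(us) == 0) us <- NULL
    chance <- grp$chance[1]
    mods <- as.list(grp[1, mods_cols, drop = FALSE])
    raw_study(grp$paradigm[1], grammatical = gs, ungrammatical = us,
              chance = if (is.finite(chance)) chance else NULL,
              ci_level = if (is.finite(grp$ci_level[1])) grp$ci_level[1] else 0.95,
              familiarity_resign = isTRUE(as.logical(grp$familiarity_resign[1])),
              article_id = grp$article_id[1], study_id = grp$study_id[1],
              moderators = mods)
  })
}

# Categorical moderator levels are normalized case-insensitively at ingest.
normalize_moderators <- function(df) {
  for (m in intersect(agl_moderators, names(df))) {
    if (is.character(df[[m]])) df[[m]] <- tolower(trimws(df[[m]]))
  }
  df
}

#' Read and validate a coding sheet
#'
#' Auto-detects whether the sheet carries precomputed effects (`g`, `v_g`
#' columns) or raw per-session statistics (long format with `arm` and
#' `session` columns). Invalid precomputed rows (missing or non-positive
#' `v_g`, missing `g`) are dropped with a per-row reason, reported in the
#' `dropped` attribute and as a message.
#'
#' @param path CSV path (UTF-8, header row required).
#' @return A [meta_dataset()] (precomputed sheet) or a list of [raw_study()]
#'   records (raw sheet).
#' @export
read_coding_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("coding sheet is empty: ", path, call. = FALSE)
  df <- normalize_moderators(df)
  if (all(c("g", "v_g") %in% names(df))) {
    reasons <- character(0)
    bad_g <- !is.finite(df$g)
    bad_v <- !is.finite(df$v_g) | df$v_g <= 0
    if (any(bad_g)) reasons <- c(reasons, sprintf("row %d: missing or non-finite g",
                                                  which(bad_g)))
    if (any(bad_v)) reasons <- c(reasons, sprintf("row %d: v_g missing or <= 0",
                                                  which(bad_v)))
    keep <- !(bad_g | bad_v)
    if (!any(keep)) stop("no valid effect rows in ", path, call. = FALSE)
    if (length(reasons) > 0) {
      message(length(reasons), " row(s) dropped:\n  ",
              paste(reasons, collapse = "\n  "))
    }
    ds <- meta_dataset(df[keep, , drop = FALSE],
                       moderators = intersect(agl_moderators, names(df)))
    attr(ds, "dropped") <- reasons
    ds
  } else if (all(c("arm", "session", "mean") %in% names(df))) {
    sheet_to_records(df)
  } else {
    stop("unrecognized coding-sheet layout: expected either g/v_g columns ",
         "(precomputed) or arm/session/mean columns (raw)", call. = FALSE)
  }
}

#' Omnibus moderator table
#'
#' Runs [omnibus_moderator_test()] for each moderator and assembles the
#' moderator / F / df1 / df2 / p table. Moderators that are absent, constant
#' in the (complete-case) data, or otherwise unfittable are skipped with a
#' reason.
#'
#' @param dataset A [meta_dataset()].
#' @param moderators Moderator columns to test (default: all declared).
#' @return Data frame with columns moderator, F, df1, df2, p; skipped
#'   moderators and reasons in the `skipped` attribute.
#' @export
moderator_table <- function(dataset, moderators = moderator_names(dataset)) {
  rows <- list(); skipped <- character()
  for (m in moderators) {
    if (!m %in% names(dataset)) {
      skipped[m] <- "column absent"
      next
    }
    vals <- stats::na.omit(as.data.frame(dataset)[[m]])
    if (length(unique(as.character(vals))) < 2) {
      skipped[m] <- "constant in this dataset"
      next
    }
    res <- tryCatch(omnibus_moderator_test(dataset, m),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[m] <- res
      next
    }
    rows[[m]] <- data.frame(moderator = m, F = res$F, df1 = res$df1,
                            df2 = res$df2, p = res$p,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(moderator = character(), F = numeric(), df1 = integer(),
               df2 = integer(), p = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Run the full meta-analysis pipeline
#'
#' Chains harmonization (when the input sheet is raw), the intercept-only
#' multilevel fit, Cochran's Q, the omnibus moderator table on the full
#' dataset, per-subgroup moderator tables and subgroup estimates, and the
#' publication-bias diagnostics, writing every result table under
#' `output_dir`. Runs are deterministic: the same input yields byte-identical
#' outputs.
#'
#' @param input Path to a coding-sheet CSV, a [meta_dataset()], or a list of
#'   [raw_study()] records.
#' @param output_dir Directory for the result tables (created if needed).
#' @param subgroup_factor Categorical moderator defining the per-class
#'   analyses (default `animal_class`).
#' @param moderators Moderators to test (default: all declared).
#' @return Invisibly, a list with the dataset, fits, tables and the log.
#' @export
run_pipeline <- function(input, output_dir, subgroup_factor = "animal_class",
                         moderators = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    message(line)
  }

  obj <- if (is.character(input)) read_coding_sheet(input) else input
  if (is.list(obj) && !is.data.frame(obj) &&
      all(vapply(obj, inherits, TRUE, "raw_study"))) {
    note("harmonizing ", length(obj), " raw study records")
    effects <- normalize_moderators(harmonize_records(obj))
    dataset <- meta_dataset(effects,
                            moderators = intersect(agl_moderators, names(effects)))
  } else {
    dataset <- if (inherits(obj, "meta_dataset")) obj else meta_dataset(obj)
  }
  if (is.null(moderators)) moderators <- moderator_names(dataset)
  note("dataset: ", nrow(dataset), " effects in ",
       length(unique(dataset$article_id)), " articles")
  write_coding_sheet(dataset, file.path(output_dir, "harmonized_effects.csv"))

  overall <- reml_fit(dataset)
  write_table_exact(coefficient_tests(overall),
                    file.path(output_dir, "overall_model.tsv"), sep = "\t")
  q <- cochran_q(dataset)
  het <- data.frame(k = overall$k, Q = q$Q, Q_df = q$df, Q_p = q$p,
                    sigma2_article = overall$sigma2_article,
                    sigma2_study = overall$sigma2_study,
                    reml_loglik = overall$reml_loglik)
  write_table_exact(het, file.path(output_dir, "heterogeneity.tsv"), sep = "\t")
  note(sprintf("overall effect %.4f (SE %.4f), Q(%d) = %.3f",
               overall$beta[1], overall$se[1], q$df, q$Q))

  mt <- moderator_table(dataset, moderators)
  for (m in names(attr(mt, "skipped"))) {
    note("moderator skipped (full dataset): ", m, " — ", attr(mt, "skipped")[m])
  }
  write_table_exact(mt, file.path(output_dir, "moderator_tests.tsv"), sep = "\t")

  subgroups <- NULL
  if (subgroup_factor %in% names(dataset) &&
      length(unique(dataset[[subgroup_factor]])) > 1) {
    subgroups <- subgroup_effects(dataset, subgroup_factor)
    write_table_exact(subgroups,
                      file.path(output_dir, "subgroup_estimates.tsv"), sep = "\t")
    sub_mods <- setdiff(moderators,
                        c(subgroup_factor, "animal_class", "animal_species",
                          "human_vs_nonhuman"))
    for (lev in sort(unique(as.character(dataset[[subgroup_factor]])))) {
      sub <- filter_subset(dataset, function(d) d[[subgroup_factor]] == lev)
      for (m in intersect(sub_mods, skipped_moderators(sub))) {
        note("moderator skipped (", lev, "): ", m, " — constant in subgroup")
      }
      smt <- moderator_table(sub, setdiff(sub_mods, skipped_moderators(sub)))
      for (m in names(attr(smt, "skipped"))) {
        note("moderator skipped (", lev, "): ", m, " — ", attr(smt, "skipped")[m])
      }
      write_table_exact(smt, file.path(output_dir,
                                       paste0("moderator_tests_", lev, ".tsv")),
                        sep = "\t")
    }
  }

  bias <- NULL
  if ("n" %in% names(dataset) && length(unique(dataset$n)) > 1) {
    bias <- peters_test(dataset)
    bias_row <- data.frame(t = bias$t_stat, df = bias$df, p = bias$p,
                           slope = bias$slope, intercept = bias$intercept)
    write_table_exact(bias_row, file.path(output_dir, "bias_summary.tsv"),
                      sep = "\t")
    note(sprintf("Peters' test: t(%d) = %.3f, p = %.4g",
                 bias$df, bias$t_stat, bias$p))
  } else {
    note("Peters' test skipped: no usable sample sizes")
  }
  funnel <- funnel_coordinates(dataset)
  fun_df <- funnel$points
  fun_df$reference <- funnel$reference
  write_table_exact(fun_df, file.path(output_dir, "funnel.tsv"), sep = "\t")

  writeLines(log, file.path(output_dir, "pipeline_log.txt"))
  invisible(list(dataset = dataset, overall = overall, q = q,
                 moderator_tests = mt, subgroups = subgroups, bias = bias,
                 funnel = funnel, log = log))
}
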