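# Container for a harmonized effect table with declared moderators.

#' Construct a meta-analytic dataset
#'
#' Wraps a harmonized effect table (one row per effect) together with the
#' names of the moderator columns. Effects are nested within articles: every
#' row needs an `article_id`, a `g` and a positive sampling variance `v_g`.
#'
#' @param effects Data frame with columns `article_id`, `g`, `v_g` and
#'   optionally `study_id`, `n` and moderator columns.
#' @param moderators Character vector naming moderator columns present in
#'   `effects`.
#' @return An object of class `meta_dataset` (a data frame subclass with a
#'   `moderators` attribute).
#' @export
meta_dataset <- function(effects, moderators = character()) {
  effects <- as.data.frame(effects)
  required <- c("article_id", "g", "v_g")
  missing <- setdiff(required, names(effects))
  if (length(missing) > 0) {
    stop("effects table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(effects) == 0) stop("effects table is empty", call. = FALSE)
  if (any(!is.finite(effects$g))) stop("all g must be finite", call. = FALSE)
  if (any(!is.finite(effects$v_g) | effects$v_g <= 0)) {
    stop("all sampling variances v_g must be positive", call. = FALSE)
  }
  if (any(is.na(effects$article_id))) stop("article_id must not be missing", call. = FALSE)
  absent <- setdiff(moderators, names(effects))
  if (length(absent) > 0) {
    stop("declared moderators not in table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (!"study_id" %in% names(effects)) {
    effects$study_id <- stats::ave(seq_len(nrow(effects)), effects$article_id,
                                   FUN = seq_along)
  }
  structure(effects,
            moderators = moderators,
            class = c("meta_dataset", "data.frame"))
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("meta_dataset: %d effects in %d articles; %d moderators\n",
              nrow(x), length(unique(x$article_id)),
              length(attr(x, "moderators"))))
  NextMethod()
}

#' Moderator columns declared for a dataset
#' @param dataset A [meta_dataset()].
#' @return Character vector of moderator names.
#' @export
moderator_names <- function(dataset) attr(dataset, "moderators")

#' Subset a meta-analytic dataset, flagging degenerate moderators
#'
#' Used for per-class analyses: the subset keeps the full moderator schema
#' but records which moderators are constant within the subset (e.g. all
#' non-human mammal studies were auditory), so downstream moderator analyses
#' skip them rather than fitting a degenerate model.
#'
#' @param dataset A [meta_dataset()].
#' @param predicate Either a logical vector over rows or a function taking
#'   the effect table and returning one.
#' @return A `meta_dataset` with an additional attribute
#'   `skipped_moderators`, the names of moderators constant in the subset.
#' @export
filter_subset <- function(dataset, predicate) {
  keep <- if (is.function(predicate)) predicate(as.data.frame(dataset)) else predicate
  if (!is.logical(keep) || length(keep) != nrow(dataset)) {
    stop("predicate must give one logical per row", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("subset is empty", call. = FALSE)
  sub <- as.data.frame(dataset)[keep, , drop = FALSE]
  mods <- moderator_names(dataset)
  constant <- mods[vapply(mods, function(m) {
    v <- sub[[m]][!is.na(sub[[m]])]
    length(unique(v)) < 2
  }, logical(1))]
  out <- meta_dataset(sub, moderators = mods)
  attr(out, "skipped_moderators") <- constant
  out
}

#' Moderators flagged as constant (skipped) in a subset
#' @param dataset A dataset produced by [filter_subset()].
#' @return Character vector (empty if none flagged).
#' @export
skipped_moderators <- function(dataset) {
  sk <- attr(dataset, "skipped_moderators")
  if (is.null(sk)) character() else sk
}
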