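# Publication-bias diagnostics: Peters' regression test and funnel-plot data.

#' Peters' regression test for funnel-plot asymmetry
#'
#' Adds inverse total sample size (1/n) as the sole moderator in the
#' multilevel random-effects model and tests its coefficient with the t
#' method on k - 2 degrees of freedom. A significant slope indicates that
#' effect sizes depend on study size — the asymmetry signature of
#' publication bias. For standardized mean differences the inverse-n
#' moderator is run inside the same nested REML machinery as every other
#' moderator.
#'
#' @param dataset A [meta_dataset()] whose effects carry a sample size `n`.
#' @return List of class `peters_test`: `t_stat`, `df`, `p`, `slope`,
#'   `intercept`, and the underlying `fit`.
#' @export
peters_test <- function(dataset) {
  if (!inherits(dataset, "meta_dataset")) dataset <- meta_dataset(dataset)
  if (nrow(dataset) < 3) stop("Peters' test requires at least 3 effects", call. = FALSE)
  if (!"n" %in% names(dataset) || any(!is.finite(dataset$n) | dataset$n <= 0)) {
    stop("all effects need a positive sample size n", call. = FALSE)
  }
  d <- as.data.frame(dataset)
  if (length(unique(d$n)) < 2) {
    stop("sample size is constant across effects; 1/n is a degenerate regressor",
         call. = FALSE)
  }
  d$inv_n <- 1 / d$n
  ds <- meta_dataset(d, moderators = "inv_n")
  fit <- reml_fit(ds, moderators = "inv_n", intercept = TRUE)
  structure(list(
    t_stat = unname(fit$t_stats["inv_n"]),
    df = fit$df,
    p = unname(fit$p_values["inv_n"]),
    slope = unname(fit$beta["inv_n"]),
    intercept = unname(fit$beta["intercept"]),
    fit = fit
  ), class = "peters_test")
}

#' @export
print.peters_test <- function(x, ...) {
  cat(sprintf("Peters' test: t(%d) = %.3f, p = %.4g (slope on 1/n = %.3f)\n",
              x$df, x$t_stat, x$p, x$slope))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' One point per effect: Hedges' g against its standard error, labelled by
#' animal class when available, plus the overall intercept-only multilevel
#' estimate as the reference line.
#'
#' @param dataset A [meta_dataset()].
#' @param group Column to use as the point label (default `animal_class`
#'   when present).
#' @return List of class `funnel_data`: `points` (data frame g, se, group)
#'   and `reference` (overall estimate).
#' @export
funnel_coordinates <- function(dataset, group = "animal_class") {
  if (!inherits(dataset, "meta_dataset")) dataset <- meta_dataset(dataset)
  d <- as.data.frame(dataset)
  pts <- data.frame(
    g = d$g,
    se = sqrt(d$v_g),
    group = if (group %in% names(d)) as.character(d[[group]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  reference <- if (nrow(d) > 1) unname(reml_fit(dataset)$beta[1]) else d$g[1]
  structure(list(points = pts, reference = reference),
            class = "funnel_data")
}

#' Funnel plot
#'
#' Scatter of effect size against standard error (inverted axis), with the
#' overall multilevel estimate as a vertical reference line. Requires
#' ggplot2.
#'
#' @param funnel A [funnel_coordinates()] result.
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  pts <- funnel$points
  ggplot2::ggplot(pts, ggplot2::aes(x = g, y = se, colour = group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = funnel$reference, linetype = "dashed") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Hedges' g", y = "Standard error", colour = NULL) +
    ggplot2::theme_minimal()
}
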