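# Three-level random-effects meta-regression fitted by REML.
#
# Model: g_ij = x_ij' beta + u_i + w_ij + e_ij, with article effects
# u_i ~ N(0, sigma2_article), effect-level deviations w_ij ~ N(0, sigma2_study)
# and known sampling errors e_ij ~ N(0, v_ij). Marginally,
#   V(theta) = sigma2_article * A + sigma2_study * I + diag(v),
# where A is the same-article indicator matrix. beta is profiled out by GLS
# and the two variance components are estimated by restricted maximum
# likelihood with an analytic gradient.

# Design matrix for a set of moderator terms. Categorical moderators expand
# by treatment coding when an intercept is present (reference level = first
# alphabetically) and by cell-means coding otherwise.
build_design <- function(data, moderators = NULL, intercept = TRUE) {
  if (is.null(moderators) || length(moderators) == 0) {
    if (!intercept) stop("a model needs an intercept or at least one moderator",
                         call. = FALSE)
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "intercept"))
    return(list(X = X, assign = 0L, keep = rep(TRUE, nrow(data)),
                terms = character()))
  }
  keep <- stats::complete.cases(data[, moderators, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  for (m in moderators) {
    if (is.character(d[[m]]) || is.logical(d[[m]])) {
      d[[m]] <- factor(d[[m]], levels = sort(unique(as.character(d[[m]]))))
    }
    if (is.factor(d[[m]]) && nlevels(droplevels(d[[m]])) < 2) {
      stop("moderator '", m, "' is constant in this dataset", call. = FALSE)
    }
  }
  rhs <- paste(vapply(moderators, function(m) paste0("`", m, "`"), ""),
               collapse = " + ")
  fml <- stats::as.formula(paste("~", if (intercept) rhs else paste("0 +", rhs)))
  X <- stats::model.matrix(fml, data = d)
  assign <- attr(X, "assign")
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  list(X = X, assign = assign, keep = keep, terms = moderators)
}

# Restricted log-likelihood and its gradient at variance components theta =
# (sigma2_article, sigma2_study). The marginal covariance is block diagonal
# by article, each block compound-symmetric on top of the known sampling
# variances: V_i = sa * J + diag(ss + v_ij). All solves use the
# Sherman-Morrison identity, so one evaluation costs O(k p^2) rather than
# O(k^3). `blk` is the integer article index (1..B) per row.
reml_pieces <- function(theta, X, y, v, blk, want_gradient = FALSE) {
  k <- length(y); p <- ncol(X)
  sa <- theta[1]; ss <- theta[2]
  Dv <- ss + v
  if (any(Dv <= 0)) return(list(ll = -Inf))
  Dinv <- 1 / Dv
  s_i <- drop(rowsum(Dinv, blk))            # 1' D^-1 1 per article
  c_i <- sa / (1 + sa * s_i)                # Sherman-Morrison factor
  logdetV <- sum(log(Dv)) + sum(log1p(sa * s_i))
  # V^-1 M = D^-1 M - D^-1 c_i (1' D^-1 M) expanded back to rows
  vsolve <- function(M) {
    DM <- Dinv * M
    DM - Dinv * (c_i * rowsum(DM, blk))[blk, , drop = FALSE]
  }
  Vinv_y <- vsolve(cbind(y))
  Vinv_X <- vsolve(X)
  XtVinvX <- crossprod(X, Vinv_X)
  Rx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(Rx)) return(list(ll = -Inf))
  logdetXtVX <- 2 * sum(log(diag(Rx)))
  beta <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, Vinv_y)))
  r <- y - X %*% beta
  Vinv_r <- drop(Vinv_y - Vinv_X %*% beta)
  quad <- sum(r * Vinv_r)
  ll <- -0.5 * ((k - p) * log(2 * pi) + logdetV + logdetXtVX + quad)
  out <- list(ll = ll, beta = drop(beta), XtVinvX = XtVinvX,
              Vinv_r = Vinv_r, Vinv_X = Vinv_X)
  if (want_gradient) {
    XtVXinv <- chol2inv(Rx)
    q <- Vinv_r
    qA <- rowsum(q, blk)
    # traces of P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1 against dV/dtheta
    trVinv <- sum(Dinv) - sum(c_i * drop(rowsum(Dinv^2, blk)))
    trVinvA <- sum(s_i / (1 + sa * s_i))
    M1 <- crossprod(Vinv_X)                     # X'V^-2 X
    M2 <- crossprod(rowsum(Vinv_X, blk))        # X'V^-1 A V^-1 X
    g_a <- -0.5 * ((trVinvA - sum(XtVXinv * M2)) - sum(qA^2))
    g_s <- -0.5 * ((trVinv - sum(XtVXinv * M1)) - sum(q^2))
    out$gradient <- c(g_a, g_s)
  }
  out
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the restricted log-likelihood of the nested random-effects
#' model at given values of the two variance components, with the fixed
#' effects profiled out by generalized least squares. Useful for profiling
#' and for verifying the optimizer against a grid.
#'
#' @param dataset A [meta_dataset()].
#' @param sigma2_article,sigma2_study Variance components (>= 0).
#' @param moderators Optional moderator columns for the fixed part.
#' @param intercept Include an intercept?
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(dataset, sigma2_article, sigma2_study,
                              moderators = NULL, intercept = TRUE) {
  des <- build_design(dataset, moderators, intercept)
  d <- as.data.frame(dataset)[des$keep, , drop = FALSE]
  blk <- as.integer(factor(d$article_id))
  reml_pieces(c(sigma2_article, sigma2_study), des$X, d$g, d$v_g, blk)$ll
}

#' Fit the multilevel random-effects meta-regression by REML
#'
#' Estimates the between-article and within-article (between-effect) variance
#' components by restricted maximum likelihood, with the coefficient vector
#' obtained by generalized least squares at the optimum. Inference uses the
#' t method: each coefficient is referred to a t distribution with k - p
#' degrees of freedom, where k is the number of effects used and p the number
#' of coefficients.
#'
#' Optimization is a bounded quasi-Newton search with the analytic restricted
#' likelihood gradient, run from the fixed starting points (0, 0),
#' (0.1, 0.1) and (1, 1) and keeping the best optimum, so fits are fully
#' deterministic. Components are constrained to be non-negative.
#'
#' @param dataset A [meta_dataset()].
#' @param moderators Character vector of moderator columns (NULL for the
#'   intercept-only overall model). Rows missing a used moderator are
#'   excluded from that fit (count reported in the result).
#' @param intercept Include an intercept? Set FALSE with one categorical
#'   moderator for cell-means (subgroup) coding.
#' @param fix_variance Optional numeric vector `c(sigma2_article, sigma2_study)`
#'   to hold the components fixed instead of estimating them.
#' @param level Confidence level for coefficient intervals.
#' @return An object of class `agl_reml`: coefficient table (estimate, SE, t,
#'   df, p, CI), variance components, restricted log-likelihood, Cochran's Q
#'   for the same fixed-effects structure, and bookkeeping (`k`, `p`,
#'   `n_dropped`).
#' @export
reml_fit <- function(dataset, moderators = NULL, intercept = TRUE,
                     fix_variance = NULL, level = 0.95) {
  if (!inherits(dataset, "meta_dataset")) dataset <- meta_dataset(dataset)
  des <- build_design(dataset, moderators, intercept)
  d <- as.data.frame(dataset)[des$keep, , drop = FALSE]
  k <- nrow(d); p <- ncol(des$X)
  if (k <= p) stop("need more effects (k = ", k, ") than coefficients (p = ",
                   p, ")", call. = FALSE)
  blk <- as.integer(factor(d$article_id))
  X <- des$X; y <- d$g; v <- d$v_g

  if (is.null(fix_variance)) {
    cache <- new.env(parent = emptyenv())
    evaluate <- function(theta) {
      key <- paste(format(theta, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$val <- reml_pieces(theta, X, y, v, blk, want_gradient = TRUE)
        cache$key <- key
      }
      cache$val
    }
    starts <- list(c(0, 0), c(0.1, 0.1), c(1, 1))
    best <- NULL
    trace <- list()
    for (s in starts) {
      opt <- stats::nlminb(
        start = s,
        objective = function(th) -evaluate(th)$ll,
        gradient = function(th) -evaluate(th)$gradient,
        lower = c(0, 0),
        control = list(rel.tol = 1e-10, iter.max = 500)
      )
      trace[[length(trace) + 1]] <- c(start = s, objective = opt$objective,
                                      convergence = opt$convergence)
      if (is.null(best) || opt$objective < best$objective) best <- opt
    }
    if (!is.finite(best$objective)) {
      stop("REML optimization failed to converge; trace: ",
           paste(vapply(trace, function(t) paste(round(unlist(t), 4),
                                                 collapse = "/"), ""),
                 collapse = "; "), call. = FALSE)
    }
    theta <- pmax(best$par, 0)
  } else {
    if (length(fix_variance) != 2 || any(fix_variance < 0)) {
      stop("fix_variance must be two non-negative values", call. = FALSE)
    }
    theta <- as.numeric(fix_variance)
  }

  fin <- reml_pieces(theta, X, y, v, blk)
  vb <- chol2inv(chol(fin$XtVinvX))
  dimnames(vb) <- list(colnames(X), colnames(X))
  beta <- fin$beta
  names(beta) <- colnames(X)
  se <- sqrt(diag(vb))
  df <- k - p
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = df)

  # Cochran's Q from the fixed-effect (inverse-variance weighted) fit with
  # the same fixed-effects structure.
  w <- 1 / v
  XtWX <- crossprod(X, w * X)
  beta_fe <- solve(XtWX, crossprod(X, w * y))
  r_fe <- y - X %*% beta_fe
  Q <- drop(crossprod(r_fe, w * r_fe))
  q_df <- k - p
  q_p <- stats::pchisq(Q, df = q_df, lower.tail = FALSE)

  structure(list(
    beta = beta, se = se, t_stats = tstat, df = df, p_values = pval,
    ci_lower = beta - tcrit * se, ci_upper = beta + tcrit * se,
    sigma2_article = theta[1], sigma2_study = theta[2],
    vb = vb, k = k, p = p, reml_loglik = fin$ll,
    Q = Q, Q_df = q_df, Q_p = q_p,
    moderators = moderators, intercept = intercept,
    assign = des$assign, level = level,
    n_dropped = sum(!des$keep)
  ), class = "agl_reml")
}

#' @export
print.agl_reml <- function(x, ...) {
  cat(sprintf("Multilevel random-effects meta-regression (REML), k = %d effects\n",
              x$k))
  cat(sprintf("Variance components: sigma2_article = %.4f, sigma2_study = %.4f\n",
              x$sigma2_article, x$sigma2_study))
  cat(sprintf("Restricted log-likelihood: %.4f\n", x$reml_loglik))
  cat(sprintf("Cochran's Q(%d) = %.3f, p = %.4g\n\n", x$Q_df, x$Q, x$Q_p))
  print(coefficient_tests(x), digits = 4)
  if (x$n_dropped > 0) {
    cat(sprintf("(%d rows excluded for missing moderator values)\n", x$n_dropped))
  }
  invisible(x)
}

#' Coefficient table with t-method inference
#'
#' @param fit An [reml_fit()] result.
#' @return Data frame with one row per coefficient: estimate, SE, t,
#'   df = k - p, two-sided p, and the t-based confidence interval.
#' @export
coefficient_tests <- function(fit) {
  stopifnot(inherits(fit, "agl_reml"))
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se), t = unname(fit$t_stats), df = fit$df,
             p = unname(fit$p_values), ci_lower = unname(fit$ci_lower),
             ci_upper = unname(fit$ci_upper),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Omnibus F-test for a moderator
#'
#' Fits the multilevel model with the moderator and jointly tests all of its
#' m coefficients: the Wald chi-square statistic divided by m is referred to
#' an F distribution with (m, k - p) degrees of freedom, so the test asks
#' whether the moderator accounts for any between-study heterogeneity.
#'
#' @param dataset A [meta_dataset()].
#' @param moderator Name of a moderator column (categorical with >= 2
#'   observed levels, or continuous).
#' @return List with `F`, `df1`, `df2`, `p`, and the underlying `fit`.
#' @export
omnibus_moderator_test <- function(dataset, moderator) {
  fit <- reml_fit(dataset, moderators = moderator, intercept = TRUE)
  idx <- which(fit$assign == 1L)
  m <- length(idx)
  b <- fit$beta[idx]
  Fstat <- drop(crossprod(b, solve(fit$vb[idx, idx, drop = FALSE], b))) / m
  df2 <- fit$k - fit$p
  list(F = Fstat, df1 = m, df2 = df2,
       p = stats::pf(Fstat, m, df2, lower.tail = FALSE), fit = fit)
}

#' Per-level subgroup estimates from a cell-means fit
#'
#' Fits the multilevel model with the factor's level indicators and no
#' intercept, so each coefficient is that level's weighted mean effect with
#' a t-method confidence interval.
#'
#' @param dataset A [meta_dataset()].
#' @param factor_name Name of a categorical moderator column.
#' @param level Confidence level.
#' @param ... Passed on to [reml_fit()] (e.g. `fix_variance`).
#' @return Data frame with one row per observed level: estimate, SE, t, df,
#'   p, CI. Levels with no effects are absent (with a warning if the column
#'   is a factor with empty levels).
#' @export
subgroup_effects <- function(dataset, factor_name, level = 0.95, ...) {
  vals <- as.data.frame(dataset)[[factor_name]]
  if (is.factor(vals) && any(table(droplevels(vals)) == 0)) {
    warning("levels with zero effects are omitted from subgroup estimation")
  }
  n_levels <- length(unique(stats::na.omit(as.character(vals))))
  if (n_levels < 2) {
    # A single observed level reduces to the overall intercept-only fit.
    fit <- reml_fit(dataset, moderators = NULL, intercept = TRUE,
                    level = level, ...)
    tab <- coefficient_tests(fit)
    tab$term <- as.character(unique(stats::na.omit(as.character(vals))))
    return(tab)
  }
  fit <- reml_fit(dataset, moderators = factor_name, intercept = FALSE,
                  level = level, ...)
  tab <- coefficient_tests(fit)
  tab$term <- sub(paste0("^`?", factor_name, "`?"), "", tab$term)
  tab
}

#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations from the inverse-variance weighted
#' (fixed-effect) fit, referred to a chi-square distribution. With no
#' moderators the reference value is the fixed-effect weighted mean and
#' df = k - 1; with moderators, df = k - p.
#'
#' @param dataset A [meta_dataset()].
#' @param moderators Optional moderator columns.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(dataset, moderators = NULL) {
  if (!inherits(dataset, "meta_dataset")) dataset <- meta_dataset(dataset)
  if (nrow(dataset) < 2) stop("Q requires at least two effects", call. = FALSE)
  des <- build_design(dataset, moderators, intercept = TRUE)
  d <- as.data.frame(dataset)[des$keep, , drop = FALSE]
  w <- 1 / d$v_g
  X <- des$X
  beta_fe <- solve(crossprod(X, w * X), crossprod(X, w * d$g))
  r <- d$g - X %*% beta_fe
  Q <- drop(crossprod(r, w * r))
  df <- nrow(d) - ncol(X)
  list(Q = Q, df = df, p = stats::pchisq(Q, df = df, lower.tail = FALSE))
}
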