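test_that("with variance components forced to zero the fit is the weighted mean", {
  # single effect per article, equal v: intercept = arithmetic mean, SE = sqrt(v/k)
  g <- c(0.2, 0.5, 0.9, 1.4, 0.7)
  ds <- meta_dataset(data.frame(article_id = paste0("A", 1:5), g = g, v_g = 0.04))
  fit <- reml_fit(ds, fix_variance = c(0, 0))
  expect_equal(unname(fit$beta), mean(g))
  expect_equal(unname(fit$se), sqrt(0.04 / 5))

  # unequal v: inverse-variance weighted mean
  v <- c(0.01, 0.04, 0.09, 0.25, 0.16)
  ds2 <- meta_dataset(data.frame(article_id = paste0("A", 1:5), g = g, v_g = v))
  fit2 <- reml_fit(ds2, fix_variance = c(0, 0))
  expect_equal(unname(fit2$beta), sum(g / v) / sum(1 / v))
})

test_that("the REML optimum beats a dense grid-search oracle on tiny instances", {
  for (seed in c(2, 9, 17)) {
    ds <- meta_dataset(make_effects(k = 8, seed = seed))
    fit <- reml_fit(ds)
    oracle <- grid_oracle(ds)
    # optimizer never loses to any grid point, and agrees with the refined
    # grid maximum to 1e-4 in restricted log-likelihood
    expect_gte(fit$reml_loglik + 1e-10, oracle$ll)
    expect_lt(fit$reml_loglik - oracle$ll, 1e-4)
  }
})

test_that("fit agrees with the independent multilevel REML implementation", {
  library(metafor)
  cfg <- synthetic_config(n_articles = 25, seed = 13,
                          moderator_effects = list(repetition_of_items = 0.4))
  ds <- simulate_effects(cfg)
  d <- as.data.frame(ds)

  fit <- reml_fit(ds)
  ref <- metafor::rma.mv(g, v_g, random = ~ 1 | article_id / study_id,
                         data = d, test = "t")
  expect_equal(unname(fit$beta), as.numeric(ref$beta), tolerance = 1e-5)
  expect_equal(unname(fit$se), ref$se, tolerance = 1e-5)
  expect_equal(sort(c(fit$sigma2_article, fit$sigma2_study)),
               sort(ref$sigma2), tolerance = 1e-4)
  expect_equal(unname(fit$p_values), as.numeric(ref$pval), tolerance = 1e-5)

  # moderated fit and omnibus F against the reference QM F-test
  omn <- omnibus_moderator_test(ds, "animal_class")
  refm <- metafor::rma.mv(g, v_g, mods = ~ animal_class,
                          random = ~ 1 | article_id / study_id,
                          data = d, test = "t")
  expect_equal(omn$F, refm$QM, tolerance = 1e-4)
  expect_equal(omn$df1, refm$QMdf[1])
  expect_equal(omn$df2, refm$QMdf[2])
  expect_equal(omn$p, refm$QMp, tolerance = 1e-5)
})

test_that("location and scale equivariance hold", {
  ds <- meta_dataset(make_effects(k = 20, seed = 5))
  fit <- reml_fit(ds)

  shifted <- as.data.frame(ds); shifted$g <- shifted$g + 3
  fs <- reml_fit(meta_dataset(shifted))
  expect_equal(unname(fs$beta), unname(fit$beta) + 3, tolerance = 1e-6)
  expect_equal(fs$sigma2_article, fit$sigma2_article, tolerance = 1e-6)
  expect_equal(fs$Q, fit$Q, tolerance = 1e-8)

  scaled <- as.data.frame(ds); scaled$g <- scaled$g * 2; scaled$v_g <- scaled$v_g * 4
  fc <- reml_fit(meta_dataset(scaled))
  expect_equal(unname(fc$beta), unname(fit$beta) * 2, tolerance = 1e-6)
  expect_equal(unname(fc$se), unname(fit$se) * 2, tolerance = 1e-6)
  expect_equal(unname(fc$t_stats), unname(fit$t_stats), tolerance = 1e-6)
  expect_equal(fc$Q, fit$Q, tolerance = 1e-8)
})

test_that("t-method inference uses k - p df and the CI/p duality", {
  ds <- meta_dataset(make_effects(k = 30, seed = 21))
  d <- as.data.frame(ds)
  d$x <- stats::rnorm(30)
  ds <- meta_dataset(d, moderators = "x")
  fit <- reml_fit(ds, moderators = "x")
  expect_equal(fit$df, fit$k - 2)
  tab <- coefficient_tests(fit)
  for (i in seq_len(nrow(tab))) {
    excludes0 <- tab$ci_lower[i] > 0 || tab$ci_upper[i] < 0
    expect_equal(excludes0, tab$p[i] < 0.05)
  }
})

test_that("omnibus tests are permutation invariant and reject degenerate moderators", {
  cfg <- synthetic_config(n_articles = 20, seed = 31)
  ds <- simulate_effects(cfg)
  omn <- omnibus_moderator_test(ds, "animal_class")
  set.seed(99)
  perm <- as.data.frame(ds)[sample(nrow(ds)), , drop = FALSE]
  omn2 <- omnibus_moderator_test(meta_dataset(perm, moderators = agl_moderators),
                                 "animal_class")
  expect_equal(omn$F, omn2$F, tolerance = 1e-6)

  d <- as.data.frame(ds); d$const <- "same"
  expect_error(omnibus_moderator_test(meta_dataset(d, moderators = "const"),
                                      "const"),
               "constant")
})

test_that("subgroup estimation reduces to per-subgroup means in the closed-form case", {
  # two disjoint single-article groups with equal v and variance forced to 0
  d <- data.frame(article_id = rep(c("A1", "A2"), each = 4),
                  g = c(0.4, 0.6, 0.5, 0.5, 1.4, 1.6, 1.5, 1.5),
                  v_g = 0.09,
                  grp = rep(c("low", "high"), each = 4),
                  stringsAsFactors = FALSE)
  ds <- meta_dataset(d, moderators = "grp")
  tab <- subgroup_effects(ds, "grp", fix_variance = c(0, 0))
  expect_equal(sort(tab$estimate), c(0.5, 1.5))
  # a single-level factor reduces to the overall intercept-only fit
  d1 <- d; d1$grp <- "only"
  tab1 <- subgroup_effects(meta_dataset(d1, moderators = "grp"), "grp",
                           fix_variance = c(0, 0))
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$estimate, mean(d$g))
})

test_that("Cochran's Q matches the hand formula", {
  d <- data.frame(article_id = c("A1", "A2"), g = c(0, 1), v_g = c(1, 1))
  q <- cochran_q(meta_dataset(d))
  expect_equal(q$Q, 0.5)
  expect_equal(q$df, 1)

  same <- data.frame(article_id = paste0("A", 1:6), g = 0.7, v_g = 0.04)
  expect_equal(cochran_q(meta_dataset(same))$Q, 0)

  ds <- meta_dataset(make_effects(k = 12, seed = 8))
  expect_equal(cochran_q(ds)$df, 11)
})

test_that("rank-deficient designs error with the collinear terms named", {
  d <- make_effects(k = 12, seed = 40)
  d$x1 <- rep(c("a", "b"), 6)
  d$x2 <- d$x1  # perfectly aliased
  ds <- meta_dataset(d, moderators = c("x1", "x2"))
  expect_error(reml_fit(ds, moderators = c("x1", "x2")), "collinear")
})

test_that("filter_subset flags constant moderators and keeps bookkeeping", {
  cfg <- synthetic_config(n_articles = 30, seed = 77)
  ds <- simulate_effects(cfg)
  all_rows <- filter_subset(ds, rep(TRUE, nrow(ds)))
  expect_equal(nrow(all_rows), nrow(ds))

  # birds are simulated auditory-only, so modality must be flagged as constant
  birds <- filter_subset(ds, function(d) d$animal_class == "bird")
  expect_equal(nrow(birds), sum(ds$animal_class == "bird"))
  expect_true("stimulus_modality" %in% skipped_moderators(birds))
  expect_true("animal_class" %in% skipped_moderators(birds))

  expect_error(filter_subset(ds, function(d) d$animal_class == "dragon"), "empty")
})
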