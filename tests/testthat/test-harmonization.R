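test_that("correction factor follows the small-sample formula and its limits", {
  expect_equal(correction_factor(1), 0)
  expect_equal(correction_factor(19), 0.96)
  expect_lt(abs(correction_factor(1e6) - 1), 1e-5)
  for (df in c(2, 5, 24, 100)) {
    expect_true(correction_factor(df) > 0 && correction_factor(df) < 1)
  }
  expect_error(correction_factor(0), "df")
  expect_error(correction_factor(-3), "df")
})

test_that("one-sample d is the standardized difference from chance", {
  expect_equal(one_sample_d(0.5, 0.5, 0.2), 0)
  expect_equal(one_sample_d(0.6, 0.5, 0.1), 1.0)
  expect_equal(one_sample_d(0.4, 0.5, 0.2), -0.5)
  expect_error(one_sample_d(0.6, 0.5, 0), "positive")
  expect_error(one_sample_d(0.6, 0.5, -1), "positive")
})

test_that("Hedges' g shrinks d and never exceeds it in magnitude", {
  expect_equal(hedges_g(0, 5), 0)
  expect_equal(hedges_g(1, 19), 0.96)
  expect_equal(hedges_g(-2, 7), -16 / 9)
  set.seed(3)
  for (i in 1:25) {
    d <- stats::rnorm(1, 0, 2)
    df <- sample(2:200, 1)
    expect_lte(abs(hedges_g(d, df)), abs(d))
  }
})

test_that("variance of g matches the Borenstein form", {
  expect_equal(variance_g(0, 25, 24), 0.0375135734072022, tolerance = 1e-12)
  expect_equal(variance_g(1, 1, 1), 0)  # degenerate J = 0, must not error
  # consistency: variance shrinks like 1/n
  v1 <- variance_g(0.5, 100, 99)
  v2 <- variance_g(0.5, 10000, 9999)
  expect_lt(v2, v1 / 50)
  expect_error(variance_g(1, 0, 1), "n")
})

test_that("session pooling weights by participants and df", {
  expect_equal(pooled_mean(0.7, 12), 0.7)
  expect_equal(pooled_mean(c(0.6, 0.8), c(10, 10)), 0.7)
  expect_equal(pooled_mean(c(0.5, 0.9), c(10, 30)), 0.8)
  expect_error(pooled_mean(numeric(0), numeric(0)), "session")

  expect_equal(average_sd(0.3, 8), 0.3)
  expect_equal(average_sd(c(0, 2), c(2, 2)), sqrt(2))
  expect_equal(average_sd(c(0.4, 0.4, 0.4), c(5, 9, 31)), 0.4)
  expect_error(average_sd(c(1, 2), c(1, 1)), "undefined")
  set.seed(4)
  for (i in 1:20) {
    sds <- stats::runif(3, 0.1, 2)
    ns <- sample(2:50, 3)
    pooled <- average_sd(sds, ns)
    expect_gte(pooled, min(sds) - 1e-12)
    expect_lte(pooled, max(sds) + 1e-12)
  }
})

test_that("CI-to-SD inversion assumes the t distribution", {
  # independent oracle: tabled t_{0.025,15} = 2.1314
  expect_equal(ci_to_sd(16, 1, 0, 0.95), 0.938328568, tolerance = 1e-4)
  # linearity in the interval width
  expect_equal(ci_to_sd(16, 2, 0, 0.95), 2 * ci_to_sd(16, 1, 0, 0.95))
  # monotone in n at fixed width: sqrt(n) growth dominates shrinking tcrit
  widths <- sapply(2:100, function(n) ci_to_sd(n, 1, 0, 0.95))
  expect_true(all(diff(widths) > 0))
  # round trip sd -> CI -> sd is the identity
  for (n in c(2, 5, 17, 120, 1000)) {
    sd0 <- 0.37
    half <- stats::qt(0.975, n - 1) * sd0 / sqrt(n)
    expect_equal(ci_to_sd(n, half, -half, 0.95), sd0, tolerance = 1e-10)
  }
  expect_error(ci_to_sd(1, 1, 0), "n must be")
  expect_error(ci_to_sd(16, 0, 1), "upper")
})

test_that("paired difference d uses the paradigm sign convention", {
  expect_equal(paired_difference_d(0.7, 0.7, 0.2), 0)
  # RT: grammatical 500 ms vs ungrammatical 550 ms, SD 100 -> +0.5
  expect_equal(paired_difference_d(500, 550, 100, direction = -1), 0.5)
  # looking time: longer looking to ungrammatical is learning
  expect_equal(paired_difference_d(8, 10, 2, direction = -1), 1)
  expect_error(paired_difference_d(1, 0, 0), "positive")
})

test_that("harmonize routes chance paradigms and matches the manual chain", {
  rec <- raw_study("forced_choice",
                   grammatical = data.frame(mean = 0.5, sd = 0.1, n = 20),
                   chance = 0.5)
  eff <- harmonize(rec)
  expect_equal(eff$g, 0)
  expect_equal(eff$v_g, correction_factor(19)^2 / 20)

  # compositional oracle, chain computed by hand:
  # pooled mean = (10*0.6 + 30*0.7)/40 = 0.675
  # average SD  = sqrt((9*0.01 + 29*0.04)/38) = 0.18136906
  # d = 0.175/0.18136906 = 0.96488341 ; J(39) = 1 - 3/155
  rec2 <- raw_study("accuracy_vs_chance",
                    grammatical = data.frame(mean = c(0.6, 0.7),
                                             sd = c(0.1, 0.2),
                                             n = c(10, 30)),
                    chance = 0.5)
  eff2 <- harmonize(rec2)
  expect_equal(eff2$n, 40)
  expect_equal(eff2$d, 0.9648834126463157, tolerance = 1e-10)
  expect_equal(eff2$g, 0.9462082498209031, tolerance = 1e-10)
  expect_equal(eff2$v_g, 0.0352329989594173, tolerance = 1e-10)
})

test_that("harmonize handles paired paradigms, CI-only reporting and re-signing", {
  rt <- raw_study("serial_reaction_time",
                  grammatical = data.frame(mean = 500, sd = 100, n = 24),
                  ungrammatical = data.frame(mean = 550, sd = 100, n = 24))
  eff <- harmonize(rt)
  expect_equal(eff$d, 0.5)
  expect_equal(eff$n, 24)
  expect_equal(eff$g, hedges_g(0.5, 23))

  # CI-only session converted at ingest
  half <- stats::qt(0.975, 15) * 0.2 / sqrt(16)
  ci_rec <- raw_study("yes_no",
                      grammatical = data.frame(mean = 0.62, sd = NA,
                                               ci_lower = 0.62 - half,
                                               ci_upper = 0.62 + half, n = 16),
                      chance = 0.5)
  direct <- raw_study("yes_no",
                      grammatical = data.frame(mean = 0.62, sd = 0.2, n = 16),
                      chance = 0.5)
  expect_equal(harmonize(ci_rec)$g, harmonize(direct)$g, tolerance = 1e-10)

  # re-signing flips g only, and is an involution
  look <- function(resign) {
    raw_study("looking_time",
              grammatical = data.frame(mean = 12, sd = 2, n = 15),
              ungrammatical = data.frame(mean = 10, sd = 2, n = 15),
              familiarity_resign = resign)
  }
  e0 <- harmonize(look(FALSE)); e1 <- harmonize(look(TRUE))
  expect_equal(e1$g, -e0$g)
  expect_equal(e1$v_g, e0$v_g)
  expect_equal(-(-e0$g), e0$g)
})

test_that("harmonize is invariant to the outcome scale of chance paradigms", {
  base <- raw_study("forced_choice",
                    grammatical = data.frame(mean = c(0.61, 0.66),
                                             sd = c(0.12, 0.2), n = c(14, 22)),
                    chance = 0.5)
  scaled <- raw_study("forced_choice",
                      grammatical = data.frame(mean = c(61, 66),
                                               sd = c(12, 20), n = c(14, 22)),
                      chance = 50)
  expect_equal(harmonize(scaled)$g, harmonize(base)$g, tolerance = 1e-12)
  expect_equal(harmonize(scaled)$v_g, harmonize(base)$v_g, tolerance = 1e-12)
})

test_that("invalid records are rejected with informative errors", {
  expect_error(raw_study("telepathy",
                         grammatical = data.frame(mean = 1, sd = 1, n = 5)),
               "unsupported paradigm")
  expect_error(raw_study("yes_no",
                         grammatical = data.frame(mean = 0.6, sd = 0.1, n = 10)),
               "chance")
  expect_error(raw_study("looking_time",
                         grammatical = data.frame(mean = 10, sd = 2, n = 10)),
               "ungrammatical")
  expect_error(raw_study("yes_no", grammatical = data.frame(mean = 0.6, n = 10),
                         chance = 0.5),
               "ci_lower")
})
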