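# Fixtures and independent oracles shared across test files.

# A small effect table with articles contributing 1-3 effects each.
make_effects <- function(k = 8, seed = 11, tau2_a = 0.3, tau2_s = 0.1,
                         mu = 0.8) {
  set.seed(seed)
  article <- sort(sample(paste0("A", 1:max(2, ceiling(k / 2))), k, replace = TRUE))
  u <- stats::rnorm(length(unique(article)), 0, sqrt(tau2_a))
  names(u) <- unique(article)
  n <- sample(10:40, k, replace = TRUE)
  theta <- mu + u[article] + stats::rnorm(k, 0, sqrt(tau2_s))
  v <- 1 / n + theta^2 / (2 * n)
  data.frame(article_id = article,
             study_id = paste0(article, "_", seq_len(k)),
             g = theta + stats::rnorm(k, 0, sqrt(v)),
             v_g = v, n = n, stringsAsFactors = FALSE)
}

# Dense two-stage grid search over the variance components: the independent
# oracle for the REML optimum.
grid_oracle <- function(dataset, coarse = 0.05, fine = 0.005, lim = 2) {
  ll <- function(a, s) restricted_loglik(dataset, a, s)
  grid <- expand.grid(a = seq(0, lim, by = coarse), s = seq(0, lim, by = coarse))
  vals <- mapply(ll, grid$a, grid$s)
  best <- grid[which.max(vals), ]
  fa <- seq(max(0, best$a - coarse), min(lim, best$a + coarse), by = fine)
  fs <- seq(max(0, best$s - coarse), min(lim, best$s + coarse), by = fine)
  grid2 <- expand.grid(a = fa, s = fs)
  vals2 <- mapply(ll, grid2$a, grid2$s)
  list(ll = max(c(vals, vals2)),
       par = unlist(grid2[which.max(vals2), ]),
       coarse_max = max(vals))
}
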