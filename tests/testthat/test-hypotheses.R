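test_that("rate normalization is scale-free and validates input", {
  expect_equal(normalize_rates(rep(7, 6)), rep(1, 6))
  expect_equal(normalize_rates(c(6, 0, 0, 0, 0, 0)), c(6, 0, 0, 0, 0, 0))
  set.seed(3)
  r <- rexp(6)
  expect_equal(normalize_rates(r * 17), normalize_rates(r))
  expect_error(normalize_rates(rep(0, 6)), "all-zero")
  expect_equal(sum(normalize_rates(r, method = "sum")), 1)
})

test_that("Stirling and Bell numbers follow the recurrence exactly", {
  for (n in 1:7) {
    expect_equal(stirling2(n, 1), 1)
    expect_equal(stirling2(n, n), 1)
  }
  expect_equal(stirling2(6, 3), 90)
  expect_equal(bell(6), 203)
  expect_equal(bell(7), 877)
  expect_equal(bell(6), sum(vapply(1:6, function(k) stirling2(6, k),
                                   numeric(1))))
  expect_error(stirling2(3, 5), "0 <= k <= n")
})

fake_chain <- function(R, root_p = NULL) {
  s <- as.data.frame(R)
  names(s) <- c("q01", "q02", "q10", "q12", "q20", "q21")
  s$iteration <- seq_len(nrow(s))
  if (!is.null(root_p)) {
    s$root_p0 <- root_p
    s$root_p1 <- (1 - root_p) / 2
    s$root_p2 <- (1 - root_p) / 2
  }
  s
}

test_that("pathway posterior proportions match brute-force recounts", {
  h <- pathway_hypothesis(1, 2, 0)   # direct = q10, steps q12 * q20
  ## direct rate zero, steps positive: Mi in every sample
  R <- matrix(rep(c(1, 1, 0, 2, 2, 1), 10), 10, 6, byrow = TRUE)
  res <- pathway_posterior_proportion(fake_chain(R), h)
  expect_equal(res$p_Mi_given_D, 1)
  ## all rates equal: normalized to 1, product 1, tie -> Mj
  Rt <- matrix(3, 12, 6)
  res2 <- pathway_posterior_proportion(fake_chain(Rt), h)
  expect_equal(res2$p_Mj_given_D, 1)
  expect_equal(res2$n_ties, 12)
  ## random chain against an independent recount
  set.seed(8)
  Rr <- matrix(rexp(6 * 1000), 1000, 6)
  Rr[sample(1000, 50), 3] <- 0
  res3 <- pathway_posterior_proportion(fake_chain(Rr), h)
  manual <- 0
  for (i in 1:1000) {
    rn <- Rr[i, ] / mean(Rr[i, ])
    if (rn[3] < rn[4] * rn[5]) manual <- manual + 1
  }
  expect_equal(res3$p_Mi_given_D, manual / 1000)
  expect_equal(res3$n_samples, 1000)
  ## all-zero samples are excluded and counted
  Rz <- rbind(Rr[1:10, ], matrix(0, 3, 6))
  res4 <- pathway_posterior_proportion(fake_chain(Rz), h)
  expect_equal(res4$n_excluded, 3)
  expect_equal(res4$n_samples, 10)
})

test_that("pathway proportions are invariant to block thinning", {
  h <- pathway_hypothesis(0, 1, 2)
  set.seed(9)
  block <- matrix(rexp(6 * 20), 20, 6)
  R <- do.call(rbind, rep(list(block), 5))
  a <- pathway_posterior_proportion(fake_chain(R), h)
  b <- pathway_posterior_proportion(fake_chain(block), h)
  expect_equal(a$p_Mi_given_D, b$p_Mi_given_D)
})

test_that("pathway prior Monte Carlo is consistent and well-formed", {
  h <- pathway_hypothesis(1, 2, 0)
  pr <- prior_spec(mean_bounds = c(0.1, 10))
  a <- pathway_prior(h, pr, n_draws = 2e4, seed = 1)
  b <- pathway_prior(h, pr, n_draws = 2e4, seed = 2)
  expect_equal(a$p_Mi + a$p_Mj, 1)
  expect_gt(a$se, 0)
  ## two seeds agree within 4 combined standard errors
  expect_lt(abs(a$p_Mi - b$p_Mi), 4 * sqrt(a$se^2 + b$se^2))
  ## model-space counts are computed, not hard-coded
  expect_equal(a$n_models, 877)
  expect_equal(pathway_prior(h, pr, zero_class = FALSE, n_draws = 1e4,
                             seed = 1)$n_models, 203)
  expect_error(pathway_prior(h, pr, n_draws = 100), ">= 1e4")
})

test_that("ancestral-dominance posterior proportions recount correctly", {
  ch <- fake_chain(matrix(1, 5, 6), root_p = rep(0.6, 5))
  r <- root_posterior_proportion(ch, 0)
  expect_equal(r$p_Mi_given_D, 1)
  ch2 <- fake_chain(matrix(1, 5, 6), root_p = rep(1 / 3, 5))
  r2 <- root_posterior_proportion(ch2, 0)
  expect_equal(r2$p_Mj_given_D, 1)
  set.seed(13)
  p <- runif(200)
  ch3 <- fake_chain(matrix(1, 200, 6), root_p = p)
  r3 <- root_posterior_proportion(ch3, 0)
  expect_equal(r3$p_Mi_given_D, mean(p > 0.5))
  expect_error(root_posterior_proportion(fake_chain(matrix(1, 5, 6)), 0),
               "marginals")
})

test_that("simplex prior for dominance is exact and matches Monte Carlo", {
  r <- root_prior_probability(0, 3)
  expect_identical(r$p_Mi, 0.25)
  expect_identical(r$p_Mj, 0.75)
  expect_equal(root_prior_probability(1, 2)$p_Mi, 0.5)
  ## MC integration over the uniform simplex (scaled-down here; the full
  ## 1e6-draw check runs in the acceptance suite)
  set.seed(21)
  n <- 2e5
  e <- matrix(rexp(3 * n), n, 3)
  x <- e / rowSums(e)
  mc <- mean(x[, 1] > 0.5)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(mc - 0.25), 3 * se)
  expect_error(root_prior_probability(5, 3), "invalid state")
})

test_that("Bayes factors follow the posterior-to-prior odds formula", {
  expect_equal(bayes_factor(0.5, 0.5, 0.5, 0.5)$bayes_factor, 1)
  expect_equal(bayes_factor(0.9, 0.1, 0.25, 0.75)$bayes_factor, 27)
  expect_equal(bayes_factor(0.2, 0.8, 0.5, 0.5)$bayes_factor, 0.25)
  ## reciprocal identity
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.05, 0.95); p <- runif(1, 0.05, 0.95)
    bf1 <- bayes_factor(a, 1 - a, p, 1 - p)$bayes_factor
    bf2 <- bayes_factor(1 - a, a, 1 - p, p)$bayes_factor
    expect_equal(bf1 * bf2, 1, tolerance = 1e-12)
  }
  expect_true(is.infinite(bayes_factor(1, 0, 0.25, 0.75)$bayes_factor))
  expect_error(bayes_factor(0, 0, 0.5, 0.5), "both posterior")
  expect_error(bayes_factor(0.5, 0.5, 0, 1), "positive")
})

test_that("support classification uses the 3 and 12 thresholds", {
  expect_equal(classify_support(25.88), "strong")
  expect_equal(classify_support(16.68), "strong")
  expect_equal(classify_support(8.53), "positive")
  expect_equal(classify_support(3.10), "positive")
  expect_equal(classify_support(3), "positive")
  expect_equal(classify_support(12), "positive")
  expect_equal(classify_support(12.01), "strong")
  expect_equal(classify_support(1.51), "none")
  expect_equal(classify_support(0.75), "none")
  expect_error(classify_support(-1), ">= 0")
})
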