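make_prior <- function() prior_spec(mean_bounds = c(0.1, 10))

single_class_partition <- function(value, zero_class = TRUE) {
  if (zero_class)
    rjmk:::new_partition(list(1:6, integer(0)), c(value, 0), zero = 2L)
  else
    rjmk:::new_partition(list(1:6), value)
}

test_that("log prior combines model, value, and hyperprior terms", {
  pr <- make_prior()
  hyper <- c(mean = 2, shape = 4)
  p <- single_class_partition(1.7, zero_class = FALSE)
  expected <- -log(bell(6)) - log(10 - 0.1) - log(20 - 0.5) +
    dgamma(1.7, shape = 4, rate = 2, log = TRUE)
  expect_equal(rj_log_prior(p, hyper, pr, zero_class = FALSE), expected)
  ## with the zero class the model space grows to bell(7) = 877
  pz <- single_class_partition(1.7, zero_class = TRUE)
  expect_equal(rj_log_prior(pz, hyper, pr, zero_class = TRUE),
               expected + log(bell(6)) - log(bell(7)))
  ## a nonzero value in the zero class is outside the support
  bad <- rjmk:::new_partition(list(1:5, 6L), c(1.7, 0.5), zero = 2L)
  expect_equal(rj_log_prior(bad, hyper, pr, TRUE), -Inf)
  ## hyperparameters outside the uniform bounds
  expect_equal(rj_log_prior(p, c(mean = 100, shape = 4), pr, FALSE), -Inf)
  ## gamma-mode value maximizes the value term over values
  mode <- (4 - 1) / 2
  lps <- vapply(c(mode, 0.1, 1, 5),
                function(v) rj_log_prior(single_class_partition(v, FALSE),
                                         hyper, pr, FALSE), numeric(1))
  expect_equal(which.max(lps), 1L)
})

test_that("proposal moves have correct mechanics", {
  pr <- make_prior()
  hyper <- c(mean = 1, shape = 2)
  w <- c(rate_scale = .6, split = .15, merge = .15, zero = .05, hyper = .05)
  ## rate-scale: multiplier Jacobian
  set.seed(1)
  p <- single_class_partition(2, zero_class = FALSE)
  prop <- rj_propose(p, hyper, "rate_scale", pr, w)
  m <- prop$partition$values[1] / 2
  expect_equal(prop$log_hastings, log(m))
  ## merge on a single-class partition is a forced rejection
  expect_equal(rj_propose(p, hyper, "merge", pr, w)$log_hastings, -Inf)
  ## split on an all-singleton partition is a forced rejection
  ps <- rjmk:::new_partition(as.list(1:6), rexp(6))
  expect_equal(rj_propose(ps, hyper, "split", pr, w)$log_hastings, -Inf)
  ## split produces a valid two-block partition; a merge can restore it
  set.seed(7)
  prop2 <- rj_propose(p, hyper, "split", pr, w)
  expect_equal(length(prop2$partition$blocks), 2)
  expect_setequal(unlist(prop2$partition$blocks), 1:6)
  merged <- rj_propose(prop2$partition, hyper, "merge", pr, w)
  expect_equal(sort(unlist(merged$partition$blocks[1])), 1:6)
  ## expanded rates respect the partition
  r <- expand_rates(prop2$partition)
  expect_equal(length(unique(r)), 2)
})

test_that("chains are deterministic, sized correctly, and well-tuned", {
  tr <- blowfly_tree_synthetic()
  pm <- prune_to_ingroup(tr, blowfly_traits())
  tv <- tip_likelihood_matrix(pm$matrix, "trophic")
  pr <- prior_spec(mean_bounds = c(0.5, 50))
  cfg <- mcmc_config(iterations = 3000, sample_interval = 10, burn_in = 600,
                     seed = 11)
  ch1 <- run_chain(pm$tree, tv, pr, cfg)
  ch2 <- run_chain(pm$tree, tv, pr, cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_equal(nrow(ch1$samples), (3000 - 600) %/% 10)
  expect_true(all(is.finite(ch1$samples$log_likelihood)))
  expect_gte(ch1$acceptance[["rate_scale"]], 0.10)
  expect_lte(ch1$acceptance[["rate_scale"]], 0.80)
  ## focal-node marginals are recorded and normalized
  probs <- as.matrix(ch1$samples[, c("root_p0", "root_p1", "root_p2")])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("chain logs round-trip through TSV", {
  tr <- simulate_yule_tree(8, seed = 3)
  tv <- sim_tipvec(tr, build_generator(rep(1, 6)), 0, seed = 4)
  cfg <- mcmc_config(iterations = 800, sample_interval = 5, burn_in = 100,
                     seed = 2)
  ch <- run_chain(tr, tv, make_prior(), cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chain_log(ch, f)
  back <- read_chain_log(f)
  expect_equal(back$q01, ch$samples$q01, tolerance = 1e-12)
  expect_equal(back$partition, ch$samples$partition)
})

test_that("no-data chains reproduce the partition prior (scaled run)", {
  ## likelihood disabled via all-missing tips; compare sampled class-count
  ## frequencies to S(6,k)/bell(6) with the zero class off
  tr <- simulate_yule_tree(4, seed = 1)
  tv <- matrix(1, 4, 3, dimnames = list(tr$tip.label, NULL))
  cfg <- mcmc_config(iterations = 2.5e5, sample_interval = 20,
                     burn_in = 1e4, seed = 5, zero_class = FALSE)
  ch <- run_chain(tr, tv, make_prior(), cfg, focal_node = NULL)
  kk <- vapply(strsplit(ch$samples$partition, ""),
               function(s) length(unique(s)), integer(1))
  obs <- tabulate(kk, 6)
  expected <- vapply(1:6, function(k) stirling2(6, k), numeric(1)) / bell(6)
  p <- suppressWarnings(chisq.test(obs, p = expected)$p.value)
  expect_gt(p, 0.01)
})

test_that("effective sample size matches closed forms", {
  set.seed(42)
  n <- 4000
  fake <- function(x) {
    s <- data.frame(iteration = seq_len(n), log_likelihood = x)
    for (lab in c("q01", "q02", "q10", "q12", "q20", "q21")) s[[lab]] <- x
    s
  }
  ## i.i.d. stream: ESS about n
  ess <- effective_samples(fake(rnorm(n)))
  expect_equal(unname(ess[["log_likelihood"]]), n, tolerance = 0.2)
  ## constant (perfectly correlated) stream: ESS 1
  expect_equal(unname(effective_samples(fake(rep(3, n)))[["q01"]]), 1)
  ## AR(1) with known rho: ESS about n (1 - rho) / (1 + rho)
  rho <- 0.6
  x <- as.numeric(arima.sim(list(ar = rho), n))
  ess_ar <- effective_samples(fake(x))[["q01"]]
  expect_equal(unname(ess_ar), n * (1 - rho) / (1 + rho), tolerance = 0.25)
  expect_error(effective_samples(fake(rnorm(5))[1:5, ]), "too short")
})
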