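## Posterior-proportion Bayes-factor tests: (a) stepping-stone transition
## pathways on normalized rates, with prior probabilities obtained by exact
## model-space counting (Stirling/Bell numbers) plus Monte-Carlo over rate
## values; (b) ancestral-state dominance, with the uniform-simplex
## (triangle-area) prior. BF_ij = [P(Mi|D)/P(Mj|D)] * [P(Mj)/P(Mi)].

#' Stirling numbers of the second kind
#'
#' `S(n, k)`: number of partitions of n labeled items into k non-empty
#' blocks, via the recurrence `S(n,k) = k S(n-1,k) + S(n-1,k-1)`.
#'
#' @param n,k Non-negative integers, `0 <= k <= n`.
#' @return Exact integer count (as numeric for large values).
#' @export
stirling2 <- function(n, k) {
  if (n < 0 || k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  if (n == 0) return(as.numeric(k == 0))
  S <- matrix(0, n + 1, n + 1)
  S[1, 1] <- 1  # S(0,0)
  for (nn in 1:n) for (kk in 1:nn)
    S[nn + 1, kk + 1] <- kk * S[nn, kk + 1] + S[nn, kk]
  S[n + 1, k + 1]
}

#' Bell numbers
#'
#' `bell(n) = sum_k S(n, k)`: total number of set partitions of n items.
#' @param n Non-negative integer.
#' @return Exact count.
#' @export
bell <- local({
  cache <- c()
  function(n) {
    if (n < 0) stop("n must be >= 0", call. = FALSE)
    if (n == 0) return(1)
    key <- as.character(n)
    if (is.null(cache[[key]]))
      cache[[key]] <<- sum(vapply(0:n, function(k) stirling2(n, k), numeric(1)))
    cache[[key]]
  }
})

#' Normalize a vector of six transition rates
#'
#' Default: divide by the arithmetic mean of the six, so normalized rates
#' average 1 and products of normalized rates are comparable with single
#' rates. Alternatives: geometric mean of the positive rates, or sum-to-one.
#'
#' @param rates Numeric vector of 6 non-negative rates.
#' @param method `"mean"` (default), `"geometric"`, or `"sum"`.
#' @return Normalized rates; all-zero input is an error (callers exclude
#'   and log such samples).
#' @export
normalize_rates <- function(rates, method = c("mean", "geometric", "sum")) {
  method <- match.arg(method)
  rates <- as.numeric(rates)
  if (length(rates) != 6L || anyNA(rates) || any(rates < 0))
    stop("need 6 non-negative rates", call. = FALSE)
  if (all(rates == 0))
    stop("normalization undefined for all-zero rates", call. = FALSE)
  div <- switch(method,
    mean = mean(rates),
    geometric = exp(mean(log(rates[rates > 0]))),
    sum = sum(rates))
  rates / div
}

#' Pathway hypothesis: origin -> intermediate -> terminal
#'
#' Mi: the direct normalized rate origin->terminal is LOWER than the product
#' of the two stepping-stone normalized rates (origin->intermediate times
#' intermediate->terminal). Mj: equal or greater.
#'
#' @param origin,intermediate,terminal Distinct state indices (0-based).
#' @return A `pathway_hypothesis` list.
#' @export
pathway_hypothesis <- function(origin, intermediate, terminal) {
  s <- c(origin, intermediate, terminal)
  if (length(unique(s)) != 3L || !all(s %in% 0:2))
    stop("origin, intermediate, terminal must be distinct state indices 0..2",
         call. = FALSE)
  structure(list(origin = origin, intermediate = intermediate,
                 terminal = terminal), class = "pathway_hypothesis")
}

rate_label <- function(i, j) paste0("q", i, j)

#' Posterior proportions for a pathway hypothesis
#'
#' Per posterior sample, normalized rates are computed and the inequality
#' `q'[i->k] < q'[i->j] * q'[j->k]` evaluated. Ties (including 0 vs 0)
#' count to Mj. Samples with all six rates zero are excluded and counted.
#'
#' @param chain An `rj_chain`, its samples data frame, or a chain log read
#'   by [read_chain_log()].
#' @param h A [pathway_hypothesis()].
#' @param method Normalization method, see [normalize_rates()].
#' @return List: `p_Mi_given_D`, `p_Mj_given_D`, `n_ties`, `n_samples`
#'   (used), `n_excluded` (all-zero samples).
#' @export
pathway_posterior_proportion <- function(chain, h, method = "mean") {
  samples <- if (inherits(chain, "rj_chain")) chain$samples else chain
  if (!nrow(samples)) stop("empty chain", call. = FALSE)
  R <- as.matrix(samples[, RATE_LABELS])
  keep <- rowSums(R) > 0
  n_excl <- sum(!keep)
  R <- R[keep, , drop = FALSE]
  if (!nrow(R)) stop("all samples excluded (all-zero rates)", call. = FALSE)
  Rn <- t(apply(R, 1, normalize_rates, method = method))
  colnames(Rn) <- RATE_LABELS
  direct <- Rn[, rate_label(h$origin, h$terminal)]
  step <- Rn[, rate_label(h$origin, h$intermediate)] *
    Rn[, rate_label(h$intermediate, h$terminal)]
  mi <- direct < step
  ties <- direct == step
  list(p_Mi_given_D = mean(mi), p_Mj_given_D = mean(!mi),
       n_ties = sum(ties), n_samples = nrow(R), n_excluded = n_excl)
}

## enumerate all set partitions of n labeled items as restricted growth
## strings; rows = partitions, entries = block index of each item
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxb) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (b in seq_len(maxb + 1L)) rec(c(assign, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  do.call(rbind, out)
}

#' Monte-Carlo prior probability of a pathway hypothesis
#'
#' The model space is counted exactly (partitions of the six rate labels,
#' with or without the distinguished zero class; `bell(6) = 203` or
#' `bell(7) = 877` models, each equally likely). A model is drawn uniformly,
#' class values are drawn from the gamma prior under its uniform hyperprior,
#' rates are normalized, and the inequality evaluated; all-zero draws are
#' excluded as in the posterior. Ties count to Mj.
#'
#' @param h A [pathway_hypothesis()].
#' @param priors A [prior_spec()].
#' @param zero_class Include the zero class in the model space (default
#'   `TRUE`).
#' @param n_draws Monte-Carlo draws (default `1e5`, minimum `1e4`).
#' @param seed RNG seed.
#' @param method Normalization method.
#' @return List: `p_Mi`, `p_Mj`, `se` (binomial standard error of `p_Mi`),
#'   `n_draws`, `n_excluded`, `n_models`.
#' @export
pathway_prior <- function(h, priors, zero_class = TRUE, n_draws = 1e5,
                          seed = 1L, method = "mean") {
  if (n_draws < 1e4) stop("n_draws must be >= 1e4", call. = FALSE)
  n_items <- if (zero_class) 7L else 6L
  parts <- enumerate_partitions(n_items)   # item 7 = phantom zero marker
  n_models <- nrow(parts)
  withr_seed(seed, {
    idx <- sample.int(n_models, n_draws, replace = TRUE)
    mean_h <- runif(n_draws, priors$mean_bounds[1], priors$mean_bounds[2])
    shape_h <- runif(n_draws, priors$shape_bounds[1], priors$shape_bounds[2])
    mi <- logical(n_draws); ok <- logical(n_draws)
    for (d in seq_len(n_draws)) {
      asg <- parts[idx[d], ]
      zero_block <- if (zero_class) asg[7L] else 0L
      lab_asg <- asg[1:6]
      blocks <- unique(lab_asg)
      vals <- setNames(rgamma(length(blocks), shape = shape_h[d],
                              rate = shape_h[d] / mean_h[d]), blocks)
      if (zero_class) vals[as.character(zero_block)] <- 0
      rates <- unname(vals[as.character(lab_asg)])
      if (all(rates == 0)) next
      ok[d] <- TRUE
      rn <- normalize_rates(rates, method = method)
      names(rn) <- RATE_LABELS
      mi[d] <- rn[rate_label(h$origin, h$terminal)] <
        rn[rate_label(h$origin, h$intermediate)] *
        rn[rate_label(h$intermediate, h$terminal)]
    }
    n_used <- sum(ok)
    p_mi <- sum(mi[ok]) / n_used
    list(p_Mi = p_mi, p_Mj = 1 - p_mi,
         se = sqrt(p_mi * (1 - p_mi) / n_used),
         n_draws = n_used, n_excluded = n_draws - n_used,
         n_models = n_models)
  })
}

#' Posterior proportions for ancestral-state dominance
#'
#' Per sample, Mi holds when the focal-node probability of state `s`
#' exceeds the combined probability of the other two states, i.e.
#' `p(s) > 1/2`; ties count to Mj.
#'
#' @param chain An `rj_chain` or samples data frame carrying focal-node
#'   probability columns `root_p0..root_p2`.
#' @param state Focal state index (0-based).
#' @return List: `p_Mi_given_D`, `p_Mj_given_D`, `n_ties`, `n_samples`.
#' @export
root_posterior_proportion <- function(chain, state) {
  samples <- if (inherits(chain, "rj_chain")) chain$samples else chain
  col <- paste0("root_p", state)
  if (!col %in% names(samples) || anyNA(samples[[col]]))
    stop("chain lacks focal-node marginals", call. = FALSE)
  p <- samples[[col]]
  mi <- p > 0.5
  list(p_Mi_given_D = mean(mi), p_Mj_given_D = mean(!mi),
       n_ties = sum(p == 0.5), n_samples = length(p))
}

#' Prior probability of ancestral-state dominance
#'
#' Under a uniform distribution on the probability simplex (the triangle
#' where the three ancestral probabilities sum to 1), the region where one
#' coordinate exceeds the sum of the others is a scaled sub-simplex with
#' factor 1/2 per free dimension: `p_Mi = (1/2)^(n_states - 1)` — 1/4 for
#' three states.
#'
#' @param state Focal state index (unused beyond validation; all states are
#'   exchangeable under the uniform simplex).
#' @param n_states Number of states (default 3).
#' @return List: `p_Mi`, `p_Mj`.
#' @export
root_prior_probability <- function(state = 0, n_states = 3) {
  if (n_states < 2) stop("n_states must be >= 2", call. = FALSE)
  if (!state %in% (seq_len(n_states) - 1L))
    stop("invalid state index", call. = FALSE)
  p <- 0.5^(n_states - 1)
  list(p_Mi = p, p_Mj = 1 - p)
}

#' Bayes factor from posterior and prior model proportions
#'
#' `BF_ij = [P(Mi|D) / P(Mj|D)] * [P(Mj) / P(Mi)]`.
#'
#' @param p_mi_given_d,p_mj_given_d Posterior proportions in `[0, 1]`.
#' @param p_mi,p_mj Prior probabilities in `(0, 1]`.
#' @return A `hypothesis_result` list: the four inputs, `bayes_factor`
#'   (`Inf` flagged when `P(Mj|D) = 0`), and `support_category`.
#' @export
bayes_factor <- function(p_mi_given_d, p_mj_given_d, p_mi, p_mj) {
  vals <- c(p_mi_given_d, p_mj_given_d, p_mi, p_mj)
  if (anyNA(vals) || any(vals < 0) || any(vals > 1))
    stop("all inputs must be in [0, 1]", call. = FALSE)
  if (p_mi <= 0 || p_mj <= 0)
    stop("prior probabilities must be positive", call. = FALSE)
  if (p_mi_given_d == 0 && p_mj_given_d == 0)
    stop("both posterior proportions are zero", call. = FALSE)
  bf <- if (p_mj_given_d == 0) Inf
        else (p_mi_given_d / p_mj_given_d) * (p_mj / p_mi)
  structure(list(p_Mi_given_D = p_mi_given_d, p_Mj_given_D = p_mj_given_d,
                 p_Mi = p_mi, p_Mj = p_mj, bayes_factor = bf,
                 support_category = classify_support(bf)),
            class = "hypothesis_result")
}

#' Classify Bayes-factor support
#'
#' Values between 3 and 12 count as positive support, above 12 as strong
#' positive support, below 3 as no support.
#'
#' @param bf Non-negative Bayes factor.
#' @return `"none"`, `"positive"`, or `"strong"`.
#' @export
classify_support <- function(bf) {
  if (is.na(bf) || bf < 0) stop("bf must be >= 0", call. = FALSE)
  if (bf > 12) "strong" else if (bf >= 3) "positive" else "none"
}

#' @export
print.hypothesis_result <- function(x, ...) {
  cat(sprintf("BF = %.4g  [P(Mi|D)=%.4g, P(Mj|D)=%.4g, P(Mi)=%.4g, P(Mj)=%.4g]\n",
              x$bayes_factor, x$p_Mi_given_D, x$p_Mj_given_D, x$p_Mi, x$p_Mj))
  cat("support:", x$support_category, "\n")
  invisible(x)
}
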