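## Mk-model machinery for a 3-state character: generator matrices,
## transition probabilities, pruning likelihood, marginal ancestral states,
## and maximum-likelihood rate estimation used for prior elicitation.

## fixed rate-label order; q01 means state 0 -> state 1 (0-based indices)
RATE_LABELS <- c("q01", "q02", "q10", "q12", "q20", "q21")
RATE_FROM <- c(1L, 1L, 2L, 2L, 3L, 3L)  # 1-based row
RATE_TO   <- c(2L, 3L, 1L, 3L, 1L, 2L)  # 1-based col

#' Build a 3-state generator (Q) matrix from six off-diagonal rates
#'
#' @param rates Numeric vector of 6 non-negative rates, in the fixed label
#'   order `q01, q02, q10, q12, q20, q21` (`qij` = instantaneous rate from
#'   state index i to j, 0-based). Names, when present, are checked.
#' @return 3x3 matrix with rows summing to zero.
#' @export
build_generator <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) != 6L) stop("need exactly 6 rates", call. = FALSE)
  if (anyNA(rates) || any(rates < 0))
    stop("rates must be non-negative and finite", call. = FALSE)
  Q <- matrix(0, 3, 3)
  for (i in seq_len(6L)) Q[RATE_FROM[i], RATE_TO[i]] <- rates[i]
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(0:2, 0:2)
  Q
}

#' Extract the six off-diagonal rates from a generator matrix
#' @param Q 3x3 generator matrix.
#' @return Named numeric vector in the fixed label order.
#' @export
generator_rates <- function(Q) {
  setNames(Q[cbind(RATE_FROM, RATE_TO)], RATE_LABELS)
}

#' Transition probability matrix P = exp(Qt)
#'
#' Computed by scaling-and-squaring with Pade approximation; robust for
#' non-symmetric generators including zero rates.
#'
#' @param Q 3x3 generator matrix.
#' @param t Branch length (time), `t >= 0`.
#' @return 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  .cpp_transition_matrix(unname(Q), t)
}

## prepare a tree + tip matrix for the C++ kernels
prune_inputs <- function(tree, tip_vectors) {
  if (is.null(rownames(tip_vectors)))
    stop("tip_vectors must have species row names", call. = FALSE)
  rownames(tip_vectors) <- canonical_species(rownames(tip_vectors))
  miss <- setdiff(tree$tip.label, rownames(tip_vectors))
  if (length(miss))
    stop("no tip vector for: ", paste(miss, collapse = ", "), call. = FALSE)
  tv <- tip_vectors[tree$tip.label, , drop = FALSE]
  if (anyNA(tv)) stop("NaN/NA in tip vectors", call. = FALSE)
  tp <- ape::reorder.phylo(tree, "postorder")
  list(edge = tp$edge, len = tp$edge.length, tipvec = unname(tv))
}

#' Log-likelihood of tip data under the Mk model (Felsenstein pruning)
#'
#' Conditional likelihoods are propagated postorder with per-node rescaling
#' (factors accumulated in log space) to prevent underflow on large trees.
#'
#' @param tree Rooted `phylo`.
#' @param tip_vectors Species x 3 matrix of tip likelihood vectors (row
#'   names = tip labels); indicator rows for observed states, all-ones for
#'   missing.
#' @param Q 3x3 generator matrix.
#' @param pi Root prior over the 3 states (default uniform).
#' @return Log-probability (`-Inf` when the likelihood is exactly zero).
#' @export
prune_log_likelihood <- function(tree, tip_vectors, Q,
                                 pi = rep(1 / 3, 3)) {
  if (abs(sum(pi) - 1) > 1e-9 || any(pi < 0))
    stop("pi must be a probability vector", call. = FALSE)
  if (anyNA(Q)) stop("NaN in Q", call. = FALSE)
  pin <- prune_inputs(tree, tip_vectors)
  .cpp_prune_loglik(pin$edge, pin$len, pin$tipvec, unname(Q), pi)
}

#' Marginal ancestral-state probabilities at every node
#'
#' Standard two-pass (outside-inside) algorithm; the root marginal is
#' proportional to `pi * L_root`.
#'
#' @inheritParams prune_log_likelihood
#' @return Matrix `(Ntip + Nnode) x 3` in ape node numbering, rows summing
#'   to 1. Tip rows are posteriors too (informative for missing tips).
#' @export
node_marginals <- function(tree, tip_vectors, Q, pi = rep(1 / 3, 3)) {
  pin <- prune_inputs(tree, tip_vectors)
  m <- .cpp_node_marginals(pin$edge, pin$len, pin$tipvec, unname(Q), pi)
  colnames(m) <- colnames(tip_vectors)
  m
}

#' Maximum-likelihood estimation of the six transition rates
#'
#' Box-constrained quasi-Newton optimization on log-rates with multiple
#' random restarts. Bounds default to `[1e-8, 100 / mean(branch length)]`,
#' scale-aware for the tree at hand.
#'
#' @inheritParams prune_log_likelihood
#' @param n_restarts Number of random restarts (default 10).
#' @param rate_min,rate_max Box constraints on each rate.
#' @param seed Integer seed for the restart draws.
#' @return List: `rates` (named 6-vector), `log_likelihood`, `convergence`
#'   (0 = success for the best start), `Q`.
#' @export
ml_estimate_rates <- function(tree, tip_vectors, pi = rep(1 / 3, 3),
                              n_restarts = 10, rate_min = 1e-8,
                              rate_max = NULL, seed = 1L) {
  pin <- prune_inputs(tree, tip_vectors)
  if (sum(rowSums(pin$tipvec) < 3) < 2)
    stop("need at least 2 tips with non-missing data", call. = FALSE)
  if (is.null(rate_max)) rate_max <- 100 / mean(pin$len[pin$len > 0])
  nll <- function(lr) {
    ll <- .cpp_prune_loglik(pin$edge, pin$len, pin$tipvec,
                            unname(build_generator(exp(lr))), pi)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lo <- log(rate_min); hi <- log(rate_max)
  starts <- withr_seed(seed, {
    s <- matrix(runif(6 * n_restarts, log(0.1), log(10)), ncol = 6)
    s[1, ] <- 0  # deterministic first start at rate 1
    s
  })
  starts <- pmin(pmax(starts, lo), hi)
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[r, ], nll, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed in all restarts", call. = FALSE)
  rates <- setNames(exp(best$par), RATE_LABELS)
  list(rates = rates, log_likelihood = -best$value,
       convergence = best$convergence, Q = build_generator(rates))
}

## evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
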