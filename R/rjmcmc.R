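## Reversible-jump MCMC over transition-rate values and rate-class
## partitions. The model space is the set of partitions of the six rate
## labels into shared-value classes, optionally with one distinguished
## (possibly empty) zero class; every model carries equal prior mass.
## Class values get a gamma prior whose mean and shape follow uniform
## hyperpriors.

#' Prior specification for the rjMCMC sampler
#'
#' Gamma prior on class rate values; the gamma mean and shape each follow a
#' uniform hyperprior. Default mean bounds span the maximum-likelihood mean
#' rate by a factor of ten in each direction (see [elicit_priors()]);
#' default shape bounds are `[0.5, 20]`.
#'
#' @param mean_bounds Length-2 positive increasing vector for the gamma mean.
#' @param shape_bounds Length-2 positive increasing vector for the gamma
#'   shape.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(mean_bounds = c(0.1, 10), shape_bounds = c(0.5, 20)) {
  stopifnot(length(mean_bounds) == 2L, length(shape_bounds) == 2L)
  if (any(c(mean_bounds, shape_bounds) <= 0) ||
      mean_bounds[1] >= mean_bounds[2] || shape_bounds[1] >= shape_bounds[2])
    stop("bounds must be positive with lower < upper", call. = FALSE)
  structure(list(mean_bounds = as.numeric(mean_bounds),
                 shape_bounds = as.numeric(shape_bounds)),
            class = "prior_spec")
}

#' Elicit hyperprior bounds from a maximum-likelihood fit
#'
#' Runs [ml_estimate_rates()] and centres the gamma-mean hyperprior on the
#' mean of the six ML rates, spanning one order of magnitude either side.
#'
#' @inheritParams ml_estimate_rates
#' @return A [prior_spec()].
#' @export
elicit_priors <- function(tree, tip_vectors, pi = rep(1 / 3, 3), seed = 1L) {
  fit <- ml_estimate_rates(tree, tip_vectors, pi = pi, seed = seed)
  ml_mean <- mean(fit$rates)
  ml_mean <- max(ml_mean, 1e-6)  # guard degenerate all-at-lower-bound fits
  prior_spec(mean_bounds = c(ml_mean / 10, ml_mean * 10))
}

#' MCMC run configuration
#'
#' The default schedule is a desk-scale reduction of a 110-million-iteration
#' production schedule (sample every 1000, ~9% burn-in): 1.1 million
#' iterations, sampling every 100, with the first 10% discarded.
#'
#' @param iterations Total iterations.
#' @param sample_interval Record a sample every this many post-burn-in
#'   iterations.
#' @param burn_in Iterations discarded before sampling starts.
#' @param seed Integer RNG seed; runs are deterministic given the seed.
#' @param move_weights Named weights for the move mixture
#'   (`rate_scale`, `split`, `merge`, `zero`, `hyper`). The `zero` weight is
#'   ignored when `zero_class = FALSE`.
#' @param zero_class Whether the distinguished zero class is part of the
#'   model space (the default, giving `bell(7) = 877` models; `bell(6) =
#'   203` without it).
#' @param tune Auto-tune the rate-scale step size during burn-in only.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(iterations = 1.1e6, sample_interval = 100,
                        burn_in = floor(iterations / 10), seed = 1L,
                        move_weights = c(rate_scale = 0.60, split = 0.15,
                                         merge = 0.15, zero = 0.05,
                                         hyper = 0.05),
                        zero_class = TRUE, tune = TRUE) {
  stopifnot(burn_in < iterations, sample_interval >= 1)
  req <- c("rate_scale", "split", "merge", "zero", "hyper")
  if (!all(req %in% names(move_weights)))
    stop("move_weights must name: ", paste(req, collapse = ", "), call. = FALSE)
  if (!zero_class) move_weights["zero"] <- 0
  structure(list(iterations = as.integer(iterations),
                 sample_interval = as.integer(sample_interval),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 move_weights = move_weights / sum(move_weights),
                 zero_class = isTRUE(zero_class), tune = isTRUE(tune)),
            class = "mcmc_config")
}

## ---- partition state ------------------------------------------------------
## blocks: list of integer vectors over rate labels 1..6 (zero block may be
## empty); zero: index into blocks of the zero block, or NA; values: one
## non-negative value per block (0 for the zero block).

new_partition <- function(blocks, values, zero = NA_integer_) {
  structure(list(blocks = blocks, values = values, zero = zero),
            class = "rate_partition")
}

#' Expand a rate partition to the six per-label rates
#' @param partition A `rate_partition`.
#' @return Named numeric vector in the fixed label order.
#' @export
expand_rates <- function(partition) {
  r <- numeric(6)
  for (b in seq_along(partition$blocks))
    r[partition$blocks[[b]]] <- partition$values[b]
  setNames(r, RATE_LABELS)
}

#' Partition signature string
#'
#' One letter per rate label in the fixed order; classes lettered by first
#' appearance, the zero class printed as `Z`.
#' @param partition A `rate_partition`.
#' @return Single string, e.g. `"AABZCA"`.
#' @export
partition_signature <- function(partition) {
  lab <- character(6)
  nxt <- 1L
  for (b in seq_along(partition$blocks)) {
    ch <- if (!is.na(partition$zero) && b == partition$zero) "Z" else NA
    for (i in sort(partition$blocks[[b]])) lab[i] <- ch %||% ""
  }
  ## letter assignment must follow label order, not block order
  seen <- list()
  for (i in 1:6) {
    if (lab[i] == "Z") next
    b <- block_of(partition, i)
    key <- as.character(b)
    if (is.null(seen[[key]])) {
      seen[[key]] <- LETTERS[nxt]
      nxt <- nxt + 1L
    }
    lab[i] <- seen[[key]]
  }
  paste(lab, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

block_of <- function(partition, label) {
  for (b in seq_along(partition$blocks))
    if (label %in% partition$blocks[[b]]) return(b)
  stop("label not in partition")
}

## effective size for split counting: the zero block carries a phantom
## element marking it, so an empty zero block has effective size 1
eff_size <- function(partition, b) {
  length(partition$blocks[[b]]) +
    (!is.na(partition$zero) && b == partition$zero)
}

n_bipartitions <- function(partition, b) {
  k <- length(partition$blocks[[b]])
  if (!is.na(partition$zero) && b == partition$zero) 2^k - 1
  else 2^(k - 1) - 1
}

#' Log prior density of a sampler state
#'
#' Sum of (i) the uniform prior over the model space (`-log bell(7)` with
#' the zero class, `-log bell(6)` without), (ii) gamma log-densities of the
#' non-zero class values at the current hyperparameters, and (iii) the
#' uniform hyperprior log-densities.
#'
#' @param partition A `rate_partition`.
#' @param hyper Named numeric: `mean`, `shape`.
#' @param priors A [prior_spec()].
#' @param zero_class Whether the model space includes the zero class.
#' @return Log-density (`-Inf` outside the support).
#' @export
rj_log_prior <- function(partition, hyper, priors, zero_class = TRUE) {
  mb <- priors$mean_bounds; sb <- priors$shape_bounds
  if (hyper[["mean"]] < mb[1] || hyper[["mean"]] > mb[2] ||
      hyper[["shape"]] < sb[1] || hyper[["shape"]] > sb[2]) return(-Inf)
  n_models <- if (zero_class) bell(7) else bell(6)
  lp <- -log(n_models) - log(mb[2] - mb[1]) - log(sb[2] - sb[1])
  shape <- hyper[["shape"]]; rate <- shape / hyper[["mean"]]
  for (b in seq_along(partition$blocks)) {
    if (!is.na(partition$zero) && b == partition$zero) {
      if (partition$values[b] != 0) return(-Inf)
    } else {
      v <- partition$values[b]
      if (!is.finite(v) || v <= 0) return(-Inf)
      lp <- lp + dgamma(v, shape = shape, rate = rate, log = TRUE)
    }
  }
  lp
}

## draw one class value from the gamma prior at the current hypers
draw_value <- function(hyper) {
  rgamma(1, shape = hyper[["shape"]], rate = hyper[["shape"]] / hyper[["mean"]])
}

dens_value <- function(v, hyper) {
  dgamma(v, shape = hyper[["shape"]], rate = hyper[["shape"]] / hyper[["mean"]],
         log = TRUE)
}

#' Propose a reversible-jump move
#'
#' Moves: `rate_scale` (log-scale multiplier on one class value),
#' `split` (bipartition one class, fresh value from the gamma prior for the
#' new block), `merge` (fuse two classes), `zero` (swap the whole zero class
#' in or out), `hyper` (random-walk on the gamma mean or shape). The
#' returned log Hastings ratio includes all proposal densities so the
#' sampler is reversible with respect to the prior when the likelihood is
#' flat. Unavailable moves return the current state with a forced rejection.
#'
#' @param partition Current `rate_partition`.
#' @param hyper Current named hyperparameters (`mean`, `shape`).
#' @param move One of `"rate_scale"`, `"split"`, `"merge"`, `"zero"`,
#'   `"hyper"`.
#' @param priors A [prior_spec()] (bounds used by the hyper move).
#' @param weights Normalized move weights (for the cross-move Hastings
#'   terms between split and merge).
#' @param scale_step Log-scale window of the rate-scale move.
#' @return List: `partition`, `hyper`, `log_hastings` (`-Inf` for forced
#'   rejections), `move`.
#' @export
rj_propose <- function(partition, hyper, move, priors, weights,
                       scale_step = 1.5) {
  reject <- list(partition = partition, hyper = hyper,
                 log_hastings = -Inf, move = move)
  p <- partition
  nb <- length(p$blocks)
  nz_idx <- setdiff(seq_len(nb), p$zero)
  if (move == "rate_scale") {
    if (!length(nz_idx)) return(reject)
    b <- nz_idx[sample.int(length(nz_idx), 1L)]
    m <- exp(scale_step * (runif(1) - 0.5))
    p$values[b] <- p$values[b] * m
    return(list(partition = p, hyper = hyper, log_hastings = log(m),
                move = move))
  }
  if (move == "hyper") {
    ## random walks on one hyperparameter, or a joint independence refresh
    ## of the hyperparameters AND all class values from the prior (the
    ## refresh is what keeps the hyperparameters mixing across their range;
    ## its Hastings term cancels the prior ratio exactly, so it is always
    ## accepted when the likelihood is flat)
    u <- runif(1)
    if (u < 2 / 3) {
      which_h <- if (u < 1 / 3) "mean" else "shape"
      bounds <- if (which_h == "mean") priors$mean_bounds else priors$shape_bounds
      w <- (bounds[2] - bounds[1]) / 4
      hyper[[which_h]] <- hyper[[which_h]] + w * (runif(1) - 0.5)
      return(list(partition = p, hyper = hyper, log_hastings = 0,
                  move = move, values_changed = FALSE))
    }
    new_hyper <- c(mean = runif(1, priors$mean_bounds[1], priors$mean_bounds[2]),
                   shape = runif(1, priors$shape_bounds[1], priors$shape_bounds[2]))
    lh <- 0
    for (b in nz_idx) {
      lh <- lh + dens_value(p$values[b], hyper)       # reverse density
      p$values[b] <- draw_value(new_hyper)
      lh <- lh - dens_value(p$values[b], new_hyper)   # forward density
    }
    return(list(partition = p, hyper = new_hyper, log_hastings = lh,
                move = move, values_changed = TRUE))
  }
  if (move == "split") {
    splittable <- which(vapply(seq_len(nb), function(b) eff_size(p, b) >= 2,
                               logical(1)))
    if (!length(splittable)) return(reject)
    b <- splittable[sample.int(length(splittable), 1L)]
    members <- sort(p$blocks[[b]])
    is_zero <- !is.na(p$zero) && b == p$zero
    if (is_zero) {
      ## choose the non-empty label subset that leaves the zero block
      k <- length(members)
      code <- sample.int(2^k - 1, 1L)
      out <- members[bitwAnd(code, 2^(seq_len(k) - 1L)) > 0]
      p$blocks[[b]] <- setdiff(members, out)
      v_new <- draw_value(hyper)
      p$blocks[[nb + 1L]] <- out
      p$values[nb + 1L] <- v_new
      nbp <- 2^k - 1
    } else {
      k <- length(members)
      ## non-empty subset of the non-head members leaves; the sub-block
      ## holding the smallest label keeps the old value
      code <- sample.int(2^(k - 1) - 1, 1L)
      rest <- members[-1]
      out <- rest[bitwAnd(code, 2^(seq_len(k - 1) - 1L)) > 0]
      p$blocks[[b]] <- setdiff(members, out)  # keeps the old value
      v_new <- draw_value(hyper)
      p$blocks[[nb + 1L]] <- out
      p$values[nb + 1L] <- v_new
      nbp <- 2^(k - 1) - 1
    }
    log_qf <- log(weights[["split"]]) - log(length(splittable)) - log(nbp) +
      dens_value(v_new, hyper)
    log_qr <- log(weights[["merge"]]) - log(choose(nb + 1L, 2L))
    return(list(partition = p, hyper = hyper,
                log_hastings = log_qr - log_qf, move = move))
  }
  if (move == "merge") {
    if (nb < 2L) return(reject)
    pair <- sample.int(nb, 2L)
    b1 <- min(pair); b2 <- max(pair)
    zero_involved <- !is.na(p$zero) && p$zero %in% c(b1, b2)
    merged <- sort(c(p$blocks[[b1]], p$blocks[[b2]]))
    if (zero_involved) {
      zb <- p$zero; ob <- setdiff(c(b1, b2), zb)
      v_disc <- p$values[ob]
      keep <- zb
    } else {
      ## merged class keeps the value of the block holding the smallest label
      holder <- if (min(p$blocks[[b1]]) < min(p$blocks[[b2]])) b1 else b2
      v_disc <- p$values[setdiff(c(b1, b2), holder)]
      keep <- holder
    }
    drop <- setdiff(c(b1, b2), keep)
    p$blocks[[keep]] <- merged
    p$blocks[[drop]] <- NULL
    p$values <- p$values[-drop]
    if (!is.na(p$zero)) {
      if (zero_involved) p$zero <- keep - (drop < keep)
      else p$zero <- p$zero - (drop < p$zero)
    }
    ## reverse split bookkeeping on the proposal
    keep_new <- keep - (drop < keep)
    splittable_y <- which(vapply(seq_along(p$blocks),
                                 function(b) eff_size(p, b) >= 2, logical(1)))
    nbp_y <- n_bipartitions(p, keep_new)
    log_qf <- log(weights[["merge"]]) - log(choose(nb, 2L))
    log_qr <- log(weights[["split"]]) - log(length(splittable_y)) -
      log(nbp_y) + dens_value(v_disc, hyper)
    return(list(partition = p, hyper = hyper,
                log_hastings = log_qr - log_qf, move = move))
  }
  if (move == "zero") {
    if (is.na(p$zero)) return(reject)
    zb <- p$zero
    zero_empty <- length(p$blocks[[zb]]) == 0L
    go_zeroing <- runif(1) < 0.5
    if (go_zeroing) {
      ## move one whole non-zero block into the (empty) zero block
      if (!zero_empty || !length(nz_idx)) return(reject)
      b <- nz_idx[sample.int(length(nz_idx), 1L)]
      v_disc <- p$values[b]
      p$blocks[[zb]] <- sort(p$blocks[[b]])
      p$blocks[[b]] <- NULL
      p$values <- p$values[-b]
      if (b < zb) p$zero <- zb - 1L
      log_qf <- log(0.5) - log(length(nz_idx))
      log_qr <- log(0.5) + dens_value(v_disc, hyper)
    } else {
      ## restore the whole zero class as one fresh-valued block
      if (zero_empty) return(reject)
      v_new <- draw_value(hyper)
      p$blocks[[nb + 1L]] <- p$blocks[[zb]]
      p$values[nb + 1L] <- v_new
      p$blocks[[zb]] <- integer(0)
      log_qf <- log(0.5) + dens_value(v_new, hyper)
      log_qr <- log(0.5) - log(length(nz_idx) + 1L)
    }
    return(list(partition = p, hyper = hyper,
                log_hastings = log_qr - log_qf, move = move))
  }
  stop("unknown move: ", move, call. = FALSE)
}

#' Run the reversible-jump MCMC sampler
#'
#' Deterministic given `config$seed`. Samples are recorded after burn-in at
#' the configured interval; the chain length is
#' `floor((iterations - burn_in) / sample_interval)`.
#'
#' @inheritParams prune_log_likelihood
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param focal_node Internal node id at which per-sample marginal state
#'   probabilities are recorded (default the root); `NULL` to skip.
#' @return An `rj_chain`: list with `samples` (data frame: iteration,
#'   log_likelihood, log_prior, the six expanded rates, partition signature,
#'   hyperparameters, focal-node state probabilities), `acceptance` (per
#'   move type), `config`, `priors`, `focal_node`, `n_excluded_init`.
#' @export
run_chain <- function(tree, tip_vectors, priors, config,
                      pi = rep(1 / 3, 3), focal_node = "root") {
  pin <- prune_inputs(tree, tip_vectors)
  nt <- nrow(pin$tipvec)
  if (identical(focal_node, "root")) focal_node <- nt + 1L
  no_data <- all(pin$tipvec == 1)
  loglik_fun <- if (no_data) {
    function(partition) 0
  } else {
    function(partition) {
      .cpp_prune_loglik(pin$edge, pin$len, pin$tipvec,
                        unname(build_generator(expand_rates(partition))), pi)
    }
  }

  set.seed(config$seed)
  zero_on <- config$zero_class
  weights <- config$move_weights
  hyper <- c(mean = runif(1, priors$mean_bounds[1], priors$mean_bounds[2]),
             shape = runif(1, priors$shape_bounds[1], priors$shape_bounds[2]))
  init_tries <- 0L
  repeat {
    part <- if (zero_on)
      new_partition(list(1:6, integer(0)), c(draw_value(hyper), 0), zero = 2L)
    else
      new_partition(list(1:6), draw_value(hyper))
    ll <- loglik_fun(part)
    if (is.finite(ll)) break
    init_tries <- init_tries + 1L
    if (init_tries >= 100L)
      stop("non-finite likelihood at initialization after 100 re-draws",
           call. = FALSE)
  }
  lp <- rj_log_prior(part, hyper, priors, zero_on)

  n_samples <- (config$iterations - config$burn_in) %/% config$sample_interval
  move_names <- names(weights)
  att <- setNames(numeric(length(weights)), move_names)
  acc <- att
  scale_step <- 1.5
  tune_att <- 0; tune_acc <- 0

  samp_it <- integer(n_samples); samp_ll <- numeric(n_samples)
  samp_lp <- numeric(n_samples)
  samp_rates <- matrix(NA_real_, n_samples, 6,
                       dimnames = list(NULL, RATE_LABELS))
  samp_sig <- character(n_samples)
  samp_hyper <- matrix(NA_real_, n_samples, 2,
                       dimnames = list(NULL, c("hyper_mean", "hyper_shape")))
  samp_marg <- if (!is.null(focal_node))
    matrix(NA_real_, n_samples, 3, dimnames = list(NULL, paste0("root_p", 0:2)))
  s_i <- 0L

  for (iter in seq_len(config$iterations)) {
    move <- move_names[sample.int(length(weights), 1L, prob = weights)]
    prop <- rj_propose(part, hyper, move, priors, weights,
                       scale_step = scale_step)
    att[move] <- att[move] + 1
    accepted <- FALSE
    if (is.finite(prop$log_hastings)) {
      lp_new <- rj_log_prior(prop$partition, prop$hyper, priors, zero_on)
      if (is.finite(lp_new)) {
        ll_new <- if (move == "hyper" && !isTRUE(prop$values_changed)) ll
                  else loglik_fun(prop$partition)
        if (is.finite(ll_new)) {
          log_alpha <- (lp_new + ll_new) - (lp + ll) + prop$log_hastings
          if (log(runif(1)) < log_alpha) {
            part <- prop$partition; hyper <- prop$hyper
            lp <- lp_new; ll <- ll_new
            accepted <- TRUE
          }
        }
      }
    }
    if (accepted) acc[move] <- acc[move] + 1
    if (move == "rate_scale" && config$tune && iter <= config$burn_in) {
      tune_att <- tune_att + 1
      tune_acc <- tune_acc + accepted
      if (tune_att == 200) {
        r <- tune_acc / tune_att
        scale_step <- min(20, max(0.05, scale_step * exp(r - 0.3)))
        tune_att <- 0; tune_acc <- 0
      }
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$sample_interval == 0L) {
      s_i <- s_i + 1L
      samp_it[s_i] <- iter
      samp_ll[s_i] <- ll
      samp_lp[s_i] <- lp
      samp_rates[s_i, ] <- expand_rates(part)
      samp_sig[s_i] <- partition_signature(part)
      samp_hyper[s_i, ] <- hyper
      if (!is.null(focal_node)) {
        marg <- .cpp_node_marginals(pin$edge, pin$len, pin$tipvec,
                                    unname(build_generator(expand_rates(part))),
                                    pi)
        samp_marg[s_i, ] <- marg[focal_node, ]
      }
    }
  }

  samples <- data.frame(iteration = samp_it, log_likelihood = samp_ll,
                        log_prior = samp_lp, samp_rates,
                        partition = samp_sig, samp_hyper,
                        stringsAsFactors = FALSE)
  if (!is.null(focal_node)) samples <- cbind(samples, samp_marg)
  structure(list(samples = samples,
                 acceptance = ifelse(att > 0, acc / att, NA_real_),
                 attempts = att, config = config, priors = priors,
                 focal_node = focal_node, scale_step = scale_step,
                 n_excluded_init = init_tries),
            class = "rj_chain")
}

#' @export
print.rj_chain <- function(x, ...) {
  cat(sprintf("rjMCMC chain: %d samples (of %d iterations, burn-in %d)\n",
              nrow(x$samples), x$config$iterations, x$config$burn_in))
  cat("acceptance rates:\n")
  print(round(x$acceptance, 3))
  invisible(x)
}

#' Write / read a chain sample log as TSV
#'
#' The column layout (iteration, log-likelihood, six expanded rates,
#' partition signature, hyperparameters, focal-node probabilities) is
#' column-compatible with multistate sampler logs from other software, so
#' the hypothesis tests can also consume external logs.
#'
#' @param chain An `rj_chain` (or its `samples` data frame).
#' @param path Output TSV path.
#' @export
write_chain_log <- function(chain, path) {
  samples <- if (inherits(chain, "rj_chain")) chain$samples else chain
  utils::write.table(samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_chain_log
#' @return `read_chain_log()` returns the samples data frame.
#' @export
read_chain_log <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Autocorrelation-based effective sample sizes
#'
#' ESS per expanded rate and for the log-likelihood, using
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at the
#' first non-positive lag. Constant series report an ESS of 1.
#'
#' @param chain An `rj_chain` or a samples data frame.
#' @return Named numeric vector of ESS values.
#' @export
effective_samples <- function(chain) {
  samples <- if (inherits(chain, "rj_chain")) chain$samples else chain
  if (nrow(samples) < 10L) stop("chain too short (need >= 10)", call. = FALSE)
  cols <- c(RATE_LABELS, "log_likelihood")
  vapply(cols, function(cn) ess_one(samples[[cn]]), numeric(1))
}

ess_one <- function(x) {
  n <- length(x)
  if (stats::var(x) < .Machine$double.eps * max(1, mean(x)^2)) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1L, 10 * ceiling(sqrt(n))),
                    plot = FALSE)$acf[-1]
  upto <- which(rho <= 0)[1]
  if (is.na(upto)) upto <- length(rho) + 1L
  s <- sum(rho[seq_len(upto - 1L)])
  max(1, min(n, n / (1 + 2 * s)))
}
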