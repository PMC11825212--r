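## Synthetic data with the statistical structure the analysis assumes:
## Yule (pure-birth) ultrametric trees, tip states evolved by exact CTMC
## simulation, missing-data injection, and a three-trait study generator
## with an optional trait-coupling mode.

#' Simulate a Yule (pure-birth) ultrametric tree
#'
#' Wraps [ape::rphylo()] with extinction zero; by default the tree height
#' is rescaled to 1 so rate magnitudes are comparable across runs.
#'
#' @param n_tips Number of tips (`>= 2`).
#' @param birth_rate Speciation rate (`> 0`, default 1).
#' @param seed Integer seed; trees are deterministic given the seed.
#' @param rescale_height Rescale total height to this value (`NULL` keeps
#'   the raw Yule time scale).
#' @param tip_labels Optional character vector of tip names (length
#'   `n_tips`); default `t1..tn`.
#' @return Rooted ultrametric binary `phylo`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L,
                               rescale_height = 1, tip_labels = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  tree <- withr_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  if (!is.null(rescale_height)) {
    h <- max(tip_depths(tree))
    tree$edge.length <- tree$edge.length * (rescale_height / h)
  }
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_tips)
    tree$tip.label <- canonical_species(tip_labels)
  }
  tree
}

## exact CTMC path sampling along one branch: exponential waiting times
sim_branch <- function(state, Q, t) {
  repeat {
    out_rate <- -Q[state, state]
    if (out_rate <= 0) return(state)
    w <- rexp(1, out_rate)
    if (w >= t) return(state)
    t <- t - w
    probs <- Q[state, ]
    probs[state] <- 0
    state <- sample.int(3L, 1L, prob = probs)
  }
}

#' Simulate a discrete character along a tree
#'
#' Forward simulation by exact CTMC sampling (exponential waiting times,
#' embedded-chain jumps) from a fixed root state.
#'
#' @param tree Rooted `phylo`.
#' @param Q 3x3 generator matrix.
#' @param root_state Root state index (0-based, in `0..2`).
#' @param seed Integer seed.
#' @return Named integer vector of 0-based tip states.
#' @export
simulate_trait <- function(tree, Q, root_state = 0, seed = 1L) {
  stopifnot(root_state %in% 0:2)
  root_state <- as.integer(root_state)
  Q <- unname(Q)
  nt <- ape::Ntip(tree)
  n_all <- nt + tree$Nnode
  tc <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  withr_seed(seed, {
    state <- integer(n_all)
    state[nt + 1L] <- root_state + 1L
    for (e in seq_len(nrow(tc$edge))) {
      par <- tc$edge[e, 1]; ch <- tc$edge[e, 2]
      state[ch] <- sim_branch(state[par], Q, tc$edge.length[e])
    }
    setNames(state[seq_len(nt)] - 1L, tree$tip.label)
  })
}

#' Replace a fixed fraction of entries with missing values
#'
#' Exactly `floor(fraction * n)` entries, chosen uniformly at random, are
#' set to `NA`.
#'
#' @param states Vector of states.
#' @param fraction Missing fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return The vector with `NA`s injected.
#' @export
inject_missing <- function(states, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n_na <- floor(fraction * length(states))
  if (n_na == 0) return(states)
  idx <- withr_seed(seed, sample.int(length(states), n_na))
  states[idx] <- NA
  states
}

#' Specification for a synthetic three-trait study
#'
#' Defaults mirror the bundled blowfly dataset: 61 tips, unit-height Yule
#' tree, three 3-state traits with moderate missingness. In coupled mode
#' the second and third traits are deterministic functions of the first
#' (state 0 <-> 0, 1 <-> 1, 2 <-> 2 under each trait's own labels),
#' flipped to a random other state with probability `epsilon` — emulating
#' the observed association obligatory/fresh/constant,
#' saprophagous/necrotic/variable, facultative/both/both.
#'
#' @param n_tips Number of tips.
#' @param birth_rate Yule speciation rate.
#' @param Q Generator for the first trait (and, in independent mode, all
#'   traits unless `Q_list` is given).
#' @param Q_list Optional list of three generators (independent mode).
#' @param root_states Integer vector of three 0-based root states.
#' @param missing_fraction Numeric (recycled to three) missing fractions.
#' @param coupled Couple traits 2 and 3 to trait 1.
#' @param epsilon Flip probability in coupled mode.
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_tips = 61, birth_rate = 1,
                            Q = build_generator(rep(1, 6)), Q_list = NULL,
                            root_states = c(1, 0, 1),
                            missing_fraction = c(0.15, 0.15, 0.15),
                            coupled = FALSE, epsilon = 0.05, seed = 1L) {
  stopifnot(n_tips >= 2, epsilon >= 0, epsilon <= 1)
  missing_fraction <- rep_len(missing_fraction, 3L)
  stopifnot(all(missing_fraction >= 0), all(missing_fraction < 1))
  structure(list(n_tips = n_tips, birth_rate = birth_rate, Q = Q,
                 Q_list = Q_list, root_states = rep_len(root_states, 3L),
                 missing_fraction = missing_fraction, coupled = coupled,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a complete synthetic study (tree + trait matrix)
#'
#' @param spec A [simulation_spec()].
#' @param defs Trait definitions used to label states (default
#'   [blowfly_trait_definitions()]).
#' @return List with `tree` (`phylo`), `traits` (`trait_matrix`), and
#'   `tip_states` (list of three 0-based integer state vectors before
#'   missingness injection).
#' @export
simulate_study <- function(spec, defs = blowfly_trait_definitions()) {
  tree <- simulate_yule_tree(spec$n_tips, spec$birth_rate, seed = spec$seed)
  Qs <- if (!is.null(spec$Q_list)) spec$Q_list else rep(list(spec$Q), 3L)
  tip_states <- vector("list", 3L)
  tip_states[[1]] <- simulate_trait(tree, Qs[[1]], spec$root_states[1],
                                    seed = spec$seed + 1L)
  if (spec$coupled) {
    n <- spec$n_tips
    ## index maps from trait 1 to traits 2 and 3 producing the blowfly
    ## association: obligatory->fresh/constant, saprophagous->necrotic/
    ## variable, facultative->both/both under the default state orderings
    maps <- list(c(1L, 0L, 2L), c(0L, 1L, 2L))
    for (k in 2:3) {
      st <- unname(maps[[k - 1L]][tip_states[[1]] + 1L])
      flips <- withr_seed(spec$seed + 10L * k, {
        do_flip <- runif(n) < spec$epsilon
        alt <- vapply(st, function(s) sample(setdiff(0:2, s), 1L), integer(1))
        list(do_flip = do_flip, alt = alt)
      })
      st[flips$do_flip] <- flips$alt[flips$do_flip]
      tip_states[[k]] <- setNames(st, tree$tip.label)
    }
  } else {
    for (k in 2:3)
      tip_states[[k]] <- simulate_trait(tree, Qs[[k]], spec$root_states[k],
                                        seed = spec$seed + k)
  }
  names(tip_states) <- names(defs)
  df <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (k in 1:3) {
    def <- defs[[k]]
    st <- inject_missing(tip_states[[k]], spec$missing_fraction[k],
                         seed = spec$seed + 100L + k)
    lab <- ifelse(is.na(st), def$missing_token, def$states[st + 1L])
    df[[def$name]] <- unname(lab)
  }
  attr(df, "defs") <- defs
  attr(df, "ingroup") <- rep(TRUE, nrow(df))
  class(df) <- c("trait_matrix", "data.frame")
  list(tree = tree, traits = df, tip_states = tip_states)
}
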