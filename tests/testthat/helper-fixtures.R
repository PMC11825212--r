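## Shared fixtures and independent oracles used across the suite.

abc_def <- trait_definition("x", c("s0", "s1", "s2"))

## tip likelihood matrix from a named 0-based integer state vector
## (NA = missing)
states_to_tipvec <- function(states) {
  m <- t(vapply(states, function(s) {
    if (is.na(s)) rep(1, 3) else { v <- numeric(3); v[s + 1] <- 1; v }
  }, numeric(3)))
  rownames(m) <- names(states)
  m
}

random_rates <- function() rexp(6, rate = 1 / runif(1, 0.2, 3))

## independent brute-force likelihood: enumerate all internal-node state
## assignments; transition probabilities via Matrix::expm (a code path
## disjoint from the package kernel)
enum_loglik <- function(tree, tipvec, Q, pi = rep(1 / 3, 3)) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  tipvec <- tipvec[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:3), nn)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    a <- grid[g, ]                      # state of internal node nt+i
    prob <- pi[a[1]]                    # root = nt + 1
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sp <- a[p - nt]
      if (ch <= nt) prob <- prob * sum(Pm[[e]][sp, ] * tipvec[ch, ])
      else prob <- prob * Pm[[e]][sp, a[ch - nt]]
    }
    total <- total + prob
  }
  log(total)
}

## brute-force marginal at one internal node by restricted enumeration
enum_marginal <- function(tree, tipvec, Q, node, pi = rep(1 / 3, 3)) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  tipvec <- tipvec[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:3), nn)))
  mass <- numeric(3)
  for (g in seq_len(nrow(grid))) {
    a <- grid[g, ]
    prob <- pi[a[1]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sp <- a[p - nt]
      if (ch <= nt) prob <- prob * sum(Pm[[e]][sp, ] * tipvec[ch, ])
      else prob <- prob * Pm[[e]][sp, a[ch - nt]]
    }
    s <- a[node - nt]
    mass[s] <- mass[s] + prob
  }
  mass / sum(mass)
}

## random small binary ultrametric-ish tree for oracle tests
random_small_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1.5)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

## tip vectors for a whole simulated trait, package-definition based
sim_tipvec <- function(tree, Q, root_state, seed) {
  st <- simulate_trait(tree, Q, root_state, seed = seed)
  states_to_tipvec(st)
}
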