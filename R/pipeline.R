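## End-to-end orchestration: per-trait rjMCMC on a fixed ultrametric tree,
## ancestral-state estimates at a focal ancestor, the three stepping-stone
## pathway tests and three ancestral-dominance tests, and file outputs.

#' Restrict tree and trait matrix to the ingroup
#'
#' Tips absent from the trait table (or flagged as outgroup) are either
#' pruned (default; the root becomes the ingroup MRCA) or retained with
#' all-missing trait assignments.
#'
#' @param tree Rooted `phylo`.
#' @param matrix A `trait_matrix`.
#' @param mode `"prune"` (default) or `"retain"`.
#' @return List with `tree`, `matrix` (row order matching the tree), and
#'   `outgroup` (dropped or retained tip labels).
#' @export
prune_to_ingroup <- function(tree, matrix, mode = c("prune", "retain")) {
  mode <- match.arg(mode)
  ingroup <- intersect(tree$tip.label, matrix$species)
  if (!length(ingroup)) stop("no tree tip matches the trait table", call. = FALSE)
  outgroup <- setdiff(tree$tip.label, ingroup)
  defs <- attr(matrix, "defs")
  if (mode == "prune") {
    if (length(outgroup)) {
      if (length(ingroup) < 2L) stop("pruning would empty the tree", call. = FALSE)
      tree <- ape::keep.tip(tree, ingroup)
    }
    m <- matrix[match(tree$tip.label, matrix$species), , drop = FALSE]
  } else {
    m <- matrix[match(tree$tip.label, matrix$species), , drop = FALSE]
    m$species <- tree$tip.label
    for (tr in names(defs)) {
      miss <- is.na(m[[tr]])
      m[[tr]][miss] <- defs[[tr]]$missing_token
    }
  }
  rownames(m) <- NULL
  attr(m, "defs") <- defs
  attr(m, "ingroup") <- m$species %in% ingroup
  class(m) <- c("trait_matrix", "data.frame")
  list(tree = tree, matrix = m, outgroup = outgroup)
}

#' Run the full comparative analysis
#'
#' For each requested trait: maximum-likelihood rate estimation,
#' hyperprior elicitation, an rjMCMC chain, posterior rate summaries,
#' mean focal-node state probabilities, the stepping-stone pathway test and
#' the ancestral-dominance test, and (optionally) per-file outputs: chain
#' TSV, hypothesis TSV, node-probability CSV, annotated NEXUS tree, and a
#' JSON run-metadata record of every design decision in force. No
#' multiple-testing correction is applied across the tests.
#'
#' @param tree Rooted `phylo` (time-proportional branch lengths).
#' @param traits A `trait_matrix`.
#' @param trait_names Traits to analyse (default all defined).
#' @param config An [mcmc_config()].
#' @param outgroup_mode `"prune"` (default) or `"retain"`, see
#'   [prune_to_ingroup()].
#' @param hypotheses Named list per trait with elements `pathway`
#'   (a [pathway_hypothesis()]) and `root_state` (0-based dominance state);
#'   defaults follow the blowfly analysis: saprophagous -> facultative ->
#'   obligatory, necrotic -> both -> fresh, variable -> both -> constant,
#'   with dominance of saprophagous / necrotic / variable.
#' @param pi Root prior (default uniform).
#' @param prior_n_draws Monte-Carlo draws for the pathway prior.
#' @param out_dir Output directory (`NULL` for no file output).
#' @param seed Master seed; per-trait chain seeds are derived from it.
#' @return An `rjmk_analysis` list: per-trait results (`ml`, `chain`,
#'   `rate_summary`, `focal_probs`, `hypotheses`), the hypothesis table
#'   (data frame), the pruned tree, focal node id, and run metadata.
#' @export
run_analysis <- function(tree, traits, trait_names = NULL,
                         config = mcmc_config(), outgroup_mode = "prune",
                         hypotheses = NULL, pi = rep(1 / 3, 3),
                         prior_n_draws = 1e4, out_dir = NULL, seed = 1L) {
  defs <- attr(traits, "defs")
  if (is.null(trait_names)) trait_names <- names(defs)
  unknown <- setdiff(trait_names, names(defs))
  if (length(unknown))
    stop("undefined trait(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  pruned <- prune_to_ingroup(tree, traits, mode = outgroup_mode)
  tree <- pruned$tree
  matrix <- pruned$matrix
  focal <- if (length(pruned$outgroup) && outgroup_mode == "retain")
    mrca_node(tree, matrix$species[attr(matrix, "ingroup")])
  else ape::Ntip(tree) + 1L

  if (is.null(hypotheses)) {
    hypotheses <- list(
      trophic = list(pathway = pathway_hypothesis(1, 2, 0), root_state = 1),
      substrate = list(pathway = pathway_hypothesis(0, 2, 1), root_state = 0),
      temperature = list(pathway = pathway_hypothesis(1, 2, 0), root_state = 1))
    hypotheses <- hypotheses[intersect(trait_names, names(hypotheses))]
  }

  um <- check_ultrametric(tree)
  if (!um$is_ultrametric)
    warning(sprintf("tree is not ultrametric (max deviation %.3g)",
                    um$max_depth_deviation))

  per_trait <- list()
  hyp_rows <- list()
  for (ti in seq_along(trait_names)) {
    tr <- trait_names[ti]
    def <- defs[[tr]]
    tipvec <- tip_likelihood_matrix(matrix, tr)
    trait_seed <- seed + 1000L * ti
    ml <- ml_estimate_rates(tree, tipvec, pi = pi, seed = trait_seed)
    priors <- elicit_priors_from_ml(ml)
    cfg <- config
    cfg$seed <- trait_seed
    chain <- run_chain(tree, tipvec, priors, cfg, pi = pi,
                       focal_node = focal)
    R <- as.matrix(chain$samples[, RATE_LABELS])
    rate_summary <- data.frame(
      rate = RATE_LABELS,
      from = def$states[RATE_FROM], to = def$states[RATE_TO],
      ml = unname(ml$rates),
      posterior_mean = colMeans(R),
      q2.5 = apply(R, 2, stats::quantile, 0.025),
      q97.5 = apply(R, 2, stats::quantile, 0.975),
      row.names = NULL, stringsAsFactors = FALSE)
    focal_probs <- colMeans(chain$samples[, paste0("root_p", 0:2)])
    names(focal_probs) <- def$states

    hyp <- hypotheses[[tr]]
    results <- list()
    if (!is.null(hyp$pathway)) {
      post <- pathway_posterior_proportion(chain, hyp$pathway)
      prior <- pathway_prior(hyp$pathway, priors,
                             zero_class = cfg$zero_class,
                             n_draws = prior_n_draws, seed = trait_seed)
      res <- bayes_factor(post$p_Mi_given_D, post$p_Mj_given_D,
                          prior$p_Mi, prior$p_Mj)
      results$pathway <- res
      hyp_rows[[length(hyp_rows) + 1L]] <- data.frame(
        hypothesis = "pathway", trait = tr,
        description = sprintf("%s -> %s -> %s vs direct",
                              def$states[hyp$pathway$origin + 1L],
                              def$states[hyp$pathway$intermediate + 1L],
                              def$states[hyp$pathway$terminal + 1L]),
        p_Mi_given_D = res$p_Mi_given_D, p_Mj_given_D = res$p_Mj_given_D,
        p_Mi = res$p_Mi, p_Mi_se = prior$se, p_Mj = res$p_Mj,
        bayes_factor = res$bayes_factor, support = res$support_category,
        n_samples = post$n_samples, n_excluded = post$n_excluded,
        stringsAsFactors = FALSE)
    }
    if (!is.null(hyp$root_state)) {
      post <- root_posterior_proportion(chain, hyp$root_state)
      prior <- root_prior_probability(hyp$root_state)
      res <- bayes_factor(post$p_Mi_given_D, post$p_Mj_given_D,
                          prior$p_Mi, prior$p_Mj)
      results$root <- res
      hyp_rows[[length(hyp_rows) + 1L]] <- data.frame(
        hypothesis = "root_dominance", trait = tr,
        description = sprintf("ancestor %s dominant",
                              def$states[hyp$root_state + 1L]),
        p_Mi_given_D = res$p_Mi_given_D, p_Mj_given_D = res$p_Mj_given_D,
        p_Mi = res$p_Mi, p_Mi_se = 0, p_Mj = res$p_Mj,
        bayes_factor = res$bayes_factor, support = res$support_category,
        n_samples = post$n_samples, n_excluded = 0L,
        stringsAsFactors = FALSE)
    }
    per_trait[[tr]] <- list(ml = ml, priors = priors, chain = chain,
                            rate_summary = rate_summary,
                            focal_probs = focal_probs, hypotheses = results)
  }
  hyp_table <- do.call(rbind, hyp_rows)

  metadata <- list(
    traits = trait_names, seed = seed,
    iterations = config$iterations, sample_interval = config$sample_interval,
    burn_in = config$burn_in, zero_class = config$zero_class,
    normalization = "mean", root_prior = "uniform",
    outgroup_mode = outgroup_mode, focal_node = focal,
    outgroup = pruned$outgroup,
    hyperprior = lapply(per_trait, function(x)
      list(mean_bounds = x$priors$mean_bounds,
           shape_bounds = x$priors$shape_bounds)),
    ultrametric = um$is_ultrametric,
    multiple_testing_correction = "none")

  result <- structure(list(per_trait = per_trait, hypothesis_table = hyp_table,
                           tree = tree, focal_node = focal,
                           metadata = metadata),
                      class = "rjmk_analysis")
  if (!is.null(out_dir)) write_analysis(result, matrix, out_dir, pi = pi)
  result
}

## prior elicitation from an existing ML fit (avoids refitting)
elicit_priors_from_ml <- function(ml) {
  ml_mean <- max(mean(ml$rates), 1e-6)
  prior_spec(mean_bounds = c(ml_mean / 10, ml_mean * 10))
}

write_analysis <- function(result, matrix, out_dir, pi = rep(1 / 3, 3)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  defs <- attr(matrix, "defs")
  for (tr in names(result$per_trait)) {
    x <- result$per_trait[[tr]]
    write_chain_log(x$chain, file.path(out_dir, paste0("chain_", tr, ".tsv")))
    utils::write.table(x$rate_summary,
                       file.path(out_dir, paste0("rates_", tr, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ## posterior-mean node probabilities across sampled models
    np <- posterior_node_probs(result$tree, matrix, tr, x$chain, pi = pi)
    utils::write.table(
      node_probability_table(result$tree, np, defs[[tr]]$states),
      file.path(out_dir, paste0("node_probs_", tr, ".csv")),
      sep = ",", row.names = FALSE, quote = FALSE)
    write_annotated_tree(result$tree, np,
                         file.path(out_dir, paste0("tree_", tr, ".nex")),
                         state_labels = defs[[tr]]$states)
  }
  utils::write.table(result$hypothesis_table,
                     file.path(out_dir, "hypotheses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(result$metadata, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_metadata.json"))
  invisible(out_dir)
}

#' Posterior-mean marginal state probabilities at every node
#'
#' Averages the per-sample marginal reconstruction over (a thinning of) the
#' posterior rate samples.
#'
#' @param tree Rooted `phylo` (as analysed).
#' @param matrix Trait matrix matching the tree.
#' @param trait Trait name.
#' @param chain An `rj_chain` for that trait.
#' @param max_samples Cap on the number of samples averaged (evenly thinned).
#' @param pi Root prior.
#' @return Matrix `(Ntip + Nnode) x 3`, rows summing to 1.
#' @export
posterior_node_probs <- function(tree, matrix, trait, chain,
                                 max_samples = 500, pi = rep(1 / 3, 3)) {
  tipvec <- tip_likelihood_matrix(matrix, trait)
  pin <- prune_inputs(tree, tipvec)
  R <- as.matrix(chain$samples[, RATE_LABELS])
  idx <- unique(round(seq(1, nrow(R), length.out = min(max_samples, nrow(R)))))
  acc <- 0
  for (i in idx) {
    acc <- acc + .cpp_node_marginals(pin$edge, pin$len, pin$tipvec,
                                     unname(build_generator(R[i, ])), pi)
  }
  acc / length(idx)
}
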