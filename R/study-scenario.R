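# A bundled synthetic study scenario exercising every pipeline stage at desk
# scale: a small mammal-like species tree, three opsin-like genes with
# contrasting selective regimes, and a photic trait table whose discrete and
# continuous characters were evolved on that tree. All sizes and parameters
# are fixed properties of the scenario (see the methods vignette for the
# rationale); only the seed varies.

#' Simulate the bundled study scenario
#'
#' Generates a species tree, three codon alignments and a photic trait table
#' with the statistical structure the analysis chain assumes:
#' \itemize{
#'   \item `rh1like`: strong purifying selection (dN/dS = 0.1) with one
#'     foreground terminal branch at dN/dS = 3 (a recent lineage-specific
#'     adaptation, detectable by the omega-lineage scan and two-ratio test);
#'   \item `sws1like`: site-class mixture with beta(0.5, 1.5) background and
#'     a 15% class at dN/dS = 4 (site-specific positive selection);
#'   \item `rrhlike`: M7-style neutral-to-purifying beta(0.8, 2) site classes
#'     (a null gene for the site scan).
#' }
#' Activity pattern (nocturnal/cathemeral/diurnal) evolves under an Mk chain
#' rooted in the nocturnal state; the SWS1 site-86 residue follows a two-state
#' UVS (F) / VS (Y) chain rooted in the UVS state; the site-93 residue is
#' drawn T-biased for nocturnal and P-biased for diurnal species; orbit
#' convergence is Brownian (root 60 degrees) plus an activity effect
#' (-20 degrees for nocturnal, +20 for diurnal species, emulating the
#' panoramic-vision/nocturnality association); visual acuity is Brownian on
#' the log scale (root ~5 cycles/degree).
#'
#' @param seed Integer master seed.
#' @param n_tips Number of species.
#' @param n_codons Codon sites per gene.
#' @return A list with `tree`, `alignments` (named list of three
#'   [codon_alignment()]s), `traits` (a [trait_table()]) and `truth` (the
#'   generating parameters, including the foreground tip).
#' @export
simulate_study <- function(seed = 1, n_tips = 12, n_codons = 300) {
  tree <- simulate_tree(n_tips, birth = 1, seed = seed)
  # scale total depth to ~1 expected substitution per codon root-to-tip
  depth <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length / depth

  # the recent adaptive lineage sits on the longest terminal branch: a
  # near-zero-length branch cannot carry a measurable burst of substitutions
  terminal <- match(seq_len(n_tips), tree$edge[, 2])
  fg_edge <- terminal[which.max(tree$edge.length[terminal])]
  fg_tip <- tree$tip.label[tree$edge[fg_edge, 2]]
  om_edges <- rep(0.1, nrow(tree$edge))
  om_edges[fg_edge] <- 3
  rh1 <- simulate_codon_alignment(tree, n_codons, kappa = 2.5,
                                  per_edge_omega = om_edges,
                                  seed = seed + 101)
  sws1 <- simulate_codon_alignment(
    tree, n_codons, kappa = 2.5,
    classes = rbind(
      transform(discretize_beta(0.5, 1.5, 10), weight = weight * 0.85),
      data.frame(omega = 4, weight = 0.15)),
    seed = seed + 102)
  rrh <- simulate_codon_alignment(tree, n_codons, kappa = 2.5,
                                  classes = discretize_beta(0.8, 2, 10),
                                  seed = seed + 103)

  act_states <- c("nocturnal", "cathemeral", "diurnal")
  Q_act <- mk_generator(c(1.2, 0.4, 0.8, 0.6, 0.3, 1.0), act_states, "ARD")
  activity <- simulate_discrete_trait(tree, Q_act, "nocturnal",
                                      seed = seed + 201)
  Q_vu <- mk_generator(0.8, c("UVS", "VS"), "ER")
  vs_uvs <- simulate_discrete_trait(tree, Q_vu, "UVS", seed = seed + 202)
  site86 <- ifelse(vs_uvs == "UVS", "F", "Y")
  site93 <- with_seed(seed + 203, vapply(activity, function(a) {
    if (a == "nocturnal") sample(c("T", "S", "A", "P"), 1,
                                 prob = c(0.6, 0.15, 0.15, 0.1))
    else if (a == "diurnal") sample(c("P", "V", "T"), 1,
                                    prob = c(0.6, 0.25, 0.15))
    else sample(c("T", "P"), 1)
  }, character(1)))
  orbit <- simulate_continuous_trait(tree, sigma2 = 225, root_value = 60,
                                     seed = seed + 204)
  orbit <- orbit + c(nocturnal = -20, cathemeral = 0, diurnal = 20)[activity]
  orbit <- pmin(pmax(orbit, 1), 179)
  acuity <- exp(simulate_continuous_trait(tree, sigma2 = 0.5,
                                          root_value = log(5),
                                          seed = seed + 205))
  traits <- trait_table(data.frame(
    species_id = tree$tip.label,
    activity_pattern = unname(activity),
    site86_residue = unname(site86),
    site93_residue = unname(site93),
    sws1_active = TRUE, is_primate = FALSE,
    orbit_convergence = unname(orbit),
    visual_acuity = unname(acuity),
    stringsAsFactors = FALSE))

  list(tree = tree,
       alignments = list(rh1like = rh1, sws1like = sws1, rrhlike = rrh),
       traits = traits,
       truth = list(foreground_tip = fg_tip, foreground_omega = 3,
                    background_omega = 0.1,
                    sws1_classes = list(p = 0.5, q = 1.5, p1 = 0.15,
                                        omega_s = 4),
                    activity_root = "nocturnal", vs_uvs_root = "UVS",
                    orbit_root = 60, orbit_sigma2 = 225,
                    log_acuity_root = log(5), log_acuity_sigma2 = 0.5))
}

#' Simulate the trait-reconstruction scenario
#'
#' The ancestral-reconstruction stage of the study operated on omega-trees
#' estimated from many more species than are tractable for desk-scale codon
#' fits, so this scenario generates that stage's inputs directly: a larger
#' species tree, per-gene omega-trees that emulate free-ratios estimates
#' (branch dN/dS drawn log-normally around a purifying mean on the species
#' topology), and the photic trait table evolved on the species tree
#' (identical generating processes to [simulate_study()]).
#'
#' @param seed Integer master seed.
#' @param n_tips Number of species.
#' @param genes Gene names for the emulated omega-trees.
#' @param mean_omega Median branch dN/dS of the emulated estimates.
#' @param omega_sdlog Log-scale spread of branch dN/dS around the median.
#' @return A list with `tree`, `omega_trees` (named list), `traits` and
#'   `truth`.
#' @export
simulate_trait_study <- function(seed = 1, n_tips = 48,
                                 genes = c("rh1like", "sws1like", "rrhlike"),
                                 mean_omega = 0.15, omega_sdlog = 0.6) {
  tree <- simulate_tree(n_tips, birth = 1, seed = seed)
  tree$edge.length <- tree$edge.length / max(node_depths(tree))
  omega_trees <- with_seed(seed + 50, {
    out <- lapply(genes, function(g) {
      ot <- tree
      ot$edge.length <- mean_omega *
        exp(rnorm(nrow(tree$edge), 0, omega_sdlog))
      class(ot) <- c("omega_tree", class(tree))
      ot
    })
    names(out) <- genes
    out
  })
  act_states <- c("nocturnal", "cathemeral", "diurnal")
  Q_act <- mk_generator(c(1.2, 0.4, 0.8, 0.6, 0.3, 1.0), act_states, "ARD")
  activity <- simulate_discrete_trait(tree, Q_act, "nocturnal",
                                      seed = seed + 201)
  Q_vu <- mk_generator(0.8, c("UVS", "VS"), "ER")
  vs_uvs <- simulate_discrete_trait(tree, Q_vu, "UVS", seed = seed + 202)
  orbit <- simulate_continuous_trait(tree, sigma2 = 225, root_value = 60,
                                     seed = seed + 204)
  orbit <- orbit + c(nocturnal = -20, cathemeral = 0, diurnal = 20)[activity]
  orbit <- pmin(pmax(orbit, 1), 179)
  acuity <- exp(simulate_continuous_trait(tree, sigma2 = 0.5,
                                          root_value = log(5),
                                          seed = seed + 205))
  traits <- trait_table(data.frame(
    species_id = tree$tip.label,
    activity_pattern = unname(activity),
    site86_residue = ifelse(vs_uvs == "UVS", "F", "Y"),
    sws1_active = TRUE, is_primate = FALSE,
    orbit_convergence = unname(orbit),
    visual_acuity = unname(acuity),
    stringsAsFactors = FALSE))
  list(tree = tree, omega_trees = omega_trees, traits = traits,
       truth = list(activity_root = "nocturnal", vs_uvs_root = "UVS",
                    orbit_root = 60, orbit_sigma2 = 225,
                    log_acuity_root = log(5), log_acuity_sigma2 = 0.5))
}
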