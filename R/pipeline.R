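# Orchestration of the full study design: per-gene site scans, the
# omega-lineage scan with two-ratio follow-ups under Bonferroni correction,
# and Moran-gated ancestral reconstructions with cross-gene aggregation.

#' Assemble and validate a run configuration
#'
#' @param alignments Named list: per-gene [codon_alignment()] objects or
#'   FASTA paths.
#' @param tree Species tree (`phylo` or newick path).
#' @param traits A [trait_table()] or CSV path (needed for `run_ancestral`).
#' @param K Beta discretization classes for site models.
#' @param n_starts Optimizer starts per fit.
#' @param alpha Nominal significance level, in (0, 1).
#' @param bonferroni_n Optional pinned Bonferroni denominator; by default the
#'   number of tests actually performed is used.
#' @param outlier_threshold Omega-lineage flagging threshold
#'   (see [flag_outliers()]).
#' @param df_override Optional pinned degrees of freedom for the Mk scheme
#'   comparison.
#' @param activity_gene,sws1_gene Gene names (of `alignments`) whose
#'   omega-trees carry the discrete reconstructions of activity pattern and
#'   VS/UVS vision.
#' @param seed Integer master seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(alignments, tree, traits = NULL, K = 10, n_starts = 3,
                       alpha = 0.05, bonferroni_n = NULL,
                       outlier_threshold = 1.5, df_override = NULL,
                       activity_gene = NULL, sws1_gene = NULL, seed = 1) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(alignments) == 0L) stop("config error: no genes supplied")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    stop("config error: alignments must be a named list")
  }
  alignments <- lapply(setNames(names(alignments), names(alignments)),
                       function(g) {
    a <- alignments[[g]]
    if (is.character(a)) {
      if (!file.exists(a)) stop("config error: alignment file for gene '",
                                g, "' not found: ", a)
      a <- read_codon_fasta(a)
    }
    stopifnot(inherits(a, "codon_alignment"))
    a
  })
  if (is.character(tree)) {
    if (!file.exists(tree)) stop("config error: tree file not found: ", tree)
    tree <- parse_newick(tree)
  }
  validate_tree(tree)
  if (is.character(traits)) {
    if (!file.exists(traits)) stop("config error: trait file not found: ", traits)
    traits <- read_trait_table(traits)
  }
  structure(list(alignments = alignments, tree = tree, traits = traits,
                 K = K, n_starts = n_starts, alpha = alpha,
                 bonferroni_n = bonferroni_n,
                 outlier_threshold = outlier_threshold,
                 df_override = df_override, activity_gene = activity_gene,
                 sws1_gene = sws1_gene, seed = seed),
            class = "run_config")
}

#' Per-gene site-selection scan
#'
#' Fits M7, M8 and M8a to every gene, performs the M8-vs-M7 and M8-vs-M8a
#' likelihood-ratio tests, and flags positively selected sites by naive
#' empirical Bayes (posterior > 0.75 on the selected class) for genes whose
#' M8 test is significant at `alpha`.
#'
#' @param config A [run_config()].
#' @return A list with `report` (one row per gene: log-likelihoods, LRT
#'   statistics, degrees of freedom and p-values, number of flagged sites)
#'   and `fits`/`flagged_sites` per gene.
#' @export
run_site_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genes <- names(config$alignments)
  fits <- list(); flagged <- list(); rows <- list()
  for (g in genes) {
    aln <- config$alignments[[g]]
    f7 <- fit_site_model(aln, config$tree, "M7", K = config$K,
                         seed = config$seed, n_starts = config$n_starts)
    f8a <- fit_site_model(aln, config$tree, "M8a", K = config$K,
                          seed = config$seed + 1, n_starts = config$n_starts)
    f8 <- fit_site_model(aln, config$tree, "M8", K = config$K,
                         seed = config$seed + 2, n_starts = config$n_starts)
    # monotone repair across the nested pair: M8 must not fall below M8a/M7
    lnL8 <- max(f8$lnL, f8a$lnL, f7$lnL)
    t87 <- lrt_from_stat(max(0, 2 * (lnL8 - f7$lnL)), df = f8$np - f7$np)
    t88a <- lrt_from_stat(max(0, 2 * (lnL8 - f8a$lnL)), df = f8$np - f8a$np)
    post <- site_posteriors(f8)
    sig8 <- t88a$p_value < config$alpha
    fl <- if (sig8) post$site[post$flagged] else integer(0)
    fits[[g]] <- list(M7 = f7, M8a = f8a, M8 = f8)
    flagged[[g]] <- fl
    rows[[g]] <- data.frame(
      gene = g, lnL_M7 = f7$lnL, lnL_M8a = f8a$lnL, lnL_M8 = f8$lnL,
      lrt_M8_vs_M7 = t87$statistic, df_M8_vs_M7 = t87$df,
      p_M8_vs_M7 = t87$p_value,
      lrt_M8_vs_M8a = t88a$statistic, df_M8_vs_M8a = t88a$df,
      p_M8_vs_M8a = t88a$p_value,
      significant = sig8, n_flagged_sites = length(fl),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, fits = fits, flagged_sites = flagged,
       alpha = config$alpha)
}

#' Omega-lineage scan and two-ratio follow-up tests
#'
#' Per gene: fits the free-ratios model, builds the omega-tree (outlier
#' branches recalculated), linearizes it into root-to-tip omega-lineages and
#' flags outlier tips; then tests each candidate lineage (flagged tips, or
#' `candidates` if given) with the one-ratio vs two-ratio LRT. The Bonferroni
#' threshold is computed from the number of tests actually performed unless
#' `config$bonferroni_n` pins it.
#'
#' @param config A [run_config()].
#' @param candidates Optional character vector of tip labels to test in every
#'   gene, bypassing the omega-lineage flags.
#' @return A list with `report` (one row per gene x candidate: LRT, df,
#'   p-value, Bonferroni threshold and significance), `omega_trees`,
#'   `lineages` and `free_fits` per gene, and `bonferroni_threshold`.
#' @export
run_branch_scan <- function(config, candidates = NULL) {
  stopifnot(inherits(config, "run_config"))
  genes <- names(config$alignments)
  otrees <- list(); lineages <- list(); free_fits <- list()
  cand <- list()
  for (g in genes) {
    aln <- config$alignments[[g]]
    # free-ratios: one seeded start — with one parameter per branch the
    # default starting point dominates and restarts add little
    ff <- fit_branch_model(aln, config$tree, "free_ratios",
                           seed = config$seed, n_starts = 1)
    ot <- build_omega_tree(config$tree, ff$per_branch)
    lin <- flag_outliers(omega_lineages(ot),
                         threshold = config$outlier_threshold)
    free_fits[[g]] <- ff
    otrees[[g]] <- ot
    lineages[[g]] <- lin
    cand[[g]] <- if (is.null(candidates)) lin$tip[lin$outlier] else candidates
  }
  rows <- list()
  for (g in genes) {
    if (!length(cand[[g]])) next
    f1 <- fit_branch_model(config$alignments[[g]], config$tree, "one_ratio",
                           seed = config$seed + 10,
                           n_starts = config$n_starts)
    for (tip in cand[[g]]) {
      f2 <- fit_branch_model(config$alignments[[g]], config$tree, "two_ratio",
                             foreground = tip, seed = config$seed + 11,
                             n_starts = config$n_starts)
      tt <- lrt_from_stat(max(0, 2 * (max(f2$lnL, f1$lnL) - f1$lnL)), df = 1)
      rows[[paste(g, tip)]] <- data.frame(
        gene = g, lineage = tip,
        lnL_one_ratio = f1$lnL, lnL_two_ratio = f2$lnL,
        omega_background = f2$estimates$omega[1],
        omega_foreground = f2$estimates$omega[2],
        lrt = tt$statistic, df = tt$df, p_value = tt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), lineage = character(),
               lnL_one_ratio = numeric(), lnL_two_ratio = numeric(),
               omega_background = numeric(), omega_foreground = numeric(),
               lrt = numeric(), df = numeric(), p_value = numeric())
  n_tests <- if (!is.null(config$bonferroni_n)) config$bonferroni_n
  else max(1L, nrow(report))
  thr <- bonferroni_threshold(config$alpha, n_tests)
  if (nrow(report)) {
    report$bonferroni_threshold <- thr
    report$significant <- report$p_value < thr
  }
  rownames(report) <- NULL
  list(report = report, omega_trees = otrees, lineages = lineages,
       free_fits = free_fits, bonferroni_threshold = thr,
       n_tests = n_tests)
}

#' Moran-gated ancestral reconstructions with cross-gene aggregation
#'
#' Runs the ancestral-reconstruction stage on a set of omega-trees: discrete
#' reconstructions (activity pattern on `config$activity_gene`; VS/UVS on
#' `config$sws1_gene` after [classify_vs_uvs()]) with the SYM-vs-ARD scheme
#' comparison; continuous reconstructions (orbit convergence, visual acuity)
#' on every gene's omega-tree, gated by Moran's I with a Bonferroni-corrected
#' threshold over the gene-by-trait comparisons actually made, then
#' aggregated across surviving genes per node; and the Wilcoxon rank-sum test
#' of orbit convergence between nocturnal and diurnal species.
#'
#' @param config A [run_config()] whose `traits` is set.
#' @param omega_trees Named list of omega-trees (e.g. from
#'   [run_branch_scan()]); names must include the marker genes.
#' @return A list with components `discrete` (per marker gene: fits, scheme
#'   LRT, node probabilities), `moran` (gene x trait gate table),
#'   `continuous` (per gene x trait reconstructions), `aggregated` (per node
#'   x trait means and SDs across gated genes, or an empty table with an
#'   `explanation` when every gene is gated out) and `wilcoxon`.
#' @export
run_ancestral <- function(config, omega_trees) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$traits)) stop("config error: trait table required")
  traits <- classify_vs_uvs(config$traits)
  genes <- names(omega_trees)

  discrete <- list()
  do_discrete <- function(gene, states_vec, label) {
    ot <- omega_trees[[gene]]
    st <- states_vec[intersect(names(states_vec), ot$tip.label)]
    if (length(unique(st[!is.na(st)])) < 2) {
      return(list(trait = label, gene = gene, skipped = "fewer than 2 states"))
    }
    fs <- fit_mk(ot, st, "SYM", seed = config$seed)
    fa <- fit_mk(ot, st, "ARD", seed = config$seed)
    cmp <- compare_mk_schemes(fs, fa, df_override = config$df_override)
    chosen <- if (cmp$p_value < config$alpha) fa else fs
    rec <- marginal_ancestral_states(chosen)
    list(trait = label, gene = gene, fit_sym = fs, fit_ard = fa,
         scheme_lrt = cmp, chosen_scheme = chosen$scheme,
         reconstruction = rec)
  }
  if (!is.null(config$activity_gene) &&
      config$activity_gene %in% genes) {
    act <- setNames(ifelse(traits$activity_pattern == "unknown", NA,
                           traits$activity_pattern), traits$species_id)
    discrete$activity <- do_discrete(config$activity_gene, act, "activity")
  }
  if (!is.null(config$sws1_gene) && config$sws1_gene %in% genes) {
    vu <- as.character(traits$vs_uvs)
    vu[!vu %in% c("UVS", "VS")] <- NA
    discrete$vs_uvs <- do_discrete(config$sws1_gene,
                                   setNames(vu, traits$species_id), "vs_uvs")
  }

  cont_traits <- c(orbit_convergence = "orbit_convergence",
                   visual_acuity = "visual_acuity")
  moran_rows <- list(); recs <- list(); est_rows <- list()
  for (g in genes) {
    ot <- omega_trees[[g]]
    for (tr_name in names(cont_traits)) {
      v <- setNames(traits[[cont_traits[[tr_name]]]], traits$species_id)
      v <- v[intersect(names(v)[!is.na(v)], ot$tip.label)]
      if (length(v) < 3) next
      sub <- if (length(v) < length(ot$tip.label)) {
        ape::drop.tip(ot, setdiff(ot$tip.label, names(v)))
      } else ot
      mi <- tryCatch(morans_i(v[sub$tip.label], moran_weights(sub)),
                     error = function(e) NULL)
      if (is.null(mi)) next
      moran_rows[[paste(g, tr_name)]] <- data.frame(
        gene = g, trait = tr_name, moran_i = mi$observed,
        expected = mi$expected, p_value = mi$p_value,
        stringsAsFactors = FALSE)
      rec <- bm_ancestral(sub, v)
      recs[[paste(g, tr_name)]] <- rec
      est_rows[[paste(g, tr_name)]] <- data.frame(
        gene = g, trait = tr_name,
        node = rec$node_estimates$node,
        estimate = rec$node_estimates$estimate,
        stringsAsFactors = FALSE)
    }
  }
  moran <- if (length(moran_rows)) do.call(rbind, moran_rows) else
    data.frame(gene = character(), trait = character(), moran_i = numeric(),
               expected = numeric(), p_value = numeric())
  n_comp <- if (!is.null(config$bonferroni_n)) config$bonferroni_n
  else max(1L, nrow(moran))
  gate_thr <- bonferroni_threshold(config$alpha, n_comp)
  aggregated <- list()
  for (tr_name in names(cont_traits)) {
    sub_est <- do.call(rbind, est_rows[moran$p_value < gate_thr &
                                         moran$trait == tr_name])
    if (is.null(sub_est) || !nrow(sub_est)) next
    agg <- aggregate_across_genes(sub_est[c("gene", "node", "estimate")])
    agg$trait <- tr_name
    aggregated[[tr_name]] <- agg
  }
  aggregated <- if (length(aggregated)) do.call(rbind, aggregated) else {
    out <- data.frame(node = integer(), mean = numeric(), sd = numeric(),
                      n_genes = integer(), trait = character())
    attr(out, "explanation") <-
      "no gene passed the Moran's I phylogenetic-signal gate"
    out
  }
  rownames(moran) <- rownames(aggregated) <- NULL

  noct <- traits$orbit_convergence[traits$activity_pattern == "nocturnal" &
                                     !is.na(traits$orbit_convergence)]
  diur <- traits$orbit_convergence[traits$activity_pattern == "diurnal" &
                                     !is.na(traits$orbit_convergence)]
  wilcox <- if (length(noct) && length(diur)) {
    wilcoxon_ranksum(noct, diur)
  } else NULL

  list(discrete = discrete, moran = moran, gate_threshold = gate_thr,
       n_comparisons = n_comp, continuous = recs, aggregated = aggregated,
       wilcoxon = wilcox)
}

#' Deterministic run manifest
#'
#' Machine-readable provenance for a pipeline run: the master seed, a
#' checksum of the canonicalized configuration, the package version and the
#' stage names run. Re-running with an identical manifest reproduces
#' identical outputs for the deterministic stages.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names that were (or will be) run.
#' @param file Optional path to also write the manifest as JSON.
#' @return A list of class `run_manifest`.
#' @export
manifest <- function(config, stages = character(), file = NULL) {
  stopifnot(inherits(config, "run_config"))
  man <- list(seed = config$seed,
              config_hash = config_hash(config),
              package = "opsinevo",
              version = as.character(packageVersion("opsinevo")),
              genes = names(config$alignments),
              n_tips = length(config$tree$tip.label),
              stages = stages)
  class(man) <- "run_manifest"
  if (!is.null(file)) {
    jsonlite::write_json(unclass(man), file, auto_unbox = TRUE, digits = NA)
  }
  man
}

#' Verify a manifest against a configuration
#'
#' @param man A [manifest()] result (or a path to its JSON form).
#' @param config The [run_config()] to check against.
#' @return TRUE if the manifest's configuration checksum matches; otherwise
#'   an error describing the mismatch.
#' @export
verify_manifest <- function(man, config) {
  if (is.character(man)) man <- jsonlite::read_json(man, simplifyVector = TRUE)
  h <- config_hash(config)
  if (!identical(man$config_hash, h)) {
    stop("manifest config hash mismatch: manifest has ", man$config_hash,
         ", configuration hashes to ", h)
  }
  TRUE
}

# md5 checksum of the canonical JSON form of a configuration (alignments and
# trees serialized as text so the hash is representation-independent)
config_hash <- function(config) {
  canon <- list(
    alignments = lapply(config$alignments, write_codon_fasta),
    tree = write_newick(config$tree),
    traits = if (!is.null(config$traits)) {
      as.list(as.data.frame(config$traits))
    },
    options = config[setdiff(names(config),
                             c("alignments", "tree", "traits"))])
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(canon, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
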