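# Tabular export of results: TSV tables (per-branch dN/dS in the layout of
# published omega-tree supplements, per-site posteriors, per-tip lineage
# scores, per-node reconstructions) and JSON summaries.

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export a codon fit
#'
#' Writes a JSON summary (model, estimates, lnL, np) and, where available,
#' TSV tables of per-branch omega/dN/dS and naive-empirical-Bayes site
#' posteriors.
#'
#' @param fit A `codon_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (e.g. the gene name).
#' @return Character vector of the files written, invisibly.
#' @export
export_codon_fit <- function(fit, dir, prefix = fit$model) {
  stopifnot(inherits(fit, "codon_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  est <- fit$estimates[setdiff(names(fit$estimates), "codon_freqs")]
  summ <- list(model = fit$model, lnL = fit$lnL, np = fit$np,
               converged = fit$converged, estimates = est)
  f <- file.path(dir, paste0(prefix, "_fit.json"))
  jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (!is.null(fit$per_branch)) {
    f <- file.path(dir, paste0(prefix, "_branches.tsv"))
    write_tsv(fit$per_branch, f)
    files <- c(files, f)
  }
  if (fit$model %in% c("M7", "M8", "M8a")) {
    f <- file.path(dir, paste0(prefix, "_site_posteriors.tsv"))
    write_tsv(site_posteriors(fit), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Export an omega-tree and its lineage scores
#'
#' Writes the omega-tree as newick (branch values = dN/dS), the per-branch
#' provenance table, and the standardized per-tip omega-lineage ranking.
#'
#' @param otree A [build_omega_tree()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param threshold Outlier threshold forwarded to [flag_outliers()].
#' @return Character vector of the files written, invisibly.
#' @export
export_omega_tree <- function(otree, dir, prefix = "omega_tree",
                              threshold = 1.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, paste0(prefix, ".nwk"))
  writeLines(write_newick(otree), f1)
  f2 <- file.path(dir, paste0(prefix, "_branches.tsv"))
  write_tsv(attr(otree, "provenance"), f2)
  f3 <- file.path(dir, paste0(prefix, "_lineages.tsv"))
  write_tsv(flag_outliers(omega_lineages(otree), threshold = threshold), f3)
  invisible(c(f1, f2, f3))
}

#' Export an ancestral reconstruction
#'
#' Discrete reconstructions are written as a per-node state-probability table
#' (pie-chart-ready CSV when `format = "csv"`); continuous ones as a per-node
#' estimate/SD table.
#'
#' @param recon An `ancestral_recon`.
#' @param file Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `file`, invisibly.
#' @export
export_reconstruction <- function(recon, file, format = c("tsv", "csv")) {
  stopifnot(inherits(recon, "ancestral_recon"))
  format <- match.arg(format)
  df <- if (recon$type == "discrete") recon$node_probs else recon$node_estimates
  if (format == "tsv") write_tsv(df, file) else {
    write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}
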