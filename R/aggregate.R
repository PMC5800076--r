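# Cross-gene aggregation of ancestral reconstructions: gene trees whose
# trait fails the phylogenetic-signal gate are excluded, as are nodes whose
# clade is represented by at most one sampled species in a given gene; the
# surviving per-gene estimates are summarized by their unweighted mean and
# population standard deviation.

#' Aggregate ancestral estimates across genes
#'
#' @param estimates Long-format data.frame with columns `gene`, `node`,
#'   `estimate`, and optionally `state` (for discrete reconstructions, one
#'   row per gene x node x state).
#' @param gate Optional data.frame with columns `gene` and `p_value`
#'   (typically Moran's I p-values): genes with `p_value >= threshold` are
#'   excluded.
#' @param threshold Significance threshold for the gate; pass a
#'   Bonferroni-corrected value (see [bonferroni_threshold()]) to mirror a
#'   corrected gate.
#' @param representation Optional data.frame with columns `gene`, `node`,
#'   `n_species`: gene x node combinations represented by fewer than
#'   `min_species` sampled species are excluded.
#' @param min_species Minimum number of sampled species representing a clade
#'   for a gene's estimate at that node to count.
#' @return A data.frame with one row per node (and state, if present):
#'   `mean`, `sd` (population convention, divide by n) and `n_genes`.
#'   Nodes for which no gene survives are absent from the output.
#' @examples
#' est <- data.frame(gene = c("g1", "g2"), node = 1, estimate = c(40, 50))
#' aggregate_across_genes(est) # mean 45, sd 5
#' @export
aggregate_across_genes <- function(estimates, gate = NULL, threshold = 0.05,
                                   representation = NULL, min_species = 2) {
  stopifnot(is.data.frame(estimates),
            all(c("gene", "node", "estimate") %in% names(estimates)))
  df <- estimates
  if (!is.null(gate)) {
    stopifnot(all(c("gene", "p_value") %in% names(gate)))
    pass <- gate$gene[gate$p_value < threshold]
    df <- df[df$gene %in% pass, , drop = FALSE]
  }
  if (!is.null(representation)) {
    stopifnot(all(c("gene", "node", "n_species") %in% names(representation)))
    ok <- representation[representation$n_species >= min_species,
                         c("gene", "node")]
    key <- paste(df$gene, df$node)
    df <- df[key %in% paste(ok$gene, ok$node), , drop = FALSE]
  }
  if (!nrow(df)) {
    out <- data.frame(node = integer(), mean = numeric(), sd = numeric(),
                      n_genes = integer())
    if ("state" %in% names(estimates)) out$state <- character()
    return(out)
  }
  keys <- if ("state" %in% names(df)) df[c("node", "state")] else df["node"]
  pop_sd <- function(x) sqrt(mean((x - mean(x)) ^ 2))
  agg <- aggregate(df$estimate, by = as.list(keys),
                   FUN = function(x) c(mean = mean(x), sd = pop_sd(x),
                                       n = length(x)))
  out <- cbind(agg[setdiff(names(agg), "x")],
               mean = agg$x[, "mean"], sd = agg$x[, "sd"],
               n_genes = as.integer(agg$x[, "n"]))
  rownames(out) <- NULL
  out[order(out$node), , drop = FALSE]
}
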