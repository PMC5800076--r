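# Omega-trees: trees whose branch values are per-branch dN/dS estimates
# (from a free-ratios fit), with robust recalculation of outlier branches,
# root-to-tip linearization (omega-lineages), and median/IQR standardization
# for outlier scanning.

#' Build an omega-tree from per-branch estimates
#'
#' Replaces the branch lengths of `tree` by per-branch dN/dS estimates.
#' Branches whose ratio exceeds `outlier_cutoff` (strict inequality; such
#' values typically arise from near-zero dS estimates) are recalculated in a
#' single pass as `dN / median(dS)`, where the median is taken over all
#' branches with positive dS; the substitution is applied once and not
#' iterated even if the recalculated value still exceeds the cutoff.
#'
#' @param tree Rooted `phylo` supplying the topology.
#' @param per_branch A data.frame with columns `edge` (row index into
#'   `tree$edge`), `omega`, `dN` and `dS` covering every edge — the
#'   `per_branch` table of a free-ratios [fit_branch_model()] fit works
#'   directly.
#' @param outlier_cutoff Ratio above which a branch is recalculated.
#' @return An object of class `omega_tree`: the `phylo` with
#'   `edge.length` set to the (possibly recalculated) dN/dS values, plus a
#'   `provenance` data.frame recording, per edge, the flag
#'   (`"direct"`/`"recalculated"`) and the original `omega`, `dN`, `dS`.
#' @export
build_omega_tree <- function(tree, per_branch, outlier_cutoff = 10) {
  validate_tree(tree)
  stopifnot(is.data.frame(per_branch),
            all(c("edge", "omega", "dN", "dS") %in% names(per_branch)))
  nedge <- nrow(tree$edge)
  if (!setequal(per_branch$edge, seq_len(nedge))) {
    stop("per_branch must provide an estimate for every tree edge")
  }
  pb <- per_branch[match(seq_len(nedge), per_branch$edge), ]
  if (any(pb$omega < 0, na.rm = TRUE)) stop("negative omega estimate")
  pos_ds <- pb$dS[pb$dS > 0]
  omega <- pb$omega
  flag <- rep("direct", nedge)
  out <- which(omega > outlier_cutoff)
  if (length(out)) {
    if (!length(pos_ds)) {
      stop("all branch dS estimates are zero; median dS undefined")
    }
    med_ds <- median(pos_ds)
    omega[out] <- pb$dN[out] / med_ds
    flag[out] <- "recalculated"
  }
  otree <- tree
  otree$edge.length <- omega
  attr(otree, "provenance") <- data.frame(
    edge = seq_len(nedge), flag = flag,
    omega_original = pb$omega, dN = pb$dN, dS = pb$dS,
    stringsAsFactors = FALSE)
  class(otree) <- c("omega_tree", class(tree))
  otree
}

#' @export
print.omega_tree <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat("omega-tree:", length(x$tip.label), "tips;",
      sum(pv$flag == "recalculated"), "branch(es) recalculated\n")
  invisible(x)
}

#' Omega-lineages: root-to-tip linearization of an omega-tree
#'
#' The omega-lineage of a species is the sum of the branch dN/dS values along
#' the path from the root to its tip; the root contributes zero.
#'
#' @param otree An [build_omega_tree()] result (any valid `phylo` whose
#'   branch values are dN/dS works).
#' @return A data.frame of class `omega_lineages` with columns `tip` and
#'   `raw` (the root-to-tip sum).
#' @export
omega_lineages <- function(otree) {
  validate_tree(otree)
  depth <- node_depths(otree)
  ntip <- length(otree$tip.label)
  structure(data.frame(tip = otree$tip.label, raw = depth[seq_len(ntip)],
                       stringsAsFactors = FALSE),
            class = c("omega_lineages", "data.frame"))
}

#' Robust standardization by median and interquartile range
#'
#' Standardizes scores as `(x - median(x)) / IQR(x)`. Quartiles use linear
#' interpolation between order statistics (the type-7 convention, R's
#' default), so e.g. `1:5` standardizes to `(-1, -0.5, 0, 0.5, 1)`.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Standardized numeric vector.
#' @export
standardize_scores <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  iqr <- IQR(values, type = 7)
  if (iqr == 0) stop("IQR is zero; scores cannot be standardized")
  (values - median(values)) / iqr
}

#' Flag omega-lineage outliers
#'
#' Standardizes raw omega-lineages (median/IQR) and flags tips whose absolute
#' standardized score exceeds `threshold` (the default 1.5 follows the
#' box-plot whisker convention on the median/IQR scale).
#'
#' @param lineages An [omega_lineages()] data.frame (or any data.frame with
#'   `tip` and `raw` columns).
#' @param threshold Positive flagging threshold on |standardized score|.
#' @return The input ranked by |standardized score| (largest first) with
#'   added columns `standardized`, `outlier` and `rank`.
#' @export
flag_outliers <- function(lineages, threshold = 1.5) {
  stopifnot(threshold > 0, all(c("tip", "raw") %in% names(lineages)))
  z <- standardize_scores(lineages$raw)
  out <- data.frame(tip = lineages$tip, raw = lineages$raw, standardized = z,
                    outlier = abs(z) > threshold, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$standardized)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
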