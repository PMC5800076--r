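# Static reference fixtures transcribed from the published description of
# tetrapod opsin gene repertoires and from the printed example phenotypes.
# These encode reported genome-survey results as data; the package does not
# recompute genome searches. Entries whose support comes only from a figure
# (not from printed text) carry provenance "figure_only" and are excluded
# from text-level checks.

.OPSIN_GENES <- c("RH1", "RH2", "OPN1sw1", "OPN1sw2", "OPN1lw",
                  "OPN3", "TMT", "TMT2",
                  "PARA", "PARIE", "PIN", "VA",
                  "OPN5", "RGR", "RRH",
                  "OPN4x", "OPN4m")

.MAMMAL_OPSINS <- c("RH1", "OPN1sw1", "OPN1sw2", "OPN1lw", "OPN3", "TMT",
                    "OPN5", "RGR", "RRH", "OPN4m")

#' Tetrapod opsin repertoire fixture
#'
#' Presence/absence of the 17 tetrapod opsin genes in amphibians, reptiles,
#' birds and mammals, transcribed from reported genome-survey counts
#' (amphibians 16, reptiles 17, birds 15, mammals 10) and the stated gene
#' losses (the ten-gene mammalian repertoire; birds lacking the PARA and
#' PARIE pineal opsins). The identity of the single opsin missing from
#' amphibians is shown only in a figure, so that one cell carries provenance
#' `figure_only`; all other cells are `text`.
#'
#' @return A data.frame with columns `gene`, `lineage`, `present` and
#'   `provenance`.
#' @export
opsin_repertoire <- function() {
  lineages <- c("amphibians", "reptiles", "birds", "mammals")
  df <- expand.grid(gene = .OPSIN_GENES, lineage = lineages,
                    stringsAsFactors = FALSE)
  df$present <- TRUE
  df$provenance <- "text"
  df$present[df$lineage == "mammals"] <- df$gene[df$lineage == "mammals"] %in%
    .MAMMAL_OPSINS
  df$present[df$lineage == "birds" & df$gene %in% c("PARA", "PARIE")] <- FALSE
  amph_missing <- df$lineage == "amphibians" & df$gene == "PIN"
  df$present[amph_missing] <- FALSE
  df$provenance[amph_missing] <- "figure_only"
  df
}

#' Repertoire sizes per lineage
#'
#' @param repertoire An [opsin_repertoire()] table (default: the fixture).
#' @return Named integer vector of present-gene counts per lineage.
#' @export
repertoire_sizes <- function(repertoire = opsin_repertoire()) {
  vapply(split(repertoire$present, repertoire$lineage), sum, numeric(1))
}

#' Example phenotype fixture
#'
#' Mini trait table with the two printed reference phenotypes: the diurnal
#' human (orbit convergence 79.3 degrees, visual acuity 64 cycles/degree) and
#' the nocturnal brown rat (32 degrees, 1.6 cycles/degree).
#'
#' @return A [trait_table()] with two rows.
#' @export
example_phenotypes <- function() {
  trait_table(data.frame(
    species_id = c("Homo_sapiens", "Rattus_norvegicus"),
    activity_pattern = c("diurnal", "nocturnal"),
    is_primate = c(TRUE, FALSE),
    orbit_convergence = c(79.3, 32),
    visual_acuity = c(64, 1.6),
    stringsAsFactors = FALSE))
}

#' All bundled static fixtures
#'
#' @return A list with `repertoire` ([opsin_repertoire()]),
#'   `repertoire_sizes` and `phenotypes` ([example_phenotypes()]).
#' @export
published_fixtures <- function() {
  list(repertoire = opsin_repertoire(),
       repertoire_sizes = repertoire_sizes(),
       phenotypes = example_phenotypes())
}
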