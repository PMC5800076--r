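# Spectral-tuning rules for the short-wavelength-sensitive SWS1 (OPN1sw1)
# opsin: reference-numbering site maps, the site-86 violet/ultraviolet
# classification rule, and the site-93 residue-by-activity segregation
# summary.

#' Map alignment columns to reference positions
#'
#' Builds the column-to-reference-position map used to talk about alignment
#' sites in a reference numbering (e.g. bovine rhodopsin): column `i` maps to
#' the count of non-missing reference codons up to and including `i`; columns
#' where the reference has a gap/missing codon are unmapped.
#'
#' @param aln A [codon_alignment()].
#' @param reference_id Id of the reference sequence row.
#' @return An object of class `site_map`: data.frame with columns `column`
#'   (alignment codon column) and `position` (reference position), covering
#'   mapped columns only.
#' @export
build_site_map <- function(aln, reference_id) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!reference_id %in% aln$ids) {
    stop("reference sequence '", reference_id, "' absent from alignment")
  }
  ref <- aln$codons[reference_id, ]
  present <- !is.na(ref)
  map <- data.frame(column = which(present), position = cumsum(present)[present])
  attr(map, "reference_id") <- reference_id
  class(map) <- c("site_map", "data.frame")
  map
}

#' Alignment column for a reference position
#'
#' @param map A [build_site_map()] result.
#' @param position Reference position(s) (1-based).
#' @return Alignment column(s); NA when the position exceeds the reference.
#' @export
site_map_column <- function(map, position) {
  map$column[match(position, map$position)]
}

.VS_RESIDUES <- c("Y", "S", "V", "C", "L")

#' Classify SWS1 pigments as violet- or ultraviolet-sensitive
#'
#' Applies the site-86 residue rule to each species record: species with an
#' inactive SWS1 copy are `excluded`; phenylalanine (F) at site 86 implies
#' `UVS`, except in primates, where the rule does not apply and the record is
#' `unclassified`; Y, S, V, C or L imply `VS`; any other residue (or a
#' missing one) is `unclassified`.
#'
#' @param traits A [trait_table()].
#' @return The trait table with an added factor column `vs_uvs` taking values
#'   `UVS`, `VS`, `unclassified`, `excluded`.
#' @export
classify_vs_uvs <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  res <- traits$site86_residue
  cls <- rep("unclassified", nrow(traits))
  cls[!is.na(res) & res == "F" & !traits$is_primate] <- "UVS"
  cls[!is.na(res) & res %in% .VS_RESIDUES] <- "VS"
  cls[!traits$sws1_active] <- "excluded"
  traits$vs_uvs <- factor(cls, levels = c("UVS", "VS", "unclassified",
                                          "excluded"))
  traits
}

.SITE93_NOCTURNAL <- c("T", "S", "A", "M")
.SITE93_DIURNAL <- c("P", "V", "C")

#' Site-93 residue-by-activity segregation table
#'
#' Cross-tabulates the amino acid at SWS1 site 93 against the
#' nocturnal/diurnal activity pattern. Cathemeral and unknown-activity
#' records carry no signal for this two-way contrast and are excluded from
#' the table but counted separately; records lacking the site-93 residue are
#' dropped.
#'
#' @param traits A [trait_table()]; an optional `order` column enables the
#'   per-order breakdown.
#' @return A list of class `site93_segregation`: `table` (residue x
#'   activity counts), `excluded` (named counts of cathemeral / unknown /
#'   missing-residue records), `by_order` (residue x activity x order counts,
#'   or NULL), and `concordance` — the proportion of tabulated records whose
#'   residue falls in the activity-concordant set (T/S/A/M for nocturnal,
#'   P/V/C for diurnal), reported against those literature sets rather than
#'   used as a classifier.
#' @export
site93_segregation <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  has93 <- !is.na(traits$site93_residue)
  two_way <- traits$activity_pattern %in% c("nocturnal", "diurnal")
  keep <- has93 & two_way
  excluded <- c(cathemeral = sum(has93 & traits$activity_pattern == "cathemeral"),
                unknown_activity = sum(has93 & traits$activity_pattern == "unknown"),
                missing_residue = sum(!has93))
  sub <- traits[keep, , drop = FALSE]
  tab <- table(residue = sub$site93_residue,
               activity = factor(sub$activity_pattern,
                                 levels = c("nocturnal", "diurnal")))
  by_order <- if (!is.null(sub$order) && nrow(sub)) {
    table(residue = sub$site93_residue,
          activity = factor(sub$activity_pattern,
                            levels = c("nocturnal", "diurnal")),
          order = sub$order)
  }
  concord <- if (nrow(sub)) {
    mean((sub$activity_pattern == "nocturnal" &
            sub$site93_residue %in% .SITE93_NOCTURNAL) |
           (sub$activity_pattern == "diurnal" &
              sub$site93_residue %in% .SITE93_DIURNAL))
  } else NA_real_
  structure(list(table = tab, excluded = excluded, by_order = by_order,
                 concordance = concord),
            class = "site93_segregation")
}

#' @export
print.site93_segregation <- function(x, ...) {
  cat("site-93 residue x activity segregation\n")
  print(x$table)
  cat("excluded:", paste(names(x$excluded), x$excluded, sep = "=",
                         collapse = ", "), "\n")
  if (!is.na(x$concordance)) {
    cat(sprintf("concordance with nocturnal {T,S,A,M} / diurnal {P,V,C}: %.3f\n",
                x$concordance))
  }
  invisible(x)
}
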