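# Universal genetic code over the 61 sense codons.
#
# Codons are ordered lexicographically over (A, C, G, T) triplets with the
# three stop codons (TAA, TAG, TGA) removed; this ordering is part of the
# package contract and is stable across versions.

.NUC <- c("A", "C", "G", "T")

# amino acid for each of the 64 lexicographic codons (universal code)
.GENETIC_CODE_64 <- c(
  AAA = "K", AAC = "N", AAG = "K", AAT = "N",
  ACA = "T", ACC = "T", ACG = "T", ACT = "T",
  AGA = "R", AGC = "S", AGG = "R", AGT = "S",
  ATA = "I", ATC = "I", ATG = "M", ATT = "I",
  CAA = "Q", CAC = "H", CAG = "Q", CAT = "H",
  CCA = "P", CCC = "P", CCG = "P", CCT = "P",
  CGA = "R", CGC = "R", CGG = "R", CGT = "R",
  CTA = "L", CTC = "L", CTG = "L", CTT = "L",
  GAA = "E", GAC = "D", GAG = "E", GAT = "D",
  GCA = "A", GCC = "A", GCG = "A", GCT = "A",
  GGA = "G", GGC = "G", GGG = "G", GGT = "G",
  GTA = "V", GTC = "V", GTG = "V", GTT = "V",
  TAA = "*", TAC = "Y", TAG = "*", TAT = "Y",
  TCA = "S", TCC = "S", TCG = "S", TCT = "S",
  TGA = "*", TGC = "C", TGG = "W", TGT = "C",
  TTA = "L", TTC = "F", TTG = "L", TTT = "F"
)

.STOP_CODONS <- names(.GENETIC_CODE_64)[.GENETIC_CODE_64 == "*"]
.SENSE_CODONS <- names(.GENETIC_CODE_64)[.GENETIC_CODE_64 != "*"]
.SENSE_AA <- unname(.GENETIC_CODE_64[.SENSE_CODONS])
.N_CODON <- length(.SENSE_CODONS) # 61

#' Sense-codon table
#'
#' The 61 sense codons of the universal genetic code in the package's
#' canonical order (lexicographic over A, C, G, T with stops removed),
#' together with their encoded amino acids.
#'
#' @return A data.frame with columns `index` (1-based position in the
#'   canonical order), `codon` and `aa` (one-letter amino-acid code).
#' @examples
#' head(codon_table())
#' @export
codon_table <- function() {
  data.frame(index = seq_len(.N_CODON), codon = .SENSE_CODONS, aa = .SENSE_AA,
             stringsAsFactors = FALSE)
}

# 61 x 3 matrix of nucleotide indices (1..4) per codon position
.codon_nuc_idx <- local({
  m <- t(vapply(strsplit(.SENSE_CODONS, ""), function(s) match(s, .NUC),
                integer(3)))
  dimnames(m) <- list(.SENSE_CODONS, NULL)
  m
})

# Pairwise codon relations, computed once at load time:
#   .codon_diff     - number of differing nucleotide positions (61 x 61)
#   .codon_ts       - TRUE where the single difference is a transition
#   .codon_nonsyn   - TRUE where the amino acids differ
.codon_rel <- local({
  n <- .N_CODON
  diffs <- matrix(0L, n, n)
  for (pos in 1:3) diffs <- diffs + outer(.codon_nuc_idx[, pos],
                                          .codon_nuc_idx[, pos], "!=")
  is_ts <- function(a, b) (a == 1 & b == 3) | (a == 3 & b == 1) |
    (a == 2 & b == 4) | (a == 4 & b == 2)
  ts <- matrix(FALSE, n, n)
  for (pos in 1:3) {
    d_here <- outer(.codon_nuc_idx[, pos], .codon_nuc_idx[, pos], "!=")
    ts <- ts | (d_here & outer(.codon_nuc_idx[, pos], .codon_nuc_idx[, pos], is_ts))
  }
  nonsyn <- outer(.SENSE_AA, .SENSE_AA, "!=")
  list(diff = diffs, ts = ts, nonsyn = nonsyn)
})

codon_index <- function(codons) match(toupper(codons), .SENSE_CODONS)
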