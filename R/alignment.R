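# Codon alignment container and FASTA I/O.
#
# A codon_alignment stores species-by-codon-site integer indices into the
# canonical 61 sense-codon order (see codon_table()); NA marks a missing
# site (any triplet containing a gap, an ambiguity character or a stop).

#' Construct a codon alignment
#'
#' @param codons An integer matrix (species x codon sites) of indices in
#'   1..61 or NA for missing; rownames are the sequence ids.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  if (ncol(codons) < 1L) stop("alignment must have at least one codon site")
  storage.mode(codons) <- "integer"
  rng <- range(codons, na.rm = TRUE)
  if (!all(is.na(codons)) && (rng[1] < 1L || rng[2] > .N_CODON)) {
    stop("codon indices must lie in 1..", .N_CODON)
  }
  if (anyDuplicated(rownames(codons))) stop("duplicate sequence ids")
  structure(list(ids = rownames(codons), codons = codons,
                 n_sites = ncol(codons)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$ids), "sequences x", x$n_sites,
      "codon sites;", sum(is.na(x$codons)), "missing\n")
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$codons)

#' Read an in-frame coding alignment from FASTA
#'
#' Sequences must be aligned (equal length) and in frame (length divisible
#' by three). Each nucleotide triplet is mapped to its index in the canonical
#' sense-codon order; triplets containing gaps or ambiguity codes become
#' missing (NA), and in-frame stop codons become missing with one warning per
#' occurrence.
#'
#' @param file Path to a FASTA file, or a character vector of its lines.
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(file) {
  if (!(length(file) == 1L && file.exists(file))) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), path)
    file <- path
  }
  d <- ape::read.FASTA(file)
  if (!length(d)) stop("no FASTA records found")
  ids <- sub("\\s.*$", "", names(d))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- vapply(as.character(d), function(x) toupper(paste(x, collapse = "")),
                 character(1))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) stop("sequences are not aligned (unequal lengths)")
  bad <- len %% 3L != 0L
  if (any(bad)) {
    stop("sequence length not divisible by 3 for record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  n_sites <- len[1] %/% 3L
  mat <- matrix(NA_integer_, length(ids), n_sites, dimnames = list(ids, NULL))
  n_stop <- 0L
  for (i in seq_along(seqs)) {
    trip <- substring(seqs[i], 3L * seq_len(n_sites) - 2L, 3L * seq_len(n_sites))
    idx <- match(trip, .SENSE_CODONS)
    stops <- trip %in% .STOP_CODONS
    for (s in which(stops)) {
      warning("stop codon ", trip[s], " at codon site ", s, " in ", ids[i],
              "; treated as missing", call. = FALSE)
    }
    mat[i, ] <- idx
  }
  codon_alignment(mat)
}

#' Write a codon alignment to FASTA
#'
#' Missing codon sites are written as `---`.
#'
#' @param aln A [codon_alignment()].
#' @param file Output path; when `NULL` the FASTA lines are returned instead.
#' @return `file` invisibly, or the FASTA lines when `file` is `NULL`.
#' @export
write_codon_fasta <- function(aln, file = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$codons, 1L, function(row) {
    paste(ifelse(is.na(row), "---", .SENSE_CODONS[row]), collapse = "")
  })
  out <- as.vector(rbind(paste0(">", aln$ids), seqs))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(file)
}

# check that alignment ids and tree tips agree; returns alignment rows
# reordered to tree tip order
match_alignment_tree <- function(aln, tree) {
  missing_tips <- setdiff(tree$tip.label, aln$ids)
  extra <- setdiff(aln$ids, tree$tip.label)
  if (length(missing_tips) || length(extra)) {
    stop("alignment/tree id mismatch; missing from alignment: {",
         paste(missing_tips, collapse = ", "), "}; not in tree: {",
         paste(extra, collapse = ", "), "}", call. = FALSE)
  }
  aln$codons[tree$tip.label, , drop = FALSE]
}
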