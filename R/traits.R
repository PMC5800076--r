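# Photic-character trait tables.
#
# One row per species: activity pattern, SWS1 spectral-tuning residues at
# reference positions 86 and 93, whether the SWS1 copy is intact, primate
# flag, and the two continuous eye-design variables (orbit convergence in
# degrees, visual acuity in cycles/degree).

.ACTIVITY_LEVELS <- c("nocturnal", "cathemeral", "diurnal", "unknown")

#' Construct and validate a trait table
#'
#' Normalizes and validates per-species photic-character records. Crepuscular
#' activity is merged into nocturnal on construction (the merge is idempotent);
#' unknown activity categories are rejected rather than coerced.
#'
#' @param df A data.frame with columns `species_id`, `activity_pattern`
#'   (nocturnal / crepuscular / cathemeral / diurnal / unknown), and
#'   optionally `site86_residue`, `site93_residue` (one-letter amino-acid
#'   codes or NA), `sws1_active` (logical), `is_primate` (logical),
#'   `orbit_convergence` (degrees, in \[0, 180\]) and `visual_acuity`
#'   (cycles/degree, positive). Missing optional columns are filled with NA
#'   (flags default to `TRUE` for `sws1_active`, `FALSE` for `is_primate`).
#' @return A validated data.frame of class `trait_table`.
#' @examples
#' trait_table(data.frame(species_id = "rat", activity_pattern = "crepuscular"))
#' @export
trait_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("species_id", "activity_pattern") %in% names(df))) {
    stop("trait table needs 'species_id' and 'activity_pattern' columns")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$species_id)) {
    stop("duplicate species_id: ",
         paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", "))
  }
  act <- tolower(trimws(as.character(df$activity_pattern)))
  act[act == "crepuscular"] <- "nocturnal"
  act[is.na(df$activity_pattern) | act == ""] <- "unknown"
  bad <- !(act %in% .ACTIVITY_LEVELS)
  if (any(bad)) {
    stop("unknown activity pattern(s): ",
         paste(unique(act[bad]), collapse = ", "))
  }
  df$activity_pattern <- act
  defaults <- list(site86_residue = NA_character_, site93_residue = NA_character_,
                   sws1_active = TRUE, is_primate = FALSE,
                   orbit_convergence = NA_real_, visual_acuity = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  }
  for (nm in c("site86_residue", "site93_residue")) {
    r <- toupper(trimws(as.character(df[[nm]])))
    r[!is.na(r) & r == ""] <- NA_character_
    if (any(!is.na(r) & !grepl("^[A-Z]$", r))) {
      stop(nm, " must be single amino-acid letters")
    }
    df[[nm]] <- r
  }
  df$sws1_active <- as.logical(df$sws1_active)
  df$is_primate <- as.logical(df$is_primate)
  oc <- as.numeric(df$orbit_convergence)
  if (any(!is.na(oc) & (oc < 0 | oc > 180))) {
    stop("orbit_convergence must lie in [0, 180] degrees")
  }
  df$orbit_convergence <- oc
  va <- as.numeric(df$visual_acuity)
  if (any(!is.na(va) & va <= 0)) stop("visual_acuity must be positive")
  df$visual_acuity <- va
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row; see
#' [trait_table()] for the column contract and normalization rules.
#'
#' @param file Path to the CSV file.
#' @return A `trait_table` data.frame.
#' @export
read_trait_table <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trait_table(df)
}

#' Write a trait table to CSV
#'
#' @param traits A `trait_table`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trait_table <- function(traits, file) {
  stopifnot(inherits(traits, "trait_table"))
  write.csv(as.data.frame(traits), file, row.names = FALSE)
  invisible(file)
}
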