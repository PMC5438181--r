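# Standard genetic code tables shared across the package.
# Derived once at install time from Biostrings::GENETIC_CODE.

.GC_ALL <- Biostrings::GENETIC_CODE

#' Sense codons of the standard genetic code
#'
#' The 61 sense codons (stop codons excluded), in alphabetical order. This
#' fixed ordering is used for all internal codon indexing.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  sort(names(.GC_ALL)[.GC_ALL != "*"])
}

.SENSE <- sort(names(.GC_ALL)[.GC_ALL != "*"])
.SENSE_AA <- unname(.GC_ALL[.SENSE])
.STOPS <- names(.GC_ALL)[.GC_ALL == "*"]
.AA20 <- sort(unique(.SENSE_AA))
# codon index sets per amino acid, in .SENSE order
.SYN_SETS <- split(seq_along(.SENSE), .SENSE_AA)[.AA20]
# third-position G/C indicator per sense codon
.IS_GC3 <- substr(.SENSE, 3, 3) %in% c("G", "C")

#' Genetic code lookup table
#'
#' @return A tibble with one row per sense codon: `codon`, `amino_acid`
#'   (one-letter code), and `gc3` (logical, third base is G or C).
#' @export
#' @examples
#' genetic_code_tbl()
genetic_code_tbl <- function() {
  tibble::tibble(codon = .SENSE, amino_acid = .SENSE_AA, gc3 = .IS_GC3)
}

# Split a CDS string into codons. Assumes length %% 3 == 0.
split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3L), seq(3, nchar(cds), 3L))
}

# Map codons to indices in .SENSE; NA for stops/ambiguous.
codon_index <- function(codons) match(codons, .SENSE)

# Translate a vector of sense-codon indices to one-letter amino acids.
aa_of <- function(idx) .SENSE_AA[idx]
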