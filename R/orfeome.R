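#' Read and validate an ORFeome FASTA file
#'
#' Reads a FASTA file of coding sequences (CDS) for one species and applies
#' the validation rules used throughout the package: sequences whose length
#' is not a multiple of 3 are dropped; sequences containing ambiguous bases
#' or internal stop codons are dropped; a trailing stop codon is stripped;
#' when one gene identifier carries more than one sequence only the longest
#' is kept (first encountered on a length tie).
#'
#' @param path Path to a nucleotide FASTA file.
#' @param species_id Species identifier attached to every record. Defaults
#'   to the file stem.
#' @param quiet Suppress messages about dropped records.
#' @return A tibble with one row per retained CDS: `gene_id`, `species_id`,
#'   `cds` (stop-stripped, uppercase) and `protein` (standard genetic code).
#' @export
read_orfeome <- function(path, species_id = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  species_id <- species_id %||% sub("\\.[^.]*$", "", basename(path))
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
    error = function(e) abort(paste0("unparseable FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(seqs) == 0) abort(paste0("empty FASTA file: ", path))
  orfeome_records(
    gene_id = sub("\\s.*$", "", names(seqs)),
    cds = toupper(as.character(seqs)),
    species_id = species_id, quiet = quiet
  )
}

#' Build validated ORF records from in-memory sequences
#'
#' The in-memory core of [read_orfeome()]; useful for simulated data.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param cds Character vector of nucleotide CDS strings.
#' @param species_id Single species identifier.
#' @param quiet Suppress messages about dropped records.
#' @return A tibble: `gene_id`, `species_id`, `cds`, `protein`.
#' @export
orfeome_records <- function(gene_id, cds, species_id, quiet = FALSE) {
  stopifnot(length(gene_id) == length(cds))
  gene_id <- unname(gene_id)
  cds <- unname(toupper(cds))
  keep_len <- nchar(cds) %% 3L == 0L & nchar(cds) >= 3L
  n_len <- sum(!keep_len)
  gene_id <- gene_id[keep_len]
  cds <- cds[keep_len]

  clean <- !grepl("[^ACGT]", cds)
  n_ambig <- sum(!clean)
  gene_id <- gene_id[clean]
  cds <- cds[clean]

  # strip a single trailing stop codon
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  has_stop <- last %in% .STOPS
  cds[has_stop] <- substr(cds[has_stop], 1L, nchar(cds[has_stop]) - 3L)
  nonempty <- nchar(cds) >= 3L
  gene_id <- gene_id[nonempty]
  cds <- cds[nonempty]

  # internal stop codons -> drop
  idx_list <- lapply(cds, function(s) codon_index(split_codons(s)))
  ok <- !vapply(idx_list, anyNA, logical(1))
  n_stop <- sum(!ok)
  gene_id <- gene_id[ok]
  cds <- cds[ok]
  idx_list <- idx_list[ok]

  # longest sequence per gene_id; first wins on ties
  if (anyDuplicated(gene_id)) {
    o <- order(-nchar(cds), seq_along(cds))
    first <- o[!duplicated(gene_id[o])]
    first <- sort(first)
    gene_id <- gene_id[first]
    cds <- cds[first]
    idx_list <- idx_list[first]
  }

  if (!quiet && (n_len + n_ambig + n_stop) > 0) {
    inform(sprintf(
      "%s: dropped %d record(s) (length not multiple of 3: %d, ambiguous bases: %d, internal stops: %d)",
      species_id, n_len + n_ambig + n_stop, n_len, n_ambig, n_stop
    ))
  }
  tibble(
    gene_id = gene_id,
    species_id = species_id,
    cds = cds,
    protein = vapply(idx_list, function(i) paste(aa_of(i), collapse = ""), character(1))
  )
}

#' Codon usage table of an ORFeome
#'
#' Counts every sense codon across the supplied records and derives usage
#' frequencies per 1000 codons. A codon is flagged rare when its frequency
#' is below the mean frequency of its synonymous set (relative rarity).
#'
#' @param records A tibble of ORF records (see [read_orfeome()]).
#' @return A tibble with class `codon_usage` and one row per sense codon:
#'   `codon`, `amino_acid`, `count`, `freq_per_1000`, `is_rare`; the species
#'   identifier is kept in attribute `species_id`.
#' @export
usage_table <- function(records) {
  if (nrow(records) == 0) abort("usage_table() needs at least one record")
  idx <- unlist(lapply(records$cds, function(s) codon_index(split_codons(s))), use.names = FALSE)
  counts <- tabulate(idx, nbins = length(.SENSE))
  total <- sum(counts)
  freq <- 1000 * counts / total
  syn_mean <- stats::ave(freq, .SENSE_AA)
  out <- tibble(
    codon = .SENSE,
    amino_acid = .SENSE_AA,
    count = counts,
    freq_per_1000 = freq,
    is_rare = freq < syn_mean
  )
  attr(out, "species_id") <- unique(records$species_id)[1]
  class(out) <- c("codon_usage", class(out))
  out
}

#' Is a codon rare in a usage table?
#'
#' @param table A `codon_usage` tibble from [usage_table()].
#' @param codon Character vector of sense codons.
#' @return Logical vector: `TRUE` where the codon's frequency is strictly
#'   below its synonymous-set mean. Codons in single-codon sets (ATG, TGG)
#'   are never rare. Stop codons are an error.
#' @export
is_rare <- function(table, codon) {
  codon <- toupper(codon)
  if (any(codon %in% .STOPS)) abort("is_rare() is undefined for stop codons")
  i <- match(codon, table$codon)
  if (anyNA(i)) abort("unknown codon(s): ", paste(codon[is.na(i)], collapse = ", "))
  table$is_rare[i]
}

#' Write a codon usage table to TSV
#'
#' @param table A `codon_usage` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

# Per-codon lookup vectors used by the %MinMax kernel; memoised on the table.
usage_lookup <- function(table) {
  lk <- attr(table, "lookup")
  if (!is.null(lk)) return(lk)
  freq <- table$freq_per_1000[match(.SENSE, table$codon)]
  aa <- .SENSE_AA
  list(
    freq = freq,
    syn_max = stats::ave(freq, aa, FUN = max),
    syn_min = stats::ave(freq, aa, FUN = min),
    syn_mean = stats::ave(freq, aa, FUN = mean)
  )
}
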