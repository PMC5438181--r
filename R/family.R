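#' Construct a homolog family from aligned members
#'
#' Low-level constructor: validates that all aligned rows have equal length,
#' that ungapping each row reproduces the member's protein, and that each
#' species contributes at most one member. Builds the residue-to-column maps
#' and the set of columns free of gaps in every member.
#'
#' @param family_id Family identifier.
#' @param members A tibble with columns `species_id`, `gene_id`, `aligned`
#'   (aligned protein with `-` gaps) and optionally `cds`/`protein`.
#' @return An object of class `homolog_family`: a list with `family_id`,
#'   `members` (tibble, with `protein` filled in), `n`, `L` (alignment
#'   columns), `col_map` (per member, integer vector mapping residue index
#'   to alignment column) and `eligible_cols` (columns gap-free in all
#'   members).
#' @export
homolog_family <- function(family_id, members) {
  stopifnot(is.data.frame(members), all(c("species_id", "gene_id", "aligned") %in% names(members)))
  L <- unique(nchar(members$aligned))
  if (length(L) != 1) abort(paste0("family ", family_id, ": alignment rows of unequal length"))
  if (anyDuplicated(members$species_id)) {
    abort(paste0("family ", family_id, ": more than one member per species; run filter_paralogs() first"))
  }
  chars <- lapply(members$aligned, function(a) strsplit(a, "", fixed = TRUE)[[1]])
  col_map <- lapply(chars, function(ch) which(ch != "-"))
  ungapped <- vapply(seq_along(chars), function(i) paste(chars[[i]][col_map[[i]]], collapse = ""), character(1))
  if (!"protein" %in% names(members)) members$protein <- ungapped
  if (any(members$protein != ungapped)) {
    bad <- which(members$protein != ungapped)
    abort(paste0(
      "family ", family_id, ": ungapped alignment row differs from protein for ",
      paste(members$gene_id[bad], collapse = ", ")
    ))
  }
  gap_any <- Reduce(`|`, lapply(chars, function(ch) ch == "-"))
  structure(
    list(
      family_id = family_id,
      members = as_tibble(members),
      n = nrow(members),
      L = L,
      col_map = col_map,
      eligible_cols = which(!gap_any)
    ),
    class = "homolog_family"
  )
}

#' @export
print.homolog_family <- function(x, ...) {
  cat(sprintf(
    "<homolog_family %s: %d members, %d columns (%d gap-free)>\n",
    x$family_id, x$n, x$L, length(x$eligible_cols)
  ))
  print(x$members[, c("species_id", "gene_id")])
  invisible(x)
}

#' Keep one member per species, chosen at random
#'
#' Paralog filtering: when a species contributes several members to a
#' family, one representative is retained, chosen uniformly at random.
#' Deterministic under a fixed RNG seed.
#'
#' @param members A member tibble with a `species_id` column.
#' @param seed Optional integer seed applied locally (the surrounding RNG
#'   state is restored). With `NULL`, the current RNG stream is used.
#' @return The filtered member tibble (original row order preserved).
#' @export
filter_paralogs <- function(members, seed = NULL) {
  pick <- function() {
    keep <- unlist(lapply(split(seq_len(nrow(members)), members$species_id), function(i) {
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
    }), use.names = FALSE)
    members[sort(keep), , drop = FALSE]
  }
  if (is.null(seed)) pick() else with_seed_local(seed, pick())
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Load a homolog family from membership rows, an aligned FASTA and ORFeomes
#'
#' Cross-checks each member against its ORFeome: the translated CDS must
#' equal the ungapped alignment row, otherwise the member is dropped with a
#' warning. Paralogs (several members from one species) are reduced to a
#' random representative. Families with fewer than 2 surviving members are
#' rejected (`NULL` with a warning).
#'
#' @param membership A tibble with columns `family_id`, `species_id`,
#'   `gene_id` (rows of one family).
#' @param aligned_fasta Path to the family's aligned protein FASTA with
#'   headers `species_id|gene_id`, or a named character vector of aligned
#'   sequences with such names.
#' @param orfeomes A tibble of ORF records covering all member species (rows
#'   from [read_orfeome()] / [orfeome_records()], bound together).
#' @param seed Optional seed for the paralog draw.
#' @return A `homolog_family` (members carry `cds` and `protein`), or
#'   `NULL` when fewer than 2 members survive validation.
#' @export
load_family <- function(membership, aligned_fasta, orfeomes, seed = NULL) {
  fid <- unique(membership$family_id)
  stopifnot(length(fid) == 1L)
  if (is.character(aligned_fasta) && length(aligned_fasta) == 1L && file.exists(aligned_fasta)) {
    aln <- Biostrings::readAAStringSet(aligned_fasta)
    aligned <- setNames(as.character(aln), names(aln))
  } else {
    aligned <- aligned_fasta
  }
  if (length(unique(nchar(aligned))) > 1) {
    abort(paste0("family ", fid, ": alignment rows of unequal length"))
  }
  key <- paste(membership$species_id, membership$gene_id, sep = "|")
  i <- match(key, sub("\\s.*$", "", names(aligned)))
  if (anyNA(i)) {
    warn(paste0("family ", fid, ": members missing from alignment dropped: ", paste(key[is.na(i)], collapse = ", ")))
  }
  mem <- membership[!is.na(i), , drop = FALSE]
  mem$aligned <- toupper(unname(aligned[i[!is.na(i)]]))

  j <- match(paste(mem$species_id, mem$gene_id), paste(orfeomes$species_id, orfeomes$gene_id))
  if (anyNA(j)) {
    warn(paste0("family ", fid, ": members absent from ORFeomes dropped: ", paste(mem$gene_id[is.na(j)], collapse = ", ")))
    mem <- mem[!is.na(j), , drop = FALSE]
    j <- j[!is.na(j)]
  }
  mem$cds <- orfeomes$cds[j]
  mem$protein <- orfeomes$protein[j]
  consistent <- gsub("-", "", mem$aligned, fixed = TRUE) == mem$protein
  if (any(!consistent)) {
    warn(paste0(
      "family ", fid, ": translated CDS differs from ungapped alignment row; dropped: ",
      paste(mem$gene_id[!consistent], collapse = ", ")
    ))
    mem <- mem[consistent, , drop = FALSE]
  }
  mem <- filter_paralogs(mem, seed = seed)
  if (nrow(mem) < 2L) {
    warn(paste0("family ", fid, ": fewer than 2 members after filtering; skipped"))
    return(NULL)
  }
  homolog_family(fid, mem[, c("species_id", "gene_id", "aligned", "cds", "protein")])
}

#' Map cluster peaks to alignment columns
#'
#' Splices per-gene rare codon cluster peaks into the family alignment:
#' a peak at residue `r` of member `k` lands in column `col_map[[k]][r]`.
#'
#' @param family A `homolog_family`.
#' @param clusters A cluster tibble (from [detect_clusters()], rows of all
#'   members bound together) with columns `gene_id` and `peak_codon`.
#' @return A tibble with one row per peak: `family_id`, `member` (row index
#'   into `family$members`), `species_id`, `gene_id`, `peak_codon`, `column`.
#' @export
map_peaks_to_columns <- function(family, clusters) {
  cl <- clusters[clusters$gene_id %in% family$members$gene_id, , drop = FALSE]
  if (nrow(cl) == 0) {
    return(tibble(
      family_id = character(), member = integer(), species_id = character(),
      gene_id = character(), peak_codon = integer(), column = integer()
    ))
  }
  k <- match(cl$gene_id, family$members$gene_id)
  col <- integer(nrow(cl))
  for (r in seq_len(nrow(cl))) {
    cm <- family$col_map[[k[r]]]
    if (cl$peak_codon[r] > length(cm)) {
      abort(paste0(
        "family ", family$family_id, ": peak at residue ", cl$peak_codon[r],
        " beyond protein length for ", cl$gene_id[r]
      ))
    }
    col[r] <- cm[cl$peak_codon[r]]
  }
  tibble(
    family_id = family$family_id,
    member = k,
    species_id = family$members$species_id[k],
    gene_id = cl$gene_id,
    peak_codon = cl$peak_codon,
    column = col
  )
}
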