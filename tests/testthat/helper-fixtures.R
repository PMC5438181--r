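# Shared fixture builders. Everything is generated in code; no data files.

gc_tbl <- genetic_code_tbl()

# Build a codon_usage table directly from a named count vector (codons not
# named get count `fill`).
make_usage <- function(counts, fill = 10, species_id = "toy") {
  cnt <- rep(fill, nrow(gc_tbl))
  names(cnt) <- gc_tbl$codon
  cnt[names(counts)] <- counts
  freq <- 1000 * cnt / sum(cnt)
  syn_mean <- stats::ave(freq, gc_tbl$amino_acid)
  out <- tibble::tibble(
    codon = gc_tbl$codon, amino_acid = gc_tbl$amino_acid,
    count = as.integer(cnt), freq_per_1000 = unname(freq),
    is_rare = unname(freq < syn_mean)
  )
  attr(out, "species_id") <- species_id
  class(out) <- c("codon_usage", class(out))
  out
}

# Random positive usage table (distinct counts so no rarity ties).
random_usage <- function(seed) {
  set.seed(seed)
  cnt <- as.integer(sample(5:500, nrow(gc_tbl), replace = FALSE))
  names(cnt) <- gc_tbl$codon
  make_usage(cnt, species_id = paste0("rand", seed))
}

# Encode a protein with, per amino acid, the most common / rarest codon of
# a usage table (first codon on frequency ties).
extreme_cds <- function(protein, table, which = c("common", "rare")) {
  which <- match.arg(which)
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    rows <- table[table$amino_acid == a, ]
    i <- if (which == "common") which.max(rows$freq_per_1000) else which.min(rows$freq_per_1000)
    rows$codon[i]
  }, character(1))
  paste(codons, collapse = "")
}

# Random protein over the 20 amino acids.
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(sort(unique(gc_tbl$amino_acid)), n, replace = TRUE), collapse = "")
}

# Random CDS (sense codons only).
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(gc_tbl$codon, n_codons, replace = TRUE), collapse = "")
}

# Independent brute-force %MinMax oracle: direct per-window evaluation of
# the formula with explicit loops over synonymous sets.
oracle_minmax <- function(cds, table, w = 17L) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  n <- length(codons)
  if (n < w) return(numeric(0))
  freq <- setNames(table$freq_per_1000, table$codon)
  aa_of <- setNames(table$amino_acid, table$codon)
  out <- numeric(n - w + 1)
  for (i in seq_len(n - w + 1)) {
    win <- codons[i:(i + w - 1)]
    xact <- mean(freq[win])
    fmax <- fmin <- favg <- numeric(w)
    for (j in seq_len(w)) {
      syn <- freq[names(aa_of)[aa_of == aa_of[[win[j]]]]]
      fmax[j] <- max(syn); fmin[j] <- min(syn); favg[j] <- mean(syn)
    }
    xmax <- mean(fmax); xmin <- mean(fmin); xavg <- mean(favg)
    out[i] <- if (xact >= xavg) {
      if (xmax > xavg) 100 * (xact - xavg) / (xmax - xavg) else 0
    } else {
      if (xavg > xmin) -100 * (xavg - xact) / (xavg - xmin) else 0
    }
  }
  out
}

# Exact conditional binomial oracle by term-wise enumeration with choose().
oracle_cond_binom <- function(m, n, p0) {
  pmf <- vapply(0:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k), numeric(1))
  sum(pmf[(m + 1):(n + 1)]) / sum(pmf[2:(n + 1)])
}

# Two-sided Fisher oracle: full hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  probs <- vapply(lo:hi, function(x) {
    choose(m1, x) * choose(m2, n1 - x) / choose(m1 + m2, n1)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A gapless homolog family from explicit per-member CDS strings (proteins
# must align without gaps).
family_from_cds <- function(cds_list, family_id = "famX") {
  prot <- vapply(cds_list, function(s) {
    paste(gc_tbl$amino_acid[match(
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)), gc_tbl$codon
    )], collapse = "")
  }, character(1))
  homolog_family(family_id, tibble::tibble(
    species_id = sprintf("s%02d", seq_along(cds_list)),
    gene_id = sprintf("%s_g%02d", family_id, seq_along(cds_list)),
    aligned = unname(prot), cds = unname(cds_list), protein = unname(prot)
  ))
}

# Peaks tibble for column_stats() from a list of per-member peak columns.
peaks_at <- function(family, cols_by_member) {
  rows <- lapply(seq_along(cols_by_member), function(k) {
    cols <- cols_by_member[[k]]
    if (length(cols) == 0) return(NULL)
    tibble::tibble(
      family_id = family$family_id, member = k,
      species_id = family$members$species_id[k],
      gene_id = family$members$gene_id[k],
      peak_codon = match(cols, family$col_map[[k]]),
      column = cols
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      family_id = character(), member = integer(), species_id = character(),
      gene_id = character(), peak_codon = integer(), column = integer()
    )
  }
  out
}
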