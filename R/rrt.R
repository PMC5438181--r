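#' %GC3 of coding sequences
#'
#' Fraction of third codon positions occupied by G or C, expressed as a
#' percentage. Trailing stop codons are assumed already stripped.
#'
#' @param cds Character vector of CDS strings (lengths multiples of 3).
#' @return Numeric vector of %GC3 values in \[0, 100\].
#' @export
gc3_percent <- function(cds) {
  vapply(cds, function(s) {
    third <- substring(s, seq(3, nchar(s), 3), seq(3, nchar(s), 3))
    100 * mean(third %in% c("G", "C", "g", "c"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Partially overlapping %GC3 codon-count bins
#'
#' Sorts an ORFeome's coding sequences into overlapping %GC3 bins
#' (`bin_width` points wide, advancing by `bin_step`, e.g. 20-30, 25-35,
#' 30-40, ...) and accumulates codon counts per bin. A CDS contributes its
#' codon counts to every bin whose interval contains its %GC3, which is
#' what makes the overlap useful: each bin pools roughly twice the
#' sequences of a disjoint binning while adjacent bin means stay close.
#' For generating reverse translations a CDS is served by the bin whose
#' midpoint is nearest its %GC3 (ties toward the lower bin).
#'
#' @param records A tibble of ORF records.
#' @param bin_width Bin width in %GC3 points (default 10).
#' @param bin_step Step between bin starts (default 5).
#' @return An object of class `gc3_bins`: list with `bins` (tibble `low`,
#'   `high`, `mid`, `n_cds`, `total_codons`), `counts` (61 x n_bins codon
#'   count matrix), and `global` (codon counts over the whole ORFeome).
#' @export
build_gc3_bins <- function(records, bin_width = 10, bin_step = 5) {
  if (nrow(records) == 0) abort("build_gc3_bins() needs at least one record")
  lows <- seq(0, 100 - bin_width, by = bin_step)
  highs <- lows + bin_width
  mids <- lows + bin_width / 2
  gc3 <- gc3_percent(records$cds)
  per_cds <- vapply(
    records$cds,
    function(s) tabulate(codon_index(split_codons(s)), nbins = length(.SENSE)),
    integer(length(.SENSE)),
    USE.NAMES = FALSE
  )
  counts <- matrix(0L, nrow = length(.SENSE), ncol = length(lows),
    dimnames = list(.SENSE, NULL)
  )
  n_cds <- integer(length(lows))
  for (b in seq_along(lows)) {
    inbin <- gc3 >= lows[b] & (gc3 < highs[b] | (highs[b] == 100 & gc3 <= 100))
    n_cds[b] <- sum(inbin)
    if (n_cds[b] > 0) counts[, b] <- rowSums(per_cds[, inbin, drop = FALSE])
  }
  structure(
    list(
      bins = tibble(
        low = lows, high = highs, mid = mids,
        n_cds = n_cds, total_codons = colSums(counts)
      ),
      counts = counts,
      global = rowSums(per_cds),
      bin_width = bin_width,
      bin_step = bin_step
    ),
    class = "gc3_bins"
  )
}

#' Assign a %GC3 value to its generation bin
#'
#' @param bins A `gc3_bins` object.
#' @param gc3 Numeric vector of %GC3 values.
#' @return Integer vector of bin indices (nearest midpoint; ties toward the
#'   lower bin).
#' @export
gc3_bin_assign <- function(bins, gc3) {
  vapply(gc3, function(g) which.min(abs(bins$bins$mid - g)), integer(1))
}

#' Codon pair multipliers of an ORFeome
#'
#' For an ordered codon pair (A, B), the multiplier measures how enriched
#' codon A is immediately 5' of codon B (the -1 position) relative to A's
#' local background: the usage of A among its amino acid's codons at the -1
#' slots of all B occurrences, divided by the same usage ratio computed
#' over `window`-codon windows centred on B occurrences (excluding the -1
#' slot and B itself). A multiplier of 1 means no pair preference; 0 means
#' A is never observed directly before B although its amino acid is
#' (strong avoidance). Pairs whose focal or background denominators are 0,
#' or with zero background usage of A, default to 1.
#'
#' @param records A tibble of ORF records.
#' @param window Odd window length in codons for the local background
#'   (default 17).
#' @return An object of class `pair_mult`: list with `mult` (61 x 61 matrix,
#'   rows = codon A, cols = codon B), `focal` and `background` count
#'   matrices, `focal_aa_total` (count of aa(A) at -1 of B, for filtering
#'   to well-observed pairs), and `window`.
#' @export
pair_multipliers <- function(records, window = 17L) {
  if (window %% 2L != 1L) abort("pair_multipliers(): window must be odd")
  radius <- (window - 1L) %/% 2L
  nc <- length(.SENSE)
  # concatenate codon indices with zero padding so windows never span genes
  pad <- rep(0L, radius)
  v <- unlist(lapply(records$cds, function(s) c(codon_index(split_codons(s)), pad)), use.names = FALSE)
  N <- length(v)
  tab_offset <- function(d) {
    i <- seq.int(max(1L, 1L - d), min(N, N - d))
    a <- v[i + d]
    b <- v[i]
    keep <- a > 0L & b > 0L
    # linear index (b-1)*nc + a puts codon A on rows, codon B on columns
    tabulate((b[keep] - 1L) * nc + a[keep], nbins = nc * nc)
  }
  focal <- matrix(tab_offset(-1L), nc, nc, dimnames = list(.SENSE, .SENSE))
  bg <- matrix(0, nc, nc, dimnames = list(.SENSE, .SENSE))
  for (d in setdiff(seq.int(-radius, radius), c(0L, -1L))) {
    bg <- bg + matrix(tab_offset(d), nc, nc)
  }
  aa_f <- factor(.SENSE_AA, levels = .AA20)
  focal_aa <- rowsum(focal, aa_f)[.SENSE_AA, , drop = FALSE]
  bg_aa <- rowsum(bg, aa_f)[.SENSE_AA, , drop = FALSE]
  mult <- matrix(1, nc, nc, dimnames = list(.SENSE, .SENSE))
  ok <- focal_aa > 0 & bg_aa > 0 & bg > 0
  mult[ok] <- (focal[ok] / focal_aa[ok]) / (bg[ok] / bg_aa[ok])
  structure(
    list(mult = mult, focal = focal, background = bg,
         focal_aa_total = focal_aa, window = window),
    class = "pair_mult"
  )
}

#' Bundle the per-species inputs of the RRT generator
#'
#' @param records ORF records of one species.
#' @param bin_width,bin_step %GC3 binning parameters (see [build_gc3_bins()]).
#' @param pair_window Window for [pair_multipliers()].
#' @return An object of class `rrt_model`: list with `bins`, `pairs` and
#'   the species identifier.
#' @export
build_rrt_model <- function(records, bin_width = 10, bin_step = 5, pair_window = 17L) {
  structure(
    list(
      species_id = records$species_id[1],
      bins = build_gc3_bins(records, bin_width, bin_step),
      pairs = pair_multipliers(records, pair_window)
    ),
    class = "rrt_model"
  )
}

# Per-codon base weights for a CDS: counts of its generation bin, patched
# per amino acid from the global table where the bin has no observations.
rrt_base_weights <- function(model, cds) {
  b <- gc3_bin_assign(model$bins, gc3_percent(cds))
  w <- as.numeric(model$bins$counts[, b])
  if (sum(w) == 0) w <- as.numeric(model$bins$global)
  for (s in .SYN_SETS) {
    if (sum(w[s]) == 0) w[s] <- as.numeric(model$bins$global[s])
  }
  w
}

#' Random reverse translation of a coding sequence
#'
#' Generates alternative codings of the protein encoded by `cds`, sampled
#' 3' to 5': the last codon is drawn proportionally to its count in the
#' sequence's %GC3 bin; every earlier codon proportionally to its bin count
#' times the codon pair multiplier against the codon already chosen 3' of
#' it. The translation of every draw equals the original protein exactly.
#'
#' @param cds A CDS string (sense codons only).
#' @param model An `rrt_model` for the species of origin.
#' @param n Number of replicates to draw.
#' @param seed Optional local seed (RNG state restored afterwards).
#' @return Character vector of `n` reverse-translated CDS strings.
#' @export
generate_rrt <- function(cds, model, n = 1L, seed = NULL) {
  idx <- codon_index(split_codons(toupper(cds)))
  if (anyNA(idx)) abort("generate_rrt(): CDS contains stop or ambiguous codons")
  aa_sets <- .SYN_SETS[.SENSE_AA[idx]]
  w <- rrt_base_weights(model, cds)
  draw <- function() {
    vapply(seq_len(n), function(i) {
      paste(.SENSE[sample_codons_chain(aa_sets, w, model$pairs$mult)], collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else with_seed_local(seed, draw())
}

#' RRT suspect-position mask for a homolog family
#'
#' Re-runs the full co-occurrence scan on `n_replicates` replicate families
#' in which every member's CDS is replaced by a fresh random reverse
#' translation. Replicate peaks are re-detected against the original
#' species usage tables -- the null asks how rarity-free re-encodings of the
#' same proteins behave under identical scoring. For each alignment column
#' the number of replicates with significant co-occurrence (p below
#' `threshold`) is counted; among columns significant in at least one
#' replicate, the top `top_frac` by count (ties at the cutoff included,
#' at least one column) are suspect -- their co-occurrence is attributable
#' to sequence composition rather than codon rarity -- and columns within
#' `radius` of a suspect are masked.
#'
#' @param family A `homolog_family` whose members carry `cds`.
#' @param models Named list of `rrt_model` objects, indexed by species.
#' @param usage_tables Named list of `codon_usage` tables, indexed by
#'   species.
#' @param n_replicates Number of RRT replicates (default 200).
#' @param threshold Per-column significance threshold (default 1e-4).
#' @param top_frac Fraction of ever-significant columns regarded suspect
#'   (default 0.05).
#' @param radius Mask radius around suspect columns (default 8).
#' @param tolerance Co-occurrence column tolerance (default 2).
#' @param window_size %MinMax window (default 17).
#' @param seed Optional local seed.
#' @return A tibble with one row per alignment column: `family_id`,
#'   `column`, `n_significant_replicates`, `suspect`, `masked`.
#' @export
suspect_mask <- function(family, models, usage_tables, n_replicates = 200L,
                         threshold = 1e-4, top_frac = 0.05, radius = 8L,
                         tolerance = 2L, window_size = 17L, seed = NULL) {
  if (n_replicates < 1L) abort("suspect_mask(): need at least one replicate")
  L <- family$L
  elig <- family$eligible_cols
  n <- family$n
  prep <- lapply(seq_len(n), function(k) {
    sp <- family$members$species_id[k]
    if (is.null(models[[sp]]) || is.null(usage_tables[[sp]])) {
      abort(paste0("suspect_mask(): no model/usage table for species ", sp))
    }
    idx <- codon_index(split_codons(family$members$cds[k]))
    list(
      aa_sets = .SYN_SETS[.SENSE_AA[idx]],
      w = rrt_base_weights(models[[sp]], family$members$cds[k]),
      mult = models[[sp]]$pairs$mult,
      lk = usage_lookup(usage_tables[[sp]]),
      col_map = family$col_map[[k]]
    )
  })
  run <- function() {
    counts <- integer(L)
    for (b in seq_len(n_replicates)) {
      pk <- vector("list", n)
      p_total <- 0L
      for (k in seq_len(n)) {
        pr <- prep[[k]]
        idx <- sample_codons_chain(pr$aa_sets, pr$w, pr$mult)
        res <- peak_codons_idx(idx, pr$lk, window_size)
        pk[[k]] <- pr$col_map[res]
        p_total <- p_total + length(res)
      }
      if (p_total == 0L || length(elig) == 0L) next
      m <- column_m(pk, L, as.integer(tolerance))
      p0 <- min(1, (2 * tolerance + 1) * p_total / (n * length(elig)))
      me <- m[elig]
      hit <- me >= 1
      if (any(hit)) {
        pv <- cond_binom_p(me[hit], n, p0)
        sig <- elig[hit][pv < threshold]
        counts[sig] <- counts[sig] + 1L
      }
    }
    counts
  }
  counts <- if (is.null(seed)) run() else with_seed_local(seed, run())
  sus <- select_suspect_columns(counts, top_frac)
  suspect <- logical(L)
  masked <- logical(L)
  suspect[sus] <- TRUE
  for (s in sus) masked[max(1L, s - radius):min(L, s + radius)] <- TRUE
  tibble(
    family_id = family$family_id,
    column = seq_len(L),
    n_significant_replicates = counts,
    suspect = suspect,
    masked = masked
  )
}

# Suspect selection rule: among columns significant in >= 1 replicate, the
# top `top_frac` by replicate count -- at least one column, ties at the
# cutoff all included. Returns column indices.
select_suspect_columns <- function(counts, top_frac = 0.05) {
  nonzero <- which(counts >= 1L)
  if (length(nonzero) == 0L) return(integer(0))
  k <- max(1L, ceiling(top_frac * length(nonzero)))
  cutoff <- sort(counts[nonzero], decreasing = TRUE)[k]
  nonzero[counts[nonzero] >= cutoff]
}

#' Apply an RRT mask to a column-stat table
#'
#' @param stats A column-stat tibble from [column_stats()].
#' @param mask A mask tibble from [suspect_mask()] for the same family.
#' @return `stats` with the `rrt_masked` flag set.
#' @export
apply_rrt_mask <- function(stats, mask) {
  stats$rrt_masked <- mask$masked[match(stats$column, mask$column)]
  stats
}
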