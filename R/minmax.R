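#' %MinMax sliding-window codon rarity profile
#'
#' Scores each window of `window_size` codons against hypothetical encodings
#' of the same amino acids that use, at every position, the most common
#' (score +100) or most rare (score -100) synonymous codon of the species.
#' With `Xact` the window mean of actual codon frequencies and `Xmax`,
#' `Xmin`, `Xavg` the window means of the per-amino-acid maximum, minimum
#' and average synonymous frequencies, the score is
#' `100 (Xact - Xavg) / (Xmax - Xavg)` when `Xact >= Xavg` and
#' `-100 (Xavg - Xact) / (Xavg - Xmin)` otherwise. Windows whose amino acids
#' are all encoded by a single codon carry no synonymous signal and score 0.
#'
#' @param cds A CDS string of sense codons (no stops), or a one-row record
#'   tibble with columns `gene_id` and `cds`.
#' @param table A `codon_usage` tibble for the species of origin.
#' @param window_size Window length in codons (default 17).
#' @param gene_id Gene identifier for the output (taken from `cds` when a
#'   record row is given).
#' @return A tibble with one row per window: `gene_id`, `window` (1-based
#'   window index), `window_start` (1-based codon index of the window's
#'   first codon, the anchor) and `score` in \[-100, 100\]. Proteins shorter
#'   than the window yield zero rows.
#' @export
minmax_profile <- function(cds, table, window_size = 17L, gene_id = NULL) {
  if (is.data.frame(cds)) {
    stopifnot(nrow(cds) == 1L)
    gene_id <- gene_id %||% cds$gene_id
    cds <- cds$cds
  }
  gene_id <- gene_id %||% NA_character_
  stopifnot(window_size >= 1L)
  idx <- codon_index(split_codons(toupper(cds)))
  if (anyNA(idx)) abort("minmax_profile(): CDS contains stop or ambiguous codons")
  scores <- minmax_scores_idx(idx, usage_lookup(table), as.integer(window_size))
  out <- tibble(
    gene_id = gene_id,
    window = seq_along(scores),
    window_start = seq_along(scores),
    score = scores
  )
  class(out) <- c("minmax_profile", class(out))
  attr(out, "window_size") <- as.integer(window_size)
  out
}

# Vectorised %MinMax kernel on codon indices. Returns numeric(0) when the
# sequence is shorter than the window.
minmax_scores_idx <- function(idx, lk, w) {
  n <- length(idx)
  if (n < w) return(numeric(0))
  roll <- function(x) {
    cs <- cumsum(c(0, x))
    (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  }
  xact <- roll(lk$freq[idx])
  xmax <- roll(lk$syn_max[idx])
  xmin <- roll(lk$syn_min[idx])
  xavg <- roll(lk$syn_mean[idx])
  hi <- xmax - xavg
  lo <- xavg - xmin
  up <- xact >= xavg
  score <- numeric(length(xact))
  ok_hi <- up & hi > 0
  ok_lo <- !up & lo > 0
  score[ok_hi] <- 100 * (xact[ok_hi] - xavg[ok_hi]) / hi[ok_hi]
  score[ok_lo] <- -100 * (xavg[ok_lo] - xact[ok_lo]) / lo[ok_lo]
  score
}

#' Detect rare codon clusters in a %MinMax profile
#'
#' A cluster is a maximal run of consecutive windows with score strictly
#' below zero. Each cluster's peak is its most negative window; ties are
#' broken toward the most 5' (smallest-index) window.
#'
#' @param profile A profile tibble from [minmax_profile()].
#' @return A tibble with one row per cluster: `gene_id`, `cluster`,
#'   `start_window`, `end_window`, `peak_window`, `peak_codon` (the codon
#'   index anchoring the peak window) and `peak_score`.
#' @export
detect_clusters <- function(profile) {
  empty <- tibble(
    gene_id = character(), cluster = integer(),
    start_window = integer(), end_window = integer(),
    peak_window = integer(), peak_codon = integer(), peak_score = numeric()
  )
  if (nrow(profile) == 0) return(empty)
  runs <- peak_runs(profile$score)
  if (nrow(runs) == 0) {
    empty$gene_id <- character(0)
    return(empty)
  }
  tibble(
    gene_id = profile$gene_id[1],
    cluster = seq_len(nrow(runs)),
    start_window = profile$window[runs$start],
    end_window = profile$window[runs$end],
    peak_window = profile$window[runs$peak],
    peak_codon = profile$window_start[runs$peak],
    peak_score = profile$score[runs$peak]
  )
}

# Run-scan shared by detect_clusters() and the fast pipeline path: positions
# of negative runs and their peak index (first minimum).
peak_runs <- function(scores) {
  neg <- scores < 0
  if (!any(neg)) return(data.frame(start = integer(), end = integer(), peak = integer()))
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]
  ends <- ends[keep]
  peaks <- mapply(function(s, e) s + which.min(scores[s:e]) - 1L, starts, ends)
  data.frame(start = starts, end = ends, peak = as.integer(peaks))
}

# Peak codon indices (window anchors) for a codon-index sequence: the fast
# path used inside RRT replicates, skipping tibble construction.
peak_codons_idx <- function(idx, lk, w) {
  scores <- minmax_scores_idx(idx, lk, w)
  if (length(scores) == 0) return(integer(0))
  peak_runs(scores)$peak
}
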