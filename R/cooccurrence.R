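#' Conditional binomial co-occurrence p-value
#'
#' For an alignment column where `m` of `n` members carry a peak nearby,
#' the co-occurrence p-value is `P(X >= m | X >= 1)` with
#' `X ~ Binomial(n, p0)`. By construction the p-value is 1 when `m = 1`.
#'
#' @param m Number of members with a peak within tolerance of the column.
#' @param n Family size.
#' @param p0 Per-member probability of a peak falling within tolerance of a
#'   given column under the null.
#' @return Numeric vector of p-values (NA where `m < 1`).
#' @export
cond_binom_p <- function(m, n, p0) {
  if (any(p0 <= 0 & m >= 1)) abort("p0 = 0 with m >= 1: inconsistent inputs")
  p <- ifelse(
    m >= 1,
    pbinom(m - 1, n, p0, lower.tail = FALSE) / pbinom(0, n, p0, lower.tail = FALSE),
    NA_real_
  )
  pmin(p, 1)
}

# m per column: number of members with >= 1 peak within +/- tol of each
# column. peak_cols_by_member: list of integer vectors of peak columns.
column_m <- function(peak_cols_by_member, L, tol) {
  m <- integer(L)
  for (pc in peak_cols_by_member) {
    if (length(pc) == 0) next
    cover <- logical(L)
    for (col in pc) cover[max(1L, col - tol):min(L, col + tol)] <- TRUE
    m <- m + cover
  }
  m
}

#' Per-column co-occurrence statistics for a homolog family
#'
#' For every alignment column, counts the members with at least one rare
#' codon cluster peak within `tolerance` columns (each member contributes at
#' most 1 regardless of how many of its peaks fall in the window) and
#' computes the conditional binomial p-value. The per-member per-column hit
#' probability is `p0 = min(1, (2 tolerance + 1) P / (n L_eligible))` where
#' `P` is the total number of peaks across members, so that the binomial
#' event has the correct marginal rate. Columns containing a gap in any
#' member are flagged `gap_excluded` and carry no p-value, although peaks
#' near them still count toward neighbouring eligible columns.
#'
#' @param family A `homolog_family`.
#' @param peak_columns Peak-to-column map from [map_peaks_to_columns()].
#' @param tolerance Column tolerance for co-occurrence (default 2).
#' @return A tibble with one row per alignment column: `family_id`,
#'   `column`, `n`, `m`, `p0`, `p_value`, and flag columns `gap_excluded`,
#'   `trimmed`, `rrt_masked` (the latter two initialised to `FALSE`; see
#'   [trim_termini()] and [suspect_mask()]).
#' @export
column_stats <- function(family, peak_columns, tolerance = 2L) {
  if (family$n < 2L) abort(paste0("family ", family$family_id, ": fewer than 2 members"))
  stopifnot(tolerance >= 0L)
  L <- family$L
  elig <- family$eligible_cols
  pk <- split(peak_columns$column, factor(peak_columns$member, levels = seq_len(family$n)))
  m <- column_m(pk, L, as.integer(tolerance))
  p_total <- nrow(peak_columns)
  p0 <- if (length(elig) > 0) min(1, (2 * tolerance + 1) * p_total / (family$n * length(elig))) else 0
  gap_excluded <- !(seq_len(L) %in% elig)
  p <- rep(NA_real_, L)
  usable <- !gap_excluded & m >= 1
  if (any(usable)) p[usable] <- cond_binom_p(m[usable], family$n, p0)
  tibble(
    family_id = family$family_id,
    column = seq_len(L),
    n = family$n,
    m = m,
    p0 = p0,
    p_value = p,
    gap_excluded = gap_excluded,
    trimmed = FALSE,
    rrt_masked = FALSE
  )
}

#' Flag terminally trimmed alignment columns
#'
#' Locates the most N-terminal column with no gaps in any member and flags
#' it together with the following `trim` columns; symmetrically, the most
#' C-terminal gap-free column and the `trim` columns preceding it. Trimmed
#' columns are excluded from family-level significance, removing the known
#' codon-usage signal at sequence termini.
#'
#' @param family A `homolog_family`.
#' @param stats A column-stat tibble from [column_stats()].
#' @param trim Number of columns trimmed inward of each boundary (default 50).
#' @return `stats` with the `trimmed` flag set.
#' @export
trim_termini <- function(family, stats, trim = 50L) {
  elig <- family$eligible_cols
  L <- family$L
  if (length(elig) == 0) {
    warn(paste0("family ", family$family_id, ": no gap-free column; whole family trimmed"))
    stats$trimmed <- TRUE
    return(stats)
  }
  nb <- min(elig)
  cb <- max(elig)
  tr <- c(nb:min(L, nb + trim), max(1L, cb - trim):cb)
  stats$trimmed <- stats$column %in% tr
  stats
}

#' Family-level significance call
#'
#' A family shows conserved rare codon co-occurrence when at least one
#' column that is gap-free, untrimmed and not masked by the RRT null has a
#' co-occurrence p-value at or below the threshold. The reported best
#' column is the usable column with the smallest p-value (ties broken
#' toward the most N-terminal column).
#'
#' @param stats A column-stat tibble (flags applied as desired).
#' @param threshold Per-column significance threshold (default 1e-4).
#' @return A one-row tibble: `family_id`, `significant`, `best_column`,
#'   `best_p`, `n_usable` (usable columns with a defined p-value).
#' @export
family_significant <- function(stats, threshold = 1e-4) {
  usable <- !stats$gap_excluded & !stats$trimmed & !stats$rrt_masked & !is.na(stats$p_value)
  out <- tibble(
    family_id = stats$family_id[1] %||% NA_character_,
    significant = FALSE,
    best_column = NA_integer_,
    best_p = NA_real_,
    n_usable = sum(usable)
  )
  if (!any(usable)) return(out)
  i <- which(usable)[which.min(stats$p_value[usable])]
  out$best_column <- stats$column[i]
  out$best_p <- stats$p_value[i]
  out$significant <- out$best_p <= threshold
  out
}

#' Circularly shift peak positions within each member
#'
#' Null-randomisation device: every member's peak residues are shifted by
#' one independent uniform circular offset within the member's ungapped
#' length and re-mapped to alignment columns. Peak counts and within-member
#' spacing are preserved; cross-member alignment is destroyed. Useful for
#' calibration experiments on the co-occurrence statistics.
#'
#' @param family A `homolog_family`.
#' @param peaks A peak tibble from [map_peaks_to_columns()] (this family's
#'   rows).
#' @param seed Optional local seed.
#' @return The peak tibble with shifted `peak_codon` and re-mapped `column`.
#' @export
shift_peaks <- function(family, peaks, seed = NULL) {
  run <- function() {
    res <- peaks$peak_codon
    for (k in unique(peaks$member)) {
      sel <- peaks$member == k
      len <- length(family$col_map[[k]])
      s <- sample.int(len, 1L) - 1L
      res[sel] <- ((res[sel] - 1L + s) %% len) + 1L
    }
    peaks$peak_codon <- res
    peaks$column <- vapply(
      seq_along(res),
      function(r) family$col_map[[peaks$member[r]]][res[r]],
      integer(1)
    )
    peaks
  }
  if (is.null(seed)) run() else with_seed_local(seed, run())
}

# Count unordered peak pairs from different members within +/- tol columns.
# peaks: data.frame/list with member and column vectors.
count_cooccurring_pairs <- function(member, column, tol) {
  o <- order(column)
  member <- member[o]
  column <- column[o]
  n <- length(column)
  if (n < 2L) return(0L)
  total <- 0L
  j <- 1L
  for (i in seq_len(n)) {
    while (column[i] - column[j] > tol) j <- j + 1L
    if (i > j) {
      idx <- j:(i - 1L)
      total <- total + sum(member[idx] != member[i])
    }
  }
  total
}

#' Dataset-level shift-permutation test of peak co-occurrence
#'
#' The observed statistic is the total number of co-occurring peak pairs
#' (peaks of different members within `tolerance` alignment columns of each
#' other) summed over families. The null distribution is generated by
#' circularly shifting each member's peak positions within its own ungapped
#' sequence by an independent uniform offset -- preserving each member's
#' peak count and spacing while destroying cross-member alignment -- and
#' re-mapping the shifted positions to alignment columns.
#'
#' @param families List of `homolog_family` objects.
#' @param peaks A tibble of mapped peaks (rows of [map_peaks_to_columns()]
#'   for all families, bound together).
#' @param n_permutations Number of permutations (>= 10).
#' @param tolerance Column tolerance (default 2).
#' @param seed Optional local seed.
#' @return An object of class `shift_test`: list with `observed`,
#'   `null_mean`, `null_sd`, `n_permutations`, `p_normal` (upper-tail
#'   normal approximation on the permutation z-score), `p_empirical`
#'   (`(1 + #{null >= obs}) / (B + 1)`), and `z`.
#' @export
global_shift_test <- function(families, peaks, n_permutations = 199L, tolerance = 2L, seed = NULL) {
  if (n_permutations < 10L) abort("global_shift_test(): need at least 10 permutations")
  run <- function() {
    fam_ids <- vapply(families, function(f) f$family_id, character(1))
    per_fam <- lapply(families, function(f) {
      pk <- peaks[peaks$family_id == f$family_id, , drop = FALSE]
      list(
        member = pk$member,
        residue = pk$peak_codon,
        column = pk$column,
        len = vapply(f$col_map, length, integer(1)),
        col_map = f$col_map
      )
    })
    obs <- sum(vapply(per_fam, function(x) count_cooccurring_pairs(x$member, x$column, tolerance), integer(1)))
    null <- vapply(seq_len(n_permutations), function(b) {
      sum(vapply(per_fam, function(x) {
        if (length(x$member) < 2L) return(0L)
        res <- x$residue
        for (k in unique(x$member)) {
          sel <- x$member == k
          lk <- x$len[k]
          s <- sample.int(lk, 1L) - 1L
          res[sel] <- ((res[sel] - 1L + s) %% lk) + 1L
        }
        cols <- vapply(seq_along(res), function(r) x$col_map[[x$member[r]]][res[r]], integer(1))
        count_cooccurring_pairs(x$member, cols, tolerance)
      }, integer(1)))
    }, numeric(1))
    mu <- mean(null)
    sdv <- sd(null)
    z <- if (sdv > 0) (obs - mu) / sdv else ifelse(obs > mu, Inf, 0)
    structure(
      list(
        observed = obs, null_mean = mu, null_sd = sdv,
        n_permutations = n_permutations,
        z = z,
        p_normal = stats::pnorm(z, lower.tail = FALSE),
        p_empirical = (1 + sum(null >= obs)) / (n_permutations + 1)
      ),
      class = "shift_test"
    )
  }
  if (is.null(seed)) run() else with_seed_local(seed, run())
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf(
    "Shift-permutation test: observed %d co-occurring peak pairs, null %.1f +/- %.1f (B = %d)\n  z = %.2f, normal-tail p = %.3g, empirical p >= %.3g\n",
    x$observed, x$null_mean, x$null_sd, x$n_permutations, x$z, x$p_normal, x$p_empirical
  ))
  invisible(x)
}

#' @rdname global_shift_test
#' @param x A `shift_test` object.
#' @param ... Unused.
#' @export
glance.shift_test <- function(x, ...) {
  tibble(
    observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
    z = x$z, p_normal = x$p_normal, p_empirical = x$p_empirical,
    n_permutations = x$n_permutations
  )
}
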