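#' Pipeline stage parameters
#'
#' All stage parameters with their standard defaults: 17-codon %MinMax
#' windows, a +/-2-column co-occurrence tolerance, 50-column terminal
#' trimming, a 1e-4 per-column significance threshold, 200 RRT replicates
#' with the top 5% of ever-significant positions masked +/-8 columns, and
#' %GC3 bins 10 points wide advancing by 5.
#'
#' @param window_size %MinMax window in codons.
#' @param tolerance Co-occurrence column tolerance.
#' @param trim Terminal trimming depth in columns.
#' @param threshold Per-column significance threshold.
#' @param rrt_replicates RRT replicates per family (0 disables the RRT
#'   stage).
#' @param suspect_frac Fraction of ever-significant columns deemed suspect.
#' @param mask_radius Mask radius around suspect columns.
#' @param gc3_bin_width,gc3_bin_step %GC3 binning of the RRT usage tables.
#' @param pair_window Window for codon pair multipliers.
#' @param shift_permutations Permutations of the dataset-level shift test
#'   (0 disables it).
#' @param seed Optional seed governing the whole run.
#' @return A list of class `crcc_params`.
#' @export
crcc_params <- function(window_size = 17L, tolerance = 2L, trim = 50L,
                        threshold = 1e-4, rrt_replicates = 200L,
                        suspect_frac = 0.05, mask_radius = 8L,
                        gc3_bin_width = 10, gc3_bin_step = 5,
                        pair_window = 17L, shift_permutations = 199L,
                        seed = NULL) {
  structure(
    list(
      window_size = as.integer(window_size), tolerance = as.integer(tolerance),
      trim = as.integer(trim), threshold = threshold,
      rrt_replicates = as.integer(rrt_replicates), suspect_frac = suspect_frac,
      mask_radius = as.integer(mask_radius), gc3_bin_width = gc3_bin_width,
      gc3_bin_step = gc3_bin_step, pair_window = as.integer(pair_window),
      shift_permutations = as.integer(shift_permutations), seed = seed
    ),
    class = "crcc_params"
  )
}

#' Run the conserved rare codon cluster pipeline
#'
#' Executes the full analysis on a dataset: species codon usage tables,
#' %MinMax profiles and rare codon cluster peaks per member gene, peak
#' splicing into family alignments, per-column co-occurrence statistics,
#' RRT suspect masking, terminal trimming, family-level significance calls
#' at three stages (raw co-occurrence, after RRT masking, after masking
#' plus trimming -- a monotone funnel), and the dataset-level
#' shift-permutation test.
#'
#' @param dataset A `crcc_dataset` (from [simulate_crcc_dataset()] or
#'   [load_crcc_dataset()]), a directory path of the on-disk layout, or any
#'   list with `orfeomes` (ORF-record tibble) and `families` (list of
#'   `homolog_family` whose members carry `cds`).
#' @param params A `crcc_params` list.
#' @return An object of class `crcc_analysis`: list with `family_results`
#'   (per-family calls), `column_stats` (per-column statistics with all
#'   flags and RRT replicate counts), `peaks` (mapped peak columns),
#'   `global_test` (a `shift_test`, or `NULL`), `usage_tables`, `params`
#'   and, when the dataset carries ground truth, `truth`.
#' @export
run_crcc_pipeline <- function(dataset, params = crcc_params()) {
  if (is.character(dataset)) dataset <- load_crcc_dataset(dataset)
  run <- function() {
    orf <- dataset$orfeomes
    species <- unique(orf$species_id)
    usage <- lapply(setNames(species, species), function(sp) usage_table(orf[orf$species_id == sp, ]))
    lookups <- lapply(usage, usage_lookup)
    models <- NULL
    if (params$rrt_replicates > 0L) {
      models <- lapply(setNames(species, species), function(sp) {
        build_rrt_model(orf[orf$species_id == sp, ],
          bin_width = params$gc3_bin_width, bin_step = params$gc3_bin_step,
          pair_window = params$pair_window
        )
      })
    }
    fams <- dataset$families
    fam_out <- vector("list", length(fams))
    col_out <- vector("list", length(fams))
    peak_out <- vector("list", length(fams))
    for (i in seq_along(fams)) {
      f <- fams[[i]]
      pk <- lapply(seq_len(f$n), function(k) {
        idx <- codon_index(split_codons(f$members$cds[k]))
        res <- peak_codons_idx(idx, lookups[[f$members$species_id[k]]], params$window_size)
        tibble(
          family_id = f$family_id, member = k,
          species_id = f$members$species_id[k], gene_id = f$members$gene_id[k],
          peak_codon = res, column = f$col_map[[k]][res]
        )
      })
      pk <- bind_rows(pk)
      stats_raw <- column_stats(f, pk, tolerance = params$tolerance)
      stats <- trim_termini(f, stats_raw, trim = params$trim)
      mask <- NULL
      if (!is.null(models)) {
        mask <- suspect_mask(f, models, usage,
          n_replicates = params$rrt_replicates, threshold = params$threshold,
          top_frac = params$suspect_frac, radius = params$mask_radius,
          tolerance = params$tolerance, window_size = params$window_size
        )
        stats <- apply_rrt_mask(stats, mask)
        stats$n_significant_replicates <- mask$n_significant_replicates
      } else {
        stats$n_significant_replicates <- 0L
      }
      pre <- family_significant(stats_raw, params$threshold)
      post_rrt <- family_significant(
        if (is.null(mask)) stats_raw else apply_rrt_mask(stats_raw, mask),
        params$threshold
      )
      final <- family_significant(stats, params$threshold)
      fam_out[[i]] <- tibble(
        family_id = f$family_id, n = f$n, L = f$L,
        n_eligible = length(f$eligible_cols),
        n_peaks = nrow(pk),
        sig_pre_rrt = pre$significant,
        sig_post_rrt = post_rrt$significant,
        significant = final$significant,
        best_column = final$best_column,
        best_p = final$best_p
      )
      col_out[[i]] <- stats
      peak_out[[i]] <- pk
    }
    peaks <- bind_rows(peak_out)
    global <- NULL
    if (params$shift_permutations >= 10L) {
      global <- global_shift_test(fams, peaks,
        n_permutations = params$shift_permutations, tolerance = params$tolerance
      )
    }
    structure(
      list(
        family_results = bind_rows(fam_out),
        column_stats = bind_rows(col_out),
        peaks = peaks,
        global_test = global,
        usage_tables = usage,
        params = params,
        truth = dataset$truth
      ),
      class = "crcc_analysis"
    )
  }
  if (is.null(params$seed)) run() else with_seed_local(params$seed, run())
}

#' @export
print.crcc_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<crcc_analysis: %d families>\n  significant co-occurrence: %d raw, %d after RRT masking, %d after masking + trimming\n",
    g$n_families, g$n_sig_pre_rrt, g$n_sig_post_rrt, g$n_sig_post_trim
  ))
  if (!is.null(x$global_test)) print(x$global_test)
  invisible(x)
}

#' @rdname run_crcc_pipeline
#' @param x A `crcc_analysis`.
#' @param ... Unused.
#' @export
glance.crcc_analysis <- function(x, ...) {
  fr <- x$family_results
  tibble(
    n_families = nrow(fr),
    n_sig_pre_rrt = sum(fr$sig_pre_rrt),
    n_sig_post_rrt = sum(fr$sig_post_rrt),
    n_sig_post_trim = sum(fr$significant),
    global_observed = if (!is.null(x$global_test)) x$global_test$observed else NA_integer_,
    global_z = if (!is.null(x$global_test)) x$global_test$z else NA_real_,
    global_p_normal = if (!is.null(x$global_test)) x$global_test$p_normal else NA_real_
  )
}

#' @rdname run_crcc_pipeline
#' @export
tidy.crcc_analysis <- function(x, ...) {
  x$family_results
}

#' Compare pipeline calls with simulation ground truth
#'
#' For analyses of simulated datasets: family-level sensitivity (planted
#' families called significant with the best column within `tolerance` of
#' the planted column) and false-positive rate (non-planted families called
#' significant), both after RRT masking and terminal trimming.
#'
#' @param analysis A `crcc_analysis` carrying `truth`.
#' @param tolerance Column tolerance for localisation (default 2).
#' @return A one-row tibble: `n_planted`, `n_detected`, `n_localised`,
#'   `sensitivity` (localised detections / planted), `n_null`,
#'   `n_false_positive`, `false_positive_rate`.
#' @export
truth_performance <- function(analysis, tolerance = 2L) {
  if (is.null(analysis$truth)) abort("truth_performance(): analysis has no ground truth")
  fr <- left_join(analysis$family_results, analysis$truth, by = "family_id")
  planted <- fr[fr$planted, ]
  null <- fr[!fr$planted, ]
  localised <- planted$significant & !is.na(planted$best_column) &
    abs(planted$best_column - planted$plant_column) <= tolerance
  tibble(
    n_planted = nrow(planted),
    n_detected = sum(planted$significant),
    n_localised = sum(localised),
    sensitivity = if (nrow(planted) > 0) mean(localised) else NA_real_,
    n_null = nrow(null),
    n_false_positive = sum(null$significant),
    false_positive_rate = if (nrow(null) > 0) mean(null$significant) else NA_real_
  )
}
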