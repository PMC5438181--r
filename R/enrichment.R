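.GO_CLASSES <- c("cellular_component", "molecular_function", "biological_process")

#' GO term enrichment among families with conserved rare codon clusters
#'
#' Fisher's exact test (two-sided) per GO term on the 2x2 table of families
#' with/without a conserved rare codon cluster versus with/without the
#' term. Terms are counted at family level: a family counts once per term
#' no matter how many members carry it. By default only the 10 most common
#' terms of each GO class are tested.
#'
#' @param go_table A tibble with columns `family_id`, `go_term`, `go_class`
#'   (one of `cellular_component`, `molecular_function`,
#'   `biological_process`). Duplicate (family, term) rows are collapsed.
#' @param crcc_families Character vector of family ids with a CRCC.
#' @param background_families Character vector of family ids without.
#' @param top_n Number of most common terms tested per class (default 10).
#' @param all_terms Test every term instead (default `FALSE`).
#' @return A tibble with one row per tested term: counts, `odds_ratio`,
#'   `p_value`, `direction` (`enriched`/`depleted`/`none`) and a
#'   `degenerate` flag (empty margin, p forced to 1).
#' @export
go_enrichment <- function(go_table, crcc_families, background_families,
                          top_n = 10L, all_terms = FALSE) {
  bad <- setdiff(unique(go_table$go_class), .GO_CLASSES)
  if (length(bad) > 0) abort(paste0("invalid go_class: ", paste(bad, collapse = ", ")))
  go <- distinct(go_table, .data$family_id, .data$go_term, .data$go_class)
  go <- go[go$family_id %in% c(crcc_families, background_families), , drop = FALSE]
  terms <- go %>%
    count(.data$go_class, .data$go_term, sort = TRUE) %>%
    group_by(.data$go_class)
  if (!all_terms) terms <- slice(terms, seq_len(min(top_n, n())))
  terms <- ungroup(terms)
  n_crcc <- length(unique(crcc_families))
  n_bg <- length(unique(background_families))
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    fams <- go$family_id[go$go_term == terms$go_term[i] & go$go_class == terms$go_class[i]]
    a <- sum(unique(crcc_families) %in% fams)
    c_ <- sum(unique(background_families) %in% fams)
    tab <- matrix(c(a, n_crcc - a, c_, n_bg - c_), nrow = 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      p <- 1
      or <- NA_real_
    } else {
      p <- fisher.test(tab)$p.value
      or <- (a * (n_bg - c_)) / pmax(1e-300, (n_crcc - a) * c_)
    }
    tibble(
      go_term = terms$go_term[i], go_class = terms$go_class[i],
      n_crcc_with_term = a, n_background_with_term = c_,
      n_crcc = n_crcc, n_background = n_bg,
      odds_ratio = or, p_value = p,
      direction = if (degenerate || a / n_crcc == c_ / n_bg) {
        "none"
      } else if (a / n_crcc > c_ / n_bg) "enriched" else "depleted",
      degenerate = degenerate
    )
  })
  bind_rows(rows)
}

# residues of a protein within +/- w of any domain boundary
.near_boundary_mask <- function(len, starts, ends, w) {
  near <- logical(len)
  for (b in c(starts, ends)) {
    near[max(1L, b - w):min(len, b + w)] <- TRUE
  }
  near
}

#' CRCC positions relative to domain boundaries
#'
#' Tests whether conserved rare codon clusters fall near domain boundaries
#' (within `near_window` residues of a domain start or end) more or less
#' often than expected under a null model in which CRCCs are distributed
#' evenly across the (gapless) residues of the analysed proteins: a
#' two-sided binomial test of the observed near-count against the expected
#' near-fraction. `test = "within"` runs the analogous test for CRCCs
#' falling inside domains.
#'
#' @param crccs A tibble with `protein_id` and `position` (residue
#'   coordinate of each CRCC).
#' @param domains A tibble with `protein_id`, `start`, `end` (1-based
#'   inclusive residue coordinates).
#' @param protein_lengths A tibble with `protein_id` and `length`.
#'   Proteins without any domain annotation are excluded from the test.
#' @param near_window "Near" distance in residues (default 10).
#' @param test `"boundary"` or `"within"`.
#' @return A one-row tibble: `test`, `n_crcc`, `n_observed`,
#'   `expected_frac`, `p_value`, `direction`, `degenerate`.
#' @export
boundary_enrichment <- function(crccs, domains, protein_lengths,
                                near_window = 10L, test = c("boundary", "within")) {
  test <- match.arg(test)
  prot <- intersect(unique(domains$protein_id), protein_lengths$protein_id)
  if (length(prot) == 0) abort("boundary_enrichment(): no annotated proteins")
  lens <- setNames(protein_lengths$length, protein_lengths$protein_id)
  bad <- domains$start < 1 | domains$end > lens[domains$protein_id] | domains$start > domains$end
  if (any(bad)) abort("boundary_enrichment(): domain coordinates outside protein")
  total_res <- 0L
  marked_res <- 0L
  masks <- list()
  for (p in prot) {
    d <- domains[domains$protein_id == p, , drop = FALSE]
    len <- lens[[p]]
    mask <- if (test == "boundary") {
      .near_boundary_mask(len, d$start, d$end, near_window)
    } else {
      inside <- logical(len)
      for (i in seq_len(nrow(d))) inside[d$start[i]:d$end[i]] <- TRUE
      inside
    }
    masks[[p]] <- mask
    total_res <- total_res + len
    marked_res <- marked_res + sum(mask)
  }
  expected <- marked_res / total_res
  cc <- crccs[crccs$protein_id %in% prot, , drop = FALSE]
  n <- nrow(cc)
  obs <- sum(vapply(seq_len(n), function(i) masks[[cc$protein_id[i]]][cc$position[i]], logical(1)))
  degenerate <- n == 0 || expected <= 0 || expected >= 1
  p_value <- if (degenerate) 1 else binom.test(obs, n, expected)$p.value
  tibble(
    test = test, n_crcc = n, n_observed = obs, expected_frac = expected,
    p_value = p_value,
    direction = if (degenerate || obs == n * expected) {
      "none"
    } else if (obs > n * expected) "enriched" else "depleted",
    degenerate = degenerate
  )
}

#' N- versus C-terminal boundary windows
#'
#' Compares fixed `window`-residue windows at the N-terminal boundary
#' (domain start) against the C-terminal boundary (domain end) of every
#' annotated domain: windows either follow the boundary, are centred on
#' it, or flank (precede) it. Domains whose two windows overlap each other
#' or extend beyond the protein are skipped. CRCC counts in the N- versus
#' C-side windows are compared with a two-sided sign test
#' (Binomial(nN + nC, 1/2)).
#'
#' @inheritParams boundary_enrichment
#' @param window Window size in residues (default 50).
#' @param mode `"following"`, `"centered"` or `"flanking"`.
#' @return A one-row tibble: `mode`, `n_domains_used`, `n_domains_skipped`,
#'   `n_N`, `n_C`, `p_value`, `direction`, `degenerate`.
#' @export
nc_window_test <- function(crccs, domains, protein_lengths, window = 50L,
                           mode = c("following", "centered", "flanking")) {
  mode <- match.arg(mode)
  lens <- setNames(protein_lengths$length, protein_lengths$protein_id)
  half <- window %/% 2L
  win_of <- function(b) {
    switch(mode,
      following = c(b, b + window - 1L),
      centered = c(b - half, b + (window - half) - 1L),
      flanking = c(b - window, b - 1L)
    )
  }
  n_N <- 0L
  n_C <- 0L
  used <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(domains))) {
    p <- domains$protein_id[i]
    len <- lens[[p]]
    if (is.null(len)) {
      skipped <- skipped + 1L
      next
    }
    wn <- win_of(domains$start[i])
    wc <- win_of(domains$end[i])
    if (wn[1] < 1L || wc[2] > len || wn[2] >= wc[1]) {
      skipped <- skipped + 1L
      next
    }
    used <- used + 1L
    pos <- crccs$position[crccs$protein_id == p]
    n_N <- n_N + sum(pos >= wn[1] & pos <= wn[2])
    n_C <- n_C + sum(pos >= wc[1] & pos <= wc[2])
  }
  degenerate <- (n_N + n_C) == 0L
  p_value <- if (degenerate) NA_real_ else binom.test(n_N, n_N + n_C, 0.5)$p.value
  tibble(
    mode = mode, n_domains_used = used, n_domains_skipped = skipped,
    n_N = n_N, n_C = n_C, p_value = p_value,
    direction = if (degenerate || n_N == n_C) {
      "none"
    } else if (n_N > n_C) "N_enriched" else "C_enriched",
    degenerate = degenerate
  )
}

#' Length-matched control set
#'
#' Greedily matches each case protein (in input order) to the unused
#' control-pool protein of most similar length (minimum absolute length
#' difference; ties broken toward the shorter control, then input order).
#' Matching is without replacement: each control is used at most once.
#'
#' @param cases A tibble with `protein_id` and `length` (proteins with a
#'   CRCC).
#' @param pool A tibble with `protein_id` and `length` (candidate controls,
#'   disjoint from `cases`).
#' @return A tibble with one row per case: `protein_id`, `length`,
#'   `control_id`, `control_length`, `length_diff`.
#' @export
length_matched_controls <- function(cases, pool) {
  if (length(intersect(cases$protein_id, pool$protein_id)) > 0) {
    abort("length_matched_controls(): case and pool sets overlap")
  }
  if (nrow(pool) < nrow(cases)) {
    abort(paste0(
      "length_matched_controls(): control pool exhausted; unmatched cases: ",
      paste(cases$protein_id[(nrow(pool) + 1):nrow(cases)], collapse = ", ")
    ))
  }
  avail <- rep(TRUE, nrow(pool))
  ctrl <- integer(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    d <- abs(pool$length - cases$length[i])
    d[!avail] <- Inf
    cand <- which(d == min(d))
    j <- cand[order(pool$length[cand], cand)][1]
    ctrl[i] <- j
    avail[j] <- FALSE
  }
  tibble(
    protein_id = cases$protein_id,
    length = cases$length,
    control_id = pool$protein_id[ctrl],
    control_length = pool$length[ctrl],
    length_diff = abs(cases$length - pool$length[ctrl])
  )
}
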