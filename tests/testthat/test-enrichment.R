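test_that("GO enrichment agrees with the hypergeometric oracle", {
  # 100 CRCC families, 900 background; term hits 10 and 10 -> [[10,90],[10,890]]
  crcc <- sprintf("c%03d", 1:100)
  bg <- sprintf("b%03d", 1:900)
  go <- tibble::tibble(
    family_id = c(crcc[1:10], bg[1:10]),
    go_term = "GO:0001", go_class = "biological_process"
  )
  res <- go_enrichment(go, crcc, bg)
  expect_equal(res$p_value, oracle_fisher(10, 90, 10, 890), tolerance = 1e-10)
  expect_equal(res$p_value, fisher.test(matrix(c(10, 90, 10, 890), 2, byrow = TRUE))$p.value)
  expect_equal(res$direction, "enriched")
})

test_that("GO enrichment handles flat and degenerate tables", {
  crcc <- sprintf("c%02d", 1:20)
  bg <- sprintf("b%02d", 1:20)
  go_flat <- tibble::tibble(
    family_id = c(crcc[1:5], bg[1:5]),
    go_term = "GO:0002", go_class = "molecular_function"
  )
  res <- go_enrichment(go_flat, crcc, bg)
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")
  # term present in every family: degenerate margin
  go_all <- tibble::tibble(
    family_id = c(crcc, bg), go_term = "GO:0003", go_class = "cellular_component"
  )
  res2 <- go_enrichment(go_all, crcc, bg)
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 1)
  expect_error(
    go_enrichment(
      tibble::tibble(family_id = "x", go_term = "t", go_class = "bogus"), crcc, bg
    ),
    "invalid go_class"
  )
})

test_that("only the most common terms per class are tested by default", {
  crcc <- sprintf("c%02d", 1:30)
  bg <- sprintf("b%02d", 1:30)
  go <- dplyr::bind_rows(lapply(1:15, function(i) {
    tibble::tibble(
      family_id = sample(c(crcc, bg), 20 - i),
      go_term = sprintf("GO:%04d", i), go_class = "biological_process"
    )
  }))
  expect_equal(nrow(go_enrichment(go, crcc, bg)), 10L)
  expect_equal(nrow(go_enrichment(go, crcc, bg, all_terms = TRUE)), 15L)
})

test_that("boundary enrichment flags planted extremes and small samples", {
  lens <- tibble::tibble(protein_id = sprintf("p%d", 1:10), length = 400L)
  doms <- tibble::tibble(
    protein_id = sprintf("p%d", 1:10), start = 100L, end = 300L
  )
  on_boundary <- tibble::tibble(
    protein_id = rep(sprintf("p%d", 1:10), each = 4),
    position = rep(c(98L, 101L, 299L, 302L), 10)
  )
  res <- boundary_enrichment(on_boundary, doms, lens, near_window = 10)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, "enriched")
  expect_equal(res$n_observed, 40L)
  # a single CRCC cannot reach significance but returns a valid p
  one <- boundary_enrichment(
    tibble::tibble(protein_id = "p1", position = 100L), doms, lens
  )
  expect_gte(one$p_value, 0.05)
  expect_lte(one$p_value, 1)
  # within-domain test on the same extreme data
  inside <- tibble::tibble(protein_id = "p1", position = 200L)
  res_in <- boundary_enrichment(inside, doms, lens, test = "within")
  expect_equal(res_in$n_observed, 1L)
  expect_equal(res_in$expected_frac, 201 / 400)
})

test_that("N/C window sign test matches the exact binomial", {
  lens <- tibble::tibble(protein_id = "p", length = 500L)
  doms <- tibble::tibble(protein_id = "p", start = 150L, end = 350L)
  # 9 CRCCs in the N-side following window, 1 in the C-side
  crccs <- tibble::tibble(
    protein_id = "p",
    position = c(150L + 0:8, 355L)
  )
  res <- nc_window_test(crccs, doms, lens, window = 50, mode = "following")
  expect_equal(res$n_N, 9L)
  expect_equal(res$n_C, 1L)
  expect_equal(res$p_value, binom.test(9, 10, 0.5)$p.value)
  expect_equal(res$p_value, 2 * sum(choose(10, 9:10)) / 2^10, tolerance = 1e-12)
  expect_equal(res$direction, "N_enriched")
  # equal counts: p = 1
  eq <- nc_window_test(
    tibble::tibble(protein_id = "p", position = c(160L, 360L)), doms, lens
  )
  expect_equal(eq$p_value, 1)
  # no CRCC in either window: degenerate, no p
  none <- nc_window_test(
    tibble::tibble(protein_id = "p", position = 10L), doms, lens
  )
  expect_true(none$degenerate)
  expect_true(is.na(none$p_value))
  # overlapping windows cause the domain to be skipped
  tight <- tibble::tibble(protein_id = "p", start = 200L, end = 220L)
  sk <- nc_window_test(crccs, tight, lens, window = 50, mode = "following")
  expect_equal(sk$n_domains_skipped, 1L)
})

test_that("length matching is greedy, tie-broken toward shorter, without replacement", {
  cases <- tibble::tibble(protein_id = c("a", "b"), length = c(100L, 200L))
  pool <- tibble::tibble(protein_id = c("x", "y", "z"), length = c(101L, 199L, 500L))
  m <- length_matched_controls(cases, pool)
  expect_equal(m$control_id, c("x", "y"))
  # tie in |delta|: shorter control chosen
  cases2 <- tibble::tibble(protein_id = "a", length = 100L)
  pool2 <- tibble::tibble(protein_id = c("u", "v"), length = c(99L, 101L))
  expect_equal(length_matched_controls(cases2, pool2)$control_id, "u")
  # bijection: no control reused
  set.seed(91)
  cases3 <- tibble::tibble(protein_id = sprintf("c%d", 1:50), length = sample(100:900, 50))
  pool3 <- tibble::tibble(protein_id = sprintf("p%d", 1:80), length = sample(100:900, 80))
  m3 <- length_matched_controls(cases3, pool3)
  expect_equal(anyDuplicated(m3$control_id), 0L)
  # greedy nearest beats random pairing on mean |delta|
  rnd <- mean(abs(cases3$length - pool3$length[sample(80, 50)]))
  expect_lte(mean(m3$length_diff), rnd)
  # exhausted pool errors
  expect_error(
    length_matched_controls(cases3, pool3[1:10, ]),
    "exhausted"
  )
  expect_error(length_matched_controls(cases3, cases3), "overlap")
})
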