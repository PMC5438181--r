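test_that("conditional binomial p-value matches enumeration and its identities", {
  expect_equal(cond_binom_p(1, 10, 0.01), 1)
  expect_equal(cond_binom_p(1, 50, 0.3), 1)
  got <- cond_binom_p(3, 10, 0.01)
  expect_equal(got, oracle_cond_binom(3, 10, 0.01), tolerance = 1e-12)
  expect_equal(got, 1.19e-3, tolerance = 0.01)
  # non-increasing in m
  for (p0 in c(0.001, 0.05, 0.3)) {
    p <- cond_binom_p(1:12, 12, p0)
    expect_true(all(diff(p) <= 1e-15))
  }
  expect_error(cond_binom_p(2, 10, 0), "inconsistent")
})

test_that("column_stats counts members once and flags gap columns", {
  cds <- random_cds(30, seed = 3)
  fam <- family_from_cds(rep(list(cds), 4))
  # member 1 has two peaks near column 10: contributes 1 to m there
  pk <- peaks_at(fam, list(c(9L, 11L), 10L, 10L, integer(0)))
  st <- column_stats(fam, pk, tolerance = 2L)
  expect_equal(st$m[st$column == 10], 3L)
  expect_equal(st$n[1], 4L)
  expect_equal(st$p0[1], min(1, 5 * 4 / (4 * 30)))
  expect_equal(st$p_value[st$column == 25], NA_real_)  # m = 0 -> no p-value
  expect_error(column_stats(family_from_cds(list(cds)), pk), "fewer than 2")
})

test_that("unanimous peak columns in a large family are highly significant", {
  cds <- random_cds(60, seed = 8)
  fam <- family_from_cds(rep(list(cds), 20))
  pk <- peaks_at(fam, rep(list(30L), 20))
  st <- column_stats(fam, pk)
  expect_lt(st$p_value[st$column == 30], 1e-4)
  expect_equal(st$m[st$column == 30], 20L)
})

test_that("peaks near gap-excluded columns still support neighbouring columns", {
  fam <- homolog_family("f", tibble::tibble(
    species_id = c("a", "b"), gene_id = c("ga", "gb"),
    aligned = c("KKKKK-KKKK", "KKKKKKKKKK"),
    protein = c("KKKKKKKKK", "KKKKKKKKKK"),
    cds = c(strrep("AAA", 9), strrep("AAA", 10))
  ))
  pk <- peaks_at(fam, list(integer(0), 6L))  # peak of member b at the gap column
  st <- column_stats(fam, pk, tolerance = 2L)
  expect_true(st$gap_excluded[st$column == 6])
  expect_equal(st$m[st$column == 5], 1L)     # counted at neighbours
  expect_equal(st$m[st$column == 8], 1L)
})

test_that("terminal trimming follows the gap-free boundaries", {
  # gapless alignment of 300 columns: 1-51 and 250-300 trimmed
  cds <- random_cds(300, seed = 5)
  fam <- family_from_cds(rep(list(cds), 3))
  st <- trim_termini(fam, column_stats(fam, peaks_at(fam, list(100L, 100L, 100L))))
  expect_equal(which(st$trimmed), c(1:51, 250:300))

  # first gap-free column at 12: N-side trim covers 12-62
  left <- paste(rep("-", 11), collapse = "")
  fam2 <- homolog_family("f2", tibble::tibble(
    species_id = c("a", "b"),
    gene_id = c("ga", "gb"),
    aligned = c(paste0(left, strrep("K", 289)), strrep("K", 300))
  ))
  st2 <- trim_termini(fam2, column_stats(fam2, peaks_at(fam2, list(100L, 100L))))
  expect_true(all(st2$trimmed[12:62]))
  expect_false(st2$trimmed[63])
  expect_true(all(st2$gap_excluded[1:11]))  # columns before the boundary are gap-excluded
  expect_false(any(st2$trimmed[1:11]))      # trimming starts at the gap-free boundary

  # short gapless alignment: N and C windows overlap, everything trimmed
  cds3 <- random_cds(80, seed = 6)
  fam3 <- family_from_cds(rep(list(cds3), 2))
  st3 <- trim_termini(fam3, column_stats(fam3, peaks_at(fam3, list(40L, 40L))))
  expect_true(all(st3$trimmed))
})

test_that("family significance requires a usable significant column", {
  cds <- random_cds(300, seed = 9)
  fam <- family_from_cds(rep(list(cds), 20))
  pk <- peaks_at(fam, rep(list(150L), 20))
  st <- trim_termini(fam, column_stats(fam, pk))
  call <- family_significant(st)
  expect_true(call$significant)
  # ties across the +/-2 neighbourhood break toward the most N-terminal column
  expect_equal(call$best_column, 148L)
  expect_lt(call$best_p, 5e-6 * 10)  # deep in the significant regime

  # the same unanimous column inside the trimmed region is not usable
  pk2 <- peaks_at(fam, rep(list(30L), 20))
  st2 <- trim_termini(fam, column_stats(fam, pk2))
  expect_false(family_significant(st2)$significant)

  # all p-values 1: not significant
  pk3 <- peaks_at(fam, c(list(150L), rep(list(integer(0)), 19)))
  st3 <- trim_termini(fam, column_stats(fam, pk3))
  expect_false(family_significant(st3)$significant)
  expect_equal(max(st3$p_value, na.rm = TRUE), 1)
})

test_that("co-occurring pair counting matches a quadratic oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    member <- sample(1:5, n, replace = TRUE)
    column <- sample(1:60, n, replace = TRUE)
    brute <- 0L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (member[i] != member[j] && abs(column[i] - column[j]) <= 2) brute <- brute + 1L
      }
    }
    expect_equal(
      codonconserve:::count_cooccurring_pairs(member, column, 2L),
      brute
    )
  }
})

test_that("the shift test flags planted co-occurrence and not its absence", {
  cds <- random_cds(200, seed = 10)
  fams <- lapply(1:4, function(i) family_from_cds(rep(list(cds), 10), family_id = paste0("f", i)))
  shared <- dplyr::bind_rows(lapply(fams, function(f) peaks_at(f, rep(list(100L), 10))))
  st <- global_shift_test(fams, shared, n_permutations = 99, seed = 2)
  expect_gt(st$z, 5)
  expect_lt(st$p_normal, 1e-6)
  expect_equal(st$p_empirical, 1 / 100)

  set.seed(15)
  scattered <- dplyr::bind_rows(lapply(fams, function(f) {
    peaks_at(f, lapply(1:10, function(k) sample(200L, 3)))
  }))
  st2 <- global_shift_test(fams, scattered, n_permutations = 99, seed = 3)
  expect_gt(st2$p_empirical, 0.01)

  # single member: statistic zero, p 1
  solo <- family_from_cds(rep(list(cds), 2), family_id = "solo")
  pk <- peaks_at(solo, list(50L, integer(0)))
  st3 <- global_shift_test(list(solo), pk, n_permutations = 19, seed = 4)
  expect_equal(st3$observed, 0L)
  expect_equal(st3$p_empirical, 1)

  expect_error(global_shift_test(fams, shared, n_permutations = 5), "at least 10")
})

test_that("glance on a shift test returns a one-row summary", {
  cds <- random_cds(100, seed = 20)
  fam <- family_from_cds(rep(list(cds), 3))
  st <- global_shift_test(list(fam), peaks_at(fam, list(50L, 50L, 50L)), n_permutations = 19, seed = 1)
  g <- glance(st)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("observed", "null_mean", "z", "p_normal", "p_empirical") %in% names(g)))
})
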