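test_that("Bonferroni thresholds floor to three decimals for reporting", {
  b <- bonferroni_alpha(0.05, 3)
  expect_equal(b$reported, 0.016)
  expect_equal(b$raw, 0.05 / 3)
  expect_equal(bonferroni_alpha(0.05, 1)$reported, 0.05)
  expect_equal(bonferroni_alpha(0.05, 5)$reported, 0.01)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("region averages are unweighted means over the CpG subset", {
  m <- fake_matrix(c(10, 20, 30))
  expect_equal(region_average(m, 2), 20)
  expect_equal(region_average(m), 20)
  expect_equal(region_average(fake_matrix(rep(0, 5))), 0)
  expect_error(region_average(m, integer(0)), "empty")
  expect_error(region_average(m, 4), "range")
  # zero-denominator CpGs drop out with a warning
  m2 <- fake_matrix(c(10, NaN, 30))
  expect_warning(avg <- region_average(m2), "zero called")
  expect_equal(avg, 20)
})

test_that("paired difference tables pair donors and difference percentages", {
  mk <- function(donor, pop, pct) fake_matrix(pct, donor = donor, population = pop)
  ms <- list(mk("D1", "A", c(50, 60)), mk("D1", "B", c(50, 60)),
             mk("D2", "A", c(10, 20)), mk("D2", "B", c(10, 20)))
  dt <- paired_difference_table(ms, "A", "B")
  expect_true(all(dt$diff == 0))
  expect_identical(nrow(dt), 4L)

  ms2 <- list(mk("D1", "A", c(70, 80)), mk("D1", "B", c(40, 50)))
  dt2 <- paired_difference_table(ms2, "A", "B")
  expect_true(all(dt2$diff == 30))

  # 6 donors x 15 CpGs -> 90 rows
  ms3 <- unlist(lapply(1:6, function(d)
    list(mk(paste0("D", d), "A", rep(50, 15)),
         mk(paste0("D", d), "B", rep(40, 15)))), recursive = FALSE)
  expect_identical(nrow(paired_difference_table(ms3, "A", "B")), 90L)

  expect_error(paired_difference_table(list(mk("D1", "A", 1:3)), "A", "B"),
               "absent")
  expect_error(
    paired_difference_table(list(mk("D1", "A", 1:3), mk("D2", "B", 1:3)),
                            "A", "B"), "pair")
})

test_that("the mixed-effects test handles the all-zero degenerate case exactly", {
  dt <- expand.grid(donor = paste0("D", 1:4), cpg = 1:5)
  dt$diff <- 0
  res <- mixed_effects_test(dt)
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_identical(res$n_donors, 4L)
  expect_identical(res$n_cpgs, 5L)
  expect_error(mixed_effects_test(dt[dt$donor == "D1", ]), ">= 2 donors")
})

test_that("a clear 40-point shift is detected at the corrected threshold", {
  dt <- simulate_diff_table(rep(0.9, 10), rep(0.5, 10), n_donors = 6,
                            n_clones = 20, seed = 91)
  res <- mixed_effects_test(dt, contrast = "shifted")
  expect_lt(res$p_value, 0.016)
  expect_true(res$significant)
  expect_lt(abs(res$estimate - 40), 10)
  expect_identical(res$method, "mixed_effects")
})

test_that("constant nonzero differences fall back to the permutation companion", {
  dt <- expand.grid(donor = paste0("D", 1:6), cpg = 1:5)
  dt$diff <- 30
  res <- mixed_effects_test(dt)
  expect_identical(res$method, "permutation")
  expect_match(res$note, "permutation")
  # |mean| attains 30 only when all six donors keep the same sign: 2 of the
  # 64 sign patterns, so the exhaustive two-sided p is 2/64
  expect_equal(res$p_value, 2 / 64)
})

test_that("donor-level sign-flip permutation matches exhaustive enumeration", {
  set.seed(61)
  for (rep in 1:10) {
    dt <- simulate_diff_table(stats::runif(5, 0.3, 0.9), rep(0.5, 5),
                              n_donors = 6, n_clones = 20)
    res <- permutation_test(dt, n_perm = 10000)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_sign_flip_p(dt))
  }
  zero <- data.frame(donor = rep(paste0("D", 1:6), each = 3),
                     cpg = rep(1:3, 6), diff = 0)
  expect_equal(permutation_test(zero)$p_value, 1)
  expect_warning(permutation_test(zero, n_perm = 50), "coarse")
})

test_that("permutation and mixed-effects significance calls agree on most scenarios", {
  set.seed(71)
  agree <- 0L
  for (i in 1:50) {
    shift <- sample(c(0, 0, 0.2, 0.4), 1)
    dt <- simulate_diff_table(rep(0.4 + shift, 8), rep(0.4, 8),
                              n_donors = 6, n_clones = 20)
    # compare calls at the family alpha: with six donors the exact sign-flip
    # p-value has granularity 1/64 and can never reach the 0.0167 Bonferroni
    # quotient, so that threshold would make the comparison vacuous
    a <- mixed_effects_test(dt, alpha = 0.05)$significant
    b <- permutation_test(dt, alpha = 0.05)$significant
    agree <- agree + (a == b)
  }
  expect_gte(agree / 50, 0.9)
})

test_that("strand-bias indices are absolute per-CpG strand differences", {
  top <- fake_matrix(c(100, 100, 100), strand = "top")
  bot <- fake_matrix(c(100, 100, 100), strand = "bottom")
  sb <- strand_bias_analysis(top, bot)
  expect_true(all(sb$per_cpg$index == 0))

  top2 <- fake_matrix(c(60, 100), strand = "top")
  bot2 <- fake_matrix(c(100, 100), strand = "bottom")
  sb2 <- strand_bias_analysis(top2, bot2)
  expect_equal(sb2$per_cpg$index, c(40, 0))
  expect_equal(sb2$per_cpg$signed, c(-40, 0))
  expect_true(all(sb2$per_cpg$index >= 0 & sb2$per_cpg$index <= 100))

  # strand mismatch in inputs is rejected
  expect_error(strand_bias_analysis(bot2, bot2), "expected top")
})

test_that("the region-level strand test flags hemimethylation across donors", {
  mk <- function(donor, strand, pct) fake_matrix(pct, donor = donor,
                                                 strand = strand)
  set.seed(81)
  donors <- paste0("D", 1:4)
  top <- lapply(donors, function(d) mk(d, "top", stats::rbinom(10, 20, 0.02) * 5))
  bot <- lapply(donors, function(d) mk(d, "bottom", stats::rbinom(10, 20, 0.99) * 5))
  sb <- strand_bias_analysis(top, bot)
  expect_gt(mean(sb$per_cpg$index), 80)
  expect_true(sb$test$significant)

  sym_a <- lapply(donors, function(d) mk(d, "top", stats::rbinom(10, 20, 0.5) * 5))
  sym_b <- lapply(donors, function(d) mk(d, "bottom", stats::rbinom(10, 20, 0.5) * 5))
  sb0 <- strand_bias_analysis(sym_a, sym_b)
  expect_lt(mean(sb0$per_cpg$index), 10)
  expect_false(sb0$test$significant)
})

test_that("complete-linkage clustering matches a brute-force oracle", {
  set.seed(92)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    m <- matrix(stats::runif(n * 4, 0, 100), nrow = n,
                dimnames = list(paste0("S", 1:n), NULL))
    res <- cluster_subtypes(m)
    oracle <- oracle_complete_linkage(res$dist)
    expect_equal(res$hclust$height, oracle$heights)
    expect_identical(partitions_from_hclust(res$hclust, res$labels),
                     oracle$partitions)
  }
})

test_that("clustering is row-order invariant and handles degenerate inputs", {
  m <- matrix(c(0, 0, 0, 50, 50, 50, 100, 100, 100), nrow = 3, byrow = TRUE,
              dimnames = list(c("b", "a", "c"), NULL))
  r1 <- cluster_subtypes(m)
  r2 <- cluster_subtypes(m[c(3, 1, 2), ])
  expect_identical(r1$newick, r2$newick)
  expect_identical(r1$labels, sort(rownames(m)))
  # identical rows merge at height zero
  ident <- matrix(5, nrow = 3, ncol = 4,
                  dimnames = list(c("x", "y", "z"), NULL))
  expect_true(all(cluster_subtypes(ident)$hclust$height == 0))
  expect_error(cluster_subtypes(m[1, , drop = FALSE]), "two subtypes")
  expect_warning(cluster_subtypes(rbind(a = c(NA, 1), b = c(2, 3), c = c(4, 5))),
                 "imputing")
})

test_that("Tcon is the outgroup when Treg subsets share a demethylated profile", {
  cfg <- make_paper_scenario("conventional_male", clones_per_group = 10,
                             seq_error_rate = 0, model = conversion_model(1, 1))
  ds <- simulate_dataset(cfg, seed = 17)
  res <- call_clones(ds$sequences, ds$sheet, cfg$amplicons)
  avg <- average_by_population(res$matrices, "TSDR", "bottom")
  cl <- cluster_subtypes(avg)
  two <- stats::cutree(cl$hclust, k = 2)
  expect_identical(sum(two == two[["Tcon"]]), 1L)  # Tcon alone in its branch
  expect_match(cl$newick, "Tcon")
})
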