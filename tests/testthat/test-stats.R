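test_that("pairwise distances follow the JC69 correction", {
  r <- pairwise_distance(strrep("A", 100), strrep("A", 100))
  expect_equal(r$d, 0)
  expect_equal(r$sites, 100)
  expect_equal(r$diffs, 0)

  x <- paste0(strrep("A", 97), "CCC")
  y <- strrep("A", 100)
  r2 <- pairwise_distance(x, y)
  expect_equal(r2$diffs, 3)
  expect_equal(r2$d, -0.75 * log(0.96), tolerance = 1e-12)
  expect_equal(r2$d, 0.030617, tolerance = 1e-4)
  r2r <- pairwise_distance(x, y, correction = "raw")
  expect_equal(r2r$d, 0.03)

  # gaps and N are missing data, not mismatches
  r3 <- pairwise_distance("AC-GN", "ACTGA")
  expect_equal(r3$sites, 3)
  expect_equal(r3$diffs, 0)

  # zero overlap: undefined distance
  r4 <- pairwise_distance("AAAA----", "----CCCC")
  expect_true(is.na(r4$d))
  expect_equal(r4$sites, 0)

  # saturation falls back to the raw proportion with a warning
  expect_warning(
    r5 <- pairwise_distance(strrep("A", 10), strrep("C", 10)),
    "saturat")
  expect_equal(r5$d, 1)
})

test_that("JC69 dominates the raw distance for all p in (0, 0.75)", {
  for (diffs in 1:74) {
    d_jc <- pairwise_distance(
      paste0(strrep("C", diffs), strrep("A", 100 - diffs)),
      strrep("A", 100))$d
    expect_gt(d_jc, diffs / 100)
  }
})

test_that("mean pairwise frequency equals the all-pairs formula", {
  # n = 3 with distances 0.01, 0.02, 0.03: 2 * 0.06 / (3 * 2) = 0.02
  d <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  d["A", "B"] <- d["B", "A"] <- 0.01
  d["A", "C"] <- d["C", "A"] <- 0.02
  d["B", "C"] <- d["C", "B"] <- 0.03
  pr <- structure(list(d = d, sites = matrix(100, 3, 3), n = 3),
                  class = "substitution_profile")
  expect_equal(mean_pairwise_frequency(pr),
               2 * sum(0.01, 0.02, 0.03) / (3 * 2), tolerance = 1e-15)

  # n = 2 reduces to the single distance; equal distances give that value
  p2 <- fake_profile("e", 4, 100)
  expect_equal(mean_pairwise_frequency(p2), 0.04)
})

test_that("mean frequency matches a brute-force loop on random profiles", {
  set.seed(1234)
  tr <- oryza_aa_tree()
  for (rep in 1:200) {
    n_sp <- sample(3:8, 1)
    sp <- tr$tip.label[seq_len(n_sp)]
    L <- sample(20:60, 1)
    texts <- vapply(sp, function(s) {
      paste(sample(c("A", "C", "G", "T", "N", "-"), L, replace = TRUE,
                   prob = c(0.22, 0.22, 0.22, 0.22, 0.06, 0.06)),
            collapse = "")
    }, "")
    # short random sequences routinely saturate the JC69 correction; the
    # raw-proportion fallback warning is expected here
    prof <- suppressWarnings(substitution_profile("e",
                                                  encode_alignment(texts)))
    # independent oracle: explicit double loop over pairs
    acc <- c(); cnt <- 0
    for (i in seq_len(n_sp - 1)) for (j in (i + 1):n_sp) {
      pd <- suppressWarnings(pairwise_distance(texts[i], texts[j]))
      if (pd$sites > 0) { acc <- c(acc, pd$d); cnt <- cnt + 1 }
    }
    if (cnt == 0) {
      expect_true(is.na(mean_pairwise_frequency(prof)))
    } else {
      expect_equal(mean_pairwise_frequency(prof), sum(acc) / cnt,
                   tolerance = 1e-12)
    }
  }
})

test_that("the pooled baseline aggregates counts exactly", {
  p1 <- fake_profile("e1", 1, 100)
  p2 <- fake_profile("e2", 3, 100)
  bl <- compute_baseline(list(p1, p2))
  expect_equal(bl$p0, 4 / 200)
  expect_equal(bl$unweighted_mean, mean(c(0.01, 0.03)))

  single <- compute_baseline(list(p2))
  expect_equal(single$p0, 0.03)

  # identical per-pair frequencies: pooled value independent of weighting
  p3 <- fake_profile("e3", 2, 100)
  p4 <- fake_profile("e4", 10, 500)
  expect_equal(compute_baseline(list(p3, p4))$p0, 0.02)
})

test_that("the rapid-region chi-squared test matches direct evaluation", {
  prof <- fake_profile("e", 35, 1000)
  bl <- fake_baseline(0.0144)
  r <- chi_squared_rapid_test(prof, bl)
  chi2_expected <- (35 - 14.4)^2 / 14.4 + (965 - 985.6)^2 / 985.6
  expect_equal(r$chi2, chi2_expected, tolerance = 1e-12)
  expect_equal(r$chi2, 29.90, tolerance = 1e-3)
  expect_equal(r$p, stats::pchisq(chi2_expected, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(r$p, 1e-7)
  expect_true(r$is_rapid)

  # dispersion divisor shrinks the statistic
  r2 <- chi_squared_rapid_test(prof, bl, dispersion = 4)
  expect_equal(r2$chi2, chi2_expected / 4, tolerance = 1e-12)

  # at the null frequency: chi2 = 0, p = 1, not rapid
  r3 <- chi_squared_rapid_test(fake_profile("e", 18, 1250),
                               fake_baseline(18 / 1250))
  expect_equal(r3$chi2, 0)
  expect_equal(r3$p, 1)
  expect_false(r3$is_rapid)

  # direction filter: depressed frequency is never 'rapid'
  r4 <- chi_squared_rapid_test(fake_profile("e", 0, 1000),
                               fake_baseline(0.0144))
  expect_gt(r4$chi2, 0)
  expect_false(r4$is_rapid)

  # low expected count flag
  r5 <- chi_squared_rapid_test(fake_profile("e", 2, 100),
                               fake_baseline(0.01))
  expect_true(r5$low_expected)
})

test_that("chi2 grows with D on the elevated side at fixed N and p0", {
  bl <- fake_baseline(0.02)
  chis <- vapply(25:60, function(D) {
    chi_squared_rapid_test(fake_profile("e", D, 1000), bl)$chi2
  }, 0)
  expect_true(all(diff(chis) > 0))
})

test_that("per-species frequencies average the defined pairs", {
  d <- matrix(NA_real_, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  sites <- matrix(0, 4, 4, dimnames = dimnames(d))
  d["A", "B"] <- d["B", "A"] <- 0.01
  d["A", "C"] <- d["C", "A"] <- 0.03
  sites["A", "B"] <- sites["B", "A"] <- 100
  sites["A", "C"] <- sites["C", "A"] <- 100
  pr <- structure(list(element_id = "e", species = LETTERS[1:4], d = d,
                       sites = sites),
                  class = "substitution_profile")
  expect_equal(species_frequency(pr, "A"), 0.02)   # mean of defined pairs
  expect_equal(species_frequency(pr, "B"), 0.01)
  expect_true(is.na(species_frequency(pr, "D")))   # no defined pair
  expect_true(is.na(species_frequency(pr, "Z")))   # absent species
})

test_that("species-specific flags need both significance and elevation", {
  tr <- oryza_aa_tree()
  cfg <- sim_config(scale_tree(tr, 50), n_blocks = 30, block_length = 400,
                    segments = data.frame(class = "conserved", length = 400,
                                          r_c = 0.2, accel_species = NA,
                                          m = 1),
                    seed = 55)
  sim <- simulate_blocks(cfg)
  el <- data.frame(element_id = sprintf("E%02d", 1:30),
                   block_id = vapply(sim$blocks, function(b) b$block_id, ""),
                   col_start = 1, col_end = 400, stringsAsFactors = FALSE)
  pr <- element_profiles(sim$blocks, el)
  bl <- compute_baseline(pr)
  disp <- estimate_dispersion(pr, bl)
  st <- species_specific_tests(pr, bl, dispersion = disp$c_s)
  # all species evolve at the baseline rate: (almost) nothing is flagged
  expect_lt(mean(st$flagged), 0.01)

  # direction filter: enormous N with depressed frequency is not flagged
  pr1 <- fake_profile("e", 10, 100000)
  bl1 <- fake_baseline(0.02, species = c("A", "B"))
  st1 <- species_specific_test(pr1, bl1)
  expect_true(all(st1$p < 0.001))
  expect_false(any(st1$flagged))
})

test_that("group comparison pools counts and uses the 2x2 chi-squared", {
  r <- compare_pooled_counts(50, 1000, 20, 1000)
  # independent check: Pearson chi-squared on the 2x2 table by hand
  p_pool <- 70 / 2000
  chi2_hand <- (50 - 1000 * p_pool)^2 / (1000 * p_pool) +
    (950 - 1000 * (1 - p_pool))^2 / (1000 * (1 - p_pool)) +
    (20 - 1000 * p_pool)^2 / (1000 * p_pool) +
    (980 - 1000 * (1 - p_pool))^2 / (1000 * (1 - p_pool))
  expect_equal(r$chi2, chi2_hand, tolerance = 1e-9)
  expect_equal(r$chi2, 13.3235, tolerance = 1e-4)
  expect_equal(r$p, 0.000262, tolerance = 1e-3)
  expect_equal(r$freq_a, 0.05)
  expect_equal(r$freq_b, 0.02)

  same <- compare_pooled_counts(30, 1000, 30, 1000)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  expect_error(compare_pooled_counts(0, 0, 5, 100), "zero compared")
})

test_that("group frequencies are restricted to the rapid element set", {
  p1 <- fake_profile("e1", 10, 100)
  p2 <- fake_profile("e2", 30, 100)
  # only e2 in the rapid set: counts must come from e2 alone
  r <- compare_group_frequencies(list(p1, p2), "e2", "A", "B")
  expect_equal(r$D_a, 30)
  expect_equal(r$N_a, 100)
  expect_error(compare_group_frequencies(list(p1), character(0), "A", "B"),
               "empty rapid set")
  expect_error(compare_group_frequencies(list(p1), "e1", "A", "A"),
               "disjoint")
})

test_that("dispersion is near 1 for independent pairs and inflated on trees", {
  # two-species profiles: one pair only, counts are genuinely binomial
  set.seed(77)
  prs <- lapply(1:50, function(i) fake_profile(paste0("e", i),
                                               stats::rbinom(1, 400, 0.02),
                                               400))
  bl <- compute_baseline(prs)
  disp <- estimate_dispersion(prs, bl)
  expect_lt(disp$c, 1.3)

  # eight species on a tree: shared branches inflate the variance several-fold
  tr <- scale_tree(oryza_aa_tree(), 50)
  cfg <- sim_config(tr, n_blocks = 20, block_length = 300,
                    segments = data.frame(class = "conserved", length = 300,
                                          r_c = 0.2, accel_species = NA,
                                          m = 1),
                    seed = 78)
  sim <- simulate_blocks(cfg)
  el <- data.frame(element_id = sprintf("E%02d", 1:20),
                   block_id = vapply(sim$blocks, function(b) b$block_id, ""),
                   col_start = 1, col_end = 300, stringsAsFactors = FALSE)
  pr <- element_profiles(sim$blocks, el)
  bl2 <- compute_baseline(pr)
  disp2 <- estimate_dispersion(pr, bl2)
  expect_gt(disp2$c, 3)
  expect_true(all(disp2$c_s > 1.2))
})
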