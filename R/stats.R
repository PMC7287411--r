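# Per-element substitution statistics: pairwise distances, the mean
# pairwise substitution frequency, the pooled baseline, and chi-squared
# tests for rapidly evolving and species-specific rapidly evolving regions.

#' Pairwise distance between two gapped sequences
#'
#' Compared sites are the columns where both sequences carry a real base
#' (A/C/G/T; gaps and N are missing data). The distance is the JC69-corrected
#' number of substitutions per site, \code{d = -3/4 log(1 - 4p/3)} for
#' mismatch proportion \code{p}, or the raw proportion when
#' \code{correction = "raw"}. If \code{p >= 0.75} the JC69 correction is
#' saturated: the raw proportion is returned with a warning. With zero
#' compared sites the distance is undefined (\code{NA}).
#'
#' @param x,y Gapped sequences (strings, or integer code vectors from
#'   \code{\link{encode_alignment}}).
#' @param correction \code{"jc69"} (default) or \code{"raw"}.
#' @return List with \code{d}, \code{sites}, \code{diffs}.
#' @export
pairwise_distance <- function(x, y, correction = c("jc69", "raw")) {
  correction <- match.arg(correction)
  if (is.character(x)) x <- as.vector(encode_alignment(c(a = x))[1, ])
  if (is.character(y)) y <- as.vector(encode_alignment(c(a = y))[1, ])
  if (length(x) != length(y)) stop("sequences of unequal length")
  ok <- x > 0L & y > 0L
  sites <- sum(ok)
  diffs <- sum(ok & x != y)
  list(d = distance_from_counts(diffs, sites, correction),
       sites = sites, diffs = diffs)
}

distance_from_counts <- function(diffs, sites, correction) {
  if (sites == 0) return(NA_real_)
  p <- diffs / sites
  if (correction == "raw") return(p)
  if (p >= 0.75) {
    warning("mismatch proportion ", signif(p, 4),
            " saturates the JC69 correction; using the raw proportion")
    return(p)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Build substitution profiles for called elements
#'
#' For every element, computes the symmetric matrices of compared-site
#' counts, differing-site counts and distances over all species pairs in
#' the element's column span, plus the per-column pair-difference tallies
#' used for dispersion estimation.
#'
#' @param blocks List of \code{alignment_block} objects.
#' @param elements Element table from \code{\link{detect_cns}} (needs
#'   \code{element_id}, \code{block_id}, \code{col_start}, \code{col_end}).
#' @param correction Distance correction, \code{"jc69"} or \code{"raw"}.
#' @return Named list of \code{substitution_profile} objects.
#' @export
element_profiles <- function(blocks, elements,
                             correction = c("jc69", "raw")) {
  correction <- match.arg(correction)
  block_ids <- vapply(blocks, function(b) b$block_id, "")
  out <- vector("list", nrow(elements))
  codes_cache <- NULL
  cache_id <- ""
  for (r in seq_len(nrow(elements))) {
    bid <- elements$block_id[r]
    bi <- match(bid, block_ids)
    if (is.na(bi)) stop("element ", elements$element_id[r],
                        ": unknown block ", bid)
    if (cache_id != bid) {
      codes_cache <- encode_alignment(blocks[[bi]])
      cache_id <- bid
    }
    sub <- codes_cache[, elements$col_start[r]:elements$col_end[r],
                       drop = FALSE]
    out[[r]] <- substitution_profile(elements$element_id[r], sub, correction)
  }
  names(out) <- elements$element_id
  out
}

#' Substitution profile of one element
#'
#' @param element_id Element identifier.
#' @param codes Species-by-column bitmask matrix of the element's columns
#'   (from \code{\link{encode_alignment}}).
#' @param correction Distance correction.
#' @return An object of class \code{substitution_profile} with fields
#'   \code{n} (species with at least one defined pair), \code{d},
#'   \code{sites}, \code{diffs} (symmetric matrices),
#'   \code{mean_frequency}, and per-column tallies \code{col_diffs},
#'   \code{col_pairs} (plus per-species variants) used for dispersion
#'   estimation.
#' @export
substitution_profile <- function(element_id, codes,
                                 correction = c("jc69", "raw")) {
  correction <- match.arg(correction)
  sp <- rownames(codes)
  S <- nrow(codes)
  L <- ncol(codes)
  d <- matrix(NA_real_, S, S, dimnames = list(sp, sp))
  diag(d) <- 0
  sites <- matrix(0, S, S, dimnames = list(sp, sp))
  diffs <- matrix(0, S, S, dimnames = list(sp, sp))
  col_pairs <- integer(L)
  col_diffs <- integer(L)
  col_pairs_sp <- matrix(0L, S, L, dimnames = list(sp, NULL))
  col_diffs_sp <- matrix(0L, S, L, dimnames = list(sp, NULL))
  for (i in seq_len(S - 1L)) {
    vi <- codes[i, ]
    for (j in (i + 1L):S) {
      vj <- codes[j, ]
      ok <- vi > 0L & vj > 0L
      df <- ok & vi != vj
      sites[i, j] <- sites[j, i] <- sum(ok)
      diffs[i, j] <- diffs[j, i] <- sum(df)
      d[i, j] <- d[j, i] <- distance_from_counts(diffs[i, j], sites[i, j],
                                                 correction)
      col_pairs <- col_pairs + ok
      col_diffs <- col_diffs + df
      col_pairs_sp[i, ] <- col_pairs_sp[i, ] + ok
      col_pairs_sp[j, ] <- col_pairs_sp[j, ] + ok
      col_diffs_sp[i, ] <- col_diffs_sp[i, ] + df
      col_diffs_sp[j, ] <- col_diffs_sp[j, ] + df
    }
  }
  ut <- upper.tri(d)
  defined <- ut & !is.na(d) & sites > 0
  n <- sum(rowSums(defined | t(defined)) > 0)
  mean_frequency <- if (any(defined)) mean(d[defined]) else NA_real_
  structure(list(element_id = element_id, species = sp, n = n, d = d,
                 sites = sites, diffs = diffs,
                 mean_frequency = mean_frequency,
                 col_pairs = col_pairs, col_diffs = col_diffs,
                 col_pairs_sp = col_pairs_sp, col_diffs_sp = col_diffs_sp),
            class = "substitution_profile")
}

#' Mean pairwise substitution frequency of an element
#'
#' The core per-element statistic: \code{2 * sum_{i<j} d_ij / (n (n - 1))},
#' the mean of the pairwise per-site distances over all species pairs with
#' usable coverage. Pairs with zero compared sites are excluded from both
#' the sum and the pair count, so with missing pairs the value is the mean
#' over defined pairs.
#'
#' @param profile A \code{substitution_profile}.
#' @return Numeric scalar; \code{NA} if fewer than two species have a
#'   defined pair.
#' @export
mean_pairwise_frequency <- function(profile) {
  d <- profile$d
  ut <- upper.tri(d)
  defined <- ut & !is.na(d) & profile$sites > 0
  if (!any(defined)) return(NA_real_)
  mean(d[defined])
}

#' Pooled baseline substitution frequency over all elements
#'
#' The null frequency for the rapid-region tests: pooled
#' \code{p0 = sum(diffs) / sum(sites)} over all elements and defined pairs
#' (count-weighted), the unweighted mean of per-element mean frequencies
#' (for comparison), and per-species pooled baselines over pairs involving
#' each species.
#'
#' @param profiles List of \code{substitution_profile} objects.
#' @return An object of class \code{global_baseline}.
#' @export
compute_baseline <- function(profiles) {
  if (!length(profiles)) stop("no profiles")
  species <- sort(unique(unlist(lapply(profiles, function(p) p$species))))
  D <- 0; N <- 0
  D_s <- stats::setNames(numeric(length(species)), species)
  N_s <- D_s
  means <- numeric(0)
  for (p in profiles) {
    ut <- upper.tri(p$sites)
    D <- D + sum(p$diffs[ut])
    N <- N + sum(p$sites[ut])
    D_s[p$species] <- D_s[p$species] + rowSums(p$diffs)
    N_s[p$species] <- N_s[p$species] + rowSums(p$sites)
    if (!is.na(p$mean_frequency)) means <- c(means, p$mean_frequency)
  }
  if (N == 0) stop("zero compared sites across all elements")
  structure(list(p0 = D / N, D = D, N = N,
                 unweighted_mean = mean(means),
                 species = species,
                 p0_s = ifelse(N_s > 0, D_s / N_s, NA_real_),
                 D_s = D_s, N_s = N_s),
            class = "global_baseline")
}

#' Estimate the overdispersion of pooled pair-difference counts
#'
#' The chi-squared tests pool differing-site counts over species pairs, but
#' a single substitution on an internal branch changes several pairs at the
#' same column, so pooled counts are overdispersed relative to the binomial
#' assumption. This estimates the variance inflation factor (design effect)
#' from the per-column pair-difference tallies: the ratio of the empirical
#' variance of per-column totals to the binomial variance implied by the
#' baseline. Dividing the chi-squared statistic by this factor (Rao-Scott
#' first-order correction) restores approximate calibration.
#'
#' @param profiles List of \code{substitution_profile} objects.
#' @param baseline A \code{global_baseline}.
#' @return List with \code{c} (global factor, floored at 1) and \code{c_s}
#'   (named per-species factors, floored at 1).
#' @export
estimate_dispersion <- function(profiles, baseline) {
  p0 <- baseline$p0
  num <- 0; den <- 0
  species <- baseline$species
  num_s <- stats::setNames(numeric(length(species)), species)
  den_s <- num_s
  for (p in profiles) {
    num <- num + sum((p$col_diffs - p$col_pairs * p0)^2)
    den <- den + sum(p$col_pairs) * p0 * (1 - p0)
    p0s <- baseline$p0_s[p$species]
    num_s[p$species] <- num_s[p$species] +
      rowSums((p$col_diffs_sp - p$col_pairs_sp * p0s)^2)
    den_s[p$species] <- den_s[p$species] +
      rowSums(p$col_pairs_sp) * p0s * (1 - p0s)
  }
  list(c = max(1, num / den),
       c_s = stats::setNames(pmax(1, ifelse(den_s > 0, num_s / den_s, 1)),
                             species))
}

# 1-df goodness-of-fit of pooled counts (D, N) against null frequency p0,
# with optional variance-inflation (dispersion) divisor
gof_chi2 <- function(D, N, p0, dispersion = 1) {
  e1 <- p0 * N
  e0 <- (1 - p0) * N
  chi2 <- ((D - e1)^2 / e1 + ((N - D) - e0)^2 / e0) / dispersion
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       low_expected = e1 < 5)
}

#' Chi-squared test for a rapidly evolving region
#'
#' Compares an element's pooled differing/compared site counts over all
#' defined pairs against the baseline frequency \code{p0} with a 1-df
#' goodness-of-fit statistic. The element is flagged rapid when
#' \code{p < alpha} \emph{and} its pooled frequency exceeds \code{p0}
#' (one-sided by direction filter). When the expected count \code{p0*N} is
#' below 5 the result carries a low-expected-count flag (the test is still
#' computed). \code{dispersion} divides the statistic to correct for the
#' phylogenetic overdispersion of pooled pair counts (see
#' \code{\link{estimate_dispersion}}); the default 1 is the uncorrected
#' statistic.
#'
#' @param profile A \code{substitution_profile}.
#' @param baseline A \code{global_baseline}.
#' @param alpha Significance threshold (default 0.001).
#' @param dispersion Variance inflation divisor.
#' @return One-row data.frame: \code{element_id}, \code{n},
#'   \code{mean_frequency}, \code{D}, \code{N}, \code{freq}, \code{chi2},
#'   \code{p}, \code{is_rapid}, \code{low_expected}.
#' @export
chi_squared_rapid_test <- function(profile, baseline, alpha = 0.001,
                                   dispersion = 1) {
  ut <- upper.tri(profile$sites)
  D <- sum(profile$diffs[ut])
  N <- sum(profile$sites[ut])
  if (N == 0) {
    return(data.frame(element_id = profile$element_id, n = profile$n,
                      mean_frequency = NA_real_, D = 0, N = 0,
                      freq = NA_real_, chi2 = NA_real_, p = NA_real_,
                      is_rapid = FALSE, low_expected = TRUE,
                      stringsAsFactors = FALSE))
  }
  g <- gof_chi2(D, N, baseline$p0, dispersion)
  data.frame(element_id = profile$element_id, n = profile$n,
             mean_frequency = profile$mean_frequency, D = D, N = N,
             freq = D / N, chi2 = g$chi2, p = g$p,
             is_rapid = g$p < alpha && D / N > baseline$p0,
             low_expected = g$low_expected, stringsAsFactors = FALSE)
}

#' Rapid-region tests for a set of elements
#'
#' Applies \code{\link{chi_squared_rapid_test}} to every profile and adds a
#' Benjamini-Hochberg adjusted p column (informational; the rapid flag uses
#' the fixed \code{alpha} threshold on the unadjusted p).
#'
#' @inheritParams chi_squared_rapid_test
#' @param profiles List of \code{substitution_profile} objects.
#' @return data.frame with one row per element.
#' @export
rapid_region_tests <- function(profiles, baseline, alpha = 0.001,
                               dispersion = 1) {
  rows <- lapply(profiles, chi_squared_rapid_test, baseline = baseline,
                 alpha = alpha, dispersion = dispersion)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-species substitution frequency within an element
#'
#' The average of a species' pairwise distances to the other species present
#' in the element, over defined pairs.
#'
#' @param profile A \code{substitution_profile}.
#' @param species Species identifier.
#' @return Numeric scalar; \code{NA} if the species has no defined pair.
#' @export
species_frequency <- function(profile, species) {
  if (!species %in% profile$species) return(NA_real_)
  d <- profile$d[species, ]
  s <- profile$sites[species, ]
  keep <- names(d) != species & !is.na(d) & s > 0
  if (!any(keep)) return(NA_real_)
  mean(d[keep])
}

#' Species-specific rapid-evolution tests for one element
#'
#' For each species present in the element: pools its differing/compared
#' site counts over defined pairs to the other species and tests them
#' against the species' baseline frequency (1-df goodness-of-fit, direction
#' filter as in \code{\link{chi_squared_rapid_test}}). Species with
#' \code{p < alpha} and elevated frequency form the element's
#' species-specific set.
#'
#' @param profile A \code{substitution_profile}.
#' @param baseline A \code{global_baseline}.
#' @param alpha Significance threshold (default 0.001).
#' @param dispersion Scalar or named per-species vector of variance
#'   inflation divisors.
#' @param baseline_mode \code{"per_species"} (default) tests against each
#'   species' own pooled baseline; \code{"global"} tests against \code{p0}.
#' @return data.frame with one row per species with a defined pair:
#'   \code{element_id}, \code{species}, \code{f_s}, \code{D_s}, \code{N_s},
#'   \code{freq}, \code{p0_s}, \code{chi2}, \code{p}, \code{flagged},
#'   \code{low_expected}.
#' @export
species_specific_test <- function(profile, baseline, alpha = 0.001,
                                  dispersion = 1,
                                  baseline_mode = c("per_species",
                                                    "global")) {
  baseline_mode <- match.arg(baseline_mode)
  rows <- lapply(profile$species, function(s) {
    D_s <- sum(profile$diffs[s, ])
    N_s <- sum(profile$sites[s, ])
    if (N_s == 0) return(NULL)
    p0s <- if (baseline_mode == "global") baseline$p0 else
      unname(baseline$p0_s[s])
    if (is.na(p0s) || p0s <= 0 || p0s >= 1) return(NULL)
    disp <- if (length(dispersion) > 1L) {
      if (!s %in% names(dispersion)) 1 else unname(dispersion[s])
    } else dispersion
    g <- gof_chi2(D_s, N_s, p0s, disp)
    data.frame(element_id = profile$element_id, species = s,
               f_s = species_frequency(profile, s), D_s = D_s, N_s = N_s,
               freq = D_s / N_s, p0_s = p0s, chi2 = g$chi2, p = g$p,
               flagged = g$p < alpha && D_s / N_s > p0s,
               low_expected = g$low_expected, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) {
    return(data.frame(element_id = character(), species = character(),
                      f_s = numeric(), D_s = numeric(), N_s = numeric(),
                      freq = numeric(), p0_s = numeric(), chi2 = numeric(),
                      p = numeric(), flagged = logical(),
                      low_expected = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Species-specific tests for a set of elements
#'
#' @inheritParams species_specific_test
#' @param profiles List of \code{substitution_profile} objects.
#' @return data.frame with one row per element-species combination, plus a
#'   BH-adjusted p column.
#' @export
species_specific_tests <- function(profiles, baseline, alpha = 0.001,
                                   dispersion = 1,
                                   baseline_mode = c("per_species",
                                                     "global")) {
  baseline_mode <- match.arg(baseline_mode)
  rows <- lapply(profiles, species_specific_test, baseline = baseline,
                 alpha = alpha, dispersion = dispersion,
                 baseline_mode = baseline_mode)
  if (!length(rows)) {
    out <- species_specific_test(
      structure(list(species = character(),
                     element_id = character(),
                     diffs = matrix(0, 0, 0), sites = matrix(0, 0, 0)),
                class = "substitution_profile"),
      baseline)
  } else {
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  out$p_bh <- numeric(nrow(out))
  if (nrow(out)) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Compare pooled substitution frequencies between two species groups
#'
#' Pools differing/compared site counts over pairs involving any species of
#' each group, restricted to the rapid elements, and compares the two
#' pooled frequencies with a 2x2 Pearson chi-squared test (no continuity
#' correction).
#'
#' @param profiles List of \code{substitution_profile} objects.
#' @param rapid_ids Element ids of the rapid set.
#' @param group_a,group_b Disjoint, non-empty species sets.
#' @return List with \code{freq_a}, \code{freq_b}, \code{D_a}, \code{N_a},
#'   \code{D_b}, \code{N_b}, \code{chi2}, \code{p}.
#' @export
compare_group_frequencies <- function(profiles, rapid_ids, group_a,
                                      group_b) {
  if (!length(rapid_ids)) stop("empty rapid set")
  if (!length(group_a) || !length(group_b)) stop("empty species group")
  if (length(intersect(group_a, group_b))) {
    stop("species groups must be disjoint")
  }
  D_a <- N_a <- D_b <- N_b <- 0
  for (p in profiles) {
    if (!p$element_id %in% rapid_ids) next
    ut <- upper.tri(p$sites)
    ia <- p$species %in% group_a
    ib <- p$species %in% group_b
    inv_a <- ut & (outer(ia, rep(TRUE, length(ia))) |
                     outer(rep(TRUE, length(ia)), ia))
    inv_b <- ut & (outer(ib, rep(TRUE, length(ib))) |
                     outer(rep(TRUE, length(ib)), ib))
    D_a <- D_a + sum(p$diffs[inv_a]); N_a <- N_a + sum(p$sites[inv_a])
    D_b <- D_b + sum(p$diffs[inv_b]); N_b <- N_b + sum(p$sites[inv_b])
  }
  if (N_a == 0 || N_b == 0) stop("a group has zero compared sites")
  compare_pooled_counts(D_a, N_a, D_b, N_b)
}

#' 2x2 chi-squared comparison of two pooled count pairs
#'
#' @param D_a,N_a,D_b,N_b Differing and compared site counts of the two
#'   groups.
#' @return List with \code{freq_a}, \code{freq_b}, counts, \code{chi2},
#'   \code{p} (Pearson, 1 df, no continuity correction).
#' @export
compare_pooled_counts <- function(D_a, N_a, D_b, N_b) {
  if (N_a == 0 || N_b == 0) stop("a group has zero compared sites")
  tab <- matrix(c(D_a, N_a - D_a, D_b, N_b - D_b), nrow = 2)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(freq_a = D_a / N_a, freq_b = D_b / N_b,
       D_a = D_a, N_a = N_a, D_b = D_b, N_b = N_b,
       chi2 = unname(ct$statistic), p = unname(ct$p.value))
}
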