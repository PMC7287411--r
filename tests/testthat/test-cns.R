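test_that("the coding mask is the merged union of CDS intervals", {
  g1 <- gene_model("g1", "chr1", "+", exons = rbind(c(50, 300)),
                   cds = rbind(c(100, 200)))
  g2 <- gene_model("g2", "chr1", "+", exons = rbind(c(120, 260)),
                   cds = rbind(c(150, 250)))
  mask <- build_coding_mask(list(g1, g2))
  expect_equal(IRanges::start(mask$chr1) - 1, 100)
  expect_equal(IRanges::end(mask$chr1), 250)

  utr_only <- gene_model("g3", "chr2", "+", exons = rbind(c(0, 100)),
                         utr5 = rbind(c(0, 100)))
  expect_null(build_coding_mask(list(utr_only))$chr2)
  expect_length(build_coding_mask(list()), 0)
})

test_that("score_column matches the rejected-substitutions definition", {
  tr <- oryza_aa_tree()
  model <- neutral_model(tr, lambda = 1)
  col <- stats::setNames(rep("A", 8), tr$tip.label)
  sc <- score_column(col, model)
  expect_equal(sc$O, 0)
  expect_equal(sc$E, 0.057882, tolerance = 1e-12)
  expect_equal(sc$RS, 0.057882, tolerance = 1e-12)
  expect_true(sc$usable)

  # quartet with two cherries: one substitution suffices
  q <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  sq <- score_column(c(A = "A", B = "A", C = "G", D = "G"),
                     neutral_model(q, 1), min_species = 3)
  expect_equal(sq$O, 1)
  expect_equal(sq$O, brute_force_parsimony(
    encode_alignment(c(A = "A", B = "A", C = "G", D = "G")), q))

  # below min_species: unusable, RS forced to 0
  sparse <- stats::setNames(c("A", "C", rep("-", 6)), tr$tip.label)
  ssp <- score_column(sparse, model, min_species = 4)
  expect_false(ssp$usable)
  expect_identical(ssp$RS, 0)
  expect_equal(sort(ssp$present), sort(tr$tip.label[1:2]))

  expect_error(score_column(c(A = "A", Z = "C", B = "G"), model),
               "not in tree")
})

test_that("Fitch counts equal brute-force minimization on random columns", {
  set.seed(42)
  tr <- oryza_aa_tree()
  model_trees <- list(tr, read_newick("((A:1,B:2):1,(C:1,(D:1,E:1):2):1);"),
                      read_newick("(A:1,(B:1,(C:1,(D:1,(E:1,F:1):1):1):1):1);"))
  for (t in model_trees) {
    for (rep in 1:70) {
      col <- random_column(t$tip.label, p_missing = 0.25)
      codes <- encode_alignment(col)
      fc <- fitch_counts(codes, t)
      expect_equal(fc$O, brute_force_parsimony(codes, t),
                   info = paste(col, collapse = ""))
    }
  }
})

test_that("restricted tree length is monotone in the species subset", {
  set.seed(7)
  tr <- oryza_aa_tree()
  for (rep in 1:25) {
    col <- random_column(tr$tip.label, p_missing = 0.3)
    present <- names(col)[col %in% c("A", "C", "G", "T")]
    if (length(present) < 2) next
    codes <- encode_alignment(col)
    E_full <- fitch_counts(codes, tr)$restricted_length
    drop <- sample(present, 1)
    col2 <- col
    col2[drop] <- "-"
    E_less <- fitch_counts(encode_alignment(col2), tr)$restricted_length
    expect_lte(E_less, E_full + 1e-12)
  }
})

test_that("adding a species with the consensus base never increases O", {
  set.seed(8)
  tr <- oryza_aa_tree()
  for (rep in 1:25) {
    col <- random_column(tr$tip.label, p_missing = 0.4)
    present <- names(col)[col %in% c("A", "C", "G", "T")]
    absent <- setdiff(names(col), present)
    if (!length(absent) || !length(present)) next
    O1 <- fitch_counts(encode_alignment(col), tr)$O
    col2 <- col
    # most frequent present base
    col2[absent[1]] <- names(sort(table(col[present]), decreasing = TRUE))[1]
    O2 <- fitch_counts(encode_alignment(col2), tr)$O
    expect_lte(O2, O1)
  }
})

test_that("the neutral scale is recovered on neutral data and scales inversely", {
  tr <- oryza_aa_tree()
  cfg <- sim_config(tr, n_blocks = 1, block_length = 1e5,
                    segments = data.frame(class = "neutral", length = 1e5,
                                          r_c = 1, accel_species = NA, m = 1),
                    seed = 33)
  sim <- simulate_blocks(cfg)
  lam <- estimate_neutral_scale(sim$blocks, tr, "Osativa")
  expect_gt(lam, 0.8)
  expect_lt(lam, 1.2)
  # doubling every branch length halves lambda on the same data
  lam2 <- estimate_neutral_scale(sim$blocks, scale_tree(tr, 2), "Osativa")
  expect_equal(lam2, lam / 2, tolerance = 1e-12)
})

test_that("degenerate inputs to neutral-scale estimation raise errors", {
  tr <- oryza_aa_tree()
  txt <- strrep("A", 2000)
  rows <- data.frame(species = tr$tip.label, chrom = "chr1", start = 0,
                     size = 2000, strand = "+", src_size = 5000, text = txt,
                     stringsAsFactors = FALSE)
  invariant <- alignment_block("inv", rows)
  expect_error(estimate_neutral_scale(list(invariant), tr, "Osativa"),
               "positive")
  short <- alignment_block("short", transform(rows, size = 50,
                                              text = strrep("A", 50)))
  expect_error(estimate_neutral_scale(list(short), tr, "Osativa"),
               "too few")
})

test_that("element calling follows the gap-tolerant run rule", {
  block <- toy_block(strrep("A", 40), strrep("A", 40))
  mk_scores <- function(rs) {
    data.frame(col = seq_along(rs), ref_pos = seq_along(rs) - 1,
               n_present = 8, O = 0, E = 0.5, RS = rs, masked = FALSE,
               usable = TRUE)
  }
  # 12 consecutive positive columns -> one element of length 12
  rs <- c(rep(0, 5), rep(0.05, 12), rep(0, 23))
  el <- call_elements(mk_scores(rs), block, "ref", min_element_length = 10,
                      max_gap_run = 3)
  expect_equal(nrow(el), 1)
  expect_equal(el$end - el$start, 12)
  expect_equal(el$sum_rs, 0.6, tolerance = 1e-12)

  # two 12-column runs separated by 5 non-positive columns: two elements
  rs2 <- c(rep(0.05, 12), rep(0, 5), rep(0.05, 12), rep(0, 11))
  el2 <- call_elements(mk_scores(rs2), block, "ref", min_element_length = 10,
                       max_gap_run = 3)
  expect_equal(nrow(el2), 2)
  oracle <- brute_force_segments(rs2 > 0, max_gap = 3)
  expect_equal(nrow(oracle), 2)
  expect_equal(el2$col_start, oracle[, 1])
  expect_equal(el2$col_end, oracle[, 2])

  # the same two runs separated by only 3 bad columns are bridged
  rs3 <- c(rep(0.05, 12), rep(0, 3), rep(0.05, 12), rep(0, 13))
  el3 <- call_elements(mk_scores(rs3), block, "ref", min_element_length = 10,
                       max_gap_run = 3)
  expect_equal(nrow(el3), 1)
  expect_equal(el3$col_start, 1)
  expect_equal(el3$col_end, 27)

  # a 6-base run is below the minimum element length
  rs4 <- c(rep(0.05, 6), rep(0, 34))
  expect_equal(nrow(call_elements(mk_scores(rs4), block, "ref",
                                  min_element_length = 10, max_gap_run = 3)),
               0)
})

test_that("random score vectors segment exactly like the exhaustive oracle", {
  set.seed(99)
  block <- toy_block(strrep("A", 60), strrep("A", 60))
  for (rep in 1:40) {
    rs <- ifelse(stats::runif(60) < 0.5, 0.05, 0)
    gap <- sample(0:3, 1)
    scores <- data.frame(col = 1:60, ref_pos = 0:59, n_present = 8, O = 0,
                         E = 0.5, RS = rs, masked = FALSE, usable = TRUE)
    el <- call_elements(scores, block, "ref", min_element_length = 1,
                        max_gap_run = gap)
    oracle <- brute_force_segments(rs > 0, max_gap = gap)
    expect_equal(el$col_start, oracle[, 1])
    expect_equal(el$col_end, oracle[, 2])
  }
})

test_that("element coordinates skip reference gap columns", {
  # reference has gaps inside the scored run; coordinates must span only
  # real reference bases
  ref <- "AA--AAAAAAAAAAA"
  oth <- "AAAAAAAAAAAAAAA"
  block <- toy_block(ref, oth, start = 100)
  pos <- rep(NA_real_, 15)
  pos[c(1:2, 5:15)] <- 100 + 0:12
  scores <- data.frame(col = 1:15, ref_pos = pos, n_present = 8, O = 0,
                       E = 0.5, RS = 0.05, masked = FALSE, usable = TRUE)
  el <- call_elements(scores, block, "ref", min_element_length = 10,
                      max_gap_run = 0)
  expect_equal(el$start, 100)
  expect_equal(el$end, 113)
})

test_that("called elements never use coding-masked columns", {
  fx_dir <- file.path(tempdir(), "fx_mask")
  fx <- make_fixture_suite(fx_dir, seed = 6, n_blocks = 10)
  blocks <- read_maf(fx$maf)
  tree <- read_newick(fx$tree)
  genes <- read_gff3(fx$gff3)
  det <- detect_cns(blocks, tree, "Osativa", gene_models = genes,
                    min_element_length = 30, max_gap_run = 2,
                    keep_scores = TRUE)
  expect_gt(nrow(det$elements), 0)
  for (r in seq_len(nrow(det$elements))) {
    sc <- det$scores[[det$elements$block_id[r]]]
    span <- det$elements$col_start[r]:det$elements$col_end[r]
    expect_false(any(sc$usable[span] & sc$masked[span]))
  }
  # CDS runs are longer than the gap tolerance, so whole elements stay
  # outside the mask
  mask <- build_coding_mask(genes)
  el_ir <- IRanges::IRanges(det$elements$start + 1, det$elements$end)
  expect_equal(sum(IRanges::overlapsAny(el_ir, mask$chr1)), 0)
})

test_that("conserved segments are recovered on a small fixture", {
  fx <- make_fixture_suite(file.path(tempdir(), "fx_rec"), seed = 13,
                           n_blocks = 20)
  blocks <- read_maf(fx$maf)
  tree <- read_newick(fx$tree)
  genes <- read_gff3(fx$gff3)
  det <- detect_cns(blocks, tree, "Osativa", gene_models = genes,
                    min_element_length = 30, max_gap_run = 2)
  ts <- fx$truth$segments
  cons <- ts[ts$class != "neutral", ]
  neut <- ts[ts$class == "neutral", ]
  expect_gt(interval_coverage(det$elements, cons), 0.8)
  expect_lt(interval_coverage(det$elements, neut), 0.05)
})
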