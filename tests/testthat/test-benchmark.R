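test_that("true-positive regions are centred with deterministic width", {
  sites <- genomic_intervals("chr1", c(90L, 300L), c(111L, 301L),
                             name = c("t1", "t2"))
  tp <- make_true_positive_regions(sites, width = 50L)
  expect_equal(nrow(tp), 2L)
  expect_equal(tp$start[1], 75L)   # centre 100 -> [75, 125)
  expect_equal(tp$end[1], 125L)
  expect_equal(tp$end - tp$start, c(50L, 50L))
  expect_equal(tp$anchor, c("t1", "t2"))
  # site near the chromosome edge is skipped with a warning
  expect_warning(
    tp2 <- make_true_positive_regions(
      genomic_intervals("chr1", c(5L, 300L), c(6L, 301L)), width = 50L),
    "skipped")
  expect_equal(nrow(tp2), 1L)
})

test_that("true-negative sampling honours count, distance and window", {
  tp <- data.frame(tf_name = "T", chrom = "chr1", start = 975L,
                   end = 1025L, label = "true_positive", anchor = "t1",
                   stringsAsFactors = FALSE)
  tn <- sample_true_negatives(tp, c(0L, 3000L), seed = 42L)
  expect_equal(nrow(tn), 50L)
  centers <- tn$start + 25L
  expect_true(all(abs(centers - 1000L) >= 25L))
  expect_true(all(abs(centers - 1000L) <= 1000L))
  # no TN overlaps the TP region
  expect_true(all(tn$start >= tp$end | tn$end <= tp$start |
                    abs(centers - 1000L) >= 50L))
  expect_true(all(!(tn$start < tp$end & tn$end > tp$start)))
  # reproducible under the seed; without replacement
  tn2 <- sample_true_negatives(tp, c(0L, 3000L), seed = 42L)
  expect_identical(tn, tn2)
  expect_equal(anyDuplicated(tn$start), 0L)
})

test_that("feasible-count enumeration matches constrained sampling", {
  # narrow promoter: count the feasible centres by brute force
  tp <- data.frame(tf_name = "T", chrom = "chr1", start = 75L,
                   end = 125L, label = "true_positive", anchor = "t1",
                   stringsAsFactors = FALSE)
  bounds <- c(50L, 260L)
  brute <- sum(vapply((100L - 1000L):(100L + 1000L), function(ctr) {
    s <- ctr - 25L; e <- s + 50L
    abs(ctr - 100L) >= 25L && s >= bounds[1] && e <= bounds[2] &&
      !(s < tp$end && e > tp$start)
  }, TRUE))
  expect_equal(count_feasible_negatives(tp, bounds), brute)
  expect_error(sample_true_negatives(tp, bounds, n = brute + 1L),
               as.character(brute))
  tn <- sample_true_negatives(tp, bounds, n = brute, seed = 1L)
  expect_equal(nrow(tn), brute)
})

test_that("TN sampling never violates constraints over random instances", {
  set.seed(99)
  for (i in 1:20) {
    width <- sample(20:60, 1)
    tss <- sample(2000:4000, 1)
    tp_start <- tss - sample(100:900, 1)
    tp <- data.frame(tf_name = "T", chrom = "chr1", start = tp_start,
                     end = tp_start + width, label = "true_positive",
                     anchor = "t", stringsAsFactors = FALSE)
    bounds <- c(tss - 1500L, tss + 500L)
    n <- 25L
    tn <- sample_true_negatives(tp, bounds, n = n, window = 2000L,
                                min_dist = 25L, seed = i)
    ctr_tp <- tp_start + width %/% 2L
    ctr <- tn$start + width %/% 2L
    expect_true(all(abs(ctr - ctr_tp) >= 25L))
    expect_true(all(abs(ctr - ctr_tp) <= 1000L))
    expect_true(all(tn$start >= bounds[1] & tn$end <= bounds[2]))
    expect_true(all(!(tn$start < tp$end & tn$end > tp$start)))
  }
})

test_that("rank-based AUROC equals all-pairs counting", {
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(5, 6), c(1, 2)), 1.0)
  expect_equal(roc_auc(c(-Inf, 5), c(1, 2)), 0.5)
  expect_error(roc_auc(numeric(), 1), "non-empty")
  set.seed(12)
  for (i in 1:25) {
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    a <- sample(0:10, n1, replace = TRUE) / 2
    b <- sample(0:10, n2, replace = TRUE) / 2
    pairs <- outer(a, b, function(x, y)
      (x > y) + 0.5 * (x == y))
    expect_equal(roc_auc(a, b), sum(pairs) / (n1 * n2))
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  a <- rnorm(40, 1); b <- rnorm(60)
  ref <- suppressMessages(pROC::auc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(a, b),
    direction = "<"))
  expect_equal(roc_auc(a, b), as.numeric(ref))
})

test_that("feature-combination enumeration is complete and PWM-anchored", {
  combos <- enumerate_combinations()
  expect_length(combos, 128L)
  expect_true(all(vapply(combos, function(cc) "pwm" %in% cc, TRUE)))
  keys <- vapply(combos, paste, "", collapse = "+")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true("pwm" %in% keys)   # the singleton is present
  expect_identical(combos, enumerate_combinations())  # deterministic
})

test_that("best-score reduction and combination evaluation behave", {
  expect_equal(best_score_per_region(c(1.2, 3.4, -0.5)), 3.4)
  expect_identical(best_score_per_region(numeric()), -Inf)

  # two-TF fixture where only the PWM component is informative
  set.seed(41)
  mk <- function(tf, label, n, pwm_shift) {
    do.call(rbind, lapply(seq_len(n), function(i) data.frame(
      site = paste(tf, label, i), tf_name = tf, label = label,
      pwm = rnorm(3) + pwm_shift, cage = 0, correlation = 0,
      metaclusters = 0, atac = 0, eqtl = 0, cpg = 0,
      conservation = 0, stringsAsFactors = FALSE)))
  }
  cs <- rbind(mk("A", "true_positive", 8, 3), mk("A", "true_negative", 8, 0),
              mk("B", "true_positive", 8, 3), mk("B", "true_negative", 8, 0))
  cs$site <- match(cs$site, unique(cs$site))
  ev <- evaluate_combinations(cs)
  expect_equal(nrow(ev$table), 128L * 2L)
  # AUROC is invariant to feature order within a combination
  k1 <- ev$table$auroc[ev$table$combination == "pwm+cage+cpg" &
                         ev$table$tf_name == "A"]
  manual <- {
    sc <- cs$pwm + cs$cage + cs$cpg
    best <- tapply(sc, cs$site, max)
    lab <- cs$label[!duplicated(cs$site)][order(unique(cs$site))]
    tfv <- cs$tf_name[!duplicated(cs$site)][order(unique(cs$site))]
    roc_auc(best[lab == "true_positive" & tfv == "A"],
            best[lab == "true_negative" & tfv == "A"])
  }
  expect_equal(k1, unname(manual))
  # best-by-TF dominates best-overall per TF
  for (tf in c("A", "B")) {
    bo <- ev$table$auroc[ev$table$combination ==
                           ev$best_overall$combination &
                           ev$table$tf_name == tf]
    bt <- ev$best_by_tf$auroc[ev$best_by_tf$tf_name == tf]
    expect_gte(bt, bo)
  }
  # only PWM informative: every combination ties, and the smallest-set
  # tie-break selects the {pwm} singleton as best overall
  pwm_mean <- ev$mean_auroc$auroc[ev$mean_auroc$combination == "pwm"]
  expect_equal(ev$best_overall$auroc, pwm_mean, tolerance = 1e-9)
  expect_equal(ev$best_overall$combination, "pwm")
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  a <- c(0.91, 0.85, 0.88, 0.95, 0.80)
  b <- c(0.88, 0.80, 0.86, 0.90, 0.84)
  got <- paired_t_test(a, b)
  d <- a - b
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(length(d))))
  expect_equal(got$p, 2 * pt(-abs(got$t), length(d) - 1))
  # antisymmetry
  swap <- paired_t_test(b, a)
  expect_equal(swap$t, -got$t)
  expect_equal(swap$p, got$p)
  # degenerate cases report p = 1 with a flag
  expect_true(paired_t_test(c(.5, .5), c(.5, .5))$degenerate)
  expect_equal(paired_t_test(c(.6, .6, .6), c(.5, .5, .5))$p, 1)
  expect_error(paired_t_test(1, c(1, 2)), "equal length")
})

test_that("ChIP-Seq benchmark applies thresholds and offset matching", {
  spec <- fixture_spec(seed = 2, genome_length = 80000,
                       n_transcripts = 10)
  g <- generate_genome(spec)
  set.seed(1)
  st <- seq(1000L, 60000L, by = 500L)
  peaks <- genomic_intervals("chr1", st, st + 120L,
                             value = runif(length(st)))
  # below min_peaks: excluded entirely
  expect_equal(nrow(build_chipseq_benchmark(
    list(TFY = peaks[1:99, ]), g$transcripts, seed = 3L)), 0L)
  b <- build_chipseq_benchmark(list(TFX = peaks), g$transcripts,
                               top_k = 80L, min_peaks = 100L,
                               chrom_lengths = g$lengths, seed = 3L)
  expect_equal(sum(b$label == "true_positive"), 80L)   # top_k cap
  expect_equal(sum(b$label == "true_negative"), 80L)
  expect_true(all(b$end - b$start == 200L))
  # TN offset from its TSS equals the TP offset exactly
  tp <- b[b$label == "true_positive", ]
  tn <- b[b$label == "true_negative", ]
  tss_of <- function(id) g$transcripts$tss[match(id,
                                                 g$transcripts$transcript_id)]
  expect_equal(tp$start - tss_of(tp$anchor), tp$tss_offset)
  expect_equal(tn$start - tss_of(tn$anchor), tn$tss_offset)
  # TN transcripts never carry a peak-matched transcript id
  expect_false(any(tn$anchor %in% tp$anchor))
  # seeded reproducibility
  b2 <- build_chipseq_benchmark(list(TFX = peaks), g$transcripts,
                                top_k = 80L, min_peaks = 100L,
                                chrom_lengths = g$lengths, seed = 3L)
  expect_identical(b, b2)
})
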