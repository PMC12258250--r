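test_that("combined affinity is an exact sum over the active feature set", {
  comp <- c(pwm = 1.5, cage = 0.5, cpg = 1.0, conservation = 2.0,
            atac = 9.9)
  expect_equal(combine_scores(comp, "non_human"), 5.0)   # ATAC ignored
  expect_equal(combine_scores(comp, "human"), 14.9)
  expect_equal(combine_scores(c(pwm = 0, cage = 0), "human"), 0)
  expect_error(combine_scores(c(pwm = 1, bogus = 2), "human"), "unknown")
  expect_error(species_mode("custom", c("cage")), "pwm")

  # randomized additivity: dropping a feature changes the sum by exactly
  # that feature's component
  set.seed(55)
  feats <- c("pwm", "cage", "correlation", "metaclusters", "atac",
             "eqtl", "cpg", "conservation")
  for (i in 1:20) {
    comp <- setNames(runif(8, 0, 10), feats)
    full <- combine_scores(comp, "human")
    expect_equal(full, sum(comp))
    drop <- sample(feats[-1], 1)
    reduced <- combine_scores(comp, species_mode("custom",
                                                 setdiff(feats, drop)))
    expect_equal(full - reduced, unname(comp[drop]))
    nh <- combine_scores(comp, "non_human")
    expect_equal(nh, sum(comp[c("pwm", "cage", "cpg", "conservation")]))
  }
})

test_that("empirical p-values follow (r+1)/(n+1) and rank logic", {
  bgv <- c(5, 1, 3, 2, 4)                      # n = 5
  expect_equal(empirical_pvalue(10, bgv), 1 / 6)   # above all
  expect_equal(empirical_pvalue(0, bgv), 1)        # below all
  expect_equal(empirical_pvalue(3, bgv), 4 / 6)    # r = 3 (scores >= 3)
  # median of odd n: r = (n+1)/2, p = ((n+1)/2 + 1)/(n+1)
  expect_equal(empirical_pvalue(3, bgv), ((5 + 1) / 2 + 1) / 6)
  # monotone non-increasing
  pv <- empirical_pvalue(seq(0, 6, by = 0.5), bgv)
  expect_true(all(diff(pv) <= 0))
  expect_error(empirical_pvalue(1, numeric()), "empty")
})

test_that("background distribution is order-invariant and seeded-deterministic", {
  set.seed(10)
  proms <- replicate(12, random_dna(120), simplify = FALSE)
  pfms <- list(default_test_pfm())
  bg1 <- background_score_distribution(unlist(proms), pfms)
  bg2 <- background_score_distribution(unlist(rev(proms)), pfms)
  expect_equal(bg1$per_tf$TF1$scores, bg2$per_tf$TF1$scores)
  expect_equal(sort(bg1$per_tf$TF1$top_scores),
               sort(bg2$per_tf$TF1$top_scores))
  # one promoter at threshold 1: sample size equals its hit count
  one <- background_score_distribution(proms[[1]], pfms)
  hits <- scan_sequence(build_pwm(pfms[[1]]), proms[[1]],
                        pvalue_threshold = 1)
  expect_equal(length(one$per_tf$TF1$scores), nrow(hits))
})

test_that("promoter analysis finds the implanted site first", {
  spec <- fixture_spec(seed = 3, genome_length = 30000, n_transcripts = 6)
  genome <- generate_genome(spec)
  tx <- genome$transcripts
  genome <- implant_motifs(genome, positions = tx$tss - 300L,
                           instances = "consensus")
  tr <- generate_tracks(genome)
  res <- analyze_promoter(tx[2, ], genome$sequences, tr$tracks,
                          list(spec$pfm), pval = 0.05)
  expect_s3_class(res, "tfbs_hits")
  expect_gt(nrow(res), 0)
  # implant begins 300 bp upstream of the TSS
  expect_equal(res$tss_start[1], -300L)
  expect_equal(res$start[1], tx$tss[2] - 300L)
  # sorted by combined affinity, descending
  expect_true(all(diff(res$combined_affinity) <= 0))
  # combined score equals the row-wise sum of its feature columns
  feats <- intersect(attr(res, "features"), names(res))
  expect_equal(res$combined_affinity,
               rowSums(as.data.frame(res)[, feats]))
  # defaults: 1,000 bp window (-900..+100)
  w <- attr(res, "window")
  expect_equal(unname(w["end"] - w["start"]), 1000L)
  expect_equal(unname(w["tss"] - w["start"]), 900L)
  # empty PFM list -> empty result
  expect_equal(nrow(analyze_promoter(tx[2, ], genome$sequences,
                                     tr$tracks, list())), 0L)
  # window outside the chromosome errors
  expect_error(analyze_promoter(
    data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
               tss = 100L, strand = "+"),
    genome$sequences, tr$tracks, list(spec$pfm)), "outside")
})

test_that("negative window values are honoured by signed arithmetic", {
  spec <- fixture_spec(seed = 3, genome_length = 30000, n_transcripts = 6)
  genome <- generate_genome(spec)
  tx <- genome$transcripts
  res <- analyze_promoter(tx[3, ], genome$sequences, NULL,
                          list(spec$pfm), before_tss = -100L,
                          after_tss = 300L, pval = 1)
  w <- attr(res, "window")
  expect_equal(unname(w["start"]), tx$tss[3] + 100L)
  expect_equal(unname(w["end"] - w["start"]), 200L)
  expect_error(analyze_promoter(tx[3, ], genome$sequences, NULL,
                                list(spec$pfm), before_tss = -300L,
                                after_tss = 100L), "empty")
})

test_that("reverse-complemented promoters yield mirrored results", {
  spec <- fixture_spec(seed = 17, genome_length = 30000,
                       n_transcripts = 4)
  genome <- generate_genome(spec)
  tx <- genome$transcripts
  genome <- implant_motifs(genome, positions = tx$tss - 250L,
                           instances = "consensus")
  seq <- genome$sequences[[1]]
  n <- nchar(seq)
  # mirror the genome; a + strand transcript becomes - strand
  mirrored <- c(chr1 = revcomp(seq))
  tx_m <- tx
  tx_m$strand <- "-"
  tx_m$tss <- n - 1L - tx$tss
  r1 <- analyze_promoter(tx[1, ], genome$sequences, NULL,
                         list(spec$pfm), pval = 1,
                         mode = species_mode("custom", "pwm"))
  r2 <- analyze_promoter(tx_m[1, ], mirrored, NULL, list(spec$pfm),
                         pval = 1, mode = species_mode("custom", "pwm"))
  expect_equal(nrow(r1), nrow(r2))
  k1 <- r1[order(r1$tss_start, r1$strand), ]
  k2 <- r2[order(r2$tss_start, r2$strand), ]
  expect_equal(k1$tss_start, k2$tss_start)
  expect_equal(sort(k1$combined_affinity), sort(k2$combined_affinity))
  # strands flip
  m1 <- k1[k1$strand == "+", c("tss_start", "pwm")]
  m2 <- k2[k2$strand == "-", c("tss_start", "pwm")]
  expect_equal(m1$tss_start, m2$tss_start)
  expect_equal(m1$pwm, m2$pwm)
})

test_that("leave-one-out null p-values are uniform for continuous scores", {
  set.seed(6)
  proms <- replicate(10, random_dna(200), simplify = FALSE)
  bg <- background_score_distribution(unlist(proms),
                                      list(default_test_pfm()))
  # continuous, tie-free top scores: leave-one-out ranks are exactly
  # the uniform grid, so the KS statistic is at the 1/n resolution
  bg$per_tf$TF1$top_scores <- rnorm(200)
  cal <- null_calibration(bg)
  expect_equal(cal$n, 200L)
  expect_lt(cal$ks, 0.05)
  pv <- vapply(seq_len(200), function(i)
    empirical_pvalue(bg$per_tf$TF1$top_scores[i],
                     bg$per_tf$TF1$top_scores[-i]), 0)
  expect_setequal(round(sort(pv) * 200, 9), 1:200)
})
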