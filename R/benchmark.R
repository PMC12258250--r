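#' Fixed-width true-positive regions around verified sites
#'
#' Builds regions of `width` nt centred on each experimentally verified
#' binding site (the centre of an even-width site rounds down). Sites
#' whose widened region would leave the chromosome are skipped with a
#' warning.
#'
#' @param sites [genomic_intervals()] of verified sites; an optional
#'   `name` column carries the anchor transcript id.
#' @param width region width in nt, default 50 (wide enough to hold the
#'   longest catalogued motif, 21 positions, with slack).
#' @param chrom_lengths optional named vector of chromosome lengths used
#'   for the bounds check.
#' @param tf_name TF the sites belong to.
#' @return data frame of benchmark sites: `tf_name`, `chrom`, `start`,
#'   `end`, `label` (`"true_positive"`), `anchor` (site name or `NA`).
#' @export
make_true_positive_regions <- function(sites, width = 50L,
                                       chrom_lengths = NULL,
                                       tf_name = "TF") {
  if (!nrow(sites)) stop("no verified sites supplied")
  center <- (sites$start + sites$end - 1L) %/% 2L
  start <- center - width %/% 2L
  end <- start + as.integer(width)
  keep <- start >= 0L
  if (!is.null(chrom_lengths))
    keep <- keep & end <= chrom_lengths[sites$chrom]
  if (any(!keep))
    warning(sum(!keep), " site(s) outside chromosome bounds skipped")
  data.frame(tf_name = tf_name, chrom = sites$chrom[keep],
             start = start[keep], end = end[keep],
             label = "true_positive",
             anchor = if (!is.null(sites$name)) sites$name[keep]
                      else NA_character_,
             stringsAsFactors = FALSE)
}

#' Sample matched true-negative regions for one true positive
#'
#' Draws `n` regions of the TP's width whose centres are uniform over
#' the feasible positions: within a `window` bp window centred on the TP
#' centre, at least `min_dist` bp from the TP centre, inside the
#' promoter bounds, and (by default) not overlapping any TP region of
#' the same TF. Sampling is without replacement and reproducible under
#' `seed`.
#'
#' @param tp one-row data frame from [make_true_positive_regions()].
#' @param promoter_bounds numeric `(start, end)` of the promoter the TP
#'   belongs to (genome coordinates, 0-based half-open).
#' @param n number of true negatives, default 50.
#' @param window total window width centred on the TP centre, default
#'   2000 (i.e. up to 1000 bp up- and downstream).
#' @param min_dist minimum centre-to-centre distance from the TP,
#'   default 25.
#' @param all_tp optional data frame of all TP regions of the same TF;
#'   TN regions overlapping any of them are excluded (TNs may overlap
#'   each other).
#' @param seed optional integer seed.
#' @return data frame of `n` benchmark sites labelled
#'   `"true_negative"`.
#' @export
sample_true_negatives <- function(tp, promoter_bounds, n = 50L,
                                  window = 2000L, min_dist = 25L,
                                  all_tp = NULL, seed = NULL) {
  width <- tp$end - tp$start
  tp_center <- tp$start + width %/% 2L
  half <- window %/% 2L
  centers <- (tp_center - half):(tp_center + half)
  starts <- centers - width %/% 2L
  ends <- starts + width
  ok <- abs(centers - tp_center) >= min_dist &
    starts >= promoter_bounds[1] & ends <= promoter_bounds[2]
  if (is.null(all_tp)) all_tp <- tp
  for (i in seq_len(nrow(all_tp)))
    ok <- ok & !(all_tp$chrom[i] == tp$chrom &
                   starts < all_tp$end[i] & ends > all_tp$start[i])
  feasible <- which(ok)
  if (length(feasible) < n)
    stop("only ", length(feasible),
         " feasible true-negative positions (need ", n, ")")
  if (!is.null(seed)) set.seed(seed)
  pick <- sample(feasible, n)
  data.frame(tf_name = tp$tf_name, chrom = tp$chrom,
             start = starts[pick], end = ends[pick],
             label = "true_negative", anchor = tp$anchor,
             stringsAsFactors = FALSE)
}

#' Count feasible true-negative centres for one true positive
#'
#' The enumeration behind [sample_true_negatives()], exposed so callers
#' can check feasibility up front.
#'
#' @inheritParams sample_true_negatives
#' @return integer count of feasible centres.
#' @export
count_feasible_negatives <- function(tp, promoter_bounds, window = 2000L,
                                     min_dist = 25L, all_tp = NULL) {
  width <- tp$end - tp$start
  tp_center <- tp$start + width %/% 2L
  half <- window %/% 2L
  centers <- (tp_center - half):(tp_center + half)
  starts <- centers - width %/% 2L
  ends <- starts + width
  ok <- abs(centers - tp_center) >= min_dist &
    starts >= promoter_bounds[1] & ends <= promoter_bounds[2]
  if (is.null(all_tp)) all_tp <- tp
  for (i in seq_len(nrow(all_tp)))
    ok <- ok & !(all_tp$chrom[i] == tp$chrom &
                   starts < all_tp$end[i] & ends > all_tp$start[i])
  sum(ok)
}

#' Representative score of a benchmark region
#'
#' The top prediction score among all hits in the region; a region with
#' no scorable window receives `-Inf`, which ranks below every finite
#' score.
#'
#' @param scores numeric vector of hit scores in the region (possibly
#'   empty).
#' @return scalar score.
#' @export
best_score_per_region <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) -Inf else max(scores)
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed from ranks (ties counted 0.5),
#' identical to the normalised Mann-Whitney statistic and to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param tp_scores,tn_scores numeric score vectors for the positive and
#'   negative class (non-empty; `-Inf` sentinels allowed).
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(tp_scores, tn_scores) {
  if (!length(tp_scores) || !length(tn_scores))
    stop("both score classes must be non-empty")
  n1 <- length(tp_scores)
  n2 <- length(tn_scores)
  r <- rank(c(tp_scores, tn_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' All feature combinations containing PWM
#'
#' Enumerates every subset of the eight transcription-relevant features
#' that contains PWM: 2^7 = 128 combinations, deterministic order
#' (by size, then lexicographic within size).
#'
#' @return list of character vectors, each beginning with `"pwm"`.
#' @export
enumerate_combinations <- function() {
  others <- setdiff(FEATURES_HUMAN, "pwm")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
  combos <- apply(grid, 1L, function(row) c("pwm", others[as.logical(row)]))
  combos <- unname(as.list(combos))
  sizes <- lengths(combos)
  keys <- vapply(combos, paste, "", collapse = "+")
  combos[order(sizes, keys)]
}

#' Score all benchmark regions with every PFM window
#'
#' Scans each region at PWM p-value threshold 1 (no filtering) with the
#' region TF's motif and computes the eight feature components for every
#' window, so that feature combinations can be re-assembled without
#' rescanning.
#'
#' @param sites data frame of benchmark sites (TPs and TNs) with columns
#'   `tf_name`, `chrom`, `start`, `end`, `label` and optionally `anchor`
#'   (transcript id used to resolve the target gene).
#' @param sequences named character vector of chromosome sequences.
#' @param tracks a [feature_tracks()] bundle (may be `NULL`).
#' @param pfms list of [pfm_record()]s covering the site TFs.
#' @param transcripts optional transcript table mapping `anchor` ids to
#'   `gene_id`.
#' @param background a [background_model()].
#' @param pseudocount PWM pseudocount.
#' @return data frame with one row per hit: `site` (row index into
#'   `sites`), `tf_name`, `label`, and the eight feature columns.
#' @export
score_benchmark_sites <- function(sites, sequences, tracks, pfms,
                                  transcripts = NULL,
                                  background = background_model(),
                                  pseudocount = 0.8) {
  pfm_names <- vapply(pfms, `[[`, "", "tf_name")
  pwms <- list()
  dists <- list()
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tf <- sites$tf_name[i]
    if (!tf %in% pfm_names) stop("no PFM for TF '", tf, "'")
    if (is.null(pwms[[tf]])) {
      pwms[[tf]] <- build_pwm(pfms[[match(tf, pfm_names)]], background,
                              pseudocount)
      dists[[tf]] <- pwm_score_distribution(pwms[[tf]])
    }
    chrom <- sites$chrom[i]
    seqi <- substring(sequences[[chrom]], sites$start[i] + 1L,
                      sites$end[i])
    hits <- scan_sequence(pwms[[tf]], seqi, pvalue_threshold = 1,
                          distribution = dists[[tf]])
    if (!nrow(hits)) next
    gene_id <- NA_character_
    if (!is.null(transcripts) && !is.null(sites$anchor) &&
        !is.na(sites$anchor[i])) {
      m <- match(sites$anchor[i], transcripts$transcript_id)
      if (!is.na(m)) gene_id <- transcripts$gene_id[m]
    }
    comp <- if (!is.null(tracks))
      score_hit_features(hits, tracks, chrom = chrom,
                         offset = sites$start[i], gene_id = gene_id,
                         chrom_sequence = sequences[[chrom]],
                         window_start = sites$start[i],
                         window_end = sites$end[i])
    else {
      z <- numeric(nrow(hits))
      data.frame(pwm = hits$pwm_score, cage = z, correlation = z,
                 metaclusters = z, atac = z, eqtl = z, cpg = z,
                 conservation = z)
    }
    out[[i]] <- cbind(data.frame(site = i, tf_name = tf,
                                 label = sites$label[i],
                                 stringsAsFactors = FALSE), comp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate every feature combination over a benchmark
#'
#' For each of the 128 feature combinations, each region's score is the
#' maximum over its windows of the sum of the combination's components;
#' per TF, TP and TN region scores yield a rank-based AUROC. Also
#' reports the combination with the best mean AUROC across TFs
#' (`best_overall`, ties broken by smaller feature set then
#' enumeration order) and the best combination per TF (`best_by_tf`).
#'
#' @param component_scores data frame from [score_benchmark_sites()].
#' @param combinations list of feature subsets; defaults to
#'   [enumerate_combinations()].
#' @return list with `table` (tf, combination, auroc, n_tp, n_tn),
#'   `mean_auroc` (per combination), `best_overall` and `best_by_tf`.
#' @export
evaluate_combinations <- function(component_scores,
                                  combinations = enumerate_combinations()) {
  cs <- component_scores
  keys <- vapply(combinations, paste, "", collapse = "+")
  site_tf <- cs$tf_name[!duplicated(cs$site)]
  site_label <- cs$label[!duplicated(cs$site)]
  site_ids <- cs$site[!duplicated(cs$site)]
  tfs <- unique(site_tf)
  rows <- list()
  for (k in seq_along(combinations)) {
    sc <- rowSums(cs[, combinations[[k]], drop = FALSE])
    best <- vapply(split(sc, cs$site), best_score_per_region, 0)
    best <- best[match(as.character(site_ids), names(best))]
    for (tf in tfs) {
      tp <- best[site_tf == tf & site_label == "true_positive"]
      tn <- best[site_tf == tf & site_label == "true_negative"]
      rows[[length(rows) + 1L]] <- data.frame(
        tf_name = tf, combination = keys[k],
        n_features = length(combinations[[k]]),
        auroc = roc_auc(tp, tn), n_tp = length(tp), n_tn = length(tn),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  mean_auroc <- stats::aggregate(auroc ~ combination + n_features, tab,
                                 mean)
  mean_auroc <- mean_auroc[match(keys, mean_auroc$combination), ]
  rownames(mean_auroc) <- NULL
  # best overall: max mean AUROC, ties -> smallest set, then order
  o <- order(-mean_auroc$auroc, mean_auroc$n_features,
             seq_len(nrow(mean_auroc)))
  best_overall <- mean_auroc[o[1], ]
  best_by_tf <- do.call(rbind, lapply(tfs, function(tf) {
    sub <- tab[tab$tf_name == tf, ]
    oo <- order(-sub$auroc, sub$n_features)
    sub[oo[1], ]
  }))
  rownames(best_by_tf) <- NULL
  list(table = tab, mean_auroc = mean_auroc,
       best_overall = best_overall, best_by_tf = best_by_tf)
}

#' Paired t-test between two models' per-TF AUROCs
#'
#' Classical two-sided paired t-test on AUROC differences. When every
#' difference is zero (or the differences have zero variance) the test
#' is degenerate: `p = 1` is reported with a flag instead of an error so
#' that combination sweeps stay total.
#'
#' @param aurocs_a,aurocs_b equal-length numeric vectors (>= 2), paired
#'   by TF.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_test <- function(aurocs_a, aurocs_b) {
  if (length(aurocs_a) != length(aurocs_b))
    stop("paired vectors must have equal length")
  if (length(aurocs_a) < 2L) stop("need at least 2 pairs")
  d <- aurocs_a - aurocs_b
  if (stats::sd(d) < .Machine$double.eps^0.5)
    return(list(t = NA_real_, p = 1, df = length(d) - 1L,
                degenerate = TRUE))
  ht <- stats::t.test(aurocs_a, aurocs_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Benchmark sites from ranked ChIP-Seq peaks
#'
#' The protocol for species without curated binding sites: per TF, take
#' up to the `top_k` highest-scoring ChIP-Seq peaks (TFs with fewer than
#' `min_peaks` peaks are excluded), map each peak to its nearest
#' transcript TSS, and use a `width` bp region centred on the peak
#' centre as a true positive. Each TP gets one matched true negative:
#' the same TSS-relative coordinates applied to a seeded-random
#' transcript that has no ChIP-Seq peak for that TF, so the TN window
#' sits at exactly the same distance from its TSS.
#'
#' @param peaks_by_tf named list of [genomic_intervals()]; each element
#'   holds one TF's peaks with `value` = peak score.
#' @param transcripts data frame from [read_transcripts()].
#' @param top_k maximum peaks per TF, default 500.
#' @param min_peaks minimum peaks for a TF to be included, default 100.
#' @param width region width, default 200.
#' @param chrom_lengths named vector of chromosome lengths (regions
#'   leaving the chromosome are dropped pairwise).
#' @param seed integer seed for the TN transcript draw.
#' @return data frame of benchmark sites (`tf_name`, `chrom`, `start`,
#'   `end`, `label`, `anchor`, `tss_offset`).
#' @export
build_chipseq_benchmark <- function(peaks_by_tf, transcripts,
                                    top_k = 500L, min_peaks = 100L,
                                    width = 200L, chrom_lengths = NULL,
                                    seed = 1L) {
  set.seed(seed)
  out <- list()
  for (tf in names(peaks_by_tf)) {
    pk <- peaks_by_tf[[tf]]
    if (is.null(pk) || nrow(pk) < min_peaks) next
    sc <- if (!is.null(pk$value)) pk$value else rep(0, nrow(pk))
    o <- order(-sc, pk$chrom, pk$start)
    pk <- pk[o[seq_len(min(top_k, nrow(pk)))], , drop = FALSE]
    centers <- (pk$start + pk$end - 1L) %/% 2L
    # nearest transcript by TSS distance (same chromosome)
    near_id <- vapply(seq_len(nrow(pk)), function(i) {
      tx <- transcripts[transcripts$chrom == pk$chrom[i], , drop = FALSE]
      if (!nrow(tx)) return(NA_character_)
      tx$transcript_id[which.min(abs(tx$tss - centers[i]))]
    }, "")
    eligible <- setdiff(transcripts$transcript_id, unique(near_id))
    if (!length(eligible))
      stop("no eligible true-negative transcript for TF '", tf, "'")
    for (i in seq_len(nrow(pk))) {
      if (is.na(near_id[i])) next
      tx <- transcripts[match(near_id[i], transcripts$transcript_id), ]
      tp_start <- centers[i] - width %/% 2L
      tp_end <- tp_start + as.integer(width)
      offset <- tp_start - tx$tss
      tn_tx <- transcripts[match(sample(eligible, 1L),
                                 transcripts$transcript_id), ]
      tn_start <- tn_tx$tss + offset
      tn_end <- tn_start + as.integer(width)
      ok <- tp_start >= 0L && tn_start >= 0L
      if (!is.null(chrom_lengths))
        ok <- ok && tp_end <= chrom_lengths[[tx$chrom]] &&
          tn_end <= chrom_lengths[[tn_tx$chrom]]
      if (!ok) next
      out[[length(out) + 1L]] <- data.frame(
        tf_name = tf,
        chrom = c(tx$chrom, tn_tx$chrom),
        start = c(tp_start, tn_start), end = c(tp_end, tn_end),
        label = c("true_positive", "true_negative"),
        anchor = c(tx$transcript_id, tn_tx$transcript_id),
        tss_offset = c(offset, offset), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(tf_name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      label = character(), anchor = character(),
                      tss_offset = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
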