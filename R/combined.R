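FEATURES_HUMAN <- c("pwm", "cage", "correlation", "metaclusters",
                    "atac", "eqtl", "cpg", "conservation")
FEATURES_NON_HUMAN <- c("pwm", "cage", "cpg", "conservation")

#' Species scoring mode
#'
#' Selects which feature scores enter the combined affinity score:
#' `"human"` uses all eight (PWM, CAGE, correlation, metaclusters, ATAC,
#' eQTL, CpG, conservation); `"non_human"` uses the four for which data
#' exist outside human (PWM, CAGE, CpG, conservation); `"custom"` takes
#' an explicit feature set, which must contain `"pwm"`.
#'
#' @param mode `"human"`, `"non_human"` or `"custom"`.
#' @param features explicit feature subset for `"custom"`.
#' @return object of class `"species_mode"` with element `features`.
#' @export
species_mode <- function(mode = c("human", "non_human", "custom"),
                         features = NULL) {
  mode <- match.arg(mode)
  features <- switch(mode,
    human = FEATURES_HUMAN,
    non_human = FEATURES_NON_HUMAN,
    custom = {
      if (is.null(features)) stop("custom mode requires a feature set")
      unknown <- setdiff(features, FEATURES_HUMAN)
      if (length(unknown))
        stop("unknown feature(s): ", paste(unknown, collapse = ", "))
      if (!"pwm" %in% features)
        stop("the feature set must contain 'pwm'")
      unique(features)
    })
  structure(list(mode = mode, features = features),
            class = "species_mode")
}

#' @export
print.species_mode <- function(x, ...) {
  cat("species mode '", x$mode, "': ",
      paste(x$features, collapse = " + "), "\n", sep = "")
  invisible(x)
}

as_species_mode <- function(mode) {
  if (inherits(mode, "species_mode")) mode
  else if (is.character(mode) && length(mode) == 1L &&
           mode %in% c("human", "non_human")) species_mode(mode)
  else if (is.character(mode)) species_mode("custom", features = mode)
  else stop("invalid species mode")
}

#' Combine per-feature scores into the combined affinity score
#'
#' The combined affinity score is the exact sum of the per-feature
#' log-likelihood scores over the mode's active feature set; features
#' outside the set are ignored, features absent from `components`
#' contribute 0.
#'
#' @param components named numeric vector or named list of feature
#'   scores in bits; names must be known feature names.
#' @param mode a [species_mode()] (or a mode name / feature vector).
#' @return combined score in bits.
#' @export
combine_scores <- function(components, mode = "human") {
  mode <- as_species_mode(mode)
  components <- unlist(components)
  unknown <- setdiff(names(components), FEATURES_HUMAN)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  active <- intersect(names(components), mode$features)
  sum(components[active])
}

#' Per-feature component scores for a set of motif hits
#'
#' Computes the eight feature scores for each hit of one TF within one
#' analysed region, vectorised over hits. The promoter sequence context
#' supplies the CpG ratio; all interval tracks are in genome coordinates.
#'
#' @param hits data frame from [scan_sequence()] (sequence-relative
#'   coordinates).
#' @param tracks a [feature_tracks()] bundle.
#' @param chrom chromosome of the analysed region.
#' @param offset genome coordinate of position 0 of the scanned sequence.
#' @param gene_id target gene (for CAGE peak association and expression
#'   correlation); may be `NA`.
#' @param chrom_sequence full chromosome sequence (for CpG ratios); when
#'   `NULL` the scanned sequence itself is used, truncating CpG windows
#'   at its edges.
#' @param scanned_sequence the scanned sequence (used for CpG when
#'   `chrom_sequence` is `NULL`).
#' @param window_start,window_end bounds of the analysed region in
#'   genome coordinates (restrict ATAC peaks "within the current target
#'   region"); default to the hit span.
#' @return data frame with one column per feature (bits) plus an
#'   `absent_features` attribute listing features with no usable data.
#' @export
score_hit_features <- function(hits, tracks, chrom = "chr1", offset = 0L,
                               gene_id = NA_character_,
                               chrom_sequence = NULL,
                               scanned_sequence = NULL,
                               window_start = NULL, window_end = NULL) {
  n <- nrow(hits)
  gs <- hits$start + offset
  ge <- hits$end + offset
  if (is.null(window_start)) window_start <- if (n) min(gs) else offset
  if (is.null(window_end)) window_end <- if (n) max(ge) else offset
  absent <- character()
  sub_chrom <- function(track) {
    if (is.null(track)) NULL
    else track[track$chrom == chrom, , drop = FALSE]
  }

  # CAGE: peaks associated to the target gene (name column = gene id)
  cage_all <- sub_chrom(tracks$cage)
  gene_peaks <- if (!is.null(cage_all) && !is.na(gene_id) &&
                    !is.null(cage_all$name))
    cage_all[cage_all$name == gene_id, , drop = FALSE] else NULL
  cage <- lls_cage(gs, ge, gene_peaks, tracks$tables$cage)
  if (isTRUE(attr(cage, "absent"))) absent <- c(absent, "cage")

  corr <- if (is.null(tracks$correlations) || is.na(gene_id)) {
    absent <- c(absent, "correlation")
    numeric(1)
  } else {
    lls_correlation(hits$tf_name[1], gene_id, tracks$correlations)
  }
  corr <- rep(as.numeric(corr), length.out = n)

  meta <- lls_metaclusters(gs, ge, sub_chrom(tracks$metaclusters),
                           tracks$tables$metaclusters)
  if (isTRUE(attr(meta, "absent"))) absent <- c(absent, "metaclusters")

  atac_all <- sub_chrom(tracks$atac)
  atac_in <- if (!is.null(atac_all))
    atac_all[atac_all$start < window_end & atac_all$end > window_start, ,
             drop = FALSE] else NULL
  atac <- lls_atac(gs, ge, atac_in, tracks$tables$atac)
  if (isTRUE(attr(atac, "absent"))) absent <- c(absent, "atac")

  eqtl <- lls_eqtl(gs, ge, sub_chrom(tracks$eqtls), tracks$tables$eqtl)
  if (isTRUE(attr(eqtl, "absent"))) absent <- c(absent, "eqtl")

  cpg <- if (is.null(tracks$tables$cpg)) {
    absent <- c(absent, "cpg")
    numeric(n)
  } else {
    centers <- (hits$start + hits$end) %/% 2L
    ratios <- if (!is.null(chrom_sequence))
      cpg_ratio(chrom_sequence, centers + offset, tracks$cpg_window)
    else if (!is.null(scanned_sequence))
      cpg_ratio(scanned_sequence, centers, tracks$cpg_window)
    else rep(0, n)
    lls_cpg(ratios, tracks$tables$cpg)
  }

  cons <- lls_conservation(gs, ge, sub_chrom(tracks$conservation),
                           tracks$tables$conservation)
  if (isTRUE(attr(cons, "absent"))) absent <- c(absent, "conservation")

  out <- data.frame(pwm = hits$pwm_score, cage = as.numeric(cage),
                    correlation = corr, metaclusters = as.numeric(meta),
                    atac = as.numeric(atac), eqtl = as.numeric(eqtl),
                    cpg = as.numeric(cpg),
                    conservation = as.numeric(cons))
  attr(out, "absent_features") <- unique(absent)
  out
}

#' Empirical p-value of a combined score against a background sample
#'
#' `p = (r + 1) / (n + 1)` with `r` the number of background scores at
#' or above the observed score; monotone non-increasing in the score and
#' always in (0, 1].
#'
#' @param score numeric vector of observed scores.
#' @param background numeric vector of background scores (n >= 1).
#' @return numeric vector of p-values.
#' @export
empirical_pvalue <- function(score, background) {
  n <- length(background)
  if (n < 1L) stop("background sample is empty")
  sorted <- sort(background)
  # r = n - (number of background scores < score)
  r <- n - findInterval(score, sorted, left.open = TRUE)
  (r + 1) / (n + 1)
}

#' Combined-score background distribution over a promoter corpus
#'
#' Scans each background promoter with every PFM at PWM p-value
#' threshold 1 (all windows), computes combined affinity scores, and
#' collects them per TF. Used to calibrate empirical p-values; the
#' original calibration runs over tens of thousands of real promoters,
#' here the corpus is pluggable and typically a few hundred synthetic
#' promoters.
#'
#' @param promoters list of background promoter entries; each entry is a
#'   list with `sequence` and optionally `tracks`, `chrom`, `offset`,
#'   `gene_id`. A plain character vector of sequences is also accepted
#'   (PWM-only scoring context).
#' @param pfms list of [pfm_record()]s.
#' @param mode a [species_mode()] or mode name.
#' @param background a [background_model()].
#' @param pseudocount PWM pseudocount.
#' @return object of class `"score_background"`: per TF, the sorted
#'   vector of all combined hit scores (`scores`) and the per-promoter
#'   top combined scores (`top_scores`).
#' @export
background_score_distribution <- function(promoters, pfms,
                                          mode = "human",
                                          background = background_model(),
                                          pseudocount = 0.8) {
  if (!length(promoters)) stop("background promoter set is empty")
  if (is.character(promoters))
    promoters <- lapply(unname(promoters), function(s) list(sequence = s))
  mode <- as_species_mode(mode)
  per_tf <- stats::setNames(vector("list", length(pfms)),
                            vapply(pfms, `[[`, "", "tf_name"))
  for (p in pfms) {
    pwm <- build_pwm(p, background, pseudocount)
    dist <- pwm_score_distribution(pwm)
    all_scores <- vector("list", length(promoters))
    tops <- rep(-Inf, length(promoters))
    for (j in seq_along(promoters)) {
      pr <- promoters[[j]]
      hits <- scan_sequence(pwm, pr$sequence, pvalue_threshold = 1,
                            distribution = dist)
      if (!nrow(hits)) next
      if (!is.null(pr$tracks)) {
        comp <- score_hit_features(
          hits, pr$tracks,
          chrom = if (!is.null(pr$chrom)) pr$chrom else "chr1",
          offset = if (!is.null(pr$offset)) pr$offset else 0L,
          gene_id = if (!is.null(pr$gene_id)) pr$gene_id
                    else NA_character_,
          scanned_sequence = pr$sequence,
          window_start = if (!is.null(pr$offset)) pr$offset else 0L,
          window_end = (if (!is.null(pr$offset)) pr$offset else 0L) +
            nchar(pr$sequence))
        sc <- rowSums(comp[, intersect(names(comp), mode$features),
                           drop = FALSE])
      } else {
        sc <- hits$pwm_score
      }
      all_scores[[j]] <- sc
      tops[j] <- max(sc)
    }
    per_tf[[p$tf_name]] <- list(
      scores = sort(unlist(all_scores)),
      top_scores = tops)
  }
  structure(list(per_tf = per_tf, mode = mode,
                 n_promoters = length(promoters)),
            class = "score_background")
}

#' @export
print.score_background <- function(x, ...) {
  cat("combined-score background:", x$n_promoters, "promoters,",
      length(x$per_tf), "TF(s)\n")
  for (nm in names(x$per_tf))
    cat(" ", nm, ":", length(x$per_tf[[nm]]$scores), "hit scores\n")
  invisible(x)
}

#' Null calibration of empirical p-values
#'
#' Leave-one-out empirical p-values of each background promoter's own
#' top combined score, per TF. Under the null these are approximately
#' uniform; the Kolmogorov-Smirnov statistic against Uniform(0,1) is
#' returned as the calibration summary.
#'
#' @param bg a [background_score_distribution()] result.
#' @return data frame with one row per TF: `tf_name`, `n`, `ks`.
#' @export
null_calibration <- function(bg) {
  stopifnot(inherits(bg, "score_background"))
  out <- lapply(names(bg$per_tf), function(tf) {
    tops <- bg$per_tf[[tf]]$top_scores
    tops <- tops[is.finite(tops)]
    n <- length(tops)
    pv <- vapply(seq_len(n), function(i)
      empirical_pvalue(tops[i], tops[-i]), 0)
    ks <- suppressWarnings(
      stats::ks.test(pv, "punif")$statistic)
    data.frame(tf_name = tf, n = n, ks = as.numeric(ks))
  })
  do.call(rbind, out)
}

#' Analyse a promoter region end to end
#'
#' Extracts the promoter window around a transcript's TSS, scans it with
#' every PFM on both strands, scores each hit against the evidence
#' tracks, sums the active features into the combined affinity score,
#' attaches empirical p-values when a background is supplied, filters,
#' and sorts by combined score. Promoter coordinates in the result are
#' TSS-relative with negative values upstream.
#'
#' The window is `before_tss` nt upstream to `after_tss` nt downstream
#' of the TSS (defaults 900 and 100, i.e. a 1,000 bp window). Negative
#' values are honoured by signed arithmetic: a negative `before_tss`
#' starts the window downstream of the TSS and a negative `after_tss`
#' ends it upstream; the resolved window must be non-empty.
#'
#' @param transcript one-row data frame (or list) with `transcript_id`,
#'   `gene_id`, `chrom`, `tss`, `strand` — see [read_transcripts()].
#' @param sequences named character vector of chromosome sequences.
#' @param tracks a [feature_tracks()] bundle (may be `NULL`: PWM-only).
#' @param pfms list of [pfm_record()]s.
#' @param before_tss,after_tss window extent around the TSS (defaults
#'   900/100).
#' @param pval PWM p-value cutoff (default 0.01).
#' @param pvalc combined-score empirical p-value cutoff (default 0.01;
#'   applied only when `background_scores` is supplied).
#' @param mode a [species_mode()] or mode name.
#' @param background a [background_model()].
#' @param pseudocount PWM pseudocount (default 0.8).
#' @param background_scores optional [background_score_distribution()]
#'   used for combined-score p-values.
#' @return data frame of class `"tfbs_hits"`: `tf_name`, `chrom`,
#'   `start`, `end` (genome, 0-based half-open), `tss_start`, `tss_end`
#'   (TSS-relative), `strand`, `sequence`, `pwm_pvalue`, one column per
#'   feature score, `combined_affinity`, `combined_pvalue`; sorted by
#'   combined score, descending. Attributes: `transcript_id`, `gene_id`,
#'   `window` and `absent_features`.
#' @export
analyze_promoter <- function(transcript, sequences, tracks, pfms,
                             before_tss = 900L, after_tss = 100L,
                             pval = 0.01, pvalc = 0.01, mode = "human",
                             background = background_model(),
                             pseudocount = 0.8,
                             background_scores = NULL) {
  tx <- as.list(transcript)
  mode <- as_species_mode(mode)
  chrom <- as.character(tx$chrom)
  if (!chrom %in% names(sequences))
    stop("chromosome '", chrom, "' not in sequences")
  chrom_seq <- sequences[[chrom]]
  tss <- as.integer(tx$tss)
  upstream <- if (identical(tx$strand, "-")) -1L else 1L
  # TSS-relative window [-before_tss, after_tss) mapped to the + strand
  # of the genome; width = before_tss + after_tss
  if (upstream == 1L) {
    win_start <- tss - as.integer(before_tss)
    win_end <- tss + as.integer(after_tss)
  } else {
    win_start <- tss - as.integer(after_tss) + 1L
    win_end <- tss + as.integer(before_tss) + 1L
  }
  if (win_start >= win_end)
    stop("promoter window is empty after sign resolution")
  if (win_start < 0L || win_end > nchar(chrom_seq))
    stop("promoter window [", win_start, ",", win_end,
         ") outside chromosome bounds")
  promoter_seq <- substring(chrom_seq, win_start + 1L, win_end)

  results <- list()
  absent_all <- character()
  for (p in pfms) {
    pwm <- build_pwm(p, background, pseudocount)
    hits <- scan_sequence(pwm, promoter_seq, pvalue_threshold = pval)
    if (!nrow(hits)) next
    if (!is.null(tracks)) {
      comp <- score_hit_features(hits, tracks, chrom = chrom,
                                 offset = win_start,
                                 gene_id = as.character(tx$gene_id),
                                 chrom_sequence = chrom_seq,
                                 window_start = win_start,
                                 window_end = win_end)
      absent_all <- union(absent_all, attr(comp, "absent_features"))
    } else {
      comp <- data.frame(pwm = hits$pwm_score)
      absent_all <- union(absent_all, setdiff(FEATURES_HUMAN, "pwm"))
    }
    active <- intersect(names(comp), mode$features)
    combined <- rowSums(comp[, active, drop = FALSE])
    gs <- hits$start + win_start
    ge <- hits$end + win_start
    rel <- if (upstream == 1L)
      cbind(gs - tss, ge - tss) else cbind(tss - ge + 1L, tss - gs + 1L)
    df <- data.frame(tf_name = hits$tf_name, chrom = chrom, start = gs,
                     end = ge, tss_start = rel[, 1], tss_end = rel[, 2],
                     strand = hits$strand, sequence = hits$sequence,
                     pwm_pvalue = hits$pwm_pvalue,
                     stringsAsFactors = FALSE)
    df <- cbind(df, comp[, active, drop = FALSE])
    df$combined_affinity <- combined
    df$combined_pvalue <- if (!is.null(background_scores) &&
                              !is.null(background_scores$per_tf[[p$tf_name]]))
      empirical_pvalue(combined,
                       background_scores$per_tf[[p$tf_name]]$scores)
    else NA_real_
    results[[length(results) + 1L]] <- df
  }
  out <- if (length(results)) do.call(rbind, results) else
    data.frame(tf_name = character(), chrom = character(),
               start = integer(), end = integer(), tss_start = integer(),
               tss_end = integer(), strand = character(),
               sequence = character(), pwm_pvalue = numeric(),
               combined_affinity = numeric(), combined_pvalue = numeric(),
               stringsAsFactors = FALSE)
  if (!is.null(background_scores) && nrow(out))
    out <- out[is.na(out$combined_pvalue) | out$combined_pvalue <= pvalc,
               , drop = FALSE]
  out <- out[order(-out$combined_affinity), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "transcript_id") <- as.character(tx$transcript_id)
  attr(out, "gene_id") <- as.character(tx$gene_id)
  attr(out, "window") <- c(start = win_start, end = win_end, tss = tss)
  attr(out, "features") <- mode$features
  attr(out, "absent_features") <- absent_all
  class(out) <- c("tfbs_hits", "data.frame")
  out
}

#' @export
print.tfbs_hits <- function(x, n = 10L, ...) {
  cat("TFBS predictions for transcript",
      attr(x, "transcript_id") %||% "?", "-", nrow(x), "hit(s)\n")
  ab <- attr(x, "absent_features")
  if (length(ab)) cat("  absent features:", paste(ab, collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
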