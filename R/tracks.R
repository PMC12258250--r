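#' Bundle of evidence tracks for one species
#'
#' Collects the interval/value tracks a promoter is scored against and
#' the empirical score tables built from them. Any track may be `NULL`;
#' a missing track contributes 0 bits and raises a per-feature "absent"
#' flag in results instead of erroring, because the tool routinely runs
#' with feature subsets (non-human species have no metacluster, ATAC,
#' eQTL or correlation data).
#'
#' @param cage [genomic_intervals()] of CAGE (or CAGE-like) peaks; the
#'   `value` column holds the peak count, the `name` column the gene the
#'   peak is associated to.
#' @param metaclusters [genomic_intervals()] of ChIP-Seq metaclusters.
#' @param atac [genomic_intervals()] of open-chromatin peaks.
#' @param eqtls [genomic_intervals()] of eQTL positions; `value` holds
#'   the (signed) effect size.
#' @param conservation [genomic_intervals()] of conserved elements.
#' @param correlations a [correlation_table()] (or the raw pairs data
#'   frame, which is converted).
#' @param tables named list of [empirical_table()]s; missing tables are
#'   built from the tracks when `genome_lengths`/`sequences` are given.
#' @param genome_lengths named integer vector of chromosome lengths
#'   (needed to build distance/overlap tables).
#' @param sequences named character vector of chromosome sequences
#'   (needed to build the CpG ratio table).
#' @param cpg_window CpG window width in nt, default 200.
#' @return object of class `"feature_tracks"`.
#' @export
feature_tracks <- function(cage = NULL, metaclusters = NULL, atac = NULL,
                           eqtls = NULL, conservation = NULL,
                           correlations = NULL, tables = list(),
                           genome_lengths = NULL, sequences = NULL,
                           cpg_window = 200L) {
  if (is.data.frame(correlations))
    correlations <- correlation_table(correlations)
  tr <- structure(list(cage = cage, metaclusters = metaclusters,
                       atac = atac, eqtls = eqtls,
                       conservation = conservation,
                       correlations = correlations, tables = tables,
                       cpg_window = as.integer(cpg_window)),
                  class = "feature_tracks")
  if (!is.null(genome_lengths)) {
    if (is.null(tr$tables$cage) && !is.null(cage) && nrow(cage))
      tr$tables$cage <- build_distance_table(cage, genome_lengths, "cage")
    if (is.null(tr$tables$atac) && !is.null(atac) && nrow(atac))
      tr$tables$atac <- build_distance_table(atac, genome_lengths, "atac")
    if (is.null(tr$tables$conservation) && !is.null(conservation) &&
        nrow(conservation))
      tr$tables$conservation <-
        build_distance_table(conservation, genome_lengths, "conservation")
    if (is.null(tr$tables$metaclusters) && !is.null(metaclusters) &&
        nrow(metaclusters))
      tr$tables$metaclusters <-
        build_overlap_table(metaclusters, genome_lengths, "metaclusters")
  }
  if (is.null(tr$tables$eqtl) && !is.null(eqtls) && nrow(eqtls))
    tr$tables$eqtl <- build_tail_table(abs(eqtls$value), "upper_tail",
                                       feature = "eqtl")
  if (is.null(tr$tables$cpg) && !is.null(sequences)) {
    ratios <- unlist(lapply(sequences, cpg_ratio_track,
                            window = cpg_window), use.names = FALSE)
    tr$tables$cpg <- build_tail_table(ratios, "upper_tail",
                                      feature = "cpg")
  }
  if (is.null(tr$tables$correlation) && !is.null(tr$correlations))
    tr$tables$correlation <- tr$correlations$table
  tr
}

#' @export
print.feature_tracks <- function(x, ...) {
  nrow0 <- function(d) if (is.null(d)) 0L else nrow(d)
  cat("feature tracks:\n",
      " cage:", nrow0(x$cage), "peaks;",
      "metaclusters:", nrow0(x$metaclusters), ";",
      "atac:", nrow0(x$atac), ";",
      "eqtls:", nrow0(x$eqtls), ";",
      "conservation:", nrow0(x$conservation), ";",
      "correlation pairs:",
      if (is.null(x$correlations)) 0L else nrow(x$correlations$pairs), "\n",
      " tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

# shared guard: NULL table/track -> score 0 with absent flag
.absent <- function(feature) {
  structure(0, absent = TRUE, feature = feature)
}

#' CAGE proximity log-likelihood score
#'
#' Sum over all CAGE peaks associated with the target gene of
#' `-log2( P(x <= d_i) * p_i / p_total )`, where `d_i` is the distance
#' from the putative TFBS to peak `i` (0 when overlapping), `p_i` the
#' peak's count and `p_total` the gene's total peak count.
#'
#' @param hit_start,hit_end hit interval (0-based half-open, genome
#'   coordinates); vectors are scored in parallel.
#' @param peaks [genomic_intervals()] of the target gene's CAGE peaks
#'   (the `value` column holds the peak counts; missing counts default
#'   to 1).
#' @param table the genome-wide CAGE distance [empirical_table()].
#' @return numeric vector of scores in bits; attribute `absent` is set
#'   when the gene has no peaks or no table exists.
#' @export
lls_cage <- function(hit_start, hit_end, peaks, table) {
  if (is.null(table) || is.null(peaks) || !nrow(peaks))
    return(rep(0, length(hit_start)) |> `attr<-`("absent", TRUE))
  counts <- peaks$value
  if (is.null(counts) || all(is.na(counts))) counts <- rep(1, nrow(peaks))
  counts[is.na(counts)] <- 1
  p_total <- sum(counts)
  score <- numeric(length(hit_start))
  for (i in seq_len(nrow(peaks))) {
    d <- nearest_distance(hit_start, hit_end,
                          peaks$start[i], peaks$end[i])
    score <- score - log2(table_prob(table, d) * counts[i] / p_total)
  }
  score
}

#' Expression-correlation log-likelihood score
#'
#' `-log2 P(x >= |c_current|)` under the distribution of all TF-gene
#' correlation magnitudes; 0 when the pair is absent from the table
#' (its magnitude fell below the retention cutoff).
#'
#' @param tf_name,gene_id the pair to score.
#' @param correlations a [correlation_table()] (or `NULL`).
#' @return score in bits (scalar).
#' @export
lls_correlation <- function(tf_name, gene_id, correlations) {
  if (is.null(correlations)) return(.absent("correlation"))
  cc <- lookup_correlation(correlations, tf_name, gene_id)
  if (is.na(cc)) return(0)
  table_lls(correlations$table, abs(cc))
}

#' Metacluster overlap log-likelihood score
#'
#' `-log2 P(x >= n_overlap)` where `n_overlap` is the number of
#' metacluster intervals intersecting the hit.
#'
#' @inheritParams lls_cage
#' @param metaclusters [genomic_intervals()] of metaclusters.
#' @param table the genome-wide overlap-count [empirical_table()].
#' @export
lls_metaclusters <- function(hit_start, hit_end, metaclusters, table) {
  if (is.null(table))
    return(rep(0, length(hit_start)) |> `attr<-`("absent", TRUE))
  n_overlap <- if (is.null(metaclusters) || !nrow(metaclusters))
    integer(length(hit_start))
  else count_overlaps(hit_start, hit_end,
                      metaclusters$start, metaclusters$end)
  table_lls(table, n_overlap)
}

#' ATAC-Seq proximity log-likelihood score
#'
#' Sum over the open-chromatin peaks within the analysed target region
#' of `-log2 P(x <= d_i)`, `d_i` the distance from the hit to peak `i`.
#'
#' @inheritParams lls_cage
#' @param peaks [genomic_intervals()] of the ATAC peaks within the
#'   analysed window (the caller restricts them).
#' @param table the genome-wide ATAC distance [empirical_table()].
#' @export
lls_atac <- function(hit_start, hit_end, peaks, table) {
  if (is.null(table))
    return(rep(0, length(hit_start)) |> `attr<-`("absent", TRUE))
  if (is.null(peaks) || !nrow(peaks))
    return(rep(0, length(hit_start)) |> `attr<-`("absent", TRUE))
  score <- numeric(length(hit_start))
  for (i in seq_len(nrow(peaks))) {
    d <- nearest_distance(hit_start, hit_end,
                          peaks$start[i], peaks$end[i])
    score <- score + table_lls(table, d)
  }
  score
}

#' eQTL magnitude log-likelihood score
#'
#' Sum over the eQTLs overlapping the hit of `-log2 P(x >= |m_i|)`,
#' `m_i` the eQTL's effect size.
#'
#' @inheritParams lls_cage
#' @param eqtls [genomic_intervals()] of eQTLs (`value` = signed effect).
#' @param table upper-tail magnitude [empirical_table()].
#' @export
lls_eqtl <- function(hit_start, hit_end, eqtls, table) {
  if (is.null(table) || is.null(eqtls) || !nrow(eqtls))
    return(rep(0, length(hit_start)) |> `attr<-`("absent", TRUE))
  score <- numeric(length(hit_start))
  for (i in seq_len(nrow(eqtls))) {
    ov <- eqtls$start[i] < hit_end & eqtls$end[i] > hit_start
    if (any(ov))
      score[ov] <- score[ov] + table_lls(table, abs(eqtls$value[i]))
  }
  score
}

#' CpG ratio log-likelihood score
#'
#' `-log2 P(x >= r)` for an observed/expected CpG ratio `r` under the
#' genome-wide ratio distribution.
#'
#' @param ratio numeric vector of observed/expected CpG ratios.
#' @param table upper-tail CpG ratio [empirical_table()].
#' @export
lls_cpg <- function(ratio, table) {
  if (is.null(table))
    return(rep(0, length(ratio)) |> `attr<-`("absent", TRUE))
  table_lls(table, ratio)
}

#' Conserved-element proximity log-likelihood score
#'
#' `-log2 P(x <= d)` where `d` is the distance from the hit to the
#' nearest conserved element (0 when overlapping).
#'
#' @inheritParams lls_cage
#' @param elements [genomic_intervals()] of conserved elements.
#' @param table the genome-wide distance [empirical_table()] from
#'   [build_distance_table()].
#' @export
lls_conservation <- function(hit_start, hit_end, elements, table) {
  if (is.null(table) || is.null(elements) || !nrow(elements))
    return(rep(0, length(hit_start)) |> `attr<-`("absent", TRUE))
  d <- nearest_distance(hit_start, hit_end, elements$start, elements$end)
  table_lls(table, d)
}
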