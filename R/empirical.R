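#' Empirical score table
#'
#' Maps an observed feature value to a tail or cumulative probability
#' estimated from a genome-derived sample, with a probability floor
#' `eps = 1/(n+1)` that keeps every log-likelihood score finite. The
#' log-likelihood score of a value `v` is `-log2(prob(v))`, which is
#' always `>= 0` and at most `-log2(eps)`.
#'
#' Direction conventions: distance features use `lower_tail`
#' (`P(x <= v)` — small distances are surprising, hence informative);
#' overlap counts, effect magnitudes, CpG ratios and correlation
#' magnitudes use `upper_tail` (`P(x >= v)`).
#'
#' @param values numeric sample the table is built from (n >= 1).
#' @param direction `"lower_tail"` or `"upper_tail"`.
#' @param feature optional feature name carried in the object.
#' @return object of class `"empirical_table"`.
#' @export
empirical_table <- function(values, direction = c("lower_tail",
                                                  "upper_tail"),
                            feature = NULL) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("empirical table needs at least one observation",
                   if (!is.null(feature)) paste0(" (feature '", feature, "')"))
  tab <- table(values)
  support <- as.numeric(names(tab))
  count_at <- as.numeric(tab)
  structure(list(feature = feature, direction = direction,
                 support = support, count_at = count_at,
                 cum_le = cumsum(count_at), n = n, eps = 1 / (n + 1)),
            class = "empirical_table")
}

#' @export
print.empirical_table <- function(x, ...) {
  cat("empirical score table", if (!is.null(x$feature)) x$feature else "",
      "\n  direction:", x$direction, " n =", x$n,
      " support:", length(x$support), "values in [",
      format(min(x$support)), ",", format(max(x$support)), "]",
      " eps =", format(x$eps), "\n")
  invisible(x)
}

#' Tail/cumulative probability of observed values under a table
#'
#' @param table an [empirical_table()].
#' @param v numeric vector of observed values.
#' @return probabilities in `[eps, 1]`; `lower_tail` tables return
#'   `P(x <= v)`, `upper_tail` tables `P(x >= v)`.
#' @export
table_prob <- function(table, v) {
  stopifnot(inherits(table, "empirical_table"))
  j <- findInterval(v, table$support)
  if (table$direction == "lower_tail") {
    cnt <- ifelse(j == 0L, 0, table$cum_le[pmax(j, 1L)])
    p <- cnt / table$n
  } else {
    j1 <- pmax(j, 1L)
    at <- table$support[j1] == v
    cnt_lt <- ifelse(j == 0L, 0,
                     table$cum_le[j1] - ifelse(at, table$count_at[j1], 0))
    p <- (table$n - cnt_lt) / table$n
  }
  pmin(pmax(p, table$eps), 1)
}

#' Log-likelihood score of observed values under a table
#'
#' `LLS(v) = -log2(prob(v))`, non-negative and finite.
#'
#' @inheritParams table_prob
#' @return numeric vector of scores in bits.
#' @export
table_lls <- function(table, v) {
  -log2(table_prob(table, v))
}

#' Build an upper- or lower-tail table from raw observations
#'
#' @param values numeric observations.
#' @param direction tail direction.
#' @param feature optional feature name.
#' @return an [empirical_table()].
#' @export
build_tail_table <- function(values, direction = c("upper_tail",
                                                   "lower_tail"),
                             feature = NULL) {
  empirical_table(values, match.arg(direction), feature = feature)
}

#' Genome-wide distance-to-nearest-element table
#'
#' For every nucleotide position of the genome, the distance to the
#' nearest element (0 inside an element, nearest-edge distance outside),
#' summarised as a lower-tail table: `P(x <= d)` over all positions.
#'
#' @param elements a [genomic_intervals()] data frame (>= 1 element).
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param feature optional feature name.
#' @return an [empirical_table()] with direction `lower_tail`.
#' @export
build_distance_table <- function(elements, genome_lengths, feature = NULL) {
  if (is.null(elements) || !nrow(elements))
    stop("cannot build distance table",
         if (!is.null(feature)) paste0(" for feature '", feature, "'"),
         ": element list is empty")
  if (!length(genome_lengths)) stop("genome_lengths is empty")
  dists <- unlist(lapply(names(genome_lengths), function(chr) {
    len <- genome_lengths[[chr]]
    el <- elements[elements$chrom == chr, , drop = FALSE]
    pos <- 0:(len - 1L)
    if (!nrow(el)) return(rep(Inf, len))
    nearest_distance(pos, pos + 1L, el$start, el$end)
  }), use.names = FALSE)
  dists <- dists[is.finite(dists)]
  if (!length(dists))
    stop("no finite distances; elements missing from every chromosome")
  empirical_table(dists, "lower_tail", feature = feature)
}

#' Genome-wide overlap-count table
#'
#' For every nucleotide position, the number of elements covering it,
#' summarised as an upper-tail table (`P(x >= n_overlap)`).
#'
#' @inheritParams build_distance_table
#' @return an [empirical_table()] with direction `upper_tail`.
#' @export
build_overlap_table <- function(elements, genome_lengths, feature = NULL) {
  counts <- unlist(lapply(names(genome_lengths), function(chr) {
    len <- genome_lengths[[chr]]
    el <- if (is.null(elements)) NULL
          else elements[elements$chrom == chr, , drop = FALSE]
    if (is.null(el) || !nrow(el)) return(integer(len))
    position_coverage(len, el$start, el$end)
  }), use.names = FALSE)
  empirical_table(counts, "upper_tail", feature = feature)
}

#' Observed/expected CpG ratio around a position
#'
#' `ratio = (#CG dinucleotides * window length) / (#C * #G)` in a window
#' of `window` nt centred on `center`, truncated at sequence ends; 0 by
#' convention when the window has no C or no G.
#'
#' @param sequence DNA string.
#' @param center 0-based position the window is centred on.
#' @param window window width in nt, default 200.
#' @return numeric ratio.
#' @export
cpg_ratio <- function(sequence, center, window = 200L) {
  n <- nchar(sequence)
  half <- window %/% 2L
  lo <- pmax(center - half, 0L)
  hi <- pmin(center + half, n)   # exclusive
  win <- substring(sequence, lo + 1L, hi)
  nC <- nchar(gsub("[^C]", "", win))
  nG <- nchar(gsub("[^G]", "", win))
  obs <- vapply(gregexpr("(?=CG)", win, perl = TRUE), function(m)
    sum(m > 0L), 0L)
  wl <- hi - lo
  ifelse(nC * nG == 0, 0, obs * wl / (nC * nG))
}

#' CpG observed/expected ratio at every position of a sequence
#'
#' Vectorised rolling-window version of [cpg_ratio()], used both to build
#' the genome-wide CpG ratio table and to score hits.
#'
#' @param sequence DNA string.
#' @param window window width in nt, default 200.
#' @return numeric vector of ratios, one per position.
#' @export
cpg_ratio_track <- function(sequence, window = 200L) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  isC <- as.integer(ch == "C")
  isG <- as.integer(ch == "G")
  isCG <- as.integer(ch == "C" & c(ch[-1], "") == "G")
  cumC <- c(0L, cumsum(isC))
  cumG <- c(0L, cumsum(isG))
  cumCG <- c(0L, cumsum(isCG))
  half <- window %/% 2L
  pos <- 0:(n - 1L)
  lo <- pmax(pos - half, 0L)
  hi <- pmin(pos + half, n)
  nC <- cumC[hi + 1L] - cumC[lo + 1L]
  nG <- cumG[hi + 1L] - cumG[lo + 1L]
  # CG dinucleotides fully inside [lo, hi): start positions in [lo, hi-1)
  obs <- cumCG[pmax(hi, 1L)] - cumCG[lo + 1L]
  wl <- hi - lo
  ifelse(nC * nG == 0, 0, obs * wl / (nC * nG))
}

#' TF-gene correlation table
#'
#' Holds pairwise Spearman correlations between TF and target gene
#' expression, filtered at a magnitude cutoff (default 0.3) and
#' optionally Bonferroni-filtered when per-pair p-values are supplied,
#' plus the upper-tail table of all correlation magnitudes used for
#' scoring.
#'
#' @param pairs data frame with `tf_name`, `gene_id`, `correlation` and
#'   optional `pvalue` (see [read_correlations()]).
#' @param cutoff correlation magnitude cutoff; pairs below it are
#'   discarded, default 0.3.
#' @param bonferroni_alpha when `pairs$pvalue` is present, keep only
#'   pairs with `pvalue * nrow(pairs) <= bonferroni_alpha`; `NULL`
#'   disables the filter. Default 0.05.
#' @return object of class `"correlation_table"` with elements `pairs`
#'   and `table` (an upper-tail [empirical_table()] of magnitudes), or
#'   `NULL` when no pair survives filtering.
#' @export
correlation_table <- function(pairs, cutoff = 0.3,
                              bonferroni_alpha = 0.05) {
  if (is.null(pairs) || !nrow(pairs)) return(NULL)
  if (!is.null(pairs$pvalue) && !is.null(bonferroni_alpha)) {
    m <- nrow(pairs)
    pairs <- pairs[pairs$pvalue * m <= bonferroni_alpha, , drop = FALSE]
  }
  pairs <- pairs[abs(pairs$correlation) >= cutoff, , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  structure(list(pairs = pairs, cutoff = cutoff,
                 table = empirical_table(abs(pairs$correlation),
                                         "upper_tail",
                                         feature = "correlation")),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("correlation table:", nrow(x$pairs), "TF-gene pairs, |c| >=",
      x$cutoff, "\n")
  invisible(x)
}

#' Look up a TF-gene correlation
#' @param table a [correlation_table()] (or `NULL`).
#' @param tf_name,gene_id pair identifiers.
#' @return the signed correlation, or `NA` if the pair is absent.
#' @export
lookup_correlation <- function(table, tf_name, gene_id) {
  if (is.null(table)) return(NA_real_)
  i <- which(table$pairs$tf_name == tf_name &
               table$pairs$gene_id == gene_id)
  if (!length(i)) NA_real_ else table$pairs$correlation[i[1]]
}
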