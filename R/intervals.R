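#' Construct a table of genomic intervals
#'
#' The package-internal interval container: a plain data frame in 0-based
#' half-open coordinates, sorted by (chrom, start). All track data
#' (CAGE peaks, metaclusters, ATAC peaks, eQTLs, conserved elements) is
#' held in this form.
#'
#' @param chrom character vector of sequence names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param value optional numeric per-interval value (peak count, eQTL
#'   magnitude, peak score ...).
#' @param name optional character per-interval name.
#' @return a `data.frame` with class `"genomic_intervals"`, sorted by
#'   (chrom, start, end).
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              value = NULL, name = NULL) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval start/end must be integral and non-missing")
  if (any(start < 0L))
    stop("interval start must be >= 0 (coordinates are 0-based half-open)")
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("invalid interval at row %d: start (%d) >= end (%d)",
                 bad[1], start[bad[1]], end[bad[1]]))
  strand <- rep_len(as.character(strand), length(chrom))
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- rep_len(as.character(name), nrow(df))
  if (!is.null(value)) df$value <- rep_len(as.numeric(value), nrow(df))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

empty_intervals <- function() {
  genomic_intervals(character(), integer(), integer())
}

#' Merge overlapping or bookended intervals on one chromosome
#'
#' @param starts,ends integer vectors (0-based half-open), any order.
#' @return list with sorted, disjoint `starts` and `ends`.
#' @keywords internal
merge_intervals <- function(starts, ends) {
  if (!length(starts)) return(list(starts = integer(), ends = integer()))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

#' Distance from query intervals to the nearest element interval
#'
#' Nearest-edge distance in nucleotides between closest base positions:
#' 0 when the query overlaps an element, 1 when bookended (adjacent), and
#' `gap + 1` in general — identical to the per-position convention used by
#' [build_distance_table()], so a width-1 query at position p returns the
#' same distance as position p in the genome-wide table.
#'
#' @param q_start,q_end query interval vectors (0-based half-open).
#' @param e_start,e_end element intervals (same chromosome); need not be
#'   disjoint — they are merged internally.
#' @return integer vector of distances (`Inf` when no elements).
#' @export
nearest_distance <- function(q_start, q_end, e_start, e_end) {
  if (!length(e_start)) return(rep(Inf, length(q_start)))
  m <- merge_intervals(as.integer(e_start), as.integer(e_end))
  s <- m$starts; e <- m$ends; K <- length(s)
  j <- findInterval(q_start, s)
  ov_left <- j >= 1L & e[pmax(j, 1L)] > q_start
  ov_right <- j < K & s[pmin(j + 1L, K)] < q_end
  d_left <- ifelse(j >= 1L, q_start - e[pmax(j, 1L)] + 1L, Inf)
  d_right <- ifelse(j < K, s[pmin(j + 1L, K)] - q_end + 1L, Inf)
  ifelse(ov_left | ov_right, 0, pmin(d_left, d_right))
}

#' Count elements overlapping each query interval
#'
#' @param q_start,q_end query intervals (0-based half-open).
#' @param e_start,e_end element intervals (may overlap each other; each
#'   overlapping element is counted).
#' @return integer vector of overlap counts.
#' @export
count_overlaps <- function(q_start, q_end, e_start, e_end) {
  if (!length(e_start)) return(integer(length(q_start)))
  ss <- sort(as.integer(e_start))
  ee <- sort(as.integer(e_end))
  # elements with start < q_end and end > q_start
  findInterval(q_end - 1L, ss) - findInterval(q_start, ee)
}

#' Per-position coverage counts over a chromosome
#'
#' @param len chromosome length.
#' @param e_start,e_end element intervals on the chromosome.
#' @return integer vector of length `len`: number of elements covering
#'   each position.
#' @keywords internal
position_coverage <- function(len, e_start, e_end) {
  if (!length(e_start)) return(integer(len))
  s <- pmax(as.integer(e_start), 0L) + 1L
  e <- pmin(as.integer(e_end), len) + 1L
  keep <- s < e
  delta <- tabulate(s[keep], nbins = len + 1L) -
    tabulate(e[keep], nbins = len + 1L)
  cumsum(delta)[seq_len(len)]
}
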