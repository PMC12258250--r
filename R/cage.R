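#' Call CAGE-like TSS peaks from coverage
#'
#' Derives TSS-proximal "CAGE-like" peaks from an RNA-Seq coverage
#' track using a three-step rule: (1) contiguous runs of coverage with
#' signal strictly above `min_signal` become candidate peaks; (2)
#' candidates within `merge_gap` nt of one another are merged; (3)
#' merged peaks with width not strictly greater than `min_width` are
#' dropped. The width filter runs after merging so that sub-threshold
#' fragments the merge step exists to join are not deleted first. A
#' merged peak's signal is the maximum (or, optionally, the sum) of its
#' members' values.
#'
#' @param coverage data frame from [read_bedgraph()] (`chrom`, `start`,
#'   `end`, `value`; non-overlapping).
#' @param min_width minimum peak width in nt, strict (`width >
#'   min_width`), default 10.
#' @param min_signal minimum signal, strict (`value > min_signal`),
#'   default 5.
#' @param merge_gap merge candidates separated by at most this many nt,
#'   default 10.
#' @param signal `"max"` (default) or `"sum"` aggregation for merged
#'   peaks.
#' @return a [genomic_intervals()] data frame of peaks with `value` =
#'   peak signal, class `c("cage_like_peaks", ...)`.
#' @export
call_cage_like_peaks <- function(coverage, min_width = 10L,
                                 min_signal = 5, merge_gap = 10L,
                                 signal = c("max", "sum")) {
  signal <- match.arg(signal)
  empty <- {
    x <- empty_intervals()
    x$value <- numeric(0)
    class(x) <- c("cage_like_peaks", class(x))
    x
  }
  if (is.null(coverage) || !nrow(coverage)) return(empty)
  cov <- coverage[coverage$value > min_signal, , drop = FALSE]
  if (!nrow(cov)) return(empty)
  cov <- cov[order(cov$chrom, cov$start), , drop = FALSE]
  out <- list()
  for (chr in unique(cov$chrom)) {
    cc <- cov[cov$chrom == chr, , drop = FALSE]
    # step 1: contiguous (bookended) above-threshold runs
    run_id <- cumsum(c(1L, as.integer(cc$start[-1] > cc$end[-nrow(cc)])))
    runs <- group_segments(cc$start, cc$end, cc$value, run_id, signal)
    # step 2: merge runs whose gap is <= merge_gap
    gap <- runs$start[-1] - runs$end[-nrow(runs)]
    peak_id <- cumsum(c(1L, as.integer(gap > merge_gap)))
    peaks <- group_segments(runs$start, runs$end, runs$value, peak_id,
                            signal)
    peaks$chrom <- chr
    out[[chr]] <- peaks
  }
  peaks <- do.call(rbind, out)
  # step 3: strict width filter after merging
  peaks <- peaks[peaks$end - peaks$start > min_width, , drop = FALSE]
  if (!nrow(peaks)) return(empty)
  res <- genomic_intervals(peaks$chrom, peaks$start, peaks$end,
                           value = peaks$value)
  class(res) <- c("cage_like_peaks", class(res))
  res
}

# collapse position-sorted segments by group id, preserving order
group_segments <- function(start, end, value, id, signal) {
  f <- factor(id, levels = unique(id))
  data.frame(
    start = as.integer(unname(tapply(start, f, min))),
    end = as.integer(unname(tapply(end, f, max))),
    value = if (signal == "max") as.numeric(unname(tapply(value, f, max)))
            else as.numeric(unname(tapply(value, f, sum))))
}

#' Associate CAGE-like peaks to transcript TSSs
#'
#' A peak is assigned to every transcript whose TSS lies within
#' `max_distance` nt of the peak's nearest edge (distance 0 when the
#' TSS falls inside the peak; "within" is read inclusively, so a TSS at
#' exactly `max_distance` is associated and one at `max_distance + 1`
#' is not). Peaks with no associated transcript are dropped.
#'
#' @param peaks a [call_cage_like_peaks()] result.
#' @param transcripts data frame from [read_transcripts()].
#' @param max_distance association distance in nt, default 50.
#' @return data frame with one row per (peak, transcript) association:
#'   `chrom`, `start`, `end`, `value`, `transcript_id`, `gene_id`,
#'   `distance`.
#' @export
associate_peaks_to_tss <- function(peaks, transcripts,
                                   max_distance = 50L) {
  if (!nrow(peaks) || !nrow(transcripts))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric(),
                      transcript_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    tx <- transcripts[transcripts$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(tx)) next
    d <- nearest_distance(tx$tss, tx$tss + 1L,
                          peaks$start[i], peaks$end[i])
    keep <- d <= max_distance
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = peaks$chrom[i], start = peaks$start[i], end = peaks$end[i],
      value = peaks$value[i], transcript_id = tx$transcript_id[keep],
      gene_id = tx$gene_id[keep], distance = d[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(associate_peaks_to_tss(peaks[0, , drop = FALSE], transcripts))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CAGE peak track from peak-transcript associations
#'
#' Converts [associate_peaks_to_tss()] output into the CAGE track format
#' consumed by [feature_tracks()] (`name` = gene id, `value` = signal).
#'
#' @param associations data frame from [associate_peaks_to_tss()].
#' @return a [genomic_intervals()] data frame.
#' @export
cage_track_from_associations <- function(associations) {
  if (!nrow(associations)) return(empty_intervals())
  genomic_intervals(associations$chrom, associations$start,
                    associations$end, value = associations$value,
                    name = associations$gene_id)
}
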