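#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased. Characters outside the unambiguous DNA
#' alphabet `{A,C,G,T,N}` are either mapped to `N` (`ambiguous = "map"`,
#' the default — scanners skip windows containing `N`) or rejected
#' (`ambiguous = "strict"`).
#'
#' @param path path to a FASTA file.
#' @param ambiguous `"map"` or `"strict"`.
#' @return named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path, ambiguous = c("map", "strict")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (!length(set)) stop("malformed FASTA '", path, "': no records")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs)))
    stop("malformed FASTA '", path, "': empty record '",
         names(seqs)[!nzchar(seqs)][1], "'")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (ambiguous == "strict") {
      ch <- regmatches(seqs[bad][1], regexpr("[^ACGTN]", seqs[bad][1]))
      stop(sprintf(
        "record '%s' contains non-ACGTN character '%s' (strict mode)",
        names(seqs)[bad][1], ch))
    }
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR flat text format: a `>` header per motif (matrix id
#' and TF name) followed by four labelled count rows, e.g.
#' `A [ 3 10 ... ]`. The motif's sequence count `S` is the column count
#' sum (columns must agree within rounding tolerance).
#'
#' @param path path to a JASPAR PFM file.
#' @return list of PFM records; each is a list with `tf_name`, `counts`
#'   (4 x L numeric matrix, rows A,C,G,T) and `n_sequences`.
#' @export
read_jaspar_pfms <- function(path) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("malformed JASPAR file '", path, "': no '>' header")
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4L)
      stop("malformed JASPAR record '", lines[heads[k]],
           "': expected 4 count rows, found ", length(block))
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    parts <- strsplit(hdr, "[\t ]+")[[1]]
    tf_name <- if (length(parts) >= 2L) parts[2] else parts[1]
    rows <- lapply(block, function(ln) {
      nuc <- toupper(substr(trimws(ln), 1L, 1L))
      nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (any(is.na(vals)))
        stop("malformed count row in motif '", tf_name, "': ", ln)
      list(nuc = nuc, vals = vals)
    })
    nucs <- vapply(rows, `[[`, "", "nuc")
    if (!setequal(nucs, c("A", "C", "G", "T")))
      stop("motif '", tf_name, "': count rows must be labelled A, C, G, T")
    lens <- vapply(rows, function(r) length(r$vals), 0L)
    if (length(unique(lens)) != 1L)
      stop("motif '", tf_name, "': row lengths differ (",
           paste(lens, collapse = ","), ")")
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- nucs
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(counts < 0)) stop("motif '", tf_name, "': negative counts")
    csums <- colSums(counts)
    if (max(csums) - min(csums) > 1 + 1e-6)
      stop("motif '", tf_name,
           "': column sums differ beyond rounding tolerance")
    out[[k]] <- pfm_record(tf_name, counts)
  }
  out
}

#' Construct a PFM record
#'
#' @param tf_name TF name.
#' @param counts 4 x L non-negative count matrix (rows A,C,G,T).
#' @param n_sequences motif sequence count S; defaults to the mean column
#'   sum.
#' @return a list of class `"pfm_record"`.
#' @export
pfm_record <- function(tf_name, counts, n_sequences = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    stop("PFM counts must be a 4 x L matrix with L >= 1")
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (is.null(n_sequences)) n_sequences <- mean(colSums(counts))
  structure(list(tf_name = tf_name, counts = counts,
                 n_sequences = n_sequences),
            class = "pfm_record")
}

#' @export
print.pfm_record <- function(x, ...) {
  cat("PFM", x$tf_name, "- length", ncol(x$counts),
      "- S =", format(x$n_sequences), "\n")
  print(x$counts)
  invisible(x)
}

#' Write PFM records in JASPAR format
#' @param pfms list of PFM records.
#' @param path output path.
#' @export
write_jaspar_pfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$tf_name, "\t", p$tf_name), con)
    for (nuc in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", nuc,
                         paste(format(p$counts[nuc, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a BED-style interval file
#'
#' 0-based half-open BED with at least 3 columns; column 4 is taken as a
#' name and column 5 as a numeric value (CAGE peak count, eQTL magnitude,
#' ChIP peak score ...) when present. Output is sorted by (chrom, start).
#'
#' @param path path to a BED file.
#' @param kind optional label recorded as an attribute (e.g. `"cage"`,
#'   `"atac"`).
#' @return a [genomic_intervals()] data frame.
#' @export
read_intervals <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("interval file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- empty_intervals()
    attr(out, "kind") <- kind
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d in '%s': fewer than 3 fields",
                 lineno[which(nf < 3L)[1]], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad))
    stop(sprintf("malformed BED line %d in '%s': invalid coordinates (%s)",
                 lineno[bad[1]], path, lines[bad[1]]))
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  value <- rep(NA_real_, length(lines))
  has5 <- nf >= 5L
  if (any(has5))
    value[has5] <- suppressWarnings(as.numeric(
      vapply(fields[has5], `[[`, "", 5L)))
  strand <- rep(".", length(lines))
  has6 <- nf >= 6L
  if (any(has6))
    strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  out <- genomic_intervals(chrom, start, end, strand,
                           value = if (any(has5)) value else NULL,
                           name = if (any(nf >= 4L)) name else NULL)
  attr(out, "kind") <- kind
  out
}

#' Write intervals as BED
#'
#' Round-trips with [read_intervals()]: (chrom, start, end, value) are
#' preserved exactly.
#'
#' @param intervals a [genomic_intervals()] data frame.
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  df <- as.data.frame(intervals)
  n <- nrow(df)
  name <- if (!is.null(df$name)) df$name else rep(".", n)
  name[is.na(name)] <- "."
  cols <- list(df$chrom, df$start, df$end, name)
  if (!is.null(df$value)) {
    val <- format(df$value, trim = TRUE, digits = 15)
    val[is.na(df$value)] <- "0"
    cols <- c(cols, list(val, df$strand))
  } else if (any(df$strand != ".")) {
    cols <- c(cols, list(rep("0", n), df$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read transcript models from GFF3/GTF
#'
#' Extracts transcript-level features and converts 1-based inclusive
#' coordinates to the internal 0-based convention. The TSS is the feature
#' start for `+` strand transcripts and the feature end for `-` strand
#' transcripts (0-based genomic position in both cases). Records lacking
#' a transcript identifier are skipped; the number skipped is reported as
#' a warning and stored in the `"n_skipped"` attribute.
#'
#' @param path path to a GFF3 or GTF file.
#' @param feature_types feature types treated as transcripts.
#' @return data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `tss`.
#' @export
read_transcripts <- function(path,
                             feature_types = c("transcript", "mRNA")) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type)) gr <- gr[as.character(md$type) %in% feature_types]
  md <- S4Vectors::mcols(gr)
  tid <- rep(NA_character_, length(gr))
  for (col in c("transcript_id", "ID", "Name")) {
    if (!is.null(md[[col]])) {
      v <- as.character(md[[col]])
      tid[is.na(tid) & !is.na(v) & nzchar(v)] <-
        v[is.na(tid) & !is.na(v) & nzchar(v)]
    }
  }
  gid <- if (!is.null(md$gene_id)) as.character(md$gene_id)
         else if (!is.null(md$Parent)) as.character(md$Parent)
         else tid
  keep <- !is.na(tid)
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(n_skipped, " transcript record(s) without an identifier skipped")
  gr <- gr[keep]; tid <- tid[keep]; gid <- gid[keep]
  start0 <- BiocGenerics::start(gr) - 1L   # 1-based inclusive -> 0-based
  end0 <- BiocGenerics::end(gr)            # inclusive -> exclusive
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-'")
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  out <- data.frame(transcript_id = tid, gene_id = gid,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = start0, end = end0, strand = strand,
                    tss = as.integer(tss), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write transcript models as GFF3
#'
#' Converts internal 0-based half-open coordinates back to 1-based
#' inclusive GFF3.
#'
#' @param transcripts data frame as returned by [read_transcripts()].
#' @param path output path.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf(
    "%s\ttfscan\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;transcript_id=%s;gene_id=%s",
    transcripts$chrom, transcripts$start + 1L, transcripts$end,
    transcripts$strand, transcripts$transcript_id,
    transcripts$transcript_id, transcripts$gene_id), con)
  invisible(path)
}

#' Read a 4-column bedGraph coverage file
#'
#' Segments must not overlap; zero-valued segments are dropped (adjacent
#' equal-valued segments are retained — merging is the peak caller's job).
#'
#' @param path path to a bedGraph file.
#' @return data frame with columns `chrom`, `start`, `end`, `value`,
#'   sorted by (chrom, start).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop(sprintf("malformed bedGraph line %d in '%s': need 4 fields",
                 lineno[which(lengths(fields) < 4L)[1]], path))
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end |
                 is.na(df$value) | df$value < 0)
  if (length(bad))
    stop(sprintf("malformed bedGraph line %d in '%s'", lineno[bad[1]], path))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  ov <- which(df$chrom[-1] == df$chrom[-nrow(df)] &
                df$start[-1] < df$end[-nrow(df)])
  if (length(ov))
    stop("overlapping bedGraph segments at ", df$chrom[ov[1] + 1L], ":",
         df$start[ov[1] + 1L])
  df <- df[df$value > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write coverage segments as bedGraph
#' @param segments data frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_bedgraph <- function(segments, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", segments$chrom,
                     as.integer(segments$start), as.integer(segments$end),
                     format(segments$value, trim = TRUE, digits = 15)),
             path)
  invisible(path)
}

#' Read a TF-gene expression correlation table
#'
#' Tab-delimited with columns `tf_name`, `gene_id`, `correlation` and an
#' optional fourth column of p-values (used for Bonferroni filtering at
#' table-build time, see [correlation_table()]).
#'
#' @param path path to the TSV (a header line is detected and skipped).
#' @return data frame with columns `tf_name`, `gene_id`, `correlation`
#'   (and `pvalue` when present).
#' @export
read_correlations <- function(path) {
  if (!file.exists(path)) stop("correlation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1, 3]))))
    df <- df[-1, , drop = FALSE]   # header line
  if (ncol(df) < 3L) stop("correlation table needs >= 3 columns")
  out <- data.frame(tf_name = as.character(df[[1]]),
                    gene_id = as.character(df[[2]]),
                    correlation = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$pvalue <- as.numeric(df[[4]])
  if (any(abs(out$correlation) > 1))
    stop("correlations must lie in [-1, 1]")
  rownames(out) <- NULL
  out
}
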