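#' Specification for a synthetic fixture
#'
#' Defines the study conditions every synthetic dataset is generated
#' under: a random genome of configurable GC content, evenly spaced
#' transcripts with room for 1,000 bp promoters, motif implants, and
#' feature tracks spatially enriched at implant sites. With enrichment
#' `e` for a feature, a fraction `e` of its elements is placed within
#' `radius` bp of a random implant and the remainder uniformly.
#'
#' @param seed integer seed; all generation is reproducible under it.
#' @param genome_length genome length in bp (default 100,000).
#' @param gc GC fraction (default 0.41, human-like).
#' @param n_transcripts number of transcripts (default 20).
#' @param chrom chromosome name.
#' @param pfm motif implanted and scanned; defaults to
#'   [default_test_pfm()].
#' @param enrichment named list of per-feature enrichment probabilities
#'   in `[0, 1]`.
#' @param radius enrichment radius in bp around implant centres
#'   (default 25).
#' @param n_elements named list of per-feature element counts.
#' @param element_width named list of per-feature element widths.
#' @param correlation_cutoff magnitude cutoff for the correlation table
#'   (default 0.3).
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 100000L, gc = 0.41,
                         n_transcripts = 20L, chrom = "chr1",
                         pfm = default_test_pfm(),
                         enrichment = list(cage = 0.8, metaclusters = 0.8,
                                           atac = 0.8, eqtl = 0.5,
                                           conservation = 0.8,
                                           correlation = 0.8),
                         radius = 25L,
                         n_elements = list(cage = 40L, metaclusters = 60L,
                                           atac = 40L, eqtl = 50L,
                                           conservation = 50L),
                         element_width = list(cage = 15L,
                                              metaclusters = 150L,
                                              atac = 200L, eqtl = 1L,
                                              conservation = 80L),
                         correlation_cutoff = 0.3) {
  stopifnot(genome_length >= 1000L, gc > 0, gc < 1,
            all(unlist(enrichment) >= 0), all(unlist(enrichment) <= 1))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length), gc = gc,
                 n_transcripts = as.integer(n_transcripts), chrom = chrom,
                 pfm = pfm, enrichment = enrichment,
                 radius = as.integer(radius), n_elements = n_elements,
                 element_width = element_width,
                 correlation_cutoff = correlation_cutoff),
            class = "fixture_spec")
}

#' A realistic test motif
#'
#' An 8-position PFM with one dominant base per position (default count
#' 85 of 100, the rest split evenly), giving roughly 1.1 bits of
#' information per position — typical of a well-defined JASPAR motif.
#'
#' @param consensus consensus sequence, default `"TGACGTCA"`.
#' @param tf_name TF name.
#' @param dominant count of the consensus base per column (of 100).
#' @return a [pfm_record()].
#' @export
default_test_pfm <- function(consensus = "TGACGTCA", tf_name = "TF1",
                             dominant = 85) {
  bases <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  other <- (100 - dominant) / 3
  counts <- matrix(other, nrow = 4L, ncol = length(bases),
                   dimnames = list(NUCS, NULL))
  counts[cbind(match(bases, NUCS), seq_along(bases))] <- dominant
  pfm_record(tf_name, counts, n_sequences = 100)
}

#' Generate a random genome with transcript annotations
#'
#' Nucleotides are i.i.d. at the spec's GC fraction. Transcripts are
#' evenly spaced on the `+` strand with TSSs placed so that every
#' transcript has room for a 1,000 bp promoter window.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `"synthetic_genome"`: `sequences` (named
#'   character vector), `lengths`, `transcripts` (as
#'   [read_transcripts()]), `spec`, `implants` (filled by
#'   [implant_motifs()]).
#' @export
generate_genome <- function(spec) {
  set.seed(spec$seed)
  n <- spec$genome_length
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
         T = (1 - spec$gc) / 2)
  seq <- paste(sample(NUCS, n, replace = TRUE, prob = p), collapse = "")
  k <- spec$n_transcripts
  tx <- if (k > 0L) {
    spacing <- (n - 2200L) %/% max(k, 1L)
    if (spacing < 1L)
      stop("genome too short for ", k, " transcripts with promoters")
    tss <- 1100L + spacing * (seq_len(k) - 1L)
    data.frame(transcript_id = sprintf("TX%04d", seq_len(k)),
               gene_id = sprintf("GENE%04d", seq_len(k)),
               chrom = spec$chrom, start = tss, end = tss + 1000L,
               strand = "+", tss = tss, stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), tss = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(sequences = stats::setNames(seq, spec$chrom),
                 lengths = stats::setNames(n, spec$chrom),
                 transcripts = tx, implants = NULL, spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic genome:", x$lengths, "bp,",
      nrow(x$transcripts), "transcript(s),",
      if (is.null(x$implants)) 0L else nrow(x$implants), "implant(s)\n")
  invisible(x)
}

#' Sample a motif instance from PFM column frequencies
#' @keywords internal
sample_motif_instance <- function(pfm) {
  freq <- sweep(pfm$counts, 2L, colSums(pfm$counts), "/")
  paste(vapply(seq_len(ncol(freq)), function(i)
    sample(NUCS, 1L, prob = freq[, i]), ""), collapse = "")
}

#' Implant motif instances into a synthetic genome
#'
#' Writes a consensus or PFM-sampled motif instance at each position
#' (0-based start of the implant); all other bases are unchanged.
#'
#' @param genome a [generate_genome()] result.
#' @param pfm the motif to implant; defaults to the spec's.
#' @param positions integer vector of non-overlapping 0-based start
#'   positions.
#' @param strand `"+"` (instances written as-is) or `"-"` (reverse
#'   complemented before writing).
#' @param instances `"sample"` (PFM-sampled, the default) or
#'   `"consensus"`.
#' @return the genome with modified `sequences` and an `implants` data
#'   frame (`chrom`, `start`, `end`, `strand`, `sequence`).
#' @export
implant_motifs <- function(genome, pfm = genome$spec$pfm, positions,
                           strand = "+",
                           instances = c("sample", "consensus")) {
  instances <- match.arg(instances)
  positions <- sort(as.integer(positions))
  L <- ncol(pfm$counts)
  if (length(positions) == 0L) return(genome)
  if (any(diff(positions) < L)) stop("overlapping implant positions")
  if (any(positions < 0L) ||
      any(positions + L > genome$lengths[[genome$spec$chrom]]))
    stop("implant position outside genome")
  seq <- genome$sequences[[genome$spec$chrom]]
  written <- character(length(positions))
  for (i in seq_along(positions)) {
    inst <- if (instances == "consensus")
      paste(NUCS[apply(pfm$counts, 2L, which.max)], collapse = "")
    else sample_motif_instance(pfm)
    written[i] <- inst
    put <- if (strand == "-") revcomp(inst) else inst
    substr(seq, positions[i] + 1L, positions[i] + L) <- put
  }
  genome$sequences[[genome$spec$chrom]] <- seq
  genome$implants <- rbind(
    genome$implants,
    data.frame(chrom = genome$spec$chrom, start = positions,
               end = positions + L, strand = strand, sequence = written,
               tf_name = pfm$tf_name, stringsAsFactors = FALSE))
  genome
}

# place n element start positions: fraction e within radius of a random
# implant centre, remainder uniform over the chromosome
place_elements <- function(n, width, enrich, implant_centers,
                           genome_length, radius) {
  n_near <- stats::rbinom(1L, n, enrich)
  if (!length(implant_centers)) n_near <- 0L
  near <- if (n_near > 0L) {
    ctr <- sample(implant_centers, n_near, replace = TRUE)
    ctr + sample(seq(-radius, radius), n_near, replace = TRUE)
  } else integer()
  unif <- if (n - n_near > 0L)
    sample.int(genome_length - width, n - n_near) - 1L else integer()
  starts <- c(near - width %/% 2L, unif)
  pmin(pmax(starts, 0L), genome_length - width)
}

#' Generate feature tracks enriched at implant sites
#'
#' Builds the full evidence-track bundle for a synthetic genome. Element
#' positions follow the spec's enrichment model; CAGE peaks carry
#' Poisson(20) counts and are associated to the gene whose TSS is
#' nearest; eQTL magnitudes are drawn as |Normal(0, 1)|; TF-gene
#' correlations are Uniform(-1, 1) filtered at the magnitude cutoff,
#' except that implanted promoters' (TF, gene) pairs receive a strong
#' correlation (|c| in 0.5-0.95) with the feature's enrichment
#' probability. Coverage (for the CAGE-like caller) is emitted as the
#' CAGE peaks' count profile.
#'
#' @param genome a [generate_genome()] result, after
#'   [implant_motifs()].
#' @param seed optional seed; defaults to `spec$seed + 1`.
#' @return list with `tracks` (a [feature_tracks()] bundle, tables
#'   built), `coverage` (bedGraph-style data frame) and `correlations`
#'   (raw pairs).
#' @export
generate_tracks <- function(genome, seed = genome$spec$seed + 1L) {
  set.seed(seed)
  spec <- genome$spec
  n <- spec$genome_length
  chrom <- spec$chrom
  imp <- genome$implants
  centers <- if (!is.null(imp)) (imp$start + imp$end) %/% 2L else integer()
  ew <- spec$element_width
  ne <- spec$n_elements
  e <- spec$enrichment

  mk <- function(feature, value = NULL, name = NULL) {
    starts <- place_elements(ne[[feature]], ew[[feature]], e[[feature]],
                             centers, n, spec$radius)
    genomic_intervals(chrom, starts, starts + ew[[feature]],
                      value = value, name = name)
  }

  cage_starts <- place_elements(ne$cage, ew$cage, e$cage, centers, n,
                                spec$radius)
  cage_counts <- stats::rpois(ne$cage, 20) + 1L
  tx <- genome$transcripts
  cage_gene <- if (nrow(tx)) tx$gene_id[vapply(cage_starts, function(s)
    which.min(abs(tx$tss - s)), 0L)] else NA_character_
  cage <- genomic_intervals(chrom, cage_starts, cage_starts + ew$cage,
                            value = cage_counts, name = cage_gene)

  metaclusters <- mk("metaclusters")
  atac <- mk("atac")
  eqtls <- mk("eqtl", value = abs(stats::rnorm(ne$eqtl)))
  conservation <- mk("conservation")

  # TF-gene correlations
  tf <- spec$pfm$tf_name
  implanted_genes <- if (!is.null(imp) && nrow(tx)) {
    unique(tx$gene_id[vapply(centers, function(ctr)
      which.min(abs(tx$tss - ctr)), 0L)])
  } else character()
  cors <- if (nrow(tx)) {
    cc <- stats::runif(nrow(tx), -1, 1)
    strong <- tx$gene_id %in% implanted_genes &
      stats::runif(nrow(tx)) < e$correlation
    cc[strong] <- sign(stats::runif(sum(strong), -1, 1) + 0.5) *
      stats::runif(sum(strong), 0.5, 0.95)
    data.frame(tf_name = tf, gene_id = tx$gene_id, correlation = cc,
               stringsAsFactors = FALSE)
  } else data.frame(tf_name = character(), gene_id = character(),
                    correlation = numeric(), stringsAsFactors = FALSE)
  cors <- cors[abs(cors$correlation) >= spec$correlation_cutoff, ,
               drop = FALSE]

  coverage <- if (nrow(cage))
    data.frame(chrom = chrom, start = cage$start, end = cage$end,
               value = as.numeric(cage$value))
  else data.frame(chrom = character(), start = integer(),
                  end = integer(), value = numeric())
  # coverage segments must not overlap: drop later overlapping peaks
  if (nrow(coverage) > 1L) {
    coverage <- coverage[order(coverage$start), , drop = FALSE]
    keep <- c(TRUE, coverage$start[-1] >=
                cummax(coverage$end[-nrow(coverage)]))
    coverage <- coverage[keep, , drop = FALSE]
  }

  tracks <- feature_tracks(
    cage = cage, metaclusters = metaclusters, atac = atac,
    eqtls = eqtls, conservation = conservation,
    correlations = correlation_table(cors,
                                     cutoff = spec$correlation_cutoff),
    genome_lengths = genome$lengths, sequences = genome$sequences)
  list(tracks = tracks, coverage = coverage, correlations = cors)
}

#' Generate a labelled benchmark fixture
#'
#' Builds a complete benchmark: a genome whose first `n_tp` transcripts
#' get one PFM-sampled motif implant at a fixed TSS-relative position,
#' feature tracks enriched at the implants, 50 bp true-positive regions
#' centred on the implants, and `n_tn` matched true negatives per TP
#' drawn with [sample_true_negatives()]. Also emits ranked ChIP-style
#' peaks (rank score = implant PWM score plus noise) for the
#' ChIP-Seq-protocol entry point.
#'
#' @param spec a [fixture_spec()]; `n_transcripts` bounds `n_tp`.
#' @param n_tp number of true positives (default 12).
#' @param n_tn true negatives per TP (default 50).
#' @param tp_width TP region width (default 50).
#' @param implant_offset implant start relative to the TSS (default
#'   -300).
#' @return list: `genome`, `tracks`, `sites` (TPs then TNs),
#'   `chip_peaks` (named list for [build_chipseq_benchmark()]), `spec`.
#' @export
generate_benchmark_fixture <- function(spec = fixture_spec(), n_tp = 12L,
                                       n_tn = 50L, tp_width = 50L,
                                       implant_offset = -300L) {
  if (n_tp > spec$n_transcripts)
    stop("n_tp exceeds the number of transcripts")
  genome <- generate_genome(spec)
  tx <- genome$transcripts
  L <- ncol(spec$pfm$counts)
  implant_pos <- tx$tss[seq_len(n_tp)] + implant_offset
  genome <- implant_motifs(genome, spec$pfm, implant_pos,
                           instances = "sample")
  tr <- generate_tracks(genome)

  imp <- genome$implants
  site_src <- genomic_intervals(imp$chrom, imp$start, imp$end,
                                name = tx$transcript_id[seq_len(n_tp)])
  tps <- make_true_positive_regions(site_src, width = tp_width,
                                    chrom_lengths = genome$lengths,
                                    tf_name = spec$pfm$tf_name)
  tns <- do.call(rbind, lapply(seq_len(nrow(tps)), function(i) {
    tss <- tx$tss[match(tps$anchor[i], tx$transcript_id)]
    bounds <- c(max(tss - 1500L, 0L),
                min(tss + 500L, spec$genome_length))
    sample_true_negatives(tps[i, ], bounds, n = n_tn, all_tp = tps,
                          seed = spec$seed + 100L + i)
  }))
  sites <- rbind(tps, tns)

  set.seed(spec$seed + 7L)
  pwm <- build_pwm(spec$pfm)
  rank_score <- vapply(imp$sequence, function(s) score_window(pwm, s),
                       0, USE.NAMES = FALSE) + stats::rnorm(nrow(imp), 0, 0.5)
  chip <- genomic_intervals(imp$chrom, pmax(imp$start - 40L, 0L),
                            imp$end + 40L, value = rank_score)
  list(genome = genome, tracks = tr$tracks, coverage = tr$coverage,
       sites = sites,
       chip_peaks = stats::setNames(list(chip), spec$pfm$tf_name),
       spec = spec)
}

#' Write a fixture to disk in standard formats
#'
#' Emits FASTA + GFF3 for the genome, BED for each interval track, TSV
#' for correlations, bedGraph for coverage, and a sidecar JSON recording
#' the generation parameters.
#'
#' @param genome a [generate_genome()] result.
#' @param tracks_bundle result of [generate_tracks()] (optional).
#' @param dir output directory (created).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture <- function(genome, tracks_bundle = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = write_fasta(genome$sequences, file.path(dir, "genome.fa")),
    gff = write_transcripts_gff3(genome$transcripts,
                                 file.path(dir, "transcripts.gff3")))
  if (!is.null(tracks_bundle)) {
    tr <- tracks_bundle$tracks
    for (feat in c("cage", "metaclusters", "atac", "eqtls",
                   "conservation")) {
      if (!is.null(tr[[feat]]) && nrow(tr[[feat]])) {
        f <- file.path(dir, paste0(feat, ".bed"))
        write_intervals(tr[[feat]], f)
        paths[feat] <- f
      }
    }
    if (!is.null(tracks_bundle$correlations) &&
        nrow(tracks_bundle$correlations)) {
      f <- file.path(dir, "correlations.tsv")
      utils::write.table(tracks_bundle$correlations, f, sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      paths["correlations"] <- f
    }
    if (!is.null(tracks_bundle$coverage) &&
        nrow(tracks_bundle$coverage)) {
      f <- file.path(dir, "coverage.bedgraph")
      write_bedgraph(tracks_bundle$coverage, f)
      paths["coverage"] <- f
    }
  }
  spec <- genome$spec
  prov <- list(seed = spec$seed, genome_length = spec$genome_length,
               gc = spec$gc, n_transcripts = spec$n_transcripts,
               enrichment = spec$enrichment, radius = spec$radius)
  jsonlite::write_json(prov, file.path(dir, "fixture.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths["provenance"] <- file.path(dir, "fixture.json")
  invisible(paths)
}
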