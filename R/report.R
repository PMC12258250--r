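#' Run configuration for a promoter analysis batch
#'
#' Mirrors the command-line parameters: transcript id list, optional TF
#' subset, promoter window before/after the TSS (defaults 900/100; a
#' negative value moves the corresponding boundary across the TSS), the
#' number of top TFs drawn in the figure (default 10), the PWM and
#' combined-score p-value cutoffs (defaults 0.01), and whether to emit
#' the figure.
#'
#' @param transcript_ids character vector of transcript ids to analyse.
#' @param tf_ids optional character vector restricting the PFM set.
#' @param promoter_before_tss,promoter_after_tss window extent
#'   (defaults 900/100).
#' @param top_x_tfs unique TFs drawn in the figure legend (default 10).
#' @param pval PWM p-value cutoff (default 0.01).
#' @param pvalc combined-score p-value cutoff (default 0.01).
#' @param nofig suppress the figure (default FALSE).
#' @param mode species mode name or [species_mode()].
#' @param seed integer seed recorded in outputs.
#' @param out_dir output directory.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(transcript_ids, tf_ids = NULL,
                       promoter_before_tss = 900L,
                       promoter_after_tss = 100L, top_x_tfs = 10L,
                       pval = 0.01, pvalc = 0.01, nofig = FALSE,
                       mode = "human", seed = 1L, out_dir = ".") {
  if (pval <= 0 || pval > 1 || pvalc <= 0 || pvalc > 1)
    stop("pval and pvalc must lie in (0, 1]")
  if (promoter_before_tss + promoter_after_tss <= 0)
    stop("promoter window is empty after sign resolution")
  structure(list(transcript_ids = transcript_ids, tf_ids = tf_ids,
                 promoter_before_tss = as.integer(promoter_before_tss),
                 promoter_after_tss = as.integer(promoter_after_tss),
                 top_x_tfs = as.integer(top_x_tfs), pval = pval,
                 pvalc = pvalc, nofig = isTRUE(nofig),
                 mode = mode, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# stable non-cryptographic hash of the configuration (out_dir excluded)
config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  fields <- vapply(keep, function(x) paste(format(x), collapse = ","), "")
  bytes <- as.integer(charToRaw(paste(names(fields), fields, sep = "=",
                                      collapse = ";")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%010d", h)
}

#' Analyse a batch of transcripts and write result artifacts
#'
#' For each transcript id: run [analyze_promoter()], write a results CSV
#' and JSON (plus an SVG track figure unless `nofig`). Unknown
#' transcript ids are logged and skipped; per-transcript failures do not
#' abort the batch.
#'
#' @param config a [run_config()].
#' @param sequences named character vector of chromosome sequences.
#' @param transcripts transcript table ([read_transcripts()]).
#' @param tracks a [feature_tracks()] bundle (or `NULL`).
#' @param pfms list of [pfm_record()]s.
#' @param background_scores optional [background_score_distribution()].
#' @return invisibly, a list per analysed transcript with elements
#'   `results`, `csv`, `json`, `figure` (NA when suppressed), plus a
#'   `log` data frame of skipped ids.
#' @export
run_analysis <- function(config, sequences, transcripts, tracks, pfms,
                         background_scores = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$tf_ids))
    pfms <- Filter(function(p) p$tf_name %in% config$tf_ids, pfms)
  out <- list()
  log <- data.frame(transcript_id = character(), status = character(),
                    stringsAsFactors = FALSE)
  for (tid in config$transcript_ids) {
    m <- match(tid, transcripts$transcript_id)
    if (is.na(m)) {
      log <- rbind(log, data.frame(transcript_id = tid,
                                   status = "unknown id; skipped"))
      next
    }
    res <- tryCatch(
      analyze_promoter(transcripts[m, ], sequences, tracks, pfms,
                       before_tss = config$promoter_before_tss,
                       after_tss = config$promoter_after_tss,
                       pval = config$pval, pvalc = config$pvalc,
                       mode = config$mode,
                       background_scores = background_scores),
      error = function(e) e)
    if (inherits(res, "error")) {
      log <- rbind(log, data.frame(transcript_id = tid,
                                   status = conditionMessage(res)))
      next
    }
    files <- emit_outputs(res, config, prefix = tid)
    fig <- NA_character_
    if (!config$nofig && nrow(res)) {
      fig <- file.path(config$out_dir, paste0(tid, "_tracks.svg"))
      render_track_figure(res, tracks, file = fig,
                          top_x_tfs = config$top_x_tfs)
    }
    log <- rbind(log, data.frame(transcript_id = tid, status = "ok"))
    out[[tid]] <- list(results = res, csv = files["csv"],
                       json = files["json"], figure = fig)
  }
  out$log <- log
  invisible(out)
}

#' Write a result table as CSV and JSON
#'
#' The CSV has the fixed leading columns `tf_name`, `start`, `end`,
#' `tss_start`, `strand`, `sequence`, then one column per active feature
#' score, then `combined_affinity` and `combined_pvalue`. The JSON
#' mirrors the rows and adds provenance (seed, config hash, window,
#' absent features).
#'
#' @param results a [analyze_promoter()] result.
#' @param config a [run_config()].
#' @param prefix file name prefix (default the transcript id).
#' @return named character vector with the `csv` and `json` paths.
#' @export
emit_outputs <- function(results, config, prefix = NULL) {
  if (is.null(prefix))
    prefix <- attr(results, "transcript_id") %||% "results"
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  features <- intersect(attr(results, "features") %||% FEATURES_HUMAN,
                        names(results))
  cols <- c("tf_name", "start", "end", "tss_start", "strand", "sequence",
            features, "combined_affinity", "combined_pvalue")
  df <- as.data.frame(results)[, cols, drop = FALSE]
  csv <- file.path(config$out_dir, paste0(prefix, "_results.csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  json <- file.path(config$out_dir, paste0(prefix, "_results.json"))
  payload <- list(
    provenance = list(
      transcript_id = attr(results, "transcript_id"),
      gene_id = attr(results, "gene_id"),
      window = as.list(attr(results, "window")),
      absent_features = attr(results, "absent_features"),
      seed = config$seed, config_hash = config_hash(config)),
    results = df)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  c(csv = csv, json = json)
}

#' Read a results JSON back into a data frame
#' @param path path written by [emit_outputs()].
#' @return list with `provenance` and `results`.
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render the promoter track figure
#'
#' A multi-panel SVG schematic of one promoter analysis: a colour-coded
#' legend of the top TFs, TFBS bars whose height is the combined
#' affinity score (positive y-axis = sense strand, negative =
#' antisense), then one panel each for conserved elements, the CpG
#' ratio line, eQTL lollipops signed by effect, metacluster bars, ATAC
#' bars and CAGE bars. The x-axis is TSS-relative. Empty panels are
#' rendered blank.
#'
#' @param results a [analyze_promoter()] result (non-empty).
#' @param tracks a [feature_tracks()] bundle (or `NULL`).
#' @param file output SVG path.
#' @param top_x_tfs number of unique TFs in the legend (default 10).
#' @return invisibly, the data frame of TFBS bars drawn (tf_name,
#'   tss_start, strand, height).
#' @export
render_track_figure <- function(results, tracks = NULL, file,
                                top_x_tfs = 10L) {
  if (!nrow(results)) stop("no results to draw")
  win <- attr(results, "window")
  tss <- win[["tss"]]
  xlim <- c(win[["start"]], win[["end"]]) - tss
  top_tfs <- unique(results$tf_name)[seq_len(min(top_x_tfs,
                                                 length(unique(results$tf_name))))]
  shown <- results[results$tf_name %in% top_tfs, , drop = FALSE]
  cols <- grDevices::rainbow(length(top_tfs))
  names(cols) <- top_tfs
  bars <- data.frame(tf_name = shown$tf_name,
                     tss_start = shown$tss_start, strand = shown$strand,
                     height = shown$combined_affinity,
                     stringsAsFactors = FALSE)

  grDevices::svg(file, width = 8, height = 9)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(7, 1), mar = c(1.5, 4, 1, 1),
                       oma = c(3, 0, 2, 0))
  on.exit(graphics::par(old), add = TRUE)

  # panel 1: TFBS bars, signed by strand
  ymax <- max(abs(bars$height), 1)
  graphics::plot(NA, xlim = xlim, ylim = c(-ymax, ymax), xlab = "",
                 ylab = "combined affinity", xaxt = "n")
  graphics::abline(h = 0, col = "grey")
  h <- ifelse(bars$strand == "+", bars$height, -bars$height)
  graphics::rect(bars$tss_start, pmin(0, h), bars$tss_start +
                   (shown$tss_end - shown$tss_start), pmax(0, h),
                 col = cols[bars$tf_name], border = NA)
  graphics::legend("topleft", legend = top_tfs, fill = cols, cex = 0.6,
                   ncol = min(5L, length(top_tfs)), bty = "n")

  panel_bars <- function(track, ylab, col = "grey30") {
    graphics::plot(NA, xlim = xlim, ylim = c(0, 1), xlab = "",
                   ylab = ylab, yaxt = "n", xaxt = "n")
    if (!is.null(track) && nrow(track)) {
      tr <- track[track$start - tss < xlim[2] &
                    track$end - tss > xlim[1], , drop = FALSE]
      if (nrow(tr))
        graphics::rect(tr$start - tss, 0.1, tr$end - tss, 0.9,
                       col = col, border = NA)
    }
  }
  panel_bars(tracks$conservation, "conserved", "black")

  # CpG score line over the window (per-hit CpG LLS at the hit centre)
  ytop <- if ("cpg" %in% names(shown)) max(shown$cpg, 1) else 1
  graphics::plot(NA, xlim = xlim, ylim = c(0, ytop), xlab = "",
                 ylab = "CpG (bits)", xaxt = "n")
  if (nrow(shown) && "cpg" %in% names(shown)) {
    o <- order(shown$tss_start)
    graphics::lines(shown$tss_start[o], shown$cpg[o], col = "red")
  }

  # eQTL lollipops signed by effect
  graphics::plot(NA, xlim = xlim, ylim = c(-1.2, 1.2), xlab = "",
                 ylab = "eQTL", xaxt = "n")
  graphics::abline(h = 0, col = "grey")
  if (!is.null(tracks$eqtls) && nrow(tracks$eqtls)) {
    eq <- tracks$eqtls[tracks$eqtls$start - tss < xlim[2] &
                         tracks$eqtls$end - tss > xlim[1], , drop = FALSE]
    if (nrow(eq)) {
      x <- eq$start - tss
      y <- pmax(pmin(eq$value, 1.2), -1.2)
      graphics::segments(x, 0, x, y,
                         col = ifelse(eq$value >= 0, "darkgreen", "red"))
      graphics::points(x, y, pch = 19, cex = 0.5,
                       col = ifelse(eq$value >= 0, "darkgreen", "red"))
    }
  }
  panel_bars(tracks$metaclusters, "metaclusters")
  panel_bars(tracks$atac, "ATAC")
  panel_bars(tracks$cage, "CAGE", "black")
  graphics::axis(1)
  graphics::mtext("position relative to TSS (nt)", side = 1, line = 2)
  graphics::mtext(paste0(attr(results, "transcript_id") %||% "",
                         " promoter"), outer = TRUE, line = 0.5)
  invisible(bars)
}
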