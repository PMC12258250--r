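NUCS <- c("A", "C", "G", "T")

#' Nucleotide background model
#'
#' Either explicit frequencies or background counts. With counts, the
#' frequency of each nucleotide is `(n_nuc + b) / (l_bg + b)` where
#' `n_nuc` is the nucleotide's count in the background sequence, `l_bg`
#' the background length and `b` the pseudocount — the same pseudocount
#' treatment as the PWM numerator. The default frequencies follow human
#' genome composition (A = T = 0.295, C = G = 0.205).
#'
#' @param freq named numeric vector of A,C,G,T frequencies.
#' @param counts optional named vector of A,C,G,T background counts;
#'   overrides `freq`.
#' @param length_bg background sequence length `l_bg` (required with
#'   `counts`).
#' @param pseudocount pseudocount `b` used with `counts`.
#' @return object of class `"background_model"` with element `freq`.
#' @export
background_model <- function(freq = c(A = 0.295, C = 0.205,
                                      G = 0.205, T = 0.295),
                             counts = NULL, length_bg = NULL,
                             pseudocount = 0.8) {
  if (!is.null(counts)) {
    counts <- counts[NUCS]
    if (any(is.na(counts))) stop("counts must be named A, C, G, T")
    if (is.null(length_bg)) length_bg <- sum(counts)
    freq <- (counts + pseudocount) / (length_bg + pseudocount)
    freq <- freq / sum(freq)
  }
  freq <- freq[NUCS]
  if (any(is.na(freq)) || any(freq <= 0) || any(freq >= 1))
    stop("background frequencies must be named A,C,G,T and lie in (0,1)")
  if (abs(sum(freq) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  structure(list(freq = freq), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("background model:",
      paste(sprintf("%s=%.4g", NUCS, x$freq), collapse = " "), "\n")
  invisible(x)
}

#' Build a position weight matrix from a PFM
#'
#' The weight of nucleotide `a` at motif position `i` is
#' \deqn{w(a,i) = \log_2 \frac{(a_i + b/4)/(S + b)}{p_{bg}(a)}}
#' where `a_i` is the count of `a` at position `i`, `S` the motif's
#' sequence count, `b` the pseudocount (default 0.8), and `p_bg` the
#' background frequency. A window's PWM score is the sum of its
#' per-position weights (bits).
#'
#' @param pfm a [pfm_record()].
#' @param background a [background_model()].
#' @param pseudocount pseudocount `b` (> 0), default 0.8.
#' @return object of class `"pwm"` with elements `tf_name`, `weights`
#'   (4 x L), `pseudocount`, `background`.
#' @export
build_pwm <- function(pfm, background = background_model(),
                      pseudocount = 0.8) {
  stopifnot(inherits(pfm, "pfm_record"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  L <- ncol(pfm$counts)
  if (L < 1L) stop("zero-length PFM")
  S <- pfm$n_sequences
  p <- (pfm$counts + pseudocount / 4) / (S + pseudocount)
  w <- log2(p / background$freq)
  if (any(!is.finite(w))) stop("non-finite PWM weights")
  dimnames(w) <- list(NUCS, NULL)
  structure(list(tf_name = pfm$tf_name, weights = w,
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$tf_name, "- length", ncol(x$weights),
      "- consensus", pwm_consensus(x), "\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Consensus sequence of a PWM (highest weight per column)
#' @param pwm a `"pwm"` object.
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(NUCS[apply(pwm$weights, 2L, which.max)], collapse = "")
}

encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], NUCS)
}

#' Reverse complement of a DNA string (N-preserving)
#' @param sequence character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(sequence) {
  vapply(sequence, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "",
                       fixed = TRUE)[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

#' Score a single window against a PWM
#'
#' @param pwm a `"pwm"` object.
#' @param window string of length equal to the motif length, A/C/G/T only.
#' @return score in bits; `NA` if the window contains `N` (the caller
#'   drops such windows).
#' @export
score_window <- function(pwm, window) {
  L <- ncol(pwm$weights)
  code <- encode_dna(window)
  if (length(code) != L)
    stop("window length ", length(code), " != motif length ", L)
  sum(pwm$weights[cbind(code, seq_len(L))])
}

# reverse-strand weight matrix: scoring the + strand sequence with this
# matrix equals scoring the reverse complement with the original
revcomp_weights <- function(w) {
  w[4:1, rev(seq_len(ncol(w))), drop = FALSE]
}

#' Exact PWM score distribution under the background model
#'
#' Per-position convolution of the four cell weights, each weighted by
#' its background frequency, discretised on a fixed-width score grid.
#' The result is the exact distribution of the PWM score of a random
#' background window (up to grid rounding).
#'
#' @param pwm a `"pwm"` object.
#' @param background background model; defaults to the PWM's own.
#' @param grid grid width in bits (default 1e-3).
#' @return object of class `"pwm_score_dist"`: `grid`, `offset` (integer
#'   grid index of the lowest atom), `prob` (atom masses) and `tail`
#'   (upper-tail sums, `tail[k] = P(X >= atom k)`).
#' @export
pwm_score_distribution <- function(pwm, background = pwm$background,
                                   grid = 1e-3) {
  w <- pwm$weights
  bg <- background$freq
  k <- round(w / grid)   # integer grid offsets per cell
  prob <- 1
  offset <- 0
  for (i in seq_len(ncol(w))) {
    ki <- k[, i]
    lo <- min(ki); hi <- max(ki)
    new <- numeric(length(prob) + (hi - lo))
    for (nuc in 1:4) {
      sh <- ki[nuc] - lo
      idx <- seq_along(prob) + sh
      new[idx] <- new[idx] + prob * bg[nuc]
    }
    prob <- new
    offset <- offset + lo
  }
  total <- sum(prob)
  if (abs(total - 1) > 1e-9) prob <- prob / total
  structure(list(grid = grid, offset = as.integer(offset), prob = prob,
                 tail = rev(cumsum(rev(prob))),
                 cell_index = matrix(as.integer(k), nrow = 4L,
                                     dimnames = dimnames(w))),
            class = "pwm_score_dist")
}

# tail probability at integer grid indices, clamped into (0, 1]
tail_at_index <- function(distribution, idx) {
  pos <- idx - distribution$offset + 1L
  n <- length(distribution$prob)
  p <- numeric(length(idx))
  p[pos <= 1L] <- 1
  mid <- pos > 1L & pos <= n
  p[mid] <- distribution$tail[pos[mid]]
  p[pos > n] <- distribution$tail[n]
  p
}

#' p-value of a PWM score
#'
#' `P(X >= score)` under the background score distribution; monotone
#' non-increasing in the score and always in (0, 1]. The score is
#' rounded onto the distribution's grid; [scan_sequence()] avoids even
#' this rounding by addressing each window's distribution atom through
#' the same per-position integer offsets the convolution uses.
#'
#' @param score numeric vector of scores (bits).
#' @param distribution a [pwm_score_distribution()] result.
#' @return numeric vector of p-values.
#' @export
pwm_pvalue <- function(score, distribution) {
  tail_at_index(distribution, round(score / distribution$grid))
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window of motif length on both strands is scored; windows
#' containing `N` are skipped. Hits with a PWM p-value at or below
#' `pvalue_threshold` are retained (both strands of the same position may
#' both be reported).
#'
#' @param pwm a `"pwm"` object.
#' @param sequence promoter sequence (A/C/G/T/N).
#' @param pvalue_threshold PWM p-value cutoff, default 0.01.
#' @param distribution optional precomputed [pwm_score_distribution()].
#' @return data frame of hits: `tf_name`, `start`, `end` (0-based
#'   half-open, sequence-relative), `strand`, `sequence` (motif-oriented),
#'   `pwm_score`, `pwm_pvalue`; sorted by position.
#' @export
scan_sequence <- function(pwm, sequence, pvalue_threshold = 0.01,
                          distribution = NULL) {
  L <- ncol(pwm$weights)
  code <- encode_dna(sequence)
  n <- length(code)
  empty <- data.frame(tf_name = character(), start = integer(),
                      end = integer(), strand = character(),
                      sequence = character(), pwm_score = numeric(),
                      pwm_pvalue = numeric(), stringsAsFactors = FALSE)
  if (n < L) {
    warning("sequence shorter than motif (", n, " < ", L, ")")
    return(empty)
  }
  if (is.null(distribution))
    distribution <- pwm_score_distribution(pwm)
  nw <- n - L + 1L
  w <- pwm$weights
  wrc <- revcomp_weights(w)
  k <- distribution$cell_index
  krc <- revcomp_weights(k)
  sc_f <- numeric(nw)
  sc_r <- numeric(nw)
  ix_f <- numeric(nw)
  ix_r <- numeric(nw)
  for (i in seq_len(L)) {
    idx <- code[i:(i + nw - 1L)]
    sc_f <- sc_f + w[cbind(idx, i)]
    sc_r <- sc_r + wrc[cbind(idx, i)]
    ix_f <- ix_f + k[cbind(idx, i)]
    ix_r <- ix_r + krc[cbind(idx, i)]
  }
  starts <- 0:(nw - 1L)
  hit_df <- function(sc, ix, strand) {
    ok <- !is.na(sc)
    pv <- tail_at_index(distribution, ix[ok])
    keep <- pv <= pvalue_threshold
    st <- starts[ok][keep]
    seqs <- if (length(st)) substring(sequence, st + 1L, st + L)
            else character()
    if (strand == "-") seqs <- revcomp(seqs)
    data.frame(tf_name = rep(pwm$tf_name, sum(keep)), start = st,
               end = st + L, strand = rep(strand, sum(keep)),
               sequence = seqs, pwm_score = sc[ok][keep],
               pwm_pvalue = pv[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(hit_df(sc_f, ix_f, "+"), hit_df(sc_r, ix_r, "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
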