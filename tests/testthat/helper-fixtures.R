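# shared helpers for building tiny in-code fixtures

# a short, fully specified PFM for exact arithmetic checks
toy_pfm <- function(L = 3L, tf_name = "TOY") {
  counts <- matrix(c(3, 1, 0, 0,
                     0, 0, 2, 2,
                     1, 1, 1, 1), nrow = 4L)[, seq_len(L), drop = FALSE]
  pfm_record(tf_name, counts)
}

uniform_bg <- function() background_model(c(A = .25, C = .25,
                                            G = .25, T = .25))

# brute-force oracle: score every 4^L window of a PWM
enumerate_windows <- function(L) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L))
  apply(g, 1L, paste, collapse = "")
}

# enumerates all 4^L windows; `score` is the exact bit score, and
# `grid_score` the score after per-cell rounding onto the p-value grid
# (the same convention the score-distribution convolution uses)
brute_force_distribution <- function(pwm, bg = pwm$background,
                                     grid = 1e-3) {
  wins <- enumerate_windows(ncol(pwm$weights))
  k <- round(pwm$weights / grid)
  scores <- vapply(wins, function(w) score_window(pwm, w), 0)
  grid_scores <- vapply(wins, function(w) {
    code <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    sum(k[cbind(code, seq_along(code))]) * grid
  }, 0)
  probs <- vapply(wins, function(w) {
    prod(bg$freq[strsplit(w, "")[[1]]])
  }, 0)
  data.frame(window = wins, score = scores, grid_score = grid_scores,
             prob = probs, stringsAsFactors = FALSE)
}

brute_force_pvalue <- function(bf, window) {
  q <- bf$grid_score[bf$window == window]
  sum(bf$prob[bf$grid_score >= q - 1e-9])
}

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
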