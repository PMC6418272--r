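# Independent reference implementations used as oracles.  These are written
# naively (per-unit loops, textbook formulas) on purpose: they share no code
# with the package internals they check.

# --- interactive-activation dynamics, unit by unit ------------------------

# words: character vector; freqs: numeric; stimulus: string; p: model_params
# Returns list(words = (n_cycles+1) x n_words, letters = (n_cycles+1) x n_units)
naive_ia <- function(words, freqs, alphabet, stimulus, p, n_cycles) {
  n_w <- length(words)
  n_pos <- max(nchar(words))
  n_a <- length(alphabet)
  wchars <- strsplit(words, "")
  schars <- strsplit(stimulus, "")[[1]]

  logf <- log10(freqs + 1)
  spread <- max(logf) - min(logf)
  rest_w <- if (spread == 0) rep(p$rest_range[2], n_w) else
    p$rest_range[1] + (logf - min(logf)) / spread *
      (p$rest_range[2] - p$rest_range[1])

  lidx <- function(pos, a) (pos - 1L) * n_a + match(a, alphabet)
  act_l <- rep(0, n_pos * n_a)
  act_w <- rest_w
  L_hist <- matrix(0, n_cycles + 1L, n_pos * n_a)
  W_hist <- matrix(0, n_cycles + 1L, n_w)
  L_hist[1L, ] <- act_l
  W_hist[1L, ] <- act_w

  upd <- function(a, net, rest) {
    d <- if (net > 0) net * (p$a_max - a) else net * (a - p$a_min)
    min(max(a + d - p$decay * (a - rest), p$a_min), p$a_max)
  }

  for (cyc in seq_len(n_cycles)) {
    lp <- pmax(act_l, 0)
    wp <- pmax(act_w, 0)
    new_w <- numeric(n_w)
    for (w in seq_len(n_w)) {
      net <- 0
      for (pos in seq_along(wchars[[w]])) {
        own <- lidx(pos, wchars[[w]][pos])
        for (a in seq_len(n_a)) {
          u <- (pos - 1L) * n_a + a
          net <- net + if (u == own) p$excite_letter_word * lp[u] else
            -p$inhibit_letter_word * lp[u]
        }
      }
      for (v in seq_len(n_w)) {
        if (v != w) net <- net - p$inhibit_word_word * wp[v]
      }
      new_w[w] <- upd(act_w[w], net, rest_w[w])
    }
    new_l <- numeric(n_pos * n_a)
    for (pos in seq_len(n_pos)) {
      for (a in seq_len(n_a)) {
        u <- (pos - 1L) * n_a + a
        net <- 0
        if (pos <= length(schars) && schars[pos] == alphabet[a]) {
          net <- net + p$input_clamp
        }
        for (w in seq_len(n_w)) {
          if (pos <= length(wchars[[w]]) && wchars[[w]][pos] == alphabet[a]) {
            net <- net + p$feedback_word_letter * wp[w]
          }
        }
        new_l[u] <- upd(act_l[u], net, 0)
      }
    }
    act_w <- new_w
    act_l <- new_l
    W_hist[cyc + 1L, ] <- act_w
    L_hist[cyc + 1L, ] <- act_l
  }
  list(words = W_hist, letters = L_hist)
}

# --- orthographic measures by brute enumeration ---------------------------

naive_ortho <- function(target, words, freqs, target_freq = 0) {
  tch <- strsplit(target, "")[[1]]
  nb <- character(0); nbf <- numeric(0)
  for (i in seq_along(words)) {
    w <- words[i]
    if (w == target || nchar(w) != length(tch)) next
    wch <- strsplit(w, "")[[1]]
    if (sum(wch != tch) == 1L) { nb <- c(nb, w); nbf <- c(nbf, freqs[i]) }
  }
  tbi <- unique(vapply(seq_len(length(tch) - 1L),
                       function(i) paste0(tch[i], tch[i + 1L]), ""))
  bic <- 0L; bif <- 0; bin <- 0L
  for (i in seq_along(words)) {
    w <- words[i]
    if (w == target) next
    wch <- strsplit(w, "")[[1]]
    hits <- 0L
    if (length(wch) >= 2L) {
      for (j in seq_len(length(wch) - 1L)) {
        if (paste0(wch[j], wch[j + 1L]) %in% tbi) hits <- hits + 1L
      }
    }
    if (hits > 0L) { bic <- bic + hits; bif <- bif + freqs[i]; bin <- bin + 1L }
  }
  list(N = length(nb), FN = sum(nbf), NHF = sum(nbf > target_freq),
       FHN = sum(nbf[nbf > target_freq]), BiC = bic, BiF = bif, BiN = bin)
}

# --- repeated-measures sums of squares by cell-mean loops -----------------

# y: array n_subj x 2 x 3 (subject, lexicality, level)
brute_rm_anova <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  gm <- mean(y)
  SSa <- 0; for (i in 1:a) SSa <- SSa + b * n * (mean(y[, i, ]) - gm)^2
  SSb <- 0; for (j in 1:b) SSb <- SSb + a * n * (mean(y[, , j]) - gm)^2
  SSs <- 0; for (s in 1:n) SSs <- SSs + a * b * (mean(y[s, , ]) - gm)^2
  SSab <- 0
  for (i in 1:a) for (j in 1:b) {
    SSab <- SSab + n * (mean(y[, i, j]) - mean(y[, i, ]) - mean(y[, , j]) + gm)^2
  }
  SSas <- 0
  for (s in 1:n) for (i in 1:a) {
    SSas <- SSas + b * (mean(y[s, i, ]) - mean(y[s, , ]) - mean(y[, i, ]) + gm)^2
  }
  SSbs <- 0
  for (s in 1:n) for (j in 1:b) {
    SSbs <- SSbs + a * (mean(y[s, , j]) - mean(y[s, , ]) - mean(y[, , j]) + gm)^2
  }
  SStot <- sum((y - gm)^2)
  SSabs <- SStot - SSa - SSb - SSs - SSab - SSas - SSbs
  Fa <- (SSa / (a - 1)) / (SSas / ((a - 1) * (n - 1)))
  Fb <- (SSb / (b - 1)) / (SSbs / ((b - 1) * (n - 1)))
  Fab <- (SSab / ((a - 1) * (b - 1))) / (SSabs / ((a - 1) * (b - 1) * (n - 1)))
  list(SSa = SSa, SSb = SSb, SSab = SSab, Fa = Fa, Fb = Fb, Fab = Fab)
}

# single-df polynomial contrast via per-subject scores, from first principles
brute_contrast <- function(y, weights, slice = NULL) {
  # slice: 1 (word), 2 (nonword) or NULL (pooled over lexicality)
  n <- dim(y)[1]
  scores <- numeric(n)
  for (s in 1:n) {
    m <- numeric(3)
    for (j in 1:3) {
      m[j] <- if (is.null(slice)) mean(y[s, , j]) else y[s, slice, j]
    }
    scores[s] <- sum(weights * m)
  }
  tt <- stats::t.test(scores)
  list(F = unname(tt$statistic)^2, p = tt$p.value, df2 = n - 1)
}

# --- misc ------------------------------------------------------------------

random_micro_lexicon <- function(n_words, len_range = c(3L, 5L),
                                 alphabet = letters[1:8]) {
  words <- character(0)
  while (length(words) < n_words) {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    w <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
    if (!(w %in% words)) words <- c(words, w)
  }
  lexicon(words, stats::runif(n_words, 0, 500), length_bounds = len_range,
          alphabet = alphabet)
}

rst_to_array <- function(tab) {
  subj <- sort(unique(tab$subject))
  y <- array(NA_real_, c(length(subj), 2, 3))
  for (r in seq_len(nrow(tab))) {
    y[match(tab$subject[r], subj),
      match(as.character(tab$lexicality[r]), c("word", "nonword")),
      match(as.character(tab$level[r]), c("low", "medium", "high"))] <-
      tab$value[r]
  }
  y
}
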