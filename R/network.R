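# Interactive-activation network: position-specific letter units feeding
# word units, with lateral inhibition among words, word-to-letter feedback,
# decay toward resting level and hard activation bounds.  Updates are
# synchronous; only units with positive activation transmit.  The engine is
# batched over stimuli (one column per trial), since the dynamics of
# different stimuli never interact.

#' Model parameters for the interactive-activation / multiple read-out model
#'
#' Connection gains, activation bounds, the GLA window and the three
#' read-out criteria. All gains are per-sender and apply to the positive
#' part of the sender's activation.
#'
#' @param excite_letter_word Gain from a word's own letter-at-position units.
#' @param inhibit_letter_word Gain from all other letter units at the word's
#'   positions.
#' @param inhibit_word_word Lateral inhibition gain between distinct words.
#' @param feedback_word_letter Gain from a word back to its own letters.
#' @param decay Decay rate toward resting level.
#' @param a_max,a_min Hard activation bounds, `a_min < 0 <= a_max`.
#' @param rest_range Word resting levels: `c(most_negative, 0)`. Log
#'   frequency is mapped linearly onto this range, the most frequent word
#'   resting at the top (0).
#' @param input_clamp External evidence added to the net input of the
#'   stimulus letter at each position.
#' @param gla_cycles Width of the GLA averaging window (cycles 1..window,
#'   cycle 0 being rest).
#' @param m_criterion Word-unit identification threshold (M criterion).
#' @param s_base Baseline summed-activity threshold for the fast-guess S
#'   criterion.
#' @param s_gain,s_min S is lowered by `s_gain` times early global activity,
#'   floored at `s_min`.
#' @param t_base Baseline temporal deadline in cycles (T criterion).
#' @param t_gain The deadline is delayed by `t_gain` times early global
#'   activity.
#' @param adjust_cycle Cycle at which global activity is read to adjust S
#'   and T.
#' @return Object of class `model_params` (named list).
#' @export
model_params <- function(excite_letter_word = 0.07,
                         inhibit_letter_word = 0.04,
                         inhibit_word_word = 0.21,
                         feedback_word_letter = 0.30,
                         decay = 0.07,
                         a_max = 1.0,
                         a_min = -1.0,
                         rest_range = c(-0.92, 0),
                         input_clamp = 1.0,
                         gla_cycles = 7L,
                         m_criterion = 0.55,
                         s_base = 1.5,
                         s_gain = 1.5,
                         s_min = 0.4,
                         t_base = 18L,
                         t_gain = 15,
                         adjust_cycle = 7L) {
  p <- list(excite_letter_word = excite_letter_word,
            inhibit_letter_word = inhibit_letter_word,
            inhibit_word_word = inhibit_word_word,
            feedback_word_letter = feedback_word_letter,
            decay = decay, a_max = a_max, a_min = a_min,
            rest_range = as.numeric(rest_range),
            input_clamp = input_clamp,
            gla_cycles = as.integer(gla_cycles),
            m_criterion = m_criterion,
            s_base = s_base, s_gain = s_gain, s_min = s_min,
            t_base = as.integer(t_base), t_gain = t_gain,
            adjust_cycle = as.integer(adjust_cycle))
  gains <- c("excite_letter_word", "inhibit_letter_word", "inhibit_word_word",
             "feedback_word_letter", "decay")
  stopifnot(all(unlist(p[gains]) >= 0),
            p$a_min < 0, p$a_max > 0,
            p$rest_range[1] <= p$rest_range[2], p$rest_range[2] <= 0,
            p$rest_range[1] > p$a_min || isTRUE(all.equal(p$rest_range[1], p$a_min)),
            p$m_criterion >= 0, p$m_criterion <= p$a_max,
            p$gla_cycles >= 1L, p$t_base >= 1L, p$adjust_cycle >= 1L)
  structure(p, class = "model_params")
}

#' Build an interactive-activation network over a lexicon
#'
#' Creates position-specific letter units (position x alphabet) and one unit
#' per lexicon word. A word of length L connects to positions 1..L:
#' excitation from its own letter-at-position units, inhibition from all
#' other letters at those positions; word-word connections are mutually
#' inhibitory. Word resting levels are a linear map of log frequency onto
#' `params$rest_range`, the most frequent word resting at 0 (a single word,
#' or all-equal frequencies, rest at 0).
#'
#' @param lex A [lexicon].
#' @param params A [model_params] object.
#' @return Object of class `ia_network`.
#' @export
build_network <- function(lex, params = model_params()) {
  stopifnot(inherits(lex, "lexicon"), nrow(lex) >= 1L,
            inherits(params, "model_params"))
  alphabet <- attr(lex, "alphabet")
  n_a <- length(alphabet)
  n_pos <- max(nchar(lex$word))
  n_units <- n_pos * n_a
  n_w <- nrow(lex)

  # own-letter incidence: word w has letter a at position p
  M <- matrix(0, n_w, n_units)
  chars <- strsplit(lex$word, "", fixed = TRUE)
  for (w in seq_len(n_w)) {
    a_idx <- match(chars[[w]], alphabet)
    M[w, (seq_along(a_idx) - 1L) * n_a + a_idx] <- 1
  }
  # position usage: word w spans positions 1..len
  lens <- nchar(lex$word)
  Pm <- outer(lens, seq_len(n_pos), ">=") * 1

  logf <- log_frequency(lex$freq_per_million)
  spread <- max(logf) - min(logf)
  rest <- if (spread == 0) {
    rep(params$rest_range[2], n_w)
  } else {
    params$rest_range[1] +
      (logf - min(logf)) / spread * diff(params$rest_range)
  }

  structure(list(lexicon = lex, params = params, alphabet = alphabet,
                 n_pos = n_pos, n_alpha = n_a, n_units = n_units,
                 own = M, pos_mask = Pm, word_rest = rest),
            class = "ia_network")
}

#' @export
print.ia_network <- function(x, ...) {
  cat(sprintf(
    "<ia_network> %d word units, %d letter units (%d positions x %d letters)\n",
    nrow(x$lexicon), x$n_units, x$n_pos, x$n_alpha))
  invisible(x)
}

# Encode stimuli as clamp matrices (n_units x n_trials): input_clamp at the
# stimulus letter of each occupied position, 0 elsewhere.
stimulus_clamp <- function(stimuli, net) {
  stimuli <- tolower(stimuli)
  C <- matrix(0, net$n_units, length(stimuli))
  for (i in seq_along(stimuli)) {
    ch <- strsplit(stimuli[i], "", fixed = TRUE)[[1]]
    if (length(ch) > net$n_pos) {
      stop("stimulus longer than the network's position channels: ",
           stimuli[i])
    }
    a_idx <- match(ch, net$alphabet)
    if (anyNA(a_idx)) {
      stop("stimulus letter outside the network alphabet: ", stimuli[i])
    }
    C[(seq_along(a_idx) - 1L) * net$n_alpha + a_idx, i] <- net$params$input_clamp
  }
  C
}

# Core synchronous cycle engine, batched over trials.  Returns final state
# or, with keep_trace, the full per-cycle history.
ia_run <- function(net, clamp, n_cycles, keep_trace = FALSE) {
  p <- net$params
  n_tr <- ncol(clamp)
  Lact <- matrix(0, net$n_units, n_tr)              # letters rest at 0
  Wact <- matrix(net$word_rest, nrow(net$lexicon), n_tr)
  # per-position letter sums: rows of this indicator pick one position block
  posrow <- rep(seq_len(net$n_pos), each = net$n_alpha)
  if (keep_trace) {
    Ltr <- array(0, c(n_cycles + 1L, net$n_units, n_tr))
    Wtr <- array(0, c(n_cycles + 1L, nrow(net$lexicon), n_tr))
    Ltr[1L, , ] <- Lact
    Wtr[1L, , ] <- Wact
  }
  word_sum_pos <- matrix(0, n_cycles, n_tr)  # summed positive word activity
  word_max <- matrix(-Inf, n_cycles, n_tr)
  e <- p$excite_letter_word; i_lw <- p$inhibit_letter_word
  ww <- p$inhibit_word_word; fb <- p$feedback_word_letter
  for (cyc in seq_len(n_cycles)) {
    Lp <- pmax(Lact, 0)
    Wp <- pmax(Wact, 0)
    pos_sum <- rowsum(Lp, posrow, reorder = TRUE)   # n_pos x n_tr
    wsum <- colSums(Wp)
    net_w <- (e + i_lw) * (net$own %*% Lp) -
      i_lw * (net$pos_mask %*% pos_sum) -
      ww * sweep(-Wp, 2L, wsum, `+`, check.margin = FALSE)
    net_l <- clamp + fb * crossprod(net$own, Wp)
    Wact <- ia_step(Wact, net_w, net$word_rest, p)
    Lact <- ia_step(Lact, net_l, 0, p)
    if (keep_trace) {
      Ltr[cyc + 1L, , ] <- Lact
      Wtr[cyc + 1L, , ] <- Wact
    }
    word_sum_pos[cyc, ] <- colSums(pmax(Wact, 0))
    word_max[cyc, ] <- apply(Wact, 2L, max)
  }
  out <- list(word_sum_pos = word_sum_pos, word_max = word_max,
              letters = Lact, words = Wact)
  if (keep_trace) {
    out$letter_trace <- Ltr
    out$word_trace <- Wtr
  }
  out
}

#' One activation update of the interactive-activation rule
#'
#' The per-cycle update applied to every unit: shunting growth toward
#' `a_max` when the net input is positive (`net * (a_max - a)`), shunting
#' suppression toward `a_min` otherwise (`net * (a - a_min)`), decay toward
#' the resting level, then hard clipping to `[a_min, a_max]`. Exposed so the
#' single-unit fixed point `a* = (n * a_max + decay * rest) / (n + decay)`
#' under constant positive input `n` can be inspected directly.
#'
#' @param a Current activation(s).
#' @param net_in Net input(s).
#' @param rest Resting level(s).
#' @param params A [model_params] object (uses `a_max`, `a_min`, `decay`).
#' @return Updated activation(s), clipped to the bounds.
#' @export
activation_update <- function(a, net_in, rest, params) {
  ia_step(a, net_in, rest, params)
}

# One synchronous update of a unit bank: shunting toward the bound the net
# input points at, decay toward rest, then hard clipping.
ia_step <- function(a, net_in, rest, p) {
  up <- net_in > 0
  delta <- ifelse(up,
                  net_in * (p$a_max - a),
                  net_in * (a - p$a_min)) - p$decay * (a - rest)
  pmin(pmax(a + delta, p$a_min), p$a_max)
}

#' Run one stimulus presentation and record the activation trace
#'
#' Cycle 0 is the resting state; each subsequent cycle applies the
#' synchronous interactive-activation update with the stimulus letters
#' clamped at their position channels.
#'
#' @param stimulus Letter string (letters must be in the network alphabet).
#' @param net An [ia_network].
#' @param n_cycles Number of update cycles, >= 1.
#' @return Object of class `activation_trace` with elements `stimulus`,
#'   `letters` (cycles+1 x letter units), `words` (cycles+1 x word units)
#'   and `params`.
#' @export
run_trial <- function(stimulus, net, n_cycles = net$params$gla_cycles) {
  stopifnot(inherits(net, "ia_network"), n_cycles >= 1L)
  clamp <- stimulus_clamp(stimulus, net)
  res <- ia_run(net, clamp, n_cycles, keep_trace = TRUE)
  structure(list(stimulus = tolower(stimulus),
                 letters = matrix(res$letter_trace[, , 1L],
                                  ncol = net$n_units),
                 words = matrix(res$word_trace[, , 1L],
                                ncol = nrow(net$lexicon)),
                 params = net$params,
                 word_labels = net$lexicon$word),
            class = "activation_trace")
}

#' @export
print.activation_trace <- function(x, ...) {
  cat(sprintf("<activation_trace> '%s': %d cycles, %d word units\n",
              x$stimulus, nrow(x$words) - 1L, ncol(x$words)))
  invisible(x)
}
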