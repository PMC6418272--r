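# Global lexical activity (GLA) and the multiple read-out lexical decision.
# GLA is the mean, over the first `window` processing cycles, of the summed
# positive activation of all word units: a scalar word-likeness /
# familiarity estimate for any letter string.

#' Global lexical activity of a recorded trace
#'
#' Mean over cycles `1..window` (cycle 0 is rest and excluded) of the sum
#' over word units of the positive part of activation.
#'
#' @param trace An [run_trial()] `activation_trace`.
#' @param window Averaging window in cycles; must not exceed the trace
#'   length.
#' @return Non-negative scalar.
#' @export
global_lexical_activity <- function(trace, window = 7L) {
  stopifnot(inherits(trace, "activation_trace"), window >= 1L)
  n_cycles <- nrow(trace$words) - 1L
  if (window > n_cycles) {
    stop("window (", window, ") exceeds trace length (", n_cycles, ")")
  }
  W <- trace$words[1L + seq_len(window), , drop = FALSE]
  mean(rowSums(pmax(W, 0)))
}

#' Batched GLA for many stimuli
#'
#' Runs the network once per stimulus (vectorised across stimuli) and
#' returns the raw GLA of each. Identical to
#' `global_lexical_activity(run_trial(s, net, window), window)` for every
#' stimulus, but orders of magnitude faster for large stimulus sets.
#'
#' @param stimuli Character vector.
#' @param net An [ia_network].
#' @param window GLA window in cycles (default: the network's `gla_cycles`).
#' @return Numeric vector of raw GLA values, one per stimulus.
#' @export
compute_gla <- function(stimuli, net, window = net$params$gla_cycles) {
  stopifnot(inherits(net, "ia_network"), window >= 1L)
  clamp <- stimulus_clamp(stimuli, net)
  res <- ia_run(net, clamp, n_cycles = window, keep_trace = FALSE)
  colMeans(res$word_sum_pos[seq_len(window), , drop = FALSE])
}

#' z-transform a vector of values
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation. The
#' population over which GLA is standardised is the full candidate pool
#' (words and nonwords jointly) unless the caller splits it.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
z_transform <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero spread: cannot z-transform")
  (values - mean(values)) / s
}

#' GLA table for a stimulus set
#'
#' Computes raw and z-scored GLA for a set of stimuli against a lexicon.
#' z-scores are taken over the full set by default (`z_by_lexicality =
#' FALSE`), i.e. words and nonwords share one standardisation.
#'
#' @param stimuli Character vector.
#' @param lex A [lexicon] (used both as the network's word layer and to
#'   label lexicality).
#' @param params [model_params].
#' @param window GLA window.
#' @param z_by_lexicality Standardise within each lexicality instead of
#'   jointly.
#' @return Data frame with columns `stimulus`, `lexicality`, `GLA`, `GLAz`.
#' @export
gla_table <- function(stimuli, lex, params = model_params(),
                      window = params$gla_cycles, z_by_lexicality = FALSE) {
  net <- build_network(lex, params)
  gla <- compute_gla(stimuli, net, window)
  lexicality <- ifelse(tolower(stimuli) %in% lex$word, "word", "nonword")
  z <- if (z_by_lexicality) {
    stats::ave(gla, lexicality, FUN = z_transform)
  } else {
    z_transform(gla)
  }
  data.frame(stimulus = tolower(stimuli), lexicality = lexicality,
             GLA = gla, GLAz = z, stringsAsFactors = FALSE)
}

#' Simulate one lexical decision with the multiple read-out criteria
#'
#' Runs the network on a stimulus and reads out a YES/NO decision from
#' three criteria checked in order at every cycle:
#' \describe{
#'   \item{M}{any word unit's activation reaches `m_criterion` -> YES
#'     (identification).}
#'   \item{S}{instantaneous summed positive word activity reaches the
#'     adjusted threshold -> YES (fast guess by familiarity).}
#'   \item{T}{the adjusted temporal deadline expires -> NO.}
#' }
#' At cycle `adjust_cycle` the early global activity g is read; the deadline
#' becomes `round(t_base + t_gain * g)` (high familiarity delays the
#' deadline) and the fast-guess threshold becomes
#' `max(s_min, s_base - s_gain * g)` (high familiarity lowers it).
#'
#' @param stimulus Letter string.
#' @param net An [ia_network].
#' @return Object of class `decision_outcome`: list with `response`
#'   ("YES"/"NO"), `rt_cycles`, `criterion` ("M"/"S"/"T"), `gla_at_adjust`.
#' @export
simulate_lexical_decision <- function(stimulus, net) {
  stopifnot(inherits(net, "ia_network"))
  p <- net$params
  clamp <- stimulus_clamp(stimulus, net)
  # peek at the early cycles to learn the adjusted deadline, then run the
  # trajectory to that horizon (dynamics are deterministic, so re-running
  # from rest reproduces the same cycles)
  peek <- ia_run(net, clamp, n_cycles = p$adjust_cycle, keep_trace = FALSE)
  g_peek <- peek$word_sum_pos[p$adjust_cycle, 1L]
  max_cycles <- max(p$t_base,
                    as.integer(round(p$t_base + p$t_gain * g_peek)),
                    p$adjust_cycle) + 1L
  res <- ia_run(net, clamp, n_cycles = max_cycles, keep_trace = FALSE)
  s_thr <- p$s_base
  deadline <- p$t_base
  g_adj <- NA_real_
  for (cyc in seq_len(max_cycles)) {
    if (cyc == p$adjust_cycle) {
      g_adj <- res$word_sum_pos[cyc, 1L]
      deadline <- as.integer(round(p$t_base + p$t_gain * g_adj))
      s_thr <- max(p$s_min, p$s_base - p$s_gain * g_adj)
    }
    if (res$word_max[cyc, 1L] >= p$m_criterion) {
      return(decision_outcome("YES", cyc, "M", g_adj))
    }
    if (res$word_sum_pos[cyc, 1L] >= s_thr) {
      return(decision_outcome("YES", cyc, "S", g_adj))
    }
    if (cyc >= deadline) {
      return(decision_outcome("NO", cyc, "T", g_adj))
    }
  }
  decision_outcome("NO", max_cycles, "T", g_adj)  # unreachable in practice
}

decision_outcome <- function(response, rt, criterion, g) {
  structure(list(response = response, rt_cycles = as.integer(rt),
                 criterion = criterion, gla_at_adjust = g),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat(sprintf("<decision> %s at cycle %d via %s criterion\n",
              x$response, x$rt_cycles, x$criterion))
  invisible(x)
}

#' Simulate lexical decisions for a stimulus set
#'
#' @param stimuli Character vector.
#' @param net An [ia_network].
#' @return Data frame with `stimulus`, `response`, `rt_cycles`, `criterion`.
#' @export
simulate_decisions <- function(stimuli, net) {
  rows <- lapply(stimuli, function(s) {
    d <- simulate_lexical_decision(s, net)
    data.frame(stimulus = tolower(s), response = d$response,
               rt_cycles = d$rt_cycles, criterion = d$criterion,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
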