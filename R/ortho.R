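# Orthographic similarity statistics against a reference lexicon.
# Conventions: neighbors are same-length one-substitution words (Coltheart's
# N); bigrams are adjacent ordered letter pairs, position-independent by
# default; the target itself never counts as its own neighbor or bigram
# sharer.

#' Orthographic neighbors (Coltheart's N set)
#'
#' All lexicon words of the same length as `target` at Hamming distance
#' exactly 1 (one letter substituted). The target itself is never returned.
#'
#' @param target A letter string.
#' @param lex A [lexicon].
#' @return Character vector of neighbor words (possibly empty), in lexicon
#'   order.
#' @export
neighbors <- function(target, lex) {
  stopifnot(inherits(lex, "lexicon"), is.character(target),
            length(target) == 1L, nzchar(target))
  target <- tolower(target)
  same <- lex$word[nchar(lex$word) == nchar(target) & lex$word != target]
  if (!length(same)) return(character(0))
  tch <- strsplit(target, "", fixed = TRUE)[[1]]
  d <- vapply(strsplit(same, "", fixed = TRUE),
              function(ch) sum(ch != tch), integer(1))
  same[d == 1L]
}

#' Orthographic measures for one letter string
#'
#' Computes the neighborhood and bigram statistics used in the stimulus
#' descriptor tables and correlation analyses:
#' \describe{
#'   \item{N}{number of one-substitution same-length neighbors}
#'   \item{FN}{summed `freq_per_million` of those neighbors}
#'   \item{NHF}{number of neighbors with frequency strictly higher than the
#'     target's}
#'   \item{FHN}{summed frequency of those higher-frequency neighbors}
#'   \item{BiC}{number of times the target's bigrams occur in other lexicon
#'     words (token counting with multiplicity by default)}
#'   \item{BiF}{summed frequency of lexicon words sharing at least one
#'     bigram with the target}
#'   \item{BiN}{number of such bigram-sharing words}
#' }
#' For nonwords `target_freq` is left `NULL` and treated as 0, so every
#' neighbor with positive frequency counts as higher-frequency.
#'
#' @param target Letter string of length >= 2.
#' @param lex A [lexicon].
#' @param target_freq The target's own frequency per million, or `NULL` for
#'   nonwords.
#' @param bigram_counting `"token"` (default) counts every occurrence of a
#'   shared bigram; `"type"` counts each distinct shared bigram once per
#'   sharing word.
#' @param position_specific If `TRUE`, a bigram only matches at the same
#'   letter positions as in the target.
#' @return Named list with elements `N`, `FN`, `NHF`, `FHN`, `BiC`, `BiF`,
#'   `BiN`.
#' @examples
#' lex <- lexicon(c("cat", "cot", "cog", "dog"), c(10, 5, 3, 7))
#' ortho_measures("cot", lex, target_freq = 5)
#' @export
ortho_measures <- function(target, lex, target_freq = NULL,
                           bigram_counting = c("token", "type"),
                           position_specific = FALSE) {
  bigram_counting <- match.arg(bigram_counting)
  stopifnot(inherits(lex, "lexicon"))
  target <- tolower(target)
  if (nchar(target) < 2L) stop("target too short for bigram measures: ", target)
  tf <- if (is.null(target_freq)) 0 else as.numeric(target_freq)

  nb <- neighbors(target, lex)
  nb_freq <- lex$freq_per_million[match(nb, lex$word)]
  hi <- nb_freq > tf

  others <- lex$word != target
  ow <- lex$word[others]
  of <- lex$freq_per_million[others]

  tch <- strsplit(target, "", fixed = TRUE)[[1]]
  tbi <- paste0(tch[-length(tch)], tch[-1])
  tpos <- seq_along(tbi)

  per_word <- vapply(strsplit(ow, "", fixed = TRUE), function(ch) {
    if (length(ch) < 2L) return(0L)
    wbi <- paste0(ch[-length(ch)], ch[-1])
    if (position_specific) {
      k <- min(length(wbi), length(tbi))
      hit <- wbi[seq_len(k)] == tbi[seq_len(k)]
      if (bigram_counting == "token") sum(hit) else sum(hit)
    } else {
      if (bigram_counting == "token") {
        sum(wbi %in% unique(tbi))
      } else {
        length(intersect(unique(wbi), unique(tbi)))
      }
    }
  }, integer(1))

  shares <- per_word > 0L
  list(N = length(nb),
       FN = sum(nb_freq),
       NHF = sum(hi),
       FHN = sum(nb_freq[hi]),
       BiC = sum(per_word),
       BiF = sum(of[shares]),
       BiN = sum(shares))
}

#' Orthographic measures for a set of stimuli
#'
#' Vectorised wrapper over [ortho_measures]: one row per stimulus. Words
#' (present in the lexicon) use their lexicon frequency; nonwords use an
#' implicit frequency of 0 and get `NA` for `LogF` and `Fmio`.
#'
#' @param strings Character vector of stimuli.
#' @param lex A [lexicon].
#' @param ... Passed to [ortho_measures].
#' @return Data frame with columns `word`, `lexicality`, `LogF`, `Fmio`,
#'   `N`, `FN`, `NHF`, `FHN`, `BiC`, `BiF`, `BiN`.
#' @export
ortho_measures_table <- function(strings, lex, ...) {
  strings <- tolower(strings)
  idx <- match(strings, lex$word)
  is_word <- !is.na(idx)
  freq <- ifelse(is_word, lex$freq_per_million[idx], NA_real_)
  rows <- lapply(seq_along(strings), function(i) {
    m <- ortho_measures(strings[i], lex,
                        target_freq = if (is_word[i]) freq[i] else NULL, ...)
    as.data.frame(m)
  })
  out <- do.call(rbind, rows)
  data.frame(word = strings,
             lexicality = ifelse(is_word, "word", "nonword"),
             LogF = ifelse(is_word, log_frequency(freq), NA_real_),
             Fmio = freq,
             out,
             stringsAsFactors = FALSE)
}
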