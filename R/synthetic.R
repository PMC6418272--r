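# Seeded generators that stand in for the study-type inputs: a monosyllabic
# 3-5 letter lexicon with Zipf-distributed frequencies and realistic
# neighborhood overlap, and balanced per-region signal-change tables with
# subject random effects and programmed per-lexicality linear GLA slopes.

#' Specification for a synthetic lexicon
#'
#' @param n_words Lexicon size.
#' @param length_distribution Named or ordered proportions over lengths
#'   3, 4, 5; must sum to 1. The default puts most mass on four-letter
#'   words so that four-letter candidate pools of several hundred items
#'   exist.
#' @param consonants,vowels Letter inventories; consonant/vowel skeletons
#'   (CVC, CVCC, CCVC, CVCVC-free templates per length) emulate monosyllabic
#'   phonotactics well enough to induce realistic neighbor overlap.
#' @param zipf_exponent Frequency of the rank-r word is proportional to
#'   `r^-zipf_exponent`.
#' @param freq_max Frequency per million of the rank-1 word.
#' @param seed Integer seed; the lexicon is a pure function of the spec.
#' @return Object of class `lexicon_spec`.
#' @export
lexicon_spec <- function(n_words = 1025L,
                         length_distribution = c(0.18, 0.62, 0.20),
                         consonants = c("b", "d", "f", "g", "h", "k", "l",
                                        "m", "n", "r", "s", "t"),
                         vowels = c("a", "e", "i", "o", "u"),
                         zipf_exponent = 1.05,
                         freq_max = 2000,
                         seed = 1L) {
  stopifnot(n_words >= 1L, length(length_distribution) == 3L,
            abs(sum(length_distribution) - 1) < 1e-8,
            all(length_distribution >= 0),
            zipf_exponent >= 0, freq_max > 0,
            length(consonants) >= 2L, length(vowels) >= 1L)
  structure(list(n_words = as.integer(n_words),
                 length_distribution = as.numeric(length_distribution),
                 consonants = consonants, vowels = vowels,
                 zipf_exponent = zipf_exponent, freq_max = freq_max,
                 seed = as.integer(seed)),
            class = "lexicon_spec")
}

# consonant/vowel skeletons per word length
cv_templates <- list(
  `3` = c("CVC"),
  `4` = c("CVCC", "CCVC"),
  `5` = c("CCVCC", "CVCCC", "CCCVC")
)

#' Generate a synthetic lexicon
#'
#' Draws unique consonant/vowel-skeleton strings of lengths 3-5 with
#' Zipf-distributed frequencies per million. Letters are drawn with
#' rank-weighted probabilities (common letters much more likely), which
#' concentrates the words in a small orthographic space and produces the
#' neighborhood overlap real monosyllabic lexicons show. If fewer than 10%
#' of the four-letter words end up with at least one neighbor, the letter
#' weights are sharpened and the lexicon regenerated.
#'
#' @param spec A [lexicon_spec].
#' @return A [lexicon] whose `alphabet` is the union of the spec's
#'   consonants and vowels.
#' @export
generate_synthetic_lexicon <- function(spec = lexicon_spec()) {
  stopifnot(inherits(spec, "lexicon_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  n_len <- round(spec$n_words * spec$length_distribution)
  while (sum(n_len) < spec$n_words) n_len[2] <- n_len[2] + 1L
  while (sum(n_len) > spec$n_words) n_len[which.max(n_len)] <-
      n_len[which.max(n_len)] - 1L
  space <- vapply(cv_templates, function(tpl) {
    sum(vapply(tpl, function(t) {
      nc <- sum(strsplit(t, "")[[1]] == "C")
      length(spec$consonants)^nc *
        length(spec$vowels)^(nchar(t) - nc)
    }, numeric(1)))
  }, numeric(1))
  if (any(n_len > space)) {
    stop("requested more words than the template space holds")
  }
  sharp <- 1.0
  for (attempt in 1:8) {
    wc <- 1 / rank(seq_along(spec$consonants))^sharp
    wv <- 1 / rank(seq_along(spec$vowels))^sharp
    words <- character(0)
    for (li in 1:3) {
      len <- li + 2L
      need <- n_len[li]
      if (need == 0L) next
      tpls <- cv_templates[[as.character(len)]]
      got <- character(0)
      guard <- 0L
      while (length(got) < need && guard < 500L * need) {
        guard <- guard + 1L
        t <- strsplit(sample(tpls, 1L), "")[[1]]
        ch <- character(len)
        for (j in seq_len(len)) {
          ch[j] <- if (t[j] == "C") sample(spec$consonants, 1L, prob = wc)
          else sample(spec$vowels, 1L, prob = wv)
        }
        w <- paste(ch, collapse = "")
        if (!(w %in% got) && !(w %in% words)) got <- c(got, w)
      }
      if (length(got) < need) {
        stop("template space too tight for ", need, " words of length ", len)
      }
      words <- c(words, got)
    }
    freq <- spec$freq_max * seq_len(spec$n_words)^(-spec$zipf_exponent)
    words <- sample(words)  # decouple frequency rank from generation order
    lex <- lexicon(words, freq,
                   length_bounds = c(3L, 5L),
                   alphabet = sort(unique(c(spec$consonants, spec$vowels))))
    four <- lex$word[nchar(lex$word) == 4L]
    if (!length(four)) return(lex)
    nn <- vapply(four, function(w) length(neighbors(w, lex)), integer(1))
    if (mean(nn >= 1L) >= 0.10) return(lex)
    sharp <- sharp + 0.5  # concentrate letters harder and retry
  }
  stop("could not realise non-degenerate neighborhood structure")
}

#' Specification for synthetic region signals
#'
#' Cell values follow
#' `value(s, lex, level j in 0,1,2) = grand_mean + b_s + slope_lex * j + e`,
#' with subject effects `b_s ~ N(0, subject_sd^2)` and residuals
#' `e ~ N(0, residual_sd^2)`; the design is balanced by construction.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param word_slope,nonword_slope Programmed per-level signal increments.
#' @param grand_mean Baseline signal change.
#' @param subject_sd Between-subject sd of the random intercept.
#' @param residual_sd Within-cell residual sd.
#' @param seed Integer seed.
#' @return Object of class `signal_spec`.
#' @export
signal_spec <- function(n_subjects = 20L, word_slope = 0.1,
                        nonword_slope = 0, grand_mean = 0.3,
                        subject_sd = 0.15, residual_sd = 0.2, seed = 1L) {
  stopifnot(n_subjects >= 3L, subject_sd >= 0, residual_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 word_slope = word_slope, nonword_slope = nonword_slope,
                 grand_mean = grand_mean, subject_sd = subject_sd,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Generate a balanced synthetic region signal table
#'
#' @param spec A [signal_spec].
#' @param region Region label for the output table.
#' @return A [region_signal_table].
#' @export
generate_region_signals <- function(spec = signal_spec(), region = "synthetic") {
  stopifnot(inherits(spec, "signal_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  n <- spec$n_subjects
  b_s <- stats::rnorm(n, 0, spec$subject_sd)
  grid <- expand.grid(subject = sprintf("s%02d", seq_len(n)),
                      lexicality = LEX2, level = LEVELS3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  j <- match(grid$level, LEVELS3) - 1L
  slope <- ifelse(grid$lexicality == "word", spec$word_slope,
                  spec$nonword_slope)
  grid$value <- spec$grand_mean + b_s[match(grid$subject,
                                            sprintf("s%02d", seq_len(n)))] +
    slope * j + stats::rnorm(nrow(grid), 0, spec$residual_sd)
  grid$region <- region
  region_signal_table(grid, region = region)
}

#' Fixed micro fixture for oracle tests
#'
#' A frozen 8-word toy lexicon, four probe stimuli (a high- and a
#' low-neighborhood word, a high- and a low-neighborhood nonword) and a
#' frozen parameter set. Byte-identical on every call; golden activation
#' and GLA values computed from it can therefore be stored and re-checked
#' exactly.
#'
#' @return List with `lexicon`, `stimuli` (data frame: `stimulus`,
#'   `lexicality`, `neighborhood`) and `params`.
#' @export
micro_fixture <- function() {
  lex <- lexicon(
    words = c("case", "cast", "care", "card", "core", "tore", "mint", "flux"),
    freq_per_million = c(120, 35, 80, 18, 55, 7, 42, 3),
    length_bounds = c(3L, 5L))
  stimuli <- data.frame(
    stimulus = c("care", "mint", "cade", "fost"),
    lexicality = c("word", "word", "nonword", "nonword"),
    neighborhood = c("high", "low", "high", "low"),
    stringsAsFactors = FALSE)
  params <- model_params()  # frozen defaults
  list(lexicon = lex, stimuli = stimuli, params = params)
}
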