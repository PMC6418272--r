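#' Construct a validated lexicon
#'
#' A lexicon is the reference word set for all orthographic statistics and
#' the word layer of the interactive-activation network: an ordered
#' collection of unique lowercase letter strings with occurrence frequencies
#' per million.
#'
#' @param words Character vector of word forms. Lower-cased on input.
#' @param freq_per_million Numeric vector of non-negative frequencies, one
#'   per word.
#' @param length_bounds Integer pair `c(min, max)`; words outside the bounds
#'   are invalid.
#' @param alphabet Character vector of allowed single letters. Defaults to
#'   the set of letters occurring in `words`.
#'
#' @return An object of class `lexicon`: a `data.frame` with columns `word`
#'   and `freq_per_million`, carrying attributes `alphabet` and
#'   `length_bounds`.
#' @examples
#' lex <- lexicon(c("cat", "cot", "cog", "dog"), c(10, 5, 3, 7))
#' neighbors("cot", lex)
#' @export
lexicon <- function(words, freq_per_million, length_bounds = c(3L, 5L),
                    alphabet = NULL) {
  stopifnot(is.character(words), length(words) >= 1L,
            length(words) == length(freq_per_million))
  words <- tolower(words)
  freq_per_million <- as.numeric(freq_per_million)
  if (anyNA(freq_per_million)) {
    stop("non-numeric or missing frequency for: ",
         paste(words[is.na(freq_per_million)], collapse = ", "))
  }
  if (any(freq_per_million < 0)) {
    stop("negative frequency for: ",
         paste(words[freq_per_million < 0], collapse = ", "))
  }
  dup <- words[duplicated(words)]
  if (length(dup)) {
    stop("duplicate word(s) in lexicon: ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(words, "", fixed = TRUE))))
  }
  len <- nchar(words)
  bad_len <- len < length_bounds[1] | len > length_bounds[2]
  bad_alpha <- !vapply(strsplit(words, "", fixed = TRUE),
                       function(ch) all(ch %in% alphabet), logical(1))
  if (any(bad_len | bad_alpha)) {
    stop("invalid word(s): ",
         paste(words[bad_len | bad_alpha], collapse = ", "))
  }
  out <- data.frame(word = words, freq_per_million = freq_per_million,
                    stringsAsFactors = FALSE)
  structure(out,
            alphabet = alphabet,
            length_bounds = as.integer(length_bounds),
            class = c("lexicon", "data.frame"))
}

#' Read a lexicon from delimited text
#'
#' Expects two-column tab- or comma-delimited text with columns `word` and
#' `freq_per_million` (header optional). Rows whose word violates the length
#' bounds or the alphabet are rejected, not fatal; the retained lexicon
#' carries a rejection report. Duplicate words and non-numeric frequencies
#' are errors.
#'
#' @param path Path to the file.
#' @param length_bounds Allowed word lengths, `c(min, max)`.
#' @param alphabet Allowed letters; default `letters` plus any character
#'   occurring in the accepted rows is *not* assumed — rows with letters
#'   outside `alphabet` are rejected. `NULL` means "infer from the file".
#' @return A [lexicon] object. Attribute `rejections` is a data.frame of
#'   rejected rows (`line`, `word`, `reason`), empty if none.
#' @export
read_lexicon <- function(path, length_bounds = c(3L, 5L), alphabet = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  header <- grepl("word", first, ignore.case = TRUE)
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", strip.white = TRUE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected two columns (word, freq_per_million)")
  words <- tolower(raw[[1]])
  freq <- suppressWarnings(as.numeric(raw[[2]]))
  line0 <- seq_along(words) + as.integer(header)
  if (anyNA(freq)) {
    stop("non-numeric frequency at line(s): ",
         paste(line0[is.na(freq)], collapse = ", "))
  }
  dup <- duplicated(words) | duplicated(words, fromLast = TRUE)
  if (any(duplicated(words))) {
    stop("duplicate word(s): ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  }
  if (is.null(alphabet)) {
    alphabet <- sort(unique(unlist(strsplit(words, "", fixed = TRUE))))
  }
  len <- nchar(words)
  bad_len <- len < length_bounds[1] | len > length_bounds[2]
  bad_alpha <- !vapply(strsplit(words, "", fixed = TRUE),
                       function(ch) all(ch %in% alphabet), logical(1))
  reject <- bad_len | bad_alpha | freq < 0
  report <- data.frame(
    line = line0[reject],
    word = words[reject],
    reason = ifelse(bad_len[reject], "length out of bounds",
                    ifelse(bad_alpha[reject], "letter outside alphabet",
                           "negative frequency")),
    stringsAsFactors = FALSE)
  if (all(reject)) stop("no valid rows in ", path)
  lex <- lexicon(words[!reject], freq[!reject],
                 length_bounds = length_bounds, alphabet = alphabet)
  attr(lex, "rejections") <- report
  lex
}

#' Write a lexicon as tab-delimited text
#' @param lex A [lexicon].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  utils::write.table(as.data.frame(lex), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d words, lengths %d-%d, alphabet of %d letters\n",
              nrow(x), attr(x, "length_bounds")[1],
              attr(x, "length_bounds")[2], length(attr(x, "alphabet"))))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej)) {
    cat(sprintf("  (%d input row(s) rejected)\n", nrow(rej)))
  }
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Base-10 log frequency
#'
#' `log10(freq + 1)`, the frequency scale used for word-unit resting levels
#' and stimulus descriptor tables; the +1 offset keeps zero-frequency
#' entries finite.
#' @param freq_per_million Non-negative numeric vector.
#' @return Numeric vector.
#' @export
log_frequency <- function(freq_per_million) log10(freq_per_million + 1)
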