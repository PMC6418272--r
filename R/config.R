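# Flat key = value configuration files for model parameters and generator
# specs.  Lines starting with '#' and blank lines are ignored; values are
# parsed as numeric vectors (comma-separated) where possible, otherwise
# kept as strings.

parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(x) {
    raw <- trimws(strsplit(x[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) raw else num
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), ""))
}

#' Read model parameters from a key = value config file
#'
#' Any [model_params] argument can appear as a line `name = value`
#' (`rest_range` as two comma-separated numbers); unknown keys are an
#' error, missing keys keep their defaults.
#'
#' @param path Config file path.
#' @return A [model_params] object.
#' @export
read_model_params <- function(path) {
  cfg <- parse_config(path)
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown model parameter(s): ",
                        paste(bad, collapse = ", "))
  do.call(model_params, cfg)
}

#' Read a synthetic-lexicon spec from a key = value config file
#' @param path Config file path.
#' @return A [lexicon_spec] object.
#' @export
read_lexicon_spec <- function(path) {
  cfg <- parse_config(path)
  known <- names(formals(lexicon_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown lexicon spec field(s): ",
                        paste(bad, collapse = ", "))
  do.call(lexicon_spec, cfg)
}

#' Read a region-signal spec from a key = value config file
#' @param path Config file path.
#' @return A [signal_spec] object.
#' @export
read_signal_spec <- function(path) {
  cfg <- parse_config(path)
  known <- names(formals(signal_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown signal spec field(s): ",
                        paste(bad, collapse = ", "))
  do.call(signal_spec, cfg)
}
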