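# Stimulus construction: nonword pool by letter substitution, constrained
# selection of word/nonword sets whose z-GLA distributions are normal with
# different means and equal variances, tertile GLA leveling, descriptor
# tables and GLA-structure correlations.

#' Generate a nonword pool by letter substitution
#'
#' Each nonword derives from a uniformly chosen source word by substituting
#' k in 1..4 uniformly chosen positions with uniformly chosen *different*
#' letters from the lexicon's alphabet. Strings that are lexicon words, or
#' duplicates, are rejected and redrawn. Transpositions, insertions and
#' deletions are not used.
#'
#' @param words Character vector of same-length source words.
#' @param lex The reference [lexicon] (membership test and alphabet).
#' @param n_pool Number of nonwords to produce.
#' @param seed Integer seed; the pool is a pure function of
#'   `(words, lex, n_pool, seed)`.
#' @param max_sub Maximum number of substituted positions (default 4).
#' @return Character vector of `n_pool` unique nonwords.
#' @export
generate_nonword_pool <- function(words, lex, n_pool, seed, max_sub = 4L) {
  stopifnot(inherits(lex, "lexicon"), n_pool >= 0L)
  if (n_pool == 0L) return(character(0))
  words <- tolower(words)
  lens <- unique(nchar(words))
  if (length(lens) != 1L) stop("source words must all have the same length")
  alphabet <- attr(lex, "alphabet")
  if (length(alphabet) < 2L) {
    stop("alphabet of size ", length(alphabet),
         ": no letter substitutions possible")
  }
  max_sub <- min(max_sub, lens)
  out <- character(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  in_lex <- new.env(hash = TRUE, parent = emptyenv())
  for (w in lex$word) assign(w, TRUE, envir = in_lex)
  budget <- max(1000L, 200L * n_pool)
  tries <- 0L
  withr_seed <- local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  while (length(out) < n_pool && tries < budget) {
    tries <- tries + 1L
    src <- strsplit(sample(words, 1L), "", fixed = TRUE)[[1]]
    k <- sample.int(max_sub, 1L)
    pos <- sample.int(lens, k)
    for (p in pos) {
      src[p] <- sample(setdiff(alphabet, src[p]), 1L)
    }
    cand <- paste(src, collapse = "")
    if (!is.null(in_lex[[cand]]) || !is.null(seen[[cand]])) next
    assign(cand, TRUE, envir = seen)
    out <- c(out, cand)
  }
  if (length(out) < n_pool) {
    stop("could not reach a pool of ", n_pool, " nonwords within ",
         budget, " draws (got ", length(out), ")")
  }
  out
}

# save/restore .Random.seed so generators are pure functions of their seed
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Selection constraints for the stimulus sets
#'
#' The selected word and nonword z-GLA samples must each look normal
#' (Shapiro-Wilk p > `normality_alpha`), differ in mean (Welch t-test
#' p < `mean_diff_alpha`) and have equal variances (median-centred Levene
#' p > `variance_alpha`).
#'
#' @param n_per_class Items to select per lexicality.
#' @param normality_alpha,mean_diff_alpha,variance_alpha Test levels.
#' @param max_iterations Rejection/trimming iterations before giving up.
#' @param seed Integer seed.
#' @return Object of class `selection_constraints`.
#' @export
selection_constraints <- function(n_per_class = 300L,
                                  normality_alpha = 0.10,
                                  mean_diff_alpha = 0.01,
                                  variance_alpha = 0.10,
                                  max_iterations = 200L,
                                  seed = 1L) {
  stopifnot(n_per_class >= 3L,
            normality_alpha > 0, normality_alpha < 1,
            mean_diff_alpha > 0, mean_diff_alpha < 1,
            variance_alpha > 0, variance_alpha < 1,
            max_iterations >= 1L)
  structure(list(n_per_class = as.integer(n_per_class),
                 normality_alpha = normality_alpha,
                 mean_diff_alpha = mean_diff_alpha,
                 variance_alpha = variance_alpha,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "selection_constraints")
}

# The three distributional tests; returns p-values.
selection_audit <- function(z_words, z_nonwords) {
  lev <- car::leveneTest(
    c(z_words, z_nonwords),
    factor(rep(c("word", "nonword"), c(length(z_words), length(z_nonwords)))),
    center = stats::median)
  list(shapiro_words = stats::shapiro.test(z_words)$p.value,
       shapiro_nonwords = stats::shapiro.test(z_nonwords)$p.value,
       welch = stats::t.test(z_words, z_nonwords)$p.value,
       levene = lev[["Pr(>F)"]][1L])
}

selection_pass <- function(audit, con) {
  audit$shapiro_words > con$normality_alpha &&
    audit$shapiro_nonwords > con$normality_alpha &&
    audit$welch < con$mean_diff_alpha &&
    audit$levene > con$variance_alpha
}

# Pick, without replacement, the pool items whose values best match the n
# theoretical quantiles of Normal(mu, sigma): both sequences are ascending,
# so a monotone greedy walk gives a near-optimal matching.
quantile_match <- function(values, n, mu, sigma) {
  m <- length(values)
  stopifnot(n <= m)
  targets <- stats::qnorm(stats::ppoints(n), mu, sigma)
  ord <- order(values)
  sorted <- values[ord]
  idx <- integer(n)
  j <- 1L
  for (i in seq_len(n)) {
    limit <- m - (n - i)  # leave room for the remaining targets
    while (j < limit &&
           abs(sorted[j + 1L] - targets[i]) <= abs(sorted[j] - targets[i])) {
      j <- j + 1L
    }
    idx[i] <- ord[j]
    j <- j + 1L
  }
  idx
}

#' Select word and nonword stimulus sets with constrained z-GLA
#' distributions
#'
#' Selects `n_per_class` words and nonwords from candidate pools so that
#' the two z-GLA samples are normal, differ in mean and have equal
#' variances (see [selection_constraints]). Selection is seeded
#' quantile-matched sampling with a trimming heuristic: an initial draw
#' matches each class's values to the quantiles of a target normal
#' distribution (common sd, class-specific means); failed audits trigger
#' replacement of the worst-fitting tail items, and, if the means are too
#' close, the class targets are pushed apart.
#'
#' @param word_pool,nonword_pool Data frames with at least columns
#'   `stimulus` and `GLAz` (e.g. rows of [gla_table()] output).
#' @param constraints A [selection_constraints] object.
#' @return List with data frames `words` and `nonwords` (the selected rows)
#'   and `audit`, the p-values of the three tests on the returned sets.
#' @export
select_stimuli <- function(word_pool, nonword_pool,
                           constraints = selection_constraints()) {
  con <- constraints
  stopifnot(nrow(word_pool) >= con$n_per_class,
            nrow(nonword_pool) >= con$n_per_class)
  n <- con$n_per_class
  # identity fast-path: pools already of the right size and passing
  if (nrow(word_pool) == n && nrow(nonword_pool) == n) {
    audit <- selection_audit(word_pool$GLAz, nonword_pool$GLAz)
    if (selection_pass(audit, con)) {
      return(list(words = word_pool, nonwords = nonword_pool, audit = audit))
    }
  }
  restore <- local_seed(con$seed)
  on.exit(restore(), add = TRUE)
  zw <- word_pool$GLAz; zn <- nonword_pool$GLAz
  # a normal target only fits where the pool has support: keep the +-3 sigma
  # window inside each class's central mass, and as wide as that allows
  support <- function(x) stats::quantile(x, c(0.01, 0.99), names = FALSE)
  sw_sup <- support(zw); sn_sup <- support(zn)
  sigma0 <- 0.9 * min(diff(sw_sup), diff(sn_sup)) / 6
  sig_w <- sig_n <- sigma0
  clamp_mu <- function(mu, sup, sigma) {
    min(max(mu, sup[1] + 3 * sigma), sup[2] - 3 * sigma)
  }
  mu_w0 <- mean(zw); mu_n0 <- mean(zn)
  sgn <- if (mu_w0 >= mu_n0) 1 else -1
  push <- 0
  best <- NULL
  best_score <- -Inf
  for (iter in seq_len(con$max_iterations)) {
    tw <- clamp_mu(mu_w0 + sgn * push, sw_sup, sig_w)
    tn <- clamp_mu(mu_n0 - sgn * push, sn_sup, sig_n)
    jw <- stats::runif(1, -0.05, 0.05) * sig_w
    jn <- stats::runif(1, -0.05, 0.05) * sig_n
    wi <- quantile_match(zw, n, tw + jw, sig_w)
    ni <- quantile_match(zn, n, tn + jn, sig_n)
    sel_w <- word_pool[wi, , drop = FALSE]
    sel_n <- nonword_pool[ni, , drop = FALSE]
    audit <- selection_audit(sel_w$GLAz, sel_n$GLAz)
    if (selection_pass(audit, con)) {
      return(list(words = sel_w, nonwords = sel_n, audit = audit))
    }
    score <- min(audit$shapiro_words, audit$shapiro_nonwords, audit$levene) -
      audit$welch
    if (score > best_score) {
      best_score <- score
      best <- list(words = sel_w, nonwords = sel_n, audit = audit)
    }
    # trimming heuristics: a failed normality audit means the target's tails
    # could not be matched in that class, so narrow it; unequal achieved
    # variances pull the wider class in; a failed mean-difference audit
    # pushes the class targets apart
    if (audit$welch >= con$mean_diff_alpha) push <- push + 0.25 * sigma0
    if (audit$shapiro_words <= con$normality_alpha) sig_w <- sig_w * 0.95
    if (audit$shapiro_nonwords <= con$normality_alpha) sig_n <- sig_n * 0.95
    if (audit$levene <= con$variance_alpha) {
      s_aw <- stats::sd(sel_w$GLAz); s_an <- stats::sd(sel_n$GLAz)
      if (s_aw > s_an) sig_w <- sig_w * (s_an / s_aw)^0.5
      else sig_n <- sig_n * (s_aw / s_an)^0.5
    }
    if (min(sig_w, sig_n) <= 0) break
  }
  stop("selection constraints not satisfied within ", con$max_iterations,
       " iterations; best attempt p-values: shapiro ",
       signif(min(best$audit$shapiro_words, best$audit$shapiro_nonwords), 3),
       ", welch ", signif(best$audit$welch, 3),
       ", levene ", signif(best$audit$levene, 3))
}

#' Assign GLA tertile levels within one lexicality
#'
#' Sorts by z-GLA ascending (stable on input order for ties) and labels the
#' first third `low`, the last third `high`, and the remainder `medium`;
#' level sizes differ by at most 1.
#'
#' @param records Data frame with a `GLAz` column, one lexicality.
#' @param k Number of levels; only 3 is supported.
#' @return `records` with a `level` factor column
#'   (`low` < `medium` < `high`), in the original row order.
#' @export
assign_gla_levels <- function(records, k = 3L) {
  if (k != 3L) stop("only k = 3 GLA levels are supported")
  n <- nrow(records)
  stopifnot(n >= 3L)
  base <- n %/% 3L
  rem <- n %% 3L
  # near-equal split; an odd remainder goes to the outer levels first, but
  # never lets sizes differ by more than 1
  sizes <- switch(rem + 1L,
                  c(base, base, base),
                  c(base + 1L, base, base),
                  c(base + 1L, base, base + 1L))
  ord <- order(records$GLAz)  # stable: ties keep input order
  lev <- character(n)
  lev[ord] <- rep(c("low", "medium", "high"), times = sizes)
  records$level <- factor(lev, levels = c("low", "medium", "high"))
  records
}

#' Per-level stimulus descriptor table
#'
#' Means of GLA and the linguistic measures for every lexicality-by-level
#' cell, the summary conventionally reported for leveled stimulus sets.
#' Frequency columns (`LogF`, `Fmio`) are `NA` for nonwords.
#'
#' @param records Data frame with columns `lexicality`, `level`, `GLA`, and
#'   measure columns `LogF`, `Fmio`, `N`, `FN`, `BiC`, `BiF` (extra measure
#'   columns are averaged too).
#' @return Data frame, one row per lexicality x level.
#' @export
descriptor_table <- function(records) {
  stopifnot(all(c("lexicality", "level", "GLA") %in% names(records)))
  if (anyNA(records$level)) stop("levels must be assigned first")
  cols <- intersect(c("GLA", "LogF", "Fmio", "N", "FN", "NHF", "FHN",
                      "BiC", "BiF", "BiN"), names(records))
  combos <- table(records$lexicality, factor(records$level,
                                             levels = levels(factor(records$level))))
  if (any(combos == 0L)) stop("empty lexicality x level cell")
  cells <- split(records, list(records$lexicality, records$level),
                 drop = TRUE)
  rows <- lapply(cells, function(d) {
    m <- vapply(cols, function(cc) mean(d[[cc]]), numeric(1))
    cbind(data.frame(lexicality = d$lexicality[1L], level = d$level[1L],
                     n = nrow(d)), as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lexicality, out$level), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GLA-structure correlations
#'
#' Pearson correlations of raw GLA with each orthographic measure,
#' separately for words and nonwords: the check that GLA, a single model
#' quantity, tracks the classical linguistic variables.
#'
#' @param records Data frame with `lexicality`, `GLA` and measure columns
#'   `N`, `FN`, `NHF`, `FHN`, `BiC`, `BiF`, `BiN`.
#' @return Data frame with one row per measure and columns `measure`,
#'   `r_words`, `r_nonwords`; `NA` where a measure is constant.
#' @export
gla_correlations <- function(records) {
  measures <- intersect(c("N", "FN", "NHF", "FHN", "BiC", "BiF", "BiN"),
                        names(records))
  stopifnot(length(measures) >= 1L, "GLA" %in% names(records))
  one <- function(d) {
    if (nrow(d) < 3L) stop("need >= 3 records per lexicality")
    vapply(measures, function(mm) {
      x <- d[[mm]]
      if (stats::sd(x) == 0 || stats::sd(d$GLA) == 0) return(NA_real_)
      stats::cor(d$GLA, x)
    }, numeric(1))
  }
  w <- one(records[records$lexicality == "word", , drop = FALSE])
  nw <- one(records[records$lexicality == "nonword", , drop = FALSE])
  data.frame(measure = measures, r_words = unname(w),
             r_nonwords = unname(nw), stringsAsFactors = FALSE)
}

#' Build a complete leveled stimulus set from a lexicon
#'
#' The full construction chain: take the lexicon's four-letter words as the
#' word candidate pool, generate a nonword pool by letter substitution,
#' compute GLA for every candidate, z-transform over the joint pool, select
#' constrained word and nonword sets, assign tertile GLA levels within each
#' lexicality, and attach the orthographic measures.
#'
#' @param lex A [lexicon].
#' @param n_words,n_nonwords Set sizes (selection constraint
#'   `n_per_class` is taken from these; they must be equal).
#' @param pool_size Size of the generated nonword pool.
#' @param word_pool_size Optional cap on the word candidate pool (a seeded
#'   subsample of the four-letter words); `NULL` uses all of them.
#' @param seed Integer seed driving pool generation and selection.
#' @param params [model_params] for the GLA simulation.
#' @param constraints Optional [selection_constraints]; `n_per_class` and
#'   `seed` are overridden by the arguments above.
#' @return Data frame of selected stimuli with columns `word`, `lexicality`,
#'   `GLA`, `GLAz`, `level`, `LogF`, `Fmio`, `N`, `FN`, `NHF`, `FHN`,
#'   `BiC`, `BiF`, `BiN`.
#' @export
build_stimuli <- function(lex, n_words = 300L, n_nonwords = 300L,
                          pool_size = 2000L, word_pool_size = NULL,
                          seed = 1L, params = model_params(),
                          constraints = NULL) {
  stopifnot(n_words == n_nonwords)
  four <- lex$word[nchar(lex$word) == 4L]
  if (!is.null(word_pool_size)) {
    stopifnot(word_pool_size <= length(four))
    restore <- local_seed(seed + 1L)
    four <- sample(four, word_pool_size)
    restore()
  }
  if (length(four) < n_words) {
    stop("lexicon has only ", length(four), " four-letter words; need >= ",
         n_words)
  }
  nonwords <- generate_nonword_pool(four, lex, pool_size, seed = seed)
  pool <- gla_table(c(four, nonwords), lex, params = params)
  wp <- pool[pool$lexicality == "word", , drop = FALSE]
  np <- pool[pool$lexicality == "nonword", , drop = FALSE]
  if (is.null(constraints)) constraints <- selection_constraints()
  constraints$n_per_class <- as.integer(n_words)
  constraints$seed <- as.integer(seed)
  sel <- select_stimuli(wp, np, constraints)
  sw <- assign_gla_levels(sel$words)
  sn <- assign_gla_levels(sel$nonwords)
  out <- rbind(sw, sn)
  meas <- ortho_measures_table(out$stimulus, lex)
  res <- cbind(meas[, c("word", "lexicality", "LogF", "Fmio")],
               GLA = out$GLA, GLAz = out$GLAz, level = out$level,
               meas[, c("N", "FN", "NHF", "FHN", "BiC", "BiF", "BiN")])
  res <- res[, c("word", "lexicality", "GLA", "GLAz", "level", "LogF",
                 "Fmio", "N", "FN", "NHF", "FHN", "BiC", "BiF", "BiN")]
  attr(res, "audit") <- sel$audit
  rownames(res) <- NULL
  res
}

#' Write a stimulus table as delimited text
#' @param records Stimulus data frame (e.g. from [build_stimuli]).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_stimuli <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
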