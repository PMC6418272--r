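# Linking analysis for extracted region signals: balanced
# 2 (lexicality) x 3 (GLA level) fully within-subject ANOVA, orthogonal
# polynomial trend contrasts, per-lexicality simple effects, and a profile
# classifier for the resulting significance pattern.
#
# Error-term conventions: every effect is tested against its own
# subject-by-effect interaction; contrasts use contrast-specific
# (subject-by-contrast) error terms; simple effects use slice-wise error
# terms (a pooled option is exposed).  No sphericity correction is applied
# by default, so the GLA main effect with n subjects reports dfs
# (2, 2(n-1)) and single-df contrasts (1, n-1).

LEVELS3 <- c("low", "medium", "high")
LEX2 <- c("word", "nonword")

#' Construct / validate a region signal table
#'
#' A balanced per-region table of signal-change values: one value for every
#' (subject, lexicality, GLA level) cell.
#'
#' @param data Data frame with columns `subject`, `lexicality`
#'   (`word`/`nonword`), `level` (`low`/`medium`/`high`), `value`, and
#'   optionally `region`.
#' @param region Region label; taken from the data if present.
#' @return Object of class `region_signal_table` (a validated data frame).
#' @export
region_signal_table <- function(data, region = NULL) {
  need <- c("subject", "lexicality", "level", "value")
  stopifnot(all(need %in% names(data)))
  if (is.null(region)) {
    region <- if ("region" %in% names(data)) as.character(data$region[1L]) else "region"
  }
  data$lexicality <- as.character(data$lexicality)
  data$level <- as.character(data$level)
  stopifnot(all(data$lexicality %in% LEX2), all(data$level %in% LEVELS3),
            is.numeric(data$value), !anyNA(data$value))
  tab <- table(data$subject, data$lexicality, data$level)
  if (any(tab != 1L)) {
    stop("unbalanced table for region '", region,
         "': every subject needs exactly one value per lexicality x level cell")
  }
  if (length(unique(data$subject)) < 3L) stop("need >= 3 subjects")
  out <- data.frame(region = region,
                    subject = as.character(data$subject),
                    lexicality = factor(data$lexicality, levels = LEX2),
                    level = factor(data$level, levels = LEVELS3),
                    value = as.numeric(data$value),
                    stringsAsFactors = FALSE)
  structure(out, class = c("region_signal_table", "data.frame"))
}

#' Read region signal tables from long-format delimited text
#'
#' @param path File with columns `region`, `subject`, `lexicality`,
#'   `level`, `value` (comma- or tab-delimited, header required).
#' @return Named list of [region_signal_table] objects, one per region.
#' @export
read_region_signals <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!"region" %in% names(raw)) raw$region <- "region"
  lapply(split(raw, raw$region), region_signal_table)
}

# F ratio with the zero-error convention: no effect and no error is 0 (not
# 0/0), a non-zero effect against exactly zero error is infinite
f_ratio <- function(ms, mse) {
  if (mse > 0) ms / mse else if (ms == 0) 0 else Inf
}

# cell means as a subject x (lexicality, level) layout plus marginals
rst_cells <- function(table) {
  subj <- sort(unique(table$subject))
  n <- length(subj)
  Y <- array(NA_real_, c(n, 2L, 3L),
             dimnames = list(subj, LEX2, LEVELS3))
  idx <- cbind(match(table$subject, subj),
               as.integer(table$lexicality),
               as.integer(table$level))
  Y[idx] <- table$value
  Y
}

#' Two-by-three repeated-measures ANOVA on a region signal table
#'
#' Fully within-subject two-factor ANOVA (lexicality x GLA level) with
#' subject as the random blocking factor; each effect is tested against its
#' own subject-by-effect interaction. No sphericity correction is applied
#' unless `gg_correction = TRUE` (Greenhouse-Geisser on the 2-df effects).
#'
#' Alongside the omnibus effects the result carries, per lexicality, the
#' simple GLA effect and the single-df linear and quadratic polynomial
#' contrasts, plus the pooled contrasts across lexicalities.
#'
#' @param table A [region_signal_table] (or a data frame accepted by it).
#' @param gg_correction Apply Greenhouse-Geisser epsilon correction to the
#'   2-df within-subject effects.
#' @return Object of class `rm_anova_result`: list with `effects`
#'   (data.frame: effect, SS, df1, df2, F, p), `contrasts` (data.frame:
#'   lexicality, contrast, SS, df1, df2, F, p, estimate),
#'   `simple_effects`, `region`, `n_subjects`.
#' @export
rm_anova_2x3 <- function(table, gg_correction = FALSE) {
  if (!inherits(table, "region_signal_table")) {
    table <- region_signal_table(table)
  }
  Y <- rst_cells(table)
  n <- dim(Y)[1L]; a <- 2L; b <- 3L
  m_s <- apply(Y, 1L, mean)
  m_a <- apply(Y, 2L, mean)
  m_b <- apply(Y, 3L, mean)
  m_sa <- apply(Y, c(1L, 2L), mean)
  m_sb <- apply(Y, c(1L, 3L), mean)
  m_ab <- apply(Y, c(2L, 3L), mean)
  gm <- mean(Y)

  ss_a <- b * n * sum((m_a - gm)^2)
  ss_b <- a * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1L, m_a), 2L, m_b) + gm)^2)
  ss_as <- b * sum((sweep(sweep(m_sa, 1L, m_s), 2L, m_a) + gm)^2)
  ss_bs <- a * sum((sweep(sweep(m_sb, 1L, m_s), 2L, m_b) + gm)^2)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  eff <- function(name, ss, df1, ss_err, df2) {
    ms <- ss / df1; mse <- ss_err / df2
    f <- f_ratio(ms, mse)
    data.frame(effect = name, SS = ss, df1 = df1, df2 = df2, F = f,
               p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  df_s <- n - 1L
  effects <- rbind(
    eff("lexicality", ss_a, a - 1L, ss_as, (a - 1L) * df_s),
    eff("gla", ss_b, b - 1L, ss_bs, (b - 1L) * df_s),
    eff("interaction", ss_ab, (a - 1L) * (b - 1L), ss_abs,
        (a - 1L) * (b - 1L) * df_s))
  if (gg_correction) {
    effects <- gg_correct(effects, Y)
  }

  contrasts <- rbind(
    contrast_rows(Y, "pooled"),
    contrast_rows(Y, "word"),
    contrast_rows(Y, "nonword"))
  simple <- rbind(simple_effect_row(Y, "word"), simple_effect_row(Y, "nonword"))

  structure(list(effects = effects, contrasts = contrasts,
                 simple_effects = simple,
                 region = table$region[1L], n_subjects = n),
            class = "rm_anova_result")
}

# polynomial contrast (linear / quadratic) on level means, tested against
# the subject-by-contrast error; slice = "word"/"nonword"/"pooled"
contrast_rows <- function(Y, slice) {
  n <- dim(Y)[1L]
  scores_mat <- switch(slice,
                       pooled = apply(Y, c(1L, 3L), mean),
                       Y[, slice, ])
  a_eff <- if (slice == "pooled") 2L else 1L
  out <- lapply(list(linear = c(-1, 0, 1), quadratic = c(1, -2, 1)),
                function(w) {
    L <- drop(scores_mat %*% w)
    est <- mean(L)
    ss <- a_eff * n * est^2 / sum(w^2)
    ss_err <- a_eff * sum((L - est)^2) / sum(w^2)
    df2 <- n - 1L
    f <- f_ratio(ss, ss_err / df2)
    data.frame(SS = ss, df1 = 1L, df2 = df2, F = f,
               p = stats::pf(f, 1L, df2, lower.tail = FALSE),
               estimate = est)
  })
  cbind(data.frame(lexicality = slice,
                   contrast = c("linear", "quadratic")),
        do.call(rbind, out))
}

# one-way repeated-measures GLA effect within one lexicality slice
simple_effect_row <- function(Y, slice) {
  n <- dim(Y)[1L]; b <- 3L
  S <- Y[, slice, ]              # n x 3
  gm <- mean(S)
  m_b <- colMeans(S)
  m_s <- rowMeans(S)
  ss_b <- n * sum((m_b - gm)^2)
  ss_err <- sum((sweep(sweep(S, 2L, m_b), 1L, m_s) + gm)^2)
  df1 <- b - 1L; df2 <- (b - 1L) * (n - 1L)
  f <- f_ratio(ss_b / df1, ss_err / df2)
  data.frame(lexicality = slice, SS = ss_b, df1 = df1, df2 = df2, F = f,
             p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Greenhouse-Geisser epsilon for the 2-df within effects (optional)
gg_correct <- function(effects, Y) {
  n <- dim(Y)[1L]
  eps_of <- function(mat) {           # mat: n x k per-subject scores
    Sg <- stats::cov(mat)
    k <- ncol(Sg)
    num <- (k * mean(diag(Sg)) - mean(Sg))^2
    den <- (k - 1) * (sum(Sg^2) - 2 * k * sum(rowMeans(Sg)^2) +
                        k^2 * mean(Sg)^2)
    min(1, num / den)
  }
  m_sb <- apply(Y, c(1L, 3L), mean)
  eps_b <- eps_of(m_sb)
  ab <- cbind(Y[, 1L, ] - Y[, 2L, ])  # lexicality difference per level
  eps_ab <- eps_of(ab)
  for (row in c("gla", "interaction")) {
    i <- effects$effect == row
    eps <- if (row == "gla") eps_b else eps_ab
    effects$p[i] <- stats::pf(effects$F[i], effects$df1[i] * eps,
                              effects$df2[i] * eps, lower.tail = FALSE)
  }
  effects
}

#' Linear (or quadratic) polynomial trend contrast on GLA levels
#'
#' Single-df contrast with weights (-1, 0, +1) (linear) or (+1, -2, +1)
#' (quadratic) applied to the level means of one lexicality slice or pooled
#' across lexicalities, tested against the subject-by-contrast error.
#'
#' @param table A [region_signal_table].
#' @param lexicality `"word"`, `"nonword"` or `"pooled"`.
#' @param contrast `"linear"` or `"quadratic"`.
#' @return One-row data frame with `SS`, `df1`, `df2`, `F`, `p`,
#'   `estimate` (the mean per-subject contrast score; its sign is the trend
#'   direction).
#' @export
linear_contrast <- function(table, lexicality = c("pooled", "word", "nonword"),
                            contrast = c("linear", "quadratic")) {
  lexicality <- match.arg(lexicality)
  contrast <- match.arg(contrast)
  if (!inherits(table, "region_signal_table")) {
    table <- region_signal_table(table)
  }
  rows <- contrast_rows(rst_cells(table), lexicality)
  rows[rows$contrast == contrast, , drop = FALSE]
}

#' Simple GLA effects within each lexicality
#'
#' One-way repeated-measures GLA effect computed within the word slice and
#' within the nonword slice (slice-wise error terms; set `pooled_error =
#' TRUE` to test both against the omnibus GLA-by-subject error).
#'
#' @param table A [region_signal_table].
#' @param pooled_error Use the pooled (omnibus) error term.
#' @return Data frame with one row per lexicality: `SS`, `df1`, `df2`,
#'   `F`, `p`.
#' @export
simple_effects <- function(table, pooled_error = FALSE) {
  if (!inherits(table, "region_signal_table")) {
    table <- region_signal_table(table)
  }
  Y <- rst_cells(table)
  out <- rbind(simple_effect_row(Y, "word"), simple_effect_row(Y, "nonword"))
  if (pooled_error) {
    n <- dim(Y)[1L]
    # pooled error: sum of both slices' subject-by-level SS
    pool_ss <- 0
    for (sl in LEX2) {
      S <- Y[, sl, ]
      pool_ss <- pool_ss +
        sum((sweep(sweep(S, 2L, colMeans(S)), 1L, rowMeans(S)) + mean(S))^2)
    }
    df2 <- 2L * 2L * (n - 1L)
    out$F <- (out$SS / out$df1) / (pool_ss / df2)
    out$df2 <- df2
    out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  }
  out
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("<rm_anova_result> region '%s', %d subjects\n",
              x$region, x$n_subjects))
  print(x$effects, row.names = FALSE, digits = 4)
  cat("contrasts:\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Classify a region's GLA response profile
#'
#' Decision tree over the ANOVA significance pattern:
#' if the lexicality-by-GLA interaction is significant, the profile is
#' named after whichever lexicality carries a significant linear contrast
#' (`word-specific-linear`, `nonword-specific-linear`, `shared-linear` if
#' both, `interaction-nonlinear` if neither); without an interaction, a
#' significant GLA main effect with a significant pooled linear contrast is
#' `shared-linear`; anything else is `null`. The attached `direction`
#' attribute gives the sign of the relevant linear trend (increasing or
#' decreasing with GLA).
#'
#' @param result An [rm_anova_2x3] result.
#' @param alpha Significance level for every test in the tree.
#' @return Character profile label with attribute `direction`.
#' @export
classify_region_profile <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "rm_anova_result"))
  eff <- result$effects
  ctr <- result$contrasts
  p_of <- function(name) eff$p[eff$effect == name]
  crow <- function(lex) ctr[ctr$lexicality == lex & ctr$contrast == "linear", ]
  dir_of <- function(est) if (est >= 0) "increasing" else "decreasing"
  w <- crow("word"); nw <- crow("nonword"); po <- crow("pooled")
  if (p_of("interaction") < alpha) {
    ws <- w$p < alpha; ns <- nw$p < alpha
    label <- if (ws && !ns) "word-specific-linear"
    else if (ns && !ws) "nonword-specific-linear"
    else if (ws && ns) "shared-linear"
    else "interaction-nonlinear"
    est <- if (ws && !ns) w$estimate else if (ns && !ws) nw$estimate else po$estimate
  } else if (p_of("gla") < alpha && po$p < alpha) {
    label <- "shared-linear"
    est <- po$estimate
  } else {
    label <- "null"
    est <- po$estimate
  }
  structure(label, direction = dir_of(est))
}
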