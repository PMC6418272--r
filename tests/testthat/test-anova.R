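make_table <- function(n, f = function(s, l, j) 0, noise = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(subject = sprintf("s%02d", 1:n),
                      lexicality = c("word", "nonword"),
                      level = c("low", "medium", "high"),
                      stringsAsFactors = FALSE)
  j <- match(grid$level, c("low", "medium", "high")) - 1L
  grid$value <- mapply(f, grid$subject, grid$lexicality, j) +
    rnorm(nrow(grid), 0, noise)
  region_signal_table(grid, region = "test")
}

test_that("constant tables give zero F for every effect", {
  tab <- make_table(6, function(s, l, j) 2.5)
  res <- rm_anova_2x3(tab)
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$contrasts$F == 0))
})

test_that("within-subject dfs follow the balanced 2x3 design", {
  tab <- make_table(20, noise = 1)
  res <- rm_anova_2x3(tab)
  gla <- res$effects[res$effects$effect == "gla", ]
  expect_equal(c(gla$df1, gla$df2), c(2, 38))
  lexe <- res$effects[res$effects$effect == "lexicality", ]
  expect_equal(c(lexe$df1, lexe$df2), c(1, 19))
  ctr <- res$contrasts[res$contrasts$lexicality == "word" &
                         res$contrasts$contrast == "linear", ]
  expect_equal(c(ctr$df1, ctr$df2), c(1, 19))
  se <- simple_effects(tab)
  expect_equal(unique(se$df1), 2)
  expect_equal(unique(se$df2), 38)
})

test_that("unbalanced or degenerate tables are rejected", {
  tab <- as.data.frame(make_table(5, noise = 1))
  expect_error(region_signal_table(tab[-1, ]), "unbalanced")
  tab2 <- tab[tab$subject %in% c("s01", "s02"), ]
  expect_error(region_signal_table(tab2), "3 subjects")
  tab$value[1] <- NA
  expect_error(region_signal_table(tab), "value")
})

test_that("F statistics match the brute-force SS oracle on random tables", {
  set.seed(55)
  for (rep in 1:8) {
    tab <- make_table(8, noise = 1, seed = rep)
    res <- rm_anova_2x3(tab)
    y <- rst_to_array(as.data.frame(tab))
    o <- brute_rm_anova(y)
    eff <- res$effects
    expect_equal(eff$F[eff$effect == "lexicality"], o$Fa, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "gla"], o$Fb, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "interaction"], o$Fab,
                 tolerance = 1e-8)
    # contrasts against per-subject-score first principles
    for (sl in list(list("word", 1L), list("nonword", 2L),
                    list("pooled", NULL))) {
      got <- res$contrasts[res$contrasts$lexicality == sl[[1]] &
                             res$contrasts$contrast == "linear", ]
      want <- brute_contrast(y, c(-1, 0, 1), sl[[2]])
      expect_equal(got$F, want$F, tolerance = 1e-8)
      expect_equal(got$p, want$p, tolerance = 1e-8)
    }
  }
})

test_that("omnibus effects agree with aov error-stratum output", {
  tab <- make_table(7, noise = 0.8, seed = 99)
  res <- rm_anova_2x3(tab)
  d <- as.data.frame(tab)
  d$subject <- factor(d$subject)
  d$lexicality <- factor(d$lexicality)
  d$level <- factor(d$level)
  a <- summary(stats::aov(value ~ lexicality * level +
                            Error(subject / (lexicality * level)), data = d))
  f_aov <- c(a[["Error: subject:lexicality"]][[1]]$`F value`[1],
             a[["Error: subject:level"]][[1]]$`F value`[1],
             a[["Error: subject:lexicality:level"]][[1]]$`F value`[1])
  expect_equal(res$effects$F, f_aov, tolerance = 1e-8)
})

test_that("linear and quadratic contrasts decompose the GLA effect", {
  set.seed(66)
  for (rep in 1:5) {
    tab <- make_table(9, noise = 1, seed = 100 + rep)
    res <- rm_anova_2x3(tab)
    ss_gla <- res$effects$SS[res$effects$effect == "gla"]
    cc <- res$contrasts[res$contrasts$lexicality == "pooled", ]
    expect_equal(sum(cc$SS), ss_gla, tolerance = 1e-8)
  }
})

test_that("pure trends land entirely in the matching contrast", {
  lin <- make_table(6, function(s, l, j) j)      # means (0, 1, 2)
  res <- rm_anova_2x3(lin)
  cc <- res$contrasts[res$contrasts$lexicality == "pooled", ]
  expect_equal(cc$SS[cc$contrast == "quadratic"], 0, tolerance = 1e-12)
  expect_equal(cc$SS[cc$contrast == "linear"],
               res$effects$SS[res$effects$effect == "gla"],
               tolerance = 1e-12)
  bump <- make_table(6, function(s, l, j) c(1, 2, 1)[j + 1])
  res2 <- rm_anova_2x3(bump)
  cc2 <- res2$contrasts[res2$contrasts$lexicality == "pooled", ]
  expect_equal(cc2$SS[cc2$contrast == "linear"], 0, tolerance = 1e-12)
})

test_that("simple effects isolate the lexicality slices", {
  tab <- make_table(8, function(s, l, j) if (l == "nonword") j else 0,
                    noise = 0.2, seed = 7)
  se <- simple_effects(tab)
  expect_gt(se$F[se$lexicality == "nonword"], se$F[se$lexicality == "word"])
  # a slice with no GLA variation at all gives F = 0
  flat <- make_table(8, function(s, l, j) if (l == "word") 0 else j)
  se2 <- simple_effects(flat)
  expect_equal(se2$F[se2$lexicality == "word"], 0)
  expect_gt(se2$F[se2$lexicality == "nonword"], 0)
  # slice-wise oracle
  y <- rst_to_array(as.data.frame(tab))
  S <- y[, 2, ]
  d <- data.frame(v = as.vector(S),
                  subj = factor(rep(1:8, 3)),
                  lev = factor(rep(1:3, each = 8)))
  a <- summary(stats::aov(v ~ lev + Error(subj / lev), data = d))
  expect_equal(se$F[se$lexicality == "nonword"],
               a[["Error: subj:lev"]][[1]]$`F value`[1], tolerance = 1e-8)
})

test_that("F statistics are invariant to shifting and scaling", {
  tab <- make_table(6, noise = 1, seed = 13)
  res <- rm_anova_2x3(tab)
  d <- as.data.frame(tab)
  d$value <- d$value * 13.7 - 4.2
  res2 <- rm_anova_2x3(region_signal_table(d))
  expect_equal(res$effects$F, res2$effects$F, tolerance = 1e-10)
  expect_equal(res$contrasts$F, res2$contrasts$F, tolerance = 1e-10)
})

test_that("profile classification follows the significance decision tree", {
  big <- 1  # effects so large that every intended test is significant
  # word-only linear trend with interaction
  wsl <- rm_anova_2x3(make_table(12, function(s, l, j)
    if (l == "word") big * j else 0, noise = 0.15, seed = 21))
  expect_equal(unclass(classify_region_profile(wsl)),
               "word-specific-linear", ignore_attr = TRUE)
  expect_equal(attr(classify_region_profile(wsl), "direction"), "increasing")
  # decreasing nonword-only trend
  nsl <- rm_anova_2x3(make_table(12, function(s, l, j)
    if (l == "nonword") -big * j else 0, noise = 0.15, seed = 22))
  expect_equal(unclass(classify_region_profile(nsl)),
               "nonword-specific-linear", ignore_attr = TRUE)
  expect_equal(attr(classify_region_profile(nsl), "direction"), "decreasing")
  # both lexicalities share the same trend: no interaction
  sh <- rm_anova_2x3(make_table(12, function(s, l, j) big * j,
                                noise = 0.15, seed = 23))
  expect_equal(unclass(classify_region_profile(sh)), "shared-linear",
               ignore_attr = TRUE)
  # pure noise: null
  nl <- rm_anova_2x3(make_table(12, noise = 1, seed = 24))
  expect_equal(unclass(classify_region_profile(nl)), "null",
               ignore_attr = TRUE)
})

test_that("region tables round-trip through long-format files", {
  tab <- make_table(4, noise = 0.5, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(as.data.frame(tab), f, sep = ",", row.names = FALSE,
                     quote = FALSE)
  back <- read_region_signals(f)
  expect_named(back, "test")
  expect_equal(sort(back$test$value), sort(tab$value))
})
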