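test_that("nonword pools are unique substitution derivatives outside the lexicon", {
  lex <- lexicon(c("lamp", "desk", "cat"), c(10, 5, 2),
                 length_bounds = c(3, 5), alphabet = letters)
  pool <- generate_nonword_pool(c("lamp", "desk"), lex, 25, seed = 4)
  expect_length(pool, 25L)
  expect_equal(anyDuplicated(pool), 0L)
  expect_false(any(pool %in% lex$word))
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  d <- vapply(pool, function(nw)
    min(hamming(nw, "lamp"), hamming(nw, "desk")), numeric(1))
  expect_true(all(d >= 1 & d <= 4))
  # pure function of the seed
  expect_identical(pool, generate_nonword_pool(c("lamp", "desk"), lex, 25,
                                               seed = 4))
  expect_false(identical(pool,
                         generate_nonword_pool(c("lamp", "desk"), lex, 25,
                                               seed = 5)))
})

test_that("degenerate nonword-pool requests behave per contract", {
  lex <- lexicon(c("lamp", "desk"), c(10, 5), alphabet = letters)
  expect_identical(generate_nonword_pool(c("lamp", "desk"), lex, 0, seed = 1),
                   character(0))
  lex1 <- lexicon(c("aaa", "aaaa"), c(1, 1), alphabet = "a")
  expect_error(generate_nonword_pool("aaaa", lex1, 3, seed = 1),
               "alphabet of size 1")
  expect_error(generate_nonword_pool(c("cat", "lamp"), lex, 3, seed = 1),
               "same length")
})

test_that("pools already satisfying the constraints are returned unchanged", {
  set.seed(15)
  wp <- data.frame(stimulus = sprintf("w%03d", 1:60),
                   GLAz = rnorm(60, 0.8, 0.5))
  np <- data.frame(stimulus = sprintf("n%03d", 1:60),
                   GLAz = rnorm(60, -0.8, 0.5))
  con <- selection_constraints(n_per_class = 60, seed = 3)
  sel <- select_stimuli(wp, np, con)
  expect_identical(sel$words, wp)
  expect_identical(sel$nonwords, np)
  expect_gt(sel$audit$shapiro_words, con$normality_alpha)
  expect_lt(sel$audit$welch, con$mean_diff_alpha)
})

test_that("selection output passes its own three constraints", {
  set.seed(21)
  # lumpy, skewed pools like real GLA distributions
  wp <- data.frame(stimulus = sprintf("w%04d", 1:400),
                   GLAz = c(rexp(300, 2) + 0.5, rnorm(100, 1.2, 0.4)))
  np <- data.frame(stimulus = sprintf("n%04d", 1:900),
                   GLAz = c(rep(-1, 200), rexp(700, 1.5) - 1))
  con <- selection_constraints(n_per_class = 150, seed = 8)
  sel <- select_stimuli(wp, np, con)
  expect_equal(nrow(sel$words), 150L)
  expect_equal(nrow(sel$nonwords), 150L)
  # independent re-audit of the returned sets
  expect_gt(shapiro.test(sel$words$GLAz)$p.value, con$normality_alpha)
  expect_gt(shapiro.test(sel$nonwords$GLAz)$p.value, con$normality_alpha)
  expect_lt(t.test(sel$words$GLAz, sel$nonwords$GLAz)$p.value,
            con$mean_diff_alpha)
  lv <- car::leveneTest(c(sel$words$GLAz, sel$nonwords$GLAz),
                        factor(rep(1:2, each = 150)), center = median)
  expect_gt(lv[["Pr(>F)"]][1], con$variance_alpha)
  # deterministic given the seed
  sel2 <- select_stimuli(wp, np, con)
  expect_identical(sel$words$stimulus, sel2$words$stimulus)
})

test_that("undersized pools are rejected", {
  wp <- data.frame(stimulus = letters[1:10], GLAz = rnorm(10))
  expect_error(select_stimuli(wp, wp, selection_constraints(n_per_class = 300)))
})

test_that("tertile levels split near-equally in GLA order", {
  rec <- data.frame(GLAz = c(3, 1, 2, 6, 5, 4))
  lev <- assign_gla_levels(rec)
  expect_equal(as.character(lev$level),
               c("medium", "low", "low", "high", "high", "medium"))
  rec300 <- data.frame(GLAz = rnorm(300))
  expect_equal(as.integer(table(assign_gla_levels(rec300)$level)),
               c(100L, 100L, 100L))
  # non-divisible sizes differ by at most one
  for (n in 4:9) {
    sizes <- table(assign_gla_levels(data.frame(GLAz = rnorm(n)))$level)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_error(assign_gla_levels(data.frame(GLAz = rnorm(9)), k = 4),
               "k = 3")
})

test_that("ties at tertile boundaries resolve by stable input order", {
  rec <- data.frame(id = 1:6, GLAz = c(1, 1, 1, 1, 1, 2))
  lev <- assign_gla_levels(rec)
  expect_equal(as.character(lev$level),
               c("low", "low", "medium", "medium", "high", "high"))
  sizes <- table(lev$level)
  expect_lte(max(sizes) - min(sizes), 1L)
})

test_that("descriptor tables average measures per lexicality and level", {
  rec <- data.frame(lexicality = rep(c("word", "nonword"), each = 6),
                    level = factor(rep(rep(c("low", "medium", "high"), 2),
                                       each = 2),
                                   levels = c("low", "medium", "high")),
                    GLA = rep(0.5, 12), LogF = rep(1, 12),
                    Fmio = rep(9, 12), N = rep(2, 12), FN = rep(4, 12),
                    BiC = rep(3, 12), BiF = rep(7, 12))
  tab <- descriptor_table(rec)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$GLA == 0.5))
  expect_true(all(tab$N == 2))
  rec2 <- rec[rec$level != "medium" | rec$lexicality != "word", ]
  expect_error(descriptor_table(rec2), "empty")
})

test_that("level means of GLA increase with tertile by construction", {
  set.seed(31)
  rec <- data.frame(lexicality = "word", GLA = runif(90), N = 1,
                    LogF = 1, Fmio = 1, FN = 1, BiC = 1, BiF = 1)
  rec$GLAz <- z_transform(rec$GLA)
  rec <- assign_gla_levels(rec)
  tab <- descriptor_table(rec)
  expect_true(all(diff(tab$GLA[order(tab$level)]) > 0))
})

test_that("gla_correlations recovers exact and null relationships", {
  set.seed(41)
  n <- 1000
  base <- data.frame(lexicality = rep(c("word", "nonword"), each = n))
  base$N <- rpois(2 * n, 4)
  base$FN <- base$N * 10 + rnorm(2 * n)
  base$GLA <- base$N * 0.05          # exactly proportional to N
  ct <- gla_correlations(base)
  expect_equal(ct$r_words[ct$measure == "N"], 1.0, tolerance = 1e-12)
  expect_equal(ct$r_nonwords[ct$measure == "N"], 1.0, tolerance = 1e-12)
  base$GLA <- rnorm(2 * n)           # independent noise
  ct2 <- gla_correlations(base)
  expect_true(all(abs(c(ct2$r_words, ct2$r_nonwords)) < 0.1))
  base$N <- 3                        # constant column -> undefined r
  ct3 <- gla_correlations(base)
  expect_true(is.na(ct3$r_words[ct3$measure == "N"]))
})
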