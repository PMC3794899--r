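test_that("absolute rate is the product of level, occupancy and specific rate", {
  expect_equal(absolute_rate(2.0, 0.5, 1.0), 1.0)
  expect_equal(absolute_rate(3, 0, 2), 0)
  expect_equal(absolute_rate(2 * 1.7, 0.4, 0.9), 2 * absolute_rate(1.7, 0.4, 0.9))
  # rescaling all mRNA levels rescales rates without reordering
  m <- c(1, 5, 2); pr <- c(0.5, 0.9, 0.7); vs <- c(0.2, 0.1, 1)
  expect_equal(order(absolute_rate(10 * m, pr, vs)),
               order(absolute_rate(m, pr, vs)))
  expect_error(absolute_rate(-1, 0.5, 1), "non-negative")
})

test_that("category summaries use interpolated quartiles and the notch rule", {
  df <- data.frame(category = "A", V_abs = c(1, 2, 3, 4, 5))
  s <- category_summary(df)
  a <- s[s$category == "A", ]
  expect_equal(a$median, 3)
  expect_equal(a$q1, 2)          # type-7 linear interpolation
  expect_equal(a$q3, 4)
  expect_equal(a$notch, 1.57 * 2 / sqrt(5))
  expect_true("ALL" %in% s$category)
  # constant values give zero-width notches
  s0 <- category_summary(data.frame(category = "B", V_abs = rep(2, 4)))
  expect_equal(s0$notch, c(0, 0))
  # ordering is by median and invariant under shuffling
  df2 <- data.frame(category = rep(c("lo", "hi"), each = 4),
                    V_abs = c(1:4, 11:14))
  s2 <- category_summary(df2)
  set.seed(1)
  s3 <- category_summary(df2[sample(8), ])
  expect_identical(s2, s3)
  expect_identical(s2$category, c("lo", "ALL", "hi"))
})

test_that("condition comparison calls changes only on non-overlapping notches", {
  s <- category_summary(data.frame(category = rep(c("a", "b"), each = 5),
                                   V_abs = c(1:5, 8:12)))
  expect_true(all(compare_conditions(s, s)$call == "ns"))
  hi <- s; hi$median <- hi$median + 100
  cmp <- compare_conditions(s, hi)
  expect_true(all(cmp$call == "+"))
  # antisymmetry: swapping conditions flips the sign
  expect_true(all(compare_conditions(hi, s)$call == "-"))
  expect_warning(
    compare_conditions(s, s[s$category != "a", ]), "one condition")
})

test_that("stress-like shift in one category is detected as an increase", {
  set.seed(11)
  base <- data.frame(
    category = rep(c("REG", "NRJ", "TRD"), each = 30),
    V_abs = rlnorm(90, 0, 0.3))
  stress <- base
  stress$V_abs[stress$category == "REG"] <-
    stress$V_abs[stress$category == "REG"] * 6
  cmp <- compare_conditions(category_summary(base), category_summary(stress))
  expect_identical(cmp$call[cmp$category == "REG"], "+")
  expect_identical(cmp$call[cmp$category == "NRJ"], "ns")
})

test_that("operon ANOVA reproduces hand-computed sums of squares", {
  m <- matrix(0.5, 6, 7)
  rownames(m) <- paste0("g", 1:6)
  m[, 4] <- c(1, 2, 3, 2, 3, 4)   # SSB = 1.5, SSW = 4
  a <- operon_anova(m, c("g1", "g2", "g3"), 4)
  expect_equal(a$F, 1.5)
  expect_equal(a$df, c(1, 4))
  expect_equal(a$p, stats::pf(1.5, 1, 4, lower.tail = FALSE))
  # identical groups: no signal by convention
  m2 <- m; m2[, 4] <- 1
  a2 <- operon_anova(m2, c("g1", "g2", "g3"), 4)
  expect_equal(a2$F, 0)
  expect_equal(a2$p, 1)
  expect_error(operon_anova(m, "g1", 4), "at least 2")
})

test_that("operon with injected last-fraction excess is detected", {
  set.seed(13)
  mk <- function(id, hmass) {
    base <- c(0.1, 0.1, 0.15, 0.2, 0.2, 0.25 - hmass, hmass)
    reps <- t(replicate(3, {
      x <- base * exp(rnorm(7, 0, 0.05)); x / sum(x)
    }))
    fraction_profile(id, reps)
  }
  profs <- c(lapply(1:3, function(i) mk(paste0("op", i), 0.2)),
             lapply(1:20, function(i) mk(paste0("bg", i), 0.02)))
  res <- operon_anova(profs, paste0("op", 1:3), "H")
  expect_lt(res$p, 0.01)
})

test_that("hypergeometric enrichment matches exhaustive combinatorics", {
  e <- enrichment(c(rep("A", 5), rep("B", 5)),
                  c(rep("x", 4), rep("y", 6)))
  # N = 10, K = 4, n = 5, k = 4: C(4,4) C(6,1) / C(10,5)
  expect_equal(e$p[e$group == "A" & e$category == "x"], 6 / 252)
  row <- e[e$group == "A" & e$category == "x", ]
  expect_equal(c(row$k, row$K, row$n, row$N), c(4, 4, 5, 10))
  # category fully inside a group that spans the genome: p = 1
  e2 <- enrichment(rep("A", 8), c(rep("x", 3), rep("y", 5)))
  expect_equal(e2$p, c(1, 1))
  # monotone decreasing in k at fixed margins, checked by enumeration
  ps <- vapply(0:4, function(k) {
    g <- c(rep("A", 5), rep("B", 7))
    ca <- rep("y", 12)
    ca[seq_len(k)] <- "x"                   # k of category x inside A
    if (k < 4) ca[5 + seq_len(4 - k)] <- "x"  # rest of the 4 outside
    enrichment(g, ca)$p[1]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("regulatory-category enrichment reproduces the published order", {
  # 64 of 73 regulatory genes inside a 788-gene initiation-limited group
  # out of 1108: upper-tail hypergeometric p ~ 4.8e-4
  p <- stats::phyper(63, 73, 1108 - 73, 788, lower.tail = FALSE)
  expect_equal(p, 4.8e-4, tolerance = 0.01)
  expect_gt(p, 1e-4)
  expect_lt(p, 1e-3)
})
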