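test_that("fraction profiles validate their proportions", {
  expect_error(fraction_profile("g", c(0.5, 0.5)), "7 columns")
  expect_error(fraction_profile("g", c(0.5, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1)),
               "sum to 1")
  expect_error(fraction_profile("g", c(-0.1, 0.4, 0.7, 0, 0, 0, 0)),
               "non-negative")
})

test_that("single-fraction mass gives that fraction's polysome size", {
  est <- estimate_polysome_size(
    fraction_profile("g", c(0, 0, 0, 0, 1, 0, 0)), n_codons = 350)
  expect_equal(est$P_hat, 4.1)
  expect_equal(est$p_rib, 1)
  expect_equal(est$rho_hat, 10 * 4.1 / 350)
  expect_identical(est$status, "ok")
})

test_that("occupancy is the engaged complement of the B/C mass", {
  # a citC-like profile: 10% of copies in fraction B, 17% in fraction C
  pr <- fraction_profile("citC", c(0.10, 0.17, 0.08, 0.15, 0.20, 0.15, 0.15))
  est <- estimate_polysome_size(pr, n_codons = 347)
  expect_equal(est$p_rib, 0.73)
  # summation oracle: engaged + non-engaged mass = 1
  expect_equal(est$p_rib + 0.10 + 0.17, 1)
})

test_that("genes with all mass non-engaged are excluded", {
  est <- estimate_polysome_size(
    fraction_profile("g", c(1, 0, 0, 0, 0, 0, 0)), n_codons = 200)
  expect_identical(est$status, "excluded")
  expect_identical(est$p_rib, 0)
  expect_true(is.na(est$P_hat))
})

test_that("modal estimator picks the heaviest engaged fraction", {
  pr <- fraction_profile("g", c(0.1, 0.1, 0.1, 0.15, 0.3, 0.15, 0.1))
  est <- estimate_polysome_size(pr, n_codons = 300, method = "modal")
  expect_equal(est$P_hat, 4.1)
})

test_that("estimates are invariant to replicate order", {
  m <- rbind(c(0.1, 0.1, 0.1, 0.2, 0.2, 0.2, 0.1),
             c(0.2, 0.1, 0.1, 0.1, 0.2, 0.1, 0.2),
             c(0.1, 0.2, 0.2, 0.1, 0.1, 0.2, 0.1))
  a <- estimate_polysome_size(fraction_profile("g", m), 300)
  b <- estimate_polysome_size(fraction_profile("g", m[c(3, 1, 2), ]), 300)
  expect_equal(a$P_hat, b$P_hat)
  expect_equal(a$p_rib, b$p_rib)
})

test_that("co-elution recalibration removes the minimal H mass", {
  pr <- fraction_profile("g", c(0.2, 0.1, 0.05, 0.05, 0.05, 0.05, 0.5))
  est <- estimate_polysome_size(pr, n_codons = 97)
  expect_gt(est$rho_hat, 1)
  rec <- recalibrate_coelution(est, pr, n = 97)
  expect_identical(rec$estimate$status, "recalibrated")
  expect_equal(rec$estimate$rho_hat, 1, tolerance = 1e-9)
  # brute-force oracle: smallest removal delta on a grid that caps density
  grid <- seq(0, 0.5, by = 1e-5)
  pvec <- as.numeric(pr$proportions)
  rho_after <- vapply(grid, function(d) {
    v <- pvec; v[7] <- v[7] - d
    10 * sum(v[3:7] * pr$sizes[3:7]) / sum(v[3:7]) / 97
  }, numeric(1))
  d_star <- grid[min(which(rho_after <= 1))]
  expect_equal(rec$estimate$removed_mass, d_star, tolerance = 1e-4)
})

test_that("recalibration leaves compliant genes untouched and never raises density", {
  pr <- fraction_profile("g", c(0.1, 0.1, 0.2, 0.2, 0.2, 0.1, 0.1))
  est <- estimate_polysome_size(pr, n_codons = 350)
  rec <- recalibrate_coelution(est, pr, n = 350)
  expect_identical(rec$estimate$status, "ok")
  expect_identical(rec$estimate$removed_mass, 0)
  expect_identical(rec$profile$proportions, pr$proportions)
  # noisy triplicate above the cap: density is reduced, not increased
  set.seed(8)
  m <- matrix(rep(c(0.1, 0.05, 0.05, 0.05, 0.05, 0.1, 0.6), each = 3), 3)
  m <- m * exp(matrix(rnorm(21, 0, 0.15), 3))
  m <- m / rowSums(m)
  pr2 <- fraction_profile("g2", m)
  est2 <- estimate_polysome_size(pr2, n_codons = 110)
  rec2 <- recalibrate_coelution(est2, pr2, n = 110)
  expect_lte(rec2$estimate$rho_hat, 1 + 1e-9)
  expect_lt(rec2$estimate$rho_hat, est2$rho_hat)
})

test_that("genes impossible even with an empty last fraction are excluded", {
  # all engaged mass in G (7.4 ribosomes) on a 60-codon gene: rho > 1
  # no matter how much H mass is removed
  pr <- fraction_profile("g", c(0.05, 0.05, 0, 0, 0, 0.8, 0.1))
  est <- estimate_polysome_size(pr, n_codons = 60)
  rec <- recalibrate_coelution(est, pr, n = 60)
  expect_identical(rec$estimate$status, "excluded")
})

test_that("operon adjustment splits ribosomes by length only in shared mode", {
  est <- data.frame(gene_id = c("a", "b", "c"), P_hat = c(6, 6, 3))
  omap <- data.frame(gene_id = c("a", "b"), operon_id = "op1")
  lens <- c(a = 200, b = 100, c = 300)
  cons <- operon_share_adjustment(est, omap, lens, mode = "conservative")
  expect_identical(cons$P_hat, c(6, 6, 3))
  sh <- operon_share_adjustment(est, omap, lens, mode = "shared")
  expect_equal(sh$P_hat, c(4, 2, 3))
  # single-member operons are unchanged in both modes
  one <- operon_share_adjustment(est, data.frame(gene_id = "c",
                                                 operon_id = "solo"),
                                 lens, mode = "shared")
  expect_equal(one$P_hat, est$P_hat)
  expect_error(
    operon_share_adjustment(est, data.frame(gene_id = "zz", operon_id = "x"),
                            lens, mode = "shared"),
    "missing")
})

test_that("stratified profiles report per-stratum means and dispersions", {
  base <- c(0.1, 0.1, 0.2, 0.2, 0.2, 0.1, 0.1)
  p1 <- fraction_profile("a", base)
  p2 <- fraction_profile("b", base)
  s <- stratified_profiles(list(p1, p2), c("x", "x"))
  expect_equal(s$mean, base)
  expect_equal(s$sd, rep(0, 7))
  # singleton stratum: sd = 0 by convention
  s1 <- stratified_profiles(list(p1), "x")
  expect_equal(s1$sd, rep(0, 7))
  # strata constructed with shifted non-engaged mass order as built
  hiB <- fraction_profile("c", c(0.4, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05))
  s2 <- stratified_profiles(list(p1, hiB), c("lo", "hi"))
  mB <- s2$mean[s2$fraction == "B"]
  expect_gt(mB[s2$stratum[s2$fraction == "B"] == "hi"],
            mB[s2$stratum[s2$fraction == "B"] == "lo"])
  expect_error(stratified_profiles(list(p1), c("x", "y")), "label")
  expect_error(stratified_profiles(list(p1, p2), factor(c("x", "x"),
                                                        levels = c("x", "y"))),
               "empty stratum")
})
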