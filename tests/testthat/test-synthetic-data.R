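test_that("catalog bookkeeping is exact and seed-reproducible", {
  cfg <- generator_config(n_genes = 200, n_operons = 2, seed = 3)
  a <- generate_catalog(cfg, compute_kinetics = FALSE)
  b <- generate_catalog(cfg, compute_kinetics = FALSE)
  expect_identical(a, b)
  expect_identical(nrow(a$catalog), 200L)
  # category counts follow the configured composition exactly
  want <- cfg$category_counts / sum(cfg$category_counts) * 200
  got <- table(a$catalog$category)
  expect_true(all(abs(got[names(want)] - want) <= 1))
  expect_true(all(a$catalog$length_codons >= 2 * cfg$L))
  expect_true(all(a$catalog$m_rel > 0 & a$catalog$half_life_min > 0))
})

test_that("realized densities cover all six regime bins", {
  cfg <- generator_config(n_genes = 250, n_operons = 2, seed = 5)
  gen <- generate_catalog(cfg, compute_kinetics = FALSE)
  bins <- cut(gen$truths$rho_true,
              c(0, 0.19, 0.37, 0.52, 0.64, 0.86, 1))
  expect_true(all(table(bins) >= 1))
  # the assay ceiling: no gene carries more than 14 ribosomes
  expect_true(all(gen$truths$P_true <= 14 + 1e-9))
})

test_that("generated replicate rows are proper proportions", {
  cfg <- generator_config(n_genes = 40, n_operons = 1, seed = 2)
  gen <- generate_catalog(cfg, compute_kinetics = FALSE)
  profs <- generate_profiles(gen$catalog, gen$truths, cfg)
  expect_length(profs, 40)
  for (p in profs) {
    expect_equal(rowSums(p$proportions), rep(1, 3), tolerance = 1e-9)
    expect_true(all(p$proportions >= 0))
  }
})

test_that("noise-free profiles round-trip the true density exactly", {
  cfg <- generator_config(n_genes = 60, n_operons = 0, seed = 4,
                          contamination_rate = 0, noise_sd = 0,
                          dispersion_spill = 0)
  gen <- generate_catalog(cfg, compute_kinetics = FALSE)
  profs <- generate_profiles(gen$catalog, gen$truths, cfg)
  for (i in seq_len(60)) {
    est <- estimate_polysome_size(profs[[i]],
                                  n_codons = gen$catalog$length_codons[i])
    # interpolation weights make the engaged-mass-weighted mean exact,
    # up to the 1-ribosome floor of the smallest engaged fraction
    want <- max(gen$truths$P_true[i], 1)
    expect_equal(est$P_hat, want, tolerance = 1e-9)
    expect_equal(est$p_rib, gen$truths$occupancy[i], tolerance = 1e-9)
  }
})

test_that("contamination flags are confined to contaminated genes", {
  cfg <- generator_config(n_genes = 250, n_operons = 2, seed = 6)
  gen <- generate_catalog(cfg, compute_kinetics = FALSE)
  profs <- generate_profiles(gen$catalog, gen$truths, cfg)
  flagged <- logical(250)
  for (i in seq_len(250)) {
    n <- gen$catalog$length_codons[i]
    est <- estimate_polysome_size(profs[[i]], n_codons = n)
    rec <- recalibrate_coelution(est, profs[[i]], n = n)
    flagged[i] <- rec$estimate$status != "ok"
  }
  expect_true(all(gen$truths$contaminated[flagged]))
  expect_gt(sum(gen$truths$contaminated), 0)
  expect_gt(sum(flagged), 0)
  # and with contamination switched off there are no flags at all
  cfg0 <- generator_config(n_genes = 120, n_operons = 1, seed = 6,
                           contamination_rate = 0)
  gen0 <- generate_catalog(cfg0, compute_kinetics = FALSE)
  profs0 <- generate_profiles(gen0$catalog, gen0$truths, cfg0)
  flags0 <- vapply(seq_len(120), function(i) {
    n <- gen0$catalog$length_codons[i]
    est <- estimate_polysome_size(profs0[[i]], n_codons = n)
    recalibrate_coelution(est, profs0[[i]], n = n)$estimate$status != "ok"
  }, logical(1))
  expect_false(any(flags0))
})

test_that("operon members share the engaged-fraction distribution before noise", {
  cfg <- generator_config(n_genes = 80, n_operons = 3, seed = 9,
                          noise_sd = 0, contamination_rate = 0)
  gen <- generate_catalog(cfg, compute_kinetics = FALSE)
  profs <- generate_profiles(gen$catalog, gen$truths, cfg)
  ops <- unique(stats::na.omit(gen$catalog$operon_id))
  expect_gt(length(ops), 0)
  for (op in ops) {
    idx <- which(gen$catalog$operon_id == op)
    eng <- lapply(idx, function(i) {
      v <- colMeans(profs[[i]]$proportions)[3:7]
      v / sum(v)
    })
    for (j in seq_along(eng)[-1]) expect_equal(eng[[j]], eng[[1]])
  }
})

test_that("infeasible generator configurations are rejected", {
  expect_error(generator_config(n_genes = 10, n_operons = 5,
                                operon_size_range = c(4, 6)),
               "exceed")
  expect_error(generator_config(group_mix = c(I = 0.5, II = 0.4)))
})
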