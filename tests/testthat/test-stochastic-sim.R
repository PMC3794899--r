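test_that("no initiation means permanently empty copies", {
  ps <- translation_params(100, kappa_I = 0)
  sim <- simulate_translation(sim_config(ps, n_copies = 20, t_end = 100,
                                         burn_in = 10, seed = 1))
  expect_true(all(sim$time_avg == 0))
  expect_true(all(sim$final_count == 0))
})

test_that("a fixed seed reproduces the sample stream exactly", {
  ps <- translation_params(100, kappa_I = 0.05)
  cfg <- sim_config(ps, n_copies = 30, t_end = 200, burn_in = 20, seed = 7)
  a <- simulate_translation(cfg)
  b <- simulate_translation(cfg)
  expect_identical(a$time_avg, b$time_avg)
  expect_identical(a$final_count, b$final_count)
})

test_that("simulation matches the exact Markov-chain stationary law", {
  # n = 20, L = 10 is small enough to enumerate the chain exactly
  for (prm in list(c(kappa = 0.8, kT = 1e3), c(kappa = 1e3, kT = 2))) {
    ex <- oracle_ctmc(20, 10, 23, prm[["kappa"]], prm[["kT"]])
    ps <- translation_params(20, kappa_I = prm[["kappa"]], k_T = prm[["kT"]])
    sim <- simulate_translation(sim_config(ps, n_copies = 300, t_end = 1500,
                                           burn_in = 300, seed = 1))
    se <- sd(sim$time_avg) / sqrt(length(sim$time_avg))
    expect_lt(abs(mean(sim$time_avg) - ex$P), 4 * se)
  }
})

test_that("waiting times in the initiation-limited regime are exponential", {
  # elongation and termination are made fast so protein completions are a
  # renewal process with Exp(kappa) inter-arrival times
  ps <- translation_params(20, kappa_I = 0.5, k_E = 1e4, k_T = 1e4)
  sim <- simulate_translation(sim_config(ps, n_copies = 50, t_end = 500,
                                         burn_in = 0, seed = 3,
                                         collect_completions = TRUE))
  w <- unlist(lapply(sim$completions, diff))
  expect_gt(length(w), 1e4)
  expect_gt(stats::ks.test(w, "pexp", rate = 0.5)$p.value, 0.01)
})

test_that("snapshot distribution is unimodal at fraction resolution", {
  cal <- calibrate_gene(150, target_P = 6)
  sim <- simulate_translation(sim_config(cal$state$params, n_copies = 300,
                                         t_end = 600, burn_in = 150,
                                         seed = 2))
  prof <- bin_to_fractions(sim$final_count)
  eng <- prof$proportions[1, 3:7]
  top <- which.max(eng)
  # mass decays away from the single mode on both sides
  expect_true(all(diff(eng[seq_len(top)]) >= 0))
  expect_true(all(diff(eng[top:5]) <= 0))
})

test_that("an idle inhibitor leaves the simulation unchanged", {
  ps <- translation_params(100, kappa_I = 0.05)
  cfg <- sim_config(ps, n_copies = 30, t_end = 200, burn_in = 20, seed = 5)
  plain <- simulate_translation(cfg)
  idle <- simulate_with_inhibitor(cfg, inhibitor_config(0, 0))
  expect_identical(plain$time_avg, idle$time_avg)
  expect_identical(plain$final_count, idle$final_count)
})

test_that("slow inhibitor exchange yields a bimodal copy distribution", {
  cal <- calibrate_gene(150, target_P = 8)
  sim <- simulate_with_inhibitor(
    sim_config(cal$state$params, n_copies = 200, t_end = 1000, burn_in = 0,
               seed = 9),
    inhibitor_config(k_on = 1e-3, k_off = 1e-3))
  fc <- sim$final_count
  expect_gt(mean(fc <= 1), 0.25)          # near-empty mode
  expect_gt(mean(fc >= 5), 0.25)          # engaged mode
  expect_lt(mean(fc %in% 2:4), 0.15)      # trough between the modes
})

test_that("a permanently bound inhibitor silences all copies", {
  ps <- translation_params(100, kappa_I = 0.5)
  sim <- simulate_with_inhibitor(
    sim_config(ps, n_copies = 20, t_end = 100, burn_in = 0, seed = 1),
    inhibitor_config(k_on = 0, k_off = 0, initially_bound = 1))
  expect_true(all(sim$final_count == 0))
})

test_that("fragment model matches the renewal-theory closed form", {
  cfg <- fragment_config(lengths = 311, n_molecules = 20000, seed = 7)
  fr <- simulate_fragments(cfg)
  expect_lt(abs(fr$full_fraction - fr$expected), 3 * fr$se)
  tau_full <- 5 * 60 / log(2)
  expect_equal(fr$expected,
               tau_full / (933 / 69 + tau_full + 933 / 200))
  # no-decay limit: everything full-length
  fr2 <- simulate_fragments(fragment_config(lengths = 311, half_life = 1e7,
                                            n_molecules = 3000, seed = 7))
  expect_gt(fr2$full_fraction, 0.999)
})

test_that("binning splits empty copies and maps sizes to nearest fractions", {
  prof <- bin_to_fractions(c(0, 0, 14, 14))
  expect_equal(as.numeric(prof$proportions),
               c(0.25, 0.25, 0, 0, 0, 0, 0.5))
  prof2 <- bin_to_fractions(rep(4.1, 5))
  expect_equal(as.numeric(prof2$proportions), c(0, 0, 0, 0, 1, 0, 0))
  expect_error(bin_to_fractions(numeric(0)), "non-empty")
  expect_error(bin_to_fractions(c(1, NA)), "finite")
  # independent R oracle for nearest-fraction assignment
  set.seed(4)
  samples <- rpois(500, 5)
  sz <- fraction_sizes()
  nearest <- vapply(samples, function(s) {
    if (s < 0.5) return(0L)
    which.min(abs(sz[3:7] - s))
  }, integer(1))
  want <- c(mean(nearest == 0) / 2, mean(nearest == 0) / 2,
            vapply(1:5, function(k) mean(nearest == k), numeric(1)))
  got <- as.numeric(bin_to_fractions(samples)$proportions)
  expect_equal(got, want)
  # round trip: estimated polysome size of the binned profile is close to
  # the engaged-sample mean (within the binning quantization)
  est <- estimate_polysome_size(bin_to_fractions(samples), n_codons = 300)
  expect_lt(abs(est$P_hat - mean(samples[samples >= 1])), 1.5)
})
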