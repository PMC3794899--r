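#' Configuration of a stochastic translation simulation
#'
#' @param params A [translation_params()] object.
#' @param n_copies Number of independent mRNA copies to simulate.
#' @param t_end Simulated time horizon in seconds.
#' @param burn_in Time in seconds discarded before collecting statistics;
#'   must be below `t_end`.
#' @param seed Optional integer seed applied before simulation.
#' @param collect_completions If `TRUE`, record protein completion
#'   (termination) times per copy after the burn-in.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(params, n_copies = 100, t_end = 1000, burn_in = 200,
                       seed = NULL, collect_completions = FALSE) {
  stopifnot(inherits(params, "translation_params"),
            n_copies >= 1, t_end > burn_in, burn_in >= 0)
  structure(list(params = params, n_copies = as.integer(n_copies),
                 t_end = t_end, burn_in = burn_in, seed = seed,
                 collect_completions = isTRUE(collect_completions)),
            class = "sim_config")
}

#' Configuration of an initiation-inhibiting complex
#'
#' Models a complex (for instance an RNA-binding protein assembly
#' sequestering the small ribosomal subunit) that binds an mRNA copy with
#' rate `k_on` and releases it with rate `k_off`; while bound, translation
#' initiation on that copy is blocked.
#'
#' @param k_on,k_off Binding and unbinding rate constants, 1/s
#'   (non-negative).
#' @param initially_bound Probability that a copy starts in the bound
#'   state. Defaults to the stationary value `k_on / (k_on + k_off)` (0
#'   when both rates vanish).
#' @return An object of class `"inhibitor_config"`.
#' @export
inhibitor_config <- function(k_on, k_off, initially_bound = NULL) {
  stopifnot(k_on >= 0, k_off >= 0)
  if (is.null(initially_bound)) {
    initially_bound <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0
  }
  stopifnot(initially_bound >= 0, initially_bound <= 1)
  structure(list(k_on = k_on, k_off = k_off,
                 initially_bound = initially_bound),
            class = "inhibitor_config")
}

run_sim <- function(cfg, k_on = 0, k_off = 0, p_bound0 = 0) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- cfg$params
  res <- rt_simulate(p$n, p$L, p$k_E, p$kappa_I, p$k_T,
                     cfg$n_copies, cfg$t_end, cfg$burn_in,
                     k_on, k_off, p_bound0, cfg$collect_completions)
  structure(list(time_avg = res$time_avg, final_count = res$final_count,
                 completions = res$completions, config = cfg),
            class = "translation_sim")
}

#' Exact stochastic simulation of translation
#'
#' Event-driven (Gillespie) simulation of ribosome traffic on independent
#' mRNA copies with the same footprint rules as the deterministic model.
#' Returns, per copy, the time-averaged polysome size after the burn-in
#' and the polysome size at the final time (a snapshot of the copy
#' population, as a polysome gradient would sample it).
#'
#' @param cfg A [sim_config()].
#' @return An object of class `"translation_sim"` with `time_avg`,
#'   `final_count`, `completions` (per-copy protein completion times when
#'   requested) and the configuration.
#' @examples
#' ps <- translation_params(100, kappa_I = 0.05)
#' sim <- simulate_translation(sim_config(ps, n_copies = 20, t_end = 300,
#'                                        burn_in = 60, seed = 1))
#' mean(sim$time_avg)
#' @export
simulate_translation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  run_sim(cfg)
}

#' Stochastic translation with an initiation-inhibiting complex
#'
#' As [simulate_translation()], but each copy additionally carries a
#' bound/free inhibitor state; initiation is blocked while bound. With
#' slow exchange this produces a bimodal copy distribution -- one mode of
#' near-empty copies and one at the engaged polysome size -- as seen in
#' fraction-profile data with a distinct non-engaged peak.
#'
#' @param cfg A [sim_config()].
#' @param inh An [inhibitor_config()].
#' @return An object of class `"translation_sim"`.
#' @export
simulate_with_inhibitor <- function(cfg, inh) {
  stopifnot(inherits(cfg, "sim_config"), inherits(inh, "inhibitor_config"))
  run_sim(cfg, inh$k_on, inh$k_off, inh$initially_bound)
}

#' @export
print.translation_sim <- function(x, ...) {
  cat(sprintf("stochastic translation simulation: %d copies, t = %g s\n",
              length(x$time_avg), x$config$t_end))
  cat(sprintf("  mean polysome size %.3g (time-averaged), %.3g (final snapshot)\n",
              mean(x$time_avg), mean(x$final_count)))
  invisible(x)
}

#' Configuration of the mRNA fragment-size model
#'
#' Life cycle of an mRNA molecule: transcription elongates the nascent
#' chain at `tx_rate` nt/s until full length; the completed molecule then
#' initiates decay after an exponential waiting time with the gene's
#' half-life; decay erodes the molecule processively at `deg_rate` nt/s
#' until it disappears. At stationarity the population contains nascent,
#' full-length and decaying molecules in proportion to the mean time
#' spent in each phase.
#'
#' @param lengths Gene length(s) in codons.
#' @param tx_rate Transcription elongation rate, nt/s (default 69 nt/s,
#'   i.e. matching a translation rate of 23 codons/s).
#' @param deg_rate Processive degradation rate, nt/s (default 200).
#' @param half_life Half-life of the full-length molecule in minutes
#'   (default 5).
#' @param n_molecules Target number of molecules alive in the stationary
#'   snapshot, per length.
#' @param seed Optional integer seed.
#' @return An object of class `"fragment_config"`.
#' @export
fragment_config <- function(lengths, tx_rate = 69, deg_rate = 200,
                            half_life = 5, n_molecules = 10000,
                            seed = NULL) {
  stopifnot(all(lengths >= 1), tx_rate > 0, deg_rate > 0, half_life > 0,
            n_molecules >= 1)
  structure(list(lengths = as.numeric(lengths), tx_rate = tx_rate,
                 deg_rate = deg_rate, half_life = half_life,
                 n_molecules = as.integer(n_molecules), seed = seed),
            class = "fragment_config")
}

#' Stationary fraction of full-length mRNA molecules
#'
#' Simulates the birth-growth-decay renewal process of
#' [fragment_config()] at stationarity: molecules are born by a Poisson
#' process, observed in a population snapshot, and classified as nascent
#' (still being transcribed), full-length, or decaying fragments. The
#' expected full-length fraction has the renewal closed form
#' `tau_full / (tau_tx + tau_full + tau_deg)` with
#' `tau_full = half_life * 60 / ln 2`, which the simulation estimates
#' with a Monte-Carlo standard error.
#'
#' @param cfg A [fragment_config()].
#' @return A data frame with one row per gene length: `length_codons`,
#'   `n_alive` (molecules in the snapshot), `full_fraction`, `se`
#'   (binomial Monte-Carlo standard error) and `expected` (the renewal
#'   closed form).
#' @examples
#' simulate_fragments(fragment_config(lengths = 311, n_molecules = 2000,
#'                                    seed = 1))
#' @export
simulate_fragments <- function(cfg) {
  stopifnot(inherits(cfg, "fragment_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tau_full <- cfg$half_life * 60 / log(2)
  out <- lapply(cfg$lengths, function(len) {
    len_nt <- 3 * len
    tau_tx <- len_nt / cfg$tx_rate
    tau_deg <- len_nt / cfg$deg_rate
    mean_life <- tau_tx + tau_full + tau_deg
    lambda <- cfg$n_molecules / mean_life          # birth rate, 1/s
    window <- tau_tx + tau_deg + 40 * tau_full     # truncation ~ exp(-40)
    n_born <- rpois(1, lambda * window)
    age <- runif(n_born, 0, window)                # age at the snapshot
    t_full <- -tau_full * log(runif(n_born))       # exponential decay wait
    alive <- age < tau_tx + t_full + tau_deg
    full <- alive & age >= tau_tx & age < tau_tx + t_full
    n_alive <- sum(alive)
    f <- sum(full) / n_alive
    data.frame(length_codons = len, n_alive = n_alive, full_fraction = f,
               se = sqrt(f * (1 - f) / n_alive),
               expected = tau_full / mean_life)
  })
  do.call(rbind, out)
}

#' Bin simulated polysome sizes into elution fractions
#'
#' Maps per-copy polysome sizes onto the experiment's elution fractions:
#' each copy is assigned to the engaged fraction (D-H) whose mean size is
#' nearest; copies with no ribosome are split between the two
#' non-engaged fractions B and C by `bc_split`.
#'
#' @param samples Vector of polysome sizes (one per mRNA copy).
#' @param sizes Fraction mean sizes, default [fraction_sizes()].
#' @param bc_split Share of the 0-ribosome mass assigned to fraction B
#'   (the remainder goes to C). Default 0.5.
#' @param gene_id Identifier for the resulting profile.
#' @return A single-replicate [fraction_profile()].
#' @export
bin_to_fractions <- function(samples, sizes = fraction_sizes(),
                             bc_split = 0.5, gene_id = "sim") {
  if (length(samples) == 0L || anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must be a non-empty vector of finite sizes")
  }
  stopifnot(bc_split >= 0, bc_split <= 1)
  eng_sz <- sizes[ENGAGED]
  # cut points: halfway between 0 and the smallest engaged size, then
  # midpoints between consecutive engaged sizes
  cuts <- c(eng_sz[1] / 2, (eng_sz[-1] + eng_sz[-5]) / 2)
  idx <- findInterval(samples, cuts)               # 0 = non-engaged
  prop <- numeric(7)
  p0 <- mean(idx == 0)
  prop[1] <- p0 * bc_split
  prop[2] <- p0 * (1 - bc_split)
  for (k in 1:5) prop[2 + k] <- mean(idx == k)
  fraction_profile(gene_id, prop, sizes)
}
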