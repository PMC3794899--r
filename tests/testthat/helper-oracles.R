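# Independent oracles used across the suite. These deliberately avoid the
# package's C++ solver path: the integrator is plain vectorized R, and the
# small-system oracle enumerates the full Markov chain.

# Explicit-Euler pseudo-time integration of the mean-field equations.
oracle_integrate <- function(n, L, kE, kappa, kT, t_total, dt) {
  kE <- rep(kE, length.out = n)
  p <- numeric(n)
  i <- seq_len(n - 1)
  ok <- i + L <= n
  for (s in seq_len(ceiling(t_total / dt))) {
    S <- c(0, cumsum(p))
    Pempty <- max(1 - S[min(L, n) + 1], 0)
    A <- ifelse(ok, 1 - (S[pmin(i + L, n) + 1] - S[i + 1]), 1)
    B <- ifelse(ok, 1 - (S[pmin(i + L - 1, n) + 1] - S[i + 1]), 1)
    qi <- ifelse(ok, pmax(0, pmin(1, A / pmax(B, 1e-300))), 1)
    J <- c(kappa * Pempty, kE[i] * p[i] * qi, kT * p[n])
    p <- pmin(pmax(p + dt * (J[1:n] - J[2:(n + 1)]), 0), 1)
  }
  S <- c(0, cumsum(p))
  Pempty <- max(1 - S[min(L, n) + 1], 0)
  A <- ifelse(ok, 1 - (S[pmin(i + L, n) + 1] - S[i + 1]), 1)
  B <- ifelse(ok, 1 - (S[pmin(i + L - 1, n) + 1] - S[i + 1]), 1)
  qi <- ifelse(ok, pmax(0, pmin(1, A / pmax(B, 1e-300))), 1)
  J <- c(kappa * Pempty, kE[i] * p[i] * qi, kT * p[n])
  list(p = p, J = mean(J), fluxes = J)
}

# All transition fluxes implied by a front-probability profile (used to
# verify flux uniformity of solver output without trusting the solver).
oracle_fluxes <- function(p, L, kE, kappa, kT) {
  n <- length(p)
  kE <- rep(kE, length.out = n)
  S <- c(0, cumsum(p))
  i <- seq_len(n - 1)
  ok <- i + L <= n
  A <- ifelse(ok, 1 - (S[pmin(i + L, n) + 1] - S[i + 1]), 1)
  B <- ifelse(ok, 1 - (S[pmin(i + L - 1, n) + 1] - S[i + 1]), 1)
  qi <- ifelse(ok, pmax(0, pmin(1, A / pmax(B, 1e-300))), 1)
  c(kappa * max(1 - S[min(L, n) + 1], 0), kE[i] * p[i] * qi, kT * p[n])
}

# Exact stationary distribution of the small-system Markov chain: states
# are ascending ribosome-front configurations with spacing >= L.
oracle_ctmc <- function(n, L, kE, kappa, kT) {
  states <- list(integer(0))
  grow <- function(pref) {
    lo <- if (length(pref)) pref[length(pref)] + L else 1
    if (lo > n) return()
    for (i in lo:n) {
      states[[length(states) + 1L]] <<- c(pref, i)
      grow(c(pref, i))
    }
  }
  grow(integer(0))
  skey <- function(st) paste0("s", paste(st, collapse = ","))
  idx <- stats::setNames(seq_along(states),
                         vapply(states, skey, character(1)))
  ns <- length(states)
  Q <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    st <- states[[s]]
    if (length(st) == 0 || st[1] > L) {
      to <- idx[[skey(c(1, st))]]
      Q[s, to] <- Q[s, to] + kappa
    }
    for (j in seq_along(st)) {
      i <- st[j]
      if (i == n) {
        to <- idx[[skey(st[-j])]]
        Q[s, to] <- Q[s, to] + kT
      } else if (i + L > n || j == length(st) || st[j + 1] > i + L) {
        nst <- st; nst[j] <- i + 1
        to <- idx[[skey(nst)]]
        Q[s, to] <- Q[s, to] + kE
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  pi <- qr.solve(rbind(t(Q), rep(1, ns)), c(rep(0, ns), 1))
  sizes <- vapply(states, length, integer(1))
  atn <- vapply(states, function(st)
    length(st) > 0 && st[length(st)] == n, logical(1))
  list(P = sum(pi * sizes), J = kT * sum(pi[atn]))
}

# Shared expensive fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

curve_for_length <- function(n, upto = 0.99) {
  fixture(paste0("curve", n, "_", upto), function() {
    rate_density_curve(n, rho_grid = seq(0.01, upto, by = 0.01))
  })
}

# Scaled synthetic study: same composition as the 1108-gene default
# (operon and regime shares preserved), sized for the test budget.
synthetic_study <- function() {
  fixture("study", function() {
    cfg <- generator_config(n_genes = 300, n_operons = 2, seed = 1)
    gen <- generate_catalog(cfg)
    profiles <- generate_profiles(gen$catalog, gen$truths, cfg)
    run <- run_pipeline(gen$catalog, profiles)
    merged <- merge(run$results, gen$truths, by = "gene_id",
                    suffixes = c("", ".true"))
    list(cfg = cfg, gen = gen, profiles = profiles, run = run,
         merged = merged)
  })
}
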