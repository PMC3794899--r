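#' Kinetic parameters of the ribosome-traffic translation model
#'
#' Bundles the per-gene constants of the codon-level translation model: an
#' mRNA of `n` codons is traversed by ribosomes occupying an `L`-codon
#' footprint. A ribosome is indexed by its decoded codon `i` and covers
#' codons `i` to `min(i + L - 1, n)`; initiation requires codons `1..L` to
#' be empty, the elongation step `i -> i + 1` requires codon `i + L` to be
#' empty (no condition once `i + L > n`), and termination fires at codon
#' `n`.
#'
#' The free-ribosome pool is folded into the effective initiation rate
#' `kappa_I` (the product of the initiation rate constant and the free
#' ribosome concentration), since only this product is identifiable from
#' polysome data.
#'
#' @param n Gene length in codons; must be at least `2 * L`.
#' @param kappa_I Effective initiation rate, 1/s.
#' @param L Ribosome footprint in codons (default 10).
#' @param k_E Elongation rate constant in codons/s; either a scalar applied
#'   to every codon or a vector of length `n` of per-codon constants.
#'   Default 23, a cell-averaged bacterial value.
#' @param k_T Termination rate constant, 1/s (default 1000, effectively
#'   non-limiting).
#' @param gene_id Optional identifier used in error messages.
#' @return An object of class `"translation_params"`.
#' @seealso [steady_state()], [calibrate_gene()]
#' @export
translation_params <- function(n, kappa_I, L = 10, k_E = 23, k_T = 1000,
                               gene_id = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n)) stop("`n` must be a single integer")
  if (length(L) != 1L || L < 1) stop("`L` must be a positive integer")
  L <- as.integer(L)
  if (n < 2L * L) {
    stop(sprintf("gene%s too short: n = %d is below 2L = %d",
                 if (is.null(gene_id)) "" else paste0(" ", gene_id),
                 n, 2L * L))
  }
  if (!length(k_E) %in% c(1L, n) || any(k_E <= 0) || anyNA(k_E)) {
    stop("`k_E` must be a positive scalar or a positive vector of length n")
  }
  if (length(kappa_I) != 1L || is.na(kappa_I) || kappa_I < 0) {
    stop("`kappa_I` must be a single non-negative rate")
  }
  if (length(k_T) != 1L || is.na(k_T) || k_T <= 0) {
    stop("`k_T` must be a single positive rate")
  }
  structure(list(n = n, L = L, k_E = as.numeric(k_E),
                 kappa_I = as.numeric(kappa_I), k_T = as.numeric(k_T),
                 gene_id = gene_id),
            class = "translation_params")
}

#' @export
print.translation_params <- function(x, ...) {
  cat(sprintf("translation model parameters%s\n",
              if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]")))
  cat(sprintf("  n = %d codons, footprint L = %d\n", x$n, x$L))
  cat(sprintf("  kappa_I = %.4g /s, k_E = %.4g codons/s%s, k_T = %.4g /s\n",
              x$kappa_I, mean(x$k_E),
              if (length(x$k_E) > 1) " (per-codon)" else "", x$k_T))
  invisible(x)
}

# Internal: raw solver call, warm-startable. Returns the C++ list.
ss_solve <- function(n, L, k_E, kappa_I, k_T, tol = 1e-8, max_steps = 2e6,
                     p0 = NULL, dt = 0) {
  rt_steady_state(n, L, as.numeric(k_E), kappa_I, k_T, tol, max_steps,
                  if (is.null(p0)) numeric(0) else p0, dt)
}

#' Deterministic steady state of the translation model
#'
#' Solves the stationary mass-balance equations of the codon-level model
#' under the refined (conditional-vacancy) mean-field closure: the vacancy
#' probability `L` codons ahead of a ribosome front at codon `i` is
#' `q_i = (1 - sum(p[i+1..i+L])) / (1 - sum(p[i+1..i+L-1]))`.
#'
#' The solver first obtains the profile by a backward recursion in the
#' trial flux (exact in the initiation-limited and maximal-current
#' regimes), then relaxes the full system by damped pseudo-time
#' integration until all transition fluxes agree to within `tol`
#' (relative). The relaxation stage is what makes the termination-limited
#' (jammed) regime reliable, where the backward recursion is numerically
#' unstable.
#'
#' @param params A [translation_params()] object.
#' @param tol Relative flux-uniformity residual required for convergence;
#'   must lie in `(0, 1e-4]`. Default `1e-8`.
#' @param max_steps Pseudo-time iteration budget (default `2e6`).
#' @param p0 Optional warm-start profile of length `n`.
#' @return An object of class `"steady_state"` with elements
#'   \describe{
#'     \item{p}{length-`n` vector of front probabilities,}
#'     \item{J}{stationary flux in proteins/s per engaged mRNA copy,}
#'     \item{P}{expected polysome size `sum(p)` in ribosomes,}
#'     \item{rho}{ribosomal density `L * P / n`,}
#'     \item{V_s}{specific synthesis rate (equal to `J`),}
#'     \item{residual, steps}{solver diagnostics.}
#'   }
#' @examples
#' ps <- translation_params(n = 300, kappa_I = 0.01)
#' st <- steady_state(ps)
#' c(flux = st$J, polysome = st$P, density = st$rho)
#' @export
steady_state <- function(params, tol = 1e-8, max_steps = 2e6, p0 = NULL) {
  stopifnot(inherits(params, "translation_params"))
  if (length(tol) != 1L || tol <= 0 || tol > 1e-4) {
    stop("`tol` must lie in (0, 1e-4]")
  }
  sol <- ss_solve(params$n, params$L, params$k_E, params$kappa_I,
                  params$k_T, tol, max_steps, p0)
  if (!sol$converged) {
    stop(sprintf(
      "steady-state solver did not converge%s: residual %.3g after %g steps",
      if (is.null(params$gene_id)) "" else paste0(" for gene ", params$gene_id),
      sol$residual, sol$steps))
  }
  P <- sum(sol$p)
  structure(list(p = sol$p, J = sol$J, P = P,
                 rho = params$L * P / params$n, V_s = sol$J,
                 residual = sol$residual, steps = sol$steps,
                 params = params),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady state of the translation model\n")
  cat(sprintf("  flux J = V_s = %.6g proteins/s per engaged mRNA\n", x$J))
  cat(sprintf("  polysome size P = %.4g ribosomes, density rho = %.4g\n",
              x$P, x$rho))
  cat(sprintf("  flux residual %.2g after %g relaxation steps\n",
              x$residual, x$steps))
  invisible(x)
}

#' Mean-field current of the extended-particle exclusion process
#'
#' Closed-form flux of the infinite, homogeneous lattice at coverage
#' density `rho_cov` (fraction of codons covered):
#' `J = k_E * (rho_cov / L) * (1 - rho_cov) / (1 - (L - 1) * rho_cov / L)`.
#' Used as an analytic oracle and initializer for the finite-gene solver,
#' which it matches closely for long genes.
#'
#' @param rho_cov Coverage density in `[0, 1]` (vectorized).
#' @param k_E Elongation rate constant, codons/s.
#' @param L Ribosome footprint in codons.
#' @return Flux in proteins/s.
#' @export
mean_field_current <- function(rho_cov, k_E = 23, L = 10) {
  if (anyNA(rho_cov) || any(rho_cov < 0 | rho_cov > 1)) {
    stop("`rho_cov` must lie in [0, 1]")
  }
  k_E * (rho_cov / L) * (1 - rho_cov) / (1 - (L - 1) * rho_cov / L)
}

#' Density and flux at the mean-field optimum
#'
#' The homogeneous-lattice current is maximal at
#' `rho* = sqrt(L) / (1 + sqrt(L))` where it equals
#' `J* = k_E / (1 + sqrt(L))^2`. For `L = 10` and `k_E = 23` codons/s this
#' gives a density near 0.76 and a peak specific rate near 1.33 proteins/s.
#'
#' @inheritParams mean_field_current
#' @return A list with elements `rho_star` and `J_star`.
#' @export
mean_field_optimum <- function(k_E = 23, L = 10) {
  if (k_E <= 0 || L < 1) stop("`k_E` must be positive and `L` >= 1")
  s <- sqrt(L)
  list(rho_star = s / (1 + s), J_star = k_E / (1 + s)^2)
}

#' Ribosomal density from polysome size
#'
#' `rho = L * P / n`, the fraction of the mRNA's codons covered by
#' ribosomes; 0 means an empty mRNA and 1 full coverage. Values above 1
#' are physically impossible (up to a small boundary-overhang slack) and
#' are flagged: they motivate the co-elution recalibration of
#' [recalibrate_coelution()].
#'
#' @param P Polysome size in ribosomes (vectorized).
#' @param n Gene length in codons.
#' @param L Ribosome footprint in codons.
#' @return Numeric vector of densities with a logical attribute
#'   `"over_capacity"` marking entries above 1.
#' @export
ribosomal_density <- function(P, n, L = 10) {
  if (anyNA(P) || any(P < 0)) stop("`P` must be non-negative")
  if (any(n < 1)) stop("`n` must be at least 1")
  rho <- L * P / n
  attr(rho, "over_capacity") <- rho > 1
  rho
}
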