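#' Control coefficients of initiation, elongation and termination
#'
#' Sensitivities of the steady-state protein synthesis rate to the three
#' stage rate constants: `C_X = d ln J / d ln k_X`, evaluated by central
#' finite differences in log space with re-converged steady states. The
#' elongation coefficient perturbs the elongation constants of all codons
#' simultaneously. By homogeneity of the kinetics the three coefficients
#' sum to one (summation theorem), which serves as an internal accuracy
#' check.
#'
#' @param params A [translation_params()] object.
#' @param rel_step Relative perturbation of each rate constant (default
#'   0.01, i.e. 1 percent).
#' @param tol Steady-state solver tolerance.
#' @return An object of class `"control_coefficients"` with fields `C_I`,
#'   `C_E`, `C_T`, the unperturbed flux `J`, `rel_step` and the regime
#'   `group` from [assign_group()].
#' @examples
#' ps <- translation_params(300, kappa_I = 0.02)
#' control_coefficients(ps)
#' @export
control_coefficients <- function(params, rel_step = 0.01, tol = 1e-8) {
  stopifnot(inherits(params, "translation_params"))
  if (rel_step <= 0 || rel_step >= 0.5) stop("`rel_step` must be in (0, 0.5)")
  base <- steady_state(params, tol = tol)
  f <- 1 + rel_step
  # warm-start perturbed solves only in the jammed regime, where the
  # solver's recursion initializer is unstable; elsewhere a cold start
  # converges far faster than relaxing the neighbouring profile
  p_seed <- if (params$k_T < max(params$k_E)) base$p else NULL

  solve_J <- function(kappa, kE, kT, what) {
    sol <- ss_solve(params$n, params$L, kE, kappa, kT, tol,
                    2e6, p0 = p_seed)
    if (!sol$converged) {
      stop(sprintf("solver failed at perturbed point (%s)%s", what,
                   if (is.null(params$gene_id)) ""
                   else paste0(" for gene ", params$gene_id)))
    }
    sol$J
  }

  d <- 2 * log(f)
  C_I <- (log(solve_J(params$kappa_I * f, params$k_E, params$k_T, "kappa_I up")) -
          log(solve_J(params$kappa_I / f, params$k_E, params$k_T, "kappa_I down"))) / d
  C_E <- (log(solve_J(params$kappa_I, params$k_E * f, params$k_T, "k_E up")) -
          log(solve_J(params$kappa_I, params$k_E / f, params$k_T, "k_E down"))) / d
  C_T <- (log(solve_J(params$kappa_I, params$k_E, params$k_T * f, "k_T up")) -
          log(solve_J(params$kappa_I, params$k_E, params$k_T / f, "k_T down"))) / d

  structure(list(C_I = C_I, C_E = C_E, C_T = C_T, J = base$J,
                 rel_step = rel_step,
                 group = assign_group(C_I, C_E, C_T)),
            class = "control_coefficients")
}

#' @export
print.control_coefficients <- function(x, ...) {
  cat(sprintf("control coefficients (group %s): C_I = %.3f, C_E = %.3f, C_T = %.3f\n",
              x$group, x$C_I, x$C_E, x$C_T))
  cat(sprintf("  sum = %.4f (summation theorem: 1), J = %.4g proteins/s\n",
              x$C_I + x$C_E + x$C_T, x$J))
  invisible(x)
}

#' Assign a translational-control regime group
#'
#' Bins a gene into one of six control regimes. Group VI collects genes
#' with appreciable termination control (`C_T >= 0.2`); the remaining
#' genes are binned by initiation control: I `[0.8, 1]`, II `[0.6, 0.8)`,
#' III `[0.4, 0.6)`, IV `[0.2, 0.4)`, V `[0, 0.2)`. Boundary values go to
#' the lower-numbered (more initiation-limited) group. Small negative
#' coefficients from finite-difference noise are clipped to zero first.
#'
#' @param C_I Initiation control coefficient, or a
#'   `"control_coefficients"` object (then `C_E`, `C_T` are ignored).
#' @param C_E,C_T Elongation and termination control coefficients.
#' @return A factor level among `"I".."VI"`.
#' @export
assign_group <- function(C_I, C_E = NULL, C_T = NULL) {
  if (inherits(C_I, "control_coefficients")) {
    cc <- C_I; C_I <- cc$C_I; C_E <- cc$C_E; C_T <- cc$C_T
  }
  clip <- function(x) ifelse(x < 0 & x > -0.05, 0, x)
  C_I <- clip(C_I); C_T <- clip(C_T)
  g <- ifelse(C_T >= 0.2, "VI",
       ifelse(C_I >= 0.8, "I",
       ifelse(C_I >= 0.6, "II",
       ifelse(C_I >= 0.4, "III",
       ifelse(C_I >= 0.2, "IV", "V")))))
  factor(g, levels = c("I", "II", "III", "IV", "V", "VI"))
}

#' Fraction of genes with shared initiation and elongation control
#'
#' @param results A data frame with columns `C_I` and `C_E`, or a list of
#'   `"control_coefficients"` objects.
#' @param threshold Control-coefficient threshold above which a stage is
#'   counted as contributing (default 0.05).
#' @return The fraction of genes with both `C_I` and `C_E` above the
#'   threshold.
#' @export
shared_control_fraction <- function(results, threshold = 0.05) {
  if (is.data.frame(results)) {
    ci <- results$C_I; ce <- results$C_E
  } else {
    ci <- vapply(results, `[[`, numeric(1), "C_I")
    ce <- vapply(results, `[[`, numeric(1), "C_E")
  }
  if (length(ci) == 0L) stop("`results` must be non-empty")
  mean(ci > threshold & ce > threshold)
}
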