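.sat_cache <- new.env(parent = emptyenv())

#' Options controlling per-gene kinetic calibration
#'
#' @param k_T_max Upper (non-limiting) termination rate constant, 1/s.
#'   Default `1e3`, far above the elongation constant so that termination
#'   exerts essentially no control away from the jammed regime.
#' @param k_T_min Lower bound of the termination search, 1/s.
#' @param P_tol Relative tolerance on the achieved polysome size.
#' @param plateau_eps Relative change in polysome size per doubling of the
#'   initiation rate below which the initiation branch is declared
#'   saturated.
#' @param kappa_bounds Search interval for the effective initiation rate,
#'   1/s.
#' @param tol,max_steps Passed to the steady-state solver.
#' @return An object of class `"calibration_options"`.
#' @export
calibration_options <- function(k_T_max = 1e3, k_T_min = 1e-6,
                                P_tol = 1e-3, plateau_eps = 1e-3,
                                kappa_bounds = c(1e-6, 1e3),
                                tol = 1e-8, max_steps = 2e6) {
  stopifnot(k_T_max > 0, k_T_min > 0, k_T_min < k_T_max,
            P_tol > 0, plateau_eps > 0,
            length(kappa_bounds) == 2L, all(kappa_bounds > 0),
            kappa_bounds[1] < kappa_bounds[2])
  structure(list(k_T_max = k_T_max, k_T_min = k_T_min, P_tol = P_tol,
                 plateau_eps = plateau_eps, kappa_bounds = kappa_bounds,
                 tol = tol, max_steps = max_steps),
            class = "calibration_options")
}

# Bracketed root search for a monotone polysome-size response P(10^x).
# Uses the Illinois variant of false position once both bracket endpoints
# have been evaluated (superlinear, typically < 10 solver calls) and plain
# bisection while one endpoint value is still unknown; each candidate
# solve is warm-started from the previous one. `increasing` states whether
# P grows with x. Returns the last evaluated point and the final bracket.
root_search <- function(solve_x, lo, hi, g_hi, sol, x0, target, abs_tol,
                        increasing, max_iter = 100L) {
  gval <- function(P) if (increasing) P - target else target - P
  g_lo <- NA_real_
  x <- x0
  side <- 0L
  for (it in seq_len(max_iter)) {
    if (abs(sum(sol$p) - target) <= abs_tol) break
    if (hi - lo < 1e-13) break
    if (!is.na(g_lo) && !is.na(g_hi) && g_hi > g_lo) {
      x_new <- (lo * g_hi - hi * g_lo) / (g_hi - g_lo)
      w <- hi - lo  # keep strictly inside the bracket
      x_new <- min(max(x_new, lo + 0.01 * w), hi - 0.01 * w)
    } else {
      x_new <- (lo + hi) / 2
    }
    cand <- solve_x(x_new, sol$p)
    g_new <- gval(sum(cand$p))
    if (g_new < 0) {
      lo <- x_new; g_lo <- g_new
      if (side == -1L && !is.na(g_hi)) g_hi <- g_hi / 2
      side <- -1L
    } else {
      hi <- x_new; g_hi <- g_new
      if (side == 1L && !is.na(g_lo)) g_lo <- g_lo / 2
      side <- 1L
    }
    sol <- cand
    x <- x_new
  }
  list(x = x, sol = sol, lo = lo, hi = hi)
}

#' Calibrate initiation and termination rates to a target polysome size
#'
#' Determines the unique pair `(kappa_I, k_T)` that reproduces the
#' observed polysome size of a gene while maximizing its specific protein
#' synthesis rate. The termination rate constant is first pinned at a
#' high, non-limiting value and the initiation rate is raised (log-space
#' bisection) until the target polysome size is met. If the polysome size
#' saturates below the target -- the initiation branch has plateaued --
#' the initiation rate is left at its upper bound and the termination
#' rate constant is lowered instead until the target is reached. This
#' mirrors the rate-maximization assumption: of all parameter pairs
#' reproducing the observed polysome size, the returned one yields the
#' largest flux.
#'
#' @param n Gene length in codons.
#' @param target_P Target polysome size in ribosomes; must lie in
#'   `(0, n/L + 1]`.
#' @param L Ribosome footprint in codons.
#' @param k_E Elongation rate constant, codons/s (scalar or per-codon).
#' @param opts A [calibration_options()] object.
#' @param gene_id Optional identifier used in error messages.
#' @return An object of class `"calibration_result"`: `kappa_I`, `k_T`,
#'   `state` (the calibrated [steady_state()]), `branch` (either
#'   `"initiation-matched"` or `"termination-reduced"`), `achieved_P` and
#'   `target_P`.
#' @examples
#' cal <- calibrate_gene(n = 300, target_P = 3)  # density 0.1
#' cal$branch
#' cal$state$V_s
#' @export
calibrate_gene <- function(n, target_P, L = 10, k_E = 23,
                           opts = calibration_options(), gene_id = NULL) {
  n <- as.integer(n)
  if (n < 2L * L) stop(sprintf("n = %d is below 2L = %d", n, 2L * L))
  if (length(target_P) != 1L || is.na(target_P) ||
      target_P <= 0 || target_P > n / L + 1) {
    stop("`target_P` must lie in (0, n/L + 1]")
  }
  kE <- as.numeric(k_E)
  abs_tol <- opts$P_tol * target_P

  solve_P <- function(kappa, k_T, p0) {
    sol <- ss_solve(n, L, kE, kappa, k_T, opts$tol, opts$max_steps, p0)
    if (!sol$converged) {
      stop(sprintf(
        "steady-state solver did not converge%s (kappa_I = %.3g, k_T = %.3g, residual %.3g)",
        if (is.null(gene_id)) "" else paste0(" for gene ", gene_id),
        kappa, k_T, sol$residual))
    }
    sol
  }

  # --- branch 1: raise kappa_I at k_T = k_T_max -------------------------
  # The saturation solve (kappa at its upper bound) is the costliest and
  # depends only on (n, L, k_E, k_T_max, tol); cache it so density scans
  # pay for it once. The cached value is itself deterministic.
  kb <- log10(opts$kappa_bounds)
  key <- paste(n, L, paste(signif(kE, 12), collapse = ","),
               opts$kappa_bounds[2], opts$k_T_max, opts$tol, sep = "|")
  sol_hi <- get0(key, envir = .sat_cache, inherits = FALSE)
  if (is.null(sol_hi)) {
    sol_hi <- solve_P(opts$kappa_bounds[2], opts$k_T_max, NULL)
    assign(key, sol_hi, envir = .sat_cache)
  }
  P_hi <- sum(sol_hi$p)

  if (P_hi >= target_P - abs_tol) {
    # cold starts: with termination non-limiting the recursion initializer
    # is near-exact, and relaxing it is much cheaper than transporting a
    # neighbouring profile across the lattice
    sr <- root_search(function(x, p0) solve_P(10^x, opts$k_T_max, NULL),
                      lo = kb[1], hi = kb[2], g_hi = P_hi - target_P,
                      sol = sol_hi, x0 = kb[2], target = target_P,
                      abs_tol = abs_tol, increasing = TRUE)
    sol <- sr$sol
    kappa <- 10^sr$x
    if (abs(sum(sol$p) - target_P) > abs_tol) {
      # land on the feasible (upper) bracket edge
      sol <- solve_P(10^sr$hi, opts$k_T_max, sol$p)
      kappa <- 10^sr$hi
    }
    st <- as_steady_state(sol, n, L, kE, kappa, opts$k_T_max, gene_id)
    return(new_calibration(kappa, opts$k_T_max, st, "initiation-matched",
                           target_P))
  }

  # --- plateau check: is the initiation branch really saturated? --------
  sol_half <- solve_P(opts$kappa_bounds[2] / 2, opts$k_T_max, NULL)
  dP <- (P_hi - sum(sol_half$p)) / max(P_hi, 1e-300)
  if (dP > opts$plateau_eps) {
    stop(sprintf(
      "initiation branch not saturated at kappa upper bound%s; raise kappa_bounds",
      if (is.null(gene_id)) "" else paste0(" for gene ", gene_id)))
  }

  # --- branch 2: lower k_T at kappa_I fixed high ------------------------
  # P(k_T) is monotone decreasing; bisect on log k_T. Infeasibility (the
  # target exceeding the packing limit) surfaces as the bracket collapsing
  # onto k_T_min with P still short of the target.
  # warm starts: in the jammed branch the recursion initializer is
  # unstable, so the previous candidate's profile is the better seed
  kappa <- opts$kappa_bounds[2]
  sr <- root_search(function(x, p0) solve_P(kappa, 10^x, p0),
                    lo = log10(opts$k_T_min), hi = log10(opts$k_T_max),
                    g_hi = target_P - P_hi, sol = sol_hi,
                    x0 = log10(opts$k_T_max), target = target_P,
                    abs_tol = abs_tol, increasing = FALSE)
  sol <- sr$sol
  k_T <- 10^sr$x
  if (sum(sol$p) < target_P - abs_tol) {
    stop(sprintf(
      paste0("target polysome size %.4g unreachable%s: ",
             "maximum achievable near k_T = %.3g is %.4g ribosomes"),
      target_P, if (is.null(gene_id)) "" else paste0(" for gene ", gene_id),
      k_T, sum(sol$p)))
  }
  st <- as_steady_state(sol, n, L, kE, kappa, k_T, gene_id)
  new_calibration(kappa, k_T, st, "termination-reduced", target_P)
}

as_steady_state <- function(sol, n, L, kE, kappa, k_T, gene_id = NULL) {
  P <- sum(sol$p)
  structure(list(p = sol$p, J = sol$J, P = P, rho = L * P / n,
                 V_s = sol$J, residual = sol$residual, steps = sol$steps,
                 params = translation_params(n, kappa, L = L, k_E = kE,
                                             k_T = k_T, gene_id = gene_id)),
            class = "steady_state")
}

new_calibration <- function(kappa, k_T, state, branch, target_P) {
  structure(list(kappa_I = kappa, k_T = k_T, state = state,
                 branch = branch, achieved_P = state$P,
                 target_P = target_P),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration (%s branch)\n", x$branch))
  cat(sprintf("  kappa_I = %.5g /s, k_T = %.5g /s\n", x$kappa_I, x$k_T))
  cat(sprintf("  polysome size %.4g (target %.4g), V_s = %.4g proteins/s\n",
              x$achieved_P, x$target_P, x$state$V_s))
  invisible(x)
}

#' Specific synthesis rate as a function of ribosomal density
#'
#' Calibrates a gene of fixed length to each density in `rho_grid` and
#' records the resulting specific synthesis rate and rate constants. The
#' curve rises with density, peaks near the optimum of
#' [mean_field_optimum()] and falls again in the jammed regime.
#'
#' @param rho_grid Vector of target ribosomal densities in `(0, 1)`.
#' @inheritParams calibrate_gene
#' @return A data frame with one row per density: `rho`, `V_s`,
#'   `kappa_I`, `k_T`, `achieved_P` and `branch`.
#' @examples
#' \donttest{
#' curve <- rate_density_curve(300, rho_grid = seq(0.05, 0.95, by = 0.05))
#' curve$rho[which.max(curve$V_s)]
#' }
#' @export
rate_density_curve <- function(n, L = 10, k_E = 23, rho_grid,
                               opts = calibration_options()) {
  if (any(rho_grid <= 0 | rho_grid >= 1)) {
    stop("`rho_grid` entries must lie in (0, 1)")
  }
  ord <- order(rho_grid)
  out <- vector("list", length(rho_grid))
  for (i in ord) {
    cal <- calibrate_gene(n, target_P = rho_grid[i] * n / L, L = L,
                          k_E = k_E, opts = opts)
    out[[i]] <- data.frame(rho = rho_grid[i], V_s = cal$state$V_s,
                           kappa_I = cal$kappa_I, k_T = cal$k_T,
                           achieved_P = cal$achieved_P,
                           branch = cal$branch,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
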