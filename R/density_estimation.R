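#' Mean polysome sizes of the seven elution fractions
#'
#' The sucrose gradient resolves mRNA-ribosome complexes into seven
#' elution fractions B-H. Fractions B and C carry mRNAs not engaged in
#' translation (ribosome-free, or co-sedimenting with a single ribosomal
#' subunit); fractions D-H carry translating mRNAs with mean polysome
#' sizes 1, 2.1, 4.1, 7.4 and 14 ribosomes.
#'
#' @return A named numeric vector of length 7.
#' @export
fraction_sizes <- function() {
  c(B = 0, C = 0, D = 1, E = 2.1, F = 4.1, G = 7.4, H = 14)
}

ENGAGED <- 3:7  # columns D..H

#' Replicate fraction proportions of one gene
#'
#' @param gene_id Gene identifier.
#' @param proportions A replicate-by-fraction matrix (or a single
#'   proportion vector) giving, per replicate, the proportion of the
#'   gene's mRNA mass eluting in each of the 7 fractions B-H. Rows must
#'   be non-negative and sum to 1 (within 1e-6).
#' @param sizes Mean polysome size per fraction; default
#'   [fraction_sizes()].
#' @return An object of class `"fraction_profile"`.
#' @export
fraction_profile <- function(gene_id, proportions, sizes = fraction_sizes()) {
  if (is.null(dim(proportions))) proportions <- matrix(proportions, nrow = 1)
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != 7L) stop("`proportions` must have 7 columns (B-H)")
  if (anyNA(proportions) || any(proportions < 0)) {
    stop("proportions must be non-negative")
  }
  rs <- rowSums(proportions)
  if (any(abs(rs - 1) > 1e-6)) {
    stop(sprintf("replicate rows must sum to 1 (worst deviation %.2g)",
                 max(abs(rs - 1))))
  }
  colnames(proportions) <- names(fraction_sizes())
  if (length(sizes) != 7L) stop("`sizes` must have length 7")
  structure(list(gene_id = gene_id, proportions = proportions,
                 sizes = as.numeric(sizes)),
            class = "fraction_profile")
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat(sprintf("fraction profile for %s (%d replicate%s)\n", x$gene_id,
              nrow(x$proportions), if (nrow(x$proportions) > 1) "s" else ""))
  print(round(colMeans(x$proportions), 3))
  invisible(x)
}

#' Estimate polysome size, occupancy and density from a fraction profile
#'
#' The ribosome occupancy `p_rib` is the engaged share of the gene's mRNA
#' copies: the replicate-averaged mass in fractions D-H. The polysome
#' size is the engaged-mass-weighted mean of the fraction sizes (the
#' `"modal"` estimator instead takes the size of the heaviest engaged
#' fraction). The ribosomal density follows as `L * P / n`.
#'
#' @param profile A [fraction_profile()].
#' @param n_codons Gene length in codons (needed for the density; `NA`
#'   leaves `rho_hat` as `NA`).
#' @param L Ribosome footprint in codons.
#' @param method `"weighted"` (default) or `"modal"`.
#' @return An object of class `"density_estimate"`: `gene_id`, `P_hat`,
#'   `p_rib`, `rho_hat`, `removed_mass`, `status` (one of `"ok"`,
#'   `"recalibrated"`, `"excluded"`).
#' @export
estimate_polysome_size <- function(profile, n_codons = NA, L = 10,
                                   method = c("weighted", "modal")) {
  stopifnot(inherits(profile, "fraction_profile"))
  method <- match.arg(method)
  avg <- colMeans(profile$proportions)
  sz <- profile$sizes
  p_rib <- mean(rowSums(profile$proportions[, ENGAGED, drop = FALSE]))
  eng <- sum(avg[ENGAGED])
  if (eng <= 0) {
    return(new_density_estimate(profile$gene_id, NA_real_, 0, NA_real_,
                                0, "excluded"))
  }
  P_hat <- if (method == "weighted") {
    sum(avg[ENGAGED] * sz[ENGAGED]) / eng
  } else {
    sz[ENGAGED][which.max(avg[ENGAGED])]
  }
  rho <- if (is.na(n_codons)) NA_real_ else L * P_hat / n_codons
  new_density_estimate(profile$gene_id, P_hat, p_rib, rho, 0, "ok")
}

new_density_estimate <- function(gene_id, P_hat, p_rib, rho_hat,
                                 removed_mass, status) {
  structure(list(gene_id = gene_id, P_hat = P_hat, p_rib = p_rib,
                 rho_hat = rho_hat, removed_mass = removed_mass,
                 status = status),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("density estimate for %s [%s]\n", x$gene_id, x$status))
  cat(sprintf("  P = %.3g ribosomes, occupancy = %.3f, rho = %.3g\n",
              x$P_hat, x$p_rib, x$rho_hat))
  if (x$removed_mass > 0) {
    cat(sprintf("  co-elution mass removed from fraction H: %.3f\n",
                x$removed_mass))
  }
  invisible(x)
}

#' Recalibrate a fraction profile for co-elution contamination
#'
#' mRNAs co-eluting with heavy non-ribosomal complexes inflate the mass
#' of the last (heaviest) elution fraction and can push the apparent
#' ribosomal density above the physical ceiling of 1. When the estimated
#' density exceeds `rho_cap`, the minimal amount of mass is removed from
#' fraction H (and the replicate rows renormalized) so that the density
#' drops exactly to `rho_cap`; if not even an empty fraction H can bring
#' the gene below the cap, the gene is excluded. Genes already below the
#' cap are returned unchanged.
#'
#' The minimal removal has a closed form: with engaged size-weighted mass
#' `S1`, engaged mass `S0` and cap `P_cap = rho_cap * n / L`, removing
#' `delta = (S1 - P_cap * S0) / (s_H - P_cap)` from fraction H makes the
#' weighted-mean polysome size equal `P_cap` (renormalization leaves the
#' weighted mean unchanged).
#'
#' @param est The [estimate_polysome_size()] result for `profile`.
#' @param profile The gene's [fraction_profile()].
#' @param n Gene length in codons.
#' @param L Ribosome footprint in codons.
#' @param rho_cap Maximal admissible ribosomal density (default 1).
#' @return A list with the corrected `estimate` and `profile`.
#' @export
recalibrate_coelution <- function(est, profile, n, L = 10, rho_cap = 1) {
  stopifnot(inherits(est, "density_estimate"),
            inherits(profile, "fraction_profile"))
  if (est$status == "excluded") return(list(estimate = est, profile = profile))
  rho <- if (is.na(est$rho_hat)) L * est$P_hat / n else est$rho_hat
  est$rho_hat <- rho
  if (rho <= rho_cap) {
    est$status <- "ok"
    return(list(estimate = est, profile = profile))
  }
  sz <- profile$sizes
  s_H <- sz[7]
  P_cap <- rho_cap * n / L
  avg <- colMeans(profile$proportions)
  # with H emptied completely the best reachable polysome size:
  S1 <- sum(avg[ENGAGED] * sz[ENGAGED]); S0 <- sum(avg[ENGAGED])
  h <- avg[7]
  P_floor <- if (S0 - h > 0) (S1 - s_H * h) / (S0 - h) else Inf
  if (P_floor > P_cap) {
    est$status <- "excluded"
    est$removed_mass <- unname(h)
    return(list(estimate = est, profile = profile))
  }
  # One closed-form pass is exact for identical replicates; with replicate
  # scatter the per-row renormalization shifts the average slightly, so
  # repeat until the cap holds.
  prop <- profile$proportions
  removed <- 0
  for (it in seq_len(50)) {
    avg <- colMeans(prop)
    S1 <- sum(avg[ENGAGED] * sz[ENGAGED]); S0 <- sum(avg[ENGAGED])
    if (S1 / S0 <= P_cap * (1 + 1e-12)) break
    h <- avg[7]
    delta <- (S1 - P_cap * S0) / (s_H - P_cap)
    fac <- max(0, (h - delta) / h)
    removed <- removed + (1 - removed) * unname(h - h * fac)
    prop[, 7] <- prop[, 7] * fac
    prop <- prop / rowSums(prop)
  }
  newprof <- fraction_profile(profile$gene_id, prop, sz)
  newest <- estimate_polysome_size(newprof, n_codons = n, L = L)
  newest$status <- "recalibrated"
  newest$removed_mass <- removed
  list(estimate = newest, profile = newprof)
}

#' Adjust polysome sizes of operonic genes
#'
#' Genes transcribed on one polycistronic mRNA co-sediment, so each
#' member gene is detected with the polysome size of the whole
#' transcript. Mode `"conservative"` keeps the detected value for every
#' member (a deliberate overestimate); mode `"shared"` splits the
#' detected ribosome count among member genes in proportion to their
#' lengths.
#'
#' @param estimates A data frame with at least columns `gene_id` and
#'   `P_hat` (a `rho_hat` column, if present, is recomputed from the
#'   supplied lengths).
#' @param operon_map A data frame with columns `gene_id` and `operon_id`.
#' @param lengths Named vector of gene lengths in codons (names are gene
#'   ids).
#' @param mode `"conservative"` or `"shared"`.
#' @param L Ribosome footprint in codons.
#' @return The adjusted `estimates` data frame.
#' @export
operon_share_adjustment <- function(estimates, operon_map, lengths,
                                    mode = c("conservative", "shared"),
                                    L = 10) {
  mode <- match.arg(mode)
  unknown <- setdiff(operon_map$gene_id, estimates$gene_id)
  if (length(unknown) > 0) {
    stop("operon genes missing from estimates: ",
         paste(unknown, collapse = ", "))
  }
  if (mode == "conservative") return(estimates)
  for (op in unique(operon_map$operon_id)) {
    members <- operon_map$gene_id[operon_map$operon_id == op]
    if (length(members) < 2L) next
    idx <- match(members, estimates$gene_id)
    len <- lengths[members]
    detected <- mean(estimates$P_hat[idx], na.rm = TRUE)
    estimates$P_hat[idx] <- detected * len / sum(len)
    if ("rho_hat" %in% names(estimates)) {
      estimates$rho_hat[idx] <- L * estimates$P_hat[idx] / len
    }
  }
  estimates
}

#' Stratified mean fraction profiles
#'
#' Groups genes into strata (for instance by mRNA half-life) and reports,
#' per stratum and elution fraction, the mean and standard deviation of
#' the replicate-averaged fraction proportions.
#'
#' @param profiles A list of [fraction_profile()] objects.
#' @param labels Stratum label per profile (same order); every gene must
#'   be labeled and no stratum may be empty.
#' @return A data frame with columns `stratum`, `fraction`, `mean`, `sd`
#'   (`sd` is 0 for singleton strata).
#' @export
stratified_profiles <- function(profiles, labels) {
  if (length(labels) != length(profiles) || anyNA(labels)) {
    stop("every profile needs a stratum label")
  }
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("empty stratum")
  avg <- t(vapply(profiles, function(p) colMeans(p$proportions), numeric(7)))
  colnames(avg) <- names(fraction_sizes())
  out <- lapply(levels(labels), function(s) {
    m <- avg[labels == s, , drop = FALSE]
    sds <- apply(m, 2, sd)
    sds[is.na(sds)] <- 0
    data.frame(stratum = s, fraction = colnames(avg),
               mean = unname(colMeans(m)), sd = unname(sds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
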