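default_category_counts <- function() {
  # functional-category sizes of a typical lactococcal gene catalog
  c(AMI = 36, CEL = 24, COF = 27, ENV = 25, FAT = 25, INT = 25,
    NRJ = 96, OTH = 107, PUR = 38, REG = 73, REP = 25, TRD = 96,
    TRS = 25, TSP = 103, UNK = 383)
}

default_group_mix <- function() {
  c(I = 788, II = 202, III = 53, IV = 19, V = 41, VI = 5) / 1108
}

# density intervals from which ground-truth densities per control regime
# are drawn (contiguous version of the regime bins; the top bin stays
# clear of the theoretical ceiling so that only contaminated genes can
# imply impossible densities)
default_rho_bins <- function() {
  list(I  = c(0.01, 0.19), II = c(0.19, 0.37), III = c(0.37, 0.52),
       IV = c(0.52, 0.64), V  = c(0.64, 0.85), VI = c(0.87, 0.94))
}

#' Configuration of the synthetic translatome generator
#'
#' Describes the population of genes to simulate: gene lengths,
#' functional-category composition, the mix of translational-control
#' regimes (which fixes the ground-truth ribosomal densities), ribosome
#' occupancies, co-elution contamination, replicate noise and operon
#' structure. Defaults emulate a 1108-gene bacterial catalog profiled in
#' triplicate over 7 elution fractions.
#'
#' @param n_genes Number of genes (default 1108).
#' @param L,k_E Footprint and elongation rate constant shared by all
#'   genes.
#' @param length_range,length_meanlog,length_sdlog Log-normal gene-length
#'   distribution in codons, clipped to `length_range`.
#' @param category_counts Named vector of functional-category weights;
#'   converted to exact per-category gene counts by largest remainder.
#' @param group_mix Named fractions of genes per control-regime group
#'   I-VI; must sum to 1.
#' @param rho_bins Named list of density intervals sampled per group.
#' @param occupancy_mean,occupancy_conc Beta-distribution mean and
#'   concentration of the per-gene ribosome occupancy (fraction of copies
#'   engaged). The default mean matches a global engaged-ribosome
#'   fraction of 0.61.
#' @param halflife_range mRNA half-life range in minutes (log-uniform).
#' @param halflife_occ_slope Strength of the negative coupling between
#'   half-life and occupancy (longer-lived mRNAs carry more mass in the
#'   non-engaged fractions).
#' @param contamination_rate Fraction of genes receiving co-elution
#'   contamination in the last fraction (default 0.12). Contamination is
#'   placed on genes where it is observable, i.e. where it pushes the
#'   implied density past the theoretical ceiling of 1 (short,
#'   ribosome-dense mRNAs); if fewer genes qualify, all of them are
#'   contaminated.
#' @param contamination_mass Range of the contaminating mass share; the
#'   per-gene lower end is raised to what detection requires.
#' @param noise_sd Multiplicative log-normal replicate noise (sdlog).
#' @param replicates Number of replicate profiles per gene.
#' @param n_operons,operon_size_range Number and size range of operons.
#' @param bc_split Share of non-engaged mass placed in fraction B (the
#'   rest goes to C).
#' @param dispersion_spill Fraction of each gene's engaged mass spread to
#'   the fractions adjacent to the two bracketing ones (broad peaks).
#' @param eta Global engaged-ribosome fraction; stored as metadata for
#'   reporting only.
#' @param seed Integer seed making the generator reproducible.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(n_genes = 1108, L = 10, k_E = 23,
                             length_range = c(60, 1500),
                             length_meanlog = log(280),
                             length_sdlog = 0.6,
                             category_counts = default_category_counts(),
                             group_mix = default_group_mix(),
                             rho_bins = default_rho_bins(),
                             occupancy_mean = 0.61, occupancy_conc = 10,
                             halflife_range = c(2.8, 18),
                             halflife_occ_slope = 0.12,
                             contamination_rate = 0.12,
                             contamination_mass = c(0.25, 0.75),
                             noise_sd = 0.1, replicates = 3,
                             n_operons = 8, operon_size_range = c(2, 6),
                             bc_split = 0.4, dispersion_spill = 0.1,
                             eta = 0.61, seed = 1) {
  stopifnot(n_genes >= 1, L >= 1, k_E > 0,
            abs(sum(group_mix) - 1) < 1e-8,
            all(names(group_mix) %in% names(rho_bins)),
            contamination_rate >= 0, contamination_rate <= 1,
            noise_sd >= 0, replicates >= 1,
            bc_split >= 0, bc_split <= 1,
            dispersion_spill >= 0, dispersion_spill < 1)
  if (n_operons * operon_size_range[2] > n_genes) {
    stop("operon genes would exceed `n_genes`")
  }
  structure(as.list(environment()), class = "generator_config")
}

# regime bin containing a density (gap densities go to the nearer bin)
bin_of_rho <- function(rho, bins) {
  lo <- vapply(bins, `[`, numeric(1), 1)
  i <- findInterval(rho, lo)
  names(bins)[max(1L, i)]
}

# exact integer allocation by largest remainder
allocate_counts <- function(weights, total) {
  w <- weights / sum(weights)
  raw <- w * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Generate a synthetic gene catalog with kinetic ground truth
#'
#' Draws a gene catalog (lengths, functional categories, operon
#' membership, relative mRNA levels, half-lives) together with the
#' ground-truth kinetics: each gene is assigned a control-regime group,
#' a ribosomal density within that group's interval, and -- via
#' [calibrate_gene()] -- the `(kappa_I, k_T)` pair that realizes this
#' density under rate maximization. Occupancy is drawn from a Beta
#' distribution whose mean decreases with mRNA half-life, mirroring the
#' observation that long-lived mRNAs carry more mass in the non-engaged
#' fractions.
#'
#' @param cfg A [generator_config()].
#' @param compute_kinetics If `FALSE`, skip the per-gene calibration and
#'   control coefficients (faster; `kappa_I`, `k_T`, `V_s_true` and
#'   `group_true` are then `NA`).
#' @return A list with `catalog` (data frame: `gene_id`,
#'   `length_codons`, `category`, `operon_id`, `m_rel`,
#'   `half_life_min`) and `truths` (data frame: `gene_id`, `group`,
#'   `rho_true`, `P_true`, `occupancy`, `contaminated`, `kappa_I`,
#'   `k_T`, `V_s_true`, `group_true`).
#' @export
generate_catalog <- function(cfg, compute_kinetics = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(ng))

  group_counts <- allocate_counts(cfg$group_mix, ng)
  group <- sample(rep(names(group_counts), group_counts))
  bins <- cfg$rho_bins
  rho_true <- vapply(group, function(g) runif(1, bins[[g]][1], bins[[g]][2]),
                     numeric(1))

  # The gradient's heaviest fraction holds 14 ribosomes, so a gene can
  # only be observed at density rho if rho * n / L <= 14: dense genes are
  # short. Couple length to density by drawing from the log-normal
  # truncated to [lower clip, 14 L / rho] (inverse-CDF sampling, so no
  # pile-up at the cap).
  len_cap <- pmax(pmin(cfg$length_range[2], floor(14 * cfg$L / rho_true)),
                  cfg$length_range[1] + 1)
  u_lo <- stats::plnorm(cfg$length_range[1], cfg$length_meanlog,
                        cfg$length_sdlog)
  u_hi <- stats::plnorm(len_cap, cfg$length_meanlog, cfg$length_sdlog)
  len <- round(stats::qlnorm(runif(ng, u_lo, u_hi),
                             cfg$length_meanlog, cfg$length_sdlog))
  len <- pmin(pmax(len, cfg$length_range[1]), len_cap)

  cat_counts <- allocate_counts(cfg$category_counts, ng)
  category <- sample(rep(names(cat_counts), cat_counts))

  # operons: blocks of consecutive genes
  operon_id <- rep(NA_character_, ng)
  if (cfg$n_operons > 0) {
    sizes <- sample(seq(cfg$operon_size_range[1], cfg$operon_size_range[2]),
                    cfg$n_operons, replace = TRUE)
    starts <- sort(sample(seq_len(ng - max(sizes)), cfg$n_operons))
    # drop overlapping blocks
    keep <- rep(TRUE, cfg$n_operons)
    end_prev <- 0
    for (i in seq_len(cfg$n_operons)) {
      if (starts[i] <= end_prev) keep[i] <- FALSE
      else end_prev <- starts[i] + sizes[i] - 1
    }
    k <- 0
    for (i in which(keep)) {
      k <- k + 1
      operon_id[seq(starts[i], starts[i] + sizes[i] - 1)] <-
        sprintf("op%02d", k)
    }
  }

  m_rel <- rlnorm(ng, 0, 1)
  half_life <- exp(runif(ng, log(cfg$halflife_range[1]),
                         log(cfg$halflife_range[2])))

  # Operon members sit on one polycistronic transcript: they share a
  # common density, bounded so that the transcript's total ribosome load
  # stays within the gradient (<= 14) and the conservative per-member
  # overestimate stays below the density ceiling.
  for (op in unique(operon_id[!is.na(operon_id)])) {
    idx <- which(operon_id == op)
    tot <- sum(len[idx])
    rho_op <- min(c(rho_true[idx], 0.9 * 14 * cfg$L / tot,
                    0.9 * min(len[idx]) / tot))
    rho_true[idx] <- rho_op
    group[idx] <- bin_of_rho(rho_op, cfg$rho_bins)
  }

  P_true <- rho_true * len / cfg$L

  # occupancy mean decreases with half-life (standardized log scale)
  z <- scale(log(half_life))[, 1]
  if (anyNA(z)) z <- rep(0, ng)
  occ_mean <- pmin(pmax(cfg$occupancy_mean - cfg$halflife_occ_slope * z,
                        0.05), 0.95)
  occupancy <- rbeta(ng, occ_mean * cfg$occupancy_conc,
                     (1 - occ_mean) * cfg$occupancy_conc)

  # Co-elution contamination is only observable where it pushes the
  # implied density past the theoretical ceiling -- short, ribosome-dense
  # mRNAs sedimenting near the gradient bottom. Compute, per gene, the
  # minimal contaminating H-mass share that makes the implied polysome
  # size exceed n/L, and contaminate genes where a realistic share (below
  # the configured maximum) suffices.
  nL <- len / cfg$L
  a <- 14 - nL
  b <- occupancy * (nL - pmin(P_true, 14))
  m_min <- ifelse(a > 0, b / (a + b), 1)
  eligible <- which(1.25 * m_min + 0.05 <= cfg$contamination_mass[2] &
                    rho_true >= 0.6 & is.na(operon_id))
  n_cont <- min(length(eligible), round(cfg$contamination_rate * ng))
  contaminated <- rep(FALSE, ng)
  if (n_cont > 0) {
    contaminated[sample(eligible, n_cont)] <- TRUE
  }
  contamination_lo <- pmin(pmax(cfg$contamination_mass[1],
                                1.25 * m_min + 0.05),
                           cfg$contamination_mass[2])

  u <- runif(ng, contamination_lo, cfg$contamination_mass[2])
  cont_mass <- ifelse(contaminated, pmin(u, cfg$contamination_mass[2]), 0)

  kappa_I <- k_T <- V_s_true <- rep(NA_real_, ng)
  group_true <- rep(NA_character_, ng)
  if (compute_kinetics) {
    for (i in seq_len(ng)) {
      cal <- calibrate_gene(len[i], target_P = P_true[i], L = cfg$L,
                            k_E = cfg$k_E, gene_id = gene_id[i])
      kappa_I[i] <- cal$kappa_I
      k_T[i] <- cal$k_T
      V_s_true[i] <- cal$state$V_s
      cc <- control_coefficients(cal$state$params)
      group_true[i] <- as.character(cc$group)
    }
  }

  list(catalog = data.frame(gene_id = gene_id, length_codons = len,
                            category = category, operon_id = operon_id,
                            m_rel = m_rel, half_life_min = half_life,
                            stringsAsFactors = FALSE),
       truths = data.frame(gene_id = gene_id, group = group,
                           rho_true = rho_true, P_true = P_true,
                           occupancy = occupancy,
                           contaminated = contaminated,
                           cont_mass = cont_mass,
                           kappa_I = kappa_I, k_T = k_T,
                           V_s_true = V_s_true, group_true = group_true,
                           stringsAsFactors = FALSE))
}

# engaged-mass weights over fractions D..H for a true polysome size P:
# linear interpolation between the two bracketing fraction sizes (exact
# weighted mean), plus an optional symmetric spill to adjacent fractions
engaged_weights <- function(P, sizes, spill = 0) {
  s <- sizes[ENGAGED]
  w <- numeric(5)
  if (P <= s[1]) w[1] <- 1
  else if (P >= s[5]) w[5] <- 1
  else {
    k <- max(which(s <= P))
    a <- (s[k + 1] - P) / (s[k + 1] - s[k])
    w[k] <- a
    w[k + 1] <- 1 - a
  }
  if (spill > 0) {
    sm <- numeric(5)
    for (k in 1:5) {
      lo <- max(1, k - 1); hi <- min(5, k + 1)
      sm[lo:hi] <- sm[lo:hi] + w[k] / (hi - lo + 1)
    }
    w <- (1 - spill) * w + spill * sm
  }
  w
}

#' Generate triplicate fraction profiles from a catalog
#'
#' Builds, for every gene, the expected distribution of its mRNA mass
#' across the 7 elution fractions: the engaged share (the gene's
#' occupancy) is dispersed over fractions D-H around the true polysome
#' size, the non-engaged share is split between fractions B and C,
#' co-elution contamination is added to fraction H for flagged genes,
#' and replicates are drawn with multiplicative log-normal noise. Member
#' genes of one operon share a common detected polysome size (the summed
#' ribosome load of the polycistronic transcript, capped at the heaviest
#' fraction) and hence an identical pre-noise engaged distribution.
#'
#' @param catalog,truths As returned by [generate_catalog()].
#' @param cfg The same [generator_config()].
#' @return A named list of [fraction_profile()] objects, one per gene.
#' @export
generate_profiles <- function(catalog, truths, cfg) {
  stopifnot(inherits(cfg, "generator_config"),
            identical(catalog$gene_id, truths$gene_id))
  set.seed(cfg$seed + 1L)
  sizes <- fraction_sizes()
  ng <- nrow(catalog)

  # operon members co-sediment at the transcript's total ribosome load
  P_det <- truths$P_true
  if (any(!is.na(catalog$operon_id))) {
    for (op in unique(stats::na.omit(catalog$operon_id))) {
      idx <- which(catalog$operon_id == op)
      P_det[idx] <- min(sum(truths$P_true[idx]), sizes[7])
    }
  }

  profiles <- vector("list", ng)
  for (i in seq_len(ng)) {
    occ <- truths$occupancy[i]
    w <- engaged_weights(P_det[i], sizes, cfg$dispersion_spill)
    base <- c(cfg$bc_split * (1 - occ), (1 - cfg$bc_split) * (1 - occ),
              occ * w)
    if (truths$contaminated[i]) {
      m <- truths$cont_mass[i]
      base <- (1 - m) * base
      base[7] <- base[7] + m
    }
    reps <- matrix(0, cfg$replicates, 7)
    for (r in seq_len(cfg$replicates)) {
      x <- base * exp(rnorm(7, 0, cfg$noise_sd))
      reps[r, ] <- x / sum(x)
    }
    profiles[[i]] <- fraction_profile(catalog$gene_id[i], reps, sizes)
  }
  names(profiles) <- catalog$gene_id
  profiles
}
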