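#' Pipeline configuration
#'
#' Collects the constants and options shared by all pipeline stages. The
#' defaults are the study constants: a 10-codon ribosome footprint, a
#' cell-averaged elongation rate constant of 23 codons/s, and a global
#' engaged-ribosome fraction of 0.61 (metadata used for reporting only).
#'
#' @param L Ribosome footprint in codons.
#' @param k_E Elongation rate constant, codons/s.
#' @param eta Global engaged-ribosome fraction (reporting metadata).
#' @param rho_cap Density cap for the co-elution recalibration.
#' @param sizes Fraction mean polysome sizes.
#' @param operon_mode `"conservative"` or `"shared"`, see
#'   [operon_share_adjustment()].
#' @param calib [calibration_options()].
#' @param rel_step Relative perturbation for the control coefficients.
#' @param shared_threshold Threshold for [shared_control_fraction()].
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(L = 10, k_E = 23, eta = 0.61, rho_cap = 1,
                            sizes = fraction_sizes(),
                            operon_mode = c("conservative", "shared"),
                            calib = calibration_options(),
                            rel_step = 0.01, shared_threshold = 0.05) {
  operon_mode <- match.arg(operon_mode)
  structure(list(L = L, k_E = k_E, eta = eta, rho_cap = rho_cap,
                 sizes = sizes, operon_mode = operon_mode, calib = calib,
                 rel_step = rel_step, shared_threshold = shared_threshold),
            class = "pipeline_config")
}

#' Run the full translatome analysis pipeline
#'
#' Composes the analysis stages: per-gene density estimation from the
#' fraction profiles, co-elution recalibration, operon adjustment,
#' kinetic calibration of `(kappa_I, k_T)` to the estimated polysome
#' size under rate maximization, control-coefficient analysis and regime
#' grouping, absolute synthesis rates, category summaries and enrichment
#' of regimes across functional categories. Genes shorter than `2 L`
#' codons, with no engaged mass, or still above the density cap after
#' recalibration are excluded with a logged reason.
#'
#' @param catalog A gene-catalog data frame with columns `gene_id`,
#'   `length_codons`, `category`, `operon_id`, `m_rel`,
#'   `half_life_min` (see [read_gene_catalog()]).
#' @param profiles A named list of [fraction_profile()] objects (see
#'   [read_fraction_table()]).
#' @param config A [pipeline_config()].
#' @return An object of class `"pipeline_run"`: `results` (per-gene data
#'   frame), `summaries` ([category_summary()] on `V_abs`),
#'   `enrichment`, `excluded` (gene, reason) and `report` (group
#'   histogram, shared-control fraction, configuration echo and
#'   rho/V_s scatter data).
#' @export
run_pipeline <- function(catalog, profiles, config = pipeline_config()) {
  stopifnot(is.data.frame(catalog),
            all(c("gene_id", "length_codons", "category", "m_rel") %in%
                names(catalog)))
  missing_prof <- setdiff(catalog$gene_id, names(profiles))
  if (length(missing_prof) > 0) {
    stop("no fraction profile for: ", paste(missing_prof, collapse = ", "))
  }
  L <- config$L
  excluded <- data.frame(gene_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  drop_gene <- function(id, why) {
    excluded <<- rbind(excluded, data.frame(gene_id = id, reason = why,
                                            stringsAsFactors = FALSE))
  }

  short <- catalog$length_codons < 2 * L
  for (id in catalog$gene_id[short]) {
    drop_gene(id, sprintf("length below 2L = %d codons", 2 * L))
  }
  cat_ok <- catalog[!short, , drop = FALSE]

  # --- density estimation with co-elution recalibration ----------------
  est_rows <- vector("list", nrow(cat_ok))
  for (i in seq_len(nrow(cat_ok))) {
    id <- cat_ok$gene_id[i]
    n <- cat_ok$length_codons[i]
    est <- estimate_polysome_size(profiles[[id]], n_codons = n, L = L)
    rec <- recalibrate_coelution(est, profiles[[id]], n = n, L = L,
                                 rho_cap = config$rho_cap)
    e <- rec$estimate
    est_rows[[i]] <- data.frame(gene_id = id, length_codons = n,
                                P_hat = e$P_hat, p_rib = e$p_rib,
                                rho_hat = e$rho_hat,
                                removed_mass = e$removed_mass,
                                status = e$status,
                                stringsAsFactors = FALSE)
  }
  est <- do.call(rbind, est_rows)

  # --- operon adjustment ----------------------------------------------
  if ("operon_id" %in% names(cat_ok) && any(!is.na(cat_ok$operon_id))) {
    omap <- cat_ok[!is.na(cat_ok$operon_id), c("gene_id", "operon_id")]
    omap <- omap[omap$gene_id %in% est$gene_id[est$status != "excluded"], ]
    lens <- stats::setNames(cat_ok$length_codons, cat_ok$gene_id)
    keep <- est$status != "excluded"
    est[keep, ] <- operon_share_adjustment(est[keep, , drop = FALSE],
                                           omap, lens,
                                           mode = config$operon_mode, L = L)
  }

  for (i in which(est$status == "excluded")) {
    why <- if (est$p_rib[i] == 0) "no engaged mRNA mass" else
      sprintf("density above cap %.2g after recalibration", config$rho_cap)
    drop_gene(est$gene_id[i], why)
  }
  est <- est[est$status != "excluded", , drop = FALSE]
  if (nrow(est) == 0) stop("no genes left after quality control")

  # --- kinetic calibration and control analysis ------------------------
  nr <- nrow(est)
  V_s <- C_I <- C_E <- C_T <- kappa_I <- k_T <- rep(NA_real_, nr)
  group <- rep(NA_character_, nr)
  branch <- rep(NA_character_, nr)
  for (i in seq_len(nr)) {
    # full packing (rho = 1 exactly) is only reached asymptotically as
    # k_T -> 0; calibrate genes sitting at the cap just below the limit
    target <- min(est$P_hat[i], 0.995 * est$length_codons[i] / L)
    cal <- calibrate_gene(est$length_codons[i], target_P = target,
                          L = L, k_E = config$k_E, opts = config$calib,
                          gene_id = est$gene_id[i])
    cc <- control_coefficients(cal$state$params,
                               rel_step = config$rel_step,
                               tol = config$calib$tol)
    V_s[i] <- cal$state$V_s
    kappa_I[i] <- cal$kappa_I; k_T[i] <- cal$k_T
    branch[i] <- cal$branch
    C_I[i] <- cc$C_I; C_E[i] <- cc$C_E; C_T[i] <- cc$C_T
    group[i] <- as.character(cc$group)
  }

  res <- data.frame(est, kappa_I = kappa_I, k_T = k_T, branch = branch,
                    V_s = V_s, C_I = C_I, C_E = C_E, C_T = C_T,
                    group = group, stringsAsFactors = FALSE)
  meta <- cat_ok[match(res$gene_id, cat_ok$gene_id),
                 c("category", "operon_id", "m_rel", "half_life_min")]
  res <- cbind(res, meta)
  res$V_abs <- absolute_rate(res$m_rel, res$p_rib, res$V_s)
  rownames(res) <- NULL

  summaries <- category_summary(res, value = "V_abs")
  enr <- enrichment(res$group, res$category)

  report <- list(
    n_genes_in = nrow(catalog),
    n_genes_analyzed = nrow(res),
    n_excluded = nrow(excluded),
    n_recalibrated = sum(res$status == "recalibrated"),
    group_histogram = table(factor(res$group,
                                   levels = c("I", "II", "III", "IV", "V", "VI"))),
    shared_control_fraction =
      shared_control_fraction(res, config$shared_threshold),
    eta = config$eta,
    config = config,
    scatter = res[, c("gene_id", "rho_hat", "V_s", "group")]
  )
  structure(list(results = res, summaries = summaries, enrichment = enr,
                 excluded = excluded, report = report),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("translatome pipeline run: %d genes analyzed (%d in, %d excluded)\n",
              r$n_genes_analyzed, r$n_genes_in, r$n_excluded))
  cat("  control-regime histogram:\n")
  print(r$group_histogram)
  cat(sprintf("  shared initiation+elongation control: %.1f%% of genes\n",
              100 * r$shared_control_fraction))
  invisible(x)
}

#' Read a gene catalog from a tab-separated file
#'
#' Expected columns: `gene_id`, `length_codons`, `category`,
#' `operon_id` (empty for monocistronic genes), `m_rel`,
#' `half_life_min`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_gene_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_codons", "category", "m_rel")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("catalog is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"operon_id" %in% names(df)) df$operon_id <- NA_character_
  df$operon_id[df$operon_id == ""] <- NA_character_
  df
}

#' Read replicate fraction profiles from a tab-separated file
#'
#' Expected columns: `gene_id`, `replicate`, `prop_B` .. `prop_H`.
#'
#' @param path File path.
#' @param sizes Fraction mean sizes, default [fraction_sizes()].
#' @return A named list of [fraction_profile()] objects.
#' @export
read_fraction_table <- function(path, sizes = fraction_sizes()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  pcols <- paste0("prop_", names(fraction_sizes()))
  miss <- setdiff(c("gene_id", pcols), names(df))
  if (length(miss) > 0) {
    stop("fraction table is missing columns: ", paste(miss, collapse = ", "))
  }
  lapply(split(df, df$gene_id), function(d) {
    fraction_profile(d$gene_id[1], as.matrix(d[, pcols]), sizes)
  })
}

#' Write pipeline outputs as tab-separated files
#'
#' Writes `results.tsv`, `summaries.tsv`, `enrichment.tsv` and
#' `excluded.tsv` into a directory.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "pipeline_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(run$results, "results.tsv")
  wr(run$summaries, "summaries.tsv")
  wr(run$enrichment, "enrichment.tsv")
  wr(run$excluded, "excluded.tsv")
  invisible(dir)
}

#' Write fraction profiles as a tab-separated table
#'
#' Inverse of [read_fraction_table()].
#'
#' @param profiles Named list of [fraction_profile()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fraction_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    d <- as.data.frame(p$proportions)
    names(d) <- paste0("prop_", names(fraction_sizes()))
    cbind(gene_id = p$gene_id, replicate = seq_len(nrow(d)), d)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
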