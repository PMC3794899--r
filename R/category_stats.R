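#' Normalized absolute protein synthesis rate
#'
#' Scales the specific synthesis rate (proteins per second per engaged
#' mRNA copy) to the gene level: `V_abs = m_rel * p_rib * V_s`, where
#' `m_rel` is the gene's relative total mRNA concentration and `p_rib`
#' the fraction of its copies engaged in translation. Because mRNA
#' concentrations are only known relative to each other, `V_abs` is in
#' arbitrary units; ratios and rankings between genes are meaningful.
#'
#' @param m_rel Relative mRNA concentration (arbitrary units).
#' @param p_rib Ribosome occupancy in `[0, 1]`.
#' @param V_s Specific synthesis rate, proteins/s per engaged copy.
#' @return `V_abs` in arbitrary units (vectorized).
#' @export
absolute_rate <- function(m_rel, p_rib, V_s) {
  if (any(m_rel < 0, na.rm = TRUE) || any(p_rib < 0, na.rm = TRUE) ||
      any(V_s < 0, na.rm = TRUE)) {
    stop("inputs must be non-negative")
  }
  m_rel * p_rib * V_s
}

#' Per-category summaries with notched-median intervals
#'
#' Summarizes a per-gene quantity by functional category: size, median,
#' quartiles (linear-interpolation convention) and the notch half-width
#' `1.57 * IQR / sqrt(n)`. When the notch intervals of two categories do
#' not overlap their medians differ at roughly 95 percent confidence. A pooled
#' `"ALL"` pseudo-category is appended and rows are ordered by median.
#'
#' @param results A data frame with a `category` column and the value
#'   column named by `value`.
#' @param value Name of the value column (default `"V_abs"`).
#' @return A data frame with columns `category`, `n_genes`, `median`,
#'   `q1`, `q3`, `notch`, ordered by increasing median (with `"ALL"`
#'   placed by its own median).
#' @export
category_summary <- function(results, value = "V_abs") {
  stopifnot(is.data.frame(results), "category" %in% names(results),
            value %in% names(results))
  x <- results[[value]]
  keep <- !is.na(x)
  x <- x[keep]
  cats <- as.character(results$category)[keep]
  empty <- setdiff(unique(as.character(results$category)), cats)
  if (length(empty) > 0) {
    warning("dropping categories with no finite values: ",
            paste(empty, collapse = ", "))
  }
  one <- function(name, v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(category = name, n_genes = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               notch = 1.57 * (q[3] - q[1]) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(x, cats), function(v) one(NA, v)))
  out$category <- names(split(x, cats))
  out <- rbind(out, one("ALL", x))
  out <- out[order(out$median), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare category synthesis rates between two conditions
#'
#' Calls a category changed between conditions when the notched-median
#' intervals `median +/- notch` of the two summaries do not overlap:
#' `"+"` for an increase in condition B relative to condition A, `"-"`
#' for a decrease, `"ns"` otherwise. Categories present in only one
#' condition are skipped with a warning.
#'
#' @param summary_a,summary_b [category_summary()] outputs for the two
#'   conditions (A is the reference).
#' @return A data frame with `category`, `median_a`, `median_b`, `call`.
#' @export
compare_conditions <- function(summary_a, summary_b) {
  shared <- intersect(summary_a$category, summary_b$category)
  missing <- setdiff(union(summary_a$category, summary_b$category), shared)
  if (length(missing) > 0) {
    warning("categories present in one condition only: ",
            paste(missing, collapse = ", "))
  }
  a <- summary_a[match(shared, summary_a$category), ]
  b <- summary_b[match(shared, summary_b$category), ]
  no_overlap <- (b$median - b$notch > a$median + a$notch) |
                (b$median + b$notch < a$median - a$notch)
  call <- ifelse(!no_overlap, "ns", ifelse(b$median > a$median, "+", "-"))
  data.frame(category = shared, median_a = a$median, median_b = b$median,
             call = call, stringsAsFactors = FALSE)
}

#' One-way ANOVA of operon membership in one elution fraction
#'
#' Tests whether the replicate-averaged mRNA proportion of a group of
#' operonic genes in a given elution fraction differs from that of the
#' remaining genes, using a one-way fixed-effects ANOVA with genes as
#' observational units.
#'
#' @param profiles A list of [fraction_profile()] objects (all genes),
#'   or a genes-by-7 matrix of replicate-averaged proportions with gene
#'   ids as row names.
#' @param operon_genes Gene ids of the operon members (at least 2; at
#'   least 2 genes must remain outside).
#' @param fraction Elution fraction: index 1-7 or letter `"B".."H"`.
#' @return A list with `F`, `df` (numerator, denominator), `p`. If both
#'   groups have zero variance and equal means, `p = 1` by convention.
#' @export
operon_anova <- function(profiles, operon_genes, fraction) {
  if (is.character(fraction)) {
    fraction <- match(fraction, names(fraction_sizes()))
  }
  stopifnot(fraction %in% 1:7)
  if (is.list(profiles) && !is.data.frame(profiles)) {
    m <- t(vapply(profiles, function(p) colMeans(p$proportions), numeric(7)))
    rownames(m) <- vapply(profiles, `[[`, character(1), "gene_id")
  } else {
    m <- as.matrix(profiles)
  }
  inop <- rownames(m) %in% operon_genes
  if (sum(inop) < 2 || sum(!inop) < 2) {
    stop("need at least 2 genes inside and outside the operon")
  }
  x <- m[, fraction]
  g <- factor(ifelse(inop, "operon", "other"))
  if (all(x == x[1])) return(list(F = 0, df = c(1, length(x) - 2), p = 1))
  fit <- anova(aov(x ~ g))
  Fv <- fit[["F value"]][1]
  p <- fit[["Pr(>F)"]][1]
  if (is.na(Fv)) {  # zero within-group variance
    means_equal <- isTRUE(all.equal(mean(x[inop]), mean(x[!inop])))
    Fv <- if (means_equal) 0 else Inf
    p <- if (means_equal) 1 else 0
  }
  list(F = Fv, df = unname(fit$Df), p = p)
}

#' Functional-category enrichment of control-regime groups
#'
#' For every (group, category) pair, tests over-representation of the
#' category inside the group with a one-sided hypergeometric upper-tail
#' test. Reports the count columns in the `k/K` and `n/N` style: `k`
#' genes of the category inside the group, `K` in the whole set, `n`
#' genes in the group, `N` overall. Raw p-values are reported; an
#' optional Benjamini-Hochberg column can be added.
#'
#' @param group_assignments Per-gene group labels.
#' @param categories Per-gene functional categories (same order).
#' @param add_fdr If `TRUE`, append a BH-adjusted p-value column.
#' @return A data frame with one row per (group, category) pair:
#'   `group`, `category`, `k`, `K`, `n`, `N`, `p` (and `fdr`).
#' @export
enrichment <- function(group_assignments, categories, add_fdr = FALSE) {
  stopifnot(length(group_assignments) == length(categories))
  g <- as.character(group_assignments)
  ca <- as.character(categories)
  if (anyNA(g) || anyNA(ca)) stop("every gene needs a group and a category")
  N <- length(g)
  out <- list()
  for (gr in sort(unique(g))) {
    n <- sum(g == gr)
    for (cc in sort(unique(ca))) {
      K <- sum(ca == cc)
      k <- sum(g == gr & ca == cc)
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      out[[length(out) + 1L]] <-
        data.frame(group = gr, category = cc, k = k, K = K, n = n, N = N,
                   p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (add_fdr) res$fdr <- p.adjust(res$p, method = "BH")
  res
}
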