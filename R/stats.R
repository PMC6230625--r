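#' Bonferroni-corrected significance threshold
#'
#' Divides the family-wise alpha by the number of comparisons. The reported
#' threshold is floored to 3 decimals (so 0.05 over three comparisons prints
#' as 0.016); the raw quotient is retained and is what significance
#' decisions use.
#'
#' @param family_alpha family-wise error rate.
#' @param n_comparisons number of comparisons sharing the family.
#' @return list with `raw` (family_alpha / n) and `reported` (floored to 3
#'   decimals).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_comparisons = 3L) {
  stopifnot(family_alpha > 0, family_alpha <= 1)
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1", call. = FALSE)
  raw <- family_alpha / n_comparisons
  list(raw = raw, reported = floor(raw * 1000) / 1000)
}

#' Average methylation over a subset of CpG sites
#'
#' Unweighted mean of per-CpG percentages, the region-level summary used for
#' comparing sub-regions (e.g. the first eight CpGs of an amplicon). CpGs
#' with no callable clone (zero denominator) are excluded with a warning.
#'
#' @param matrix a [build_matrix()] result.
#' @param cpg_subset integer CpG ordinals (1-based, assayed-strand order);
#'   default all.
#' @return mean percentage.
#' @export
region_average <- function(matrix, cpg_subset = NULL) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  k <- length(matrix$percent)
  if (is.null(cpg_subset)) cpg_subset <- seq_len(k)
  if (length(cpg_subset) == 0L) stop("cpg_subset is empty", call. = FALSE)
  if (any(cpg_subset < 1L | cpg_subset > k))
    stop("cpg_subset out of range", call. = FALSE)
  p <- matrix$percent[cpg_subset]
  if (anyNA(p) || any(is.nan(p))) {
    warning("excluding CpG(s) with zero called clones from the average")
    p <- p[!is.na(p) & !is.nan(p)]
    if (length(p) == 0L) stop("no CpG in the subset has called clones",
                              call. = FALSE)
  }
  mean(p)
}

#' Paired per-(donor, CpG) methylation differences between two populations
#'
#' For every donor assayed in both populations (same region and strand), the
#' per-CpG difference in percent methylation is computed; this long table is
#' the unit of analysis for the paired comparison tests.
#'
#' @param matrices named list of [build_matrix()] results (one per group).
#' @param pop_a,pop_b population labels; differences are `pop_a - pop_b`.
#' @return data frame with columns `donor`, `cpg`, `diff` (percentage
#'   points).
#' @export
paired_difference_table <- function(matrices, pop_a, pop_b) {
  pick <- function(pop) Filter(function(m) m$group$population == pop, matrices)
  ma <- pick(pop_a)
  mb <- pick(pop_b)
  if (length(ma) == 0L || length(mb) == 0L)
    stop(sprintf("population '%s' absent from the matrices",
                 if (length(ma) == 0L) pop_a else pop_b), call. = FALSE)
  rs <- unique(c(vapply(c(ma, mb), function(m)
    paste(m$group$region, m$group$strand), character(1))))
  if (length(rs) != 1L)
    stop("matrices span more than one (region, strand); subset first",
         call. = FALSE)
  da <- vapply(ma, function(m) m$group$donor, character(1))
  db <- vapply(mb, function(m) m$group$donor, character(1))
  shared <- intersect(da, db)
  if (length(shared) == 0L)
    stop(sprintf("no donor has both '%s' and '%s'; cannot pair", pop_a, pop_b),
         call. = FALSE)
  rows <- lapply(shared, function(d) {
    a <- ma[[which(da == d)[1]]]
    b <- mb[[which(db == d)[1]]]
    data.frame(donor = d, cpg = seq_along(a$percent),
               diff = a$percent - b$percent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

new_paired_comparison <- function(contrast, estimate, se, p_value, alpha,
                                  n_donors, n_cpgs, method, note = NULL) {
  structure(list(contrast = contrast, estimate = estimate, se = se,
                 p_value = p_value, alpha_adjusted = alpha,
                 significant = is.finite(p_value) && p_value < alpha,
                 n_donors = n_donors, n_cpgs = n_cpgs, method = method,
                 note = note),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s [%s]\n", x$contrast, x$method))
  cat(sprintf("  estimate %.2f pp (SE %.2f), p = %.4g vs alpha = %.4g -> %s\n",
              x$estimate, x$se, x$p_value, x$alpha_adjusted,
              if (x$significant) "significant" else "not significant"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
as.data.frame.paired_comparison <- function(x, ...) {
  data.frame(contrast = x$contrast, estimate = x$estimate, se = x$se,
             p_value = x$p_value, alpha_adjusted = x$alpha_adjusted,
             significant = x$significant, n_donors = x$n_donors,
             n_cpgs = x$n_cpgs, method = x$method,
             stringsAsFactors = FALSE)
}

#' Mixed-effects test of a paired methylation difference
#'
#' Fits an intercept-only linear mixed model to the per-(donor, CpG)
#' differences with crossed random intercepts for donor and CpG position
#' (REML), and Wald-tests the intercept against zero. A nonzero intercept
#' indicates a systematic methylation difference between the two populations
#' (or strands) being compared, over and above donor-to-donor and
#' site-to-site variation.
#'
#' Degenerate inputs are handled explicitly: when every difference is
#' exactly zero the test returns p = 1; when the model cannot be fit (e.g.
#' zero residual variance with a constant offset) the donor-level sign-flip
#' [permutation_test()] is used instead, and the result carries a note.
#'
#' @param diff_table data frame from [paired_difference_table()] (or
#'   [simulate_diff_table()]), columns `donor`, `cpg`, `diff`.
#' @param contrast label for reporting.
#' @param alpha significance threshold the p-value is compared against
#'   (default the raw Bonferroni quotient 0.05/3).
#' @return a `paired_comparison` object.
#' @export
mixed_effects_test <- function(diff_table, contrast = "A - B",
                               alpha = bonferroni_alpha(0.05, 3)$raw) {
  stopifnot(all(c("donor", "cpg", "diff") %in% names(diff_table)))
  n_donors <- length(unique(diff_table$donor))
  n_cpgs <- length(unique(diff_table$cpg))
  if (n_donors < 2L || n_cpgs < 2L)
    stop("mixed_effects_test needs >= 2 donors and >= 2 CpG positions",
         call. = FALSE)
  if (all(diff_table$diff == 0)) {
    return(new_paired_comparison(contrast, 0, 0, 1, alpha, n_donors, n_cpgs,
                                 "mixed_effects"))
  }
  if (stats::sd(diff_table$diff) == 0) {
    # constant nonzero offset: zero variance everywhere, the mixed model is
    # degenerate; the donor-level sign-flip distribution still applies
    res <- permutation_test(diff_table, contrast = contrast, alpha = alpha)
    res$note <- "zero-variance differences; donor-level sign-flip permutation used"
    return(res)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(diff ~ 1 + (1 | donor) + (1 | cpg), data = diff_table,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e) NULL)
  est <- if (is.null(fit)) NA_real_ else unname(lme4::fixef(fit)[1])
  se <- if (is.null(fit)) NA_real_ else sqrt(as.numeric(stats::vcov(fit)[1, 1]))
  if (is.null(fit) || !is.finite(se) || se <= 0) {
    res <- permutation_test(diff_table, contrast = contrast, alpha = alpha)
    res$note <- "mixed model degenerate or unfittable; donor-level sign-flip permutation used"
    return(res)
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  new_paired_comparison(contrast, est, se, p, alpha, n_donors, n_cpgs,
                        "mixed_effects")
}

#' Donor-level sign-flip permutation test of a paired difference
#'
#' Model-free companion to [mixed_effects_test()]. Under the null of no
#' systematic difference, each donor's whole vector of differences is
#' exchangeable with its negation, so signs are flipped jointly per donor
#' (CpG-level flips would break within-donor correlation). The statistic is
#' the grand mean difference; the two-sided p-value is exact (full
#' enumeration of all 2^D sign patterns) whenever that is within `n_perm`,
#' otherwise Monte-Carlo with add-one correction.
#'
#' @inheritParams mixed_effects_test
#' @param n_perm permutation budget; full enumeration is used when
#'   `2^n_donors <= n_perm`.
#' @param seed optional integer seed for the Monte-Carlo branch.
#' @return a `paired_comparison` object (method `"permutation"`, with an
#'   `exact` element).
#' @export
permutation_test <- function(diff_table, n_perm = 10000L, seed = NULL,
                             contrast = "A - B",
                             alpha = bonferroni_alpha(0.05, 3)$raw) {
  stopifnot(all(c("donor", "cpg", "diff") %in% names(diff_table)))
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse p-value")
  donors <- unique(diff_table$donor)
  D <- length(donors)
  n <- nrow(diff_table)
  sums <- vapply(donors, function(d) sum(diff_table$diff[diff_table$donor == d]),
                 numeric(1))
  t_obs <- sum(sums) / n
  eps <- 1e-9 * (1 + abs(t_obs))
  exact <- 2^D <= n_perm
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), D)))
    t_perm <- as.numeric(signs %*% sums) / n
    p <- mean(abs(t_perm) >= abs(t_obs) - eps)
  } else {
    t_perm <- with_seed(seed, {
      s <- matrix(sample(c(-1, 1), n_perm * D, replace = TRUE), ncol = D)
      as.numeric(s %*% sums) / n
    })
    p <- (1 + sum(abs(t_perm) >= abs(t_obs) - eps)) / (n_perm + 1)
  }
  res <- new_paired_comparison(contrast, t_obs,
                               stats::sd(t_perm) %||% NA_real_, p, alpha,
                               D, length(unique(diff_table$cpg)),
                               "permutation")
  res$exact <- exact
  res
}

#' Strand-bias (hemimethylation) analysis of one region
#'
#' Contrasts the per-CpG methylation of the two strands of one region within
#' one population. The hemimethylation index is the absolute difference in
#' percent methylation between the strands at each CpG (a signed top-minus-
#' bottom variant is also reported); the region-level test applies
#' [mixed_effects_test()] to the per-(donor, CpG) top-minus-bottom
#' differences, so a systematic strand bias shows up exactly like a
#' population difference would.
#'
#' @param matrices_top,matrices_bottom [build_matrix()] result(s) (one per
#'   donor) for the same region and population, assayed on the top and
#'   bottom strand respectively.
#' @param alpha significance threshold for the region test.
#' @return an object of class `strand_bias`: `per_cpg` data frame
#'   (`cpg`, `top_percent`, `bottom_percent`, `index`, `signed`, averaged
#'   over donors), `test` (a `paired_comparison`), `region`, `population`.
#' @export
strand_bias_analysis <- function(matrices_top, matrices_bottom,
                                 alpha = bonferroni_alpha(0.05, 3)$raw) {
  as_list <- function(x) if (inherits(x, "methylation_matrix")) list(x) else x
  mt <- as_list(matrices_top)
  mb <- as_list(matrices_bottom)
  chk <- function(ms, strand) {
    for (m in ms)
      if (m$group$strand != strand)
        stop(sprintf("expected %s-strand matrices, got group %s",
                     strand, group_key(m$group)), call. = FALSE)
  }
  chk(mt, "top"); chk(mb, "bottom")
  regions <- unique(vapply(c(mt, mb), function(m)
    paste(m$group$region, m$group$population), character(1)))
  if (length(regions) != 1L)
    stop("all matrices must share one region and population", call. = FALSE)

  dt <- vapply(mt, function(m) m$group$donor, character(1))
  db <- vapply(mb, function(m) m$group$donor, character(1))
  shared <- intersect(dt, db)
  if (length(shared) == 0L)
    stop("no donor assayed on both strands", call. = FALSE)

  k <- length(mt[[1]]$percent)
  diffs <- lapply(shared, function(d) {
    a <- mt[[which(dt == d)[1]]]
    b <- mb[[which(db == d)[1]]]
    data.frame(donor = d, cpg = seq_len(k), top = a$percent,
               bottom = b$percent, diff = a$percent - b$percent,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, diffs)
  per_cpg <- do.call(rbind, lapply(split(long, long$cpg), function(g) {
    data.frame(cpg = g$cpg[1],
               top_percent = mean(g$top), bottom_percent = mean(g$bottom),
               signed = mean(g$top) - mean(g$bottom))
  }))
  per_cpg$index <- abs(per_cpg$signed)
  per_cpg <- per_cpg[order(per_cpg$cpg),
                     c("cpg", "top_percent", "bottom_percent", "index", "signed")]
  rownames(per_cpg) <- NULL

  pop <- mt[[1]]$group$population
  region <- mt[[1]]$group$region
  test <- if (length(shared) >= 2L && k >= 2L) {
    mixed_effects_test(long[, c("donor", "cpg", "diff")],
                       contrast = sprintf("%s %s: top - bottom", region, pop),
                       alpha = alpha)
  } else {
    # single-donor design: fall back on the donor... clone-level information
    # is not pooled here; report the mean with a permutation over CpGs is not
    # valid either, so return a descriptive result without a p-value
    new_paired_comparison(sprintf("%s %s: top - bottom", region, pop),
                          mean(long$diff), NA_real_, NA_real_, alpha,
                          length(shared), k, "descriptive",
                          note = "region test needs >= 2 donors")
  }
  structure(list(per_cpg = per_cpg, test = test, region = region,
                 population = pop, n_donors = length(shared)),
            class = "strand_bias")
}

#' @export
print.strand_bias <- function(x, ...) {
  cat(sprintf("<strand_bias> %s / %s over %d donor(s)\n", x$region,
              x$population, x$n_donors))
  cat(sprintf("  mean hemimethylation index %.1f pp (max %.1f)\n",
              mean(x$per_cpg$index), max(x$per_cpg$index)))
  print(x$test)
  invisible(x)
}

#' Hierarchical clustering of cell subtypes by methylation profile
#'
#' Complete-linkage agglomerative clustering on the Euclidean distances
#' between subtype-average per-CpG methylation vectors. Rows are sorted by
#' label before clustering so the result is invariant to input order (ties
#' are then broken deterministically by label order).
#'
#' @param average_matrix numeric matrix, subtypes x CpG average percents,
#'   with subtype row names. Missing values are mean-imputed per CpG with a
#'   warning.
#' @return an object of class `cluster_result`: `labels`, `dist` (the
#'   distance matrix), `hclust` (merge tree with heights), `order` (leaf
#'   order), `newick` (merge tree with heights as branch lengths).
#' @export
cluster_subtypes <- function(average_matrix) {
  m <- as.matrix(average_matrix)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("subtype", seq_len(nrow(m)))
  if (nrow(m) < 2L)
    stop("clustering needs at least two subtypes", call. = FALSE)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (anyNA(m)) {
    warning("mean-imputing missing per-CpG values before clustering")
    for (j in seq_len(ncol(m))) {
      mu <- mean(m[, j], na.rm = TRUE)
      m[is.na(m[, j]), j] <- mu
    }
  }
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  phylo <- ape::as.phylo(hc)
  structure(list(labels = rownames(m), dist = as.matrix(d), hclust = hc,
                 order = hc$order,
                 newick = ape::write.tree(phylo)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d subtypes, complete linkage\n",
              length(x$labels)))
  cat("  leaf order:", paste(x$labels[x$order], collapse = " | "), "\n")
  cat("  newick:", x$newick, "\n")
  invisible(x)
}

#' Average subtype-by-CpG matrix across donors
#'
#' Builds the input for [cluster_subtypes()]: for each population, the
#' per-CpG percent methylation averaged over the donors assayed for the
#' given region and strand.
#'
#' @param matrices named list of [build_matrix()] results.
#' @param region,strand the group to average within.
#' @return numeric matrix, populations x CpGs.
#' @export
average_by_population <- function(matrices, region, strand) {
  ms <- Filter(function(m) m$group$region == region &&
                 m$group$strand == strand, matrices)
  if (length(ms) == 0L)
    stop(sprintf("no matrices for region '%s' strand '%s'", region, strand),
         call. = FALSE)
  pops <- sort(unique(vapply(ms, function(m) m$group$population, character(1))))
  k <- length(ms[[1]]$percent)
  out <- matrix(NA_real_, nrow = length(pops), ncol = k,
                dimnames = list(pops, sprintf("CpG_%d", seq_len(k))))
  for (pop in pops) {
    sel <- Filter(function(m) m$group$population == pop, ms)
    out[pop, ] <- rowMeans(vapply(sel, `[[`, numeric(k), "percent"))
  }
  out
}

#' Write a cluster tree as Newick
#'
#' @param cluster a [cluster_subtypes()] result.
#' @param path output path.
#' @export
write_newick <- function(cluster, path) {
  stopifnot(inherits(cluster, "cluster_result"))
  writeLines(cluster$newick, path)
  invisible(path)
}
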