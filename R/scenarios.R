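# Canned study scenarios: synthetic reference regions plus donor
# configurations reproducing the qualitative patterns the pipeline is built
# to detect (conventional Treg/Tcon methylation contrast, strand-biased
# hemimethylation, X-inactivation mosaics, and a null pair for calibration).

#' The five cell-population labels used throughout
#' @export
population_labels <- function() {
  c("CD34", "CD45RA+CD15s-", "CD45RA-CD15s-", "CD45RA-CD15s+", "Tcon")
}

#' Build a synthetic reference region with a fixed number of CpGs
#'
#' Constructs a deterministic pseudo-random sequence containing exactly
#' `n_cpg` CG dinucleotides separated by CG-free spacers (which still carry
#' plenty of non-CpG Cs, so conversion-efficiency QC has material to work
#' with). The sequence is synthetic: it emulates the structure of a
#' bisulfite amplicon, not any genomic locus.
#'
#' @param name region name.
#' @param n_cpg number of CpG sites.
#' @param spacer mean CG-free spacer length between consecutive CpGs.
#' @param seed integer seed making the sequence reproducible.
#' @return the top-strand [amplicon()].
#' @export
synthetic_region <- function(name, n_cpg = 15L, spacer = 28L, seed = 1L) {
  with_seed(derive_seed(seed, paste0("region:", name)), {
    block <- function(len) {
      ch <- character(len)
      prev <- ""
      for (i in seq_len(len)) {
        pool <- if (prev == "C") c("A", "C", "T") else c("A", "C", "G", "T")
        ch[i] <- sample(pool, 1L)
        prev <- ch[i]
      }
      # a trailing C before an inserted CG would be harmless (CCG has one
      # CG), but a trailing C before the next spacer's G is prevented above
      paste(ch, collapse = "")
    }
    lens <- pmax(10L, spacer + sample(-6L:6L, n_cpg + 1L, replace = TRUE))
    pieces <- character(2L * n_cpg + 1L)
    for (i in seq_len(n_cpg)) {
      pieces[2L * i - 1L] <- block(lens[i])
      pieces[2L * i] <- "CG"
    }
    pieces[2L * n_cpg + 1L] <- block(lens[n_cpg + 1L])
    seq <- paste(pieces, collapse = "")
    # spacer blocks can end in C right before an inserted CG ("CCG") which is
    # fine, but a block starting with G after a CG would create no new site;
    # verify the construction yielded exactly n_cpg sites
    amp <- amplicon(name, seq, assayed_strand = "top")
    stopifnot(length(amp$cpg_positions) == n_cpg)
    amp
  })
}

# top- and bottom-strand amplicons for one synthetic region
region_pair <- function(name, n_cpg = 15L, seed = 1L,
                        coding_strand = c("bottom", "top")) {
  coding_strand <- match.arg(coding_strand)
  top <- synthetic_region(name, n_cpg = n_cpg, seed = seed)
  top$gene_strand_label <- if (coding_strand == "top") "coding" else "template"
  bottom <- amplicon(name, reverse_complement(top$ref_seq),
                     assayed_strand = "bottom",
                     gene_strand_label = if (coding_strand == "bottom")
                       "coding" else "template")
  list(top = top, bottom = bottom)
}

#' Canned simulation scenarios
#'
#' Returns a ready-made [donor_config()] for one synthetic TSDR-like region
#' (15 CpGs, assayed on both strands; the coding strand is the genomic
#' bottom strand, as for an X-linked gene encoded on the reverse strand):
#'
#' * `conventional_male` - the classical pattern: Treg subsets demethylated
#'   and Tcon heavily methylated, identically on both strands.
#' * `hemimethylated_donor` - strand-biased donor: the coding (bottom)
#'   strand fully methylated in every population while the top strand
#'   follows the conventional pattern (Treg near 0, Tcon near 1).
#' * `xi_female` - female donor whose X-linked region is a 50:50 mosaic of
#'   an active-X profile (Treg demethylated, Tcon methylated) and a fully
#'   methylated inactive-X profile.
#' * `null_pair` - two populations with element-wise identical profiles
#'   (for calibration of the comparison tests).
#'
#' @param name scenario name.
#' @param clones_per_group clones per group (default 20).
#' @param seq_error_rate substitution error rate (default 0.001).
#' @param model a [conversion_model()].
#' @return a [donor_config()].
#' @export
make_paper_scenario <- function(name = c("conventional_male",
                                         "hemimethylated_donor",
                                         "xi_female", "null_pair"),
                                clones_per_group = 20L,
                                seq_error_rate = 0.001,
                                model = conversion_model()) {
  name <- match.arg(name)
  amps <- region_pair("TSDR", n_cpg = 15L, seed = 2045L,
                      coding_strand = "bottom")
  k <- n_cpg(amps$top)
  pops <- population_labels()
  const <- function(p) rep(p, k)

  prof <- function(levels_by_pop, strand) {
    out <- list()
    for (pop in names(levels_by_pop)) {
      out[[profile_key(pop, "TSDR", strand)]] <-
        methylation_profile("TSDR", strand, const(levels_by_pop[[pop]]))
    }
    out
  }

  conventional <- list("CD34" = 0.05, "CD45RA+CD15s-" = 0.487,
                       "CD45RA-CD15s-" = 0.007, "CD45RA-CD15s+" = 0.115,
                       "Tcon" = 0.857)
  top_conventional <- list("CD34" = 0.02, "CD45RA+CD15s-" = 0,
                           "CD45RA-CD15s-" = 0.02, "CD45RA-CD15s+" = 0.01,
                           "Tcon" = 0.95)

  switch(name,
    conventional_male = donor_config(
      donor_id = "M1", sex = "M", populations = pops,
      profiles = c(prof(conventional, "top"), prof(conventional, "bottom")),
      amplicons = amps, clones_per_group = clones_per_group,
      seq_error_rate = seq_error_rate, model = model),
    hemimethylated_donor = donor_config(
      donor_id = "M4", sex = "M", populations = pops,
      profiles = c(prof(top_conventional, "top"),
                   prof(as.list(stats::setNames(rep(1, length(pops)), pops)),
                        "bottom")),
      amplicons = amps, clones_per_group = clones_per_group,
      seq_error_rate = seq_error_rate, model = model),
    xi_female = {
      active <- list("CD34" = 0.02, "CD45RA+CD15s-" = 0.02,
                     "CD45RA-CD15s-" = 0.02, "CD45RA-CD15s+" = 0.02,
                     "Tcon" = 0.9)
      donor_config(
        donor_id = "F4", sex = "F", populations = pops,
        profiles = c(prof(active, "top"), prof(active, "bottom")),
        amplicons = amps, clones_per_group = clones_per_group,
        seq_error_rate = seq_error_rate, model = model,
        xi_mosaic = list(
          fraction_inactive = 0.5,
          inactive_profiles = list(
            "TSDR|top" = methylation_profile("TSDR", "top", const(1)),
            "TSDR|bottom" = methylation_profile("TSDR", "bottom", const(1)))))
    },
    null_pair = {
      two <- c("CD45RA-CD15s+", "Tcon")
      null_levels <- as.list(stats::setNames(rep(0.5, 2L), two))
      donor_config(
        donor_id = "M1", sex = "M", populations = two,
        profiles = c(prof(null_levels, "top"), prof(null_levels, "bottom")),
        amplicons = amps, clones_per_group = clones_per_group,
        seq_error_rate = seq_error_rate, model = model)
    })
}

#' Simulate a paired-difference table directly at the percentage level
#'
#' Draws per-(donor, CpG) methylation percentages for two populations as
#' binomial clone counts (`n_clones` molecules per group) and returns their
#' paired differences, the input expected by [mixed_effects_test()] and
#' [permutation_test()]. This samples at the clone-count level, which is
#' exactly the sampling distribution of the sequence-level pipeline under
#' error-free chemistry, and is what makes large calibration studies cheap.
#'
#' @param p_a,p_b per-CpG methylation probabilities for the two populations
#'   (recycled to a common length).
#' @param n_donors number of donors.
#' @param n_clones clones per group.
#' @param seed optional integer seed.
#' @return data frame with columns `donor`, `cpg`, `diff` (percentage
#'   points, population A minus population B).
#' @export
simulate_diff_table <- function(p_a, p_b, n_donors = 6L, n_clones = 20L,
                                seed = NULL) {
  n_cpgs <- max(length(p_a), length(p_b))
  p_a <- rep_len(p_a, n_cpgs)
  p_b <- rep_len(p_b, n_cpgs)
  with_seed(seed, {
    grid <- expand.grid(cpg = seq_len(n_cpgs), donor = seq_len(n_donors))
    pct_a <- 100 * stats::rbinom(nrow(grid), n_clones, p_a[grid$cpg]) / n_clones
    pct_b <- 100 * stats::rbinom(nrow(grid), n_clones, p_b[grid$cpg]) / n_clones
    data.frame(donor = paste0("D", grid$donor), cpg = grid$cpg,
               diff = pct_a - pct_b, stringsAsFactors = FALSE)
  })
}
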