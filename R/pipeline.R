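#' Read and validate a sample sheet
#'
#' The sample sheet maps each clone record to its donor, sex, population,
#' region and assayed strand. Required columns are `clone_id`, `donor`,
#' `sex`, `population`, `region`, `strand`; unknown columns are preserved,
#' missing required columns are fatal.
#'
#' @param x data frame or path to a TSV.
#' @return validated data frame.
#' @export
read_sample_sheet <- function(x) {
  sheet <- if (is.character(x) && length(x) == 1L) {
    utils::read.delim(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  required <- c("clone_id", "donor", "sex", "population", "region", "strand")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sheet$clone_id))
    stop("sample sheet has duplicated clone_id values", call. = FALSE)
  bad <- setdiff(unique(sheet$strand), c("top", "bottom"))
  if (length(bad))
    stop("sample sheet strand values must be 'top' or 'bottom'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sheet
}

#' Run configuration for the end-to-end pipeline
#'
#' @param reference_fasta path to the reference amplicon FASTA (headers
#'   `name|strand=top`), or a pre-built list of [amplicon()]s.
#' @param clone_fasta path to the clone FASTA, or a named sequence vector.
#' @param sample_sheet path to the sample-sheet TSV, or a data frame.
#' @param out_dir output directory.
#' @param qc_threshold conversion-efficiency QC threshold in [0, 1].
#' @param min_identity alignment identity floor in [0, 1].
#' @param primer_k primer mismatch threshold for [validate_primer_pair()].
#' @param family_alpha,n_comparisons Bonferroni family (default 0.05 over
#'   the three Treg-vs-Tcon contrasts).
#' @param reference_population the comparator population (default `"Tcon"`).
#' @param seed integer seed used wherever the pipeline draws random numbers.
#' @return an object of class `run_config`.
#' @export
run_config <- function(reference_fasta, clone_fasta, sample_sheet, out_dir,
                       qc_threshold = 0.95, min_identity = 0.8,
                       primer_k = 2L, family_alpha = 0.05,
                       n_comparisons = 3L,
                       reference_population = "Tcon", seed = 1L) {
  stopifnot(qc_threshold >= 0, qc_threshold <= 1,
            min_identity >= 0, min_identity <= 1,
            primer_k >= 0, family_alpha > 0, family_alpha <= 1,
            n_comparisons >= 1)
  structure(list(reference_fasta = reference_fasta,
                 clone_fasta = clone_fasta, sample_sheet = sample_sheet,
                 out_dir = out_dir, qc_threshold = qc_threshold,
                 min_identity = min_identity, primer_k = primer_k,
                 family_alpha = family_alpha, n_comparisons = n_comparisons,
                 reference_population = reference_population,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[strandmeth] ", fmt), ...))
}

#' Run the full analysis pipeline: call, compare, strand-bias, cluster
#'
#' Chains the stages on one dataset: clone calling with QC, paired
#' mixed-effects comparisons of every non-reference population against the
#' reference population (per region and strand, Bonferroni-corrected as one
#' family per region/strand), strand-bias analysis for every
#' (region, population) assayed on both strands, and complete-linkage
#' clustering of the populations per region/strand. All tabular and JSON
#' outputs are written under `config$out_dir` together with a machine-
#' readable run manifest; given identical `(config, seed)` the outputs are
#' byte-identical across runs.
#'
#' @param config a [run_config()].
#' @return list with `calls` (the [call_clones()] result), `comparisons`
#'   (data frame), `strand_bias` (list of `strand_bias` objects),
#'   `clusters` (list of `cluster_result`s), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  amplicons <- if (is.character(config$reference_fasta))
    read_amplicon_fasta(config$reference_fasta) else config$reference_fasta
  pipeline_log("loaded %d reference amplicon(s)", length(amplicons))

  calls <- call_clones(config$clone_fasta, config$sample_sheet, amplicons,
                       qc_threshold = config$qc_threshold,
                       min_identity = config$min_identity)
  n_total <- nrow(calls$qc)
  n_pass <- sum(calls$qc$qc_pass)
  pipeline_log("called %d clone(s): %d passed QC, %d excluded",
               n_total, n_pass, n_total - n_pass)
  write_calls_tsv(calls$matrices, file.path(config$out_dir, "lollipop.tsv"))
  write_matrix_tsv(calls$matrices, file.path(config$out_dir, "matrix.tsv"))
  write_qc_json(calls$qc, file.path(config$out_dir, "qc.json"))

  alpha <- bonferroni_alpha(config$family_alpha, config$n_comparisons)
  sheet <- read_sample_sheet(config$sample_sheet)
  groups <- unique(sheet[, c("region", "strand")])
  comparisons <- list()
  strand_bias <- list()
  clusters <- list()

  for (i in seq_len(nrow(groups))) {
    region <- groups$region[i]
    strand <- groups$strand[i]
    ms <- Filter(function(m) m$group$region == region &&
                   m$group$strand == strand, calls$matrices)
    pops <- unique(vapply(ms, function(m) m$group$population, character(1)))
    others <- setdiff(pops, config$reference_population)
    if (config$reference_population %in% pops) {
      for (pop in others) {
        dt <- tryCatch(paired_difference_table(ms, pop,
                                               config$reference_population),
                       error = function(e) NULL)
        if (is.null(dt) || length(unique(dt$donor)) < 2L) next
        res <- mixed_effects_test(
          dt, contrast = sprintf("%s/%s: %s - %s", region, strand, pop,
                                 config$reference_population),
          alpha = alpha$raw)
        comparisons[[length(comparisons) + 1L]] <- as.data.frame(res)
      }
    }
    if (length(ms) >= 2L) {
      avg <- average_by_population(calls$matrices, region, strand)
      if (nrow(avg) >= 2L)
        clusters[[paste(region, strand, sep = "|")]] <- cluster_subtypes(avg)
    }
  }

  # strand bias per (region, population) present on both strands
  for (region in unique(groups$region)) {
    pops <- unique(sheet$population[sheet$region == region])
    for (pop in pops) {
      sel <- function(str) Filter(function(m)
        m$group$region == region && m$group$strand == str &&
          m$group$population == pop, calls$matrices)
      mt <- sel("top"); mb <- sel("bottom")
      if (length(mt) && length(mb)) {
        strand_bias[[paste(region, pop, sep = "|")]] <-
          strand_bias_analysis(mt, mb, alpha = alpha$raw)
      }
    }
  }

  comparisons <- if (length(comparisons)) {
    out <- do.call(rbind, comparisons)
    rownames(out) <- NULL
    out
  } else {
    data.frame()
  }
  if (nrow(comparisons))
    utils::write.table(comparisons,
                       file.path(config$out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(strand_bias)) {
    sb <- do.call(rbind, lapply(names(strand_bias), function(k) {
      x <- strand_bias[[k]]
      data.frame(region = x$region, population = x$population,
                 mean_index = mean(x$per_cpg$index),
                 max_index = max(x$per_cpg$index),
                 estimate = x$test$estimate, p_value = x$test$p_value,
                 significant = x$test$significant,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(sb, file.path(config$out_dir, "strand_bias.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (k in names(clusters)) {
    write_newick(clusters[[k]],
                 file.path(config$out_dir,
                           sprintf("cluster_%s.nwk", gsub("[|/]", "_", k))))
    utils::write.table(clusters[[k]]$dist,
                       file.path(config$out_dir,
                                 sprintf("distances_%s.tsv", gsub("[|/]", "_", k))),
                       sep = "\t", quote = FALSE)
  }

  manifest <- list(
    tool = "strandmeth",
    version = as.character(utils::packageVersion("strandmeth")),
    seed = config$seed,
    parameters = list(qc_threshold = config$qc_threshold,
                      min_identity = config$min_identity,
                      primer_k = config$primer_k,
                      family_alpha = config$family_alpha,
                      n_comparisons = config$n_comparisons,
                      alpha_raw = alpha$raw,
                      alpha_reported = alpha$reported,
                      reference_population = config$reference_population),
    inputs = manifest_inputs(config),
    clones = list(total = n_total, passed = n_pass,
                  excluded = n_total - n_pass))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("comparisons: %d; strand-bias analyses: %d; cluster trees: %d",
               nrow(comparisons), length(strand_bias), length(clusters))
  list(calls = calls, comparisons = comparisons, strand_bias = strand_bias,
       clusters = clusters, manifest = manifest)
}

manifest_inputs <- function(config) {
  describe <- function(x, label) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      list(path = x, md5 = unname(tools::md5sum(x)))
    } else {
      list(path = NA, md5 = NA, note = sprintf("%s passed in memory", label))
    }
  }
  list(reference = describe(config$reference_fasta, "reference"),
       clones = describe(config$clone_fasta, "clones"),
       sample_sheet = describe(config$sample_sheet, "sample sheet"))
}
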