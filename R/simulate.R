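#' Per-CpG, per-strand methylation profile of one group
#'
#' @param region region (amplicon) name.
#' @param strand `"top"` or `"bottom"`.
#' @param p_meth per-CpG methylation probabilities in [0, 1].
#' @param correlation_mode `"independent"` draws each CpG independently;
#'   `"clone_level"` draws one latent epiallele per clone from
#'   {all-methylated, all-unmethylated} with P(all-methylated) =
#'   `mean(p_meth)`, reproducing the bimodal clone rows seen in lollipop
#'   diagrams of mixed cell populations.
#' @return an object of class `methylation_profile`.
#' @export
methylation_profile <- function(region, strand = c("top", "bottom"), p_meth,
                                correlation_mode = c("independent", "clone_level")) {
  strand <- match.arg(strand)
  correlation_mode <- match.arg(correlation_mode)
  stopifnot(is.numeric(p_meth), all(p_meth >= 0), all(p_meth <= 1),
            length(p_meth) >= 1L)
  structure(list(region = region, strand = strand, p_meth = as.numeric(p_meth),
                 correlation_mode = correlation_mode),
            class = "methylation_profile")
}

profile_key <- function(population, region, strand) {
  paste(population, region, strand, sep = "|")
}

#' Simulation configuration for one donor
#'
#' Describes a donor's clone library: which populations and regions are
#' assayed, the generating per-CpG per-strand methylation probabilities, the
#' bisulfite chemistry, the Sanger-like substitution error rate, and an
#' optional X-inactivation mosaic for X-linked regions of female donors
#' (each clone derives from one X, so a fraction of clones follows the
#' inactive-X profile).
#'
#' @param donor_id donor label.
#' @param sex `"M"` or `"F"`.
#' @param populations character vector of population labels.
#' @param profiles named list of [methylation_profile()]s keyed
#'   `"population|region|strand"` (see [profile_key()]).
#' @param amplicons named list of [amplicon()]s covering every profiled
#'   region/strand.
#' @param clones_per_group clones simulated per (population, region, strand);
#'   default 20, the per-group clone count the assay design targets.
#' @param seq_error_rate per-base substitution error rate (default 0.001,
#'   Sanger-like).
#' @param model a [conversion_model()].
#' @param xi_mosaic optional list `(fraction_inactive, inactive_profiles)`:
#'   `inactive_profiles` is keyed `"region|strand"` and replaces the active
#'   profile for a clone with probability `fraction_inactive` (applied to
#'   female donors only).
#' @return an object of class `donor_config`.
#' @export
donor_config <- function(donor_id, sex = c("M", "F"), populations, profiles,
                         amplicons, clones_per_group = 20L,
                         seq_error_rate = 0.001,
                         model = conversion_model(), xi_mosaic = NULL) {
  sex <- match.arg(sex)
  stopifnot(clones_per_group >= 1L, seq_error_rate >= 0, seq_error_rate <= 1,
            inherits(model, "conversion_model"))
  if (!is.null(xi_mosaic)) {
    stopifnot(is.list(xi_mosaic),
              xi_mosaic$fraction_inactive >= 0, xi_mosaic$fraction_inactive <= 1,
              is.list(xi_mosaic$inactive_profiles))
  }
  for (p in profiles) {
    amp <- match_amplicon(amplicons, p$region, p$strand)
    if (length(p$p_meth) != n_cpg(amp))
      stop(sprintf("profile for %s/%s has %d probabilities but the amplicon has %d CpGs",
                   p$region, p$strand, length(p$p_meth), n_cpg(amp)),
           call. = FALSE)
  }
  structure(list(donor_id = donor_id, sex = sex, populations = populations,
                 profiles = profiles, amplicons = amplicons,
                 clones_per_group = as.integer(clones_per_group),
                 seq_error_rate = seq_error_rate, model = model,
                 xi_mosaic = xi_mosaic),
            class = "donor_config")
}

#' Simulate one clone: truth and sequence
#'
#' Draws the molecule's per-CpG methylation state from the profile
#' (independent Bernoulli draws, or one epiallele pattern in `clone_level`
#' mode), applies in-silico bisulfite conversion, then sprinkles uniform
#' substitution errors. Draws come from the current RNG stream.
#'
#' @param profile a [methylation_profile()].
#' @param amplicon the matching [amplicon()].
#' @param model a [conversion_model()].
#' @param error_rate per-base substitution error probability.
#' @return list with `true_state` (logical per CpG) and `seq`.
#' @export
simulate_clone <- function(profile, amplicon, model = conversion_model(),
                           error_rate = 0) {
  stopifnot(inherits(profile, "methylation_profile"),
            inherits(amplicon, "amplicon"))
  if (length(profile$p_meth) != n_cpg(amplicon))
    stop(sprintf("profile has %d probabilities but amplicon '%s' has %d CpGs",
                 length(profile$p_meth), amplicon$name, n_cpg(amplicon)),
         call. = FALSE)
  state <- if (profile$correlation_mode == "clone_level") {
    rep(stats::runif(1) < mean(profile$p_meth), n_cpg(amplicon))
  } else {
    stats::runif(n_cpg(amplicon)) < profile$p_meth
  }
  seq <- in_silico_convert(amplicon, state, model)
  if (error_rate > 0) {
    ch <- seq_chars(seq)
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    seq <- paste(ch, collapse = "")
  }
  list(true_state = state, seq = seq)
}

#' Simulate a full clone dataset for one donor
#'
#' Produces `clones_per_group` clone sequences for every
#' (population, region, strand) with a profile, together with the sample
#' sheet and the realized ground truth. Each group draws from its own RNG
#' stream derived by stable hashing of (donor, population, region, strand),
#' so the output is bit-reproducible from `(config, seed)` and independent of
#' group order.
#'
#' @param config a [donor_config()].
#' @param seed integer master seed.
#' @return list of class `bs_dataset`: `sequences` (named character vector),
#'   `sheet` (sample-sheet data frame with columns clone_id, donor, sex,
#'   population, region, strand), `truth` (list with per-group logical state
#'   matrices keyed like the groups, plus `config` and `seed`).
#' @export
simulate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "donor_config"))
  sequences <- character(0)
  sheet <- list()
  states <- list()
  for (pop in config$populations) {
    for (key in names(config$profiles)) {
      prof <- config$profiles[[key]]
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (parts[1] != pop) next
      amp <- match_amplicon(config$amplicons, prof$region, prof$strand)
      use_prof <- prof
      mosaic <- NULL
      if (config$sex == "F" && !is.null(config$xi_mosaic)) {
        mk <- paste(prof$region, prof$strand, sep = "|")
        if (mk %in% names(config$xi_mosaic$inactive_profiles))
          mosaic <- config$xi_mosaic$inactive_profiles[[mk]]
      }
      gkey <- paste(config$donor_id, pop, prof$region, prof$strand, sep = "|")
      child <- derive_seed(seed, gkey)
      grp <- with_seed(child, {
        st <- matrix(NA, nrow = config$clones_per_group,
                     ncol = n_cpg(amp))
        sq <- character(config$clones_per_group)
        for (i in seq_len(config$clones_per_group)) {
          p_i <- use_prof
          if (!is.null(mosaic) &&
              stats::runif(1) < config$xi_mosaic$fraction_inactive) {
            p_i <- mosaic
          }
          cl <- simulate_clone(p_i, amp, config$model, config$seq_error_rate)
          st[i, ] <- cl$true_state
          sq[i] <- cl$seq
        }
        list(states = st, seqs = sq)
      })
      ids <- sprintf("%s_%s_%s_%s_clone%02d", config$donor_id, pop,
                     prof$region, prof$strand,
                     seq_len(config$clones_per_group))
      names(grp$seqs) <- ids
      rownames(grp$states) <- ids
      sequences <- c(sequences, grp$seqs)
      states[[gkey]] <- grp$states
      sheet[[length(sheet) + 1L]] <- data.frame(
        clone_id = ids, donor = config$donor_id, sex = config$sex,
        population = pop, region = prof$region, strand = prof$strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(sheet) == 0L)
    stop("config has no (population, region, strand) group with a profile",
         call. = FALSE)
  structure(list(sequences = sequences,
                 sheet = do.call(rbind, sheet),
                 truth = list(states = states, config = config, seed = seed)),
            class = "bs_dataset")
}

#' Simulate a multi-donor cohort from one donor template
#'
#' Replicates a [donor_config()] across donors (donor-specific RNG streams)
#' and concatenates the datasets.
#'
#' @param config a [donor_config()] used as template.
#' @param donor_ids donor labels.
#' @param sexes optional vector of `"M"`/`"F"` per donor (defaults to the
#'   template's sex).
#' @param seed integer master seed.
#' @return a `bs_dataset` spanning all donors (truth keyed per group).
#' @export
simulate_cohort <- function(config, donor_ids, sexes = NULL, seed = 1L) {
  if (is.null(sexes)) sexes <- rep(config$sex, length(donor_ids))
  stopifnot(length(sexes) == length(donor_ids))
  parts <- Map(function(d, s) {
    cfg <- config
    cfg$donor_id <- d
    cfg$sex <- s
    simulate_dataset(cfg, seed)
  }, donor_ids, sexes)
  structure(list(
    sequences = do.call(c, unname(lapply(parts, `[[`, "sequences"))),
    sheet = do.call(rbind, c(unname(lapply(parts, `[[`, "sheet")),
                             list(make.row.names = FALSE))),
    truth = list(states = do.call(c, unname(lapply(parts, function(p) p$truth$states))),
                 config = config, donor_ids = donor_ids, sexes = sexes,
                 seed = seed)),
    class = "bs_dataset")
}

#' Write a simulated dataset to disk
#'
#' Clone FASTA, sample-sheet TSV, per-group truth TSV (one row per clone,
#' one column per CpG, values 1/0), and the generating configuration as JSON.
#'
#' @param dataset a `bs_dataset` from [simulate_dataset()] or
#'   [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named vector of the paths written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "bs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "clones.fasta")
  seqs <- Biostrings::DNAStringSet(dataset$sequences)
  Biostrings::writeXStringSet(seqs, fasta)
  sheet <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(dataset$sheet, sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- file.path(dir, "truth.tsv")
  tt <- do.call(rbind, lapply(names(dataset$truth$states), function(k) {
    st <- dataset$truth$states[[k]]
    df <- as.data.frame(st * 1L)
    names(df) <- sprintf("CpG_%d", seq_len(ncol(st)))
    cbind(data.frame(clone_id = rownames(st), group = k,
                     stringsAsFactors = FALSE), df)
  }))
  utils::write.table(tt, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  cfgp <- file.path(dir, "config.json")
  cfg <- dataset$truth$config
  jsonlite::write_json(list(
    donor_id = cfg$donor_id, sex = cfg$sex, populations = cfg$populations,
    clones_per_group = cfg$clones_per_group,
    seq_error_rate = cfg$seq_error_rate,
    conversion_rate = cfg$model$conversion_rate,
    protection_rate = cfg$model$protection_rate,
    profiles = lapply(cfg$profiles, function(p)
      list(region = p$region, strand = p$strand, p_meth = p$p_meth,
           correlation_mode = p$correlation_mode)),
    seed = dataset$truth$seed), cfgp, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(c(fasta = fasta, sample_sheet = sheet, truth = truth,
              config = cfgp))
}
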