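#' Call per-CpG methylation states from a clone alignment
#'
#' At each CpG C column of the reference, a read C means the cytosine was
#' protected (methylated), a read T means it was converted (unmethylated);
#' gaps, Ns and any other base are called ambiguous.
#'
#' @param alignment a [align_clone()] result.
#' @param amplicon the [amplicon()] the alignment was made against.
#' @return character vector over `{"methylated", "unmethylated",
#'   "ambiguous"}`, one entry per CpG site.
#' @export
call_cpg_states <- function(alignment, amplicon) {
  stopifnot(inherits(alignment, "clone_alignment"), inherits(amplicon, "amplicon"))
  bases <- read_base_at_ref(alignment)
  b <- bases[amplicon$cpg_positions]
  out <- rep("ambiguous", length(b))
  out[!is.na(b) & b == "C"] <- "methylated"
  out[!is.na(b) & b == "T"] <- "unmethylated"
  out
}

#' Conversion-efficiency QC for one clone
#'
#' Non-CpG cytosines in the reference have no biological methylation in this
#' assay, so after complete bisulfite treatment they must all read T. The
#' efficiency is the fraction of assessable non-CpG reference-C columns
#' (those aligned to a read C or T) that read T.
#'
#' @inheritParams call_cpg_states
#' @return efficiency in [0, 1], or `NA` when no column is assessable.
#' @export
conversion_efficiency <- function(alignment, amplicon) {
  stopifnot(inherits(alignment, "clone_alignment"), inherits(amplicon, "amplicon"))
  bases <- read_base_at_ref(alignment)
  ch <- seq_chars(amplicon$ref_seq)
  idx <- setdiff(which(ch == "C"), amplicon$cpg_positions)
  b <- bases[idx]
  assessable <- !is.na(b) & b %in% c("C", "T")
  if (!any(assessable)) return(NA_real_)
  sum(b[assessable] == "T") / sum(assessable)
}

#' Build a clone profile: align, call, and QC one clone
#'
#' @param clone_seq clone nucleotide string.
#' @param amplicon an [amplicon()].
#' @param clone_id identifier.
#' @param group named list or vector with `donor`, `population`, `region`,
#'   `strand`.
#' @param qc_threshold minimum conversion efficiency to pass QC.
#' @param ... passed to [align_clone()].
#' @return an object of class `clone_profile`: `clone_id`, `group`, `calls`,
#'   `conversion_efficiency`, `qc_pass`, `qc_reason`, `alignment`.
#' @export
clone_profile <- function(clone_seq, amplicon, clone_id, group,
                          qc_threshold = 0.95, ...) {
  aln <- align_clone(clone_seq, amplicon, ...)
  if (!aln$ok) {
    calls <- rep("ambiguous", n_cpg(amplicon))
    eff <- NA_real_
    pass <- FALSE
    reason <- sprintf("unalignable clone (identity %.1f%% below floor)",
                      100 * aln$identity)
  } else {
    calls <- call_cpg_states(aln, amplicon)
    eff <- conversion_efficiency(aln, amplicon)
    if (is.na(eff)) {
      pass <- FALSE
      reason <- "no assessable Cs"
    } else if (eff < qc_threshold) {
      pass <- FALSE
      reason <- sprintf("conversion efficiency %.3f below threshold %.3f",
                        eff, qc_threshold)
    } else {
      pass <- TRUE
      reason <- NA_character_
    }
  }
  structure(list(clone_id = clone_id,
                 group = as.list(group)[c("donor", "population", "region", "strand")],
                 calls = calls,
                 conversion_efficiency = eff,
                 qc_pass = pass,
                 qc_reason = reason,
                 alignment = aln),
            class = "clone_profile")
}

#' @export
print.clone_profile <- function(x, ...) {
  cat(sprintf("<clone_profile> %s [%s]: %d CpGs, %d methylated, eff %s, QC %s\n",
              x$clone_id, paste(unlist(x$group), collapse = "/"),
              length(x$calls), sum(x$calls == "methylated"),
              ifelse(is.na(x$conversion_efficiency), "NA",
                     sprintf("%.3f", x$conversion_efficiency)),
              if (x$qc_pass) "pass" else paste("FAIL:", x$qc_reason)))
  invisible(x)
}

group_key <- function(group) {
  paste(group$donor, group$population, group$region, group$strand, sep = "|")
}

#' Assemble a methylation matrix for one group of clones
#'
#' Drops QC-failing clones and computes, per CpG, the percentage of
#' methylated calls among called (non-ambiguous) clones:
#' `100 * methylated / (methylated + unmethylated)`. Ambiguous calls are
#' excluded from numerator and denominator; per-CpG denominators are
#' recorded so reduced counts stay visible.
#'
#' @param clone_profiles list of [clone_profile()] objects sharing one group
#'   key (donor, population, region, strand).
#' @return an object of class `methylation_matrix`: `group`, `calls`
#'   (clones x CpG matrix of 1/0/NA), `percent` (per-CpG percentages, `NaN`
#'   where no clone was callable), `n_called`, `n_clones`, `clone_ids`.
#' @export
build_matrix <- function(clone_profiles) {
  stopifnot(length(clone_profiles) >= 1L)
  keys <- vapply(clone_profiles, function(p) group_key(p$group), character(1))
  if (length(unique(keys)) != 1L)
    stop("all clone profiles must share one (donor, population, region, strand) group",
         call. = FALSE)
  passing <- Filter(function(p) p$qc_pass, clone_profiles)
  if (length(passing) == 0L)
    stop(sprintf("no QC-passing clones in group %s", keys[1]), call. = FALSE)
  k <- length(passing[[1]]$calls)
  calls <- t(matrix(vapply(passing, function(p) {
    v <- rep(NA_real_, length(p$calls))
    v[p$calls == "methylated"] <- 1
    v[p$calls == "unmethylated"] <- 0
    v
  }, numeric(k)), nrow = k))
  rownames(calls) <- vapply(passing, `[[`, character(1), "clone_id")
  n_meth <- colSums(calls == 1, na.rm = TRUE)
  n_called <- as.integer(colSums(!is.na(calls)))
  structure(list(group = passing[[1]]$group,
                 calls = calls,
                 percent = 100 * n_meth / n_called,
                 n_called = n_called,
                 n_clones = nrow(calls),
                 clone_ids = rownames(calls)),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("<methylation_matrix> %s: %d clones x %d CpGs\n",
              group_key(x$group), x$n_clones, ncol(x$calls)))
  cat(" percent:", paste(sprintf("%.1f", x$percent), collapse = " "), "\n")
  invisible(x)
}

#' Call every clone of a dataset and assemble per-group matrices
#'
#' Runs the full calling stage: every clone in the FASTA is aligned to its
#' region's reference (per the sample sheet), per-CpG states are called,
#' conversion-efficiency QC applied, and QC-passing clones assembled into one
#' methylation matrix per (donor, population, region, strand) group. No clone
#' is silently dropped: each appears in the QC table as called or excluded
#' with a reason.
#'
#' @param clones named character vector of clone sequences, or path to a
#'   clone FASTA.
#' @param sample_sheet data frame (or TSV path) with required columns
#'   `clone_id`, `donor`, `sex`, `population`, `region`, `strand`.
#' @param amplicons named list of [amplicon()] objects; clones of a region
#'   assayed on a given strand are matched by `region` name and `strand`.
#' @param qc_threshold conversion-efficiency QC threshold.
#' @param ... passed to [align_clone()].
#' @return list with `profiles` (all clone profiles), `matrices` (named list
#'   of [build_matrix()] results; groups where every clone failed QC are
#'   reported in `empty_groups` instead), `qc` (per-clone QC data frame),
#'   `empty_groups`.
#' @export
call_clones <- function(clones, sample_sheet, amplicons, qc_threshold = 0.95, ...) {
  if (is.character(clones) && length(clones) == 1L && file.exists(clones)) {
    set <- Biostrings::readDNAStringSet(clones)
    clones <- stats::setNames(as.character(set), names(set))
  }
  sheet <- read_sample_sheet(sample_sheet)
  missing_seq <- setdiff(sheet$clone_id, names(clones))
  if (length(missing_seq))
    stop("sample sheet rows without a clone sequence: ",
         paste(utils::head(missing_seq, 5), collapse = ", "), call. = FALSE)

  profiles <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    amp <- match_amplicon(amplicons, row$region, row$strand)
    profiles[[i]] <- clone_profile(clones[[row$clone_id]], amp,
                                   clone_id = row$clone_id,
                                   group = as.list(row),
                                   qc_threshold = qc_threshold, ...)
  }
  names(profiles) <- sheet$clone_id

  qc <- data.frame(
    clone_id = sheet$clone_id,
    donor = sheet$donor, population = sheet$population,
    region = sheet$region, strand = sheet$strand,
    conversion_efficiency = vapply(profiles, `[[`, numeric(1),
                                   "conversion_efficiency"),
    qc_pass = vapply(profiles, `[[`, logical(1), "qc_pass"),
    reason = vapply(profiles, `[[`, character(1), "qc_reason"),
    stringsAsFactors = FALSE, row.names = NULL)

  keys <- vapply(profiles, function(p) group_key(p$group), character(1))
  matrices <- list()
  empty_groups <- character(0)
  for (k in unique(keys)) {
    grp <- profiles[keys == k]
    if (!any(vapply(grp, `[[`, logical(1), "qc_pass"))) {
      empty_groups <- c(empty_groups, k)
    } else {
      matrices[[k]] <- build_matrix(grp)
    }
  }
  list(profiles = profiles, matrices = matrices, qc = qc,
       empty_groups = empty_groups)
}

match_amplicon <- function(amplicons, region, strand) {
  hit <- Filter(function(a) a$name == region && a$assayed_strand == strand,
                amplicons)
  if (length(hit) == 0L) {
    # fall back on name-only match (single-strand reference sets)
    hit <- Filter(function(a) a$name == region, amplicons)
  }
  if (length(hit) == 0L)
    stop(sprintf("no reference amplicon for region '%s' (strand %s)",
                 region, strand), call. = FALSE)
  hit[[1]]
}

#' Render a methylation matrix as a text lollipop diagram
#'
#' One row per clone, one glyph per CpG: filled circle = methylated, open
#' circle = unmethylated, dot = ambiguous/uncalled, matching the familiar
#' dark/light lollipop convention.
#'
#' @param matrix a [build_matrix()] result.
#' @param glyphs named character vector with entries `meth`, `unmeth`, `na`.
#' @return character vector of rendered rows (named by clone), invisibly
#'   printed with a percent footer when at the console.
#' @export
lollipop_text <- function(matrix,
                          glyphs = c(meth = "●", unmeth = "○", na = "·")) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  rows <- apply(matrix$calls, 1, function(v) {
    paste(ifelse(is.na(v), glyphs[["na"]],
                 ifelse(v == 1, glyphs[["meth"]], glyphs[["unmeth"]])),
          collapse = "")
  })
  names(rows) <- rownames(matrix$calls)
  rows
}

#' Write per-clone call and matrix tables
#'
#' `write_calls_tsv` writes the lollipop table (one row per clone, one column
#' per CpG, values 1/0/NA plus the group columns); `write_matrix_tsv` writes
#' per-CpG percentages and denominators; `write_qc_json` writes the per-clone
#' QC report.
#'
#' @param matrices named list of [build_matrix()] results.
#' @param path output path.
#' @name calling-io
#' @export
write_calls_tsv <- function(matrices, path) {
  tabs <- lapply(matrices, function(m) {
    df <- as.data.frame(m$calls)
    names(df) <- sprintf("CpG_%d", seq_len(ncol(m$calls)))
    cbind(data.frame(clone_id = rownames(m$calls),
                     donor = m$group$donor, population = m$group$population,
                     region = m$group$region, strand = m$group$strand,
                     stringsAsFactors = FALSE),
          df)
  })
  # groups can differ in CpG count; pad with NA columns to the widest
  width <- max(vapply(tabs, ncol, integer(1)))
  tabs <- lapply(tabs, function(df) {
    while (ncol(df) < width) df[[sprintf("CpG_%d", ncol(df) - 4L)]] <- NA
    df
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname calling-io
#' @export
write_matrix_tsv <- function(matrices, path) {
  out <- do.call(rbind, lapply(matrices, function(m) {
    data.frame(donor = m$group$donor, population = m$group$population,
               region = m$group$region, strand = m$group$strand,
               cpg = seq_along(m$percent),
               percent_methylation = m$percent,
               n_called = m$n_called,
               n_clones = m$n_clones,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname calling-io
#' @param qc the per-clone QC data frame from [call_clones()].
#' @export
write_qc_json <- function(qc, path) {
  jsonlite::write_json(qc, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
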