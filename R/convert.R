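#' In-silico bisulfite conversion of one molecule
#'
#' Applies the bisulfite chemistry model to the amplicon's reference
#' sequence given one molecule's per-CpG methylation state: unmethylated Cs
#' (all non-CpG Cs, and CpG Cs whose state is `FALSE`) read as T with
#' probability `conversion_rate`; methylated CpG Cs are preserved as C with
#' probability `protection_rate`. A, G, T and N positions are never touched.
#'
#' @param amplicon an [amplicon()].
#' @param clone_methylation_state logical vector, one entry per CpG site
#'   (`TRUE` = methylated).
#' @param model a [conversion_model()].
#' @param rng_seed optional integer; when given, the conversion is
#'   deterministic and the caller's RNG state is left untouched.
#' @return the converted nucleotide string.
#' @export
in_silico_convert <- function(amplicon, clone_methylation_state,
                              model = conversion_model(), rng_seed = NULL) {
  stopifnot(inherits(amplicon, "amplicon"), inherits(model, "conversion_model"))
  state <- as.logical(clone_methylation_state)
  if (length(state) != n_cpg(amplicon) || anyNA(state))
    stop(sprintf("methylation state must be a complete logical vector of length %d (got %d)",
                 n_cpg(amplicon), length(state)), call. = FALSE)
  with_seed(rng_seed, {
    ch <- seq_chars(amplicon$ref_seq)
    c_pos <- which(ch == "C")
    is_cpg <- c_pos %in% amplicon$cpg_positions
    u <- stats::runif(length(c_pos))
    meth <- logical(length(c_pos))
    meth[is_cpg] <- state[match(c_pos[is_cpg], amplicon$cpg_positions)]
    # unmethylated C -> T at conversion_rate; methylated C stays C at
    # protection_rate (failure of protection also reads T)
    to_t <- ifelse(meth, u > model$protection_rate, u < model$conversion_rate)
    ch[c_pos[to_t]] <- "T"
    paste(ch, collapse = "")
  })
}

# fully-converted template under a methylation assumption: with
# assume_methylated = FALSE every C reads T; with TRUE only non-CpG Cs do
converted_reference <- function(amplicon, assume_methylated = FALSE) {
  ch <- seq_chars(amplicon$ref_seq)
  c_pos <- which(ch == "C")
  if (assume_methylated) c_pos <- setdiff(c_pos, amplicon$cpg_positions)
  ch[c_pos] <- "T"
  paste(ch, collapse = "")
}

# best ungapped placement of `probe` along `template`: minimal Hamming
# distance over all offsets; returns offset (1-based start) and distance
best_placement <- function(probe, template) {
  pc <- seq_chars(probe)
  tc <- seq_chars(template)
  np <- length(pc); nt <- length(tc)
  if (np > nt) return(list(start = NA_integer_, dist = Inf))
  best <- list(start = 1L, dist = Inf)
  for (s in seq_len(nt - np + 1L)) {
    d <- sum(pc != tc[s:(s + np - 1L)])
    if (d < best$dist) best <- list(start = s, dist = d)
  }
  best
}

#' Validate a strand-specific bisulfite primer pair
#'
#' Checks the design rules that make bisulfite PCR unbiased and
#' conversion-specific: (a) no primer footprint may overlap a CpG C, since a
#' primer base there would favour one methylation state; (b) within its
#' footprint a primer must not retain a C where the converted template reads
#' T, otherwise it would amplify unconverted DNA; (c) each primer must differ
#' from the untreated genomic sequence at a minimum number of positions
#' (default `k = 2`) so that only converted DNA is amplified.
#'
#' The forward primer is located on the fully converted unmethylated
#' template, the reverse primer on its reverse complement (the strand
#' synthesized from that template).
#'
#' @param primers a [primer_pair()].
#' @param amplicon an [amplicon()].
#' @param k minimum mismatches against the untreated genomic sequence.
#' @param max_mismatch_frac placements whose best Hamming distance to the
#'   untreated region exceeds this fraction of the primer length are treated
#'   as unlocatable.
#' @return list with `ok` (logical) and `violations`, a data frame with
#'   columns `primer`, `code` (`cpg_overlap`, `retained_c`,
#'   `insufficient_mismatch`) and `detail`.
#' @export
validate_primer_pair <- function(primers, amplicon, k = 2L,
                                 max_mismatch_frac = 0.4) {
  stopifnot(inherits(primers, "primer_pair"), inherits(amplicon, "amplicon"))
  conv <- converted_reference(amplicon, assume_methylated = FALSE)
  genomic <- amplicon$ref_seq

  check_one <- function(label, primer_seq, template_conv, template_genomic,
                        cpg_pos_on_template) {
    # locate on the untreated region (conversion only changes C positions, so
    # the footprint is the same on both templates)
    loc <- best_placement(primer_seq, template_genomic)
    if (!is.finite(loc$dist) || loc$dist > max_mismatch_frac * nchar(primer_seq)) {
      loc2 <- best_placement(primer_seq, template_conv)
      if (!is.finite(loc2$dist) || loc2$dist > max_mismatch_frac * nchar(primer_seq))
        stop(sprintf("%s primer cannot be located on the amplicon", label),
             call. = FALSE)
      loc <- loc2
    }
    fp <- loc$start:(loc$start + nchar(primer_seq) - 1L)
    pc <- seq_chars(primer_seq)
    gc <- seq_chars(template_genomic)[fp]
    cc <- seq_chars(template_conv)[fp]
    v <- list()
    hit <- intersect(fp, cpg_pos_on_template)
    if (length(hit))
      v[[length(v) + 1L]] <- data.frame(
        primer = label, code = "cpg_overlap",
        detail = sprintf("footprint overlaps methylation-sensitive CpG position(s) %s",
                         paste(hit, collapse = ",")))
    # a primer base matching the unconverted template at a position the
    # conversion changes (C->T in the forward frame, G->A in the reverse
    # frame) would preferentially amplify unconverted DNA
    retained <- which(pc == gc & gc != cc)
    if (length(retained))
      v[[length(v) + 1L]] <- data.frame(
        primer = label, code = "retained_c",
        detail = sprintf("primer keeps the unconverted base at footprint offset(s) %s where the converted template differs",
                         paste(retained, collapse = ",")))
    mm <- sum(pc != gc)
    if (mm < k)
      v[[length(v) + 1L]] <- data.frame(
        primer = label, code = "insufficient_mismatch",
        detail = sprintf("only %d mismatch(es) to the untreated genomic sequence (need >= %d)",
                         mm, k))
    v
  }

  # The reverse primer anneals to the converted target strand, so its
  # sequence matches the reverse complement of the converted template; in
  # that frame the methylation-sensitive positions are the mirrors of the
  # assayed-strand CpG Cs (their complementary base reads G when methylated,
  # A when converted).
  n <- nchar(genomic)
  v <- c(check_one("forward", primers$forward_seq, conv, genomic,
                   amplicon$cpg_positions),
         check_one("reverse", primers$reverse_seq,
                   reverse_complement(conv), reverse_complement(genomic),
                   n - amplicon$cpg_positions + 1L))
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(primer = character(0), code = character(0), detail = character(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}
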