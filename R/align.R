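#' Align a clone sequence to its reference amplicon
#'
#' Global alignment with affine gaps against the untreated reference, scored
#' with a bisulfite-aware asymmetric substitution rule: a reference C accepts
#' either C or T in the read as a match (the expected conversion at non-CpG
#' Cs; the state-informative alternative at CpG Cs), all other mismatches are
#' penalized. Both the clone and its reverse complement are aligned and the
#' better-scoring orientation kept, since cloned inserts can be recovered in
#' either direction.
#'
#' The `model_assumption` chooses which fully converted template is rendered
#' alongside the alignment for inspection (`"unmeth_ref"`: every C reads T;
#' `"meth_ref"`: CpG Cs preserved). It does not change the scoring, which
#' treats CpG columns as uninformative for alignment by construction.
#'
#' @param clone_seq clone nucleotide string.
#' @param amplicon an [amplicon()].
#' @param model_assumption `"unmeth_ref"` or `"meth_ref"` (display template).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; a gap of
#'   length L costs `gap_open + (L - 1) * gap_extend`.
#' @param min_identity identity floor in [0, 1]; alignments below it are
#'   flagged unalignable (`ok = FALSE`) and excluded downstream.
#' @return an object of class `clone_alignment`: `score`, `ref_aln`,
#'   `read_aln` (gapped strings), `orientation` (`"forward"`/`"reverse"`),
#'   `identity` (matched columns / alignment columns under the asymmetric
#'   rule), `ok`, `template` (the rendered converted reference).
#' @export
align_clone <- function(clone_seq, amplicon,
                        model_assumption = c("unmeth_ref", "meth_ref"),
                        match = 2, mismatch = -3, gap_open = -5,
                        gap_extend = -2, min_identity = 0.8) {
  model_assumption <- match.arg(model_assumption)
  stopifnot(inherits(amplicon, "amplicon"))
  clone_seq <- check_nucleotides(clone_seq, "clone_seq")
  if (nchar(clone_seq) == 0L) stop("clone_seq must be non-empty", call. = FALSE)

  ref <- amplicon$ref_seq
  fwd <- .cpp_align_affine(ref, clone_seq, match, mismatch, gap_open, gap_extend)
  rev <- .cpp_align_affine(ref, reverse_complement(clone_seq),
                           match, mismatch, gap_open, gap_extend)
  orientation <- if (rev$score > fwd$score) "reverse" else "forward"
  aln <- if (orientation == "reverse") rev else fwd

  rc <- seq_chars(aln$ref_aln)
  qc <- seq_chars(aln$read_aln)
  matched <- sum(ifelse(rc == "C", qc %in% c("C", "T"),
                        rc != "-" & qc != "-" & rc == qc & rc != "N"))
  identity <- matched / length(rc)

  structure(list(score = aln$score,
                 ref_aln = aln$ref_aln,
                 read_aln = aln$read_aln,
                 orientation = orientation,
                 identity = identity,
                 ok = identity >= min_identity,
                 template = converted_reference(
                   amplicon, assume_methylated = model_assumption == "meth_ref"),
                 amplicon_name = amplicon$name),
            class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat(sprintf("<clone_alignment> vs %s: score %.1f, identity %.1f%% (%s orientation)%s\n",
              x$amplicon_name, x$score, 100 * x$identity, x$orientation,
              if (x$ok) "" else " [below identity floor]"))
  invisible(x)
}

# read bases occupying each reference position (NA where the read has a gap);
# positions are 1-based on the ungapped reference
read_base_at_ref <- function(alignment) {
  rc <- seq_chars(alignment$ref_aln)
  qc <- seq_chars(alignment$read_aln)
  keep <- rc != "-"
  out <- qc[keep]
  out[out == "-"] <- NA_character_
  out
}
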