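#' Discover CpG sites in a nucleotide sequence
#'
#' Scans a sequence (written 5'->3' on the assayed strand) for CG
#' dinucleotides and returns the 1-based position of the C of each site.
#' `N` never forms part of a CpG.
#'
#' @param ref_seq nucleotide string over A, C, G, T, N (case-insensitive).
#' @return integer vector of 1-based C positions, strictly increasing.
#' @examples
#' discover_cpg_sites("ACGTCGA")  # 2, 5
#' @export
discover_cpg_sites <- function(ref_seq) {
  ref_seq <- check_nucleotides(ref_seq, "ref_seq")
  ch <- seq_chars(ref_seq)
  n <- length(ch)
  if (n < 2L) return(integer(0))
  which(ch[-n] == "C" & ch[-1L] == "G")
}

#' Reverse complement of a nucleotide sequence
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param seq nucleotide string over A, C, G, T, N.
#' @return the reverse-complemented string, uppercase.
#' @export
reverse_complement <- function(seq) {
  seq <- check_nucleotides(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(seq_chars(comp)), collapse = "")
}

#' Primer pair for a strand-specific bisulfite PCR
#'
#' Bisulfite treatment leaves the two strands non-complementary, so each
#' primer set amplifies exactly one strand of the converted DNA; the reverse
#' primer binds the chosen target strand.
#'
#' @param forward_seq,reverse_seq primer sequences, 5'->3'.
#' @param target_strand `"top"` or `"bottom"`: the genomic strand the pair
#'   amplifies after conversion.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(forward_seq, reverse_seq, target_strand = c("top", "bottom")) {
  target_strand <- match.arg(target_strand)
  forward_seq <- check_nucleotides(forward_seq, "forward primer")
  reverse_seq <- check_nucleotides(reverse_seq, "reverse primer")
  if (nchar(forward_seq) == 0L || nchar(reverse_seq) == 0L)
    stop("primer sequences must be non-empty", call. = FALSE)
  structure(list(forward_seq = forward_seq, reverse_seq = reverse_seq,
                 target_strand = target_strand),
            class = "primer_pair")
}

#' Bisulfite conversion model
#'
#' Two probabilities describe the chemistry: `conversion_rate` is the chance
#' an unmethylated C reads as T after treatment; `protection_rate` is the
#' chance a methylated C is preserved as C. Commercial kits specify both at
#' 0.995 or better, which is the default.
#'
#' @param conversion_rate,protection_rate probabilities in [0, 1].
#' @return an object of class `conversion_model`.
#' @export
conversion_model <- function(conversion_rate = 0.995, protection_rate = 0.995) {
  stopifnot(is.numeric(conversion_rate), length(conversion_rate) == 1L,
            conversion_rate >= 0, conversion_rate <= 1,
            is.numeric(protection_rate), length(protection_rate) == 1L,
            protection_rate >= 0, protection_rate <= 1)
  structure(list(conversion_rate = conversion_rate,
                 protection_rate = protection_rate),
            class = "conversion_model")
}

#' Reference amplicon for a bisulfite assay
#'
#' Holds the untreated genomic sequence of one assayed region, written 5'->3'
#' on the assayed strand. Bottom-strand assays are represented by
#' reverse-complementing the genomic top-strand sequence once at load; all
#' downstream logic is then strand-agnostic. CpG sites are discovered
#' automatically and numbered 1..n in assayed-strand 5'->3' order, the
#' ordering used for per-CpG reporting.
#'
#' @param name region identifier.
#' @param ref_seq untreated nucleotide sequence on the assayed strand.
#' @param assayed_strand `"top"` or `"bottom"`, relative to the genome
#'   reference.
#' @param gene_strand_label optional annotation, `"coding"` or `"template"`
#'   (e.g. FOXP3's coding strand is the genomic bottom strand).
#' @param primers optional [primer_pair()].
#' @return an object of class `amplicon` with elements `name`, `ref_seq`,
#'   `assayed_strand`, `gene_strand_label`, `cpg_positions` (1-based positions
#'   of the C of each CpG), `primers`.
#' @export
amplicon <- function(name, ref_seq, assayed_strand = c("top", "bottom"),
                     gene_strand_label = NULL, primers = NULL) {
  assayed_strand <- match.arg(assayed_strand)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ref_seq <- check_nucleotides(ref_seq, "ref_seq")
  if (!is.null(gene_strand_label))
    gene_strand_label <- match.arg(gene_strand_label, c("coding", "template"))
  if (!is.null(primers) && !inherits(primers, "primer_pair"))
    stop("primers must be a primer_pair", call. = FALSE)
  obj <- structure(list(name = name, ref_seq = ref_seq,
                        assayed_strand = assayed_strand,
                        gene_strand_label = gene_strand_label,
                        cpg_positions = discover_cpg_sites(ref_seq),
                        primers = primers),
                   class = "amplicon")
  validate_amplicon(obj)
}

validate_amplicon <- function(x) {
  ch <- seq_chars(x$ref_seq)
  p <- x$cpg_positions
  if (length(p)) {
    stopifnot(all(ch[p] == "C"), all(ch[p + 1L] == "G"),
              all(diff(p) > 0L))
  }
  x
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s: %d nt on %s strand, %d CpG site(s)\n",
              x$name, nchar(x$ref_seq), x$assayed_strand,
              length(x$cpg_positions)))
  invisible(x)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> fwd %dnt / rev %dnt, target strand %s\n",
              nchar(x$forward_seq), nchar(x$reverse_seq), x$target_strand))
  invisible(x)
}

n_cpg <- function(amplicon) length(amplicon$cpg_positions)

#' Read reference amplicons from FASTA
#'
#' Headers carry the region name and assayed strand as `name|strand=top`
#' (or `strand=bottom`). A bare header defaults to the top strand.
#'
#' @param path FASTA file of untreated reference sequences.
#' @return named list of [amplicon()] objects.
#' @export
read_amplicon_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    fields <- strsplit(header, "|", fixed = TRUE)[[1]]
    name <- trimws(fields[1])
    strand <- "top"
    for (f in fields[-1]) {
      kv <- strsplit(trimws(f), "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L && kv[1] == "strand") strand <- kv[2]
    }
    amplicon(name, as.character(set[[i]]), assayed_strand = strand)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write reference amplicons to FASTA
#'
#' @param amplicons list of [amplicon()] objects.
#' @param path output path.
#' @export
write_amplicon_fasta <- function(amplicons, path) {
  seqs <- Biostrings::DNAStringSet(vapply(amplicons, `[[`, character(1), "ref_seq"))
  names(seqs) <- vapply(amplicons, function(a)
    sprintf("%s|strand=%s", a$name, a$assayed_strand), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Export CpG sites as BED
#'
#' One single-base feature per CpG C, in 0-based half-open BED coordinates on
#' the assayed strand; the name column carries the CpG ordinal.
#'
#' @param amplicon an [amplicon()].
#' @param path output path.
#' @return the BED table, invisibly.
#' @export
write_cpg_bed <- function(amplicon, path) {
  p <- amplicon$cpg_positions
  bed <- data.frame(chrom = amplicon$name,
                    start = p - 1L,
                    end = p,
                    name = sprintf("CpG_%d", seq_along(p)),
                    score = 0L,
                    strand = if (amplicon$assayed_strand == "top") "+" else "-")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
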