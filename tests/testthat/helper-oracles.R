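# Independent oracles and small fixture builders used across the suite.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate a sequence with substitutions and indels (for alignment test pairs)
mutate_seq <- function(seq, n_sub = 2L, n_ins = 0L, n_del = 0L) {
  ch <- strsplit(seq, "")[[1]]
  for (i in sample(length(ch), min(n_sub, length(ch)))) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  for (k in seq_len(n_del)) {
    if (length(ch) > 2) ch <- ch[-sample(length(ch), 1)]
  }
  for (k in seq_len(n_ins)) {
    pos <- sample(length(ch), 1)
    ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = pos)
  }
  paste(ch, collapse = "")
}

# Quadratic-time Gotoh DP, score only, written independently of the C++
# implementation (matrix form, whole-row initialisation, max() recurrences).
# Same stated convention: gap of length L costs open + (L-1)*ext; a reference
# C matches read C or T; N matches nothing.
oracle_align_score <- function(ref, read, match = 2, mismatch = -3,
                               gap_open = -5, gap_ext = -2) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(read, "")[[1]]
  n <- length(r); m <- length(q)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) X[2:(n + 1), 1] <- gap_open + (0:(n - 1)) * gap_ext
  if (m >= 1) Y[1, 2:(m + 1)] <- gap_open + (0:(m - 1)) * gap_ext
  sub_score <- function(a, b) {
    if (a == "N" || b == "N") return(mismatch)
    if (a == "C") return(if (b %in% c("C", "T")) match else mismatch)
    if (a == b) match else mismatch
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub_score(r[i - 1], q[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_ext,
                     Y[i - 1, j] + gap_open)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_ext,
                     X[i, j - 1] + gap_open)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force complete-linkage agglomeration from a distance matrix:
# repeatedly merge the pair of clusters with the smallest maximum cross
# distance. Returns merge heights and the partition after each merge
# (canonicalised as sorted strings).
oracle_complete_linkage <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- numeric(0)
  partitions <- list()
  canon <- function(cl) paste(sort(vapply(cl, function(g)
    paste(sort(g), collapse = ","), character(1))), collapse = ";")
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1]] <- canon(clusters)
  }
  list(heights = heights, partitions = partitions)
}

partitions_from_hclust <- function(hc, labs) {
  n <- length(labs)
  out <- list()
  for (s in seq_len(n - 1)) {
    ct <- stats::cutree(hc, k = n - s)
    groups <- split(labs, ct[labs])
    out[[s]] <- paste(sort(vapply(groups, function(g)
      paste(sort(g), collapse = ","), character(1))), collapse = ";")
  }
  out
}

# Exhaustive donor-level sign-flip p-value, bit-mask enumeration (independent
# of the package's expand.grid route).
oracle_sign_flip_p <- function(diff_table) {
  donors <- unique(diff_table$donor)
  D <- length(donors)
  t_obs <- mean(diff_table$diff)
  hits <- 0L
  for (mask in 0:(2^D - 1)) {
    bits <- as.integer(intToBits(mask))[1:D]
    flipped <- diff_table$diff
    for (k in seq_len(D)) {
      if (bits[k] == 1L) {
        sel <- diff_table$donor == donors[k]
        flipped[sel] <- -flipped[sel]
      }
    }
    if (abs(mean(flipped)) >= abs(t_obs) - 1e-9 * (1 + abs(t_obs)))
      hits <- hits + 1L
  }
  hits / 2^D
}

# Fabricate a methylation_matrix with given per-CpG percentages, for
# arithmetic-level tests of the statistics layer.
fake_matrix <- function(percent, donor = "D1", population = "P",
                        region = "R", strand = "top", n_clones = 20L) {
  structure(list(group = list(donor = donor, population = population,
                              region = region, strand = strand),
                 calls = matrix(NA_real_, nrow = n_clones,
                                ncol = length(percent)),
                 percent = as.numeric(percent),
                 n_called = rep(n_clones, length(percent)),
                 n_clones = n_clones,
                 clone_ids = sprintf("%s_c%02d", donor, seq_len(n_clones))),
            class = "methylation_matrix")
}

# Simulate clones with exactly the given truth states (rates 1/1, no errors)
clones_from_states <- function(amp, states) {
  vapply(seq_len(nrow(states)), function(i)
    in_silico_convert(amp, states[i, ], conversion_model(1, 1)),
    character(1))
}

# small fixed test amplicon: 2 CpGs, several non-CpG Cs
test_amplicon <- function() {
  amplicon("toy", "AACCATTACGATTACCATTACGATTACCAA", "top")
}

# bindings to package internals exercised against oracles
align_score <- function(ref, read) {
  strandmeth:::.cpp_align_affine(ref, read, 2, -3, -5, -2)$score
}
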