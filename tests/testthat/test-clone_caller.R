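test_that("error-free clones align gaplessly and calls recover the truth exactly", {
  amp <- synthetic_region("R", n_cpg = 6, seed = 4)
  set.seed(21)
  states <- matrix(stats::runif(120) < 0.5, nrow = 20)
  seqs <- clones_from_states(amp, states)
  for (i in 1:20) {
    aln <- align_clone(seqs[i], amp)
    expect_false(grepl("-", aln$ref_aln, fixed = TRUE))
    expect_false(grepl("-", aln$read_aln, fixed = TRUE))
    expect_identical(aln$orientation, "forward")
    expect_true(aln$ok)
    calls <- call_cpg_states(aln, amp)
    expect_identical(calls == "methylated", states[i, ])
    expect_equal(conversion_efficiency(aln, amp), 1.0)
  }
})

test_that("a single inserted base produces exactly one reference gap and intact calls", {
  amp <- synthetic_region("R", n_cpg = 6, seed = 4)
  set.seed(22)
  state <- stats::runif(6) < 0.5
  seq0 <- in_silico_convert(amp, state, conversion_model(1, 1))
  # insert one base away from any CpG
  pos <- 10L
  seq1 <- paste0(substr(seq0, 1, pos), "A", substr(seq0, pos + 1, nchar(seq0)))
  aln <- align_clone(seq1, amp)
  gaps_ref <- lengths(regmatches(aln$ref_aln, gregexpr("-", aln$ref_aln)))
  expect_identical(gaps_ref, 1L)
  expect_false(grepl("-", aln$read_aln, fixed = TRUE))
  expect_identical(call_cpg_states(aln, amp) == "methylated", state)
})

test_that("orientation auto-detection recovers reverse-complemented clones", {
  amp <- synthetic_region("R", n_cpg = 6, seed = 4)
  set.seed(23)
  state <- stats::runif(6) < 0.5
  seq0 <- in_silico_convert(amp, state, conversion_model(1, 1))
  fwd <- align_clone(seq0, amp)
  rev <- align_clone(reverse_complement(seq0), amp)
  expect_identical(rev$orientation, "reverse")
  expect_identical(rev$score, fwd$score)
  expect_identical(call_cpg_states(rev, amp), call_cpg_states(fwd, amp))
})

test_that("alignment scores match the quadratic-time DP oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(20:120, 1)
    ref <- rand_seq(n)
    read <- if (i %% 4 == 0) rand_seq(sample(20:120, 1)) else
      mutate_seq(ref, n_sub = sample(0:4, 1), n_ins = sample(0:2, 1),
                 n_del = sample(0:2, 1))
    got <- align_score(ref, read)
    expect_equal(got, oracle_align_score(ref, read))
  }
})

test_that("CpG state calling maps C/T/other to methylated/unmethylated/ambiguous", {
  amp <- amplicon("m", "AATTACGATTACCTTAA", "top")  # CpG C at 6
  conv_meth <- "AATTACGATTATTTTAA"    # CpG retained, other Cs converted
  conv_unmeth <- "AATTATGATTATTTTAA"
  expect_identical(call_cpg_states(align_clone(conv_meth, amp), amp), "methylated")
  expect_identical(call_cpg_states(align_clone(conv_unmeth, amp), amp), "unmethylated")
  # deletion spanning the CpG -> ambiguous
  del <- paste0(substr(conv_meth, 1, 4), substr(conv_meth, 9, nchar(conv_meth)))
  expect_identical(call_cpg_states(align_clone(del, amp), amp), "ambiguous")
})

test_that("conversion efficiency is the converted fraction of non-CpG Cs", {
  amp <- test_amplicon()  # non-CpG Cs at 3,4,15,16,27,28
  # convert 5 of the 6 non-CpG Cs, keep CpGs methylated
  ch <- strsplit(amp$ref_seq, "")[[1]]
  ch[c(3, 4, 15, 16, 27)] <- "T"
  aln <- align_clone(paste(ch, collapse = ""), amp)
  expect_equal(conversion_efficiency(aln, amp), 5 / 6)
  # fully converted -> 1.0
  full <- in_silico_convert(amp, c(TRUE, TRUE), conversion_model(1, 1))
  expect_equal(conversion_efficiency(align_clone(full, amp), amp), 1.0)
})

test_that("QC passes at the threshold and fails below it with recorded reasons", {
  amp <- synthetic_region("Q", n_cpg = 3, seed = 6)
  grp <- list(donor = "D1", population = "P", region = "Q", strand = "top")
  good <- in_silico_convert(amp, rep(TRUE, 3), conversion_model(1, 1))
  p_good <- clone_profile(good, amp, "c1", grp)
  expect_true(p_good$qc_pass)
  expect_equal(p_good$conversion_efficiency, 1.0)
  # an untreated molecule retains every C: efficiency 0 -> QC failure
  p_raw <- clone_profile(amp$ref_seq, amp, "c2", grp)
  expect_false(p_raw$qc_pass)
  expect_match(p_raw$qc_reason, "conversion efficiency")
  # unalignable garbage is excluded with its own reason
  p_bad <- clone_profile(rand_seq(40), amp, "c3", grp)
  expect_false(p_bad$qc_pass)
  expect_match(p_bad$qc_reason, "unalignable")
  # calls partition into the three states for every clone
  for (p in list(p_good, p_raw, p_bad)) {
    expect_length(p$calls, 3L)
    expect_true(all(p$calls %in% c("methylated", "unmethylated", "ambiguous")))
  }
})

test_that("percentages follow the m/(m+u) rule with ambiguous calls excluded", {
  amp <- amplicon("pct", "AATTACGATTACCTTACGTTACCATTAA", "top")  # CpGs at 6, 17
  grp <- list(donor = "D1", population = "P", region = "pct", strand = "top")
  # 20 clones: exactly 2 methylated at every CpG
  states <- matrix(FALSE, nrow = 20, ncol = 2)
  states[1:2, ] <- TRUE
  seqs <- clones_from_states(amp, states)
  profs <- lapply(1:20, function(i)
    clone_profile(seqs[i], amp, sprintf("c%02d", i), grp))
  m <- build_matrix(profs)
  expect_equal(unname(m$percent), c(10, 10))  # 2 of 20 = 10%
  expect_identical(unname(m$n_called), c(20L, 20L))

  # make CpG 2 ambiguous in 2 clones by deleting around it; of the remaining
  # 18 calls let 9 be methylated -> 9/18 = 50%
  states2 <- matrix(FALSE, nrow = 20, ncol = 2)
  states2[1:9, 2] <- TRUE
  seqs2 <- clones_from_states(amp, states2)
  for (i in 19:20) {
    seqs2[i] <- paste0(substr(seqs2[i], 1, 14), substr(seqs2[i], 20, nchar(seqs2[i])))
  }
  profs2 <- lapply(1:20, function(i)
    clone_profile(seqs2[i], amp, sprintf("c%02d", i), grp))
  m2 <- build_matrix(profs2)
  expect_identical(unname(m2$n_called[2]), 18L)
  expect_equal(unname(m2$percent[2]), 50)

  # degenerate group: every clone failing QC is an error naming the group
  raw <- lapply(1:3, function(i)
    clone_profile(amp$ref_seq, amp, sprintf("r%d", i), grp))
  expect_error(build_matrix(raw), "D1|P|pct|top", fixed = TRUE)
})

test_that("per-CpG call accuracy stays above 0.98 at a 1% substitution error rate", {
  amp <- synthetic_region("E", n_cpg = 5, seed = 12)
  prof <- methylation_profile("E", "top", rep(0.5, 5))
  set.seed(41)
  n <- 1000
  correct <- 0L
  total <- 0L
  for (i in seq_len(n)) {
    cl <- simulate_clone(prof, amp, conversion_model(1, 1), error_rate = 0.01)
    calls <- call_cpg_states(align_clone(cl$seq, amp), amp)
    correct <- correct + sum((calls == "methylated") == cl$true_state &
                               calls != "ambiguous")
    total <- total + length(calls)
  }
  expect_gte(correct / total, 0.98)
})

test_that("call_clones conserves every input clone and builds per-group matrices", {
  cfg <- make_paper_scenario("null_pair", clones_per_group = 6,
                             seq_error_rate = 0, model = conversion_model(1, 1))
  ds <- simulate_dataset(cfg, seed = 55)
  res <- call_clones(ds$sequences, ds$sheet, cfg$amplicons)
  expect_identical(nrow(res$qc), length(ds$sequences))
  expect_setequal(res$qc$clone_id, names(ds$sequences))
  n_in_matrices <- sum(vapply(res$matrices, function(m) m$n_clones, integer(1)))
  n_excluded <- sum(!res$qc$qc_pass)
  expect_identical(n_in_matrices + n_excluded, length(ds$sequences))
  # error-free chemistry: calls equal simulation truth for every clone
  for (k in names(res$matrices)) {
    st <- ds$truth$states[[k]]
    calls <- res$matrices[[k]]$calls[rownames(st), ]
    expect_identical(calls == 1, st)
  }
  # lollipop rendering covers every clone with one glyph per CpG
  lp <- lollipop_text(res$matrices[[1]], glyphs = c(meth = "M", unmeth = "o", na = "."))
  expect_length(lp, res$matrices[[1]]$n_clones)
  expect_true(all(nchar(lp) == ncol(res$matrices[[1]]$calls)))
})
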