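test_that("exact matching finds planted occurrences on both strands", {
  set.seed(3)
  mature <- random_rna(1, 21)
  contig <- paste0(random_rna(1, 40), mature, random_rna(1, 139))
  hits <- find_exact_matches(mature, c(c1 = contig))
  expect_identical(hits$start, 40L)
  expect_identical(hits$end, 61L)
  expect_identical(hits$strand, "+")

  contig_rc <- paste0(random_rna(1, 10), revcomp_rna(mature),
                      random_rna(1, 30))
  hits_rc <- find_exact_matches(mature, c(c2 = contig_rc))
  expect_identical(hits_rc$start, 10L)
  expect_identical(hits_rc$strand, "-")

  # two plants -> two hits, confirmed by a brute-force substring scan
  contig2 <- paste0(random_rna(1, 15), mature, random_rna(1, 30), mature,
                    random_rna(1, 20))
  hits2 <- find_exact_matches(mature, c(c3 = contig2))
  brute <- which(vapply(1:(nchar(contig2) - 20), function(i)
    substr(contig2, i, i + 20) == mature, logical(1))) - 1L
  expect_identical(hits2$start[hits2$strand == "+"], brute)
})

test_that("matching is strand symmetric", {
  set.seed(4)
  mature <- random_rna(1, 21)
  contig <- paste0(random_rna(1, 33), mature, random_rna(1, 66))
  n <- nchar(contig)
  fwd <- find_exact_matches(mature, c(x = contig))
  rev <- find_exact_matches(mature, c(x = revcomp_rna(contig)))
  expect_identical(rev$strand, "-")
  expect_identical(rev$start, n - fwd$end)
  expect_identical(rev$end, n - fwd$start)
})

test_that("maximum-pairing fold solves canonical examples", {
  f <- fold_window("GGGAAACCC")
  expect_identical(f$pairs$i, 1:3)
  expect_identical(f$pairs$j, 9:7)
  expect_identical(unique(f$pairs$type), "WC")
  expect_equal(f$weight, 3)
  expect_identical(dot_bracket(f), "(((...)))")

  expect_identical(nrow(fold_window("AAAAAA")$pairs), 0L)
  expect_error(fold_window(strrep("A", 500)), "max_window")
})

test_that("fold weight matches the exhaustive oracle and is well formed", {
  for (s in 1:12) {
    set.seed(s)
    w <- random_rna(1, sample(20:60, 1))
    f <- fold_window(w)
    expect_equal(f$weight, oracle_fold_weight(w), info = paste("seed", s))
    expect_true(isTRUE(oracle_fold_valid(f)), info = paste("seed", s))
  }
  # a longer window, weight against the oracle
  set.seed(3)
  w <- random_rna(1, 120)
  expect_equal(fold_window(w)$weight, oracle_fold_weight(w))
})

test_that("thermodynamic backend honours the fold_result contract", {
  pre <- make_precursor_contig(MIR408, stem_mismatches = 0, seed = 2)
  f <- fold_window_thermo(pre$contig)
  expect_s3_class(f, "fold_result")
  expect_true(isTRUE(oracle_fold_valid(f)))
  # its pairs are all legitimate WC or GU oppositions
  b <- strsplit(f$sequence, "")[[1]]
  states <- classify_pair(b[f$pairs$i], b[f$pairs$j])
  expect_true(all(states != "mismatch"))
})

test_that("a perfect planted hairpin is accepted with its star", {
  pre <- make_precursor_contig(MIR408, stem_mismatches = 0, loop_length = 6,
                               seed = 11)
  cand <- find_precursors(MIR408, c(ctg = pre$contig))[[1]]
  expect_identical(cand$verdict, "accepted")
  expect_identical(cand$arm, "5p")
  expect_identical(cand$predicted_star, pre$star)
  expect_equal(cand$mature_paired_fraction, 1)
})

test_that("mismatched planted hairpins are accepted and stars recovered", {
  for (mm in c(2, 4)) {
    pre <- make_precursor_contig(MIR408, stem_mismatches = mm, seed = 11)
    cand <- find_precursors(MIR408, c(ctg = pre$contig))[[1]]
    expect_identical(cand$verdict, "accepted", info = paste("mm", mm))
    expect_identical(cand$predicted_star, pre$star, info = paste("mm", mm))
    # every stem partner lies within the predicted star span
    partner <- rep(NA_integer_, nchar(cand$window))
    partner[cand$fold$pairs$i] <- cand$fold$pairs$j
    partner[cand$fold$pairs$j] <- cand$fold$pairs$i
    p <- partner[cand$mature_start:(cand$mature_end - 2)]
    p <- p[!is.na(p) & p > cand$mature_end]
    expect_true(all(p >= cand$star_start & p <= cand$star_end),
                info = paste("mm", mm))
  }
})

test_that("a mature spanning the terminal loop is rejected", {
  # two short inverted arms with the mature across the apex
  left <- substr(MIR408, 1, 10)
  right <- substr(MIR408, 12, 21)
  contig <- paste0(random_rna(1, 60), revcomp_rna(right), "AAA",
                   MIR408, "AAA", revcomp_rna(left), random_rna(1, 60))
  hits <- find_exact_matches(MIR408, c(ctg = contig))
  ws <- max(0, hits$start[1] - 150); we <- min(nchar(contig), hits$end[1] + 150)
  cand <- evaluate_hairpin(substr(contig, ws + 1, we),
                           hits$start[1] - ws + 1, hits$end[1] - ws)
  expect_identical(cand$verdict, "rejected")
})

test_that("loop-length and mismatch-count limits are enforced", {
  expect_error(make_precursor_contig(MIR408, loop_length = 2), "loop_length")
  expect_error(make_precursor_contig(MIR408, stem_mismatches = 16),
               "defeat")
})

test_that("a mature in plain random flanks is rejected in >= 95 of 100 draws", {
  set.seed(12)
  verdicts <- vapply(1:100, function(i) {
    contig <- flank_control_contig(MIR408)
    find_precursors(MIR408, c(sh = contig))[[1]]$verdict
  }, character(1))
  expect_gte(sum(verdicts == "rejected"), 95)
})

test_that("contigs without any exact match yield an empty candidate list", {
  set.seed(6)
  out <- find_precursors(MIR408, setNames(random_rna(3, 200), paste0("c", 1:3)))
  expect_length(out, 0)
  expect_identical(nrow(precursor_table(out)), 0L)
})

test_that("minus-strand precursors are found after reverse complementing", {
  # note the reverse-complemented contig also exposes the arm as a
  # plus-strand match (the hairpin is symmetric); select the minus hit
  pre <- make_precursor_contig(MIR408, stem_mismatches = 0, seed = 13)
  cands <- find_precursors(MIR408, c(rc = revcomp_rna(pre$contig)))
  minus <- Filter(function(x) x$strand == "-", cands)
  expect_gte(length(minus), 1)
  expect_identical(minus[[1]]$verdict, "accepted")
  expect_identical(minus[[1]]$predicted_star, pre$star)
})
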