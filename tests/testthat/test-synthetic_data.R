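test_that("generators are pure functions of their seed", {
  expect_identical(make_mirnas(10, 21, seed = 3), make_mirnas(10, 21, seed = 3))
  expect_false(identical(make_mirnas(10, 21, seed = 3),
                         make_mirnas(10, 21, seed = 4)))
  p1 <- make_precursor_contig(MIR408, 3, seed = 5)
  p2 <- make_precursor_contig(MIR408, 3, seed = 5)
  expect_identical(p1, p2)
  pat <- list(five_prime = c(gu = 1, mm = 1), three_prime = c(gu = 1, mm = 1))
  t1 <- make_target_contig(MIR408, pat, seed = 6)
  t2 <- make_target_contig(MIR408, pat, seed = 6)
  expect_identical(t1$contig, t2$contig)
  # the ambient RNG stream is untouched
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(make_mirnas(5, 21, seed = 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("catalog generation honours lengths and overrides", {
  cat10 <- make_mirnas(10, 21, seed = 2)
  expect_length(cat10, 10)
  expect_true(all(nchar(cat10) == 21))
  withmir <- make_mirnas(5, 21, overrides = c("Ib-miR408" = MIR408), seed = 2)
  expect_identical(unname(withmir["Ib-miR408"]), MIR408)
  expect_error(make_mirnas(2, lengths = 10), "18-26")
})

test_that("libraries realize the planned RPM by deterministic rounding", {
  catalog <- c(a = random_rna(1, 21), b = random_rna(1, 22))
  plan <- data.frame(mirna_id = c("a", "b"),
                     rpm_control = c(290.95, 2.7),
                     ratio = c(0.68, 1))
  libs <- make_libraries(catalog, plan, depth = 1e6, seed = 3)
  cc <- assign_to_catalog(libs$control, catalog)
  ct <- assign_to_catalog(libs$treated, catalog)
  expect_equal(unname(cc["a"]), 291)   # round(290.95)
  expect_equal(unname(ct["a"]), 198)   # round(290.95 * 0.68)
  expect_equal(unname(cc["b"]), unname(ct["b"]))  # ratio 1
  expect_equal(libs$control$total_reads, 1e6)
  expect_equal(sum(libs$control$reads$count), 1e6)
  rr <- compute_ratio(compute_rpm(cc["a"], 1e6), compute_rpm(ct["a"], 1e6))
  expect_lt(abs(rr - 0.68), 0.005)
  expect_error(make_libraries(catalog,
                              data.frame(mirna_id = "a", rpm_control = 2e6,
                                         ratio = 1), depth = 1e6),
               "infeasible")
})

test_that("generated libraries survive a FASTQ round trip intact", {
  catalog <- make_mirnas(5, 21, seed = 8)
  plan <- make_rpm_plan(catalog, rpm_range = c(50, 200), seed = 8)
  libs <- make_libraries(catalog, plan, depth = 2e4, seed = 8)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_library_fastq(libs$control, fq)
  back <- read_fastq_collapsed(fq)
  expect_identical(attr(back, "dropped"), 0L)
  expect_equal(sum(back$count), 2e4)
  ord <- order(back$residues)
  ord0 <- order(libs$control$reads$residues)
  expect_identical(back$residues[ord], libs$control$reads$residues[ord0])
  expect_equal(back$count[ord], libs$control$reads$count[ord0])
})

test_that("planted precursor contigs carry the mature at the stated locus", {
  pre <- make_precursor_contig(MIR408, 2, loop_length = 8,
                               flank_length = 120, seed = 4)
  expect_identical(substr(pre$contig, pre$mature_start, pre$mature_end),
                   MIR408)
  expect_identical(pre$mature_start, 121L)
  expect_identical(nchar(pre$star), 21L)
})

test_that("planted site scores equal the expected score for gap-free patterns", {
  set.seed(64)
  for (r in 1:40) {
    tc <- make_target_contig(MIR408, random_region_pattern(FALSE),
                             seed = 400 + r)
    sc <- score_alignment(align_site(MIR408, tc$site))
    expect_equal(sc$penalty, tc$expected$penalty, info = paste("r", r))
    expect_equal(sc$regions$gu, tc$expected$regions$gu, info = paste("r", r))
    expect_equal(sc$regions$mismatch, tc$expected$regions$mismatch,
                 info = paste("r", r))
  }
})

test_that("gap-bearing plants are explained at or below the planted penalty", {
  set.seed(65)
  for (r in 1:15) {
    tc <- make_target_contig(MIR408, random_region_pattern(TRUE),
                             seed = 500 + r)
    sc <- score_alignment(align_site(MIR408, tc$site))
    expect_lte(sc$penalty, tc$expected$penalty)
    expect_identical(nchar(tc$site), 20L)
  }
})

test_that("infeasible site patterns are refused", {
  expect_error(make_target_contig(MIR408, list(central = c(gu = 3, mm = 0))),
               "infeasible")  # central 9-11 of miR408 has a single G/U
  expect_error(make_target_contig(MIR408,
                                  list(five_prime = c(gu = 4, mm = 5))),
               "infeasible")
  expect_error(make_target_contig(
    MIR408, list(five_prime = c(gu = 0, mm = 0, gap = 1),
                 three_prime = c(gu = 0, mm = 0, gap = 1))),
    "one gap")
})

test_that("RACE clone generation respects the scission bounds", {
  tc <- make_target_contig(MIR408, list(), seed = 31)
  sites <- scan_transcriptome(MIR408, c(t1 = tc$contig))
  aln <- attr(sites, "alignments")[[1]]
  clones <- make_race_clones(aln, 10, noise_sd = 3, n = 200, seed = 9)
  map <- pairing_map(aln)
  pos <- clone_to_mirna_position(clones$endpoint, clones$method, map)
  expect_true(all(pos >= 1 & pos <= 20))
  expect_error(make_race_clones(aln, 21, n = 5), "true_position")
})
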