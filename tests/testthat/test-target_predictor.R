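test_that("miRNA regions partition positions 1-8 / 9-11 / 12-L", {
  expect_identical(region_of(9, 21), "central")
  expect_identical(region_of(11, 21), "central")
  expect_identical(region_of(1, 21), "five_prime")
  expect_identical(region_of(8, 21), "five_prime")
  expect_identical(region_of(12, 21), "three_prime")
  expect_identical(region_of(21, 21), "three_prime")
  expect_error(region_of(0, 21), "out of range")
  expect_error(region_of(22, 21), "out of range")
})

test_that("base oppositions classify as match, GU or mismatch", {
  expect_identical(classify_pair("G", "C"), "match")
  expect_identical(classify_pair("A", "U"), "match")
  expect_identical(classify_pair("G", "U"), "GU")
  expect_identical(classify_pair("U", "G"), "GU")
  expect_identical(classify_pair("A", "C"), "mismatch")
  expect_identical(classify_pair("U", "U"), "mismatch")
  expect_identical(classify_pair("A", "N"), "mismatch")
})

test_that("a perfect site aligns with zero penalty, antiparallel", {
  aln <- align_site(MIR408, revcomp_rna(MIR408))
  expect_equal(aln$penalty, 0)
  expect_identical(unique(aln$columns$state), "match")
  # target positions strictly decreasing along the miRNA 5'->3'
  expect_true(all(diff(aln$columns$target_pos) < 0))
  expect_identical(aln$columns$target_pos[1], 21L)
})

test_that("a substitution opposite position 5 costs exactly one point", {
  site <- revcomp_rna(MIR408)
  chars <- strsplit(site, "")[[1]]
  # column for miRNA position 5 sits at site position L - 5 + 1
  k <- 21 - 5 + 1
  m5 <- substr(MIR408, 5, 5)
  chars[k] <- setdiff(c("A", "C", "G", "U"),
                      c(chars[k], if (m5 %in% c("G", "U"))
                        c(G = "U", U = "G")[m5]))[1]
  aln <- align_site(MIR408, paste(chars, collapse = ""))
  expect_equal(aln$penalty, 1)
  bad <- aln$columns[aln$columns$state == "mismatch", ]
  expect_identical(bad$mirna_pos, 5L)
})

test_that("a one-shorter site gets exactly one gap at minimum penalty", {
  set.seed(8)
  for (r in 1:10) {
    mirna <- random_rna(1, 21)
    site <- revcomp_rna(mirna)
    cut <- sample(1:21, 1)
    site1 <- paste0(substr(site, 1, cut - 1), substr(site, cut + 1, 21))
    aln <- align_site(mirna, site1)
    expect_identical(aln$gap_count, 1L)
    expect_gte(aln$penalty, 2)
    expect_equal(aln$penalty, oracle_window_penalty(mirna, site1))
  }
})

test_that("scores reproduce the published per-region count patterns", {
  mk <- function(pattern, seed) {
    tc <- make_target_contig(MIR408, pattern, seed = seed)
    filter_candidate(score_alignment(align_site(MIR408, tc$site)))
  }
  kcs <- mk(list(five_prime = c(gu = 0, mm = 1),
                 three_prime = c(gu = 0, mm = 1)), 101)
  expect_equal(kcs$penalty, 2)
  expect_identical(kcs$verdict, "candidate")

  pcl <- mk(list(three_prime = c(gu = 1, mm = 2)), 102)
  expect_equal(pcl$penalty, 2.5)
  expect_identical(pcl$verdict, "candidate")

  gaut <- mk(list(five_prime = c(gu = 1, mm = 1),
                  three_prime = c(gu = 1, mm = 1)), 103)
  expect_equal(gaut$penalty, 3)
  expect_identical(gaut$verdict, "candidate")
})

test_that("the filter excludes high penalties and central mismatches", {
  sc <- function(five = c(0, 0), central = c(0, 0), three = c(0, 0), gap = 0) {
    tc <- make_target_contig(MIR408, list(
      five_prime = c(gu = five[1], mm = five[2]),
      central = c(gu = central[1], mm = central[2]),
      three_prime = c(gu = three[1], mm = three[2], gap = gap)), seed = 55)
    filter_candidate(score_alignment(align_site(MIR408, tc$site)))
  }
  expect_identical(sc(three = c(0, 3))$verdict, "candidate")      # penalty 3
  expect_identical(sc(three = c(1, 3))$verdict, "excluded")       # 3.5
  ctr <- sc(central = c(0, 1))
  expect_identical(ctr$verdict, "excluded")
  expect_match(ctr$exclusion_reason, "central")
  # central GU wobble does not exclude but still costs 0.5
  cgu <- sc(central = c(1, 0))
  expect_identical(cgu$verdict, "candidate")
  expect_equal(cgu$penalty, 0.5)
})

test_that("penalty equals 1*mm + 0.5*GU + 2*gaps for random alignments", {
  set.seed(17)
  for (r in 1:25) {
    tc <- make_target_contig(MIR408, random_region_pattern(r %% 3 == 0),
                             seed = 300 + r)
    aln <- align_site(MIR408, tc$site)
    sc <- score_alignment(aln)
    states <- aln$columns$state
    expect_equal(sc$penalty,
                 sum(states == "mismatch") + 0.5 * sum(states == "GU") +
                   2 * sum(startsWith(states, "gap")))
  }
})

test_that("swapping a match for GU or mismatch raises the penalty by its cost", {
  site <- strsplit(revcomp_rna(MIR408), "")[[1]]
  base_pen <- align_site(MIR408, paste(site, collapse = ""))$penalty
  m <- strsplit(MIR408, "")[[1]]
  for (pos in c(2, 7, 14, 20)) {
    k <- 21 - pos + 1
    if (m[pos] %in% c("G", "U")) {
      gu <- site; gu[k] <- c(G = "U", U = "G")[m[pos]]
      expect_equal(align_site(MIR408, paste(gu, collapse = ""))$penalty,
                   base_pen + 0.5, info = paste("GU at", pos))
    }
    mmv <- site
    mmv[k] <- setdiff(c("A", "C", "G", "U"),
                      c(site[k], c(A = "", C = "", G = "U", U = "G")[m[pos]]))[1]
    expect_equal(align_site(MIR408, paste(mmv, collapse = ""))$penalty,
                 base_pen + 1, info = paste("mm at", pos))
  }
})

test_that("scanning reports a planted site once at its planted penalty", {
  tc <- make_target_contig(MIR408,
                           list(five_prime = c(gu = 0, mm = 1),
                                three_prime = c(gu = 0, mm = 1)),
                           seed = 21)
  sites <- scan_transcriptome(c("miR408" = MIR408), c(ctg = tc$contig))
  expect_identical(nrow(sites), 1L)
  expect_equal(sites$penalty, 2)
  expect_identical(sites$start, tc$site_start)
  expect_identical(sites$end, tc$site_end)
  expect_identical(sites$five_prime, "0/1")
  expect_identical(sites$central, "0/0")
  expect_identical(sites$three_prime, "0/1")

  # a contig that is exactly the reverse complement -> one perfect site
  perfect <- scan_transcriptome(MIR408, c(rc = revcomp_rna(MIR408)))
  expect_identical(nrow(perfect), 1L)
  expect_equal(perfect$penalty, 0)
})

test_that("window penalties agree with the brute-force oracle", {
  set.seed(30)
  for (s in 1:6) {
    mirna <- random_rna(1, 21)
    contig <- random_rna(1, sample(60:120, 1))
    got <- window_penalties(mirna, contig)
    want <- oracle_scan(mirna, contig)
    key <- function(d) d[order(d$site_length, d$start), "penalty"]
    expect_equal(key(got), key(want), info = paste("set", s))
  }
})

test_that("planted candidates are recovered with zero decoy leakage", {
  contigs <- character(0)
  for (i in 1:5) {
    tc <- make_target_contig(MIR408, list(five_prime = c(gu = 0, mm = 1),
                                          three_prime = c(gu = 1, mm = 1)),
                             seed = 220 + i)
    contigs[paste0("cand", i)] <- tc$contig
  }
  for (i in 1:5) {
    dc <- make_target_contig(MIR408, list(central = c(gu = 0, mm = 1),
                                          three_prime = c(gu = 1, mm = 0)),
                             seed = 240 + i)
    contigs[paste0("decoy", i)] <- dc$contig
  }
  set.seed(22)
  contigs[sprintf("bg%02d", 1:40)] <- random_rna(40, 300)
  sites <- scan_transcriptome(MIR408, contigs)
  expect_identical(sort(unique(sites$contig_id)), paste0("cand", 1:5))
  expect_identical(nrow(sites), 5L)
  # filter soundness on everything emitted
  expect_true(all(sites$penalty <= 3))
  expect_true(all(sub("/.*", "", sites$central) >= 0 &
                    sub(".*/", "", sites$central) == "0"))
})

test_that("overlapping candidate windows collapse to the best site", {
  # a perfect site: the shifted/longer windows around it overlap it
  contig <- c(ctg = paste0(random_rna(1, 50), revcomp_rna(MIR408),
                           random_rna(1, 50)))
  set.seed(44)
  sites <- scan_transcriptome(MIR408, contig)
  expect_identical(nrow(sites), 1L)
  expect_equal(sites$penalty, 0)
  uncollapsed <- scan_transcriptome(MIR408, contig, collapse = FALSE)
  expect_gte(nrow(uncollapsed), nrow(sites))
})
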