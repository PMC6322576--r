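# Independent oracles and small fixture builders. The oracles share no
# code with the package: pairing rules, scoring and the fold recurrence
# are restated from first principles with naive loops.

MIR408 <- "UGCACUGCCUCUUCCCUGGCU"
MIR408_STAR <- "ACGGGGACGAGGCGGAGCAUG"

# --- penalty-scoring oracle -------------------------------------------------

# pair cost restated: WC 0, G:U wobble 0.5, otherwise 1
oracle_cost <- function(a, b) {
  wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  if (wc) return(0)
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(0.5)
  1
}

# minimum penalty of one miRNA-vs-site window, enumerating the gapless
# register and every single-gap placement with explicit loops
oracle_window_penalty <- function(mirna, site) {
  m <- strsplit(mirna, "")[[1]]
  r <- rev(strsplit(site, "")[[1]])
  L <- length(m)
  Ls <- length(r)
  best <- Inf
  if (Ls == L) {
    p <- 0
    for (i in 1:L) p <- p + oracle_cost(m[i], r[i])
    best <- p
  } else if (Ls == L - 1) {
    for (g in 1:L) {
      p <- 2
      for (i in seq_len(L)) {
        if (i < g) p <- p + oracle_cost(m[i], r[i])
        if (i > g) p <- p + oracle_cost(m[i], r[i - 1])
      }
      best <- min(best, p)
    }
  } else if (Ls == L + 1) {
    for (g in 0:L) {
      p <- 2
      for (i in seq_len(L)) {
        if (i <= g) p <- p + oracle_cost(m[i], r[i])
        else p <- p + oracle_cost(m[i], r[i + 1])
      }
      best <- min(best, p)
    }
  }
  best
}

# all per-window penalties of a contig, brute force
oracle_scan <- function(mirna, contig) {
  L <- nchar(mirna)
  n <- nchar(contig)
  rows <- list()
  for (len in (L - 1):(L + 1)) {
    if (len > n) next
    for (st in 0:(n - len)) {
      rows[[length(rows) + 1]] <- data.frame(
        start = st, site_length = len,
        penalty = oracle_window_penalty(mirna, substr(contig, st + 1, st + len)))
    }
  }
  do.call(rbind, rows)
}

# --- fold oracle ------------------------------------------------------------

# optimal nested pairing weight, bottom-up recursion without traceback;
# integer weights x10 to avoid floating ties
oracle_fold_weight <- function(seq, min_loop = 3, wc = 10, gu = 8) {
  b <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(b)
  w <- function(x, y) {
    if ((x == "A" && y == "U") || (x == "U" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G")) return(wc)
    if ((x == "G" && y == "U") || (x == "U" && y == "G")) return(gu)
    0
  }
  if (n < 2) return(0)
  dp <- matrix(0, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    if (span > n - 1) break
    for (i in 1:(n - span)) {
      j <- i + span
      best <- dp[i + 1, j]
      for (k in (i + min_loop + 1):j) {
        pw <- w(b[i], b[k])
        if (pw == 0) next
        v <- pw + (if (k - 1 >= i + 1) dp[i + 1, k - 1] else 0) +
          (if (k + 1 <= j) dp[k + 1, j] else 0)
        if (v > best) best <- v
      }
      dp[i, j] <- best
    }
  }
  dp[1, n] / 10
}

# structural validity of a fold: each position in at most one pair,
# nested (no crossings), loops at least min_loop
oracle_fold_valid <- function(fold) {
  p <- fold$pairs
  pos <- c(p$i, p$j)
  if (anyDuplicated(pos)) return("position in two pairs")
  if (any(p$j - p$i - 1 < fold$min_loop)) return("loop too short")
  if (nrow(p) >= 2) {
    for (a in 1:(nrow(p) - 1)) {
      for (b in (a + 1):nrow(p)) {
        i1 <- p$i[a]; j1 <- p$j[a]; i2 <- p$i[b]; j2 <- p$j[b]
        disjoint <- j1 < i2 || j2 < i1
        nested <- (i1 < i2 && j2 < j1) || (i2 < i1 && j1 < j2)
        if (!disjoint && !nested) return("crossing pairs")
      }
    }
  }
  TRUE
}

# --- misc helpers -----------------------------------------------------------

write_fastq_records <- function(path, seqs) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con)
  }
  invisible(path)
}

# mature embedded in fresh random flanks (no precursor arm): the
# negative control for hairpin detection
flank_control_contig <- function(mature, flank = 150) {
  paste0(random_rna(1, flank), mature, random_rna(1, flank))
}

random_region_pattern <- function(with_gap = FALSE) {
  list(five_prime = c(gu = sample(0:1, 1), mm = sample(0:1, 1)),
       central = c(gu = sample(0:1, 1), mm = 0),
       three_prime = c(gu = sample(0:1, 1), mm = sample(0:2, 1),
                       gap = if (with_gap) 1 else 0))
}
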