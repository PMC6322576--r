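# Penalty-score target prediction. Complementarity between a miRNA and
# a candidate site is scored 1 point per mismatch, 0.5 per G:U wobble
# and 2 per gap; candidates must total at most 3 points and carry no
# mismatch in the central region (miRNA positions 9-11 from the 5' end,
# where AGO-mediated cleavage occurs). Scoring is unweighted: no
# seed-region doubling is applied, matching the published arithmetic.

#' Region of a miRNA position
#'
#' Positions 1-8 from the miRNA 5' end form the 5' region, 9-11 the
#' central region, and 12 onward the 3' region.
#'
#' @param mirna_position 1-based position(s) from the miRNA 5' end.
#' @param mirna_length miRNA length.
#' @return character vector over `{five_prime, central, three_prime}`.
#' @export
region_of <- function(mirna_position, mirna_length) {
  if (any(mirna_position < 1 | mirna_position > mirna_length)) {
    stop("miRNA position out of range 1..", mirna_length)
  }
  ifelse(mirna_position <= 8, "five_prime",
         ifelse(mirna_position <= 11, "central", "three_prime"))
}

#' Classify a miRNA:target base opposition
#'
#' @param mirna_base,target_base single bases in A/C/G/U.
#' @return "match" (Watson-Crick), "GU" (G:U or U:G wobble) or
#'   "mismatch".
#' @export
classify_pair <- function(mirna_base, target_base) {
  st <- .PAIR_STATE[paste0(mirna_base, target_base)]
  st[is.na(st)] <- "mismatch"   # N and friends never pair
  unname(st)
}

.base_cost <- function(mirna_base, target_base) {
  unname(.PAIR_COST[classify_pair(mirna_base, target_base)])
}

# Enumerate the admissible alignments of a miRNA against a site.  With
# at most one gap the minimum-penalty global alignment is found exactly
# by trying the gapless register plus every single-gap placement.
.enumerate_alignments <- function(m, r) {
  L <- length(m)
  Ls <- length(r)
  out <- list()
  if (Ls == L) {
    out[[1]] <- list(mirna = seq_len(L), target = seq_len(L), gap = NA)
  } else if (Ls == L - 1) {
    for (g in seq_len(L)) {    # miRNA position g faces a gap in the target
      mir <- seq_len(L)
      tgt <- ifelse(mir < g, mir, ifelse(mir > g, mir - 1L, NA))
      out[[g]] <- list(mirna = mir, target = tgt, gap = g)
    }
  } else if (Ls == L + 1) {
    for (g in 0:L) {           # unopposed target base after miRNA position g
      mir <- c(if (g >= 1) seq_len(g), NA, if (g < L) (g + 1L):L)
      tgt <- c(if (g >= 1) seq_len(g), g + 1L,
               if (g < L) ((g + 2L):(L + 1L)))
      out[[g + 1]] <- list(mirna = mir, target = tgt, gap = g)
    }
  }
  out
}

#' Align a miRNA against a candidate target site
#'
#' Minimum-penalty global alignment of the miRNA (5'->3') against the
#' reverse-oriented site under costs mismatch 1, GU 0.5, gap 2, match 0,
#' with at most `max_gaps` (default 1) gaps. Ties prefer fewer gaps,
#' then the alignment whose penalized columns sit closest to the miRNA
#' 3' end.
#'
#' @param mirna mature miRNA sequence (single RNA string; may be named).
#' @param site_sequence target site, 5'->3' on the transcript; length
#'   must lie within one nt of the miRNA length.
#' @param max_gaps maximum gaps (0 or 1).
#' @return an object of class `duplex_alignment`: list with `mirna`,
#'   `site`, `columns` (data.frame `mirna_pos`, `target_pos` in local
#'   1-based site coordinates, `state`, `region`), `penalty`,
#'   `gap_count`, and placeholder site-location fields filled by
#'   [scan_transcriptome()].
#' @export
align_site <- function(mirna, site_sequence, max_gaps = 1) {
  id <- if (!is.null(names(mirna))) names(mirna)[1] else NA_character_
  mirna <- rna_normalize(unname(mirna))
  site <- rna_normalize(unname(site_sequence))
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(m)
  Ls <- length(s)
  band <- if (max_gaps >= 1) 1L else 0L
  if (abs(Ls - L) > band) {
    stop("site length ", Ls, " outside allowed band for miRNA length ", L)
  }
  r <- rev(s)                     # r[k] pairs the miRNA left-to-right
  cands <- .enumerate_alignments(m, r)
  pen <- vapply(cands, function(a) {
    opp <- !is.na(a$mirna) & !is.na(a$target)
    sum(.base_cost(m[a$mirna[opp]], r[a$target[opp]])) + 2 * sum(!opp)
  }, numeric(1))
  best <- which(pen == min(pen))
  if (length(best) > 1) {
    # penalized columns as miRNA-axis indices; prefer them 3'-most
    keyed <- lapply(best, function(b) {
      a <- cands[[b]]
      costs <- numeric(length(a$mirna))
      opp <- !is.na(a$mirna) & !is.na(a$target)
      costs[opp] <- .base_cost(m[a$mirna[opp]], r[a$target[opp]])
      costs[!opp] <- 2
      which(costs > 0)
    })
    ord <- order(vapply(keyed, function(k)
      paste(sprintf("%03d", k), collapse = ""), character(1)),
      decreasing = TRUE)
    best <- best[ord[1]]
  }
  a <- cands[[best[1]]]
  opp <- !is.na(a$mirna) & !is.na(a$target)
  state <- character(length(a$mirna))
  state[opp] <- classify_pair(m[a$mirna[opp]], r[a$target[opp]])
  state[!opp & !is.na(a$mirna)] <- "gap_in_target"
  state[!opp & is.na(a$mirna)] <- "gap_in_mirna"
  region_anchor <- a$mirna
  if (anyNA(region_anchor)) {   # gap column: flanking miRNA position 5' of it
    gpos <- which(is.na(region_anchor))
    region_anchor[gpos] <- max(1L, gpos - 1L)
  }
  columns <- data.frame(
    mirna_pos = a$mirna,
    target_pos = ifelse(is.na(a$target), NA_integer_, Ls - a$target + 1L),
    state = state,
    region = region_of(pmin(region_anchor, L), L))
  structure(list(mirna_id = id, mirna = mirna, site = site,
                 columns = columns, penalty = pen[best[1]],
                 gap_count = sum(!opp),
                 contig_id = NA_character_, site_start = NA_integer_,
                 site_end = NA_integer_, strand = "+"),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex_alignment: penalty ", x$penalty, ", ", x$gap_count,
      " gap(s)\n", sep = "")
  invisible(x)
}

#' Score a duplex alignment
#'
#' Tallies GU wobbles and mismatches per region and computes the
#' penalty: 1 point per mismatch, 0.5 per GU wobble, 2 per gap.
#'
#' @param alignment a [align_site()] result.
#' @return an object of class `target_score`: list with `penalty`,
#'   `gap_count`, `regions` (data.frame `region`, `gu`, `mismatch`,
#'   `gap`), `verdict` and `exclusion_reason` (filled by
#'   [filter_candidate()]).
#' @export
score_alignment <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  cols <- alignment$columns
  regions <- c("five_prime", "central", "three_prime")
  tab <- data.frame(
    region = regions,
    gu = vapply(regions, function(rg)
      sum(cols$state == "GU" & cols$region == rg), numeric(1)),
    mismatch = vapply(regions, function(rg)
      sum(cols$state == "mismatch" & cols$region == rg), numeric(1)),
    gap = vapply(regions, function(rg)
      sum(startsWith(cols$state, "gap") & cols$region == rg), numeric(1)))
  rownames(tab) <- NULL
  penalty <- sum(tab$mismatch) + 0.5 * sum(tab$gu) + 2 * sum(tab$gap)
  structure(list(penalty = penalty, gap_count = sum(tab$gap),
                 regions = tab, verdict = NA_character_,
                 exclusion_reason = NA_character_),
            class = "target_score")
}

#' @export
print.target_score <- function(x, ...) {
  fmt <- paste(sprintf("%s %g/%g", sub("_.*", "'", x$regions$region),
                       x$regions$gu, x$regions$mismatch), collapse = "  ")
  cat("target_score: penalty ", x$penalty, " (", fmt, ", ",
      x$gap_count, " gap(s))",
      if (!is.na(x$verdict)) paste0(" -> ", x$verdict), "\n", sep = "")
  invisible(x)
}

#' Apply the candidate filter to a target score
#'
#' A site is excluded when its penalty exceeds `max_penalty` (default 3)
#' or it carries any mismatch in the central region; central GU wobbles
#' do not exclude (they still cost 0.5).
#'
#' @param score a [score_alignment()] result.
#' @param max_penalty maximum admissible penalty.
#' @return the score with `verdict` ("candidate"/"excluded") and
#'   `exclusion_reason` filled.
#' @export
filter_candidate <- function(score, max_penalty = 3) {
  stopifnot(inherits(score, "target_score"))
  reasons <- character(0)
  if (score$penalty > max_penalty) {
    reasons <- c(reasons, sprintf("penalty %g > %g", score$penalty,
                                  max_penalty))
  }
  central_mm <- score$regions$mismatch[score$regions$region == "central"]
  if (central_mm > 0) reasons <- c(reasons, "mismatch in central region")
  score$verdict <- if (length(reasons)) "excluded" else "candidate"
  score$exclusion_reason <- if (length(reasons))
    paste(reasons, collapse = "; ") else NA_character_
  score
}

#' Minimum alignment penalty for every window of a contig
#'
#' Low-level scanner: for each window start and each admissible site
#' length (the miRNA length, one shorter and one longer when gaps are
#' allowed) computes the minimum alignment penalty, using vectorized
#' prefix/suffix sums over a per-base cost matrix.
#'
#' @param mirna mature miRNA sequence.
#' @param contig contig sequence.
#' @param max_gaps maximum gaps per alignment (0 or 1).
#' @return data.frame with columns `start` (0-based), `site_length`,
#'   `penalty`.
#' @export
window_penalties <- function(mirna, contig, max_gaps = 1) {
  m <- strsplit(rna_normalize(unname(mirna)), "")[[1]]
  s <- strsplit(rna_normalize(unname(contig)), "")[[1]]
  L <- length(m)
  n <- length(s)
  empty <- data.frame(start = integer(0), site_length = integer(0),
                      penalty = numeric(0))
  if (n < L - (max_gaps >= 1)) return(empty)
  C <- matrix(0, L, n)
  for (i in seq_len(L)) C[i, ] <- .base_cost(m[i], s)
  res <- list()

  # gapless: miRNA position i faces contig base w + L - i (start w, 1-based)
  nw <- n - L + 1
  if (nw >= 1) {
    pen <- numeric(nw)
    for (i in seq_len(L)) pen <- pen + C[i, (L - i + 1):(L - i + nw)]
    res$eq <- data.frame(start = 0:(nw - 1), site_length = L, penalty = pen)
  }

  if (max_gaps >= 1) {
    # site one shorter: gap in the target at miRNA position g
    nw1 <- n - (L - 1) + 1
    if (nw1 >= 1 && L >= 2) {
      A <- function(i) C[i, (L - 1 - i + 1):(L - 1 - i + nw1)]  # i < g
      B <- function(i) C[i, (L - i + 1):(L - i + nw1)]          # i > g
      suf <- numeric(nw1)
      for (i in 2:L) suf <- suf + B(i)
      pref <- numeric(nw1)
      best <- rep(Inf, nw1)
      for (g in seq_len(L)) {
        best <- pmin(best, 2 + pref + suf)
        if (g < L) {
          pref <- pref + A(g)
          suf <- suf - B(g + 1)
        }
      }
      res$short <- data.frame(start = 0:(nw1 - 1), site_length = L - 1,
                              penalty = best)
    }
    # site one longer: unopposed target base after miRNA position g
    nw2 <- n - (L + 1) + 1
    if (nw2 >= 1) {
      D <- function(i) C[i, (L + 1 - i + 1):(L + 1 - i + nw2)]  # i <= g
      E <- function(i) C[i, (L - i + 1):(L - i + nw2)]          # i > g
      suf <- numeric(nw2)
      for (i in seq_len(L)) suf <- suf + E(i)
      pref <- numeric(nw2)
      best <- rep(Inf, nw2)
      for (g in 0:L) {
        best <- pmin(best, 2 + pref + suf)
        if (g < L) {
          pref <- pref + D(g + 1)
          suf <- suf - E(g + 1)
        }
      }
      res$long <- data.frame(start = 0:(nw2 - 1), site_length = L + 1,
                             penalty = best)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Scan contigs for candidate miRNA target sites
#'
#' Aligns every window of miRNA length (+/- 1 when gaps are allowed) on
#' the sense strand of each contig, keeps windows passing the candidate
#' filter, and collapses overlapping candidate windows per contig to the
#' minimum-penalty one (ties: longest, then leftmost). Contigs are mRNA
#' transcripts, so the reverse strand is only scanned on request.
#'
#' @param mirna mature miRNA sequence (optionally named).
#' @param contigs named character vector of contig sequences.
#' @param max_penalty candidate penalty cutoff (default 3).
#' @param max_gaps maximum gaps per alignment (default 1; two gaps can
#'   never pass a 3-point cutoff at 2 points each).
#' @param both_strands also scan the reverse complement of each contig.
#' @param collapse collapse overlapping candidate windows.
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `penalty`, `gaps`, `five_prime`, `central`,
#'   `three_prime` (GU/mismatch counts as "gu/mm"), `verdict`; sorted by
#'   ascending penalty then contig id. The matching `duplex_alignment`
#'   objects are attached as the `alignments` attribute.
#' @export
scan_transcriptome <- function(mirna, contigs, max_penalty = 3,
                               max_gaps = 1, both_strands = FALSE,
                               collapse = TRUE) {
  id <- if (!is.null(names(mirna))) names(mirna)[1] else NA_character_
  mirna_seq <- rna_normalize(unname(mirna))
  contigs <- rna_normalize(contigs)
  rows <- list()
  alns <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (cid in names(contigs)) {
    for (strand in strands) {
      seq <- if (strand == "+") contigs[[cid]] else revcomp_rna(contigs[[cid]])
      n <- nchar(seq)
      wp <- window_penalties(mirna_seq, seq, max_gaps = max_gaps)
      hits <- wp[wp$penalty <= max_penalty, , drop = FALSE]
      for (k in seq_len(nrow(hits))) {
        st <- hits$start[k]
        len <- hits$site_length[k]
        site <- substr(seq, st + 1, st + len)
        aln <- align_site(setNames(mirna_seq, id), site, max_gaps = max_gaps)
        if (abs(aln$penalty - hits$penalty[k]) > 1e-9) {
          stop("internal error: window scan and alignment disagree at ",
               cid, ":", st)
        }
        sc <- filter_candidate(score_alignment(aln), max_penalty)
        if (sc$verdict != "candidate") next
        if (strand == "+") {
          fstart <- st
          fend <- st + len
        } else {
          fstart <- n - (st + len)
          fend <- n - st
        }
        aln$contig_id <- cid
        aln$site_start <- as.integer(fstart)
        aln$site_end <- as.integer(fend)
        aln$strand <- strand
        rg <- sc$regions
        fmt <- function(rgn) sprintf("%g/%g", rg$gu[rg$region == rgn],
                                     rg$mismatch[rg$region == rgn])
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = cid, start = as.integer(fstart),
          end = as.integer(fend), strand = strand,
          penalty = sc$penalty, gaps = sc$gap_count,
          five_prime = fmt("five_prime"), central = fmt("central"),
          three_prime = fmt("three_prime"), verdict = sc$verdict)
        alns[[length(alns) + 1]] <- aln
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      penalty = numeric(0), gaps = numeric(0),
                      five_prime = character(0), central = character(0),
                      three_prime = character(0), verdict = character(0))
    attr(out, "alignments") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  if (collapse) {
    ord <- order(out$penalty, -(out$end - out$start), out$start)
    keep <- logical(nrow(out))
    for (k in ord) {
      same <- which(keep & out$contig_id == out$contig_id[k] &
                      out$strand == out$strand[k])
      overlaps <- any(out$start[same] < out$end[k] &
                        out$end[same] > out$start[k])
      if (!overlaps) keep[k] <- TRUE
    }
    out <- out[keep, , drop = FALSE]
    alns <- alns[keep]
  }
  ord <- order(out$penalty, out$contig_id, out$start)
  out <- out[ord, , drop = FALSE]
  alns <- alns[ord]
  rownames(out) <- NULL
  attr(out, "alignments") <- alns
  out
}
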