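# Precursor hairpin identification: exact mature-sequence matching in
# transcriptome contigs, folding of a flanking window, and acceptance
# rules that require the mature to sit in one arm of a stem-loop pairing
# the opposite arm (the miRNA:miRNA* duplex), from which the star strand
# is predicted with the standard 2-nt 3' overhang.

#' Acceptance rules for precursor hairpins
#'
#' @param pairing_fraction minimum fraction of mature positions paired
#'   into the stem (default 0.60).
#' @param max_bulged maximum number of unpaired mature positions
#'   (default 5).
#' @param loop_overhang how many mature positions may lie beyond the
#'   innermost stem pair, toward the terminal loop (default 2, the DCL
#'   duplex 3' overhang).
#' @param star_gap pairs whose partner lies within this many nt of the
#'   mature span are treated as terminal-loop pairs rather than duplex
#'   pairs (default 6).
#' @param register_tol folds can attach stray partners far from the
#'   duplex helix; mature pairs whose antiparallel register (position +
#'   partner) deviates from the median register by more than this are
#'   treated as unpaired (default 2, accommodating small bulge-induced
#'   register shifts while rejecting register-inconsistent pairings in
#'   shuffled controls).
#' @param flank_nt window flank on each side of the mature match
#'   (default 150 nt, covering typical plant precursor stems).
#' @param min_loop,max_window folding parameters, see [fold_window()].
#' @param backend folding backend: "thermo" ([fold_window_thermo()],
#'   ViennaRNA minimum free energy; stacking energetics keep genuine
#'   helices intact), "maxpair" ([fold_window()]), or "auto" (thermo
#'   when `RNAfold` is on the PATH, else maxpair).
#' @return a list of rules for [find_precursors()].
#' @export
hairpin_rules <- function(pairing_fraction = 0.6, max_bulged = 5,
                          loop_overhang = 2, star_gap = 6,
                          register_tol = 2, flank_nt = 150, min_loop = 3,
                          max_window = 400,
                          backend = c("auto", "thermo", "maxpair")) {
  stopifnot(pairing_fraction > 0, pairing_fraction <= 1,
            max_bulged >= 0, loop_overhang >= 0, star_gap >= 0,
            register_tol >= 0, flank_nt > 0, min_loop >= 1)
  list(pairing_fraction = pairing_fraction, max_bulged = max_bulged,
       loop_overhang = loop_overhang, star_gap = star_gap,
       register_tol = register_tol, flank_nt = flank_nt,
       min_loop = min_loop, max_window = max_window,
       backend = match.arg(backend))
}

.fold_backend <- function(rules) {
  be <- rules$backend
  if (is.null(be)) be <- "auto"
  if (be == "auto") {
    be <- if (Sys.which("RNAfold") != "") "thermo" else "maxpair"
  }
  if (be == "thermo") fold_window_thermo else fold_window
}

#' Find exact occurrences of a mature miRNA in contigs
#'
#' Reports every occurrence of the mature sequence on either strand of
#' each contig, in forward-contig 0-based half-open coordinates.
#'
#' @param mature mature miRNA sequence (single RNA string).
#' @param contigs named character vector of contig sequences.
#' @return data.frame with columns `contig_id`, `start`, `end`, `strand`.
#' @export
find_exact_matches <- function(mature, contigs) {
  mature <- rna_normalize(unname(mature))
  stopifnot(length(mature) == 1, nchar(mature) >= 1)
  contigs <- rna_normalize(contigs)
  subject <- Biostrings::RNAStringSet(contigs)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") mature else revcomp_rna(mature)
    m <- Biostrings::vmatchPattern(pat, subject)
    for (k in seq_along(m)) {
      r <- m[[k]]
      if (!length(r)) next
      hits[[length(hits) + 1]] <- data.frame(
        contig_id = names(contigs)[k],
        start = Biostrings::start(r) - 1L,
        end = Biostrings::end(r),
        strand = strand)
    }
  }
  if (!length(hits)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$contig_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a folded window as a precursor hairpin
#'
#' Applies the stem-loop acceptance rules to a mature location inside a
#' folded window: enough mature positions paired, all duplex partners on
#' a single opposite arm, the mature not overlapping the terminal loop
#' (beyond the 2-nt overhang allowance), and at most `max_bulged`
#' unpaired mature positions. For accepted hairpins the star strand is
#' the window segment pairing the mature, extended by a 2-nt 3'
#' overhang.
#'
#' @param window RNA string of the folded window.
#' @param mature_start,mature_end 1-based inclusive mature location
#'   within the window.
#' @param fold optional [fold_window()] result for `window`; computed if
#'   missing.
#' @param rules a [hairpin_rules()] list.
#' @return an object of class `hairpin_candidate`: list with `window`,
#'   `mature_start`, `mature_end`, `fold`, `arm` (5p/3p or NA),
#'   `predicted_star`, `star_start`, `star_end`, `mature_paired_fraction`,
#'   `verdict` ("accepted"/"rejected") and `rejection_reason`.
#' @export
evaluate_hairpin <- function(window, mature_start, mature_end,
                             fold = NULL, rules = hairpin_rules()) {
  window <- rna_normalize(window)
  n <- nchar(window)
  if (mature_start < 1 || mature_end > n || mature_start > mature_end) {
    stop("mature location outside window")
  }
  if (is.null(fold)) {
    fold <- .fold_backend(rules)(window, min_loop = rules$min_loop,
                                 max_window = rules$max_window)
  }
  mat_pos <- mature_start:mature_end
  L <- length(mat_pos)
  partner <- .fold_partners(fold, n)
  p <- partner[mat_pos]

  cand <- structure(list(window = window, mature_start = mature_start,
                         mature_end = mature_end, fold = fold,
                         arm = NA_character_, predicted_star = NA_character_,
                         star_start = NA_integer_, star_end = NA_integer_,
                         mature_paired_fraction = NA_real_,
                         verdict = "rejected", rejection_reason = ""),
                    class = "hairpin_candidate")
  reject <- function(reason) { cand$rejection_reason <- reason; cand }

  # self-pairing means the hairpin apex lies inside the mature span
  if (any(!is.na(p) & p >= mature_start & p <= mature_end)) {
    return(reject("overlaps terminal loop"))
  }
  # partners hugging the mature span sit in the terminal loop, not the
  # duplex; treat those positions as unpaired for the stem rules
  dist <- ifelse(p > mature_end, p - mature_end, mature_start - p)
  stem <- ifelse(!is.na(p) & dist > rules$star_gap, p, NA_integer_)
  # keep the dominant helix: discard partners whose antiparallel
  # register strays from the median (stray flank pairs of a
  # maximum-pairing fold)
  if (any(!is.na(stem))) {
    reg <- mat_pos + stem
    med <- stats::median(reg, na.rm = TRUE)
    stem[!is.na(reg) & abs(reg - med) > rules$register_tol] <- NA_integer_
  }
  # the duplex spans mature positions 1..L-2; the last two are the
  # mature's own 3' overhang under DCL duplex geometry
  didx <- seq_len(max(1L, L - 2L))
  dstem <- stem[didx]
  frac <- mean(!is.na(dstem))
  cand$mature_paired_fraction <- frac
  if (frac < rules$pairing_fraction) {
    return(reject("insufficient mature pairing"))
  }
  if (sum(is.na(dstem)) > rules$max_bulged) {
    return(reject("too many unpaired mature positions"))
  }
  above <- dstem[!is.na(dstem)] > mature_end
  if (length(unique(above)) > 1) {
    return(reject("mature pairs on both arms"))
  }
  arm <- if (all(above)) "5p" else "3p"
  # duplex positions hanging past the innermost stem pair sit in the loop
  paired_idx <- which(!is.na(dstem))
  beyond <- if (arm == "5p") sum(didx > max(paired_idx))
            else sum(didx < min(paired_idx))
  if (beyond > rules$loop_overhang) {
    return(reject("overlaps terminal loop"))
  }
  # star from the helix register R = position + partner: the ideal
  # partner of window position x is R - x, so the star runs from the
  # partner of mature position L-2 to the partner of position 1 plus
  # the 2-nt 3' overhang; the median register is robust to slipped or
  # stray boundary pairs
  R <- as.integer(round(stats::median(mat_pos + stem, na.rm = TRUE)))
  star_start <- max(1L, R - mature_end + 2L)
  star_end <- min(n, R - mature_start + 2L)
  cand$arm <- arm
  cand$star_start <- star_start
  cand$star_end <- star_end
  cand$predicted_star <- substr(window, star_start, star_end)
  cand$verdict <- "accepted"
  cand$rejection_reason <- NA_character_
  cand
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("hairpin_candidate: ", x$verdict,
      if (x$verdict == "rejected") paste0(" (", x$rejection_reason, ")"),
      ", mature ", x$mature_start, "-", x$mature_end,
      ", arm ", x$arm, "\n", sep = "")
  invisible(x)
}

#' Locate precursor hairpins for a mature miRNA in a contig set
#'
#' For each exact match of the mature sequence, a window of
#' `rules$flank_nt` on each side (clipped at contig ends) is extracted
#' (reverse-complemented for minus-strand matches), folded, and
#' evaluated by [evaluate_hairpin()]. All candidates are returned with
#' verdicts; accepted candidates sort first, by descending mature
#' pairing fraction.
#'
#' @param mature mature miRNA sequence (single RNA string, optionally
#'   named).
#' @param contigs named character vector of contig sequences.
#' @param rules a [hairpin_rules()] list.
#' @return list of `hairpin_candidate` objects, each augmented with
#'   `contig_id`, `window_start`, `window_end` (0-based half-open on the
#'   forward contig) and `strand`; see [precursor_table()].
#' @export
find_precursors <- function(mature, contigs, rules = hairpin_rules()) {
  mature <- rna_normalize(unname(mature))
  contigs <- rna_normalize(contigs)
  L <- nchar(mature)
  hits <- find_exact_matches(mature, contigs)
  out <- list()
  for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    contig <- contigs[[h$contig_id]]
    n <- nchar(contig)
    ws <- max(0L, h$start - rules$flank_nt)       # 0-based
    we <- min(n, h$end + rules$flank_nt)
    window <- substr(contig, ws + 1L, we)
    if (h$strand == "+") {
      m1 <- h$start - ws + 1L                      # 1-based in window
    } else {
      window <- revcomp_rna(window)
      m1 <- we - h$end + 1L
    }
    m2 <- m1 + L - 1L
    if (nchar(window) < 2L * L + rules$min_loop) {
      cand <- structure(list(window = window, mature_start = m1,
                             mature_end = m2, fold = NULL,
                             arm = NA_character_,
                             predicted_star = NA_character_,
                             star_start = NA_integer_,
                             star_end = NA_integer_,
                             mature_paired_fraction = NA_real_,
                             verdict = "rejected",
                             rejection_reason = "window too short"),
                        class = "hairpin_candidate")
    } else {
      cand <- evaluate_hairpin(window, m1, m2, rules = rules)
    }
    cand$contig_id <- h$contig_id
    cand$window_start <- ws
    cand$window_end <- we
    cand$strand <- h$strand
    out[[length(out) + 1]] <- cand
  }
  acc <- vapply(out, function(x) x$verdict == "accepted", logical(1))
  frac <- vapply(out, function(x) {
    if (is.na(x$mature_paired_fraction)) -1 else x$mature_paired_fraction
  }, numeric(1))
  out[order(!acc, -frac)]
}

#' Tabulate precursor candidates
#'
#' @param candidates list returned by [find_precursors()].
#' @return data.frame with one row per candidate (contig, window,
#'   strand, arm, verdict, reason, pairing fraction, star sequence).
#' @export
precursor_table <- function(candidates) {
  if (!length(candidates)) {
    return(data.frame(contig_id = character(0), window_start = integer(0),
                      window_end = integer(0), strand = character(0),
                      arm = character(0), mature_paired_fraction = numeric(0),
                      verdict = character(0), rejection_reason = character(0),
                      predicted_star = character(0)))
  }
  do.call(rbind, lapply(candidates, function(x) {
    data.frame(contig_id = x$contig_id, window_start = x$window_start,
               window_end = x$window_end, strand = x$strand,
               arm = x$arm, mature_paired_fraction = x$mature_paired_fraction,
               verdict = x$verdict, rejection_reason = x$rejection_reason,
               predicted_star = x$predicted_star)
  }))
}
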