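# Seeded synthetic-data generators. These emulate the statistical
# structure the pipeline assumes -- two-condition libraries with planted
# per-miRNA RPM and ratios, contigs carrying planted precursor hairpins
# and target sites with per-region event patterns, and RACE clone sets
# with a planted modal scission -- so every stage is testable without
# sequencing data. Every generator is a pure function of its arguments
# and seed.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed` (when non-NULL) and
#' restores the caller's RNG state afterwards, so generators are pure
#' functions of their arguments.
#'
#' @param seed integer seed or NULL (use the current RNG stream).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random RNA sequences
#'
#' @param n number of sequences.
#' @param length length (recycled).
#' @return character vector of random A/C/G/U strings.
#' @export
random_rna <- function(n, length = 21) {
  length <- rep_len(length, n)
  vapply(length, function(l)
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a mature-miRNA catalog
#'
#' Random mature sequences at the requested lengths; published
#' sequences can be injected verbatim through `overrides`.
#'
#' @param n number of random entries.
#' @param lengths lengths (recycled over `n`), within 18-26 nt.
#' @param overrides named character vector of sequences to prepend
#'   as-is (e.g. a printed miR408 sequence).
#' @param seed RNG seed.
#' @return named character vector of mature sequences.
#' @export
make_mirnas <- function(n, lengths = 21, overrides = NULL, seed = NULL) {
  lengths <- rep_len(lengths, n)
  if (any(lengths < 18 | lengths > 26)) stop("lengths must be within 18-26")
  out <- with_seed(seed, {
    seqs <- random_rna(n, lengths)
    setNames(seqs, sprintf("syn-miR%03d", seq_len(n)))
  })
  if (!is.null(overrides)) {
    out <- c(rna_normalize(overrides), out[!names(out) %in% names(overrides)])
  }
  out
}

#' Plan per-miRNA abundances and wound ratios
#'
#' Draws a control RPM and a treated/control ratio for each catalog
#' entry, with ratios sampled inside the repressed (<0.8), unchanged or
#' induced (>1.2) bands, kept away from the thresholds so the planted
#' class survives count rounding.
#'
#' @param catalog named character vector of mature sequences.
#' @param classes planted classes, recycled over the catalog; subset of
#'   repressed/unchanged/induced.
#' @param rpm_range range of control RPM values.
#' @param seed RNG seed.
#' @return data.frame `mirna_id`, `rpm_control`, `ratio`,
#'   `planted_class`.
#' @export
make_rpm_plan <- function(catalog,
                          classes = c("repressed", "unchanged", "induced"),
                          rpm_range = c(5, 500), seed = NULL) {
  n <- length(catalog)
  cls <- rep_len(classes, n)
  with_seed(seed, {
    ratio <- vapply(cls, function(cl) switch(cl,
      repressed = runif(1, 0.2, 0.7),
      unchanged = runif(1, 0.9, 1.1),
      induced = runif(1, 1.3, 2.5),
      stop("unknown class: ", cl)), numeric(1))
    data.frame(mirna_id = names(catalog),
               rpm_control = runif(n, rpm_range[1], rpm_range[2]),
               ratio = unname(ratio),
               planted_class = unname(cls))
  })
}

#' Build a two-condition library pair realizing an RPM plan
#'
#' Per-miRNA read counts are chosen by deterministic half-even rounding
#' so the realized RPM matches the plan as closely as integer counts at
#' the given depth allow; random background reads absorb the remaining
#' depth. (Published RPM values are realized exactly whenever the depth
#' makes them integer counts.)
#'
#' @param catalog named character vector of mature sequences.
#' @param rpm_plan data.frame with `mirna_id`, `rpm_control`, and either
#'   `rpm_treated` or `ratio`.
#' @param depth total reads per condition (default 1e6, a realistic
#'   small-RNA library scale).
#' @param lib_names condition labels.
#' @param n_filler number of background filler sequences.
#' @param seed RNG seed (for filler sequences).
#' @return list with `control` and `treated` [read_library()] objects.
#' @export
make_libraries <- function(catalog, rpm_plan, depth = 1e6,
                           lib_names = c("unwounded", "wounded"),
                           n_filler = 5, seed = NULL) {
  stopifnot(all(c("mirna_id", "rpm_control") %in% names(rpm_plan)),
            all(rpm_plan$mirna_id %in% names(catalog)))
  rpm_t <- if ("rpm_treated" %in% names(rpm_plan)) rpm_plan$rpm_treated
           else rpm_plan$rpm_control * rpm_plan$ratio
  counts_c <- round(rpm_plan$rpm_control / 1e6 * depth)
  counts_t <- round(rpm_t / 1e6 * depth)
  if (sum(counts_c) > depth || sum(counts_t) > depth) {
    stop("rpm plan infeasible at depth ", depth)
  }
  seqs <- unname(catalog[rpm_plan$mirna_id])
  fill <- with_seed(seed, {
    f <- random_rna(n_filler, 22)
    while (any(f %in% catalog) || anyDuplicated(f)) f <- random_rna(n_filler, 22)
    f
  })
  pad <- function(counts) {
    rest <- depth - sum(counts)
    share <- rep(rest %/% n_filler, n_filler)
    share[1] <- share[1] + rest %% n_filler
    df <- data.frame(residues = c(seqs, fill), count = c(counts, share))
    df[df$count > 0, , drop = FALSE]
  }
  list(control = read_library(lib_names[1], pad(counts_c), depth),
       treated = read_library(lib_names[2], pad(counts_t), depth))
}

#' Published miR408 wounding example
#'
#' The mature and star sequences of sweet potato Ib-miR408 with their
#' reported unwounded/wounded abundances (RPM 290.95 vs 197.04 for the
#' mature, 2.7 vs 3.77 for the star). A depth of 1e8 reads is the
#' smallest power of ten at which all four RPM values are integer read
#' counts, so the published table is realized exactly.
#'
#' @return list with `catalog`, `rpm_plan` and `depth` ready for
#'   [make_libraries()].
#' @export
mir408_example <- function() {
  list(catalog = c("Ib-miR408" = "UGCACUGCCUCUUCCCUGGCU",
                   "Ib-miR408*" = "ACGGGGACGAGGCGGAGCAUG"),
       rpm_plan = data.frame(
         mirna_id = c("Ib-miR408", "Ib-miR408*"),
         rpm_control = c(290.95, 2.7),
         rpm_treated = c(197.04, 3.77)),
       depth = 1e8)
}

# sample() without the scalar-x trap
.sample_safe <- function(x, n) x[sample.int(length(x), n)]

# letters that pair a given base (WC or GU)
.pairs_of <- function(b) {
  names(which(.PAIR_STATE[paste0(b, c("A", "C", "G", "U"))] != "mismatch"))
}
.partners_of <- function(b) {
  p <- .PAIR_STATE[paste0(b, c("A", "C", "G", "U"))]
  c("A", "C", "G", "U")[p != "mismatch"]
}
.nonpairing_base <- function(b) {
  setdiff(c("A", "C", "G", "U"), .partners_of(b))
}

#' Plant a precursor hairpin in a synthetic contig
#'
#' Builds a contig of the form 5' flank + mature + loop + opposite arm +
#' 3' flank, where the opposite arm is the reverse complement of the
#' mature (the stem continues past the star boundary, as in natural
#' precursors) with `stem_mismatches` substitutions at interior,
#' non-central stem positions. The planted star is the arm segment
#' pairing mature positions 1..L-2 plus the 2-nt 3' overhang of DCL
#' duplex geometry. Loop bases are chosen, where possible, so they
#' cannot pair the mature's loop-adjacent residues.
#'
#' @param mature mature miRNA sequence.
#' @param stem_mismatches substitutions to plant in the star arm.
#' @param loop_length terminal loop length (>= 3).
#' @param flank_length random flank on each side.
#' @param seed RNG seed.
#' @return list with `contig` (sequence), `mature_start`, `mature_end`
#'   (1-based), and the planted `star` sequence.
#' @export
make_precursor_contig <- function(mature, stem_mismatches = 0,
                                  loop_length = 6, flank_length = 150,
                                  seed = NULL) {
  mature <- rna_normalize(unname(mature))
  L <- nchar(mature)
  if (loop_length < 3) stop("loop_length must be >= 3")
  if (stem_mismatches > L - 6) {
    stop("stem_mismatches > mature length - 6 would defeat the ",
         "acceptance rules by construction")
  }
  m <- strsplit(mature, "")[[1]]
  with_seed(seed, {
    arm <- strsplit(revcomp_rna(mature), "")[[1]]
    # arm[k] pairs mature position L+1-k; keep the loop-adjacent pairs,
    # the star boundaries and the central partners intact
    eligible <- which(!((L + 1 - seq_along(arm)) %in% 9:11) &
                        !(seq_along(arm) %in% c(1L, 2L, 3L, L)))
    if (stem_mismatches > length(eligible)) {
      stop("not enough eligible stem positions for ", stem_mismatches,
           " mismatches")
    }
    if (stem_mismatches > 0) {
      mut <- .sample_safe(eligible, stem_mismatches)
      for (k in mut) {
        i <- L + 1 - k
        # avoid bases that pair the mature neighbours too, or the
        # mismatch can be absorbed by a one-step register slip
        nbr <- m[intersect(c(i - 1, i, i + 1), seq_len(L))]
        safe <- setdiff(c("A", "C", "G", "U"),
                        unique(unlist(lapply(nbr, .partners_of))))
        if (!length(safe)) safe <- .nonpairing_base(m[i])
        arm[k] <- .sample_safe(safe, 1)
      }
    }
    loop <- character(loop_length)
    for (k in seq_len(loop_length)) {
      forbidden <- character(0)
      if (k >= 3) forbidden <- c(forbidden, .partners_of(m[L - 1]))
      if (k >= 4) forbidden <- c(forbidden, .partners_of(m[L]))
      safe <- setdiff(c("A", "C", "G", "U"), forbidden)
      if (!length(safe)) safe <- setdiff(c("A", "C", "G", "U"),
                                         c(.RNA_COMP[m[L - 1]],
                                           .RNA_COMP[m[L]]))
      if (!length(safe)) safe <- c("A", "C", "G", "U")
      loop[k] <- .sample_safe(safe, 1)
    }
    flank5 <- random_rna(1, flank_length)
    flank3 <- random_rna(1, flank_length)
    contig <- paste0(flank5, mature, paste(loop, collapse = ""),
                     paste(arm, collapse = ""), flank3)
    # star: arm segment pairing mature 1..L-2, plus 2-nt 3' overhang
    star <- paste(c(arm[3:L], substr(flank3, 1, 2)), collapse = "")
    list(contig = contig,
         mature_start = as.integer(flank_length + 1),
         mature_end = as.integer(flank_length + L),
         star = star)
  })
}

#' Plant a target site with a per-region event pattern
#'
#' Starts from the perfect reverse-complement site of the miRNA and
#' introduces the requested events: GU wobbles by pairing-preserving
#' swaps (only possible opposite G or U), mismatches by non-pairing
#' swaps, gaps by deleting the partner base. The site is embedded in
#' random flanks and the expected score is returned alongside.
#'
#' @param mature mature miRNA sequence.
#' @param pattern list with elements `five_prime`, `central`,
#'   `three_prime`, each a vector with entries `gu`, `mm` and optionally
#'   `gap`; at most one gap in total.
#' @param flank_length random flank on each side.
#' @param seed RNG seed.
#' @return list with `contig`, `site_start`, `site_end` (0-based
#'   half-open), `site` (the planted site sequence), and `expected`
#'   (list `penalty`, `regions` data.frame).
#' @export
make_target_contig <- function(mature, pattern, flank_length = 100,
                               seed = NULL) {
  mature <- rna_normalize(unname(mature))
  m <- strsplit(mature, "")[[1]]
  L <- length(m)
  pools <- list(five_prime = 1:8, central = 9:11, three_prime = 12:L)
  get2 <- function(rg, what) {
    v <- pattern[[rg]]
    if (is.null(v) || is.na(v[what]) || !(what %in% names(v))) 0 else v[[what]]
  }
  total_gaps <- sum(vapply(names(pools), get2, numeric(1), what = "gap"))
  if (total_gaps > 1) stop("at most one gap is supported (max_gaps = 1)")
  with_seed(seed, {
    tp <- unname(.RNA_COMP[m])          # tp[i] faces miRNA position i
    drop_pos <- integer(0)
    for (rg in names(pools)) {
      pool <- pools[[rg]]
      n_gu <- get2(rg, "gu"); n_mm <- get2(rg, "mm"); n_gap <- get2(rg, "gap")
      gu_ok <- pool[m[pool] %in% c("G", "U")]
      if (n_gu > length(gu_ok)) {
        stop("pattern infeasible: ", n_gu, " GU wobbles requested in ",
             rg, " but only ", length(gu_ok), " G/U miRNA bases there")
      }
      if (n_gu + n_mm + n_gap > length(pool)) {
        stop("pattern infeasible: more events than positions in ", rg)
      }
      gu_pos <- if (n_gu) .sample_safe(gu_ok, n_gu) else integer(0)
      rest <- setdiff(pool, gu_pos)
      mm_pos <- if (n_mm) .sample_safe(rest, n_mm) else integer(0)
      rest <- setdiff(rest, mm_pos)
      gap_pos <- if (n_gap) .sample_safe(rest, n_gap) else integer(0)
      for (i in gu_pos) tp[i] <- if (m[i] == "G") "U" else "G"
      for (i in mm_pos) tp[i] <- .sample_safe(.nonpairing_base(m[i]), 1)
      drop_pos <- c(drop_pos, gap_pos)
    }
    site_chars <- rev(tp)               # site[k] faces miRNA position L-k+1
    if (length(drop_pos)) site_chars <- site_chars[-(L - drop_pos + 1)]
    site <- paste(site_chars, collapse = "")
    flank5 <- random_rna(1, flank_length)
    flank3 <- random_rna(1, flank_length)
    regions <- data.frame(
      region = names(pools),
      gu = vapply(names(pools), get2, numeric(1), what = "gu"),
      mismatch = vapply(names(pools), get2, numeric(1), what = "mm"),
      gap = vapply(names(pools), get2, numeric(1), what = "gap"))
    rownames(regions) <- NULL
    list(contig = paste0(flank5, site, flank3),
         site_start = as.integer(flank_length),
         site_end = as.integer(flank_length + nchar(site)),
         site = site,
         expected = list(
           penalty = sum(regions$mismatch) + 0.5 * sum(regions$gu) +
             2 * sum(regions$gap),
           regions = regions))
  })
}

#' Simulate RACE clones for a validated site
#'
#' Draws `n` clone scissions as `round(rnorm(true_position, noise_sd))`
#' clipped to the duplex, assigns each clone a RACE chemistry, and
#' derives the transcript endpoint each chemistry would observe for
#' that scission (the 5'-RLM endpoint pairs position p, the 3'-PPM
#' endpoint pairs p+1).
#'
#' @param site the site's `duplex_alignment` (with transcript
#'   location).
#' @param true_position planted modal scission (miRNA coordinate,
#'   1 <= p < miRNA length).
#' @param noise_sd positional noise (nt).
#' @param n number of clones.
#' @param ppm_fraction fraction of 3'-PPM clones.
#' @param seed RNG seed.
#' @return data.frame of clones (`target_id`, `method`, `endpoint`,
#'   `count`).
#' @export
make_race_clones <- function(site, true_position, noise_sd = 1, n = 50,
                             ppm_fraction = 0.5, seed = NULL) {
  stopifnot(inherits(site, "duplex_alignment"))
  L <- nchar(site$mirna)
  if (true_position < 1 || true_position >= L) {
    stop("true_position must satisfy 1 <= p < miRNA length")
  }
  map <- pairing_map(site)
  inv <- setNames(as.integer(names(map)), map)
  with_seed(seed, {
    p <- pmin(pmax(round(rnorm(n, true_position, noise_sd)), 1L), L - 1L)
    method <- ifelse(runif(n) < ppm_fraction, "PPM3", "RLM5")
    endpoint <- ifelse(method == "RLM5",
                       inv[as.character(p)],
                       inv[as.character(p + 1L)])
    ok <- !is.na(endpoint)
    if (!any(ok)) {
      return(data.frame(target_id = character(0), method = character(0),
                        endpoint = integer(0), count = integer(0)))
    }
    data.frame(target_id = if (is.na(site$contig_id)) "target"
               else site$contig_id,
               method = method[ok],
               endpoint = as.integer(endpoint[ok]),
               count = 1L)
  })
}
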