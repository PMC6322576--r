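# End-to-end orchestration: a plain-text (YAML) config drives the four
# analysis stages, each also runnable standalone; every run writes TSV
# reports plus a checksum manifest so reruns are verifiably identical.

#' Default pipeline configuration
#'
#' All tunable thresholds with their defaults: fold-change bounds 1.2
#' and 0.8 (strict), 1 RPM detection floor, read length bounds 18-26
#' nt, penalty cutoff 3 with at most 1 gap, 150-nt folding flanks, 0.60
#' mature pairing fraction with at most 5 unpaired positions, and the
#' canonical cleavage position 10.
#'
#' @param ... named overrides for any top-level or nested field.
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    inputs = list(control = NULL, treated = NULL, catalog = NULL,
                  contigs = NULL, clones = NULL, mature_id = NULL),
    params = list(min_rpm = 1, lower_fold = 0.8, upper_fold = 1.2,
                  min_len = 18, max_len = 26,
                  max_penalty = 3, max_gaps = 1,
                  flank_nt = 150, pairing_fraction = 0.6, max_bulged = 5,
                  min_loop = 3, canonical_position = 10,
                  report_digits = 2),
    output_dir = "mirwound_results")
  mods <- list(...)
  for (nm in names(mods)) {
    if (nm %in% c("inputs", "params")) {
      cfg[[nm]][names(mods[[nm]])] <- mods[[nm]]
    } else cfg[[nm]] <- mods[[nm]]
  }
  cfg
}

#' Read a pipeline configuration file
#'
#' @param path YAML file with any subset of the [default_config()]
#'   fields; unspecified fields keep their defaults.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  do.call(default_config, yaml::read_yaml(path))
}

.require_inputs <- function(config, fields, stage) {
  for (f in fields) {
    p <- config$inputs[[f]]
    if (is.null(p) || !file.exists(p)) {
      stop("stage ", stage, ": missing input '", f, "'",
           if (!is.null(p)) paste0(" (", p, ")"), call. = FALSE)
    }
  }
}

.read_library_file <- function(path, name, config) {
  p <- config$params
  reads <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
    read_fastq_collapsed(path, p$min_len, p$max_len)
  } else {
    read_fasta_collapsed(path, p$min_len, p$max_len)
  }
  read_library(name, reads)
}

.out_path <- function(config, file) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$output_dir, file)
}

#' Run the quantification stage
#'
#' Reads both condition libraries and the catalog, quantifies, writes
#' `quant.tsv`, and logs library depths and class counts.
#'
#' @param config configuration list, see [default_config()].
#' @return the quantification data.frame, invisibly.
#' @export
run_quant <- function(config = default_config()) {
  .require_inputs(config, c("control", "treated", "catalog"), "quant")
  p <- config$params
  control <- .read_library_file(config$inputs$control, "control", config)
  treated <- .read_library_file(config$inputs$treated, "treated", config)
  catalog <- read_fasta(config$inputs$catalog)
  if (!length(catalog)) {
    message("quant: empty catalog, writing empty table")
    quant <- data.frame(mirna_id = character(0), sequence = character(0),
                        rpm_control = numeric(0), rpm_treated = numeric(0),
                        ratio = numeric(0), regulation_class = character(0))
  } else {
    quant <- quantify_experiment(control, treated, catalog,
                                 min_rpm = p$min_rpm,
                                 lower = p$lower_fold, upper = p$upper_fold)
  }
  message("quant: depths ", control$total_reads, "/", treated$total_reads,
          "; ", sum(quant$regulation_class == "induced"), " induced, ",
          sum(quant$regulation_class == "repressed"), " repressed, ",
          sum(quant$regulation_class == "unchanged"), " unchanged, ",
          sum(quant$regulation_class == "undetermined"), " undetermined")
  write_tsv_report(quant, .out_path(config, "quant.tsv"), p$report_digits)
  invisible(quant)
}

.pick_mature <- function(config) {
  catalog <- read_fasta(config$inputs$catalog)
  if (!length(catalog)) stop("catalog is empty")
  id <- config$inputs$mature_id
  if (is.null(id)) id <- names(catalog)[1]
  if (!id %in% names(catalog)) stop("mature_id '", id, "' not in catalog")
  catalog[id]
}

#' Run the precursor-identification stage
#'
#' Writes `precursors.tsv` (one row per hairpin candidate with verdict)
#' and `precursor_folds.txt` (dot-bracket structure per folded window).
#'
#' @inheritParams run_quant
#' @return the candidate list, invisibly.
#' @export
run_precursor <- function(config = default_config()) {
  .require_inputs(config, c("catalog", "contigs"), "precursor")
  p <- config$params
  mature <- .pick_mature(config)
  contigs <- read_fasta(config$inputs$contigs)
  rules <- hairpin_rules(pairing_fraction = p$pairing_fraction,
                         max_bulged = p$max_bulged,
                         flank_nt = p$flank_nt, min_loop = p$min_loop)
  cands <- find_precursors(mature, contigs, rules)
  message("precursor: ", length(cands), " candidate(s), ",
          sum(vapply(cands, function(x) x$verdict == "accepted",
                     logical(1))), " accepted")
  write_tsv_report(precursor_table(cands),
                   .out_path(config, "precursors.tsv"), p$report_digits)
  db <- vapply(cands, function(x) {
    if (is.null(x$fold)) return(sprintf(">%s (not folded)", x$contig_id))
    sprintf(">%s %d-%d %s\n%s\n%s", x$contig_id, x$window_start,
            x$window_end, x$strand, x$window, dot_bracket(x$fold))
  }, character(1))
  writeLines(db, .out_path(config, "precursor_folds.txt"))
  invisible(cands)
}

#' Run the target-prediction stage
#'
#' Writes `targets.tsv` with per-region GU/mismatch counts in the
#' published "gu/mm" style.
#'
#' @inheritParams run_quant
#' @return the candidate-site data.frame, invisibly.
#' @export
run_targets <- function(config = default_config()) {
  .require_inputs(config, c("catalog", "contigs"), "targets")
  p <- config$params
  mature <- .pick_mature(config)
  contigs <- read_fasta(config$inputs$contigs)
  sites <- scan_transcriptome(mature, contigs, max_penalty = p$max_penalty,
                              max_gaps = p$max_gaps)
  message("targets: ", nrow(sites), " candidate site(s) at penalty <= ",
          p$max_penalty)
  write_tsv_report(sites, .out_path(config, "targets.tsv"),
                   p$report_digits)
  invisible(sites)
}

#' Run the cleavage-mapping stage
#'
#' Re-derives each candidate site's duplex alignment from the target
#' table, tallies the RACE clones per target, and writes `cleavage.tsv`
#' (per-position counts) and `cleavage_calls.tsv` (one modal call per
#' target). Clones naming unknown targets are logged and skipped.
#'
#' @inheritParams run_quant
#' @return list of `cleavage_profile` objects, invisibly.
#' @export
run_cleavage <- function(config = default_config()) {
  .require_inputs(config, c("catalog", "contigs", "clones"), "cleavage")
  p <- config$params
  mature <- .pick_mature(config)
  contigs <- read_fasta(config$inputs$contigs)
  clones <- read_race_clones(config$inputs$clones)
  targets_path <- .out_path(config, "targets.tsv")
  if (!file.exists(targets_path)) {
    stop("stage cleavage: run_targets output not found at ", targets_path)
  }
  targets <- read.delim(targets_path, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(clones$target_id), targets$contig_id)
  if (length(unknown)) {
    message("cleavage: skipping clones for unknown target(s): ",
            paste(unknown, collapse = ", "))
  }
  profiles <- list()
  rows <- list()
  calls <- list()
  for (tid in intersect(unique(clones$target_id), targets$contig_id)) {
    trow <- targets[targets$contig_id == tid, , drop = FALSE][1, ]
    seq <- contigs[[tid]]
    site_seq <- substr(seq, trow$start + 1, trow$end)
    aln <- align_site(mature, site_seq, max_gaps = p$max_gaps)
    aln$contig_id <- tid
    aln$site_start <- trow$start
    aln$site_end <- trow$end
    prof <- tally_cleavage(clones[clones$target_id == tid, , drop = FALSE],
                           aln, canonical = p$canonical_position)
    profiles[[tid]] <- prof
    if (nrow(prof$tallies)) {
      rows[[tid]] <- data.frame(target_id = tid, prof$tallies)
    }
    calls[[tid]] <- data.frame(target_id = tid,
                               modal_position = prof$modal_position,
                               total_clones = prof$total_clones,
                               unmapped = prof$unmapped)
    message("cleavage: ", tid, " modal position ", prof$modal_position,
            " (", prof$total_clones, " clones)")
  }
  tallies <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(0), position = integer(0),
               count = numeric(0))
  write_tsv_report(tallies, .out_path(config, "cleavage.tsv"),
                   p$report_digits)
  write_tsv_report(if (length(calls)) do.call(rbind, calls) else
    data.frame(target_id = character(0), modal_position = integer(0),
               total_clones = numeric(0), unmapped = numeric(0)),
    .out_path(config, "cleavage_calls.tsv"), p$report_digits)
  invisible(profiles)
}

#' Run all four stages
#'
#' Executes quantification, precursor identification, target prediction
#' and cleavage mapping in order, then writes `manifest.tsv` with an
#' md5 checksum per output so a rerun with the same config and inputs
#' is verifiably byte-identical. Any stage failure aborts with the
#' stage name and cause.
#'
#' @inheritParams run_quant
#' @return path of the manifest file, invisibly.
#' @export
run_all <- function(config = default_config()) {
  stages <- list(quant = run_quant, precursor = run_precursor,
                 targets = run_targets, cleavage = run_cleavage)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config),
             error = function(e) stop("stage '", nm, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  outs <- c("quant.tsv", "precursors.tsv", "precursor_folds.txt",
            "targets.tsv", "cleavage.tsv", "cleavage_calls.tsv")
  paths <- file.path(config$output_dir, outs)
  paths <- paths[file.exists(paths)]
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  mpath <- .out_path(config, "manifest.tsv")
  write_tsv_report(manifest, mpath)
  invisible(mpath)
}

#' Write a full synthetic experiment to disk
#'
#' Generates a catalog, two condition libraries (FASTQ), a contig set
#' containing a planted precursor, planted target sites, decoys and
#' background contigs, and a RACE clone table, all under one seed, and
#' writes them in the standard formats so the pipeline can run on them
#' end to end.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param depth library depth (reads per condition; kept modest because
#'   the FASTQ files are written read by read).
#' @param n_mirnas catalog size.
#' @param n_background background contigs.
#' @param true_position planted modal cleavage position.
#' @return a [default_config()] pointing at the generated files,
#'   invisibly.
#' @export
simulate_experiment <- function(dir, seed = 7, depth = 2e5, n_mirnas = 10,
                                n_background = 20, true_position = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- mir408_example()
  catalog <- make_mirnas(n_mirnas - 1, 21, overrides = ex$catalog[1],
                         seed = seed)
  plan <- make_rpm_plan(catalog, rpm_range = c(20, 500), seed = seed + 1)
  libs <- make_libraries(catalog, plan, depth = depth, seed = seed + 2)
  mature <- catalog[1]
  pre <- make_precursor_contig(mature, stem_mismatches = 2, seed = seed + 3)
  tgt <- make_target_contig(mature,
                            list(five_prime = c(gu = 0, mm = 1),
                                 three_prime = c(gu = 1, mm = 1)),
                            seed = seed + 4)
  decoy <- make_target_contig(mature, list(central = c(gu = 0, mm = 1)),
                              seed = seed + 5)
  contigs <- with_seed(seed + 6, c(
    setNames(pre$contig, "contig_pre"),
    setNames(tgt$contig, "contig_target"),
    setNames(decoy$contig, "contig_decoy"),
    setNames(random_rna(n_background, 300),
             sprintf("contig_bg%03d", seq_len(n_background)))))
  write_fasta(catalog, file.path(dir, "catalog.fa"))
  write_fasta(contigs, file.path(dir, "contigs.fa"))
  write_library_fastq(libs$control, file.path(dir, "control.fastq"))
  write_library_fastq(libs$treated, file.path(dir, "treated.fastq"))
  sites <- scan_transcriptome(mature, contigs["contig_target"])
  clones <- make_race_clones(attr(sites, "alignments")[[1]],
                             true_position = true_position,
                             noise_sd = 1, n = 30, seed = seed + 7)
  write.table(clones, file.path(dir, "clones.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- default_config(
    inputs = list(control = file.path(dir, "control.fastq"),
                  treated = file.path(dir, "treated.fastq"),
                  catalog = file.path(dir, "catalog.fa"),
                  contigs = file.path(dir, "contigs.fa"),
                  clones = file.path(dir, "clones.tsv"),
                  mature_id = names(catalog)[1]),
    output_dir = file.path(dir, "results"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(cfg)
}

#' Expand a read library into a FASTQ file
#'
#' Each collapsed read is written `count` times with a constant
#' maximum-quality line, the inverse of [read_fastq_collapsed()].
#'
#' @param library a [read_library()].
#' @param path output FASTQ.
#' @return invisibly, `path`.
#' @export
write_library_fastq <- function(library, path) {
  stopifnot(inherits(library, "read_library"))
  seqs <- rep(library$reads$residues, library$reads$count)
  if (length(seqs) > 5e6) {
    stop("refusing to expand ", length(seqs), " reads to FASTQ; ",
         "use a smaller depth")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    recs <- paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
                   strrep("I", nchar(seqs)))
    writeLines(recs, con)
  }
  invisible(path)
}
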