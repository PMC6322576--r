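# Readers/writers for the external formats and the shared sequence model.
# Sequences live in RNA space throughout: T is normalized to U on input
# and everything is upper-cased, so printed DNA primers and RNA reads
# compare directly.

#' Normalize a sequence to the RNA alphabet
#'
#' Upper-cases and maps T to U. Characters outside A/C/G/U (ambiguity
#' codes such as N) are preserved; they never pair in any downstream
#' comparison.
#'
#' @param x character vector of sequences.
#' @return character vector in RNA space.
#' @export
#' @examples
#' rna_normalize("acgt")  # "ACGU"
rna_normalize <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Reverse complement in RNA space
#'
#' @param x character vector of RNA sequences (A/C/G/U, N allowed).
#' @return character vector of reverse complements.
#' @export
revcomp_rna <- function(x) {
  x <- rna_normalize(x)
  vapply(strsplit(x, ""), function(ch) {
    comp <- .RNA_COMP[ch]
    comp[is.na(comp)] <- "N"
    paste(rev(comp), collapse = "")
  }, character(1))
}

#' Read a FASTA file into named RNA sequences
#'
#' Records are returned in file order as a named character vector
#' (names are the full header lines without the leading `>`), with
#' residues normalized to the RNA alphabet.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  .check_fasta_wellformed(path)
  set <- Biostrings::readBStringSet(path)
  out <- rna_normalize(as.character(set))
  names(out) <- names(set)
  out
}

# A header line immediately followed by another header (or EOF) has no
# sequence; report it with its line number rather than letting the
# parser silently emit a zero-width record.
.check_fasta_wellformed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, ">")
  if (!length(lines)) return(invisible(TRUE))
  bad <- which(is_header & c(is_header[-1], TRUE))
  # headers followed only by blank lines are also sequence-less
  for (h in which(is_header)) {
    nxt <- lines[seq(h + 1, length.out = max(0, length(lines) - h))]
    upto <- which(startsWith(nxt, ">"))[1]
    body <- if (is.na(upto)) nxt else head(nxt, upto - 1)
    if (!any(nzchar(trimws(body)))) bad <- c(bad, h)
  }
  if (length(bad)) {
    stop("FASTA parse error at line ", min(bad), ": header without sequence")
  }
  invisible(TRUE)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(names(seqs)) == length(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file and collapse identical reads
#'
#' Quality lines are parsed (and validated) but otherwise ignored.
#' Identical read sequences are merged and their occurrences counted;
#' reads containing non-ACGU characters after RNA normalization are
#' dropped (their number is reported in a message and attached as the
#' `dropped` attribute), as are reads outside the small-RNA length
#' bounds.
#'
#' @param path FASTQ file.
#' @param min_len,max_len inclusive length bounds for retained reads
#'   (defaults 18 and 26 nt, a 2-nt margin around the canonical
#'   20-24 nt miRNA range).
#' @return data.frame with columns `residues` and `count`, ordered by
#'   descending count then lexicographically; attribute `dropped` holds
#'   the number of discarded records.
#' @export
read_fastq_collapsed <- function(path, min_len = 18, max_len = 26) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq"),
    error = function(e) stop("FASTQ parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  reads <- rna_normalize(as.character(set))
  clean <- !grepl("[^ACGU]", reads)
  inlen <- nchar(reads) >= min_len & nchar(reads) <= max_len
  keep <- clean & inlen
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " read(s) dropped (",
            sum(!clean), " non-ACGU, ", sum(clean & !inlen),
            " outside ", min_len, "-", max_len, " nt)")
  }
  reads <- reads[keep]
  if (!length(reads)) {
    out <- data.frame(residues = character(0), count = integer(0))
  } else {
    tab <- table(reads)
    out <- data.frame(residues = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$residues), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- n_drop
  out
}

#' Read a pre-collapsed FASTA library
#'
#' Collapsed small-RNA libraries are FASTA files whose headers carry the
#' read multiplicity as a `count=N` token (or a bare trailing integer);
#' absent counts default to 1.
#'
#' @param path FASTA file.
#' @inheritParams read_fastq_collapsed
#' @return data.frame with columns `residues` and `count`.
#' @export
read_fasta_collapsed <- function(path, min_len = 18, max_len = 26) {
  seqs <- read_fasta(path)
  counts <- rep(1L, length(seqs))
  m <- regmatches(names(seqs), regexpr("count=([0-9]+)", names(seqs)))
  has <- grepl("count=([0-9]+)", names(seqs))
  counts[has] <- as.integer(sub("count=", "", m))
  bare <- !has & grepl("[ _]([0-9]+)$", names(seqs))
  counts[bare] <- as.integer(sub(".*[ _]([0-9]+)$", "\\1", names(seqs)[bare]))
  keep <- !grepl("[^ACGU]", seqs) &
    nchar(seqs) >= min_len & nchar(seqs) <= max_len
  df <- data.frame(residues = as.character(seqs[keep]),
                   count = counts[keep])
  df <- aggregate(count ~ residues, df, sum)
  df <- df[order(-df$count, df$residues), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "dropped") <- sum(!keep)
  df
}

#' Write a tabular report as TSV
#'
#' Writes a header row and tab-separated fields; floating-point columns
#' are rendered at fixed precision (default 2 decimals, the precision
#' used for published RPM tables).
#'
#' @param records data.frame of results.
#' @param path output file.
#' @param digits decimals for double columns.
#' @return invisibly, `path`.
#' @export
write_tsv_report <- function(records, path, digits = 2) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], format = "f", digits = digits))
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}
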