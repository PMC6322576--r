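# Library-level quantification: reads-per-million normalization,
# perfect-match assignment to a mature-miRNA catalog, and fold-change
# classification of wound regulation.

#' Construct a read library
#'
#' A read library is a condition-labelled set of collapsed reads plus
#' the library sequencing depth used for normalization.
#'
#' @param name condition label (e.g. "unwounded", "wounded").
#' @param reads data.frame with columns `residues` and `count`
#'   (as produced by [read_fastq_collapsed()]).
#' @param total_reads library depth; defaults to the sum of counts.
#'   Passing a larger depth models reads excluded upstream.
#' @return an object of class `read_library`.
#' @export
read_library <- function(name, reads, total_reads = sum(reads$count)) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.data.frame(reads),
            all(c("residues", "count") %in% names(reads)))
  if (any(reads$count < 0)) stop("read counts must be non-negative")
  total_reads <- as.numeric(total_reads)
  if (total_reads < sum(reads$count)) {
    stop("total_reads (", total_reads, ") is less than the sum of counts (",
         sum(reads$count), ")")
  }
  structure(list(name = name,
                 reads = reads[, c("residues", "count")],
                 total_reads = total_reads),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat("read_library '", x$name, "': ", nrow(x$reads),
      " unique sequences, depth ", format(x$total_reads, big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' @param count non-negative read count(s).
#' @param total_reads positive library depth.
#' @return `count / total_reads * 1e6`.
#' @export
#' @examples
#' compute_rpm(25, 2e6)  # 12.5
compute_rpm <- function(count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / total_reads * 1e6
}

#' Assign collapsed reads to a mature-miRNA catalog by perfect match
#'
#' A read contributes to a catalog entry if and only if its residues
#' equal the catalog sequence exactly, full length with no offsets;
#' length variants are distinct reads. Reads matching no entry are
#' ignored here.
#'
#' @param library a [read_library()].
#' @param catalog named character vector of mature sequences (ids as
#'   names), RNA alphabet.
#' @return named numeric vector of summed counts for catalog entries
#'   with at least one matching read.
#' @export
assign_to_catalog <- function(library, catalog) {
  stopifnot(inherits(library, "read_library"))
  catalog <- rna_normalize(catalog)
  if (is.null(names(catalog)) || any(!nzchar(names(catalog)))) {
    stop("catalog sequences must be named")
  }
  if (anyDuplicated(catalog)) {
    ids <- names(catalog)[catalog %in% catalog[duplicated(catalog)]]
    stop("duplicate catalog sequences under different ids: ",
         paste(unique(ids), collapse = ", "))
  }
  idx <- match(library$reads$residues, catalog)
  hit <- !is.na(idx)
  if (!any(hit)) return(setNames(numeric(0), character(0)))
  counts <- tapply(library$reads$count[hit], names(catalog)[idx[hit]], sum)
  setNames(as.numeric(counts), names(counts))
}

#' Treated/control abundance ratio
#'
#' @param rpm_control control-condition RPM.
#' @param rpm_treated treated-condition RPM.
#' @return `rpm_treated / rpm_control`, or `NA` where the control RPM is
#'   zero (the ratio is undefined, not infinite).
#' @export
compute_ratio <- function(rpm_control, rpm_treated) {
  r <- rpm_treated / rpm_control
  r[rep_len(rpm_control == 0, length(r))] <- NA_real_
  r
}

#' Classify wound regulation from a fold-change ratio
#'
#' Strict thresholds: ratios above `upper` are induced, below `lower`
#' repressed, in between (boundaries included) unchanged. An undefined
#' ratio, or abundance below `min_rpm` in both conditions, yields
#' "undetermined".
#'
#' @param ratio treated/control ratio(s); `NA` for undefined.
#' @param rpm_control,rpm_treated optional RPM values used for the
#'   `min_rpm` floor; omit to skip that check.
#' @param min_rpm minimum RPM in at least one condition to call a class.
#' @param lower,upper repression/induction thresholds (defaults 0.8 and
#'   1.2, strict inequalities).
#' @return character vector over `{induced, repressed, unchanged,
#'   undetermined}`.
#' @export
#' @examples
#' classify_regulation(c(0.68, 1.4, 1.2))
classify_regulation <- function(ratio, rpm_control = NULL, rpm_treated = NULL,
                                min_rpm = 1, lower = 0.8, upper = 1.2) {
  if (upper <= lower) stop("upper threshold must exceed lower threshold")
  cls <- ifelse(is.na(ratio), "undetermined",
         ifelse(ratio > upper, "induced",
         ifelse(ratio < lower, "repressed", "unchanged")))
  if (!is.null(rpm_control) && !is.null(rpm_treated)) {
    low <- rpm_control < min_rpm & rpm_treated < min_rpm
    cls[low] <- "undetermined"
  }
  cls
}

#' Quantify a two-condition small-RNA experiment against a catalog
#'
#' Produces one record per catalog entry detected in either library,
#' with RPM in both conditions, the treated/control ratio, and the
#' regulation class, sorted by ascending ratio (most repressed first;
#' undefined ratios last).
#'
#' @param control,treated [read_library()] objects.
#' @param catalog named character vector of mature sequences.
#' @inheritParams classify_regulation
#' @return data.frame with columns `mirna_id`, `sequence`,
#'   `rpm_control`, `rpm_treated`, `ratio`, `regulation_class`.
#' @export
quantify_experiment <- function(control, treated, catalog,
                                min_rpm = 1, lower = 0.8, upper = 1.2) {
  stopifnot(inherits(control, "read_library"),
            inherits(treated, "read_library"))
  if (!nrow(control$reads) || !nrow(treated$reads)) {
    stop("both libraries must be non-empty")
  }
  catalog <- rna_normalize(catalog)
  cc <- assign_to_catalog(control, catalog)
  ct <- assign_to_catalog(treated, catalog)
  ids <- names(catalog)[names(catalog) %in% union(names(cc), names(ct))]
  if (!length(ids)) {
    return(data.frame(mirna_id = character(0), sequence = character(0),
                      rpm_control = numeric(0), rpm_treated = numeric(0),
                      ratio = numeric(0), regulation_class = character(0)))
  }
  n_c <- ifelse(is.na(cc[ids]), 0, cc[ids])
  n_t <- ifelse(is.na(ct[ids]), 0, ct[ids])
  rpm_c <- compute_rpm(n_c, control$total_reads)
  rpm_t <- compute_rpm(n_t, treated$total_reads)
  ratio <- compute_ratio(rpm_c, rpm_t)
  cls <- classify_regulation(ratio, rpm_c, rpm_t,
                             min_rpm = min_rpm, lower = lower, upper = upper)
  out <- data.frame(mirna_id = ids,
                    sequence = unname(catalog[ids]),
                    rpm_control = unname(rpm_c),
                    rpm_treated = unname(rpm_t),
                    ratio = unname(ratio),
                    regulation_class = unname(cls))
  out <- out[order(is.na(out$ratio), out$ratio, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
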