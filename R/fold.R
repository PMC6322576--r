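# Weighted maximum base-pairing fold. The precursor check only needs a
# binary stem-loop gate plus the position of the miRNA* strand, so a
# Nussinov-style maximum-weight nested pairing stands in for a full
# thermodynamic fold: Watson-Crick pairs weigh 1.0, G:U wobbles 0.8
# (valid stem pairs in plant precursors, discounted so GU-saturated
# spurious stems lose to genuine ones), and hairpin loops span at least
# 3 unpaired bases. Any thermodynamic backend producing the same
# fold_result contract can be plugged in instead.

#' Fold an RNA window by weighted maximum base pairing
#'
#' Computes a nested, maximum-weight set of base pairs by dynamic
#' programming (implemented in C++). Ties are broken deterministically:
#' whenever pairing the 5'-most open position attains the optimum it is
#' paired, with the smallest admissible partner, and the rule applies
#' recursively.
#'
#' @param window_sequence RNA string (A/C/G/U; other characters never
#'   pair).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @param wc_weight,gu_weight pair weights (resolved at 0.1 resolution).
#' @param max_window maximum window length accepted.
#' @return an object of class `fold_result`: list with `sequence`,
#'   `pairs` (data.frame `i`, `j`, `type` in WC/GU, 1-based, `i < j`),
#'   and `weight` (total pairing weight).
#' @export
#' @examples
#' fold_window("GGGAAACCC")$pairs  # the 3-pair stem of a perfect hairpin
fold_window <- function(window_sequence, min_loop = 3,
                        wc_weight = 1, gu_weight = 0.8, max_window = 400) {
  stopifnot(length(window_sequence) == 1)
  seq <- rna_normalize(window_sequence)
  n <- nchar(seq)
  if (n > max_window) {
    stop("window of ", n, " nt exceeds max_window = ", max_window)
  }
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U"))
  codes[is.na(codes)] <- 0L
  res <- .nussinov_fold_cpp(as.integer(codes), as.integer(min_loop),
                            as.integer(round(wc_weight * 10)),
                            as.integer(round(gu_weight * 10)))
  pairs <- data.frame(i = as.integer(res$i), j = as.integer(res$j),
                      type = c("WC", "GU")[as.integer(res$type)])
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(sequence = seq, pairs = pairs,
                 weight = res$weight / 10, min_loop = min_loop),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("fold_result: ", nchar(x$sequence), " nt, ", nrow(x$pairs),
      " pairs, weight ", x$weight, "\n", sep = "")
  invisible(x)
}

#' Dot-bracket rendering of a fold
#'
#' @param fold a [fold_window()] result.
#' @return a single dot-bracket string.
#' @export
dot_bracket <- function(fold) {
  stopifnot(inherits(fold, "fold_result"))
  db <- rep(".", nchar(fold$sequence))
  db[fold$pairs$i] <- "("
  db[fold$pairs$j] <- ")"
  paste(db, collapse = "")
}

#' Fold an RNA window thermodynamically via ViennaRNA
#'
#' Runs the `RNAfold` command-line program (minimum free energy,
#' default parameters) and returns its structure under the same
#' `fold_result` contract as [fold_window()]. Thermodynamic folding
#' rewards helix stacking and is the default backend for precursor
#' evaluation; the maximum-pairing fold is the dependency-free
#' alternative.
#'
#' @inheritParams fold_window
#' @return a `fold_result` (pair weights use the [fold_window()]
#'   weighting so the two backends are comparable).
#' @export
fold_window_thermo <- function(window_sequence, min_loop = 3,
                               wc_weight = 1, gu_weight = 0.8,
                               max_window = 400) {
  stopifnot(length(window_sequence) == 1)
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold not found on PATH; use fold_window() instead")
  }
  seq <- rna_normalize(window_sequence)
  n <- nchar(seq)
  if (n > max_window) {
    stop("window of ", n, " nt exceeds max_window = ", max_window)
  }
  out <- system2("RNAfold", c("--noPS"), input = seq, stdout = TRUE)
  db <- sub("\\s.*$", "", out[2])
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      pi <- c(pi, stack[length(stack)])
      pj <- c(pj, k)
      stack <- stack[-length(stack)]
    }
  }
  bases <- strsplit(seq, "")[[1]]
  type <- ifelse(.PAIR_STATE[paste0(bases[pi], bases[pj])] == "GU",
                 "GU", "WC")
  pairs <- data.frame(i = pi, j = pj, type = unname(type))
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  weight <- sum(ifelse(pairs$type == "GU", gu_weight, wc_weight))
  structure(list(sequence = seq, pairs = pairs, weight = weight,
                 min_loop = min_loop),
            class = "fold_result")
}

# Partner vector: partner[k] is the paired position of k, NA if unpaired.
.fold_partners <- function(fold, n = nchar(fold$sequence)) {
  partner <- rep(NA_integer_, n)
  partner[fold$pairs$i] <- fold$pairs$j
  partner[fold$pairs$j] <- fold$pairs$i
  partner
}
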