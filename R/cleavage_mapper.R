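# RACE cleavage-site mapping. Clone endpoints from the two RACE
# chemistries are converted into positions on the miRNA 5'->3' axis and
# merged: "cleaved at the kth nucleotide" means the scission between the
# target bases pairing miRNA positions k and k+1, reported as k. A
# 5'-RLM clone's endpoint (first base of the 3' fragment) pairs k; a
# 3'-PPM clone's endpoint (last base of the 5' fragment) pairs k+1 and
# is normalized down by one, so both chemistries report the same
# scission identically.

#' Read a RACE clone table
#'
#' @param path TSV with columns `target_id`, `method` (RLM5 or PPM3),
#'   `endpoint` (0-based transcript coordinate), `count`.
#' @return data.frame of clones.
#' @export
read_race_clones <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_id", "method", "endpoint", "count")
  if (!all(need %in% names(df))) {
    stop("clone table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$method), c("RLM5", "PPM3"))
  if (length(bad)) stop("unknown RACE method(s): ", paste(bad, collapse = ", "))
  if (any(df$count < 1)) stop("clone counts must be >= 1")
  df
}

#' Map aligned target bases to miRNA positions
#'
#' Inverts the antiparallel duplex alignment of a validated site: each
#' aligned target base (0-based transcript coordinate) is mapped to the
#' miRNA position it pairs; gap columns are omitted.
#'
#' @param site a `duplex_alignment` with its transcript location filled
#'   (as returned by [scan_transcriptome()]).
#' @return named integer vector, names = transcript coordinates, values
#'   = miRNA positions.
#' @export
pairing_map <- function(site) {
  stopifnot(inherits(site, "duplex_alignment"))
  if (is.na(site$site_start)) {
    stop("alignment carries no transcript location; run scan_transcriptome ",
         "or set site_start")
  }
  cols <- site$columns
  ok <- !is.na(cols$mirna_pos) & !is.na(cols$target_pos)
  coords <- site$site_start + cols$target_pos[ok] - 1L
  setNames(as.integer(cols$mirna_pos[ok]), coords)
}

#' Convert RACE clone endpoints to miRNA positions
#'
#' @param endpoint 0-based transcript coordinate(s) of clone endpoints.
#' @param method "RLM5" or "PPM3", recycled along `endpoint`.
#' @param map a [pairing_map()].
#' @return integer vector of miRNA positions; `NA` for endpoints outside
#'   the site (unmapped) or normalizing below position 1.
#' @export
clone_to_mirna_position <- function(endpoint, method, map) {
  method <- rep_len(method, length(endpoint))
  pos <- unname(map[as.character(endpoint)])
  pos <- ifelse(method == "PPM3", pos - 1L, pos)
  pos[!is.na(pos) & pos < 1L] <- NA_integer_
  as.integer(pos)
}

#' Tally RACE clones into a cleavage profile
#'
#' Accumulates clone counts by normalized miRNA position and calls the
#' modal cleavage site. Ties are broken toward the canonical slicer
#' position (default 10), then toward the smaller position. Unmapped
#' clones are counted separately and reported in a message.
#'
#' @param clones data.frame with columns `target_id`, `method`,
#'   `endpoint`, `count`, all sharing one target.
#' @param site the validated site's `duplex_alignment` (with transcript
#'   location).
#' @param canonical tie-break position (default 10).
#' @return an object of class `cleavage_profile`: list with
#'   `target_id`, `tallies` (data.frame `position`, `count`),
#'   `modal_position` (NA if nothing mapped), `total_clones` (mapped)
#'   and `unmapped`.
#' @export
tally_cleavage <- function(clones, site, canonical = 10) {
  stopifnot(is.data.frame(clones),
            all(c("target_id", "method", "endpoint", "count") %in%
                  names(clones)))
  if (length(unique(clones$target_id)) > 1) {
    stop("clones must share a single target_id")
  }
  map <- pairing_map(site)
  pos <- clone_to_mirna_position(clones$endpoint, clones$method, map)
  mapped <- !is.na(pos)
  unmapped <- sum(clones$count[!mapped])
  if (unmapped > 0) {
    message(unmapped, " clone(s) with endpoints outside the site for ",
            clones$target_id[1])
  }
  if (!any(mapped)) {
    tallies <- data.frame(position = integer(0), count = numeric(0))
    modal <- NA_integer_
  } else {
    agg <- tapply(clones$count[mapped], pos[mapped], sum)
    tallies <- data.frame(position = as.integer(names(agg)),
                          count = as.numeric(agg))
    tallies <- tallies[order(tallies$position), , drop = FALSE]
    rownames(tallies) <- NULL
    top <- tallies$position[tallies$count == max(tallies$count)]
    modal <- if (canonical %in% top) as.integer(canonical) else min(top)
  }
  structure(list(target_id = clones$target_id[1], tallies = tallies,
                 modal_position = modal,
                 total_clones = sum(clones$count[mapped]),
                 unmapped = unmapped),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat("cleavage_profile for ", x$target_id, ": modal position ",
      x$modal_position, " (", x$total_clones, " mapped clones, ",
      x$unmapped, " unmapped)\n", sep = "")
  invisible(x)
}
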