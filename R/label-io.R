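## Label maps, in-silico digestion, label merging, inter-label statistics and
## CMAP-dialect reading/writing.
##
## Coordinates are 0-based half-open internally; the CMAP dialect on disk is
## 1-based (converted at the boundary).

#' Construct a label map
#'
#' A label map is the fundamental optical-mapping object: an ordered set of
#' nicking-enzyme recognition-site positions (labels) on a molecule, contig or
#' chromosome, together with the molecule length.
#'
#' @param id character identifier.
#' @param length molecule length in bp.
#' @param labels numeric vector of strictly increasing 0-based label positions.
#' @param meta optional named list (e.g. source name, arm orientation flag).
#' @return an object of class `label_map`.
#' @export
label_map <- function(id, length, labels = numeric(0), meta = list()) {
  labels <- as.numeric(labels)
  stopifnot(is.character(id), length(id) == 1L, length >= 0)
  if (length(labels)) {
    if (any(labels < 0) || any(labels >= length)) {
      stop("label positions must lie in [0, length)")
    }
    if (is.unsorted(labels, strictly = TRUE)) {
      stop("label positions must be strictly increasing")
    }
  }
  structure(
    list(id = id, length = as.numeric(length), labels = labels, meta = meta),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map %s: %d labels over %.0f bp>\n",
              x$id, length(x$labels), x$length))
  invisible(x)
}

#' Flip a label map into the opposite orientation
#'
#' Positions become `length - pos`, order reversed. Used to put q-arm termini
#' and minus-orientation queries into a common terminus-distal frame.
#'
#' @param map a [label_map()].
#' @return a `label_map` on the flipped coordinates.
#' @export
flip_map <- function(map) {
  label_map(map$id, map$length, rev(map$length - map$labels), map$meta)
}

#' In-silico digestion: motif occurrences on both strands
#'
#' Returns the 0-based start positions of every occurrence of `motif` and of
#' its reverse complement on the forward strand, sorted and deduplicated.
#' IUPAC degeneracy in the motif is honoured (expanded to character classes,
#' no mismatches).
#'
#' @param sequence character scalar DNA sequence.
#' @param motif IUPAC motif string, length >= 4 (default the Nt.BspQI-like
#'   7-mer `GCTCTTC`, whose density on random sequence matches the ~8 kb mean
#'   inter-label spacing regime of human nicking-enzyme maps).
#' @return numeric vector of 0-based positions.
#' @export
insilico_digest <- function(sequence, motif = "GCTCTTC") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  stopifnot(is.character(motif), nchar(motif) >= 4L)
  if (!all(strsplit(toupper(motif), "")[[1]] %in%
             names(Biostrings::IUPAC_CODE_MAP))) {
    stop("motif contains non-IUPAC symbols")
  }
  if (nchar(sequence) < nchar(motif)) return(numeric(0))
  subject <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(toupper(motif)), subject, fixed = FALSE))
  rcm <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(motif)))
  rev <- Biostrings::start(Biostrings::matchPattern(rcm, subject, fixed = FALSE))
  sort(unique(c(fwd, rev))) - 1
}

#' Digest a sequence into a label map
#'
#' Convenience wrapper: digestion followed by resolution merging.
#'
#' @inheritParams insilico_digest
#' @param id map identifier.
#' @param merge_distance bp; labels closer than this are merged to their
#'   centroid (see [merge_labels()]). Use 0 to disable.
#' @return a [label_map()].
#' @export
digest_map <- function(sequence, motif = "GCTCTTC", id = "map",
                       merge_distance = 450) {
  labs <- insilico_digest(sequence, motif)
  if (merge_distance > 0) labs <- merge_labels(labs, merge_distance)
  label_map(id, nchar(sequence), labs)
}

#' Merge labels closer than a resolution limit
#'
#' Transitive clusters of labels whose adjacent spacing is at most
#' `merge_distance` are replaced by the cluster centroid (rounded half up to an
#' integer bp). Mirrors the optical-map pre-alignment step that merges labels
#' closer than the imaging resolution (default 450 bp).
#'
#' The operation is idempotent: merged centroids are always more than
#' `merge_distance` apart.
#'
#' @param labels sorted numeric label positions.
#' @param merge_distance bp.
#' @return sorted numeric vector, no two entries within `merge_distance`.
#' @export
merge_labels <- function(labels, merge_distance = 450) {
  if (length(labels) <= 1L) return(as.numeric(labels))
  if (is.unsorted(labels)) stop("labels must be sorted")
  labels <- as.numeric(labels)
  grp <- cumsum(c(1, diff(labels) > merge_distance))
  as.numeric(round_half_up(tapply(labels, grp, mean)))
}

#' Inter-label distance statistics
#'
#' Mean and population standard deviation of adjacent-label distances,
#' excluding any adjacent pair whose spanned interval intersects a reference
#' gap ("N") interval. These statistics feed the extension/missing length
#' threshold (mean + k standard deviations).
#'
#' @param map a [label_map()].
#' @param gaps optional data.frame with columns `start`, `end` (0-based
#'   half-open) of gap intervals on the same coordinates.
#' @return list with `mean_interval` and `sd_interval` (kb), `n_intervals`,
#'   `excluded_gap_intervals`.
#' @export
interlabel_stats <- function(map, gaps = NULL) {
  labs <- map$labels
  if (length(labs) < 2L) stop("need at least 2 labels")
  d <- diff(labs)
  keep <- rep(TRUE, length(d))
  if (!is.null(gaps) && nrow(gaps)) {
    for (i in seq_along(d)) {
      keep[i] <- !any(overlaps_halfopen(labs[i], labs[i + 1L],
                                        gaps$start, gaps$end))
    }
  }
  d_use <- d[keep]
  if (length(d_use) < 2L) stop("fewer than 2 usable adjacent-label pairs")
  mu <- mean(d_use)
  pop_sd <- sqrt(mean((d_use - mu)^2))
  list(
    mean_interval = mu / 1000,
    sd_interval = pop_sd / 1000,
    n_intervals = length(d_use),
    excluded_gap_intervals = sum(!keep)
  )
}

#' Write label maps in a CMAP-dialect text format
#'
#' Tab-separated dialect, 1-based positions. Each map emits one row per label
#' (channel 1) plus a terminal channel-0 row carrying the map length, so
#' label-free maps round-trip too.
#'
#' @param maps list of [label_map()] objects.
#' @param path output file.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# CMAP dialect; positions 1-based",
    "#h\tCMapID\tContigLength\tNumLabels\tLabelID\tChannel\tPosition"
  ), con)
  for (m in maps) {
    n <- length(m$labels)
    if (n) {
      writeLines(sprintf("%s\t%.0f\t%d\t%d\t1\t%.0f",
                         m$id, m$length, n, seq_len(n), m$labels + 1), con)
    }
    writeLines(sprintf("%s\t%.0f\t%d\t%d\t0\t%.0f",
                       m$id, m$length, n, n + 1L, m$length), con)
  }
  invisible(path)
}

#' Read label maps written by [write_cmap()]
#'
#' @param path input file.
#' @return list of [label_map()] objects.
#' @export
read_cmap <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  maps <- list()
  cur_id <- NULL
  cur_len <- NULL
  cur_labels <- numeric(0)
  flush_map <- function() {
    if (!is.null(cur_id)) {
      maps[[length(maps) + 1L]] <<- label_map(cur_id, cur_len, cur_labels)
    }
  }
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L) {
      stop(sprintf("malformed CMAP row at line %d: expected 6 fields", ln))
    }
    pos <- suppressWarnings(as.numeric(f[6]))
    len <- suppressWarnings(as.numeric(f[2]))
    chan <- f[5]
    if (is.na(pos) || is.na(len)) {
      stop(sprintf("malformed CMAP row at line %d: non-numeric field", ln))
    }
    if (!identical(f[1], cur_id)) {
      flush_map()
      cur_id <- f[1]
      cur_len <- len
      cur_labels <- numeric(0)
    }
    if (chan == "1") {
      p0 <- pos - 1
      if (length(cur_labels) && p0 <= cur_labels[length(cur_labels)]) {
        stop(sprintf("non-monotone label position at line %d (map %s)",
                     ln, cur_id))
      }
      cur_labels <- c(cur_labels, p0)
    }
  }
  flush_map()
  maps
}
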