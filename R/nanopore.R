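## Long-read validation of predicted chimeric extension sequences: exact-k-mer
## dotplots, collinear chaining, tandem-repeat unit/copy estimation from
## off-diagonal structure, and extension coverage verdicts.

#' Build a predicted chimeric extension sequence
#'
#' For a category-1 extension call, the predicted chromosome end is the
#' homologous origin segment joined to the reference terminal segment with an
#' estimated gap of N characters, all in terminus-distal order (position 0 is
#' the predicted chromosome tip). Category-2 calls have no known origin and
#' cannot be predicted.
#'
#' @param reference named character vector of chromosome sequences.
#' @param call a category-1 `terminus_call` (see [classify_extension()]).
#' @param gap_len gap size in bp; default the extension length minus the
#'   origin matched span, floored at 0.
#' @param terminal_len bp of the reference terminal segment to include.
#' @return list of class `predicted_extension`: `sequence`, `origin_len`,
#'   `gap_len`, `terminal_len`, `provenance`.
#' @export
build_prediction <- function(reference, call, gap_len = NULL,
                             terminal_len = 1e5) {
  if (is.na(call$category) || call$category != 1L || !length(call$origins)) {
    stop("no predicted sequence: call is not a category-1 extension")
  }
  org <- call$origins[[1]]
  don <- reference[[org$chrom]]
  dlen <- nchar(don)
  span <- c(floor(org$span[1]), ceiling(org$span[2]))
  seg <- substr(don, span[1] + 1, span[2])
  ## orient terminus-distally: a q-arm origin reads toward the tip rightwards,
  ## so its distal-first form is the reverse complement
  if (org$arm == "q") seg <- revcomp(seg)
  if (is.null(gap_len)) {
    gap_len <- max(0, round(call$extension_len - nchar(seg)))
  }
  term_len <- min(terminal_len, nchar(reference[[call$chrom]]))
  term <- terminal_segment(reference[[call$chrom]], call$arm, term_len)
  seqc <- paste0(seg, strrep("N", gap_len), term)
  structure(list(sequence = seqc, origin_len = nchar(seg),
                 gap_len = gap_len, terminal_len = term_len,
                 provenance = list(terminus = paste0(call$chrom, call$arm),
                                   origin = org)),
            class = "predicted_extension")
}

kmer_starts <- function(seqc, k) {
  n <- nchar(seqc)
  if (n < k) return(character(0))
  substring(seqc, 1:(n - k + 1L), k:n)
}

#' Exact shared k-mer dotplot
#'
#' All exact shared k-mers between `seq_x` and `seq_y`, reported as 0-based
#' `(x, y)` start pairs with orientation. Reverse-orientation matches are
#' found through reverse-complement k-mers and reported with `y` on forward
#' coordinates. K-mers containing N never match.
#'
#' @param seq_x,seq_y character sequences.
#' @param k k-mer size (>= 8).
#' @return data.frame `x`, `y`, `orient` (`"+"`/`"-"`); empty when either
#'   sequence is shorter than `k`.
#' @export
kmer_dotplot <- function(seq_x, seq_y, k = 16L) {
  stopifnot(k >= 8L)
  empty <- data.frame(x = numeric(0), y = numeric(0), orient = character(0))
  if (nchar(seq_x) < k || nchar(seq_y) < k) return(empty)
  xk <- kmer_starts(seq_x, k)
  yk <- kmer_starts(seq_y, k)
  ok_x <- !grepl("N", xk, fixed = TRUE)
  xdf <- data.frame(kmer = xk[ok_x], x = which(ok_x) - 1L)
  match_side <- function(ydf, orient) {
    m <- merge(xdf, ydf, by = "kmer")
    if (!nrow(m)) return(empty)
    data.frame(x = m$x, y = m$y, orient = orient)
  }
  ok_y <- !grepl("N", yk, fixed = TRUE)
  fwd <- match_side(data.frame(kmer = yk[ok_y], y = which(ok_y) - 1L), "+")
  yrc <- kmer_starts(revcomp(seq_y), k)
  ok_r <- !grepl("N", yrc, fixed = TRUE)
  ## k-mer at 0-based p of revcomp(y) covers forward y [n - p - k, n - p)
  rev <- match_side(
    data.frame(kmer = yrc[ok_r], y = nchar(seq_y) - (which(ok_r) - 1L) - k),
    "-")
  out <- rbind(fwd, rev)
  out[order(out$orient, out$x, out$y), , drop = FALSE]
}

#' Chain dotplot matches into collinear segments
#'
#' Greedy per-diagonal chaining: points sharing a diagonal (y - x for forward,
#' y + x for reverse matches) within `diag_tol` are chained while consecutive
#' x gaps stay within `max_gap`; segments spanning less than `min_len` are
#' dropped. This formalises reading a dotplot by eye.
#'
#' @param points data.frame from [kmer_dotplot()].
#' @param k the k-mer size used (segment ends are inclusive of the k-mer).
#' @param max_gap bp; maximum x gap inside a chain.
#' @param min_len bp; minimum segment span on x.
#' @param diag_tol bp; diagonal drift tolerated inside one chain.
#' @return data.frame `x0,x1,y0,y1,orient,diag,n_points` (coordinates 0-based,
#'   ends exclusive).
#' @export
chain_matches <- function(points, k = 16L, max_gap = 500, min_len = 1000,
                          diag_tol = 100) {
  empty <- data.frame(x0 = numeric(0), x1 = numeric(0), y0 = numeric(0),
                      y1 = numeric(0), orient = character(0),
                      diag = numeric(0), n_points = integer(0))
  if (is.null(points) || !nrow(points)) return(empty)
  segs <- list()
  for (orient in unique(points$orient)) {
    p <- points[points$orient == orient, , drop = FALSE]
    p$diag <- if (orient == "+") p$y - p$x else p$y + p$x
    p <- p[order(p$diag, p$x), ]
    brk <- c(TRUE, diff(p$diag) > diag_tol | diff(p$x) > max_gap)
    grp <- cumsum(brk)
    for (g in split(seq_len(nrow(p)), grp)) {
      xs <- p$x[g]
      ys <- p$y[g]
      segs[[length(segs) + 1L]] <- data.frame(
        x0 = min(xs), x1 = max(xs) + k,
        y0 = min(ys), y1 = max(ys) + k,
        orient = orient, diag = mean(p$diag[g]), n_points = length(g))
    }
  }
  out <- do.call(rbind, segs)
  out <- out[out$x1 - out$x0 >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Approximate greatest common divisor of chain offsets: try integer
## fractions of the smallest offset, require every offset within `tol` of an
## integer multiple, refine by averaging.
approx_gcd <- function(offsets, tol = 0.05, max_div = 6L) {
  offsets <- sort(offsets)
  for (d in seq_len(max_div)) {
    u <- offsets[1] / d
    mult <- round(offsets / u)
    if (all(mult >= 1) && all(abs(offsets - mult * u) <= tol * offsets)) {
      return(mean(offsets / mult))
    }
  }
  offsets[1]
}

#' Estimate tandem repeat unit length and copy number from a terminal window
#'
#' Self-dotplot of the terminal window; the offsets of off-main-diagonal
#' forward chains are collected and their approximate greatest common divisor
#' (5% tolerance) is the repeat unit length; the copy count is
#' `1 + max(offset) / unit`, rounded. A window with no off-diagonal chains is
#' non-repetitive (`copies = 1`, `unit_len = 0`). This is how a terminal
#' tandem expansion (e.g. four copies of an 11 kb unit) is read off a long
#' read spanning the chromosome tip.
#'
#' Only terminus-anchored chains count: a terminal tandem array abuts the
#' chromosome tip, so its off-diagonal chains run all the way to the window
#' end, whereas repeats that merely sit inside the window (e.g. interspersed
#' subtelomeric duplication copies) stop short and are ignored.
#'
#' @param seqc read (or window) sequence; the distal terminus is at the read
#'   end.
#' @param window bp of the terminal window to analyse (default: whole
#'   sequence; must be >= 2 kb).
#' @param k k-mer size.
#' @param max_gap,min_len,diag_tol chaining parameters, see
#'   [chain_matches()].
#' @param anchor_margin bp; a chain must reach within this margin of the
#'   window end to count as terminus-anchored.
#' @return list of class `tandem_estimate`: `unit_len` (bp), `copies`,
#'   `support` (number of off-diagonal chains), `offsets`.
#' @export
estimate_tandem <- function(seqc, window = nchar(seqc), k = 16L,
                            max_gap = 500, min_len = 1000, diag_tol = 100,
                            anchor_margin = 1000) {
  stopifnot(window >= 2000)
  n <- nchar(seqc)
  w <- substr(seqc, max(1L, n - window + 1L), n)
  pts <- kmer_dotplot(w, w, k)
  ch <- chain_matches(pts, k = k, max_gap = max_gap, min_len = min_len,
                      diag_tol = diag_tol)
  off <- ch[ch$orient == "+" & ch$diag > diag_tol &
              ch$y1 >= nchar(w) - anchor_margin, , drop = FALSE]
  if (!nrow(off)) {
    return(structure(list(unit_len = 0, copies = 1L, support = 0L,
                          offsets = numeric(0)),
                     class = "tandem_estimate"))
  }
  ## deduplicate near-equal offsets (the symmetric dotplot reports each once
  ## per diagonal already; cluster residual jitter)
  offs <- sort(off$diag)
  grp <- cumsum(c(1, diff(offs) > 0.05 * offs[-length(offs)] + diag_tol))
  offs <- as.numeric(tapply(offs, grp, mean))
  unit <- approx_gcd(offs)
  copies <- 1L + as.integer(round(max(offs) / unit))
  structure(list(unit_len = unit, copies = copies, support = nrow(off),
                 offsets = offs),
            class = "tandem_estimate")
}

#' @export
print.tandem_estimate <- function(x, ...) {
  cat(sprintf("<tandem estimate: %d copies of ~%.0f bp (%d chains)>\n",
              x$copies, x$unit_len, x$support))
  invisible(x)
}

#' Validate a predicted extension against a long read
#'
#' Chains the read against the predicted chimeric sequence and measures the
#' fraction of the origin (extension) part covered by chained segments. The
#' verdict is confirmed when coverage reaches `min_extension_coverage`. An
#' internal uncovered run longer than `deletion_threshold` (flanked by
#' coverage on both sides) is reported separately: the extension is real but
#' carries a large internal deletion relative to the prediction.
#'
#' @param read read sequence.
#' @param prediction a [build_prediction()] result.
#' @param k,max_gap,min_len,diag_tol dotplot/chaining parameters.
#' @param min_extension_coverage fraction of the origin part that must be
#'   covered.
#' @param deletion_threshold bp; internal uncovered run reported as a
#'   deletion.
#' @return list: `confirmed`, `covered_fraction`, `internal_deletion`
#'   (logical), `deletion_bp`, `segments`.
#' @export
validate_extension <- function(read, prediction, k = 16L, max_gap = 500,
                               min_len = 1000, diag_tol = 100,
                               min_extension_coverage = 0.5,
                               deletion_threshold = 5000) {
  pts <- kmer_dotplot(prediction$sequence, read, k)
  ch <- chain_matches(pts, k = k, max_gap = max_gap, min_len = min_len,
                      diag_tol = diag_tol)
  olen <- prediction$origin_len
  if (!nrow(ch) || olen == 0) {
    return(list(confirmed = FALSE, covered_fraction = 0,
                internal_deletion = FALSE, deletion_bp = 0, segments = ch))
  }
  keep <- ch$x0 < olen & ch$x1 > 0
  if (!any(keep)) {
    return(list(confirmed = FALSE, covered_fraction = 0,
                internal_deletion = FALSE, deletion_bp = 0, segments = ch))
  }
  ir <- IRanges::IRanges(start = pmax(1, floor(ch$x0[keep]) + 1L),
                         end = pmin(olen, ceiling(ch$x1[keep])))
  cov <- IRanges::reduce(ir)
  covered <- sum(IRanges::width(cov))
  frac <- covered / olen
  del_bp <- 0
  if (length(cov) > 1L) {
    gaps <- IRanges::gaps(cov, start = 1L, end = olen)
    internal <- IRanges::start(gaps) > 1L & IRanges::end(gaps) < olen
    if (any(internal)) del_bp <- max(IRanges::width(gaps)[internal])
  }
  list(confirmed = frac >= min_extension_coverage,
       covered_fraction = frac,
       internal_deletion = del_bp > deletion_threshold,
       deletion_bp = del_bp,
       segments = ch)
}

#' Base-graphics dotplot of chained segments
#'
#' @param segments data.frame from [chain_matches()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_dotplot <- function(segments, ...) {
  if (!nrow(segments)) {
    graphics::plot(0, 0, type = "n", xlab = "x", ylab = "y", ...)
    return(invisible(NULL))
  }
  graphics::plot(NA, xlim = range(c(segments$x0, segments$x1)),
                 ylim = range(c(segments$y0, segments$y1)),
                 xlab = "prediction (bp)", ylab = "read (bp)", ...)
  fwd <- segments$orient == "+"
  graphics::segments(segments$x0[fwd], segments$y0[fwd],
                     segments$x1[fwd], segments$y1[fwd], col = "darkgreen")
  graphics::segments(segments$x0[!fwd], segments$y1[!fwd],
                     segments$x1[!fwd], segments$y0[!fwd], col = "red")
  invisible(NULL)
}
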