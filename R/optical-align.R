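## Dynamic-programming alignment of label maps with a sizing-error likelihood
## score, end-open (endoutlier) support, multiple matches per reference, and a
## brute-force enumeration oracle for small instances.

#' Alignment parameters
#'
#' Parameters of the label-map aligner. The score of a matched interval pair is
#' `m - (q_len - r_len)^2 / (2 * sigma^2)` with
#' `sigma^2 = sd_fixed^2 + (sr * r_len)^2`; skipped interior labels are
#' penalised per label. An alignment's score is the sum of interval scores over
#' consecutive matched pairs minus penalties; a single matched label spans no
#' interval and contributes 0, so `min_labels` defaults to 3 to avoid
#' degenerate hits.
#'
#' @param m match bonus per matched interval (score units).
#' @param sd_fixed fixed sizing SD in bp. Defaults to 1 kb: a zero fixed SD
#'   would make short intervals infinitely precise.
#' @param sr relative sizing error (fraction of the reference interval).
#' @param fp_penalty score penalty per unmatched interior query label.
#' @param fn_penalty score penalty per skipped interior reference label.
#' @param max_skip maximum label-index step between consecutive matched pairs
#'   on either map (look-back depth of the DP).
#' @param max_matches maximum alignments reported per reference.
#' @param min_labels minimum matched labels for an alignment to be reported.
#' @param min_score minimum score for an alignment to be reported.
#' @param mode `"endoutlier"` (unmatched terminal query runs free) or `"fit"`
#'   (every unmatched query label penalised).
#' @return a list of class `alignment_params`.
#' @export
alignment_params <- function(m = 3, sd_fixed = 1000, sr = 0.01,
                             fp_penalty = m / 2, fn_penalty = m / 2,
                             max_skip = 12L, max_matches = 5L,
                             min_labels = 3L, min_score = 0,
                             mode = c("endoutlier", "fit")) {
  mode <- match.arg(mode)
  stopifnot(fp_penalty >= 0, fn_penalty >= 0, max_skip >= 1, max_matches >= 1,
            min_labels >= 1, sd_fixed > 0 || sr > 0)
  structure(list(m = m, sd_fixed = sd_fixed, sr = sr,
                 fp_penalty = fp_penalty, fn_penalty = fn_penalty,
                 max_skip = as.integer(max_skip),
                 max_matches = as.integer(max_matches),
                 min_labels = as.integer(min_labels),
                 min_score = min_score, mode = mode),
            class = "alignment_params")
}

#' Sizing-error likelihood score of one matched interval pair
#'
#' `m - (q_len - r_len)^2 / (2 * sigma^2)` with
#' `sigma^2 = sd_fixed^2 + (sr * r_len)^2`. Maximal at `q_len == r_len` and
#' symmetric about `r_len` in the query length.
#'
#' @param q_len,r_len query/reference interval lengths in bp (> 0). Vectorised.
#' @param params an [alignment_params()].
#' @return numeric score(s).
#' @export
interval_score <- function(q_len, r_len, params = alignment_params()) {
  if (any(q_len <= 0) || any(r_len <= 0)) {
    stop("interval lengths must be positive")
  }
  sig2 <- params$sd_fixed^2 + (params$sr * r_len)^2
  params$m - (q_len - r_len)^2 / (2 * sig2)
}

## Score a fully specified monotone pairing; shared by the brute-force oracle
## and by score recomputation, and kept formula-identical to the C++ DP.
score_pairing <- function(q_pos, r_pos, qi, ri, n_query, params) {
  k <- length(qi)
  sc <- 0
  if (k > 1L) {
    ql <- diff(q_pos[qi])
    rl <- diff(r_pos[ri])
    sc <- sum(interval_score(ql, rl, params)) -
      params$fp_penalty * sum(diff(qi) - 1L) -
      params$fn_penalty * sum(diff(ri) - 1L)
  }
  if (params$mode == "fit") {
    sc <- sc - params$fp_penalty * ((qi[1] - 1L) + (n_query - qi[k]))
  }
  sc
}

new_label_alignment <- function(query_id, ref_id, orientation, pairs,
                                q_pos, r_pos, qlen, n_query_labels, score,
                                mode) {
  structure(list(
    query_id = query_id, ref_id = ref_id, orientation = orientation,
    pairs = pairs,                    # k x 2 matrix: (query idx, ref idx),
                                      # query indices in orientation-normalised
                                      # (flipped for "-") label order, 1-based
    q_pos = q_pos, r_pos = r_pos,     # matched label positions (bp)
    qlen = qlen, n_query_labels = n_query_labels,
    score = score, mode = mode,
    query_span = range(q_pos), ref_span = range(r_pos)
  ), class = "label_alignment")
}

#' @export
print.label_alignment <- function(x, ...) {
  cat(sprintf("<alignment %s ~ %s (%s): %d pairs, score %.3f, ref %0.f-%0.f>\n",
              x$query_id, x$ref_id, x$orientation, nrow(x$pairs), x$score,
              x$ref_span[1], x$ref_span[2]))
  invisible(x)
}

#' Recompute an alignment's score from its pairs
#'
#' Every reported alignment's score is re-derivable from its matched pairs and
#' the parameters; used as an integrity check.
#'
#' @param aln a `label_alignment`.
#' @param params the [alignment_params()] it was computed with.
#' @return numeric score.
#' @export
recompute_alignment_score <- function(aln, params) {
  score_pairing(aln$all_q_pos, aln$all_r_pos,
                aln$pairs[, 1L], aln$pairs[, 2L],
                n_query = aln$n_query_labels, params = params)
}

#' Align a query label map against one or more reference maps
#'
#' Dynamic programming over label pairs, both orientations, allowing up to
#' `max_skip` consecutive unmatched labels on either side (each interior skip
#' penalised). In endoutlier mode unaligned terminal runs on the query are
#' unpenalised. Up to `max_matches` alignments are reported per reference,
#' ordered by score; secondary matches sharing more than half of their matched
#' reference labels with a better-scoring match are suppressed.
#'
#' @param query a [label_map()] with at least `min_labels` labels.
#' @param refs a [label_map()] or list of them.
#' @param params an [alignment_params()].
#' @return list of `label_alignment` objects sorted by decreasing score
#'   (possibly empty).
#' @export
align_label_maps <- function(query, refs, params = alignment_params()) {
  if (inherits(refs, "label_map")) refs <- list(refs)
  if (length(query$labels) < params$min_labels) return(list())
  out <- list()
  for (ref in refs) {
    out <- c(out, align_one_ref(query, ref, params))
  }
  out[order(-vapply(out, `[[`, numeric(1), "score"))]
}

## Queries up to this many labels get the exact min-labels-layered DP and
## full multi-match candidate enumeration (the regime of extension label maps
## and of the enumeration oracle). Longer queries -- whole contigs -- use the
## single-layer recursion and report the best path per orientation: their
## optima have far more pairs than min_labels, and their secondary matches
## arise from short homologous stretches that are re-queried as short maps.
.full_enum_max_labels <- 32L

align_one_ref <- function(query, ref, params, max_candidates = 400L) {
  if (length(ref$labels) < 1L) return(list())
  layered <- length(query$labels) <= .full_enum_max_labels
  cands <- list()
  for (orient in c("+", "-")) {
    qm <- if (orient == "+") query else flip_map(query)
    q <- qm$labels
    r <- ref$labels
    dp <- dp_align_core(q, r, params$m, params$sd_fixed, params$sr,
                        params$fp_penalty, params$fn_penalty,
                        params$max_skip, params$mode == "endoutlier",
                        if (layered) params$min_labels else 1L)
    n <- length(q)
    dp$n <- n
    dp$nr <- length(r)
    tot <- dp$S
    if (params$mode == "fit") {
      tot <- tot - params$fp_penalty * (n - matrix(seq_len(n), n, length(r)))
    }
    ord <- order(tot, decreasing = TRUE)
    ord <- ord[is.finite(tot[ord]) & tot[ord] >= params$min_score]
    ord <- head(ord, if (layered) max_candidates else 1L)
    for (cell in ord) {
      i <- (cell - 1L) %% n + 1L
      j <- (cell - 1L) %/% n + 1L
      path <- traceback_path(dp, i, j)
      if (nrow(path) < params$min_labels) next
      cands[[length(cands) + 1L]] <- list(
        orient = orient, pairs = path, score = tot[cell], q = q, r = r)
    }
  }
  if (!length(cands)) return(list())
  cands <- cands[order(-vapply(cands, `[[`, numeric(1), "score"))]
  kept <- list()
  kept_ref_labels <- list()
  for (cn in cands) {
    if (length(kept) >= params$max_matches) break
    rl <- cn$pairs[, 2L]
    dup <- FALSE
    for (prev in kept_ref_labels) {
      if (length(intersect(rl, prev)) > 0.5 * length(rl)) {
        dup <- TRUE
        break
      }
    }
    if (dup) next
    aln <- new_label_alignment(
      query_id = query$id, ref_id = ref$id, orientation = cn$orient,
      pairs = cn$pairs,
      q_pos = cn$q[cn$pairs[, 1L]], r_pos = cn$r[cn$pairs[, 2L]],
      qlen = query$length, n_query_labels = length(cn$q),
      score = cn$score, mode = params$mode)
    aln$all_q_pos <- cn$q
    aln$all_r_pos <- cn$r
    kept[[length(kept) + 1L]] <- aln
    kept_ref_labels[[length(kept_ref_labels) + 1L]] <- rl
  }
  kept
}

## Walk the layered pointer arrays back from the top layer at cell (i, j).
## The C++ arrays are laid out [t * n * nr + i * nr + j], all 0-based.
traceback_path <- function(dp, i, j) {
  off <- function(t, i, j) t * dp$n * dp$nr + (i - 1L) * dp$nr + (j - 1L) + 1L
  t <- dp$L - 1L
  qi <- integer(0)
  ri <- integer(0)
  repeat {
    qi <- c(i, qi)
    ri <- c(j, ri)
    o <- off(t, i, j)
    pi <- dp$Pi[o] + 1L   # -1 marks path start
    if (pi == 0L) break
    pj <- dp$Pj[o] + 1L
    t <- dp$Pt[o]
    i <- pi
    j <- pj
  }
  cbind(qi, ri, deparse.level = 0)
}

#' Brute-force alignment oracle
#'
#' Exhaustively enumerates all monotone pairings of query to reference labels
#' (both orientations, honouring `max_skip` and `min_labels`) and scores each
#' exactly as [align_label_maps()] does. Intended as an independent test oracle
#' for small instances.
#'
#' @param query,ref [label_map()]s with at most 10 labels each.
#' @param params an [alignment_params()].
#' @return the best-scoring `label_alignment`, or `NULL` when no pairing meets
#'   `min_labels`.
#' @export
brute_force_align <- function(query, ref, params = alignment_params()) {
  nq <- length(query$labels)
  nr <- length(ref$labels)
  if (nq > 10L || nr > 10L) stop("brute force is limited to <= 10 labels")
  if (nq < 1L || nr < 1L) return(NULL)
  best <- NULL
  r <- ref$labels
  for (orient in c("+", "-")) {
    qm <- if (orient == "+") query else flip_map(query)
    q <- qm$labels
    for (k in seq.int(max(1L, params$min_labels), min(nq, nr))) {
      qs <- if (k == nq) matrix(seq_len(nq)) else utils::combn(nq, k)
      rs <- if (k == nr) matrix(seq_len(nr)) else utils::combn(nr, k)
      for (a in seq_len(ncol(qs))) {
        qi <- qs[, a]
        if (k > 1L && any(diff(qi) > params$max_skip)) next
        for (b in seq_len(ncol(rs))) {
          ri <- rs[, b]
          if (k > 1L && any(diff(ri) > params$max_skip)) next
          sc <- score_pairing(q, r, qi, ri, nq, params)
          if (is.null(best) || sc > best$score) {
            best <- list(score = sc, qi = qi, ri = ri, orient = orient, q = q)
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  aln <- new_label_alignment(
    query_id = query$id, ref_id = ref$id, orientation = best$orient,
    pairs = cbind(best$qi, best$ri, deparse.level = 0),
    q_pos = best$q[best$qi], r_pos = r[best$ri],
    qlen = query$length, n_query_labels = nq,
    score = best$score, mode = params$mode)
  aln$all_q_pos <- best$q
  aln$all_r_pos <- r
  aln
}

#' Write alignments in an XMAP-dialect text format
#'
#' Tab-separated; pairs serialised as a `(q,r)(q,r)...` string; scores to four
#' decimals.
#'
#' @param alignments list of `label_alignment` objects.
#' @param path output file.
#' @export
write_xmap <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# XMAP dialect",
    "#h\tAlnID\tQryID\tRefID\tOrientation\tScore\tQryLen\tNQryLabels\tPairs"
  ), con)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    pairs <- paste(sprintf("(%d,%d)", a$pairs[, 1L], a$pairs[, 2L]),
                   collapse = "")
    writeLines(sprintf("%d\t%s\t%s\t%s\t%.4f\t%.0f\t%d\t%s",
                       i, a$query_id, a$ref_id, a$orientation, a$score,
                       a$qlen, a$n_query_labels, pairs), con)
  }
  invisible(path)
}

#' Read alignments written by [write_xmap()]
#'
#' Round-trips pairs, orientation and score (to four decimals). Label
#' positions are not stored in the XMAP dialect; returned alignments carry
#' pairs and metadata only.
#'
#' @param path input file.
#' @return list of `label_alignment` objects.
#' @export
read_xmap <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  out <- list()
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 8L) {
      stop(sprintf("malformed XMAP row at line %d: expected 8 fields", ln))
    }
    toks <- regmatches(f[8], gregexpr("\\((\\d+),(\\d+)\\)", f[8]))[[1]]
    if (!length(toks)) stop(sprintf("malformed pair list at line %d", ln))
    qi <- as.integer(sub("\\((\\d+),.*", "\\1", toks))
    ri <- as.integer(sub(".*,(\\d+)\\)", "\\1", toks))
    score <- suppressWarnings(as.numeric(f[5]))
    if (is.na(score)) stop(sprintf("malformed score at line %d", ln))
    a <- structure(list(
      query_id = f[2], ref_id = f[3], orientation = f[4],
      pairs = cbind(qi, ri, deparse.level = 0),
      q_pos = NULL, r_pos = NULL,
      qlen = as.numeric(f[6]), n_query_labels = as.integer(f[7]),
      score = score, mode = NA_character_,
      query_span = NULL, ref_span = NULL
    ), class = "label_alignment")
    out[[length(out) + 1L]] <- a
  }
  out
}
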