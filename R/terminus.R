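## Terminus anchoring, extension/missing calling against the inter-label
## distance threshold, category 1/2 origin classification, trio inheritance
## and diploid-terminus detection.

#' Extension/missing length threshold from inter-label statistics
#'
#' `threshold = mean + k * sd` of the adjacent-label distance distribution
#' (kb). With the human nicking-map statistics (mean 8.2 kb, SD 8.3 kb, k = 3)
#' this gives the 33.1 kb threshold used to call terminal extension or missing
#' sequence: shorter discrepancies are indistinguishable from ordinary label
#' spacing.
#'
#' @param stats list with `mean_interval` and `sd_interval` in kb
#'   (see [interlabel_stats()]).
#' @param k SD multiplier.
#' @return list of class `threshold_model` with `mean_interval`,
#'   `sd_interval`, `k`, `threshold` (kb, unrounded), `threshold_reported`
#'   (kb, rounded to 0.1).
#' @export
compute_threshold <- function(stats, k = 3) {
  thr <- stats$mean_interval + k * stats$sd_interval
  structure(list(mean_interval = stats$mean_interval,
                 sd_interval = stats$sd_interval, k = k,
                 threshold = thr,
                 threshold_reported = round(thr, 1)),
            class = "threshold_model")
}

## distal extreme of an alignment's matched reference labels for an arm
distal_index <- function(aln, arm) {
  if (arm == "q") which.max(aln$r_pos) else which.min(aln$r_pos)
}

#' Anchor a terminus to its best contig alignment
#'
#' Among alignments to the arm's terminal window, contigs reaching the most
#' distal aligned reference label win; ties are broken by alignment score,
#' then by longer aligned reference span, then by contig id. Distality
#' dominates score: a weaker alignment reaching closer to the chromosome end
#' anchors the terminus.
#'
#' Because distality outranks score, candidates must first clear a
#' per-interval quality gate (`anchor_quality * m`), so that a chance
#' collinearity of a few labels near the tip cannot out-anchor a genuine
#' full-length alignment (production aligners filter such hits by p-value).
#'
#' @param alignments list of `label_alignment`s (any references).
#' @param chrom reference chromosome id.
#' @param arm `"p"` or `"q"`.
#' @param ref_len reference chromosome length (bp).
#' @param terminal_window bp; only alignments whose reference span intersects
#'   the arm's terminal window are candidates.
#' @param params [alignment_params()] the alignments were computed with
#'   (supplies the match bonus for the quality gate).
#' @param anchor_quality minimum per-interval score as a fraction of the
#'   match bonus; 0 disables the gate.
#' @return the anchoring `label_alignment`, or `NULL` when no candidate.
#' @export
anchor_terminus <- function(alignments, chrom, arm, ref_len,
                            terminal_window = 5e5,
                            params = alignment_params(),
                            anchor_quality = 0.95) {
  win <- if (arm == "p") c(0, terminal_window) else
    c(max(0, ref_len - terminal_window), ref_len)
  cands <- Filter(function(a) {
    k <- nrow(a$pairs)
    a$ref_id == chrom &&
      overlaps_halfopen(a$ref_span[1], a$ref_span[2] + 1, win[1], win[2]) &&
      k >= 2L && a$score / (k - 1L) >= anchor_quality * params$m
  }, alignments)
  if (!length(cands)) return(NULL)
  distal <- vapply(cands, function(a) a$r_pos[distal_index(a, arm)],
                   numeric(1))
  best_distal <- if (arm == "q") max(distal) else min(distal)
  cands <- cands[distal == best_distal]
  if (length(cands) > 1L) {
    score <- vapply(cands, `[[`, numeric(1), "score")
    cands <- cands[score == max(score)]
  }
  if (length(cands) > 1L) {
    span <- vapply(cands, function(a) diff(a$ref_span), numeric(1))
    cands <- cands[span == max(span)]
  }
  if (length(cands) > 1L) {
    ids <- vapply(cands, `[[`, character(1), "query_id")
    cands <- cands[order(ids)][1]
  }
  cands[[1]]
}

#' Call extension/missing status of one terminus
#'
#' The contig tail is the distance from the contig's most terminus-distal
#' matched label to the contig's distal end; the reference tail is the
#' distance from the most distal matched reference label to the chromosome
#' end. Net extension is the contig tail in excess of the reference tail; net
#' missing is the N-gap-corrected reference tail in excess of the contig tail.
#' Each is compared to the threshold independently, so a terminus can be both
#' extended and missing (rearranged).
#'
#' @param anchor anchoring `label_alignment` from [anchor_terminus()] (or
#'   `NULL` for an excluded terminus).
#' @param ref_len reference chromosome length in bp.
#' @param arm `"p"` or `"q"`.
#' @param threshold_bp length threshold in bp.
#' @param n_gaps optional data.frame `start`,`end` (0-based half-open) of
#'   reference N-gap intervals on this chromosome.
#' @param sample sample label carried through to the call.
#' @return list of class `terminus_call`.
#' @export
call_terminus <- function(anchor, ref_len, arm, threshold_bp,
                          n_gaps = NULL, sample = NA_character_) {
  if (is.null(anchor)) {
    return(structure(list(sample = sample, chrom = NA_character_, arm = arm,
                          status = "excluded", extension_len = NA_real_,
                          missing_len = NA_real_, category = NA_integer_,
                          origins = list(), anchor_id = NA_character_,
                          anchor_score = NA_real_,
                          threshold_bp = threshold_bp, anchor = NULL),
                     class = "terminus_call"))
  }
  i <- distal_index(anchor, arm)
  if (arm == "q") {
    contig_tail <- anchor$qlen - anchor$q_pos[i]
    ref_tail <- ref_len - anchor$r_pos[i]
    nbp <- if (is.null(n_gaps)) 0 else
      intersect_bp(n_gaps$start, n_gaps$end, anchor$r_pos[i], ref_len)
  } else {
    contig_tail <- anchor$q_pos[i]
    ref_tail <- anchor$r_pos[i]
    nbp <- if (is.null(n_gaps)) 0 else
      intersect_bp(n_gaps$start, n_gaps$end, 0, anchor$r_pos[i])
  }
  extension_len <- max(0, contig_tail - ref_tail)
  missing_len <- max(0, (ref_tail - nbp) - contig_tail)
  ext <- extension_len > threshold_bp
  mis <- missing_len > threshold_bp
  status <- if (ext && mis) "extension_and_missing" else if (ext) "extension"
  else if (mis) "missing" else "reference"
  structure(list(sample = sample, chrom = anchor$ref_id, arm = arm,
                 status = status, extension_len = extension_len,
                 missing_len = missing_len, category = NA_integer_,
                 origins = list(), anchor_id = anchor$query_id,
                 anchor_score = anchor$score, threshold_bp = threshold_bp,
                 anchor = anchor),
            class = "terminus_call")
}

#' @export
print.terminus_call <- function(x, ...) {
  cat(sprintf("<terminus %s%s [%s]: %s ext=%.0f miss=%.0f cat=%s>\n",
              x$chrom, x$arm, x$sample, x$status,
              ifelse(is.na(x$extension_len), 0, x$extension_len),
              ifelse(is.na(x$missing_len), 0, x$missing_len),
              ifelse(is.na(x$category), "-", x$category)))
  invisible(x)
}

## Label map of the extension part of an anchored contig, rebased so position
## 0 is the junction (last matched label) and increasing towards the tip.
extension_label_map <- function(call, contig_map) {
  anchor <- call$anchor
  qm <- if (anchor$orientation == "+") contig_map else flip_map(contig_map)
  i <- distal_index(anchor, call$arm)
  if (call$arm == "q") {
    sel <- qm$labels > anchor$q_pos[i]
    pos <- qm$labels[sel] - anchor$q_pos[i]
    len <- qm$length - anchor$q_pos[i]
  } else {
    sel <- qm$labels < anchor$q_pos[i]
    pos <- rev(anchor$q_pos[i] - qm$labels[sel])
    len <- anchor$q_pos[i]
  }
  label_map(paste0(contig_map$id, "_ext"), max(len, 1), pos)
}

#' Classify an extension as category 1 or 2
#'
#' The extension's label subsequence is realigned genome-wide with multiple
#' matches. If any alignment covers at least `coverage_threshold` of the
#' extension labels, the extension is category 1 (homologous sequence found)
#' and all qualifying origins are recorded (chromosome, arm, matched span,
#' orientation); otherwise category 2. Extensions with fewer than
#' `min_labels` labels cannot be classified and fall to category 2 with a
#' `too_few_labels` flag.
#'
#' Origin alignments must additionally reach a per-interval score of at least
#' `origin_quality * m`: a genuine origin reproduces the extension's interval
#' sizes to within the sizing noise (per-interval score near `m`), whereas
#' chance collinearity of a handful of labels leaves residuals at the label
#' spacing scale. This filter stands in for the p-value machinery of
#' production optical-map aligners. Origins are deduplicated per chromosome
#' arm, keeping the best-scoring span.
#'
#' @param call a `terminus_call` with extension status.
#' @param contig_map the anchored contig's [label_map()].
#' @param ref_maps list of reference [label_map()]s (genome-wide).
#' @param params [alignment_params()] for the realignment.
#' @param coverage_threshold fraction of extension labels an origin alignment
#'   must cover.
#' @param origin_quality minimum per-interval score as a fraction of the
#'   match bonus.
#' @return the call with `category`, `origins` (and possibly
#'   `too_few_labels`) filled in.
#' @export
classify_extension <- function(call, contig_map, ref_maps,
                               params = alignment_params(),
                               coverage_threshold = 0.5,
                               origin_quality = 0.97) {
  if (!call$status %in% c("extension", "extension_and_missing")) {
    return(call)
  }
  ext_map <- extension_label_map(call, contig_map)
  n_ext <- length(ext_map$labels)
  if (n_ext < params$min_labels) {
    call$category <- 2L
    call$too_few_labels <- TRUE
    return(call)
  }
  alns <- align_label_maps(ext_map, ref_maps, params)
  ref_lens <- stats::setNames(
    vapply(ref_maps, `[[`, numeric(1), "length"),
    vapply(ref_maps, `[[`, character(1), "id"))
  origins <- list()
  seen_arms <- character(0)
  for (a in alns) {    # alns are sorted by decreasing score
    k <- nrow(a$pairs)
    if (k < coverage_threshold * n_ext) next
    if (k < 2L || a$score / (k - 1L) < origin_quality * params$m) next
    len <- ref_lens[[a$ref_id]]
    arm <- if (mean(a$ref_span) < len / 2) "p" else "q"
    key <- paste0(a$ref_id, arm)
    if (key %in% seen_arms) next
    seen_arms <- c(seen_arms, key)
    origins[[length(origins) + 1L]] <- list(
      chrom = a$ref_id, arm = arm, span = a$ref_span,
      orientation = a$orientation, n_matched = k)
  }
  if (length(origins)) {
    call$category <- 1L
    call$origins <- origins
  } else {
    call$category <- 2L
  }
  call
}

#' Terminus-distal window of a label map
#'
#' Returns a small distal-first map holding the `n` labels closest to the
#' terminus (the whole map if it has fewer).
#'
#' @param map a [label_map()] in chromosome-forward orientation.
#' @param arm `"p"` or `"q"` (which end is the terminus).
#' @param n window size in labels.
#' @return a [label_map()] with the terminus at position 0.
#' @export
terminal_label_window <- function(map, arm, n = 10L) {
  dm <- if (arm == "q") flip_map(map) else map
  labs <- head(dm$labels, n)
  len <- if (length(labs)) max(labs) + 1000 else 1000
  label_map(paste0(map$id, "_", arm, "win"), min(len, dm$length), labs)
}

## Terminal label difference between two maps at one terminus: unmatched
## labels on either side of the best alignment of their distal windows.
terminal_label_diff <- function(map_a, map_b, arm, params = NULL,
                                window = 10L) {
  if (is.null(params)) params <- alignment_params(min_labels = 2L)
  wa <- terminal_label_window(map_a, arm, window)
  wb <- terminal_label_window(map_b, arm, window)
  na <- length(wa$labels)
  nb <- length(wb$labels)
  if (na == 0L && nb == 0L) return(0L)
  alns <- align_label_maps(wa, wb, params)
  if (!length(alns)) return(na + nb)
  k <- nrow(alns[[1]]$pairs)
  (na - k) + (nb - k)
}

#' Trio inheritance of a chromosome end
#'
#' The child's anchored terminal label sequence is aligned to each parent's;
#' the difference is the count of unmatched terminal labels (within the distal
#' `window` labels) on either side of the best alignment. A parent within
#' `tolerance` (default: no more than one label difference) is reported as the
#' origin; both parents within tolerance give `"both"`, neither gives
#' `"neither"`.
#'
#' @param child_map,father_map,mother_map anchored contig [label_map()]s for
#'   the same terminus (chromosome-forward orientation). A parent may also be
#'   a list of maps (both haplotype contigs); the smaller difference counts,
#'   since inheritance only requires a match to one parental haplotype.
#'   Missing parent data may be `NULL`.
#' @param arm `"p"` or `"q"`.
#' @param tolerance maximum label difference for inheritance.
#' @param window distal window size in labels.
#' @param params optional [alignment_params()].
#' @return list of class `trio_call`: `parent_of_origin`, `diff_father`,
#'   `diff_mother`, `tolerance`, `flag`.
#' @export
trio_inheritance <- function(child_map, father_map, mother_map, arm,
                             tolerance = 1L, window = 10L, params = NULL) {
  if (is.null(father_map) || is.null(mother_map)) {
    return(structure(list(parent_of_origin = "neither",
                          diff_father = NA_integer_,
                          diff_mother = NA_integer_,
                          tolerance = tolerance, flag = "missing_parent"),
                     class = "trio_call"))
  }
  as_map_list <- function(x) if (inherits(x, "label_map")) list(x) else x
  min_diff <- function(parent_maps) {
    min(vapply(as_map_list(parent_maps), function(pm) {
      terminal_label_diff(child_map, pm, arm, params, window)
    }, numeric(1)))
  }
  df <- min_diff(father_map)
  dm <- min_diff(mother_map)
  poo <- if (df <= tolerance && dm <= tolerance) "both"
  else if (df <= tolerance) "father"
  else if (dm <= tolerance) "mother"
  else "neither"
  structure(list(parent_of_origin = poo, diff_father = df, diff_mother = dm,
                 tolerance = tolerance, flag = NA_character_),
            class = "trio_call")
}

#' Detect distinct alleles among contigs anchored to one terminus
#'
#' Contigs whose terminal label sequences differ by more than `tolerance`
#' labels are distinct alleles (e.g. a heterozygous extension: one extended
#' and one reference-type contig at the same terminus); near-identical
#' contigs collapse into one allele. Single-linkage clustering on the terminal
#' label difference.
#'
#' @param contig_maps list of anchored contig [label_map()]s.
#' @param arm `"p"` or `"q"`.
#' @param tolerance maximum label difference within an allele.
#' @param window distal window size in labels.
#' @param params optional [alignment_params()].
#' @return list with `n_alleles` and `assignment` (integer allele id per
#'   contig).
#' @export
detect_diploid <- function(contig_maps, arm, tolerance = 1L, window = 10L,
                           params = NULL) {
  n <- length(contig_maps)
  if (n == 0L) return(list(n_alleles = 0L, assignment = integer(0)))
  assign <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- terminal_label_diff(contig_maps[[i]], contig_maps[[j]], arm,
                                 params, window)
        if (d <= tolerance) {
          assign[assign == assign[j]] <- assign[i]
        }
      }
    }
  }
  list(n_alleles = length(unique(assign)),
       assignment = match(assign, unique(assign)))
}
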