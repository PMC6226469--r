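## Subtelomeric duplication-family analysis: base-pair copy number from a
## duplication-pair table, high-copy core regions, span-membership, the 1 Mb
## subtelomere filter, enrichment testing, pairwise divergence and
## molecular-clock dating.

check_pairs <- function(pairs, chrom_lengths = NULL) {
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs)) {
    stopifnot(all(pairs$startA < pairs$endA), all(pairs$startB < pairs$endB))
    if (!is.null(chrom_lengths)) {
      for (side in c("A", "B")) {
        ch <- pairs[[paste0("chrom", side)]]
        en <- pairs[[paste0("end", side)]]
        st <- pairs[[paste0("start", side)]]
        if (!all(ch %in% names(chrom_lengths))) {
          stop("pair interval on unknown chromosome")
        }
        if (any(st < 0) || any(en > chrom_lengths[ch])) {
          stop("pair interval beyond chromosome length")
        }
      }
    }
  }
  invisible(pairs)
}

## both sides of every pair as one interval table
pair_sides <- function(pairs) {
  data.frame(
    chrom = c(pairs$chromA, pairs$chromB),
    start = c(pairs$startA, pairs$startB),
    end = c(pairs$endA, pairs$endB),
    pair = rep(seq_len(nrow(pairs)), 2L))
}

#' Base-pair copy number profile from a duplication-pair table
#'
#' The base-pair copy number of a position is the number of
#' duplication-database entries overlapping it; both intervals of each pair
#' count as entries. Returned run-length encoded per chromosome (runs
#' partition `[0, length)`, adjacent runs differ in count).
#'
#' @param pairs data.frame with `chromA,startA,endA,chromB,startB,endB`
#'   (0-based half-open).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return data.frame `chrom,start,end,count` of class `cn_profile`.
#' @export
copy_number_profile <- function(pairs, chrom_lengths) {
  check_pairs(pairs, chrom_lengths)
  sides <- pair_sides(pairs)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    s <- sides[sides$chrom == ch, , drop = FALSE]
    if (nrow(s)) {
      cov <- IRanges::coverage(IRanges::IRanges(s$start + 1L, s$end),
                               width = len)
      rl <- data.frame(chrom = ch,
                       start = cumsum(c(0, S4Vectors::runLength(cov)))[
                         seq_along(S4Vectors::runLength(cov))],
                       end = cumsum(S4Vectors::runLength(cov)),
                       count = S4Vectors::runValue(cov))
    } else {
      rl <- data.frame(chrom = ch, start = 0, end = len, count = 0L)
    }
    out[[ch]] <- rl
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cn_profile", "data.frame")
  res
}

#' High-copy regions, longest first
#'
#' Maximal contiguous runs with base-pair copy number at least `min_cn`
#' (default 22, the high-copy threshold for subtelomeric family detection),
#' ordered by decreasing bp length; ties by chromosome then start.
#'
#' @param profile a [copy_number_profile()].
#' @param min_cn copy-number threshold.
#' @return data.frame `chrom,start,end,length`.
#' @export
high_copy_regions <- function(profile, min_cn = 22L) {
  hi <- profile[profile$count >= min_cn, , drop = FALSE]
  if (!nrow(hi)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0)))
  }
  out <- list()
  for (ch in unique(hi$chrom)) {
    h <- hi[hi$chrom == ch, , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(h$start + 1L, h$end))
    out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(red) - 1L,
                            end = IRanges::end(red))
  }
  res <- do.call(rbind, out)
  res$length <- res$end - res$start
  res <- res[order(-res$length, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Members of the duplication family anchored at a high-copy region
#'
#' Duplication copies spanning the entire region are family members: every
#' pair with a side containing the region contributes both of its intervals
#' (the spanning copy and its homolog), deduplicated by interval. Copies
#' overlapping the region only partially are excluded.
#'
#' @param region one-row data.frame or list with `chrom,start,end`.
#' @param pairs duplication-pair table.
#' @return data.frame `chrom,start,end` of member intervals (0 rows when no
#'   copy spans the region: the family is rejected).
#' @export
family_members <- function(region, pairs) {
  check_pairs(pairs)
  if (!nrow(pairs)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  contains <- function(side) {
    pairs[[paste0("chrom", side)]] == region$chrom &
      pairs[[paste0("start", side)]] <= region$start &
      pairs[[paste0("end", side)]] >= region$end
  }
  hitA <- contains("A")
  hitB <- contains("B")
  sel <- hitA | hitB
  if (!any(sel)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  mem <- rbind(
    data.frame(chrom = pairs$chromA[sel], start = pairs$startA[sel],
               end = pairs$endA[sel]),
    data.frame(chrom = pairs$chromB[sel], start = pairs$startB[sel],
               end = pairs$endB[sel]))
  mem <- unique(mem)
  mem <- mem[order(mem$chrom, mem$start), , drop = FALSE]
  rownames(mem) <- NULL
  mem
}

#' Flag subtelomeric members and drop fully interstitial families
#'
#' A member is subtelomeric when its interval intersects the first or last
#' `window` bp of its chromosome (default 1 Mb). Families with no
#' subtelomeric member are dropped.
#'
#' @param families list of families, each a list with `core` and `members`
#'   (as from [detect_families()]), or a single members data.frame.
#' @param chrom_lengths named numeric vector.
#' @param window subtelomere window in bp.
#' @return same shape as the input with a logical `subtelomeric` column added
#'   to members; list input is filtered.
#' @export
subtelomeric_filter <- function(families, chrom_lengths, window = 1e6) {
  flag_members <- function(mem) {
    len <- chrom_lengths[mem$chrom]
    mem$subtelomeric <- overlaps_halfopen(mem$start, mem$end, 0, window) |
      overlaps_halfopen(mem$start, mem$end, len - window, len)
    mem
  }
  if (is.data.frame(families)) return(flag_members(families))
  out <- lapply(families, function(f) {
    f$members <- flag_members(f$members)
    f
  })
  Filter(function(f) any(f$members$subtelomeric), out)
}

#' Detect duplication families from a pair table
#'
#' The full detection procedure: base-pair copy-number profile, high-copy
#' regions ordered by length, span-membership for each region (regions whose
#' members duplicate an already-claimed family are skipped), then the
#' subtelomere filter.
#'
#' @param pairs duplication-pair table.
#' @param chrom_lengths named numeric vector.
#' @param min_cn high-copy threshold.
#' @param window subtelomere window bp (`NULL` to skip the filter).
#' @return list of families: each `list(core =, members =)`.
#' @export
detect_families <- function(pairs, chrom_lengths, min_cn = 22L,
                            window = 1e6) {
  prof <- copy_number_profile(pairs, chrom_lengths)
  regions <- high_copy_regions(prof, min_cn)
  fams <- list()
  claimed <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0))
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    if (nrow(claimed) &&
        any(claimed$chrom == reg$chrom &
              overlaps_halfopen(claimed$start, claimed$end,
                                reg$start, reg$end))) {
      next
    }
    mem <- family_members(reg, pairs)
    if (!nrow(mem)) next
    fams[[length(fams) + 1L]] <- list(core = reg, members = mem)
    claimed <- rbind(claimed, mem[, c("chrom", "start", "end")])
  }
  if (!is.null(window)) {
    fams <- subtelomeric_filter(fams, chrom_lengths, window)
  }
  fams
}

#' Subtelomeric enrichment of family members
#'
#' One-sided exact binomial test of member placement: under the null each of
#' the `n` members falls into subtelomeres with probability
#' `p0 = subtel_bp / genome_bp`; with `k` subtelomeric members the fold
#' enrichment is `(k/n) / p0` and the p-value is `P(X >= k | n, p0)`.
#'
#' @param family a family list with a flagged `members` data.frame (see
#'   [subtelomeric_filter()]), or the data.frame itself.
#' @param subtel_bp total subtelomeric bp in the genome.
#' @param genome_bp total genome bp.
#' @return list `n`, `k`, `fold`, `p_value`.
#' @export
enrichment_test <- function(family, subtel_bp, genome_bp) {
  if (genome_bp <= 0) stop("genome_bp must be positive")
  mem <- if (is.data.frame(family)) family else family$members
  stopifnot(nrow(mem) >= 1, !is.null(mem$subtelomeric))
  n <- nrow(mem)
  k <- sum(mem$subtelomeric)
  p0 <- min(1, subtel_bp / genome_bp)
  fold <- (k / n) / p0
  p_value <- if (k == 0) 1 else pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(n = n, k = k, fold = fold, p_value = min(1, p_value))
}

#' Globally align two duplication copies
#'
#' Needleman-Wunsch global alignment (match/mismatch/gap = 1/-1/-2) via
#' [Biostrings::pairwiseAlignment()]; returns the two gapped strings for
#' [pairwise_divergence()].
#'
#' @param a,b character sequences.
#' @return list `a`, `b` of equal-length gapped strings.
#' @export
align_copies <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Pairwise divergence of two aligned duplication copies
#'
#' Percentage of single-base differences over aligned columns; insertion and
#' deletion columns are ignored (excluded from numerator and denominator).
#' Alignments shorter than `min_aligned_bp` non-indel columns are rejected
#' (too little of the family unit aligned to estimate divergence).
#'
#' @param a,b equal-length gapped alignment strings (`-` for gaps), e.g. from
#'   [align_copies()].
#' @param min_aligned_bp minimum non-indel columns.
#' @return list `divergence` (percent), `aligned_bp`, `mismatches`,
#'   `rejected`.
#' @export
pairwise_divergence <- function(a, b, min_aligned_bp = 0) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  keep <- av != "-" & bv != "-"
  aligned <- sum(keep)
  if (aligned < min_aligned_bp) {
    return(list(divergence = NA_real_, aligned_bp = aligned,
                mismatches = NA_integer_, rejected = TRUE))
  }
  mm <- sum(av[keep] != bv[keep])
  list(divergence = 100 * mm / aligned, aligned_bp = aligned,
       mismatches = mm, rejected = FALSE)
}

#' Molecular-clock age of a duplication
#'
#' `age = divergence / rate`. The default rate, 0.3 percent divergence
#' between copies per million years (3% per 10 Myr), dates human subtelomeric
#' family copies with divergences of 0.02-0.8% to the last ~2.6 Myr, i.e.
#' after the human-chimpanzee split.
#'
#' @param divergence_pct percent divergence between the two copies.
#' @param rate_pct_per_myr percent divergence accumulated per Myr.
#' @return list of class `age_estimate`: `divergence`, `rate`, `age_myr`.
#' @export
date_duplication <- function(divergence_pct, rate_pct_per_myr = 0.3) {
  if (rate_pct_per_myr <= 0) stop("rate must be positive")
  stopifnot(all(divergence_pct >= 0))
  structure(list(divergence = divergence_pct, rate = rate_pct_per_myr,
                 age_myr = divergence_pct / rate_pct_per_myr),
            class = "age_estimate")
}

#' Subtelomeric duplication region of one arm
#'
#' The longest contiguous duplication coverage starting exactly at the
#' terminus: duplication intervals (in terminus-distal coordinates, position
#' 0 = chromosome tip) are merged (adjacent intervals coalesce) and the
#' merged block containing position 0 is returned; empty when no duplication
#' touches the terminus.
#'
#' @param intervals data.frame `start,end` (0-based half-open,
#'   terminus-distal coordinates).
#' @return numeric `c(start, end)` or `NULL`.
#' @export
subtel_region <- function(intervals) {
  if (is.null(intervals) || !nrow(intervals)) return(NULL)
  red <- IRanges::reduce(IRanges::IRanges(intervals$start + 1L,
                                          intervals$end))
  first <- red[IRanges::start(red) == 1L]
  if (!length(first)) return(NULL)
  c(start = 0, end = IRanges::end(first)[1])
}

#' Exon homology rule
#'
#' Exon A is homologous to exon B when at least 90% of A's length aligns to B
#' with identity strictly greater than 95%. Asymmetric in A by construction.
#'
#' @param exon_a_len length of exon A in bp.
#' @param aligned_len aligned bp of exon A.
#' @param identity alignment identity fraction.
#' @return logical.
#' @export
exon_homology <- function(exon_a_len, aligned_len, identity) {
  stopifnot(exon_a_len > 0, aligned_len >= 0)
  (aligned_len / exon_a_len >= 0.90) & (identity > 0.95)
}
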