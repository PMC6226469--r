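#' Derive a per-stage random seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from one master seed
#' plus a stage name, so that a single `--seed` reproduces every stage while
#' stages stay independent of each other's draw counts.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.numeric(master_seed) %% 2147483647
  for (cc in utf8ToInt(stage)) {
    h <- (h * 131 + cc) %% 2147483647
  }
  as.integer(h)
}

with_stage_seed <- function(master_seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(stage_seed(master_seed, stage))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Reverse-complement a DNA string
#'
#' @param x character scalar (A/C/G/T/N and IUPAC codes).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#'
#' i.i.d. uniform A/C/G/T background; composition carries no signal for any of
#' the label- or duplication-based analyses, so a uniform background suffices.
#'
#' @param n length in bp.
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## round half up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

## overlap of half-open intervals [a0,a1) and [b0,b1)
overlaps_halfopen <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1

## total bp of [s,e) intervals intersected with [w0,w1)
intersect_bp <- function(starts, ends, w0, w1) {
  if (length(starts) == 0L) return(0)
  lo <- pmax(starts, w0)
  hi <- pmin(ends, w1)
  sum(pmax(0, hi - lo))
}
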