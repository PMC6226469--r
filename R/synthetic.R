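## Synthetic-data generator: reference genomes with planted subtelomeric
## duplication families, trio haplotypes carrying chromosome-end events, noisy
## contig label maps, error-bearing long reads, and duplication-pair tables --
## all with full ground truth, so every downstream stage can be scored.

#' Noise parameters for simulated contig label maps
#'
#' Defaults follow the error-parameter regime of production optical-map
#' aligners: fixed sizing SD 0.20 kb, relative sizing error 0.01, false
#' positives 0.6 per 100 kb, label miss rate 0.06, and a minimum resolvable
#' inter-label distance of 1450 bp (2.9 pixels at 500 bp/pixel).
#'
#' @param sizing_sd_fixed fixed component of interval sizing SD, bp.
#' @param sizing_sd_rel relative sizing SD (fraction of interval length).
#' @param fp_rate false labels per 100 kb (Poisson).
#' @param fn_rate fraction of true labels missed (Bernoulli per label).
#' @param resolution_bp labels closer than this are merged.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(sizing_sd_fixed = 200, sizing_sd_rel = 0.01,
                         fp_rate = 0.6, fn_rate = 0.06,
                         resolution_bp = 1450) {
  stopifnot(sizing_sd_fixed >= 0, sizing_sd_rel >= 0, fp_rate >= 0,
            fn_rate >= 0, fn_rate <= 1, resolution_bp >= 0)
  structure(list(sizing_sd_fixed = sizing_sd_fixed,
                 sizing_sd_rel = sizing_sd_rel,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 resolution_bp = resolution_bp),
            class = "noise_params")
}

zero_noise <- function() noise_params(0, 0, 0, 0, 0)

#' Chromosome-end event description
#'
#' The three event kinds observed at human chromosome ends: extension by
#' duplication of another terminus (e.g. a 9q extension copied from the 1p
#' tip), terminal deletion, and tandem expansion of the chromosome's own
#' terminal unit (the 15q-type allele).
#'
#' @param kind one of `"extension_by_duplication"`, `"terminal_deletion"`,
#'   `"tandem_expansion"`.
#' @param chrom,arm target chromosome name and arm (`"p"`/`"q"`).
#' @param length event length in bp (for tandem expansion: the unit length).
#'   Length 0 is the identity transform.
#' @param donor_chrom,donor_arm donor terminus (extension_by_duplication only).
#' @param copies total copy count after expansion (tandem only; 1 is the
#'   identity transform).
#' @param carrier haplotype id the event is planted on (e.g. `"father1"`).
#' @return list of class `end_event`.
#' @export
end_event <- function(kind, chrom, arm, length, donor_chrom = NULL,
                      donor_arm = NULL, copies = NULL, carrier = "father1") {
  kind <- match.arg(kind, c("extension_by_duplication", "terminal_deletion",
                            "tandem_expansion"))
  stopifnot(length >= 0, arm %in% c("p", "q"))
  if (kind == "extension_by_duplication") {
    if (is.null(donor_chrom) || is.null(donor_arm)) {
      stop("extension_by_duplication requires a donor terminus")
    }
    stopifnot(donor_arm %in% c("p", "q"))
  } else if (!is.null(donor_chrom)) {
    stop("donor is only defined for extension_by_duplication")
  }
  if (kind == "tandem_expansion") {
    if (is.null(copies) || copies < 1) {
      stop("tandem_expansion requires copies >= 1")
    }
  }
  structure(list(kind = kind, chrom = chrom, arm = arm,
                 length = as.numeric(length),
                 donor_chrom = donor_chrom, donor_arm = donor_arm,
                 copies = if (is.null(copies)) NA_integer_ else
                   as.integer(copies),
                 carrier = carrier),
            class = "end_event")
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: a multi-chromosome reference with
#' planted subtelomeric duplication families (two families by default, unit
#' lengths 9 kb and 8 kb, one interstitial ancestral copy each), chromosome-end
#' events for a trio, contig-map noise and long-read parameters.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (all equal).
#' @param enzyme_motif IUPAC nicking motif (7-mer default gives ~1 label per
#'   10 kb on random sequence, the human nicking-map spacing regime).
#' @param dup_unit_lengths named numeric vector of family unit lengths in bp.
#' @param placements data.frame with columns `family`, `chrom`, `arm`
#'   (`"p"`, `"q"` or `"i"` for interstitial) and `offset` (bp from the
#'   terminus for arms, from chromosome start for interstitial). `NULL` for a
#'   default layout (fifteen subtelomeric copies plus one interstitial
#'   ancestral copy per family -- 16 members, the human copy count of both
#'   known subtelomeric families).
#' @param divergence_schedule per-copy substitution fraction(s), recycled over
#'   placements of each family.
#' @param event_list list of [end_event()]s for the trio.
#' @param contig_noise a [noise_params()].
#' @param read_length_params numeric `c(mean, min)` read length in bp.
#' @param read_error_rate long-read substitution error fraction.
#' @param seed master seed; all stages derive substreams from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5, chrom_length = 5e6,
                       enzyme_motif = "GCTCTTC",
                       dup_unit_lengths = c(A = 9000, B = 8000),
                       placements = NULL,
                       divergence_schedule = 0.005,
                       event_list = list(),
                       contig_noise = noise_params(),
                       read_length_params = c(mean = 20000, min = 500),
                       read_error_rate = 0.1,
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0,
            all(divergence_schedule >= 0), all(divergence_schedule <= 1),
            read_error_rate >= 0, read_error_rate <= 1)
  if (length(event_list) &&
      chrom_length <= 2 * max(vapply(event_list, function(e)
        e$length * max(1, ifelse(is.na(e$copies), 1, e$copies)),
        numeric(1)))) {
    stop("chrom_length must exceed twice the largest event length")
  }
  if (is.null(placements)) {
    placements <- default_placements(names(dup_unit_lengths), n_chromosomes)
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length,
    enzyme_motif = enzyme_motif,
    dup_unit_lengths = dup_unit_lengths,
    placements = placements,
    divergence_schedule = divergence_schedule,
    event_list = event_list,
    contig_noise = contig_noise,
    read_length_params = read_length_params,
    read_error_rate = read_error_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## Default layout: per family, fifteen subtelomeric copies cycling over the
## available arms (arms revisited in later cycles receive staggered offsets,
## as real subtelomeres carry several copies) plus one interstitial ancestral
## copy mid-chromosome -- 16 members per family, the human copy count of the
## two known subtelomeric families.
default_placements <- function(families, n_chrom, n_subtel = 15L) {
  if (!length(families)) {
    return(data.frame(family = character(0), chrom = character(0),
                      arm = character(0), offset = numeric(0)))
  }
  out <- list()
  arms <- expand.grid(chrom = paste0("chr", seq_len(n_chrom)),
                      arm = c("p", "q"), stringsAsFactors = FALSE)
  for (fi in seq_along(families)) {
    idx <- ((seq_len(n_subtel) - 1L) %% nrow(arms)) + 1L
    cycle <- (seq_len(n_subtel) - 1L) %/% nrow(arms)
    base <- 20000 + (fi - 1L) * 2L * 20000
    out[[fi]] <- data.frame(
      family = families[fi],
      chrom = c(arms$chrom[idx], paste0("chr", ((fi - 1L) %% n_chrom) + 1L)),
      arm = c(arms$arm[idx], "i"),
      offset = c(base + cycle * 20000, NA)
    )
  }
  do.call(rbind, out)
}

## Independent per-base substitution at rate d; returns the mutated string.
mutate_seq <- function(seq, d) {
  if (d <= 0 || nchar(seq) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < d)
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    pick <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- substring(alt[chars[hit]], pick, pick)
  }
  paste(chars, collapse = "")
}

## terminal `len` bp of a chromosome in terminus-distal orientation
## (position 0 of the result is the chromosome tip, reading inward)
terminal_segment <- function(seq, arm, len) {
  n <- nchar(seq)
  stopifnot(len <= n, arm %in% c("p", "q"))
  if (arm == "p") substr(seq, 1, len) else revcomp(substr(seq, n - len + 1, n))
}

#' Simulate a reference genome with planted duplication families
#'
#' Chromosomes are i.i.d. uniform A/C/G/T background; each placement receives
#' a copy of its family unit mutated by the divergence schedule, oriented
#' terminus-distally on arms (so all subtelomeric copies share orientation
#' towards the chromosome end, as real subtelomeric duplications do). Truth
#' records every member interval.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `truth` (list with
#'   `members` data.frame and `units` list), and `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "reference", {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    genome <- vapply(chroms, function(ch) random_dna(config$chrom_length),
                     character(1))
    units <- lapply(config$dup_unit_lengths, function(u) random_dna(u))
    names(units) <- names(config$dup_unit_lengths)
    members <- list()
    pl <- config$placements
    if (!is.null(pl) && nrow(pl)) {
      for (fam in unique(pl$family)) {
        rows <- which(pl$family == fam)
        u <- units[[fam]]
        ulen <- nchar(u)
        divs <- rep(config$divergence_schedule, length.out = length(rows))
        for (k in seq_along(rows)) {
          row <- pl[rows[k], ]
          L <- nchar(genome[[row$chrom]])
          if (row$arm == "p") {
            start <- row$offset
          } else if (row$arm == "q") {
            start <- L - row$offset - ulen
          } else {
            start <- if (is.na(row$offset)) floor(L / 2) else row$offset
          }
          end <- start + ulen
          if (is.na(start) || start < 0 || end > L) {
            stop(sprintf("placement of family %s beyond bounds of %s",
                         fam, row$chrom))
          }
          copy <- mutate_seq(u, divs[k])
          oriented <- if (row$arm == "q") revcomp(copy) else copy
          substr(genome[[row$chrom]], start + 1, end) <- oriented
          members[[length(members) + 1L]] <- data.frame(
            family = fam, chrom = row$chrom, start = start, end = end,
            arm = row$arm, subtelomeric = row$arm %in% c("p", "q"),
            divergence = divs[k], identity = 1 - divs[k])
        }
      }
    }
    members <- if (length(members)) do.call(rbind, members) else
      data.frame(family = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), arm = character(0),
                 subtelomeric = logical(0), divergence = numeric(0),
                 identity = numeric(0))
    list(genome = genome,
         truth = list(members = members, units = units),
         config = config)
  })
}

#' Apply a chromosome-end event to a haploid genome
#'
#' Extension-by-duplication appends the donor's terminal sequence in
#' terminus-distal orientation; terminal deletion removes the distal bp;
#' tandem expansion replaces the terminal unit by `copies` concatenated copies.
#' p-arm events reuse the q-arm code path by mirroring the chromosome into
#' terminus-distal orientation and back.
#'
#' @param haplotype named character vector (chromosome sequences).
#' @param event an [end_event()].
#' @param reference named character vector; donor sequence source.
#' @return modified haplotype.
#' @export
apply_end_event <- function(haplotype, event, reference) {
  stopifnot(inherits(event, "end_event"), event$chrom %in% names(haplotype))
  seq <- haplotype[[event$chrom]]
  mirrored <- event$arm == "p"
  if (mirrored) seq <- revcomp(seq)
  n <- nchar(seq)
  if (event$kind == "extension_by_duplication") {
    don <- reference[[event$donor_chrom]]
    if (event$length > nchar(don)) stop("event length exceeds donor length")
    dd <- terminal_segment(don, event$donor_arm, event$length)
    seq <- paste0(seq, revcomp(dd))
  } else if (event$kind == "terminal_deletion") {
    if (event$length > n) stop("deletion length exceeds chromosome length")
    if (event$length > 0) seq <- substr(seq, 1, n - event$length)
  } else { # tandem_expansion
    if (event$length > n) stop("unit length exceeds chromosome length")
    unit <- substr(seq, n - event$length + 1, n)
    seq <- paste0(substr(seq, 1, n - event$length),
                  strrep(unit, event$copies))
  }
  if (mirrored) seq <- revcomp(seq)
  haplotype[[event$chrom]] <- seq
  haplotype
}

#' Simulate a trio with chromosome-end events
#'
#' Parental haplotypes start as copies of the reference; events are applied to
#' their declared carrier haplotypes (`father1`, `father2`, `mother1`,
#' `mother2`); the child then inherits one haplotype from each parent
#' (recorded in truth). Child haplotype 1 is paternal, 2 maternal.
#'
#' @param reference named character vector (from [simulate_reference()]).
#' @param event_list list of [end_event()]s.
#' @param seed integer seed (haplotype transmission choice).
#' @return list with `father`, `mother`, `child` (each a list of two named
#'   character vectors `h1`, `h2`) and `truth` (events, inheritance map,
#'   per-terminus expected net length changes).
#' @export
simulate_trio <- function(reference, event_list = list(), seed = 1L) {
  haps <- list(father1 = reference, father2 = reference,
               mother1 = reference, mother2 = reference)
  seen <- character(0)
  for (ev in event_list) {
    stopifnot(inherits(ev, "end_event"))
    if (!ev$carrier %in% names(haps)) {
      stop(sprintf("unknown carrier haplotype '%s'", ev$carrier))
    }
    key <- paste(ev$carrier, ev$chrom, ev$arm)
    if (key %in% seen) {
      stop(sprintf("conflicting events on %s %s%s", ev$carrier, ev$chrom,
                   ev$arm))
    }
    seen <- c(seen, key)
    haps[[ev$carrier]] <- apply_end_event(haps[[ev$carrier]], ev, reference)
  }
  with_stage_seed(seed, "transmission", {
    f_pick <- sample.int(2L, 1L)
    m_pick <- sample.int(2L, 1L)
  })
  child <- list(h1 = haps[[paste0("father", f_pick)]],
                h2 = haps[[paste0("mother", m_pick)]])
  inheritance <- c(h1 = paste0("father", f_pick),
                   h2 = paste0("mother", m_pick))
  truth <- list(
    events = event_list,
    inheritance = inheritance,
    termini = trio_truth_table(reference, event_list, inheritance)
  )
  list(father = list(h1 = haps$father1, h2 = haps$father2),
       mother = list(h1 = haps$mother1, h2 = haps$mother2),
       child = child, truth = truth)
}

## Expected net terminal length change per haplotype x terminus.
trio_truth_table <- function(reference, event_list, inheritance) {
  haps <- c("father1", "father2", "mother1", "mother2")
  grid <- expand.grid(hap = haps, chrom = names(reference),
                      arm = c("p", "q"), stringsAsFactors = FALSE)
  grid$extension <- 0
  grid$missing <- 0
  grid$kind <- "none"
  for (ev in event_list) {
    i <- which(grid$hap == ev$carrier & grid$chrom == ev$chrom &
                 grid$arm == ev$arm)
    if (ev$kind == "terminal_deletion") {
      grid$missing[i] <- ev$length
    } else if (ev$kind == "extension_by_duplication") {
      grid$extension[i] <- ev$length
    } else {
      grid$extension[i] <- (ev$copies - 1) * ev$length
    }
    grid$kind[i] <- ev$kind
  }
  child <- do.call(rbind, lapply(c("h1", "h2"), function(h) {
    g <- grid[grid$hap == inheritance[[h]], ]
    g$hap <- paste0("child", sub("h", "", h))
    g$inherited_from <- inheritance[[h]]
    g
  }))
  grid$inherited_from <- NA_character_
  rbind(grid, child)
}

#' Simulate noisy contig label maps
#'
#' One contig per chromosome of each haploid genome: true digestion positions
#' perturbed interval-wise by Gaussian sizing error with SD
#' `sqrt(sizing_sd_fixed^2 + (sizing_sd_rel * interval)^2)`, labels dropped
#' independently at `fn_rate`, false labels added as Poisson(`fp_rate` per
#' 100 kb), and labels closer than `resolution_bp` merged.
#'
#' @param genome named character vector.
#' @param enzyme_motif IUPAC motif.
#' @param noise a [noise_params()].
#' @param seed integer seed.
#' @param id_prefix prefix for contig ids.
#' @return list of [label_map()]s (one per chromosome; empty genome gives an
#'   empty list).
#' @export
simulate_contig_maps <- function(genome, enzyme_motif = "GCTCTTC",
                                 noise = noise_params(), seed = 1L,
                                 id_prefix = "contig") {
  if (!length(genome)) return(list())
  with_stage_seed(seed, paste0("contigs_", id_prefix), {
    out <- vector("list", length(genome))
    for (i in seq_along(genome)) {
      seqc <- genome[[i]]
      len <- nchar(seqc)
      labs <- insilico_digest(seqc, enzyme_motif)
      n <- length(labs)
      if (n) {
        iv <- diff(c(0, labs))
        sdv <- sqrt(noise$sizing_sd_fixed^2 + (noise$sizing_sd_rel * iv)^2)
        pos <- cumsum(iv + rnorm(n, 0, sdv))
        pos <- pos[runif(n) >= noise$fn_rate]
      } else {
        pos <- numeric(0)
      }
      nfp <- if (noise$fp_rate > 0) rpois(1L, noise$fp_rate * len / 1e5) else 0L
      if (nfp > 0) pos <- c(pos, runif(nfp, 0, len))
      pos <- sort(round(pmin(pmax(pos, 0), len - 1)))
      pos <- unique(pos)
      if (noise$resolution_bp > 0) {
        pos <- merge_labels(pos, noise$resolution_bp)
      }
      out[[i]] <- label_map(paste0(id_prefix, "_", names(genome)[i]), len, pos,
                            meta = list(source = names(genome)[i]))
    }
    out
  })
}

## Substitution errors (and optionally single-base indels) on a read.
apply_read_errors <- function(seq, rate, indel_frac = 0) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (!length(hit)) return(seq)
  kind <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                 prob = c(1 - indel_frac, indel_frac / 2, indel_frac / 2))
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  sub_i <- hit[kind == "sub"]
  chars[sub_i] <- vapply(chars[sub_i],
                         function(b) sample(alt[[b]], 1L), character(1))
  del_i <- hit[kind == "del"]
  if (length(del_i)) chars[del_i] <- ""
  ins_i <- hit[kind == "ins"]
  if (length(ins_i)) {
    chars[ins_i] <- paste0(chars[ins_i],
                           sample(c("A", "C", "G", "T"), length(ins_i),
                                  replace = TRUE))
  }
  paste(chars, collapse = "")
}

#' Simulate long reads
#'
#' Reads sampled uniformly over the genome with random strand; lengths are
#' Gaussian around the mean (SD 10% of mean) truncated below at the minimum;
#' substitution errors at `error_rate` (an optional `indel_frac` of errors
#' become single-base indels; default 0, matching an identity check by direct
#' mismatch counting). Terminus-anchored reads can be requested so that every
#' terminus of interest is spanned; they are reported with the chromosome tip
#' at the read end.
#'
#' @param genome named character vector.
#' @param length_params numeric `c(mean, min)` bp.
#' @param error_rate per-base error fraction.
#' @param seed integer seed.
#' @param n_reads number of random reads (0 for terminal reads only).
#' @param termini optional data.frame `chrom`, `arm`, `length` of anchored
#'   reads to generate.
#' @param indel_frac fraction of errors realised as indels.
#' @return list: `reads` named character vector, `info` data.frame with source
#'   coordinates (`chrom`, `start`, `end` 0-based half-open, `strand`,
#'   `terminal`).
#' @export
simulate_long_reads <- function(genome, length_params = c(20000, 500),
                                error_rate = 0.1, seed = 1L, n_reads = 50L,
                                termini = NULL, indel_frac = 0) {
  with_stage_seed(seed, "reads", {
    mean_len <- length_params[[1]]
    min_len <- length_params[[2]]
    stopifnot(mean_len < max(nchar(genome)))
    reads <- character(0)
    info <- list()
    lens <- nchar(genome)
    if (n_reads > 0) {
      pick <- sample(seq_along(genome), n_reads, replace = TRUE,
                     prob = lens / sum(lens))
      for (k in seq_len(n_reads)) {
        ch <- pick[k]
        rl <- min(lens[ch], max(min_len, round(rnorm(1, mean_len,
                                                     0.1 * mean_len))))
        start <- floor(runif(1, 0, lens[ch] - rl + 1))
        raw <- substr(genome[[ch]], start + 1, start + rl)
        strand <- if (runif(1) < 0.5) "+" else "-"
        if (strand == "-") raw <- revcomp(raw)
        reads <- c(reads, apply_read_errors(raw, error_rate, indel_frac))
        info[[length(info) + 1L]] <- data.frame(
          read = sprintf("read_%04d", k), chrom = names(genome)[ch],
          start = start, end = start + rl, strand = strand, terminal = FALSE)
      }
    }
    if (!is.null(termini) && nrow(termini)) {
      for (k in seq_len(nrow(termini))) {
        ch <- termini$chrom[k]
        L <- nchar(genome[[ch]])
        rl <- min(L, termini$length[k])
        if (termini$arm[k] == "q") {
          raw <- substr(genome[[ch]], L - rl + 1, L)
          start <- L - rl
          strand <- "+"
        } else {
          raw <- revcomp(substr(genome[[ch]], 1, rl))
          start <- 0
          strand <- "-"
        }
        reads <- c(reads, apply_read_errors(raw, error_rate, indel_frac))
        info[[length(info) + 1L]] <- data.frame(
          read = sprintf("terminal_%s%s", ch, termini$arm[k]), chrom = ch,
          start = start, end = start + rl, strand = strand, terminal = TRUE)
      }
    }
    info <- if (length(info)) do.call(rbind, info) else
      data.frame(read = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0),
                 terminal = logical(0))
    names(reads) <- info$read
    list(reads = reads, info = info)
  })
}

#' Emit a duplication-pair table from planted family members
#'
#' One BED-like record per unordered pair of members of the same family
#' (`n` members give `n*(n-1)/2` records), with an identity column
#' approximated from the members' divergence from the family unit.
#'
#' @param members data.frame with `family`, `chrom`, `start`, `end` and
#'   optionally `divergence` columns (truth format of
#'   [simulate_reference()]).
#' @return data.frame `chromA,startA,endA,chromB,startB,endB,identity,family`.
#' @export
emit_segdup_table <- function(members) {
  cols <- c("chromA", "startA", "endA", "chromB", "startB", "endB",
            "identity", "family")
  if (is.null(members) || !nrow(members)) {
    return(stats::setNames(data.frame(character(0), numeric(0), numeric(0),
                                      character(0), numeric(0), numeric(0),
                                      numeric(0), character(0)), cols))
  }
  if (is.null(members$divergence)) members$divergence <- 0
  out <- list()
  for (fam in unique(members$family)) {
    m <- members[members$family == fam, ]
    n <- nrow(m)
    if (n < 2L) next
    idx <- utils::combn(n, 2L)
    out[[length(out) + 1L]] <- data.frame(
      chromA = m$chrom[idx[1, ]], startA = m$start[idx[1, ]],
      endA = m$end[idx[1, ]],
      chromB = m$chrom[idx[2, ]], startB = m$start[idx[2, ]],
      endB = m$end[idx[2, ]],
      identity = pmax(0, pmin(1, 1 - (m$divergence[idx[1, ]] +
                                        m$divergence[idx[2, ]]))),
      family = fam)
  }
  if (!length(out)) {
    return(stats::setNames(data.frame(character(0), numeric(0), numeric(0),
                                      character(0), numeric(0), numeric(0),
                                      numeric(0), character(0)), cols))
  }
  do.call(rbind, out)
}

#' Background partial-duplication pairs around a family core
#'
#' Real subtelomeres are duplication-rich: the segmental-duplication database
#' stacks many partial, mutually unrelated entries on top of a family's copies,
#' which is what pushes base-pair copy number past the high-copy threshold
#' while family membership (copies spanning the whole core) stays small. This
#' helper emulates that context: it emits pairs whose near side overhangs the
#' core from the left or right, covering the whole core in union but with no
#' single side spanning it, partnered with dispersed intervals elsewhere.
#'
#' @param core list/row with `chrom`, `start`, `end` of the family core locus.
#' @param n_left,n_right number of left-/right-overhanging entries.
#' @param partner_chrom chromosome carrying the partner intervals.
#' @param partner_base start coordinate of the first partner interval.
#' @param flank_step bp of extra flank per successive entry.
#' @return data.frame in [emit_segdup_table()] format (`family = "background"`).
#' @export
simulate_segdup_background <- function(core, n_left = 8L, n_right = 8L,
                                       partner_chrom = core$chrom,
                                       partner_base = 2e6,
                                       flank_step = 1000) {
  w <- core$end - core$start
  rows <- list()
  cursor <- partner_base
  add <- function(s, e) {
    width <- e - s
    row <- data.frame(chromA = core$chrom, startA = s, endA = e,
                      chromB = partner_chrom, startB = cursor,
                      endB = cursor + width,
                      identity = 0.97, family = "background")
    cursor <<- cursor + width + 10000
    rows[[length(rows) + 1L]] <<- row
  }
  for (i in seq_len(n_left)) {
    add(max(0, core$start - i * flank_step), core$start + ceiling(0.6 * w))
  }
  for (i in seq_len(n_right)) {
    add(core$start + floor(0.4 * w), core$end + i * flank_step)
  }
  do.call(rbind, rows)
}

#' Write a genome or read set as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path input file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path output file.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$contig_noise <- unclass(x$contig_noise)
  x$dup_unit_lengths <- as.list(x$dup_unit_lengths)
  x$read_length_params <- as.list(x$read_length_params)
  x$placements <- if (nrow(x$placements)) as.list(x$placements) else NULL
  x$event_list <- lapply(x$event_list, function(e) {
    e <- unclass(e)
    e[!vapply(e, function(v) is.null(v) || all(is.na(v)), logical(1))]
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path file written by [write_sim_config()] (or hand-authored with
#'   the same fields).
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  events <- lapply(x$event_list, function(e) {
    end_event(e$kind, e$chrom, e$arm, e$length,
              donor_chrom = e$donor_chrom, donor_arm = e$donor_arm,
              copies = e$copies, carrier = e$carrier)
  })
  placements <- if (!is.null(x$placements)) {
    as.data.frame(x$placements, stringsAsFactors = FALSE)
  } else NULL
  sim_config(
    n_chromosomes = x$n_chromosomes, chrom_length = x$chrom_length,
    enzyme_motif = x$enzyme_motif,
    dup_unit_lengths = unlist(x$dup_unit_lengths),
    placements = placements,
    divergence_schedule = unlist(x$divergence_schedule),
    event_list = events,
    contig_noise = do.call(noise_params, x$contig_noise),
    read_length_params = unlist(x$read_length_params),
    read_error_rate = x$read_error_rate,
    seed = x$seed)
}
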