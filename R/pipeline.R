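## End-to-end orchestration: simulate -> digest -> align -> call -> trio ->
## validate -> dup-family -> report, with per-stage toggles, a parameter log,
## and scoring against the planted truth.

#' Pipeline configuration
#'
#' Bundles the simulation conditions and every analysis parameter block. The
#' default configuration simulates a trio over five 5-Mb chromosomes with two
#' planted duplication families (units 9 kb and 8 kb, 16 members each) and
#' three chromosome-end events: a 50 kb duplicative extension of chr2q copied
#' from the chr1p tip, a 40 kb terminal deletion on chr3p, and a five-copy
#' tandem expansion of chr4q's terminal 11 kb unit.
#'
#' @param sim a [sim_config()] (`NULL` for the default trio scenario).
#' @param stages named logical vector toggling
#'   `simulate, digest, align, call, trio, validate, dupfam, report`.
#' @param align_params an [alignment_params()].
#' @param threshold_k SD multiplier of the extension/missing threshold.
#' @param merge_distance bp, reference label merging.
#' @param terminal_window bp, anchoring window.
#' @param coverage_threshold category-1 label coverage fraction.
#' @param tolerance,label_window inheritance/diploid label-difference
#'   parameters.
#' @param min_cn high-copy threshold for family detection.
#' @param subtel_window subtelomere window bp.
#' @param validation list: `read_len`, `read_error`, `k`, `min_coverage`.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL,
                            stages = c(simulate = TRUE, digest = TRUE,
                                       align = TRUE, call = TRUE,
                                       trio = TRUE, validate = TRUE,
                                       dupfam = TRUE, report = TRUE),
                            align_params = alignment_params(),
                            threshold_k = 3,
                            merge_distance = 450,
                            terminal_window = 5e5,
                            coverage_threshold = 0.5,
                            tolerance = 1L,
                            label_window = 10L,
                            min_cn = 22L,
                            subtel_window = 1e6,
                            validation = list(read_len = 1.5e5,
                                              read_error = 0.05, k = 16L,
                                              min_coverage = 0.5),
                            seed = 1L) {
  if (is.null(sim)) {
    sim <- sim_config(
      event_list = list(
        end_event("extension_by_duplication", "chr2", "q", 5e4,
                  donor_chrom = "chr1", donor_arm = "p",
                  carrier = "father1"),
        end_event("terminal_deletion", "chr3", "p", 4e4,
                  carrier = "mother1"),
        end_event("tandem_expansion", "chr4", "q", 11000, copies = 5L,
                  carrier = "mother2")),
      seed = seed)
  }
  structure(list(sim = sim, stages = stages, align_params = align_params,
                 threshold_k = threshold_k, merge_distance = merge_distance,
                 terminal_window = terminal_window,
                 coverage_threshold = coverage_threshold,
                 tolerance = tolerance, label_window = label_window,
                 min_cn = min_cn, subtel_window = subtel_window,
                 validation = validation, seed = as.integer(seed)),
            class = "pipeline_config")
}

## pooled adjacent-label statistics over a set of reference maps
pooled_interlabel_stats <- function(maps, gaps = NULL) {
  diffs <- numeric(0)
  excluded <- 0L
  for (m in maps) {
    if (length(m$labels) < 2L) next
    st <- tryCatch(interlabel_stats(m, gaps), error = function(e) NULL)
    if (is.null(st)) next
    d <- diff(m$labels)
    diffs <- c(diffs, d)
    excluded <- excluded + st$excluded_gap_intervals
  }
  if (length(diffs) < 2L) stop("not enough labels for pooled statistics")
  mu <- mean(diffs)
  list(mean_interval = mu / 1000,
       sd_interval = sqrt(mean((diffs - mu)^2)) / 1000,
       n_intervals = length(diffs), excluded_gap_intervals = excluded)
}

#' Run the chromosome-end pipeline end to end
#'
#' Executes the enabled stages in order, writes all artefacts under `outdir`
#' (FASTA, CMAP, XMAP, TSV reports, a JSON ledger and a parameter log) and
#' returns the result bundle invisibly. Reruns with the same configuration
#' and seed produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) list with `ref`, `trio`, `ref_maps`, `threshold`,
#'   `calls`, `trio_calls`, `diploid`, `validations`, `families`, `scoring`,
#'   `log`.
#' @export
run_end_to_end <- function(config = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  on <- function(st) isTRUE(config$stages[[st]])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  bundle <- list(log = character(0))

  ref <- NULL; trio <- NULL
  if (on("simulate")) {
    note("simulate: seed=%d chroms=%d len=%.0f motif=%s events=%d",
         config$seed, config$sim$n_chromosomes, config$sim$chrom_length,
         config$sim$enzyme_motif, length(config$sim$event_list))
    ref <- simulate_reference(config$sim)
    trio <- simulate_trio(ref$genome, config$sim$event_list,
                          seed = config$seed)
    write_fasta(ref$genome, file.path(outdir, "reference.fasta"))
    utils::write.table(ref$truth$members,
                       file.path(outdir, "truth_members.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(trio$truth$termini,
                       file.path(outdir, "truth_termini.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$ref <- ref
    bundle$trio <- trio
  }

  ref_maps <- NULL; thr <- NULL
  if (on("digest") && !is.null(ref)) {
    ref_maps <- lapply(names(ref$genome), function(ch) {
      digest_map(ref$genome[[ch]], config$sim$enzyme_motif, id = ch,
                 merge_distance = config$merge_distance)
    })
    stats <- pooled_interlabel_stats(ref_maps)
    thr <- compute_threshold(stats, config$threshold_k)
    note("digest: %d reference maps, mean interval %.2f kb sd %.2f kb, threshold %.1f kb",
         length(ref_maps), stats$mean_interval, stats$sd_interval,
         thr$threshold_reported)
    write_cmap(ref_maps, file.path(outdir, "reference.cmap"))
    bundle$ref_maps <- ref_maps
    bundle$threshold <- thr
  }

  samples <- c("father1", "father2", "mother1", "mother2",
               "child1", "child2")
  hap_genomes <- NULL
  contigs <- NULL; alignments <- NULL
  if (on("align") && !is.null(ref_maps)) {
    hap_genomes <- list(
      father1 = trio$father$h1, father2 = trio$father$h2,
      mother1 = trio$mother$h1, mother2 = trio$mother$h2,
      child1 = trio$child$h1, child2 = trio$child$h2)
    contigs <- list()
    alignments <- list()
    for (s in samples) {
      maps <- simulate_contig_maps(hap_genomes[[s]], config$sim$enzyme_motif,
                                   config$sim$contig_noise,
                                   seed = config$seed, id_prefix = s)
      contigs[[s]] <- maps
      alignments[[s]] <- do.call(c, lapply(maps, function(m) {
        align_label_maps(m, ref_maps, config$align_params)
      }))
    }
    note("align: %d contigs vs %d references (max_skip=%d, multi=%d)",
         sum(lengths(contigs)), length(ref_maps),
         config$align_params$max_skip, config$align_params$max_matches)
    write_cmap(do.call(c, unname(contigs)), file.path(outdir, "contigs.cmap"))
    write_xmap(do.call(c, unname(alignments)),
               file.path(outdir, "alignments.xmap"))
    bundle$contigs <- contigs
    bundle$alignments <- alignments
  }

  calls <- NULL
  if (on("call") && !is.null(alignments)) {
    thr_bp <- thr$threshold * 1000
    calls <- list()
    for (s in samples) {
      for (rm in ref_maps) {
        for (arm in c("p", "q")) {
          anc <- anchor_terminus(alignments[[s]], rm$id, arm, rm$length,
                                 config$terminal_window,
                                 config$align_params)
          cl <- call_terminus(anc, rm$length, arm, thr_bp, sample = s)
          if (cl$status %in% c("extension", "extension_and_missing")) {
            cmap <- Find(function(m) m$id == cl$anchor_id, contigs[[s]])
            cl <- classify_extension(cl, cmap, ref_maps,
                                     config$align_params,
                                     config$coverage_threshold)
          }
          calls[[length(calls) + 1L]] <- cl
        }
      }
    }
    note("call: %d terminus calls at threshold %.1f kb", length(calls),
         thr$threshold_reported)
    utils::write.table(calls_table(calls), file.path(outdir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$calls <- calls
    if (!is.null(trio)) {
      sc <- score_against_truth(calls, trio$truth$termini, thr_bp)
      utils::write.table(sc$table, file.path(outdir, "scoring.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("score: terminus-status recovery %.1f%%",
           100 * sc$status_accuracy)
      bundle$scoring <- sc
    }
  }

  if (on("trio") && !is.null(calls)) {
    anchored_map <- function(s, chrom, arm) {
      cl <- Find(function(x) x$sample == s && identical(x$chrom, chrom) &&
                   x$arm == arm, calls)
      if (is.null(cl) || is.na(cl$anchor_id)) return(NULL)
      Find(function(m) m$id == cl$anchor_id, contigs[[s]])
    }
    trio_calls <- list()
    correct <- 0L; total <- 0L
    for (rm in ref_maps) {
      for (arm in c("p", "q")) {
        for (h in c("child1", "child2")) {
          cm <- anchored_map(h, rm$id, arm)
          if (is.null(cm)) next
          fa <- Filter(Negate(is.null), list(
            anchored_map("father1", rm$id, arm),
            anchored_map("father2", rm$id, arm)))
          mo <- Filter(Negate(is.null), list(
            anchored_map("mother1", rm$id, arm),
            anchored_map("mother2", rm$id, arm)))
          tc <- trio_inheritance(cm, fa, mo, arm,
                                 tolerance = config$tolerance,
                                 window = config$label_window)
          tc$child <- h
          tc$chrom <- rm$id
          tc$arm <- arm
          truth_parent <- sub("[12]$", "", trio$truth$inheritance[[
            sub("child", "h", h)]])
          tc$truth_parent <- truth_parent
          tc$consistent <- tc$parent_of_origin %in% c(truth_parent, "both")
          correct <- correct + tc$consistent
          total <- total + 1L
          trio_calls[[length(trio_calls) + 1L]] <- tc
        }
        ## diploid check: both child haplotype contigs at this terminus
        }
    }
    diploid <- list()
    for (rm in ref_maps) {
      for (arm in c("p", "q")) {
        maps <- Filter(Negate(is.null), list(
          anchored_map("child1", rm$id, arm),
          anchored_map("child2", rm$id, arm)))
        if (length(maps)) {
          dd <- detect_diploid(maps, arm, tolerance = config$tolerance,
                               window = config$label_window)
          dd$chrom <- rm$id
          dd$arm <- arm
          diploid[[length(diploid) + 1L]] <- dd
        }
      }
    }
    note("trio: %d/%d child termini consistent with truth", correct, total)
    bundle$trio_calls <- trio_calls
    bundle$trio_consistency <- if (total) correct / total else NA_real_
    bundle$diploid <- diploid
    tt <- do.call(rbind, lapply(trio_calls, function(x) {
      data.frame(child = x$child, chrom = x$chrom, arm = x$arm,
                 parent_of_origin = x$parent_of_origin,
                 diff_father = x$diff_father, diff_mother = x$diff_mother,
                 truth_parent = x$truth_parent, consistent = x$consistent)
    }))
    if (!is.null(tt)) {
      utils::write.table(tt, file.path(outdir, "trio.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  if (on("validate") && !is.null(calls)) {
    validations <- list()
    tandems <- list()
    for (cl in calls) {
      if (is.na(cl$category)) next
      if (cl$category == 2L) {
        ## category-2 extensions have no predicted chimera; fall back to the
        ## longest terminal read and look for self-tandem structure
        hap <- hap_genomes[[cl$sample]]
        rd <- simulate_long_reads(
          hap[cl$chrom], error_rate = config$validation$read_error,
          seed = config$seed, n_reads = 0L,
          termini = data.frame(chrom = cl$chrom, arm = cl$arm,
                               length = config$validation$read_len))
        te <- estimate_tandem(unname(rd$reads[1]),
                              window = min(config$validation$read_len,
                                           4 * cl$extension_len),
                              k = config$validation$k)
        te$terminus <- paste0(cl$chrom, cl$arm)
        te$sample <- cl$sample
        tandems[[length(tandems) + 1L]] <- te
        next
      }
      hap <- hap_genomes[[cl$sample]]
      pred <- build_prediction(ref$genome, cl,
                               terminal_len = min(config$validation$read_len,
                                                  nchar(hap[[cl$chrom]])))
      rd <- simulate_long_reads(
        hap[cl$chrom], error_rate = config$validation$read_error,
        seed = config$seed, n_reads = 0L,
        termini = data.frame(chrom = cl$chrom, arm = cl$arm,
                             length = config$validation$read_len))
      ## terminal reads carry the tip at the read end; the prediction is
      ## distal-first, so flip the read into distal-first orientation
      read <- revcomp(unname(rd$reads[1]))
      v <- validate_extension(read, pred, k = config$validation$k,
                              min_extension_coverage =
                                config$validation$min_coverage)
      v$terminus <- paste0(cl$chrom, cl$arm)
      v$sample <- cl$sample
      validations[[length(validations) + 1L]] <- v
    }
    note("validate: %d category-1 extensions checked, %d confirmed; %d category-2 tandem analyses",
         length(validations),
         sum(vapply(validations, `[[`, logical(1), "confirmed")),
         length(tandems))
    bundle$validations <- validations
    bundle$tandems <- tandems
    if (length(validations)) {
      vt <- do.call(rbind, lapply(validations, function(v) {
        data.frame(terminus = v$terminus, sample = v$sample,
                   confirmed = v$confirmed,
                   covered_fraction = round(v$covered_fraction, 4),
                   internal_deletion = v$internal_deletion)
      }))
      utils::write.table(vt, file.path(outdir, "validation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  if (on("dupfam") && !is.null(ref)) {
    chrom_lengths <- vapply(ref$genome, nchar, numeric(1))
    pairs <- emit_segdup_table(ref$truth$members)
    ## dense partial-duplication background at each family's ancestral locus
    for (fam in unique(ref$truth$members$family)) {
      anc <- ref$truth$members[ref$truth$members$family == fam &
                                 ref$truth$members$arm == "i", ]
      if (nrow(anc)) {
        bg <- simulate_segdup_background(
          list(chrom = anc$chrom[1], start = anc$start[1], end = anc$end[1]),
          partner_chrom = anc$chrom[1], partner_base = anc$end[1] + 5e4)
        pairs <- rbind(pairs, bg)
      }
    }
    fams <- detect_families(pairs, chrom_lengths, min_cn = config$min_cn,
                            window = config$subtel_window)
    subtel_bp <- 2 * config$subtel_window * length(chrom_lengths)
    fam_rows <- lapply(fams, function(f) {
      en <- enrichment_test(f, subtel_bp, sum(chrom_lengths))
      data.frame(chrom = f$core$chrom, start = f$core$start,
                 end = f$core$end, core_len = f$core$length,
                 n_members = nrow(f$members),
                 n_subtelomeric = sum(f$members$subtelomeric),
                 fold = round(en$fold, 2),
                 p_value = signif(en$p_value, 3))
    })
    note("dupfam: %d families detected (min_cn=%d)", length(fams),
         config$min_cn)
    bundle$families <- fams
    if (length(fam_rows)) {
      utils::write.table(do.call(rbind, fam_rows),
                         file.path(outdir, "families.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  if (on("report") && !is.null(calls)) {
    rep <- paralogy_report(calls)
    writeLines(rep, file.path(outdir, "report.txt"))
    bundle$report <- rep
  }

  bundle$log <- log
  if (length(log)) writeLines(log, file.path(outdir, "log.txt"))
  summary <- list(
    stages_run = names(config$stages)[vapply(names(config$stages), on,
                                             logical(1))],
    seed = config$seed,
    threshold_kb = if (!is.null(thr)) thr$threshold_reported else NULL,
    status_accuracy = if (!is.null(bundle$scoring))
      bundle$scoring$status_accuracy else NULL,
    trio_consistency = bundle$trio_consistency,
    n_families = if (!is.null(bundle$families)) length(bundle$families)
      else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle)
}

## flatten terminus calls to a data.frame
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    data.frame(
      sample = x$sample, chrom = x$chrom, arm = x$arm, status = x$status,
      extension_len = x$extension_len, missing_len = x$missing_len,
      category = x$category,
      origins = paste(vapply(x$origins, function(o)
        paste0(o$chrom, o$arm, "(", o$orientation, ")"), character(1)),
        collapse = ","),
      anchor = x$anchor_id, anchor_score = round(x$anchor_score, 3))
  }))
}

#' Score terminus calls against planted truth
#'
#' Joins calls to the truth table by haplotype and terminus, derives the
#' expected status from the planted net length changes and the threshold, and
#' reports per-terminus agreement.
#'
#' @param calls list of `terminus_call`s.
#' @param truth_termini truth data.frame from [simulate_trio()].
#' @param threshold_bp threshold in bp.
#' @return list `table` (per-terminus comparison) and `status_accuracy`.
#' @export
score_against_truth <- function(calls, truth_termini, threshold_bp) {
  ct <- calls_table(calls)
  tt <- truth_termini
  tt$expected <- ifelse(tt$extension > threshold_bp, "extension",
                        ifelse(tt$missing > threshold_bp, "missing",
                               "reference"))
  merged <- merge(ct, tt[, c("hap", "chrom", "arm", "expected",
                             "extension", "missing")],
                  by.x = c("sample", "chrom", "arm"),
                  by.y = c("hap", "chrom", "arm"))
  merged$correct <- merged$status == merged$expected
  list(table = merged,
       status_accuracy = mean(merged$correct))
}

#' Per-terminus paralogy report
#'
#' A text summary of every analysed terminus: one line per sample with
#' status, net lengths, category and origins, plus the number of distinct
#' allele classes observed across samples (samples sharing status, category,
#' origin set and extension length, binned at 10 kb, form one class).
#'
#' @param calls list of `terminus_call`s.
#' @return character vector of report lines.
#' @export
paralogy_report <- function(calls) {
  ct <- calls_table(calls)
  out <- character(0)
  for (key in unique(paste0(ct$chrom, ct$arm))) {
    sel <- ct[paste0(ct$chrom, ct$arm) == key & !is.na(ct$chrom), ,
              drop = FALSE]
    if (!nrow(sel)) next
    out <- c(out, sprintf("terminus %s", key))
    cls <- unique(paste(sel$status, sel$category, sel$origins,
                        round(sel$extension_len / 1e4)))
    for (i in seq_len(nrow(sel))) {
      r <- sel[i, ]
      line <- sprintf("  %-8s %-22s ext=%-7.0f miss=%-7.0f", r$sample,
                      r$status, r$extension_len, r$missing_len)
      if (!is.na(r$category)) {
        line <- paste0(line, sprintf(" category=%d", r$category))
        if (nzchar(r$origins)) {
          line <- paste0(line, sprintf(" origins=%s", r$origins))
        }
      }
      out <- c(out, line)
    }
    out <- c(out, sprintf("  allele classes: %d", length(cls)))
  }
  out
}
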