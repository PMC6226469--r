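test_that("RLE copy-number profile equals per-base counting", {
  set.seed(61)
  lens <- c(u = 50000, v = 80000)
  expect_true(all(copy_number_profile(random_pairs(0, names(lens),
                                                   5e4)[0, ], lens)$count == 0))
  one <- data.frame(chromA = "u", startA = 0, endA = 10,
                    chromB = "u", startB = 20, endB = 30, identity = 1)
  pr <- copy_number_profile(one, c(u = 100))
  expect_identical(expand_profile(pr, c(u = 100))[[1]],
                   c(rep(1L, 10), rep(0L, 10), rep(1L, 10), rep(0L, 70)))

  for (i in 1:30) {
    pairs <- random_pairs(sample(1:50, 1), names(lens), 5e4)
    prof <- copy_number_profile(pairs, lens)
    expect_identical(expand_profile(prof, lens), brute_force_cn(pairs, lens))
    # runs partition the chromosome and adjacent runs differ
    for (ch in names(lens)) {
      p <- prof[prof$chrom == ch, ]
      expect_equal(p$start[1], 0)
      expect_equal(p$end[nrow(p)], unname(lens[[ch]]))
      if (nrow(p) > 1) {
        expect_true(all(p$start[-1] == p$end[-nrow(p)]))
        expect_true(all(diff(p$count) != 0))
      }
    }
  }
  bad <- data.frame(chromA = "u", startA = 0, endA = 6e4,
                    chromB = "u", startB = 0, endB = 10, identity = 1)
  expect_error(copy_number_profile(bad, lens), "beyond")
})

test_that("high-copy regions are maximal runs ordered by length", {
  lens <- c(w = 20000)
  flat <- data.frame(chrom = "w", start = 0, end = 20000, count = 21)
  class(flat) <- c("cn_profile", "data.frame")
  expect_equal(nrow(high_copy_regions(flat, min_cn = 22)), 0)

  prof <- data.frame(chrom = "w",
                     start = c(0, 100, 9100, 10000, 18000),
                     end = c(100, 9100, 10000, 18000, 20000),
                     count = c(3, 25, 4, 30, 2))
  class(prof) <- c("cn_profile", "data.frame")
  hc <- high_copy_regions(prof, min_cn = 22)
  expect_equal(hc$length, c(9000, 8000))
  expect_equal(hc$start, c(100, 10000))
})

test_that("family membership requires spanning the whole core", {
  region <- list(chrom = "c0", start = 1000, end = 10000)
  none <- data.frame(chromA = "c0", startA = 2000, endA = 12000,
                     chromB = "c9", startB = 0, endB = 10000, identity = 1)
  expect_equal(nrow(family_members(region, none)), 0)

  # 16 copies: the core copy paired with 15 homologs
  partners <- data.frame(chrom = paste0("c", 1:15),
                         start = 5000, end = 14000)
  pairs <- data.frame(chromA = "c0", startA = 900, endA = 10100,
                      chromB = partners$chrom, startB = partners$start,
                      endB = partners$end, identity = 1)
  mem <- family_members(region, pairs)
  expect_equal(nrow(mem), 16)
  expect_true(any(mem$chrom == "c0"))

  # a copy overlapping the core by half is not a member
  half <- rbind(pairs, data.frame(chromA = "c0", startA = 5000, endA = 20000,
                                  chromB = "cX", startB = 0, endB = 15000,
                                  identity = 1))
  expect_equal(nrow(family_members(region, half)), 16)
})

test_that("subtelomere filter flags members within the window", {
  lens <- c(big = 1e7)
  mem <- data.frame(chrom = "big",
                    start = c(5e5, 4e6, 9.5e6, 9.9e5),
                    end = c(5.09e5, 4.09e6, 9.509e6, 1.09e6))
  fl <- subtelomeric_filter(mem, lens, window = 1e6)
  expect_identical(fl$subtelomeric, c(TRUE, FALSE, TRUE, TRUE))

  fams <- list(list(core = list(), members = mem[2, , drop = FALSE]))
  expect_length(subtelomeric_filter(fams, lens), 0)
})

test_that("enrichment is an exact one-sided binomial tail", {
  mem0 <- data.frame(chrom = "c", start = 1, end = 2,
                     subtelomeric = rep(FALSE, 4))
  e0 <- enrichment_test(mem0, 2e4, 1e6)
  expect_equal(e0$fold, 0)
  expect_equal(e0$p_value, 1)

  mem <- data.frame(chrom = "c", start = 1, end = 2,
                    subtelomeric = rep(c(TRUE, FALSE), c(12, 4)))
  en <- enrichment_test(mem, 0.02 * 1e6, 1e6)
  expect_equal(en$fold, (12 / 16) / 0.02)
  expect_equal(en$p_value, sum(dbinom(12:16, 16, 0.02)), tolerance = 1e-12)

  sat <- enrichment_test(mem, 1e6, 1e6)
  expect_equal(sat$p_value, 1)
  expect_lte(sat$fold, 1)
  expect_error(enrichment_test(mem, 1, 0), "positive")

  # monotone non-increasing in k at fixed n, p0
  ps <- vapply(0:16, function(k) {
    m <- data.frame(chrom = "c", start = 1, end = 2,
                    subtelomeric = rep(c(TRUE, FALSE), c(k, 16 - k)))
    enrichment_test(m, 2e4, 1e6)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("divergence ignores indel columns", {
  expect_equal(pairwise_divergence("ACGT", "ACGT")$divergence, 0)

  a <- paste0(strrep("A", 500), "C", strrep("A", 499), "-----")
  b <- paste0(strrep("A", 500), "G", strrep("A", 498), "T", strrep("C", 5))
  d <- pairwise_divergence(a, b)
  expect_equal(d$aligned_bp, 1000)
  expect_equal(d$divergence, 0.2)

  rej <- pairwise_divergence(strrep("A", 7000), strrep("A", 7000),
                             min_aligned_bp = 9000)
  expect_true(rej$rejected)
})

test_that("built-in global aligner supports divergence estimation", {
  set.seed(62)
  a <- random_dna(2000)
  bv <- strsplit(a, "")[[1]]
  idx <- sample(2000, 20)
  alt <- c(A = "C", C = "G", G = "T", T = "A")
  bv[idx] <- alt[bv[idx]]
  al <- align_copies(a, paste(bv, collapse = ""))
  d <- pairwise_divergence(al$a, al$b)
  expect_equal(d$divergence, 1, tolerance = 0.1)
})

test_that("molecular-clock dating is divergence over rate", {
  expect_equal(date_duplication(0)$age_myr, 0)
  expect_equal(date_duplication(3)$age_myr, 10)
  a <- date_duplication(0.79)$age_myr
  expect_equal(a, 0.79 / 0.3, tolerance = 1e-12)
  expect_lt(abs(a - 2.64) / 2.64, 0.005)
  # linearity
  expect_equal(date_duplication(1.1)$age_myr + date_duplication(0.6)$age_myr,
               date_duplication(1.7)$age_myr, tolerance = 1e-12)
  expect_error(date_duplication(1, rate_pct_per_myr = 0), "positive")
})

test_that("subtelomeric duplication region is the merged terminal prefix", {
  iv <- data.frame(start = c(0, 50000, 130000), end = c(50000, 120000, 2e5))
  expect_equal(unname(subtel_region(iv)), c(0, 120000))
  expect_null(subtel_region(data.frame(start = 5000, end = 10000)))
  expect_equal(unname(subtel_region(data.frame(start = 0, end = 10000))),
               c(0, 10000))
  expect_null(subtel_region(NULL))
})

test_that("exon homology needs 90% coverage and >95% identity", {
  expect_true(exon_homology(100, 95, 0.96))
  expect_false(exon_homology(100, 80, 0.99))
  expect_false(exon_homology(100, 95, 0.95))   # strictly more than 95%
})

test_that("planted families are recovered from the emitted pair table", {
  cfg <- sim_config(n_chromosomes = 5, chrom_length = 8e5, seed = 19,
                    divergence_schedule = 0.003)
  ref <- simulate_reference(cfg)
  truth <- ref$truth$members
  expect_equal(as.integer(table(truth$family)[c("A", "B")]), c(16L, 16L))

  pairs <- emit_segdup_table(truth)
  lens <- vapply(ref$genome, nchar, numeric(1))
  for (fam in c("A", "B")) {
    anc <- truth[truth$family == fam & truth$arm == "i", ]
    pairs <- rbind(pairs, simulate_segdup_background(
      list(chrom = anc$chrom, start = anc$start, end = anc$end),
      partner_chrom = anc$chrom, partner_base = anc$end + 5e4))
  }

  prof <- copy_number_profile(pairs, lens)
  hc <- high_copy_regions(prof, min_cn = 22)
  expect_equal(nrow(hc), 2)
  expect_equal(hc$length, c(9000, 8000))   # family A core first

  fams <- detect_families(pairs, lens, min_cn = 22, window = 1.5e5)
  expect_length(fams, 2)
  for (i in 1:2) {
    fam_name <- c("A", "B")[i]
    mem <- fams[[i]]$members
    expect_equal(nrow(mem), 16)
    tm <- truth[truth$family == fam_name, ]
    expect_setequal(paste(mem$chrom, mem$start), paste(tm$chrom, tm$start))
    # subtelomeric flags match truth (interstitial ancestral copy unflagged)
    cmp <- merge(mem, tm[, c("chrom", "start", "subtelomeric")],
                 by = c("chrom", "start"), suffixes = c("", ".truth"))
    expect_equal(nrow(cmp), 16)
    expect_identical(cmp$subtelomeric, cmp$subtelomeric.truth)
  }
})
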