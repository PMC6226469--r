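test_that("threshold is mean + k standard deviations, reported at 0.1 kb", {
  tm <- compute_threshold(list(mean_interval = 8.2, sd_interval = 8.3))
  expect_equal(tm$threshold_reported, 33.1)
  expect_equal(tm$threshold, 8.2 + 3 * 8.3)
  expect_equal(compute_threshold(list(mean_interval = 10,
                                      sd_interval = 0))$threshold, 10)
  expect_equal(compute_threshold(list(mean_interval = 5, sd_interval = 2),
                                 k = 2)$threshold, 9)
})

test_that("anchoring prefers distality, then score, then span", {
  ref_len <- 1e6
  # A reaches 50 kb from the q end with a big score; B reaches 10 kb from
  # the end with a smaller score: distality wins
  a <- fake_alignment("A", "chr1", q_pos = seq(0, 9e5, by = 1e4),
                      r_pos = seq(0, 9e5, by = 1e4), qlen = 9.5e5)
  b <- fake_alignment("B", "chr1", q_pos = seq(0, 4e4, by = 1e4),
                      r_pos = seq(9.5e5, 9.9e5, by = 1e4), qlen = 5e4)
  expect_equal(anchor_terminus(list(a, b), "chr1", "q", ref_len)$query_id,
               "B")
  # equal distality: higher score wins
  c1 <- fake_alignment("C1", "chr1", q_pos = seq(0, 4e4, by = 1e4),
                       r_pos = seq(9.5e5, 9.9e5, by = 1e4), qlen = 5e4,
                       score = 11)
  c2 <- fake_alignment("C2", "chr1", q_pos = seq(0, 4e4, by = 1e4),
                       r_pos = seq(9.5e5, 9.9e5, by = 1e4), qlen = 5e4,
                       score = 11.5)
  expect_equal(anchor_terminus(list(c1, c2), "chr1", "q", ref_len)$query_id,
               "C2")
  # low per-interval quality cannot anchor at all
  junk <- fake_alignment("J", "chr1", q_pos = c(0, 1e4, 2e4),
                         r_pos = c(9.7e5, 9.8e5, 9.9e5), qlen = 3e4,
                         score = 2)
  expect_null(anchor_terminus(list(junk), "chr1", "q", ref_len))
  expect_null(anchor_terminus(list(), "chr1", "q", ref_len))
})

test_that("terminus calling nets contig and reference tails", {
  thr <- 33100
  # contig matches the reference exactly up to the last label: tails cancel
  eq <- fake_alignment("E", "chr1", q_pos = c(1e4, 2e4, 3e4),
                       r_pos = c(9.6e5, 9.7e5, 9.8e5), qlen = 5e4)
  cl <- call_terminus(eq, 1e6, "q", thr)
  expect_equal(cl$status, "reference")
  expect_equal(cl$extension_len, 0)
  expect_equal(cl$missing_len, 0)

  # 50 kb overhang past the last matched label (reference tail 0)
  ov <- fake_alignment("O", "chr1", q_pos = c(1e4, 2e4, 3e4),
                       r_pos = c(9.8e5, 9.9e5, 1e6 - 1), qlen = 3e4 + 1 + 5e4)
  cl <- call_terminus(ov, 1e6, "q", thr)
  expect_equal(cl$status, "extension")
  expect_equal(cl$extension_len, 5e4)

  # last matched ref label 60 kb from the end, 30 kb of it N-gap, no
  # overhang: net missing 30 kb, below threshold -> reference
  mi <- fake_alignment("M", "chr1", q_pos = c(1e4, 2e4, 3e4),
                       r_pos = c(9.2e5, 9.3e5, 9.4e5), qlen = 3e4)
  cl <- call_terminus(mi, 1e6, "q", thr,
                      n_gaps = data.frame(start = 9.5e5, end = 9.8e5))
  expect_equal(cl$missing_len, 3e4)
  expect_equal(cl$status, "reference")
  # without the N correction the same terminus is missing
  cl2 <- call_terminus(mi, 1e6, "q", thr)
  expect_equal(cl2$missing_len, 6e4)
  expect_equal(cl2$status, "missing")

  # p arm mirror: overhang at the low-coordinate end
  pv <- fake_alignment("P", "chr1", q_pos = c(4e4, 5e4, 6e4),
                       r_pos = c(0, 1e4, 2e4), qlen = 7e4)
  cl <- call_terminus(pv, 1e6, "p", thr)
  expect_equal(cl$extension_len, 4e4)
  expect_equal(cl$status, "extension")

  expect_equal(call_terminus(NULL, 1e6, "q", thr)$status, "excluded")
})

test_that("raising the threshold multiplier never creates events", {
  b <- small_bundle()
  thr_lo <- b$threshold$threshold * 1000
  thr_hi <- compute_threshold(b$threshold, k = 6)$threshold * 1000
  for (cl in b$calls) {
    if (cl$status == "excluded") next
    hi_ext <- cl$extension_len > thr_hi
    lo_ext <- cl$extension_len > thr_lo
    expect_true(!hi_ext || lo_ext)
    expect_true(!(cl$missing_len > thr_hi) || cl$missing_len > thr_lo)
  }
})

test_that("planted extension is recovered with its origin; deletion as missing", {
  b <- small_bundle()
  ct <- do.call(rbind, lapply(b$calls, function(x)
    data.frame(sample = x$sample, chrom = x$chrom, arm = x$arm,
               status = x$status, ext = x$extension_len,
               mis = x$missing_len,
               category = ifelse(is.na(x$category), 0L, x$category),
               origin1 = if (length(x$origins))
                 paste0(x$origins[[1]]$chrom, x$origins[[1]]$arm) else "")))
  ext_call <- ct[ct$sample == "father1" & ct$chrom == "chr2" & ct$arm == "q", ]
  expect_equal(ext_call$status, "extension")
  expect_equal(ext_call$ext, 5e4)
  expect_equal(ext_call$category, 1L)
  expect_equal(ext_call$origin1, "chr1p")

  del_call <- ct[ct$sample == "mother1" & ct$chrom == "chr3" & ct$arm == "p", ]
  expect_equal(del_call$status, "missing")
  expect_equal(del_call$mis, 4.5e4)

  # every unaffected terminus is reference with zero net lengths
  rest <- ct[!(ct$chrom == "chr2" & ct$arm == "q") &
               !(ct$chrom == "chr3" & ct$arm == "p"), ]
  expect_true(all(rest$status == "reference"))
  expect_equal(b$scoring$status_accuracy, 1)
})

test_that("trio inheritance counts terminal label differences", {
  base <- label_map("child", 1e5, seq(5000, 55000, by = 10000))   # 6 labels
  mother <- label_map("mother", 1e5, base$labels)
  father <- label_map("father", 1e5, base$labels[-6])             # 1 distal off
  tc <- trio_inheritance(base, father, mother, arm = "q")
  expect_equal(tc$diff_mother, 0)
  expect_equal(tc$diff_father, 1)
  expect_equal(tc$parent_of_origin, "both")

  far <- label_map("far", 1e5, base$labels[1:2])                  # 4 off
  tc2 <- trio_inheritance(base, far, mother, arm = "q")
  expect_equal(tc2$diff_father, 4)
  expect_equal(tc2$parent_of_origin, "mother")

  tc3 <- trio_inheritance(base, far, label_map("m2", 1e5, base$labels[1:3]),
                          arm = "q")
  expect_equal(tc3$parent_of_origin, "neither")

  expect_equal(trio_inheritance(base, NULL, mother, "q")$parent_of_origin,
               "neither")
})

test_that("trio recovery is perfect on the noise-free simulation", {
  b <- small_bundle()
  expect_equal(b$trio_consistency, 1)
})

test_that("diploid detection separates extended from reference alleles", {
  ref_type <- label_map("c1", 1e5, seq(5000, 55000, by = 10000))
  extended <- label_map("c2", 1.45e5,
                        c(seq(5000, 55000, by = 10000),
                          seq(70000, 140000, by = 12000)))
  one <- detect_diploid(list(ref_type), "q")
  expect_equal(one$n_alleles, 1L)
  two <- detect_diploid(list(ref_type, extended), "q")
  expect_equal(two$n_alleles, 2L)
  near <- label_map("c3", 1e5, ref_type$labels[-1])
  same <- detect_diploid(list(ref_type, near), "q")
  expect_equal(same$n_alleles, 1L)
})

test_that("reference called against itself is reference everywhere", {
  set.seed(31)
  genome <- vapply(c(chr1 = 1, chr2 = 2), function(i) random_dna(5e5),
                   character(1))
  names(genome) <- c("chr1", "chr2")
  ref_maps <- lapply(names(genome), function(ch)
    digest_map(genome[[ch]], id = ch))
  contigs <- lapply(ref_maps, function(m)
    label_map(paste0("self_", m$id), m$length, m$labels))
  p <- alignment_params()
  for (i in seq_along(contigs)) {
    alns <- align_label_maps(contigs[[i]], ref_maps, p)
    for (arm in c("p", "q")) {
      anc <- anchor_terminus(alns, ref_maps[[i]]$id, arm,
                             ref_maps[[i]]$length)
      cl <- call_terminus(anc, ref_maps[[i]]$length, arm, 33100)
      expect_equal(cl$status, "reference")
      expect_equal(cl$extension_len, 0)
      expect_equal(cl$missing_len, 0)
    }
  }
})
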