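test_that("reference simulation plants family copies where asked", {
  # no placements: pure random sequence, empty member table
  cfg0 <- sim_config(n_chromosomes = 2, chrom_length = 5e4,
                     dup_unit_lengths = numeric(0),
                     placements = NULL, seed = 3)
  ref0 <- simulate_reference(cfg0)
  expect_equal(nrow(ref0$truth$members), 0)
  expect_equal(nchar(ref0$genome[["chr1"]]), 5e4)

  # three zero-divergence copies are identical and within their arm windows
  pl <- data.frame(family = "A", chrom = c("chr1", "chr2", "chr2"),
                   arm = c("p", "q", "p"), offset = c(1000, 2000, 3000))
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 1e5,
                    dup_unit_lengths = c(A = 9000), placements = pl,
                    divergence_schedule = 0, seed = 4)
  ref <- simulate_reference(cfg)
  mem <- ref$truth$members
  expect_equal(nrow(mem), 3)
  seqs <- mapply(function(ch, s, e, arm) {
    x <- substr(ref$genome[[ch]], s + 1, e)
    if (arm == "q") revcomp(x) else x
  }, mem$chrom, mem$start, mem$end, mem$arm)
  expect_equal(unique(unname(seqs)), ref$truth$units[["A"]])
  expect_true(all(mem$start[mem$arm == "p"] < 20000))
  expect_true(all(mem$end[mem$arm == "q"] > 1e5 - 20000))

  expect_error(simulate_reference(
    sim_config(n_chromosomes = 1, chrom_length = 1e4,
               dup_unit_lengths = c(A = 9000),
               placements = data.frame(family = "A", chrom = "chr1",
                                       arm = "q", offset = 5000),
               seed = 1)), "bounds")
})

test_that("divergence schedule produces the configured mismatch fraction", {
  pl <- data.frame(family = "A", chrom = "chr1", arm = "p", offset = 1000)
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 5e4,
                    dup_unit_lengths = c(A = 10000), placements = pl,
                    divergence_schedule = 0.01, seed = 8)
  ref <- simulate_reference(cfg)
  mem <- ref$truth$members
  copy <- substr(ref$genome[["chr1"]], mem$start + 1, mem$end)
  unit <- ref$truth$units[["A"]]
  mm <- sum(strsplit(copy, "")[[1]] != strsplit(unit, "")[[1]])
  # binomial oracle: within 3 SDs of n * p
  expect_lt(abs(mm - 10000 * 0.01), 3 * sqrt(10000 * 0.01 * 0.99))
})

test_that("end events edit termini as specified", {
  set.seed(5)
  ref <- c(chrA = random_dna(50000), chrB = random_dna(50000))

  # terminal deletion of length 0 is the identity
  hap <- apply_end_event(ref, end_event("terminal_deletion", "chrA", "q", 0),
                         ref)
  expect_identical(hap, ref)

  # tandem expansion length arithmetic: + (copies-1) * unit
  hap <- apply_end_event(ref, end_event("tandem_expansion", "chrA", "q",
                                        1100, copies = 4L), ref)
  expect_equal(nchar(hap[["chrA"]]), 50000 + 3 * 1100)
  # tandem with copies = 1 is the identity
  hap1 <- apply_end_event(ref, end_event("tandem_expansion", "chrA", "q",
                                         1100, copies = 1L), ref)
  expect_identical(hap1, ref)

  # duplicative extension: terminal segment of the target, read
  # terminus-distally, equals the donor's terminus-distal segment
  ev <- end_event("extension_by_duplication", "chrB", "q", 2000,
                  donor_chrom = "chrA", donor_arm = "p")
  hap <- apply_end_event(ref, ev, ref)
  expect_equal(nchar(hap[["chrB"]]), 52000)
  got <- revcomp(substr(hap[["chrB"]], 50001, 52000))
  expect_identical(got, substr(ref[["chrA"]], 1, 2000))

  # p-arm event via mirroring: same property at the p terminus
  evp <- end_event("extension_by_duplication", "chrB", "p", 2000,
                   donor_chrom = "chrA", donor_arm = "q")
  happ <- apply_end_event(ref, evp, ref)
  expect_identical(substr(happ[["chrB"]], 1, 2000),
                   revcomp(substr(ref[["chrA"]], 48001, 50000)))

  expect_error(apply_end_event(ref, end_event("terminal_deletion", "chrA",
                                              "q", 60000), ref), "length")
})

test_that("trio transmission copies parental haplotypes verbatim", {
  set.seed(6)
  ref <- c(chr1 = random_dna(30000), chr2 = random_dna(30000))
  t0 <- simulate_trio(ref, list(), seed = 2)
  expect_identical(t0$child$h1, t0[[sub("[12]$", "", t0$truth$inheritance[["h1"]])]][[
    paste0("h", sub("^\\D+", "", t0$truth$inheritance[["h1"]]))]])

  ev <- end_event("extension_by_duplication", "chr2", "q", 2000,
                  donor_chrom = "chr1", donor_arm = "p", carrier = "father1")
  tr <- simulate_trio(ref, list(ev), seed = 2)
  if (tr$truth$inheritance[["h1"]] == "father1") {
    expect_identical(tr$child$h1, tr$father$h1)
    expect_equal(nchar(tr$child$h1[["chr2"]]), 32000)
  } else {
    expect_identical(tr$child$h1, tr$father$h2)
  }
  # heterozygous child: one extended, one reference-type chromosome end
  expect_true(nchar(tr$father$h1[["chr2"]]) != nchar(tr$mother$h1[["chr2"]]) ||
                nchar(tr$father$h1[["chr2"]]) != nchar(tr$mother$h2[["chr2"]]))

  expect_error(simulate_trio(ref, list(ev, ev), seed = 1), "conflicting")
})

test_that("contig map noise model behaves at its boundaries", {
  set.seed(7)
  genome <- c(chrZ = random_dna(2e5))
  clean <- simulate_contig_maps(genome, noise = noise_params(0, 0, 0, 0, 0),
                                seed = 1)
  expect_identical(clean[[1]]$labels, insilico_digest(genome[[1]]))
  expect_equal(clean[[1]]$length, 2e5)

  none <- simulate_contig_maps(genome, noise = noise_params(0, 0, 0, 1, 0),
                               seed = 1)
  expect_length(none[[1]]$labels, 0)

  expect_identical(simulate_contig_maps(character(0)), list())
})

test_that("label miss rate follows the binomial oracle", {
  # ~1000 true labels from a repeated unit carrying one motif each
  unit <- paste0(random_dna(500), "GCTCTTC", random_dna(493))
  genome <- c(chrR = strrep(unit, 1000))
  n_true <- length(insilico_digest(genome[[1]]))
  expect_gte(n_true, 1000)
  maps <- simulate_contig_maps(genome, noise = noise_params(0, 0, 0, 0.06, 0),
                               seed = 42)
  kept <- length(maps[[1]]$labels)
  expect_lt(abs(kept - n_true * 0.94), 3 * sqrt(n_true * 0.06 * 0.94))
})

test_that("long reads are exact substrings at zero error", {
  set.seed(8)
  genome <- c(c1 = random_dna(60000), c2 = random_dna(60000))
  rd <- simulate_long_reads(genome, length_params = c(5000, 500),
                            error_rate = 0, seed = 3, n_reads = 20)
  for (i in seq_len(nrow(rd$info))) {
    src <- substr(genome[[rd$info$chrom[i]]], rd$info$start[i] + 1,
                  rd$info$end[i])
    if (rd$info$strand[i] == "-") src <- revcomp(src)
    expect_identical(unname(rd$reads[i]), src)
  }
})

test_that("read error rate matches the mismatch-count oracle", {
  set.seed(9)
  genome <- c(c1 = random_dna(80000))
  rd <- simulate_long_reads(genome, length_params = c(10000, 5000),
                            error_rate = 0.1, seed = 4, n_reads = 10)
  for (i in seq_len(nrow(rd$info))) {
    src <- substr(genome[[1]], rd$info$start[i] + 1, rd$info$end[i])
    if (rd$info$strand[i] == "-") src <- revcomp(src)
    a <- strsplit(unname(rd$reads[i]), "")[[1]]
    b <- strsplit(src, "")[[1]]
    mm <- sum(a != b)
    n <- length(b)
    # substitutions to a different base at rate 0.1: identity ~0.9
    expect_lt(abs(mm - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9))
  }
})

test_that("terminus-anchored reads end at the chromosome end", {
  set.seed(10)
  genome <- c(c1 = random_dna(50000))
  rd <- simulate_long_reads(genome, error_rate = 0, seed = 5, n_reads = 0,
                            termini = data.frame(chrom = "c1",
                                                 arm = c("q", "p"),
                                                 length = 20000))
  expect_identical(unname(rd$reads[1]), substr(genome[[1]], 30001, 50000))
  # p-arm read is reported tip-at-end: its reverse complement is the prefix
  expect_identical(revcomp(unname(rd$reads[2])),
                   substr(genome[[1]], 1, 20000))
})

test_that("segdup table has one record per unordered member pair", {
  expect_equal(nrow(emit_segdup_table(NULL)), 0)

  mem2 <- data.frame(family = "A", chrom = c("c1", "c2"),
                     start = c(0, 100), end = c(90, 190), divergence = 0)
  tab2 <- emit_segdup_table(mem2)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$startA, 0)
  expect_equal(tab2$startB, 100)

  mem16 <- data.frame(family = "A", chrom = paste0("c", 1:16),
                      start = seq(0, by = 100, length.out = 16),
                      end = seq(90, by = 100, length.out = 16),
                      divergence = 0)
  expect_equal(nrow(emit_segdup_table(mem16)), 16 * 15 / 2)
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- small_sim_config(seed = 77)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$truth, r2$truth)
  m1 <- simulate_contig_maps(r1$genome[1], seed = 77)
  m2 <- simulate_contig_maps(r2$genome[1], seed = 77)
  expect_identical(m1, m2)
  rd1 <- simulate_long_reads(r1$genome[1], seed = 77, n_reads = 5,
                             length_params = c(20000, 500))
  rd2 <- simulate_long_reads(r2$genome[1], seed = 77, n_reads = 5,
                             length_params = c(20000, 500))
  expect_identical(rd1, rd2)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- sim_config(
    seed = 4,
    event_list = list(end_event("tandem_expansion", "chr4", "q", 11000,
                                copies = 4L, carrier = "mother1")))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$dup_unit_lengths, cfg$dup_unit_lengths)
  expect_equal(cfg2$placements, cfg$placements)
  expect_identical(cfg2$event_list[[1]]$copies, 4L)
  expect_identical(cfg2$event_list[[1]]$kind, "tandem_expansion")
  expect_equal(cfg2$contig_noise, cfg$contig_noise, ignore_attr = TRUE)
})
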