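# Shared fixtures, built in code. The small trio simulation is computed once
# per test run and reused across files (noise-free, three 800 kb chromosomes,
# one supra-threshold duplicative extension, one terminal deletion).

small_sim_config <- function(seed = 101) {
  sim_config(
    n_chromosomes = 3, chrom_length = 8e5,
    event_list = list(
      end_event("extension_by_duplication", "chr2", "q", 5e4,
                donor_chrom = "chr1", donor_arm = "p", carrier = "father1"),
      end_event("terminal_deletion", "chr3", "p", 4.5e4, carrier = "mother1")),
    contig_noise = noise_params(0, 0, 0, 0, 0),
    seed = seed)
}

small_bundle_cache <- new.env()

small_bundle <- function() {
  if (is.null(small_bundle_cache$b)) {
    small_bundle_cache$b <- run_end_to_end(
      pipeline_config(sim = small_sim_config(), subtel_window = 1.5e5,
                      seed = 101),
      outdir = file.path(tempdir(), "teloforge-small-bundle"))
  }
  small_bundle_cache$b
}

# a label_alignment built directly from matched positions (identity-quality
# score by default), for exercising anchoring/calling rules in isolation
fake_alignment <- function(query_id, ref_id, q_pos, r_pos, qlen,
                           orientation = "+", m = 3,
                           score = m * (length(q_pos) - 1)) {
  structure(list(
    query_id = query_id, ref_id = ref_id, orientation = orientation,
    pairs = cbind(seq_along(q_pos), seq_along(r_pos), deparse.level = 0),
    q_pos = q_pos, r_pos = r_pos, qlen = qlen,
    n_query_labels = length(q_pos), score = score, mode = "endoutlier",
    query_span = range(q_pos), ref_span = range(r_pos)
  ), class = "label_alignment")
}

random_label_map <- function(id, n, len = 50000, lo = 1000) {
  label_map(id, len, sort(sample(seq(lo, len - 1000), n)))
}

# per-base brute-force oracle for copy-number profiles
brute_force_cn <- function(pairs, chrom_lengths) {
  lapply(names(chrom_lengths), function(ch) {
    cn <- integer(chrom_lengths[[ch]])
    for (side in c("A", "B")) {
      sel <- pairs[[paste0("chrom", side)]] == ch
      for (i in which(sel)) {
        s <- pairs[[paste0("start", side)]][i]
        e <- pairs[[paste0("end", side)]][i]
        cn[(s + 1):e] <- cn[(s + 1):e] + 1L
      }
    }
    cn
  })
}

expand_profile <- function(profile, chrom_lengths) {
  lapply(names(chrom_lengths), function(ch) {
    p <- profile[profile$chrom == ch, ]
    rep(p$count, p$end - p$start)
  })
}

random_pairs <- function(n, chroms, max_len) {
  mk <- function() {
    s <- sample.int(max_len - 2, n, replace = TRUE) - 1
    w <- sample.int(max_len / 4, n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE), start = s,
               end = pmin(s + w, max_len))
  }
  a <- mk()
  b <- mk()
  data.frame(chromA = a$chrom, startA = a$start, endA = a$end,
             chromB = b$chrom, startB = b$start, endB = b$end,
             identity = runif(n, 0.9, 1))
}
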