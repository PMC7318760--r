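test_that("genome generation is reproducible and hits its GC target", {
  g1 <- generate_genome(10000, 0.5, seed = 1)
  g2 <- generate_genome(10000, 0.5, seed = 1)
  expect_identical(g1$sequence, g2$sequence)

  g <- generate_genome(50000, 0.6, seed = 7)
  gc <- sum(strsplit(g$sequence, "")[[1L]] %in% c("C", "G"))
  expect_lt(abs(gc - 30000), 3 * sqrt(50000 * 0.6 * 0.4))

  expect_error(generate_genome(500, 0.5), "length")
  expect_error(generate_genome(10000, 0), "gc_fraction")
  expect_error(generate_genome(10000, 1), "gc_fraction")
})

test_that("strain evolution applies substitutions at the requested divergence", {
  g <- generate_genome(20000, 0.5, seed = 2)
  expect_identical(evolve_strain(g, 0, seed = 3)$sequence, g$sequence)

  m <- evolve_strain(g, 0.05, seed = 4)
  expect_equal(nchar(m$sequence), nchar(g$sequence))
  d <- sum(strsplit(g$sequence, "")[[1L]] != strsplit(m$sequence, "")[[1L]])
  expect_lt(abs(d - 1000), 3 * sqrt(20000 * 0.05 * 0.95))

  m2 <- evolve_strain(g, 0.05, seed = 5)
  expect_false(identical(m$sequence, m2$sequence))
  expect_error(evolve_strain(g, 0.3), "divergence")
})

test_that("fragment sampling respects abundances, strands and the length floor", {
  gA <- generate_genome(20000, 0.5, seed = 10, id = "A", taxon_id = "A")
  gB <- generate_genome(20000, 0.5, seed = 11, id = "B", taxon_id = "B")
  mix1 <- taxon_mix(mix_component(gA, 1))
  frag1 <- sample_fragments(mix1, 500, seed = 12)
  expect_true(all(frag1$taxon_id == "A"))

  mix <- taxon_mix(mix_component(gA, 0.8), mix_component(gB, 0.2))
  frag <- sample_fragments(mix, 10000, seed = 13)
  nA <- sum(frag$taxon_id == "A")
  expect_lt(abs(nA - 8000), 3 * sqrt(10000 * 0.8 * 0.2))
  expect_true(all(nchar(frag$seq_original) >= 30))
  expect_true(all(frag$end - frag$start == nchar(frag$seq_original)))
  expect_true(all(frag$strand %in% c("+", "-")))

  expect_error(sample_fragments(mix, 100, min_length = 30000, seed = 1),
               "min_length")
})

test_that("deamination converts Cs per the positional model and records the mask", {
  g <- generate_genome(5000, 0.5, seed = 20, id = "g")
  frag <- sample_fragments(taxon_mix(mix_component(g, 1)), 300, seed = 21)

  none <- apply_deamination(frag, damage_model(0, 0), seed = 22)
  expect_identical(none$seq_damaged, none$seq_original)
  expect_true(all(none$n_deaminated == 0L))

  all_deam <- apply_deamination(frag, damage_model(1, 1), seed = 23)
  n_c <- vapply(strsplit(frag$seq_original, ""), function(ch) sum(ch == "C"),
                integer(1L))
  expect_identical(all_deam$n_deaminated, n_c)
  expect_false(any(grepl("C", all_deam$seq_damaged)))

  part <- apply_deamination(frag, damage_model(0.5, 0.02, 3), seed = 24)
  for (i in seq_len(nrow(part))) {
    off <- part$mask[[i]]
    if (length(off) == 0L) next
    orig <- strsplit(part$seq_original[i], "")[[1L]]
    dam <- strsplit(part$seq_damaged[i], "")[[1L]]
    expect_true(all(orig[off + 1L] == "C"))
    expect_true(all(dam[off + 1L] == "T"))
  }
})

test_that("terminal deamination rate matches p_term over many molecules", {
  g <- generate_genome(50000, 0.5, seed = 30, id = "g")
  frag <- sample_fragments(taxon_mix(mix_component(g, 1)), 100000, seed = 31)
  dam <- apply_deamination(frag, damage_model(0.5, 0.01, 3), seed = 32)
  term_c <- substr(dam$seq_original, 1, 1) == "C"
  hit <- vapply(dam$mask, function(m) 0L %in% m, logical(1L))
  rate <- mean(hit[term_c])
  n <- sum(term_c)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.5 * 0.5 / n))
})

test_that("the uracil partition rule is exact at perfect efficiency and binomial otherwise", {
  g <- generate_genome(5000, 0.5, seed = 40, id = "g")
  frag <- sample_fragments(taxon_mix(mix_component(g, 1)), 10000, seed = 41)
  dam <- apply_deamination(frag, damage_model(0.9, 0.05, 3), seed = 42)

  perfect <- partition_library(dam, fractionation_model(1, 1), seed = 43)
  expect_true(all(perfect$fraction[perfect$n_deaminated > 0] == "enriched"))
  expect_true(all(perfect$fraction[perfect$n_deaminated == 0] == "depleted"))

  leaky <- partition_library(dam, fractionation_model(0.9, 1), seed = 44)
  with_u <- leaky[leaky$n_deaminated > 0, ]
  n_u <- nrow(with_u)
  spill <- sum(with_u$fraction == "depleted")
  expect_lt(abs(spill - 0.1 * n_u), 3 * sqrt(n_u * 0.9 * 0.1))

  expect_error(partition_library(frag, fractionation_model()), "mask")
})

test_that("sequencing error hits at the configured rate and never edits the truth mask", {
  g <- generate_genome(5000, 0.5, seed = 50, id = "g")
  frag <- sample_fragments(taxon_mix(mix_component(g, 1)), 8000, seed = 51)
  dam <- apply_deamination(frag, damage_model(0.3, 0.01, 3), seed = 52)

  clean <- add_sequencing_error(dam, 0, seed = 53)
  expect_identical(clean$seq_observed, clean$seq_damaged)

  noisy <- add_sequencing_error(dam, 0.003, seed = 54)
  expect_identical(noisy$mask, dam$mask)
  n_bases <- sum(nchar(noisy$seq_damaged))
  n_err <- sum(vapply(seq_len(nrow(noisy)), function(i)
    sum(strsplit(noisy$seq_damaged[i], "")[[1L]] !=
          strsplit(noisy$seq_observed[i], "")[[1L]]), integer(1L)))
  expect_lt(abs(n_err - n_bases * 0.003), 3 * sqrt(n_bases * 0.003 * 0.997))

  expect_error(add_sequencing_error(dam, 0.5), "error_rate")
})

test_that("simulate_sample conserves molecules, is byte-reproducible, and honours the partition", {
  g <- generate_genome(5000, 0.5, seed = 60, id = "anc", taxon_id = "anc")
  cont <- generate_genome(5000, 0.5, seed = 61, id = "cont", taxon_id = "cont")
  cfg <- sim_config(taxon_mix(mix_component(g, 0.5, damage_model(0.3, 0.01, 3)),
                              mix_component(cont, 0.5)),
                    n_molecules = 1000, error_rate = 0.001)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_sample(cfg, seed = 62, out_dir = d1, format = "fastq")
  simulate_sample(cfg, seed = 62, out_dir = d2, format = "fastq")
  for (f in c("enriched.fastq", "depleted.fastq", "truth.tsv", "config.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  tt <- read.delim(file.path(d1, "truth.tsv"))
  expect_equal(nrow(tt), 1000)
  n_enr <- length(Biostrings::readDNAStringSet(file.path(d1, "enriched.fastq"),
                                               format = "fastq"))
  n_dep <- length(Biostrings::readDNAStringSet(file.path(d1, "depleted.fastq"),
                                               format = "fastq"))
  expect_equal(n_enr + n_dep, 1000)
  expect_false(anyDuplicated(tt$read_id) > 0)

  # contaminant-only mix with perfect fractionation: nothing can be enriched
  cfg0 <- sim_config(taxon_mix(mix_component(cont, 1)), n_molecules = 500,
                     error_rate = 0)
  d3 <- withr::local_tempdir()
  lib0 <- simulate_sample(cfg0, seed = 63, out_dir = d3)
  expect_equal(sum(lib0$molecules$fraction == "enriched"), 0)
  expect_equal(length(Biostrings::readDNAStringSet(file.path(d3, "enriched.fasta"))), 0)
})

test_that("conditional damage oracle matches hand enumeration and brute force", {
  # single C at position 0: any deamination implies enrichment, so the
  # conditional frequency is 1
  m1 <- damage_model(0.3, 0.3, 5, symmetric_ends = FALSE)
  expect_equal(expected_conditional_damage(m1, molecules = data.frame(
    seq_original = "CAAA"), positions = 0), 1.0)

  # Cs at positions 0 and 1 with p(0)=0.3, p(1)=0.1: P(enriched)=0.37,
  # conditional frequency at 0 = 0.3/0.37
  m2 <- damage_model(p_term = 0.3, p_base = 0.1, decay_len = 0.001,
                     symmetric_ends = FALSE)
  f0 <- expected_conditional_damage(m2, molecules = data.frame(
    seq_original = "CCAAAA"), positions = 0)
  expect_equal(f0, 0.3 / 0.37, tolerance = 1e-12)

  # brute-force enumeration over random molecules agrees everywhere
  set.seed(70)
  seqs <- replicate(20, paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = ""))
  m3 <- damage_model(0.4, 0.05, 2.5)
  for (pos in c(0, 1, 3)) {
    expect_equal(
      expected_conditional_damage(m3, molecules = data.frame(seq_original = seqs),
                                  positions = pos),
      bf_conditional_freq(seqs, m3, pos), tolerance = 1e-12)
  }

  # undamaged model: enrichment conditional is undefined
  expect_warning(
    out <- expected_conditional_damage(damage_model(0, 0),
                                       molecules = data.frame(seq_original = "CCCC"),
                                       positions = 0),
    "undefined")
  expect_true(is.na(out))
  expect_error(expected_conditional_damage(m3, molecules = data.frame(
    seq_original = "CAAA"), positions = 10), "beyond")
})

test_that("amplification fold is largest for low damage and shrinks as damage grows", {
  ld <- data.frame(length = 30:70, prob = dlnorm(30:70, log(45), 0.35))
  folds <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(pt)
    conditional_fold(damage_model(pt, pt / 10, 3), length_dist = ld),
    numeric(1L))
  expect_true(all(diff(folds) < 0))
  expect_gt(folds[1L], 2)
})
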