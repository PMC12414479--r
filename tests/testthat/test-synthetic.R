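test_that("generated proteins meet the structural contract", {
  cfg <- synth_config(n_proteins = 10, length_range = c(40, 60), n_sites = 20,
                      n_pairs = 10, seed = 1)
  prot <- gen_proteins(cfg)
  expect_equal(nrow(prot), 10L)
  expect_true(all(nchar(prot$sequence) >= 40 & nchar(prot$sequence) <= 60))
  # at least 3 candidate residues each
  n_sty <- vapply(strsplit(prot$sequence, ""),
                  function(ch) sum(ch %in% c("S", "T", "Y")), integer(1))
  expect_true(all(n_sty >= 3L))
  # determinism
  expect_identical(prot, gen_proteins(cfg))
  cfg2 <- cfg; cfg2$seed <- 2L
  expect_false(identical(prot, gen_proteins(cfg2)))
})

test_that("the base sampler draws letters uniformly", {
  cfg <- synth_config(n_proteins = 1500, length_range = c(60, 80),
                      n_sites = 10, n_pairs = 10, plant_signal = FALSE,
                      seed = 3)
  prot <- gen_proteins(cfg)
  chars <- unlist(strsplit(prot$sequence, ""))
  n <- length(chars)
  expect_gt(n, 1e5)
  counts <- table(factor(chars, levels = phosppi:::AA_LETTERS))
  # binomial 3-sigma band around p = 1/20 (conditioning on >= 3 S/T/Y
  # barely perturbs letter frequencies at these lengths)
  p <- 1 / 20
  band <- 3.3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(counts / n - p) < band + 0.002))
})

test_that("noiseless site labels follow the motif rule exactly", {
  cfg <- synth_config(n_proteins = 60, n_sites = 80, n_pairs = 10, seed = 5)
  prot <- gen_proteins(cfg)
  sites <- gen_site_dataset(cfg, prot)
  expect_equal(nrow(sites), 80L)
  # balanced classes
  expect_equal(sum(sites$label == 1L), sum(sites$label == 0L))
  # every label agrees with the generating rule on the final sequence
  seqs <- stats::setNames(prot$sequence, prot$id)
  rule <- vapply(seq_len(nrow(sites)), function(i) {
    phosppi:::motif_at(seqs[[sites$protein_id[i]]], sites$position[i],
                       cfg$signal_motif, cfg$motif_offsets)
  }, logical(1))
  expect_equal(sites$label, as.integer(rule))
  # records validate against the sequences unchanged
  expect_silent(validate_sites(sites, prot))
  # determinism
  expect_identical(sites, gen_site_dataset(cfg, prot))
})

test_that("half-noise site labels are independent of the motif", {
  cfg <- synth_config(n_proteins = 80, n_sites = 100, n_pairs = 10,
                      noise_rate = 0.5, seed = 6)
  prot <- gen_proteins(cfg)
  sites <- gen_site_dataset(cfg, prot)
  seqs <- stats::setNames(prot$sequence, prot$id)
  rule <- vapply(seq_len(nrow(sites)), function(i) {
    phosppi:::motif_at(seqs[[sites$protein_id[i]]], sites$position[i],
                       cfg$signal_motif, cfg$motif_offsets)
  }, logical(1))
  # agreement should hover around chance
  agree <- mean(sites$label == as.integer(rule))
  expect_gt(agree, 0.3)
  expect_lt(agree, 0.7)
})

test_that("undersized protein sets are rejected with advice", {
  cfg <- synth_config(n_proteins = 3, n_sites = 400, n_pairs = 10, seed = 7)
  prot <- gen_proteins(cfg)
  expect_error(gen_site_dataset(cfg, prot), "increase n_proteins")
})

test_that("effect labels depend on both partners through the XOR rule", {
  cfg <- synth_config(n_proteins = 150, n_sites = 50, n_pairs = 600, seed = 8)
  prot <- gen_proteins(cfg)
  pairs <- gen_ppi_dataset(cfg, prot)
  expect_equal(nrow(pairs), 600L)
  expect_silent(validate_pairs(pairs, prot))
  expect_identical(pairs, gen_ppi_dataset(cfg, prot))
  seqs <- stats::setNames(prot$sequence, prot$id)
  motif <- vapply(seq_len(nrow(pairs)), function(i) {
    phosppi:::motif_near(seqs[[pairs$protein_a_id[i]]], pairs$position[i],
                         cfg$signal_motif)
  }, logical(1))
  trig <- vapply(pairs$protein_b_id, function(id) {
    phosppi:::has_inhibitor(seqs[[id]], cfg$inhibitor_trigram)
  }, logical(1))
  # noiseless labels are exactly XOR(motif, trigram)
  expect_equal(pairs$label, as.integer(xor(motif, trig)))
  # class mix targets the enhancement fraction (binomial 3.3-sigma)
  p_hat <- mean(pairs$label)
  expect_lt(abs(p_hat - 0.7), 3.3 * sqrt(0.7 * 0.3 / 600))
  # the generating base rates (motif 0.8, trigram 1/6) cap an A-only
  # observer at 1 - p_t: conditioned on the motif state the label is
  # right only 5/6 of the time
  expect_equal(mean(pairs$label[motif]), 5 / 6, tolerance = 0.08)
  expect_equal(mean(pairs$label[!motif]), 1 / 6, tolerance = 0.3)
  # both partners matter: within each motif state the trigram flips the
  # conditional label distribution
  expect_gt(mean(pairs$label[motif & !trig]), 0.95)
  expect_lt(mean(pairs$label[motif & trig]), 0.05)
})

test_that("simulate_dataset writes a loadable, reproducible study", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_proteins = 40, n_sites = 30, n_pairs = 40, seed = 9)
  out <- simulate_dataset(cfg, dir)
  prot <- read_fasta(out$paths$fasta)
  expect_equal(prot, out$proteins)
  expect_equal(read_site_table(out$paths$sites, prot), out$sites)
  expect_equal(read_ppi_table(out$paths$pairs, prot), out$pairs)
  man <- jsonlite::read_json(out$paths$manifest)
  expect_equal(man$config$seed, 9L)
  expect_equal(man$n_pairs, 40L)
  # identical rerun gives byte-identical tables
  dir2 <- withr::local_tempdir()
  out2 <- simulate_dataset(cfg, dir2)
  expect_identical(readLines(out$paths$sites), readLines(out2$paths$sites))
  expect_identical(readLines(out$paths$pairs), readLines(out2$paths$pairs))
})
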