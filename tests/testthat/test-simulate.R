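test_that("the generator is fully deterministic under (config, seed)", {
  cfg <- sim_config(seed = 101,
                    molecules = list(list(id = "MC1", length = 15000,
                                          topology = "circular")),
                    repeats = list(list(length = 300, identity = 0.95,
                                        orientation = "inverted",
                                        mol_a = "MC1", pos_a = 2000,
                                        mol_b = "MC1", pos_b = 9000)),
                    ssr_plants = list(list(molecule = "MC1", motif = "AT",
                                           copies = 8, pos = 13000)))
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$genome$MC1$seq, g2$genome$MC1$seq)
  expect_identical(g1$manifest$repeats, g2$manifest$repeats)
  # reads too
  r1 <- simulate_reads(list(g1$genome$MC1), 50, seed = 3)
  r2 <- simulate_reads(list(g1$genome$MC1), 50, seed = 3)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  # and a different seed changes the output
  r3 <- simulate_reads(list(g1$genome$MC1), 50, seed = 4)
  expect_false(identical(r1$reads$seq, r3$reads$seq))
})

test_that("realized GC tracks the configured value", {
  cfg <- sim_config(seed = 5,
                    molecules = list(list(id = "MC1", length = 100000,
                                          topology = "circular")),
                    gc = 0.445)
  g <- make_genome(cfg)
  expect_lt(abs(gc_content(g$genome$MC1) - 0.445), 0.01)
})

test_that("infeasible placements error before any output", {
  cfg <- sim_config(seed = 6,
                    molecules = list(list(id = "MC1", length = 10000,
                                          topology = "circular")),
                    repeats = list(list(length = 500, identity = 1,
                                        orientation = "direct",
                                        mol_a = "MC1", pos_a = 2000,
                                        mol_b = "MC1", pos_b = 2300)))
  expect_error(make_genome(cfg), "overlap")
  cfg2 <- sim_config(seed = 6,
                     molecules = list(list(id = "MC1", length = 10000,
                                           topology = "circular")),
                     ssr_plants = list(list(molecule = "MC2", motif = "AT",
                                            copies = 6, pos = 100)))
  expect_error(make_genome(cfg2), "unknown molecule")
})

test_that("realized read error rates match the configured rates", {
  set.seed(1)
  mol <- molecule("m", rand_dna(20000), "circular")
  rs <- simulate_reads(list(mol), 40, seed = 9, meanlog = log(6000),
                       sdlog = 0.2, sub = 0.05, ins = 0.025, del = 0.025)
  total <- sum(rs$truth$length)
  expect_gt(total, 1e5)
  expect_lt(abs(sum(rs$truth$n_sub) / total - 0.05) / 0.05, 0.1)
  expect_lt(abs(sum(rs$truth$n_ins) / total - 0.025) / 0.025, 0.1)
  expect_lt(abs(sum(rs$truth$n_del) / total - 0.025) / 0.025, 0.1)
})

test_that("a full-length error-free circular read is a rotation of the molecule", {
  set.seed(2)
  mol <- molecule("m", rand_dna(500), "circular")
  rs <- simulate_reads(list(mol), 20, seed = 10, meanlog = log(5000),
                       sdlog = 0.01, sub = 0, ins = 0, del = 0)
  doubled <- paste0(mol$seq, mol$seq)
  doubled_rc <- oracle_revcomp(doubled)
  for (i in seq_len(nrow(rs$reads))) {
    expect_equal(nchar(rs$reads$seq[i]), 500L)  # truncated at L
    expect_true(grepl(rs$reads$seq[i], doubled, fixed = TRUE) ||
                  grepl(rs$reads$seq[i], doubled_rc, fixed = TRUE))
  }
})

test_that("mixture weights follow rf_true at both levels", {
  toy <- toy_repeat_genome(8000, 150, 1000, 5000, "direct", seed = 12)
  mix0 <- make_mixture(list(toy$mol), toy$rp, 0, level = "local",
                       flank = 200)
  expect_equal(mix0$weights, c(0.5, 0.5, 0, 0))
  mix1 <- make_mixture(list(toy$mol), toy$rp, 1, level = "local",
                       flank = 200)
  expect_equal(mix1$weights, c(0, 0, 0.5, 0.5))
  mix54 <- make_mixture(list(toy$mol), toy$rp, 0.54, level = "genome")
  expect_equal(sum(mix54$weights), 1)
  # parent carries 0.46, the two split circles together 0.54
  expect_equal(mix54$weights[1], 0.46)
  expect_equal(sum(mix54$weights[-1]), 0.54)
  expect_error(make_mixture(list(toy$mol), toy$rp, 1.2), "rf_true")
})

test_that("FASTQ round-trip preserves simulated reads", {
  set.seed(3)
  mol <- molecule("m", rand_dna(3000), "circular")
  rs <- simulate_reads(list(mol), 25, seed = 14, meanlog = log(800),
                       sdlog = 0.3)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs$reads, fq)
  back <- read_reads(fq)
  expect_equal(back$read_id, rs$reads$read_id)
  expect_equal(back$seq, rs$reads$seq)
})

test_that("simulate_cdna validates positions and applies edits", {
  cds <- "ATGCCACGATTCTAA"
  expect_equal(simulate_cdna(cds, integer(0)), cds)
  out <- simulate_cdna(cds, c(4, 5))
  expect_equal(substr(out, 4, 5), "TT")
  expect_error(simulate_cdna(cds, 1), "no C")
  # noise never touches edit positions
  noisy <- simulate_cdna(strrep("ATGCCACGATTCGGA", 50), c(4, 5),
                         seed = 5, noise = 0.02)
  expect_equal(substr(noisy, 4, 5), "TT")
})

test_that("supported_minor tracks rf_true across orientation and placement scenarios", {
  scen <- expand.grid(orientation = c("direct", "inverted"),
                      rf = c(0, 0.1, 0.5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(scen))) {
    cfg <- sim_config(seed = 200 + i,
                      molecules = list(list(id = "MC1", length = 15000,
                                            topology = "circular")),
                      repeats = list(list(length = 150, identity = 1,
                                          orientation = scen$orientation[i],
                                          mol_a = "MC1", pos_a = 3000,
                                          mol_b = "MC1", pos_b = 10000)))
    g <- make_genome(cfg)
    rp <- g$manifest$repeats; rp$hsp_id <- "R1"
    cs <- build_local_conformations(g$genome, rp, flank = 250)
    mix <- make_mixture(g$genome, rp, scen$rf[i], level = "local",
                        flank = 250)
    rs <- simulate_reads(mix, 150, seed = 300 + i, meanlog = log(600),
                         sdlog = 0.1, sub = 0, ins = 0, del = 0)
    rep <- recombination_report(classify_reads(rs$reads, cs), "R1")
    minor_emitted <- sum(rs$truth$molecule %in% c("c3", "c4")) > 0
    expect_equal(rep$supported_minor, scen$rf[i] > 0 && minor_emitted)
  }
})
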