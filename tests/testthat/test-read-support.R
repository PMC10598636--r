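# shared toy scenario: 20 kb circle with a 200 bp direct repeat
rf_scenario <- function(seed = 7, orientation = "direct") {
  cfg <- sim_config(seed = seed,
                    molecules = list(list(id = "MC1", length = 20000,
                                          topology = "circular")),
                    repeats = list(list(length = 200, identity = 1,
                                        orientation = orientation,
                                        mol_a = "MC1", pos_a = 3000,
                                        mol_b = "MC1", pos_b = 12000)))
  g <- make_genome(cfg)
  rp <- g$manifest$repeats
  rp$hsp_id <- "R1"
  cs <- build_local_conformations(g$genome, rp, flank = 300)
  list(g = g, rp = rp, cs = cs)
}

test_that("exact reads are assigned to their source conformation", {
  sc <- rf_scenario()
  cs <- sc$cs
  # read = exact substring of c3 spanning repeat +/- 200 bp
  read <- substr(cs$c3, cs$rep_start[3] - 200, cs$rep_end[3] + 200)
  a <- classify_read(read, cs, min_anchor = 100, min_margin = 20)
  expect_true(a$usable)
  expect_equal(a$best, "c3")
  expect_equal(a$strand, "+")
  expect_gte(a$anchor_left, 100)
  # same read reverse-complemented maps on the minus strand
  a2 <- classify_read(oracle_revcomp(read), cs)
  expect_equal(a2$best, "c3")
  expect_equal(a2$strand, "-")
})

test_that("uninformative reads are rejected with a reason", {
  sc <- rf_scenario()
  cs <- sc$cs
  # read wholly inside the repeat: flank coverage impossible
  inside <- substr(cs$c1, cs$rep_start[1] + 10, cs$rep_end[1] - 10)
  a <- classify_read(inside, cs, min_anchor = 50)
  expect_false(a$usable)
  expect_equal(a$reason, "too_short")
  # long enough overall but short right anchor: no span
  onesided <- substr(cs$c1, 1, cs$rep_end[1] + 50)
  b <- classify_read(onesided, cs, min_anchor = 100)
  expect_false(b$usable)
  expect_equal(b$reason, "no_span")
  # read shorter than repeat + 2 * min_anchor
  shorty <- substr(cs$c1, cs$rep_start[1] - 110, cs$rep_end[1] + 110)
  d <- classify_read(shorty, cs, min_anchor = 150)
  expect_equal(d$reason, "too_short")
})

test_that("reads simulated from c1 at 5% error are assigned c1, never c2-c4", {
  sc <- rf_scenario()
  mix <- make_mixture(sc$g$genome, sc$rp, rf_true = 0, level = "local",
                      flank = 300)
  c1only <- mix
  c1only$weights <- c(1, 0, 0, 0)
  rs <- simulate_reads(c1only, 500, seed = 31, meanlog = log(750),
                       sdlog = 0.1, sub = 0.03, ins = 0.01, del = 0.01)
  asn <- classify_reads(rs$reads, sc$cs, min_anchor = 100, min_margin = 20)
  usable <- asn[asn$usable, ]
  expect_gte(sum(usable$best == "c1") / nrow(usable), 0.99)
  expect_equal(sum(usable$best %in% c("c2", "c3", "c4")), 0L)
})

test_that("recombination_frequency implements the minor-read fraction", {
  expect_equal(recombination_frequency(10, 10, 0, 0), 0)
  expect_equal(recombination_frequency(23, 27, 3, 7), 10 / 60)
  expect_error(recombination_frequency(0, 0, 0, 0), "no informative reads")
  # invariant under swapping within reference and within minor pairs
  expect_equal(recombination_frequency(23, 27, 3, 7),
               recombination_frequency(27, 23, 7, 3))
})

test_that("wilson_interval matches the textbook formula and boundaries", {
  expect_equal(wilson_interval(0, 10)[["lo"]], 0)
  expect_equal(wilson_interval(10, 10)[["hi"]], 1)
  w <- wilson_interval(5, 20)
  # direct evaluation of the Wilson score formula
  z <- qnorm(0.975); p <- 0.25; n <- 20
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(w[["lo"]], centre - half, tolerance = 1e-12)
  expect_equal(w[["hi"]], centre + half, tolerance = 1e-12)
  expect_error(wilson_interval(1, 0), "positive")
})

test_that("call_supported applies the minor-conformation read threshold", {
  expect_false(call_supported(list(n3 = 0, n4 = 0)))
  expect_true(call_supported(list(n3 = 1, n4 = 0), min_reads = 1))
  expect_false(call_supported(list(n3 = 1, n4 = 0), min_reads = 3))
  expect_true(call_supported(list(n3 = 0, n4 = 5), min_reads = 3))
})

test_that("error-free reference-only mixtures never support the minor conformations", {
  sc <- rf_scenario(seed = 13)
  mix <- make_mixture(sc$g$genome, sc$rp, rf_true = 0, level = "local",
                      flank = 300)
  rs <- simulate_reads(mix, 300, seed = 17, meanlog = log(750), sdlog = 0.1,
                       sub = 0, ins = 0, del = 0)
  asn <- classify_reads(rs$reads, sc$cs)
  rep <- recombination_report(asn, "R1")
  expect_equal(rep$n3 + rep$n4, 0L)
  expect_false(rep$supported_minor)
  expect_equal(rep$rf, 0)
})

test_that("RF estimates recover the true mixture fraction (error-free and noisy)", {
  sc <- rf_scenario(seed = 19)
  hit <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    rf_true <- c(0.05, 0.2, 0.5)[(i %% 3) + 1]
    mix <- make_mixture(sc$g$genome, sc$rp, rf_true, level = "local",
                        flank = 300)
    rs <- simulate_reads(mix, 400, seed = 1000 + i, meanlog = log(750),
                         sdlog = 0.1, sub = 0, ins = 0, del = 0)
    rep <- recombination_report(classify_reads(rs$reads, sc$cs), "R1")
    hit <- hit + (rep$ci_low <= rf_true && rf_true <= rep$ci_high)
  }
  expect_gte(hit, ceiling(0.9 * reps))
  # 5% read error, rf_true = 0.2
  mix <- make_mixture(sc$g$genome, sc$rp, 0.2, level = "local", flank = 300)
  rs <- simulate_reads(mix, 600, seed = 99, meanlog = log(750), sdlog = 0.1,
                       sub = 0.03, ins = 0.01, del = 0.01)
  rep <- recombination_report(classify_reads(rs$reads, sc$cs), "R1")
  expect_lt(abs(rep$rf - 0.2), 0.05)
})

test_that("raising min_anchor never increases the usable-read count", {
  sc <- rf_scenario(seed = 23)
  mix <- make_mixture(sc$g$genome, sc$rp, 0.3, level = "local", flank = 300)
  rs <- simulate_reads(mix, 200, seed = 5, meanlog = log(650), sdlog = 0.25,
                       sub = 0, ins = 0, del = 0)
  prev <- Inf
  for (anchor in c(50, 100, 200, 280)) {
    asn <- classify_reads(rs$reads, sc$cs, min_anchor = anchor)
    expect_lte(sum(asn$usable), prev)
    prev <- sum(asn$usable)
  }
})

test_that("inverted repeats support read classification equally", {
  sc <- rf_scenario(seed = 29, orientation = "inverted")
  mix <- make_mixture(sc$g$genome, sc$rp, 0.25, level = "local", flank = 300)
  rs <- simulate_reads(mix, 300, seed = 7, meanlog = log(750), sdlog = 0.1,
                       sub = 0, ins = 0, del = 0)
  asn <- classify_reads(rs$reads, sc$cs)
  # perfect assignment against the truth sidecar
  ok <- asn$usable
  expect_gt(sum(ok), 100)
  expect_equal(asn$best[ok], rs$truth$molecule[ok])
})

test_that("genome-level mixtures yield spanning reads classified to the right source", {
  sc <- rf_scenario(seed = 37)
  mix <- make_mixture(sc$g$genome, sc$rp, 0.5, level = "genome")
  expect_equal(sum(mix$weights), 1)
  rs <- simulate_reads(mix, 400, seed = 11, meanlog = log(3000),
                       sdlog = 0.3, sub = 0, ins = 0, del = 0)
  asn <- classify_reads(rs$reads, sc$cs)
  rep <- recombination_report(asn, "R1")
  # parent reads hit c1/c2; split-product reads hit c3/c4
  expect_gt(rep$n1 + rep$n2, 0)
  expect_gt(rep$n3 + rep$n4, 0)
  expect_true(rep$supported_minor)
})
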