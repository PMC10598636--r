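test_that("toy circle conformations equal by-hand string construction", {
  # 60 bp circle, exact 10 bp direct repeat at 11-20 and 41-50, flank 5
  toy <- toy_repeat_genome(60, 10, 11, 41, "direct", seed = 3)
  s <- toy$mol$seq
  cs <- build_local_conformations(list(toy$mol), toy$rp, flank = 5)
  sub <- function(a, b) substr(s, a, b)
  expect_equal(cs$c1, paste0(sub(6, 10), sub(11, 20), sub(21, 25)))
  expect_equal(cs$c2, paste0(sub(36, 40), sub(11, 20), sub(51, 55)))
  expect_equal(cs$c3, paste0(sub(6, 10), sub(11, 20), sub(51, 55)))
  expect_equal(cs$c4, paste0(sub(36, 40), sub(11, 20), sub(21, 25)))
  expect_true(all(nchar(c(cs$c1, cs$c2, cs$c3, cs$c4)) == 20))
  expect_equal(cs$rep_start, rep(6L, 4))
  expect_equal(cs$rep_end, rep(15L, 4))
})

test_that("inverted-pair conformation c2 maps back onto the genome by reverse complement", {
  toy <- toy_repeat_genome(2000, 100, 301, 1201, "inverted", seed = 4)
  cs <- build_local_conformations(list(toy$mol), toy$rp, flank = 50)
  # c2 = revcomp(genome[b1 - 50 .. b2 + 50]) for an exact inverted copy
  expect_equal(cs$c2,
               oracle_revcomp(substr(toy$mol$seq, 1201 - 50, 1300 + 50)))
  # c3's right half comes from c2, left half from c1
  expect_equal(substr(cs$c3, 1, cs$rep_end[3]),
               substr(cs$c1, 1, cs$rep_end[1]))
  expect_equal(substr(cs$c3, cs$rep_start[3], nchar(cs$c3)),
               substr(cs$c2, cs$rep_start[2], nchar(cs$c2)))
})

test_that("identical flanks make recombinants indistinguishable from references", {
  # both copies surrounded by the same context
  set.seed(6)
  ctxL <- rand_dna(40); ctxR <- rand_dna(40); rep <- rand_dna(20)
  mid1 <- rand_dna(200); mid2 <- rand_dna(300)
  s <- paste0(ctxL, rep, ctxR, mid1, ctxL, rep, ctxR, mid2)
  mol <- molecule("m", s, "circular")
  rp <- list(hsp_id = "R1", mol_a = "m", start_a = 41, end_a = 60,
             mol_b = "m", start_b = 341, end_b = 360,
             orientation = "direct")
  cs <- build_local_conformations(list(mol), rp, flank = 40)
  expect_equal(cs$c3, cs$c1)
  expect_equal(cs$c4, cs$c2)
})

test_that("flanks truncate at the midpoint when copies are close", {
  toy <- toy_repeat_genome(3000, 100, 501, 701, "direct", seed = 5)
  # inter-copy gap is 100 bp; flank 200 must truncate to 50 on that side
  expect_warning(
    cs <- build_local_conformations(list(toy$mol), toy$rp, flank = 200),
    "truncated")
  expect_equal(cs$flank_right[1], 50L)  # aD shares the 100 bp arc with bU
  expect_equal(cs$flank_left[2], 50L)
  expect_equal(cs$flank_left[1], 200L)  # the far arc is roomy
  expect_equal(nchar(cs$c1), 200 + 100 + 50)
})

test_that("inversion products conserve length and base content and are involutive", {
  toy <- toy_repeat_genome(5000, 200, 1001, 3001, "inverted", seed = 7)
  prod <- build_genome_products(list(toy$mol), toy$rp)
  expect_equal(prod$kind, "inversion")
  expect_length(prod$molecules, 1)
  m2 <- prod$molecules[[1]]
  expect_equal(m2$length, 5000L)
  # in the product frame (copy A rotated to position 1) the inter-copy
  # segment is reverse-complemented, the rest untouched
  par <- rotate_molecule(toy$mol, 1001)$seq
  expect_equal(substr(m2$seq, 1, 200), substr(par, 1, 200))
  expect_equal(substr(m2$seq, 201, 2000),
               oracle_revcomp(substr(par, 201, 2000)))
  expect_equal(substr(m2$seq, 2001, 5000), substr(par, 2001, 5000))
  # applying the inversion again restores the parent (in the rotated frame)
  rp2 <- toy$rp
  rp2$mol_a <- rp2$mol_b <- m2$id
  # coordinates in the product frame: copy A was rotated to position 1
  shift <- function(x) ((x - 1001) %% 5000) + 1
  rp2$start_a <- shift(1001); rp2$end_a <- shift(1200)
  rp2$start_b <- shift(3001); rp2$end_b <- shift(3200)
  back <- build_genome_products(list(m2), rp2)
  expect_equal(back$molecules[[1]]$seq,
               rotate_molecule(toy$mol, 1001)$seq)
})

test_that("direct intra-molecular repeats split the circle into two, conserving length", {
  # 1000 bp circle, 50 bp copies, 400 bp inter-copy arc
  toy <- toy_repeat_genome(1000, 50, 1, 451, "direct", seed = 8)
  prod <- build_genome_products(list(toy$mol), toy$rp)
  expect_equal(prod$kind, "split")
  lens <- sort(vapply(prod$molecules, `[[`, 0L, "length"))
  expect_equal(lens, c(450L, 550L))  # arc + one copy each
  expect_equal(sum(lens), 1000L)
})

test_that("direct inter-molecular repeats fuse two circles", {
  set.seed(9)
  repseq <- rand_dna(100)
  m1 <- molecule("A", paste0(rand_dna(400), repseq, rand_dna(500)),
                 "circular")
  m2 <- molecule("B", paste0(rand_dna(200), repseq, rand_dna(300)),
                 "circular")
  rp <- list(hsp_id = "R1", mol_a = "A", start_a = 401, end_a = 500,
             mol_b = "B", start_b = 201, end_b = 300,
             orientation = "direct")
  prod <- build_genome_products(list(m1, m2), rp)
  expect_equal(prod$kind, "fusion")
  expect_length(prod$molecules, 1)
  expect_equal(prod$molecules[[1]]$length, 1000L + 600L)
  # both recombinant junctions are present in the fused circle
  fused2 <- paste0(prod$molecules[[1]]$seq, prod$molecules[[1]]$seq)
  cs <- build_local_conformations(list(m1, m2), rp, flank = 50)
  expect_true(grepl(cs$c3, fused2, fixed = TRUE))
  expect_true(grepl(cs$c4, fused2, fixed = TRUE))
  # parental junctions are not
  expect_false(grepl(cs$c1, fused2, fixed = TRUE))
  expect_false(grepl(cs$c2, fused2, fixed = TRUE))
})

test_that("inter-molecular inverted pairs fuse with an orientation flip", {
  set.seed(10)
  repseq <- rand_dna(100)
  m1 <- molecule("A", paste0(rand_dna(400), repseq, rand_dna(500)),
                 "circular")
  m2 <- molecule("B", paste0(rand_dna(200), oracle_revcomp(repseq),
                             rand_dna(300)), "circular")
  rp <- list(hsp_id = "R1", mol_a = "A", start_a = 401, end_a = 500,
             mol_b = "B", start_b = 201, end_b = 300,
             orientation = "inverted")
  prod <- build_genome_products(list(m1, m2), rp)
  expect_equal(prod$kind, "fusion")
  expect_equal(prod$note, "orientation_flipped")
  expect_equal(prod$molecules[[1]]$length, 1600L)
})

test_that("split and fusion conserve length over random geometries", {
  set.seed(11)
  for (i in 1:25) {
    L <- sample(2000:6000, 1)
    rl <- sample(50:200, 1)
    pa <- sample(500:(L %/% 2 - rl - 300), 1)
    pb <- sample((L %/% 2):(L - rl - 300), 1)
    toy <- toy_repeat_genome(L, rl, pa, pb, "direct", seed = i + 100)
    prod <- build_genome_products(list(toy$mol), toy$rp)
    lens <- vapply(prod$molecules, `[[`, 0L, "length")
    expect_equal(sum(lens), L)
    # splitting then fusing the two circles restores a rotation of parent
    rp2 <- list(hsp_id = "R1",
                mol_a = prod$molecules[[1]]$id, start_a = 1, end_a = rl,
                mol_b = prod$molecules[[2]]$id, start_b = 1, end_b = rl,
                orientation = "direct")
    refused <- build_genome_products(prod$molecules, rp2)
    expect_equal(refused$molecules[[1]]$length, L)
    doubled <- paste0(toy$mol$seq, toy$mol$seq)
    expect_true(grepl(refused$molecules[[1]]$seq, doubled, fixed = TRUE))
  }
})
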