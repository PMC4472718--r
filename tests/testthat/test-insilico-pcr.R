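make_fixture_template <- function(fwd, rev, size = 140L, at = 101L,
                                  len = 400L, seed = 1L) {
  make_planted_template(fwd, rev, product_size = size, template_len = len,
                        fwd_position = at, seed = seed, id = "fix")
}

test_that("a verbatim planted site gives exactly one exact hit", {
  set.seed(21)
  oseq <- rand_dna(20)
  tpl <- make_fixture_template(oseq, rand_dna(20), seed = 5L)
  hits <- find_binding_sites(stats::setNames(oseq, "F"), tpl)
  plus <- hits[hits$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$start, 101L)
  expect_identical(plus$mismatches, 0L)

  # one substitution inside the site kills it at zero tolerated mismatches
  seqc <- strsplit(tpl$sequence, "")[[1]]
  seqc[110] <- c(A = "C", C = "A", G = "T", T = "G")[seqc[110]]
  broken <- template("fix2", paste(seqc, collapse = ""))
  expect_identical(nrow(find_binding_sites(stats::setNames(oseq, "F"),
                                           broken, max_mismatch = 0L)), 0L)
})

test_that("binding-site search equals the naive sliding-window oracle", {
  set.seed(22)
  for (i in 1:40) {
    n <- sample(200:2000, 1)
    tseq <- rand_dna(n)
    oseq <- rand_dna(18)
    at <- sample(seq_len(n - 40), 1)
    substr(tseq, at, at + 17) <- oseq
    mm <- sample(0:2, 1)
    got <- find_binding_sites(stats::setNames(oseq, "o"),
                              template("t", tseq), max_mismatch = mm)
    want <- oracle_scan(oseq, tseq, max_mismatch = mm)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$start, want$start)
    expect_identical(got$strand, want$strand)
    expect_identical(got$mismatches, want$mismatches)
  }
})

test_that("template shorter than the oligo yields an empty hit list", {
  expect_identical(nrow(find_binding_sites(c(o = "ACGTACGTACGTACGTACGT"),
                                           template("t", "ACGTA"))), 0L)
})

test_that("amplicon prediction recovers a planted product by construction", {
  set.seed(23)
  fwd <- rand_dna(20); rev <- rand_dna(20)
  tpl <- make_fixture_template(fwd, rev, size = 140L, at = 101L, seed = 6L)
  amps <- predict_amplicons(fwd, rev, tpl)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$length, 140L)
  expect_identical(amps$fwd_start, 101L)
  expect_identical(amps$rev_end, 240L)
  expect_identical(amps$length, amps$rev_end - amps$fwd_start + 1L)
  expect_identical(nchar(amps$sequence), 140L)
})

test_that("a forward site downstream of the reverse site is unproductive", {
  set.seed(24)
  fwd <- rand_dna(20); rev <- rand_dna(20)
  back <- rand_dna(300)
  # reverse-complement site first, forward site after it: divergent pair
  tseq <- paste0(substr(back, 1, 50), revcomp(rev), substr(back, 51, 150),
                 fwd, substr(back, 151, 300))
  expect_identical(nrow(predict_amplicons(fwd, rev, template("t", tseq))),
                   0L)
})

test_that("amplicons on the opposite strand are still found", {
  set.seed(25)
  fwd <- rand_dna(20); rev <- rand_dna(20)
  tpl <- make_fixture_template(fwd, rev, size = 120L, seed = 7L)
  flipped <- template("flip", revcomp(tpl$sequence))
  amps <- predict_amplicons(fwd, rev, flipped)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$length, 120L)
  expect_identical(amps$orientation, "-")
})

test_that("a multiplex of planted templates gives a diagonal matrix", {
  set.seed(26)
  assays <- data.frame(assay = paste0("A", 1:5),
                       forward = paste0("F", 1:5),
                       reverse = paste0("R", 1:5))
  oligos <- data.frame(target = assays$assay,
                       name = c(assays$forward, assays$reverse),
                       role = rep(c("forward", "reverse"), each = 5),
                       sequence = replicate(10, rand_dna(20)))
  sizes <- c(438L, 351L, 191L, 140L, 87L)
  templates <- lapply(1:5, function(i)
    make_planted_template(oligos$sequence[i], oligos$sequence[i + 5],
                          product_size = sizes[i],
                          template_len = 600L,
                          panel_oligos = oligos$sequence,
                          seed = 30L + i, id = paste0("T", i)))
  sim <- simulate_multiplex(assays, oligos, templates)
  expect_identical(unname(diag(sim$matrix)), rep(1L, 5))
  expect_identical(sum(sim$matrix), 5L)
  expect_setequal(sim$amplicons$length, sizes)
})

test_that("a 3'-clamp mismatch suppresses amplification", {
  set.seed(27)
  fwd <- rand_dna(20); rev <- rand_dna(20)
  decoy <- make_decoy_template(fwd, rev, list(forward = 1L),
                               product_size = 140L, seed = 8L)
  expect_identical(nrow(predict_amplicons(fwd, rev, decoy,
                                          max_mismatch = 0L, clamp3 = 3L)),
                   0L)
  # relaxing the clamp and allowing the mismatch restores the product
  relaxed <- predict_amplicons(fwd, rev, decoy, max_mismatch = 1L,
                               clamp3 = 0L)
  expect_identical(nrow(relaxed), 1L)
})

test_that("probe placement distinguishes strand, absence and ambiguity", {
  set.seed(28)
  fwd <- rand_dna(20); rev <- rand_dna(20); probe <- rand_dna(22)
  mid <- rand_dna(30)
  amp_seq <- paste0(fwd, mid, probe, rand_dna(28), revcomp(rev))
  amp <- list(sequence = amp_seq, fwd_start = 1L, fwd_end = 20L,
              rev_start = nchar(amp_seq) - 19L, rev_end = nchar(amp_seq))
  hit <- locate_probe(probe, amp)
  expect_identical(hit$strand, "+")
  expect_identical(hit$start, 51L)

  amp_minus <- amp
  amp_minus$sequence <- paste0(fwd, mid, revcomp(probe), rand_dna(28),
                               revcomp(rev))
  expect_identical(locate_probe(probe, amp_minus)$strand, "-")

  expect_null(locate_probe(rand_dna(22), amp))

  amp_twice <- amp
  amp_twice$sequence <- paste0(fwd, probe, rand_dna(10), probe,
                               revcomp(rev))
  expect_error(locate_probe(probe, amp_twice), "ambiguous")
})

test_that("probe overlapping a primer footprint is rejected unless allowed", {
  set.seed(29)
  fwd <- rand_dna(20); rev <- rand_dna(20)
  probe <- paste0(substr(fwd, 11, 20), rand_dna(12))
  amp_seq <- paste0(fwd, substr(probe, 11, 22), rand_dna(40), revcomp(rev))
  amp <- list(sequence = amp_seq, fwd_start = 1L, fwd_end = 20L,
              rev_start = nchar(amp_seq) - 19L, rev_end = nchar(amp_seq))
  expect_null(locate_probe(probe, amp, allow_overlap = FALSE))
  hit <- locate_probe(probe, amp, allow_overlap = TRUE)
  expect_identical(hit$start, 11L)
})

test_that("virtual gel orders sizes and flags unresolvable pairs", {
  gel <- virtual_gel(c(87, 438, 191, 140, 351), min_separation = 20)
  expect_identical(gel$size, c(438L, 351L, 191L, 140L, 87L))
  expect_true(all(gel$distinguishable))
  gel2 <- virtual_gel(c(100, 105), min_separation = 20)
  expect_false(gel2$distinguishable[1])
  expect_identical(nrow(virtual_gel(integer())), 0L)
})

test_that("circular templates find origin-spanning products once", {
  set.seed(31)
  fwd <- rand_dna(20); rev <- rand_dna(20)
  lin <- make_fixture_template(fwd, rev, size = 120L, at = 101L,
                               len = 400L, seed = 9L)
  # rotate so the product spans the origin
  rot <- paste0(substr(lin$sequence, 151, 400), substr(lin$sequence, 1, 150))
  circ <- template("circ", rot, topology = "circular")
  amps <- predict_amplicons(fwd, rev, circ)
  expect_identical(nrow(amps), 1L)
  expect_identical(amps$length, 120L)
  # the same sites, read as a linear molecule, give no product
  expect_identical(nrow(predict_amplicons(fwd, rev,
                                          template("lin", rot))), 0L)
  # doubling never duplicates a product that does not span the origin
  circ2 <- template("circ2", lin$sequence, topology = "circular")
  expect_identical(nrow(predict_amplicons(fwd, rev, circ2)), 1L)
})
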