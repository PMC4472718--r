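test_that("revcomp follows base rules and is an involution", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAC"), "GTT")
  expect_error(revcomp("ACGU"), "non-DNA")
  set.seed(101)
  for (i in 1:20) {
    s <- rand_dna(50)
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("gc_content matches printed panel values and simple cases", {
  expect_equal(gc_content("GGACAGGGTGGACGGTTTATC"), 57.1) # ObsCo12F
  expect_equal(gc_content("CGATCCCTACCGGAGTTAAAG"), 52.4) # BosCo7F
  expect_equal(gc_content("ATGC"), 50.0)
  expect_equal(gc_content("AAAA"), 0.0)
  expect_error(gc_content(""), "empty")
})

test_that("nn_tm reproduces a hand-summed nearest-neighbor ledger", {
  # ACGTACGTACGTACGT: stacks AC x4, CG x4, GT x4, TA x3; both termini A/T;
  # the sequence is self-complementary (symmetry correction, total strand
  # concentration not divided by 4)
  dh <- 4 * (-8.4) + 4 * (-10.6) + 4 * (-8.4) + 3 * (-7.2) + 2 * 2.3
  ds <- 4 * (-22.4) + 4 * (-27.2) + 4 * (-22.4) + 3 * (-21.3) + 2 * 4.1 - 1.4
  ds_salt <- ds + 0.368 * 15 * log(0.05)
  tm_expected <- 1000 * dh / (ds_salt + 1.987 * log(50e-9 / 1)) - 273.15
  expect_equal(nn_tm("ACGTACGTACGTACGT"), tm_expected, tolerance = 1e-10)
})

test_that("nn_tm is symmetric under reverse complement", {
  set.seed(7)
  for (i in 1:15) {
    s <- rand_dna(sample(10:30, 1))
    expect_equal(nn_tm(s), nn_tm(revcomp(s)), tolerance = 1e-9)
  }
})

test_that("appending GC raises Tm more than appending AT", {
  set.seed(8)
  for (i in 1:15) {
    s <- rand_dna(sample(12:25, 1))
    expect_gt(nn_tm(paste0(s, "GC")) - nn_tm(s),
              nn_tm(paste0(s, "AT")) - nn_tm(s))
  }
})

test_that("nn_tm is monotone increasing in monovalent salt", {
  salts <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1.0)
  set.seed(9)
  for (i in 1:8) {
    s <- rand_dna(20)
    tms <- vapply(salts, function(na) nn_tm(s, monovalent = na), 0)
    expect_true(all(diff(tms) > 0))
  }
  expect_error(nn_tm("ACGTACG"), "length")
})

test_that("self-complementarity scores match direct reasoning", {
  expect_identical(self_any_score("AAAAAA"), 0L)
  expect_identical(self_any_score("ATAT"), 4L)
  expect_identical(self_any_score("GGGGCCCC"), 8L)
  expect_identical(self_end3_score("AAAA"), 0L)
  expect_identical(self_end3_score("GGAT"), oracle_self_end3("GGAT"))
  expect_identical(oracle_self_end3("GGAT"), 2L)
})

test_that("scores equal brute-force enumeration and respect bounds", {
  set.seed(11)
  for (i in 1:60) {
    s <- rand_dna(sample(10:30, 1))
    any_s <- self_any_score(s)
    end_s <- self_end3_score(s)
    expect_identical(any_s, oracle_self_any(s))
    expect_identical(end_s, oracle_self_end3(s))
    expect_lte(end_s, any_s)
    expect_identical(cross_dimer_score(s, s), any_s)
  }
})

test_that("cross_dimer_score is symmetric and catches perfect duplexes", {
  expect_identical(cross_dimer_score("AAAA", "CCCC"), 0L)
  set.seed(12)
  for (i in 1:25) {
    a <- rand_dna(sample(10:25, 1)); b <- rand_dna(sample(10:25, 1))
    expect_identical(cross_dimer_score(a, b), cross_dimer_score(b, a))
    expect_identical(cross_dimer_score(a, b), oracle_cross(a, b))
    expect_identical(cross_dimer_score(a, revcomp(a)), nchar(a))
  }
})

test_that("hairpin_dg matches exhaustive stem enumeration", {
  expect_true(is.na(hairpin_dg("AAAAAAAA")))
  got <- hairpin_dg("GGGGAAAACCCC")
  expect_lt(got, 0)
  expect_equal(got, oracle_hairpin("GGGGAAAACCCC"), tolerance = 1e-9)
  set.seed(13)
  for (i in 1:25) {
    s <- rand_dna(sample(12:26, 1))
    expect_equal(hairpin_dg(s), oracle_hairpin(s), tolerance = 1e-9)
  }
})

test_that("hairpin_dg is revcomp-invariant for perfect inverted repeats", {
  for (stem in c("GGGG", "GCAT", "CCGTA")) {
    s <- paste0(stem, "AAAA", revcomp(stem))
    expect_equal(hairpin_dg(s), hairpin_dg(revcomp(s)), tolerance = 1e-9)
  }
})

test_that("oligo and dye constructors enforce their invariants", {
  o <- oligo("P1", "acgtacgtacgt", "forward")
  expect_identical(o$sequence, "ACGTACGTACGT")
  expect_error(oligo("P2", "ACGTNACGTACG"), "non-DNA")
  expect_error(oligo("P3", "ACGT"), "length")
  expect_error(dye_spec("X", 600, 550), "exceed")
  d <- dye_spec("6-FAM", 495, 520, "BHQ1")
  expect_identical(d$dye_name, "6-FAM")
})

test_that("oligo_report computes the tabulated properties", {
  rep <- oligo_report(c(P1 = "GGGGTTTTAGGGTTTGTGGTA", P2 = "ATATGCGCATATGCGC"))
  expect_identical(names(rep),
                   c("name", "length", "gc", "tm", "self_any", "self_end3",
                     "hairpin_dg"))
  expect_equal(rep$gc[1], 47.6)
  expect_true(all(rep$self_end3 <= rep$self_any))
  expect_true(all(is.na(rep$hairpin_dg) | rep$hairpin_dg <= 0))
})
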