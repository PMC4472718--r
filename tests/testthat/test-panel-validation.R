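test_that("the shipped dye set maps to the published channel layout", {
  panel <- liposcelis_panel()
  map <- assign_channels(panel$dyes)
  want <- c(`6-FAM` = "green", HEX = "yellow", `6-ROXN` = "orange",
            Cy5 = "red", Quasar705 = "crimson")
  expect_identical(stats::setNames(map$channel, map$dye_name), want)
  # and it agrees with the channel column shipped alongside the probes
  expect_identical(map$channel, panel$dyes$channel)
})

test_that("channel assignment handles degenerate dye sets", {
  one <- data.frame(dye_name = "FAM", excitation = 495, emission = 520)
  expect_identical(assign_channels(one)$channel, "green")
  clash <- data.frame(dye_name = c("A", "B"), excitation = c(490, 500),
                      emission = c(520, 520))
  expect_error(assign_channels(clash), "spectral conflict")
  near <- data.frame(dye_name = c("A", "B"), excitation = c(490, 500),
                     emission = c(520, 530))
  expect_error(assign_channels(near, min_gap_nm = 25), "spectral conflict")
  six <- data.frame(dye_name = paste0("D", 1:6), excitation = 400,
                    emission = seq(450, 700, 50))
  expect_error(assign_channels(six), "more dyes")
})

test_that("compatibility report flags revcomp primer pairs and keeps the matrix symmetric", {
  set.seed(61)
  a <- rand_dna(21)
  oligos <- data.frame(
    target = "t", name = c("F1", "F1rc", "R1"),
    role = c("forward", "forward", "reverse"),
    sequence = c(a, revcomp(a), rand_dna(21)))
  rep <- compatibility_report(new_panel(oligos), dimer_threshold = 12L)
  expect_true(isSymmetric(rep$dimer_matrix))
  expect_identical(unname(diag(rep$dimer_matrix)),
                   vapply(oligos$sequence, self_any_score, 0L,
                          USE.NAMES = FALSE))
  flagged <- rep$dimer_flags
  expect_true(any(flagged$score == 21L))
  expect_true(length(rep$findings) >= 1L)
})

test_that("an endpoint-only panel reports no channel section without error", {
  set.seed(62)
  oligos <- data.frame(target = "t", name = c("F", "R"),
                       role = c("forward", "reverse"),
                       sequence = c(rand_dna(20), rand_dna(20)))
  rep <- compatibility_report(new_panel(oligos))
  expect_null(rep$channel_assignment)
})

test_that("the shipped endpoint sizes pass the virtual-gel spacing check", {
  rep <- compatibility_report(liposcelis_panel(), min_size_gap = 20L)
  expect_true(all(rep$gel$distinguishable))
  expect_identical(rep$gel$size, c(438L, 351L, 191L, 140L, 87L))
})

test_that("exclusivity over targets, decoys, out-group and host is diagonal", {
  panel <- liposcelis_panel()
  ep <- assays_for_reaction(panel$assays, "endpoint")
  fx <- make_exclusivity_fixture(ep, panel, n_decoys = 8L, seed = 11L)
  ex <- exclusivity_check(ep, panel, fx$targets,
                          c(fx$decoys, list(fx$outgroup, fx$host)))
  expect_true(ex$verdict)
  m <- ex$matrix
  expect_identical(dim(m), c(5L, 15L))
  for (a in rownames(m)) {
    expect_identical(unname(m[a, paste0("target_", a)]), 1L)
    expect_identical(sum(m[a, ]), 1L)
  }
})

test_that("exclusivity verdicts are monotone in the decoy set and name offenders", {
  panel <- liposcelis_panel()
  ep <- assays_for_reaction(panel$assays, "endpoint")[1:2, ]
  fx <- make_exclusivity_fixture(ep, panel, n_decoys = 2L, seed = 12L)
  base <- exclusivity_check(ep, panel, fx$targets, fx$decoys)
  expect_true(base$verdict)
  # adding clean decoys preserves the pass
  more <- exclusivity_check(ep, panel, fx$targets,
                            c(fx$decoys, list(fx$outgroup)))
  expect_true(more$verdict)
  # a decoy carrying both intact sites breaks it, with assay and template
  # named
  bad <- make_planted_template(
    toupper(panel$oligos$sequence[match(ep$forward[1],
                                        panel$oligos$name)]),
    toupper(panel$oligos$sequence[match(ep$reverse[1],
                                        panel$oligos$name)]),
    product_size = 200L, seed = 13L, id = "bad_decoy")
  broken <- exclusivity_check(ep, panel, fx$targets,
                              c(fx$decoys, list(bad)))
  expect_false(broken$verdict)
  expect_true(any(broken$failures$template == "bad_decoy" &
                  broken$failures$kind == "cross_reaction"))
  # a missing target template is an input error, not a silent fail
  expect_error(exclusivity_check(ep, panel, fx$targets[1], list()),
               "without a designated target")
})
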