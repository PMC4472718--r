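# a small synthetic two-target panel used by several blocks below
toy_panel <- function(seed = 41L) {
  set.seed(seed)
  mk <- function() rand_dna(21)
  oligos <- data.frame(
    target = rep(c("alpha", "beta"), each = 3),
    name = c("AlpF", "AlpR", "AlpP", "BetF", "BetR", "BetP"),
    role = rep(c("forward", "reverse", "probe"), 2),
    sequence = replicate(6, mk()))
  assays <- data.frame(
    assay = c("Alp", "Bet"), target = c("alpha", "beta"),
    forward = c("AlpF", "BetF"), reverse = c("AlpR", "BetR"),
    probe = c("AlpP", "BetP"), use = "both",
    genomic_size = c(200L, 250L), apc_size = c(120L, 160L))
  new_panel(oligos, assays)
}

test_that("block planning hits the requested panel sizes exactly", {
  panel <- liposcelis_panel()
  blocks <- plan_apc_blocks(panel)
  expect_length(blocks, 5L)
  outer <- stats::setNames(
    vapply(blocks, `[[`, numeric(1), "outer_size"),
    vapply(blocks, `[[`, character(1), "outer_assay"))
  inner <- stats::setNames(
    vapply(blocks, `[[`, numeric(1), "inner_size"),
    vapply(blocks, `[[`, character(1), "inner_assay"))
  expect_identical(sort(unname(outer)), c(99, 140, 184, 241, 322))
  expect_identical(sort(unname(inner)), c(67, 72, 96, 99, 140))
  cases <- stats::setNames(vapply(blocks, `[[`, character(1), "case"),
                           vapply(blocks, `[[`, character(1), "target"))
  # the Bos outer forward equals the start of the inner-reverse complement,
  # which forces the merged staggered geometry
  expect_identical(unname(cases["Liposcelis bostrychophila"]), "staggered")
  expect_identical(unname(cases["Liposcelis pearmani"]), "shared_rev")
  expect_identical(unname(cases["Liposcelis obscura"]), "nested")
  # every block's element lengths add up to a span >= its outer size
  for (b in blocks) expect_identical(b$span, sum(b$elements$length))
})

test_that("a minimal single-pair block gets exactly minimal spacers", {
  panel <- toy_panel()
  lens <- nchar(panel$oligos$sequence[1:3])
  minimal <- sum(lens) + 4L # two 2-nt spacers
  blocks <- plan_apc_blocks(
    new_panel(panel$oligos, panel$assays[1, ]),
    size_requests = c(Alp = minimal))
  sp <- blocks[[1]]$elements
  expect_identical(sp$length[sp$type == "spacer"], c(2L, 2L))
  expect_identical(blocks[[1]]$span, minimal)
  # one bp below the minimum is infeasible, and the error names the target
  expect_error(plan_apc_blocks(new_panel(panel$oligos, panel$assays[1, ]),
                               size_requests = c(Alp = minimal - 1L)),
               "alpha")
})

test_that("duplicate sizes within a reaction type are rejected", {
  panel <- toy_panel()
  expect_error(plan_apc_blocks(panel,
                               size_requests = c(Alp = 120L, Bet = 120L)),
               "duplicate")
  expect_error(plan_apc_blocks(panel,
                               size_requests = c(Alp = 120L, Bet = 130L),
                               min_gap_endpoint = 20L),
               "closer")
})

test_that("synthesized spacers pass the mispriming screens", {
  panel <- liposcelis_panel()
  blocks <- synthesize_spacers(plan_apc_blocks(panel), panel, seed = 3L)
  oseqs <- toupper(panel$oligos$sequence)
  seeds8 <- unique(c(substr(oseqs, nchar(oseqs) - 7L, nchar(oseqs)),
                     revcomp(substr(oseqs, nchar(oseqs) - 7L,
                                    nchar(oseqs)))))
  win12 <- unlist(lapply(oseqs, function(s)
    vapply(1:(nchar(s) - 11L), function(i) substr(s, i, i + 11L), "")))
  win12 <- unique(c(win12, revcomp(win12)))
  for (b in blocks) {
    spacers <- b$elements$sequence[b$elements$type == "spacer"]
    spacers <- spacers[nzchar(spacers)]
    for (s in c(spacers, revcomp(spacers))) {
      expect_false(any(vapply(seeds8, grepl, TRUE, x = s, fixed = TRUE)),
                   label = paste("3' seed in spacer of", b$target))
      expect_false(any(vapply(win12, grepl, TRUE, x = s, fixed = TRUE)),
                   label = paste("12-mer match in spacer of", b$target))
    }
  }
  # per-block barcodes exist, are distinct, and are far apart
  bcs <- vapply(blocks, `[[`, "", "barcode")
  expect_identical(anyDuplicated(bcs), 0L)
  for (i in 1:(length(bcs) - 1)) for (j in (i + 1):length(bcs)) {
    hd <- sum(strsplit(bcs[i], "")[[1]] != strsplit(bcs[j], "")[[1]])
    expect_gte(hd, 4L)
  }
})

test_that("assembly is deterministic and respects simple identities", {
  panel <- toy_panel()
  b1 <- synthesize_spacers(plan_apc_blocks(panel), panel, seed = 5L)
  b2 <- synthesize_spacers(plan_apc_blocks(panel), panel, seed = 5L)
  c1 <- assemble_apc(b1, inter_spacers = 10L, panel = panel, seed = 5L)
  c2 <- assemble_apc(b2, inter_spacers = 10L, panel = panel, seed = 5L)
  expect_identical(c1$sequence, c2$sequence)
  expect_equal(nchar(c1$sequence),
               sum(vapply(b1, `[[`, numeric(1), "span")) + 10L)

  expect_error(assemble_apc(list()), "empty")

  one <- assemble_apc(b1[1], inter_spacers = character())
  expect_identical(one$sequence, paste(b1[[1]]$elements$sequence,
                                       collapse = ""))

  ad <- assemble_apc(b1[1], inter_spacers = character(),
                     adapters = c("GAATTC", "GGATCC"))
  expect_identical(nchar(ad$sequence), nchar(one$sequence) + 12L)
  expect_true(startsWith(ad$sequence, "GAATTC"))
})

test_that("the shipped panel designs to a fully verified construct", {
  panel <- liposcelis_panel()
  apc <- design_apc(panel, seed = 42L)
  ver <- apc$verification
  expect_true(ver$pass)
  sizes <- unique(ver$amplicons[, c("assay", "length")])
  want <- stats::setNames(panel$assays$apc_size, panel$assays$assay)
  expect_identical(stats::setNames(sizes$length, sizes$assay)[names(want)],
                   want)
  # design is byte-identical under the same seed
  expect_identical(design_apc(panel, seed = 42L)$sequence, apc$sequence)
  # ... and different under another seed
  expect_false(identical(design_apc(panel, seed = 43L)$sequence,
                         apc$sequence))
  # the shared BruCo5 size (140 bp on both genomic DNA and APC) is flagged
  # informationally, not fatally
  coll <- ver$report[ver$report$check == "genomic_size_collision", ]
  expect_true(all(coll$status == "info"))
  expect_true(any(grepl("BruCo5", coll$subject)))
})

test_that("design -> verify round trip holds for random feasible panels", {
  for (seed in c(7L, 19L)) {
    panel <- toy_panel(seed)
    apc <- design_apc(panel, seed = seed)
    expect_true(apc$verification$pass)
    got <- unique(apc$verification$amplicons[, c("assay", "length")])
    expect_setequal(got$length, c(120L, 160L))
  }
})

test_that("verification reports a probe planted outside its primers", {
  panel <- toy_panel()
  apc <- design_apc(panel, seed = 13L)
  # move the Alp probe site out of its amplicon: excise it and append it at
  # the construct end
  ft <- apc$features
  pr <- ft[ft$name == "AlpP", ]
  seqc <- apc$sequence
  probe_seq <- substr(seqc, pr$start, pr$end)
  broken <- paste0(substr(seqc, 1, pr$start - 1),
                   paste(rep("A", nchar(probe_seq)), collapse = ""),
                   substr(seqc, pr$end + 1, nchar(seqc)), probe_seq)
  ver <- verify_apc(list(sequence = broken, sizes = apc$sizes), panel)
  expect_false(ver$pass)
  fails <- ver$report[ver$report$status == "fail", ]
  expect_true("probe_placement" %in% fails$check)
})

test_that("exported flat files round trip and coordinates re-extract", {
  panel <- liposcelis_panel()
  apc <- design_apc(panel, seed = 42L)
  prefix <- file.path(withr::local_tempdir(), "apc")
  paths <- export_annotated(apc, prefix)
  expect_true(all(file.exists(paths)))

  fa <- read_fasta(paths[["fasta"]])
  expect_identical(fa[[1]]$sequence, apc$sequence)

  gb <- read_genbank(paths[["genbank"]])
  expect_identical(gb$sequence, apc$sequence)
  # every primer/probe feature re-extracts to its oligo's sequence (or its
  # reverse complement on the minus strand)
  oligo_seq <- stats::setNames(toupper(panel$oligos$sequence),
                               panel$oligos$name)
  feats <- gb$features[gb$features$name %in% names(oligo_seq), ]
  expect_gte(nrow(feats), 20L)
  for (i in seq_len(nrow(feats))) {
    got <- substr(gb$sequence, feats$start[i], feats$end[i])
    want <- oligo_seq[[feats$name[i]]]
    if (feats$strand[i] == "-") want <- revcomp(want)
    expect_identical(got, want)
  }
  # feature count covers all planted oligos plus spacers and barcodes
  expect_identical(sum(gb$features$type == "primer_bind"), 15L)
  expect_identical(sum(gb$features$type == "misc_binding"), 5L)
})
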