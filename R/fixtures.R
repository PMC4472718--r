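# Seeded fixture generators: planted templates, near-neighbor decoys,
# simulated Ct series. These stand in for genomic CO1 records and wet
# dilution series so that everything can be exercised offline.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random DNA with GC fraction held inside [gc_min, gc_max]
.random_dna <- function(len, gc_min = 0.4, gc_max = 0.6, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    gc <- gc_content(s)
    if (len < 10L || (gc >= 100 * gc_min && gc <= 100 * gc_max)) return(s)
  }
  stop("could not generate a GC-balanced sequence of length ", len,
       call. = FALSE)
}

# 3'-terminal k-mers of every panel oligo, both strands
.panel_seeds <- function(oligo_seqs, k = 8L) {
  seqs <- toupper(oligo_seqs)
  fwd <- substr(seqs, nchar(seqs) - k + 1L, nchar(seqs))
  unique(c(fwd, revcomp(fwd)))
}

# all w-mers of every panel oligo, both strands
.panel_windows <- function(oligo_seqs, w = 12L) {
  seqs <- toupper(oligo_seqs)
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < w) return(character())
    vapply(1L:(n - w + 1L), function(i) substr(s, i, i + w - 1L), "")
  }))
  unique(c(out, revcomp(out)))
}

# TRUE when `s` (either strand) avoids every forbidden substring
.screen_clean <- function(s, forbidden) {
  both <- c(s, revcomp(s))
  for (f in forbidden) if (any(grepl(f, both, fixed = TRUE))) return(FALSE)
  TRUE
}

.screened_dna <- function(len, forbidden, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- .random_dna(len)
    if (.screen_clean(s, forbidden)) return(s)
  }
  stop("could not generate a ", len,
       "-nt sequence passing the mispriming screens after ", max_tries,
       " tries", call. = FALSE)
}

#' Generate a template with one planted assay site
#'
#' Builds a random GC-balanced background (screened against the 3'-terminal
#' 8-mers of every panel oligo, both strands) and plants the assay's forward
#' site and the reverse complement of its reverse primer so that the assay
#' yields exactly one product of the requested size.
#'
#' @param forward,reverse primer sequences (5'->3').
#' @param product_size requested amplicon size, bp.
#' @param template_len total template length.
#' @param fwd_position 1-based start of the forward site.
#' @param panel_oligos character vector of all panel oligo sequences used for
#'   the background screen (defaults to the two primers).
#' @param seed RNG seed (mandatory: fixtures must be reproducible).
#' @param id template id.
#' @return a [template()].
#' @export
make_planted_template <- function(forward, reverse, product_size,
                                  template_len = 600L, fwd_position = 101L,
                                  panel_oligos = NULL, seed, id = "planted") {
  forward <- .check_dna(forward, "forward"); reverse <- .check_dna(reverse,
                                                                   "reverse")
  if (missing(seed)) stop("seed is mandatory for fixture generation",
                          call. = FALSE)
  lf <- nchar(forward); lr <- nchar(reverse)
  if (product_size < lf + lr)
    stop("product_size smaller than the two primer footprints",
         call. = FALSE)
  rev_site_start <- fwd_position + product_size - lr
  if (fwd_position < 1L || rev_site_start + lr - 1L > template_len)
    stop("planted sites do not fit in a template of length ", template_len,
         call. = FALSE)
  if (is.null(panel_oligos)) panel_oligos <- c(forward, reverse)
  seeds <- .panel_seeds(panel_oligos)
  with_seed(seed, {
    insert_len <- product_size - lf - lr
    insert <- if (insert_len > 0L) .screened_dna(insert_len, seeds) else ""
    left <- if (fwd_position > 1L)
      .screened_dna(fwd_position - 1L, seeds) else ""
    right_len <- template_len - (rev_site_start + lr - 1L)
    right <- if (right_len > 0L) .screened_dna(right_len, seeds) else ""
    template(id, paste0(left, forward, insert, revcomp(reverse), right),
             description = sprintf("planted %d bp product at %d",
                                   product_size, fwd_position))
  })
}

#' Generate a near-neighbor decoy template
#'
#' Starts from a planted template and corrupts the planted sites at the given
#' positions (1-based from the oligo 3' end) so that the assay is
#' unproductive at the given stringency. Errors when the plan leaves the
#' assay productive.
#'
#' @param forward,reverse primer sequences.
#' @param mismatch_plan list with optional elements `forward` and `reverse`,
#'   each an integer vector of positions to corrupt, counted from the
#'   oligo's 3' end (1 = the 3'-terminal base).
#' @param product_size,template_len,fwd_position,panel_oligos,seed,id see
#'   [make_planted_template()].
#' @param max_mismatch,clamp3 the stringency the decoy must defeat.
#' @return a [template()].
#' @export
make_decoy_template <- function(forward, reverse, mismatch_plan,
                                product_size, template_len = 600L,
                                fwd_position = 101L, panel_oligos = NULL,
                                seed, id = "decoy", max_mismatch = 0L,
                                clamp3 = 3L) {
  base <- make_planted_template(forward, reverse, product_size, template_len,
                                fwd_position, panel_oligos, seed = seed,
                                id = id)
  seqc <- strsplit(base$sequence, "", fixed = TRUE)[[1L]]
  transversion <- c(A = "C", C = "A", G = "T", T = "G")
  corrupt <- function(pos) seqc[pos] <<- transversion[seqc[pos]]
  lf <- nchar(forward); lr <- nchar(reverse)
  for (p in mismatch_plan$forward %||% integer()) {
    # oligo 3' end is the right end of the plus-strand forward site
    corrupt(fwd_position + lf - p)
  }
  rev_site_start <- fwd_position + product_size - lr
  for (p in mismatch_plan$reverse %||% integer()) {
    # reverse oligo 3' end faces left on the plus strand
    corrupt(rev_site_start + p - 1L)
  }
  decoy <- template(id, paste(seqc, collapse = ""),
                    description = "near-neighbor decoy")
  left <- predict_amplicons(forward, reverse, decoy,
                            max_mismatch = max_mismatch, clamp3 = clamp3)
  if (nrow(left) > 0L)
    stop("mismatch plan leaves the assay productive at max_mismatch = ",
         max_mismatch, call. = FALSE)
  decoy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an exclusivity fixture set
#'
#' Emulates an inclusivity/exclusivity validation panel: one planted target
#' template per assay, a set of near-neighbor decoys (each derived from a
#' target but 3'-corrupted for its assay), one out-group and one host
#' template carrying no panel sites at all.
#'
#' @param assays assay table (columns `assay`, `forward`, `reverse`).
#' @param panel a `pcr_panel` or oligo data frame.
#' @param n_decoys number of near-neighbor decoys.
#' @param seed RNG seed.
#' @return list with `targets` (named by assay), `decoys`, `outgroup`,
#'   `host`.
#' @export
make_exclusivity_fixture <- function(assays, panel, n_decoys = 8L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  oligos <- if (is.data.frame(panel)) panel else panel$oligos
  seq_of <- function(nm) toupper(oligos$sequence[match(nm, oligos$name)])
  all_seqs <- toupper(oligos$sequence)
  targets <- lapply(seq_len(nrow(assays)), function(i) {
    make_planted_template(seq_of(assays$forward[i]),
                          seq_of(assays$reverse[i]),
                          product_size = max(140L, nchar(seq_of(assays$forward[i])) +
                                               nchar(seq_of(assays$reverse[i])) + 20L),
                          panel_oligos = all_seqs, seed = seed + i,
                          id = paste0("target_", assays$assay[i]))
  })
  names(targets) <- assays$assay
  decoys <- lapply(seq_len(n_decoys), function(k) {
    i <- ((k - 1L) %% nrow(assays)) + 1L
    make_decoy_template(seq_of(assays$forward[i]), seq_of(assays$reverse[i]),
                        mismatch_plan = list(forward = 1L, reverse = 1L),
                        product_size = max(140L,
                                           nchar(seq_of(assays$forward[i])) +
                                             nchar(seq_of(assays$reverse[i])) + 20L),
                        panel_oligos = all_seqs, seed = seed + 100L + k,
                        id = paste0("decoy_", k, "_", assays$assay[i]))
  })
  with_seed(seed + 1000L, {
    seeds <- .panel_seeds(all_seqs)
    outgroup <- template("outgroup", .screened_dna(600L, seeds),
                         description = "out-group insect analogue")
    host <- template("host", .screened_dna(600L, seeds),
                     description = "host plant analogue")
    list(targets = targets, decoys = decoys, outgroup = outgroup,
         host = host)
  })
}

#' Simulate a dilution-series Ct table
#'
#' Draws `Ct = intercept + slope * log10(amount) + Normal(0, sigma)` per
#' replicate, the generating model behind an ideal qPCR standard curve.
#'
#' @param slope cycles per log10 amount (negative).
#' @param intercept Ct at 1 ng.
#' @param sigma replicate noise SD, cycles (>= 0).
#' @param replicates replicates per dilution (>= 1).
#' @param amounts template amounts in ng, strictly positive, decreasing;
#'   default the 10-fold series 1 ng .. 1 fg.
#' @param channel,kit labels carried into the result.
#' @param seed RNG seed (mandatory).
#' @return replicate-level data frame: `kit`, `channel`, `amount_ng`, `ntc`,
#'   `replicate`, `ct`.
#' @export
simulate_ct_series <- function(slope = -3.32, intercept = 29, sigma = 0.15,
                               replicates = 3L, amounts = 10^(0:-6),
                               channel = "sim", kit = "sim", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(sigma >= 0, replicates >= 1L)
  if (any(amounts <= 0)) stop("amounts must be strictly positive",
                              call. = FALSE)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        amount_ng = amounts)
    ct <- intercept + slope * log10(grid$amount_ng) +
      stats::rnorm(nrow(grid), 0, sigma)
    data.frame(kit = kit, channel = channel, amount_ng = grid$amount_ng,
               ntc = FALSE, replicate = grid$replicate, ct = ct)
  })
}
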