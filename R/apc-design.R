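# Multi-target artificial positive control (APC) design.
#
# An APC is a synthetic insert carrying, for every assay of a panel, the
# assay's priming sites laid out so that each primer pair amplifies exactly
# one product of a requested size, with the hydrolysis probe site strictly
# between its primers. Per-target "blocks" are separated by screened random
# spacers carrying per-block barcodes, so every APC amplicon has a unique,
# identifiable internal sequence distinguishable from the genomic product.
#
# Block geometries (plus-strand order, before any orientation flip):
#   single     F  .. [P] .. rc(R)               one pair serves both uses
#   shared_rev oF .. iF .. P .. rc(R)           inner/outer share the reverse
#   shared_fwd F  .. P .. rc(iR) .. rc(oR)      inner/outer share the forward
#   nested     oF .. iF .. P .. rc(iR) .. rc(oR)
#   staggered  iF .. P .. rc(iR) .. rc(oR)      outer forward site contained
#                                               in the inner-reverse site
# The staggered case arises when the outer forward primer's sequence is a
# substring of the reverse complement of the inner reverse primer; planting
# both separately would duplicate the forward site, so the two sites are
# merged and the outer amplicon starts inside the inner-reverse footprint.

.seq_of <- function(oligos, nm) {
  i <- match(nm, oligos$name)
  if (is.na(i)) stop("oligo not in panel: ", nm, call. = FALSE)
  toupper(oligos$sequence[i])
}

.element <- function(name, type, strand, sequence, length = nchar(sequence)) {
  data.frame(name = name, type = type, strand = strand,
             sequence = sequence, length = as.integer(length),
             stringsAsFactors = FALSE)
}

.spacer_el <- function(name, len) {
  .element(name, "spacer", "+", NA_character_, len)
}

#' Plan the per-target blocks of an APC construct
#'
#' Derives one block plan per target from the panel's multiplex assays
#' (endpoint-use assay = outer pair, qPCR-use assay = inner pair + probe),
#' chooses the block geometry (including shared-primer and
#' overlapping-site cases), and allocates spacer lengths so every requested
#' amplicon size is hit exactly.
#'
#' @param panel a `pcr_panel` with an assay table, or a list with `oligos`
#'   and `assays` data frames.
#' @param size_requests named numeric vector of requested APC product sizes
#'   (bp) per assay, or `"auto"`. Default: the assay table's `apc_size`
#'   column.
#' @param min_spacer minimum spacer between adjacent functional elements, nt.
#' @param min_gap_endpoint minimum pairwise size gap between endpoint
#'   products (gel-discriminated).
#' @param min_gap_qpcr minimum pairwise gap between qPCR products
#'   (channel-discriminated, so 0 = just distinct).
#' @param probe_strand embed probes on the plus strand as written (default)
#'   or as reverse complements.
#' @param min_size,max_size size range for `"auto"` mode.
#' @return list of block plans (target, case, sizes, element table).
#' @export
plan_apc_blocks <- function(panel, size_requests = NULL, min_spacer = 2L,
                            min_gap_endpoint = 20L, min_gap_qpcr = 0L,
                            probe_strand = c("plus", "minus"),
                            min_size = 60L, max_size = 450L) {
  probe_strand <- match.arg(probe_strand)
  oligos <- panel$oligos
  assays <- panel$assays
  if (is.null(assays)) stop("panel has no assay table", call. = FALSE)
  assays <- assays[assays$use %in% c("endpoint", "qpcr", "both"), ,
                   drop = FALSE]
  if (nrow(assays) == 0L) stop("no multiplex assays in panel", call. = FALSE)

  auto <- identical(size_requests, "auto")
  if (is.null(size_requests)) {
    if (!"apc_size" %in% names(assays) || any(is.na(assays$apc_size)))
      stop("no size_requests given and assay table has no complete apc_size",
           call. = FALSE)
    size_requests <- stats::setNames(assays$apc_size, assays$assay)
  }

  targets <- unique(assays$target)
  plans <- lapply(targets, function(tg) {
    rows <- assays[assays$target == tg, , drop = FALSE]
    outer <- rows[rows$use %in% c("endpoint", "both"), , drop = FALSE]
    inner <- rows[rows$use %in% c("qpcr", "both"), , drop = FALSE]
    if (nrow(outer) > 1L || nrow(inner) > 1L)
      stop("target ", tg, " has more than one assay per reaction type",
           call. = FALSE)
    list(target = tg,
         outer = if (nrow(outer)) outer else NULL,
         inner = if (nrow(inner)) inner else NULL)
  })

  if (auto) {
    # grid of endpoint sizes maximizing the minimum pairwise gap; inner
    # blocks sit at their minimal feasible size
    size_requests <- .auto_sizes(plans, oligos, min_spacer, min_size,
                                 max_size, probe_strand)
  }

  blocks <- lapply(plans, function(pl)
    .plan_one_block(pl, oligos, size_requests, min_spacer, probe_strand))

  .check_size_sets(blocks, min_gap_endpoint, min_gap_qpcr)
  blocks
}

.assay_size <- function(size_requests, assay) {
  s <- size_requests[[assay]]
  if (is.null(s) || is.na(s))
    stop("no requested size for assay ", assay, call. = FALSE)
  as.integer(s)
}

.plan_one_block <- function(pl, oligos, size_requests, min_spacer,
                            probe_strand) {
  tg <- pl$target
  sp <- function(k, len) .spacer_el(sprintf("%s_sp%d", gsub("\\s+", "_", tg),
                                            k), len)
  need <- function(len, what) {
    if (len < min_spacer)
      stop("infeasible size for target ", tg, ": ", what,
           " spacer would be ", len, " nt (< ", min_spacer, ")",
           call. = FALSE)
    len
  }
  probe_el <- function(pname) {
    pseq <- .seq_of(oligos, pname)
    if (probe_strand == "plus") .element(pname, "probe", "+", pseq)
    else .element(pname, "probe", "-", revcomp(pseq))
  }

  outer <- pl$outer; inner <- pl$inner
  same_assay <- !is.null(outer) && !is.null(inner) &&
    outer$assay == inner$assay
  if (is.null(inner) || same_assay ||
      (!is.null(outer) &&
       outer$forward == inner$forward && outer$reverse == inner$reverse)) {
    # one primer pair serves the block
    row <- if (!is.null(outer)) outer else inner
    if (!is.null(outer) && !is.null(inner) && !same_assay) {
      so <- .assay_size(size_requests, outer$assay)
      si <- .assay_size(size_requests, inner$assay)
      if (so != si)
        stop("target ", tg, ": one primer pair cannot realize two sizes (",
             so, " vs ", si, ")", call. = FALSE)
    }
    size <- .assay_size(size_requests, row$assay)
    f <- .seq_of(oligos, row$forward); r <- .seq_of(oligos, row$reverse)
    pr <- if (!is.null(inner) && !is.na(inner$probe)) inner$probe
          else if (!is.na(row$probe %||% NA)) row$probe else NA
    if (!is.na(pr)) {
      p <- .seq_of(oligos, pr)
      slack <- size - nchar(f) - nchar(p) - nchar(r)
      s2 <- need(slack - min_spacer, "probe")
      el <- rbind(.element(row$forward, "primer", "+", f),
                  sp(1L, min_spacer), probe_el(pr), sp(2L, s2),
                  .element(row$reverse, "primer", "-", revcomp(r)))
    } else {
      s1 <- need(size - nchar(f) - nchar(r), "insert")
      el <- rbind(.element(row$forward, "primer", "+", f), sp(1L, s1),
                  .element(row$reverse, "primer", "-", revcomp(r)))
    }
    return(.finish_block(tg, "single", el, outer, inner, size, size))
  }

  # distinct outer and inner assays
  so <- .assay_size(size_requests, outer$assay)
  si <- .assay_size(size_requests, inner$assay)
  oF <- .seq_of(oligos, outer$forward); oR <- .seq_of(oligos, outer$reverse)
  iF <- .seq_of(oligos, inner$forward); iR <- .seq_of(oligos, inner$reverse)
  if (is.na(inner$probe))
    stop("qPCR assay ", inner$assay, " has no probe", call. = FALSE)
  p <- .seq_of(oligos, inner$probe)
  if (si >= so && outer$reverse != inner$reverse &&
      outer$forward != inner$forward)
    stop("target ", tg, ": inner size ", si,
         " must be smaller than outer size ", so, call. = FALSE)

  inner_core <- function() {
    slack <- si - nchar(iF) - nchar(p) - nchar(iR)
    s2 <- need(slack - min_spacer, "inner probe")
    rbind(.element(inner$forward, "primer", "+", iF), sp(1L, min_spacer),
          probe_el(inner$probe), sp(2L, s2),
          .element(inner$reverse, "primer", "-", revcomp(iR)))
  }

  if (outer$reverse == inner$reverse) {
    g1 <- need(so - nchar(oF) - si, "outer-forward")
    el <- rbind(.element(outer$forward, "primer", "+", oF), sp(3L, g1),
                inner_core())
    return(.finish_block(tg, "shared_rev", el, outer, inner, so, si))
  }
  if (outer$forward == inner$forward) {
    g2 <- need(so - si - nchar(oR), "outer-reverse")
    el <- rbind(inner_core(), sp(3L, g2),
                .element(outer$reverse, "primer", "-", revcomp(oR)))
    return(.finish_block(tg, "shared_fwd", el, outer, inner, so, si))
  }

  rc_iR <- revcomp(iR)
  off <- as.integer(regexpr(oF, rc_iR, fixed = TRUE)) - 1L
  if (off >= 0L) {
    # outer forward site lives inside the inner-reverse site
    g3 <- need(so - nchar(oR) - (nchar(iR) - off), "staggered outer")
    el <- rbind(inner_core(), sp(3L, g3),
                .element(outer$reverse, "primer", "-", revcomp(oR)))
    blk <- .finish_block(tg, "staggered", el, outer, inner, so, si)
    blk$stagger_offset <- off
    # record the embedded outer-forward site so ordering and annotation
    # see it
    rel_start <- cumsum(c(1L, el$length))[seq_len(nrow(el))]
    x_start <- rel_start[match(inner$reverse, el$name)]
    blk$extra_sites <- data.frame(
      name = outer$forward, type = "primer", strand = "+",
      rel_start = x_start + off,
      rel_end = x_start + off + nchar(oF) - 1L,
      stringsAsFactors = FALSE)
    return(blk)
  }
  # guard against other containments that would duplicate a site
  planted <- c(oF, iF, revcomp(oR), rc_iR, p)
  names(planted) <- c(outer$forward, inner$forward, outer$reverse,
                      inner$reverse, inner$probe)
  for (a in names(planted)) for (b in names(planted)) {
    if (a == b) next
    if (grepl(planted[[a]], planted[[b]], fixed = TRUE) ||
        grepl(revcomp(planted[[a]]), planted[[b]], fixed = TRUE))
      stop("target ", tg, ": unsupported sequence overlap between ", a,
           " and ", b, call. = FALSE)
  }
  total <- so - nchar(oF) - nchar(oR) - si
  g1 <- min_spacer + max(0L, (total - 2L * min_spacer) %/% 2L)
  g2 <- need(total - g1, "nested")
  el <- rbind(.element(outer$forward, "primer", "+", oF), sp(3L, g1),
              inner_core(), sp(4L, g2),
              .element(outer$reverse, "primer", "-", revcomp(oR)))
  .finish_block(tg, "nested", el, outer, inner, so, si)
}

.finish_block <- function(target, case, elements, outer, inner,
                          outer_size, inner_size) {
  rownames(elements) <- NULL
  list(target = target, case = case, elements = elements,
       outer_assay = if (!is.null(outer)) outer$assay else NA_character_,
       inner_assay = if (!is.null(inner)) inner$assay else NA_character_,
       outer_size = outer_size, inner_size = inner_size,
       span = sum(elements$length))
}

.check_size_sets <- function(blocks, min_gap_endpoint, min_gap_qpcr) {
  check <- function(sizes, gap, what) {
    if (length(sizes) < 2L) return(invisible())
    if (anyDuplicated(sizes))
      stop("duplicate ", what, " product sizes requested: ",
           paste(sizes[duplicated(sizes)], collapse = ", "), call. = FALSE)
    d <- min(diff(sort(sizes)))
    if (d < gap)
      stop(what, " product sizes closer than ", gap, " bp (min gap ", d,
           ")", call. = FALSE)
  }
  ep <- unlist(lapply(blocks, function(b)
    if (!is.na(b$outer_assay)) b$outer_size else NULL))
  qp <- unlist(lapply(blocks, function(b)
    if (!is.na(b$inner_assay)) b$inner_size else NULL))
  check(ep, min_gap_endpoint, "endpoint")
  check(qp, max(1L, min_gap_qpcr), "qPCR")
  invisible()
}

.auto_sizes <- function(plans, oligos, min_spacer, min_size, max_size,
                        probe_strand) {
  # minimal feasible outer size per target given its geometry, then an even
  # grid over [min_size, max_size] maximizes the minimum pairwise gap
  mins <- vapply(plans, function(pl) {
    rows <- c(pl$outer, pl$inner)
    seqs <- unlist(lapply(list(pl$outer, pl$inner), function(r) {
      if (is.null(r)) return(NULL)
      c(r$forward, r$reverse, if (!is.na(r$probe)) r$probe)
    }))
    sum(nchar(vapply(unique(seqs), function(nm) .seq_of(oligos, nm), ""))) +
      4L * min_spacer
  }, numeric(1L))
  n <- length(plans)
  grid <- round(seq(max_size, max(min_size, max(mins)), length.out = n))
  req <- list()
  ord <- order(mins, decreasing = TRUE)
  for (k in seq_len(n)) {
    pl <- plans[[ord[k]]]
    size <- max(grid[k], ceiling(mins[ord[k]]))
    if (!is.null(pl$outer)) req[[pl$outer$assay]] <- size
    if (!is.null(pl$inner)) {
      inner_min <- if (!is.null(pl$outer) &&
                       !identical(pl$outer$assay, pl$inner$assay)) {
        seqs <- c(pl$inner$forward, pl$inner$reverse, pl$inner$probe)
        sum(nchar(vapply(seqs, function(nm) .seq_of(oligos, nm), ""))) +
          2L * min_spacer
      } else size
      req[[pl$inner$assay]] <- inner_min
    }
  }
  unlist(req)
}

# ---- spacer synthesis -------------------------------------------------------

#' Synthesize screened spacer and barcode sequences for block plans
#'
#' Fills every spacer of every block with GC-balanced random sequence that,
#' on either strand, contains no panel oligo's 3'-terminal k-mer and no
#' 12-bp stretch of any panel oligo. Each block's longest spacer receives a
#' unique barcode (pairwise Hamming distance >= 4 at equal length).
#' Deterministic for a fixed seed.
#'
#' @param blocks block plans from [plan_apc_blocks()].
#' @param panel the source panel (its oligo sequences drive the screens).
#' @param seed RNG seed (mandatory).
#' @param seed_kmer 3'-seed length screened against.
#' @param match_len minimum panel-oligo match length screened against.
#' @param barcode_len barcode length; 0 disables barcodes.
#' @return the blocks, with spacer sequences filled in and barcode features
#'   added.
#' @export
synthesize_spacers <- function(blocks, panel, seed, seed_kmer = 8L,
                               match_len = 12L, barcode_len = 12L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  oligo_seqs <- toupper(panel$oligos$sequence)
  forbidden <- c(.panel_seeds(oligo_seqs, seed_kmer),
                 .panel_windows(oligo_seqs, match_len))
  with_seed(seed, {
    barcodes <- if (barcode_len > 0L)
      .make_barcodes(length(blocks), barcode_len, forbidden) else NULL
    for (b in seq_along(blocks)) {
      el <- blocks[[b]]$elements
      sp_idx <- which(el$type == "spacer")
      host <- if (barcode_len > 0L) {
        cand <- sp_idx[el$length[sp_idx] >= barcode_len + 2L]
        if (length(cand) == 0L)
          stop("block for ", blocks[[b]]$target,
               " has no spacer long enough to host a ", barcode_len,
               "-nt barcode", call. = FALSE)
        cand[which.max(el$length[cand])]
      } else integer()
      for (i in sp_idx) {
        len <- el$length[i]
        if (len == 0L) { el$sequence[i] <- ""; next }
        if (length(host) && i == host) {
          fill <- .screened_dna_or_empty(len - barcode_len, forbidden)
          s <- paste0(barcodes[b], fill)
          if (!.screen_clean(s, forbidden)) {
            # junction between barcode and fill hit a screen; retry fill
            for (t in 1:50) {
              fill <- .screened_dna_or_empty(len - barcode_len, forbidden)
              s <- paste0(barcodes[b], fill)
              if (.screen_clean(s, forbidden)) break
            }
            if (!.screen_clean(s, forbidden))
              stop("could not place barcode for ", blocks[[b]]$target,
                   call. = FALSE)
          }
          el$sequence[i] <- s
          blocks[[b]]$barcode <- barcodes[b]
          blocks[[b]]$barcode_spacer <- el$name[i]
        } else {
          el$sequence[i] <- .screened_dna_or_empty(len, forbidden)
        }
      }
      blocks[[b]]$elements <- el
    }
    blocks
  })
}

.screened_dna_or_empty <- function(len, forbidden) {
  if (len <= 0L) return("")
  if (len < 8L) {
    # short spacers: screens are length-limited, only GC balance is moot
    for (t in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      if (.screen_clean(s, forbidden)) return(s)
    }
    stop("could not generate clean short spacer", call. = FALSE)
  }
  .screened_dna(len, forbidden)
}

.make_barcodes <- function(n, len, forbidden, min_hamming = 4L,
                           max_tries = 2000L) {
  out <- character()
  for (t in seq_len(max_tries)) {
    cand <- .random_dna(len)
    if (!.screen_clean(cand, forbidden)) next
    ok <- all(vapply(out, function(b) {
      sum(strsplit(b, "")[[1L]] != strsplit(cand, "")[[1L]]) >= min_hamming
    }, logical(1L)))
    if (ok) out <- c(out, cand)
    if (length(out) == n) return(out)
  }
  stop("could not generate ", n, " screened barcodes", call. = FALSE)
}

# ---- assembly ---------------------------------------------------------------

#' Assemble an APC construct from synthesized blocks
#'
#' Concatenates the blocks (optionally alternating their orientation, which
#' pushes cross-assay convergent primer pairs far apart), inter-block
#' spacers, and flanking adapters, and records a feature table of every
#' functional element in final construct coordinates.
#'
#' @param blocks blocks with synthesized spacers
#'   (see [synthesize_spacers()]).
#' @param inter_spacers character vector of inter-block spacer sequences
#'   (length `length(blocks) - 1`), or a single integer length to synthesize
#'   at assembly (requires `panel` and `seed`).
#' @param adapters optional `c(left, right)` flanking adapter strings (e.g. a
#'   vector cloning-site context).
#' @param orientation `"alternate"` (default) flips every second block;
#'   `"forward"` keeps all blocks as planned.
#' @param panel,seed needed only when `inter_spacers` is given as a length.
#' @return an object of class `apc_construct`: `sequence`, `features`
#'   (name, type, strand, start, end, block), `blocks`, `sizes`.
#' @export
assemble_apc <- function(blocks, inter_spacers = 10L, adapters = NULL,
                         orientation = c("alternate", "forward"),
                         panel = NULL, seed = NULL) {
  orientation <- match.arg(orientation)
  if (length(blocks) == 0L) stop("empty block list", call. = FALSE)
  if (any(vapply(blocks, function(b) anyNA(b$elements$sequence),
                 logical(1L))))
    stop("blocks have unsynthesized spacers; run synthesize_spacers()",
         call. = FALSE)
  n <- length(blocks)
  if (is.numeric(inter_spacers) && length(inter_spacers) == 1L &&
      is.null(names(inter_spacers))) {
    len <- as.integer(inter_spacers)
    if (n > 1L) {
      if (is.null(panel) || is.null(seed))
        stop("panel and seed are required to synthesize inter-block spacers",
             call. = FALSE)
      forb <- c(.panel_seeds(toupper(panel$oligos$sequence), 8L),
                .panel_windows(toupper(panel$oligos$sequence), 12L))
      inter_spacers <- with_seed(seed + 1L, vapply(seq_len(n - 1L),
        function(i) .screened_dna_or_empty(len, forb), ""))
    } else inter_spacers <- character()
  }
  if (n > 1L && length(inter_spacers) != n - 1L)
    stop("need ", n - 1L, " inter-block spacers", call. = FALSE)

  feats <- list(); pieces <- character(); pos <- 0L
  add_feat <- function(name, type, strand, start, end, block = NA) {
    feats[[length(feats) + 1L]] <<- data.frame(
      name = name, type = type, strand = strand, start = start, end = end,
      block = block, stringsAsFactors = FALSE)
  }
  add_piece <- function(s) { pieces <<- c(pieces, s); pos <<- pos + nchar(s) }

  if (!is.null(adapters) && nzchar(adapters[1L])) {
    add_feat("adapter_5p", "adapter", "+", 1L, nchar(adapters[1L]))
    add_piece(toupper(adapters[1L]))
  }
  for (b in seq_len(n)) {
    blk <- blocks[[b]]
    el <- blk$elements
    flip <- orientation == "alternate" && b %% 2L == 0L
    block_seq <- paste(el$sequence, collapse = "")
    span <- nchar(block_seq)
    rel_start <- cumsum(c(1L, el$length))[seq_len(nrow(el))]
    rel_end <- rel_start + el$length - 1L
    if (flip) {
      block_seq <- revcomp(block_seq)
      new_start <- span - rel_end + 1L
      new_end <- span - rel_start + 1L
      rel_start <- new_start; rel_end <- new_end
      el$strand <- ifelse(el$strand == "+", "-", "+")
    }
    for (i in seq_len(nrow(el))) {
      if (el$length[i] == 0L) next
      type <- switch(el$type[i], primer = "primer_bind",
                     probe = "misc_binding", spacer = "misc_feature",
                     el$type[i])
      add_feat(el$name[i], type, el$strand[i], pos + rel_start[i],
               pos + rel_end[i], blk$target)
      if (!is.null(blk$barcode_spacer) &&
          identical(el$name[i], blk$barcode_spacer)) {
        bl <- nchar(blk$barcode)
        bc_start <- if (!flip) pos + rel_start[i]
                    else pos + rel_end[i] - bl + 1L
        add_feat(paste0(blk$target, "_barcode"), "misc_feature",
                 el$strand[i], bc_start, bc_start + bl - 1L, blk$target)
      }
    }
    if (!is.null(blk$extra_sites)) {
      ex <- blk$extra_sites
      for (i in seq_len(nrow(ex))) {
        s <- ex$rel_start[i]; e <- ex$rel_end[i]; st <- ex$strand[i]
        if (flip) {
          ns <- span - e + 1L; ne <- span - s + 1L
          s <- ns; e <- ne
          st <- if (st == "+") "-" else "+"
        }
        add_feat(ex$name[i], "primer_bind", st, pos + s, pos + e,
                 blk$target)
      }
    }
    blocks[[b]]$orientation <- if (flip) "-" else "+"
    add_piece(block_seq)
    if (b < n && nzchar(inter_spacers[b])) {
      add_feat(sprintf("interblock_%d", b), "misc_feature", "+", pos + 1L,
               pos + nchar(inter_spacers[b]))
      add_piece(toupper(inter_spacers[b]))
    }
  }
  if (!is.null(adapters) && length(adapters) > 1L && nzchar(adapters[2L])) {
    add_feat("adapter_3p", "adapter", "+", pos + 1L,
             pos + nchar(adapters[2L]))
    add_piece(toupper(adapters[2L]))
  }
  sequence <- paste(pieces, collapse = "")
  features <- do.call(rbind, feats)
  sizes <- .designed_sizes(blocks)
  structure(list(sequence = sequence, features = features, blocks = blocks,
                 sizes = sizes),
            class = "apc_construct")
}

.designed_sizes <- function(blocks) {
  out <- list()
  for (b in blocks) {
    if (!is.na(b$outer_assay)) out[[b$outer_assay]] <- b$outer_size
    if (!is.na(b$inner_assay)) out[[b$inner_assay]] <- b$inner_size
  }
  unlist(out)
}

#' @export
print.apc_construct <- function(x, ...) {
  cat(sprintf("<apc_construct> %d bp, %d blocks, %d features\n",
              nchar(x$sequence), length(x$blocks), nrow(x$features)))
  sz <- x$sizes
  cat("  designed sizes:",
      paste(sprintf("%s=%d", names(sz), sz), collapse = ", "), "\n")
  invisible(x)
}

# ---- ordering ---------------------------------------------------------------

# Order blocks so the shortest possible cross-assay product is as long as
# possible. With alternating orientation, the shortest convergent cross
# pairing between two blocks runs from a rightward-extending primer site in
# the left block to a leftward-extending site in the right block; its length
# is the left block's "right margin" + inter-block gap + the right block's
# "left margin", minimized per reaction tube. Exhaustive over permutations
# for <= 8 blocks.
.order_blocks <- function(blocks, panel, inter_gap = 10L,
                          orientation = "alternate") {
  n <- length(blocks)
  if (n <= 1L) return(blocks)
  assays <- panel$assays
  tubes <- list(endpoint = assays_for_reaction(assays, "endpoint"),
                qpcr = assays_for_reaction(assays, "qpcr"))
  tube_primers <- lapply(tubes, function(tb)
    unique(c(tb$forward, tb$reverse)))
  ceilings <- vapply(names(tubes), function(tn) {
    sz <- unlist(lapply(blocks, function(b) c(
      if (!is.na(b$outer_assay) && b$outer_assay %in% tubes[[tn]]$assay)
        b$outer_size,
      if (!is.na(b$inner_assay) && b$inner_assay %in% tubes[[tn]]$assay)
        b$inner_size)))
    if (length(sz)) max(sz) else 0
  }, numeric(1L))

  # margins[[block]][[orient]][[tube]] = c(right = ..., left = ...)
  margins <- lapply(blocks, function(b) {
    el <- b$elements
    span <- b$span
    rel_start <- cumsum(c(1L, el$length))[seq_len(nrow(el))]
    rel_end <- rel_start + el$length - 1L
    sites <- data.frame(name = el$name, type = el$type, strand = el$strand,
                        rel_start = rel_start, rel_end = rel_end,
                        stringsAsFactors = FALSE)
    if (!is.null(b$extra_sites)) sites <- rbind(sites, b$extra_sites)
    per_orient <- function(flip) {
      st <- if (flip) ifelse(sites$strand == "+", "-", "+") else sites$strand
      s0 <- if (flip) span - sites$rel_end + 1L else sites$rel_start
      e0 <- if (flip) span - sites$rel_start + 1L else sites$rel_end
      lapply(tube_primers, function(prs) {
        in_tube <- sites$type == "primer" & sites$name %in% prs
        plus <- in_tube & st == "+"
        minus <- in_tube & st == "-"
        c(right = if (any(plus)) min(span - s0[plus] + 1L) else Inf,
          left = if (any(minus)) min(e0[minus]) else Inf)
      })
    }
    list(`+` = per_orient(FALSE), `-` = per_orient(TRUE))
  })

  orient_at <- function(k) {
    if (orientation == "alternate" && k %% 2L == 0L) "-" else "+"
  }
  score_perm <- function(p) {
    worst <- Inf
    for (k in seq_len(n - 1L)) {
      oi <- orient_at(k); oj <- orient_at(k + 1L)
      for (tn in names(tubes)) {
        mi <- margins[[p[k]]][[oi]][[tn]]
        mj <- margins[[p[k + 1L]]][[oj]][[tn]]
        cross <- mi["right"] + inter_gap + mj["left"]
        worst <- min(worst, cross - ceilings[[tn]])
      }
    }
    worst
  }
  if (n <= 8L) {
    perms <- .permutations(n)
    scores <- apply(perms, 1L, score_perm)
    best <- perms[which.max(scores), ]
  } else {
    spans <- vapply(blocks, `[[`, numeric(1L), "span")
    best <- order(spans, decreasing = TRUE)
    best[seq(2L, n, by = 2L)] <- rev(best[seq(2L, n, by = 2L)])
  }
  blocks[best]
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# ---- top-level design -------------------------------------------------------

#' Design a multi-target artificial positive control
#'
#' Plans per-target blocks, synthesizes screened spacers and barcodes,
#' orders and orientation-alternates the blocks, assembles the construct and
#' verifies it; spacer synthesis is retried (deterministically) when a
#' random junction happens to recreate an oligo site. Identical inputs and
#' seed give a byte-identical construct.
#'
#' @param panel a `pcr_panel` with assays.
#' @param size_requests see [plan_apc_blocks()].
#' @param seed RNG seed (mandatory).
#' @param adapters optional flanking adapters, `c(left, right)`.
#' @param inter_block_len inter-block spacer length, nt.
#' @param orientation see [assemble_apc()].
#' @param max_attempts bound on spacer re-synthesis.
#' @param ... further arguments to [plan_apc_blocks()].
#' @return a verified `apc_construct` (the verification report is attached
#'   as `$verification`).
#' @export
design_apc <- function(panel, size_requests = NULL, seed, adapters = NULL,
                       inter_block_len = 10L,
                       orientation = c("alternate", "forward"),
                       max_attempts = 25L, ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  orientation <- match.arg(orientation)
  blocks <- plan_apc_blocks(panel, size_requests, ...)
  blocks <- .order_blocks(blocks, panel, inter_gap = inter_block_len,
                          orientation = orientation)
  last_fail <- NULL
  for (attempt in seq_len(max_attempts)) {
    attempt_seed <- seed + (attempt - 1L) * 7919L
    synth <- synthesize_spacers(blocks, panel, seed = attempt_seed)
    construct <- assemble_apc(synth, inter_spacers = inter_block_len,
                              adapters = adapters,
                              orientation = orientation, panel = panel,
                              seed = attempt_seed)
    ver <- verify_apc(construct, panel)
    if (ver$pass) {
      construct$verification <- ver
      construct$seed <- seed
      return(construct)
    }
    last_fail <- ver
  }
  fails <- last_fail$report[last_fail$report$status == "fail", ]
  stop("APC design failed verification after ", max_attempts,
       " spacer syntheses; last failures: ",
       paste(sprintf("%s[%s]: %s", fails$check, fails$subject,
                     fails$detail), collapse = "; "), call. = FALSE)
}

# ---- verification -----------------------------------------------------------

#' Verify an APC construct against its panel
#'
#' Checks, per reaction type (endpoint tube / qPCR tube, since primers of
#' different intended use never share a reaction): each assay yields exactly
#' one amplicon of its designed size; each qPCR probe sits strictly between
#' its primers without overlapping them; no cross-assay primer pairing
#' yields a product of `cross_max_len` or shorter (longer cross products,
#' inevitable on a single molecule, are reported informationally). Across the
#' whole construct: every multiplex oligo has exactly one exact-match site,
#' and all designed amplicons have pairwise distinct internal sequences.
#' When the assay table carries genomic product sizes, an APC size equal to
#' its genomic size is flagged informationally (sequence barcodes still
#' guarantee identifiability).
#'
#' @param construct an `apc_construct` (or any object with `sequence`,
#'   `sizes`).
#' @param panel the source `pcr_panel`.
#' @param cross_max_len cross products at or below this length fail
#'   verification; default: the largest designed size in the tube.
#' @param designed_sizes named sizes per assay; default
#'   `construct$sizes`.
#' @return list with `pass` (logical), `report` (check/subject/status/detail
#'   rows), `amplicons`.
#' @export
verify_apc <- function(construct, panel, cross_max_len = NULL,
                       designed_sizes = NULL) {
  oligos <- panel$oligos
  assays <- panel$assays
  if (is.null(assays)) stop("panel has no assay table", call. = FALSE)
  sizes <- designed_sizes %||% construct$sizes
  tpl <- template("APC", construct$sequence)
  rows <- list()
  note <- function(check, subject, status, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, subject = subject, status = status, detail = detail,
      stringsAsFactors = FALSE)
  }
  all_amps <- .empty_amplicons()

  for (reaction in c("endpoint", "qpcr")) {
    tube <- assays_for_reaction(assays, reaction)
    tube <- tube[tube$assay %in% names(sizes), , drop = FALSE]
    if (nrow(tube) == 0L) next
    ceiling_len <- cross_max_len %||% max(sizes[tube$assay])
    for (i in seq_len(nrow(tube))) {
      amps <- predict_amplicons(
        stats::setNames(.seq_of(oligos, tube$forward[i]), tube$forward[i]),
        stats::setNames(.seq_of(oligos, tube$reverse[i]), tube$reverse[i]),
        tpl, assay_name = tube$assay[i])
      want <- sizes[[tube$assay[i]]]
      if (nrow(amps) == 1L && amps$length == want) {
        note("amplicon_size", tube$assay[i], "pass",
             sprintf("%s: one %d bp product", reaction, want))
      } else {
        note("amplicon_size", tube$assay[i], "fail",
             sprintf("%s: expected one %d bp product, got [%s]", reaction,
                     want, paste(amps$length, collapse = ",")))
      }
      if (nrow(amps)) all_amps <- rbind(all_amps, amps)
      if (reaction == "qpcr" && !is.na(tube$probe[i]) &&
          nrow(amps) == 1L) {
        placed <- tryCatch(
          locate_probe(.seq_of(oligos, tube$probe[i]), amps[1L, ],
                       allow_overlap = FALSE),
          error = function(e) conditionMessage(e))
        if (is.list(placed))
          note("probe_placement", tube$assay[i], "pass",
               sprintf("probe %s at %d-%d (%s)", tube$probe[i],
                       placed$start, placed$end, placed$strand))
        else
          note("probe_placement", tube$assay[i], "fail",
               if (is.character(placed)) placed
               else "probe not strictly between the primers")
      }
      # genomic-size discrimination (informational)
      if ("genomic_size" %in% names(tube) && !is.na(tube$genomic_size[i]) &&
          tube$genomic_size[i] == want)
        note("genomic_size_collision", tube$assay[i], "info",
             sprintf("APC size equals genomic size (%d bp); discrimination relies on sequence barcodes",
                     want))
    }
    # cross-assay products: every convergent pairing of any two primers in
    # the tube that is not a designed assay product. On a single molecule
    # some convergent cross pairing always exists; products longer than
    # every designed band are reported informationally only.
    primers <- unique(c(tube$forward, tube$reverse))
    designed_pairs <- paste(pmin(tube$forward, tube$reverse),
                            pmax(tube$forward, tube$reverse),
                            sizes[tube$assay])
    n_long <- 0L
    if (length(primers) > 1L) {
      for (a in seq_len(length(primers) - 1L)) {
        for (b in (a + 1L):length(primers)) {
          cross <- predict_amplicons(
            stats::setNames(.seq_of(oligos, primers[a]), primers[a]),
            stats::setNames(.seq_of(oligos, primers[b]), primers[b]),
            tpl, assay_name = paste0(primers[a], "x", primers[b]),
            max_len = nchar(construct$sequence))
          if (nrow(cross) == 0L) next
          key <- paste(pmin(primers[a], primers[b]),
                       pmax(primers[a], primers[b]), cross$length)
          cross <- cross[!(key %in% designed_pairs), , drop = FALSE]
          if (nrow(cross) == 0L) next
          short <- cross$length <= ceiling_len
          if (any(short))
            note("cross_assay_product",
                 paste0(reaction, ":", primers[a], "x", primers[b]),
                 "fail", sprintf("product(s) of %s bp at or below %d",
                                 paste(cross$length[short], collapse = ","),
                                 ceiling_len))
          n_long <- n_long + sum(!short)
        }
      }
    }
    if (n_long > 0L)
      note("cross_assay_product", reaction, "info",
           sprintf("%d convergent product(s) longer than every designed band (single-molecule geometry)",
                   n_long))
  }

  # exact-site uniqueness over the multiplex oligo set
  tube_all <- assays[assays$use %in% c("endpoint", "qpcr", "both"), ,
                     drop = FALSE]
  used <- unique(c(tube_all$forward, tube_all$reverse,
                   tube_all$probe[!is.na(tube_all$probe)]))
  for (nm in used) {
    hits <- find_binding_sites(stats::setNames(.seq_of(oligos, nm), nm), tpl,
                               max_mismatch = 0L, clamp3 = 0L)
    if (nrow(hits) == 1L) note("site_uniqueness", nm, "pass",
                               sprintf("%s strand %d-%d", hits$strand,
                                       hits$start, hits$end))
    else note("site_uniqueness", nm, "fail",
              sprintf("%d exact sites", nrow(hits)))
  }

  # sequence identifiability: interiors pairwise distinct
  uniq_amps <- all_amps[!duplicated(paste(all_amps$assay, all_amps$length)), ,
                        drop = FALSE]
  if (nrow(uniq_amps) > 1L) {
    interiors <- vapply(seq_len(nrow(uniq_amps)), function(i) {
      flen <- uniq_amps$fwd_end[i] - uniq_amps$fwd_start[i] + 1L
      rlen <- uniq_amps$rev_end[i] - uniq_amps$rev_start[i] + 1L
      s <- uniq_amps$sequence[i]
      substr(s, flen + 1L, nchar(s) - rlen)
    }, "")
    if (anyDuplicated(interiors))
      note("sequence_identifiability", "panel", "fail",
           "two designed amplicons share their internal sequence")
    else note("sequence_identifiability", "panel", "pass",
              sprintf("%d distinct amplicon interiors", nrow(uniq_amps)))
  }

  report <- do.call(rbind, rows)
  list(pass = !any(report$status == "fail"), report = report,
       amplicons = all_amps)
}
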