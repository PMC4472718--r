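# In-silico PCR: oligo binding sites, amplicon prediction, probe placement,
# virtual gel. Coordinates are 1-based inclusive on the plus strand; an
# amplicon includes both primer footprints, so length = rev_end - fwd_start + 1.

#' Construct a template record
#'
#' @param id accession or name.
#' @param sequence DNA string (uppercased on input).
#' @param topology `"linear"` or `"circular"`. Circular templates are searched
#'   on the doubled sequence with start positions restricted to the first
#'   copy, so origin-spanning sites and amplicons are found without creating
#'   duplicates.
#' @param description free text.
#' @return an object of class `template`.
#' @export
template <- function(id, sequence, topology = c("linear", "circular"),
                     description = "") {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- .check_dna(sequence, paste0("template ", id))
  structure(list(id = id, sequence = sequence, topology = topology,
                 description = description),
            class = "template")
}

#' @export
print.template <- function(x, ...) {
  cat(sprintf("<template> %s (%s, %d bp) %s\n", x$id, x$topology,
              nchar(x$sequence), x$description))
  invisible(x)
}

.as_template <- function(x) {
  if (inherits(x, "template")) return(x)
  if (is.character(x) && length(x) == 1L) {
    id <- if (!is.null(names(x))) names(x) else "template"
    return(template(id, unname(x)))
  }
  stop("expected a template object or a single named DNA string", call. = FALSE)
}

.search_space <- function(tpl) {
  if (tpl$topology == "circular") paste0(tpl$sequence, tpl$sequence)
  else tpl$sequence
}

.empty_hits <- function() {
  data.frame(template_id = character(), oligo_name = character(),
             strand = character(), start = integer(), end = integer(),
             mismatches = integer())
}

#' Find oligo binding sites on a template
#'
#' Scans both strands for sites where the oligo anneals with at most
#' `max_mismatch` mismatches and a perfect match over its `clamp3`
#' 3'-terminal bases (the 3' clamp required for productive extension). On the
#' plus strand the oligo reads 5'->3' left-to-right; on the minus strand its
#' reverse complement matches the plus strand and the oligo's 3' end faces
#' left.
#'
#' @param oligo an [oligo()] object, or a single DNA string (optionally
#'   named).
#' @param template a [template()] object or a named DNA string.
#' @param max_mismatch maximum mismatches tolerated outside the clamp.
#' @param clamp3 number of 3'-terminal bases that must match exactly.
#' @return data frame with columns `template_id`, `oligo_name`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive, plus strand),
#'   `mismatches`; sorted by `start`. Empty (no error) when the template is
#'   shorter than the oligo.
#' @export
find_binding_sites <- function(oligo, template, max_mismatch = 0L,
                               clamp3 = 3L) {
  if (inherits(oligo, "oligo")) {
    oname <- oligo$name; oseq <- oligo$sequence
  } else {
    oname <- if (!is.null(names(oligo))) names(oligo) else "oligo"
    oseq <- .check_dna(unname(oligo), "oligo")
  }
  tpl <- .as_template(template)
  m <- nchar(oseq)
  if (clamp3 > m) stop("clamp3 exceeds oligo length", call. = FALSE)
  subj_seq <- .search_space(tpl)
  L <- nchar(tpl$sequence)
  if (nchar(subj_seq) < m) return(.empty_hits())

  subj <- Biostrings::DNAString(subj_seq)
  scan_one <- function(pat_seq, strand) {
    hits <- Biostrings::matchPattern(pat_seq, subj,
                                     max.mismatch = max_mismatch)
    if (length(hits) == 0L) return(.empty_hits())
    starts <- BiocGenerics::start(hits)
    pat_chars <- strsplit(pat_seq, "", fixed = TRUE)[[1L]]
    keep <- logical(length(starts)); mm <- integer(length(starts))
    win <- strsplit(as.character(hits), "", fixed = TRUE)
    # clamp region in plus-strand window coordinates: rightmost clamp3 bases
    # for a plus-strand oligo, leftmost clamp3 bases for a minus-strand one
    clamp_idx <- if (strand == "+") (m - clamp3 + 1L):m
                 else seq_len(clamp3)
    if (clamp3 == 0L) clamp_idx <- integer()
    for (k in seq_along(starts)) {
      mmpos <- which(win[[k]] != pat_chars)
      mm[k] <- length(mmpos)
      keep[k] <- mm[k] <= max_mismatch && !any(mmpos %in% clamp_idx)
    }
    starts <- starts[keep]; mm <- mm[keep]
    if (tpl$topology == "circular") {
      ok <- starts <= L
      starts <- starts[ok]; mm <- mm[ok]
    }
    if (length(starts) == 0L) return(.empty_hits())
    data.frame(template_id = tpl$id, oligo_name = oname, strand = strand,
               start = as.integer(starts), end = as.integer(starts + m - 1L),
               mismatches = mm)
  }
  out <- rbind(scan_one(oseq, "+"), scan_one(revcomp(oseq), "-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR amplicons for one primer pair on one template
#'
#' Every convergent pairing of the two primers yields one amplicon: a
#' plus-strand forward hit upstream of a minus-strand reverse hit
#' (orientation `"+"`), or — since PCR is strand-symmetric — a plus-strand
#' reverse hit upstream of a minus-strand forward hit (orientation `"-"`,
#' e.g. when the target region sits on the opposite strand of a construct).
#' Products longer than `max_len` are dropped. Probes never act as extension
#' primers. Multiple productive pairings are all reported (single-product
#' assays are a design property, not an assumption).
#'
#' @param forward,reverse [oligo()] objects or (named) DNA strings.
#' @param template a [template()] or named DNA string.
#' @param assay_name label recorded on the amplicons.
#' @param max_len maximum product length in bp.
#' @param max_mismatch,clamp3 passed to [find_binding_sites()].
#' @return data frame with one row per amplicon: `template_id`, `assay`,
#'   `fwd_name`, `rev_name`, `fwd_start`, `fwd_end`, `rev_start`, `rev_end`
#'   (all in plus-strand template coordinates), `orientation`, `length`,
#'   `sequence` (written 5'->3' from the forward primer); sorted by length.
#'   Empty when no productive pairing exists.
#' @export
predict_amplicons <- function(forward, reverse, template, assay_name = NULL,
                              max_len = 3000L, max_mismatch = 0L,
                              clamp3 = 3L) {
  tpl <- .as_template(template)
  fh <- find_binding_sites(forward, tpl, max_mismatch, clamp3)
  rh <- find_binding_sites(reverse, tpl, max_mismatch, clamp3)
  if (is.null(assay_name))
    assay_name <- paste0(unique(c(fh$oligo_name, "F"))[1L], "/",
                         unique(c(rh$oligo_name, "R"))[1L])
  out <- .empty_amplicons()
  space <- .search_space(tpl)
  L <- nchar(tpl$sequence)
  circular <- tpl$topology == "circular"
  if (circular) max_len <- min(max_len, L)
  pair_up <- function(left, right, orientation) {
    # left primer extends rightward from its plus-strand site, right primer
    # leftward from its minus-strand site; on a circular template the right
    # site may sit across the origin, i.e. in the second copy of the
    # doubled search space
    if (circular && nrow(right)) {
      shifted <- right
      shifted$start <- shifted$start + L
      shifted$end <- shifted$end + L
      right <- rbind(right, shifted)
    }
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        if (left$start[i] >= right$start[j]) next
        len <- right$end[j] - left$start[i] + 1L
        if (len > max_len) next
        seq5to3 <- substr(space, left$start[i], right$end[j])
        if (orientation == "-") seq5to3 <- revcomp(seq5to3)
        fwd <- if (orientation == "+") left[i, ] else right[j, ]
        rev <- if (orientation == "+") right[j, ] else left[i, ]
        out <<- rbind(out, data.frame(
          template_id = tpl$id, assay = assay_name,
          fwd_name = fwd$oligo_name, rev_name = rev$oligo_name,
          fwd_start = fwd$start, fwd_end = fwd$end,
          rev_start = rev$start, rev_end = rev$end,
          orientation = orientation, length = len,
          sequence = seq5to3))
      }
    }
  }
  pair_up(fh[fh$strand == "+", , drop = FALSE],
          rh[rh$strand == "-", , drop = FALSE], "+")
  pair_up(rh[rh$strand == "+", , drop = FALSE],
          fh[fh$strand == "-", , drop = FALSE], "-")
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_amplicons <- function() {
  data.frame(template_id = character(), assay = character(),
             fwd_name = character(), rev_name = character(),
             fwd_start = integer(), fwd_end = integer(),
             rev_start = integer(), rev_end = integer(),
             orientation = character(),
             length = integer(), sequence = character())
}

#' Simulate a multiplex reaction across templates
#'
#' Runs [predict_amplicons()] for every assay of a panel against every
#' template (the specificity cross-product), optionally adding cross-pairings
#' of forward/reverse primers from different assays for mispriming detection.
#'
#' @param assays data frame with columns `assay`, `forward`, `reverse`
#'   (oligo names) — a panel's `$assays` table works.
#' @param panel a panel object (see [read_panel()]) or a data frame of oligos
#'   with columns `name`, `sequence`.
#' @param templates list of [template()] objects (or a named character vector
#'   of sequences).
#' @param max_mismatch,clamp3,max_len see [find_binding_sites()] /
#'   [predict_amplicons()].
#' @param cross_pairs also simulate forward x reverse combinations from
#'   different assays.
#' @return list with `matrix` (assay x template counts, assays as rows),
#'   `amplicons` (row-bound amplicon table), and `cross` (amplicons from
#'   cross-assay pairings, `NULL` unless `cross_pairs`).
#' @export
simulate_multiplex <- function(assays, panel, templates, max_mismatch = 0L,
                               clamp3 = 3L, max_len = 3000L,
                               cross_pairs = FALSE) {
  oligos <- if (is.data.frame(panel)) panel else panel$oligos
  if (is.character(templates)) {
    templates <- lapply(names(templates), function(nm)
      template(nm, templates[[nm]]))
  }
  if (inherits(templates, "template")) templates <- list(templates)
  stopifnot(nrow(assays) > 0L, length(templates) > 0L)
  seq_of <- function(nm) {
    i <- match(nm, oligos$name)
    if (is.na(i)) stop("oligo not in panel: ", nm, call. = FALSE)
    stats::setNames(toupper(oligos$sequence[i]), nm)
  }
  tids <- vapply(templates, `[[`, "", "id")
  mat <- matrix(0L, nrow(assays), length(templates),
                dimnames = list(assays$assay, tids))
  amps <- .empty_amplicons()
  for (a in seq_len(nrow(assays))) {
    fwd <- seq_of(assays$forward[a]); rev <- seq_of(assays$reverse[a])
    for (t in seq_along(templates)) {
      got <- predict_amplicons(fwd, rev, templates[[t]],
                               assay_name = assays$assay[a],
                               max_len = max_len,
                               max_mismatch = max_mismatch, clamp3 = clamp3)
      mat[a, t] <- nrow(got)
      if (nrow(got)) amps <- rbind(amps, got)
    }
  }
  cross <- NULL
  if (cross_pairs && nrow(assays) > 1L) {
    cross <- .empty_amplicons()
    for (a in seq_len(nrow(assays))) for (b in seq_len(nrow(assays))) {
      if (a == b) next
      fwd <- seq_of(assays$forward[a]); rev <- seq_of(assays$reverse[b])
      for (t in seq_along(templates)) {
        got <- predict_amplicons(fwd, rev, templates[[t]],
                                 assay_name = paste0(assays$assay[a], "x",
                                                     assays$assay[b]),
                                 max_len = max_len,
                                 max_mismatch = max_mismatch,
                                 clamp3 = clamp3)
        if (nrow(got)) cross <- rbind(cross, got)
      }
    }
  }
  list(matrix = mat, amplicons = amps, cross = cross)
}

#' Locate a hydrolysis probe inside an amplicon
#'
#' Finds the exact-match site of the probe (either strand) strictly inside
#' the amplicon sequence. With `allow_overlap = FALSE` the site must not
#' intersect either primer's annealing footprint.
#'
#' @param probe an [oligo()] or DNA string.
#' @param amplicon one row of a [predict_amplicons()] result, or a list/row
#'   with elements `sequence`, `fwd_end`, `fwd_start`, `rev_start` (primer
#'   footprints in template coordinates), or a bare DNA string (footprints
#'   then taken as zero-length).
#' @param allow_overlap may the probe overlap the primer footprints?
#' @return list with `strand`, `start`, `end` (1-based within the amplicon),
#'   or `NULL` when the probe has no site. Multiple interior sites raise an
#'   ambiguity error.
#' @export
locate_probe <- function(probe, amplicon, allow_overlap = FALSE) {
  pseq <- if (inherits(probe, "oligo")) probe$sequence
          else .check_dna(probe, "probe")
  if (is.character(amplicon)) {
    aseq <- .check_dna(amplicon, "amplicon")
    fwd_len <- 0L; rev_len <- 0L
  } else {
    aseq <- amplicon$sequence
    fwd_len <- amplicon$fwd_end - amplicon$fwd_start + 1L
    rev_len <- amplicon$rev_end - amplicon$rev_start + 1L
  }
  n <- nchar(aseq); m <- nchar(pseq)
  sites <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pseq else revcomp(pseq)
    # overlapping occurrences: rescan from each match + 1
    found <- integer()
    from <- 1L
    while (from <= n - m + 1L) {
      hit <- regexpr(pat, substr(aseq, from, n), fixed = TRUE)
      if (hit == -1L) break
      found <- c(found, from + hit - 1L)
      from <- from + hit
    }
    for (s in found)
      sites[[length(sites) + 1L]] <- list(strand = strand, start = s,
                                          end = s + m - 1L)
  }
  ok <- Filter(function(st) {
    inside <- st$start > 1L && st$end < n
    if (!inside) return(FALSE)
    if (allow_overlap) return(TRUE)
    st$start > fwd_len && st$end < n - rev_len + 1L
  }, sites)
  if (length(ok) == 0L) return(NULL)
  if (length(ok) > 1L)
    stop("probe has ", length(ok),
         " interior sites in the amplicon (ambiguous placement)",
         call. = FALSE)
  ok[[1L]]
}

#' Virtual gel lane report
#'
#' Orders product sizes as they would stack in a gel lane (largest first) and
#' flags adjacent pairs closer than `min_separation`, i.e. bands a gel of the
#' corresponding resolution could not discriminate.
#'
#' @param sizes integer vector of product sizes, bp.
#' @param min_separation minimum resolvable size difference, bp.
#' @return data frame with `size` (descending), `gap_below` (distance to the
#'   next smaller band, `NA` for the last), and `distinguishable` (FALSE when
#'   `gap_below < min_separation`). Empty input gives an empty report.
#' @export
virtual_gel <- function(sizes, min_separation = 20L) {
  stopifnot(min_separation >= 0)
  if (length(sizes) == 0L)
    return(data.frame(size = integer(), gap_below = integer(),
                      distinguishable = logical()))
  s <- sort(as.integer(sizes), decreasing = TRUE)
  gap <- c(-diff(s), NA_integer_)
  data.frame(size = s, gap_below = gap,
             distinguishable = is.na(gap) | gap >= min_separation)
}
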