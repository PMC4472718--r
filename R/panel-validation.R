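# Panel-level compatibility: fluorophore-to-channel assignment, cross-dimer
# matrix, annealing-temperature uniformity, endpoint size spacing, and
# inclusivity/exclusivity verdicts.

#' Assign reporter dyes to acquisition channels
#'
#' Maps each dye to the channel whose detection wavelength is nearest its
#' emission. The assignment must be injective (no two dyes on one channel)
#' and all assigned dyes must differ pairwise in emission by at least
#' `min_gap_nm`, otherwise a spectral-conflict error names the offending
#' pair.
#'
#' @param dyes data frame with `dye_name`, `excitation`, `emission` (a
#'   panel's `$dyes` table works), or a list of [dye_spec()] rows.
#' @param channels data frame with `name`, `detect_nm`
#'   (default [default_channels()]).
#' @param min_gap_nm minimum pairwise emission separation.
#' @return data frame `dye_name`, `emission`, `channel`.
#' @export
assign_channels <- function(dyes, channels = default_channels(),
                            min_gap_nm = 25) {
  if (is.list(dyes) && !is.data.frame(dyes)) dyes <- do.call(rbind, dyes)
  stopifnot(is.data.frame(dyes), nrow(dyes) >= 1L)
  .req_cols(dyes, c("dye_name", "emission"), "dye table")
  .req_cols(channels, c("name", "detect_nm"), "channel table")
  if (nrow(dyes) > nrow(channels))
    stop("more dyes (", nrow(dyes), ") than channels (", nrow(channels),
         ")", call. = FALSE)
  if (nrow(dyes) > 1L) {
    for (i in 1L:(nrow(dyes) - 1L)) for (j in (i + 1L):nrow(dyes)) {
      gap <- abs(dyes$emission[i] - dyes$emission[j])
      if (gap < min_gap_nm)
        stop("spectral conflict: ", dyes$dye_name[i], " and ",
             dyes$dye_name[j], " emissions differ by only ", gap,
             " nm (< ", min_gap_nm, ")", call. = FALSE)
    }
  }
  pick <- vapply(dyes$emission, function(em)
    channels$name[which.min(abs(channels$detect_nm - em))], "")
  if (anyDuplicated(pick)) {
    ch <- pick[duplicated(pick)][1L]
    pair <- dyes$dye_name[pick == ch]
    stop("spectral conflict: ", paste(pair, collapse = " and "),
         " are both nearest to channel ", ch, call. = FALSE)
  }
  data.frame(dye_name = dyes$dye_name, emission = dyes$emission,
             channel = pick, stringsAsFactors = FALSE)
}

#' Multiplex compatibility report for a panel
#'
#' Computes the full pairwise cross-dimer matrix (diagonal =
#' [self_any_score()]), flags pairs at or above `dimer_threshold`, checks
#' that computed primer melting temperatures fit a window around the shared
#' annealing temperature, assigns dyes to channels, and runs the virtual-gel
#' spacing check on expected endpoint product sizes.
#'
#' @param panel a `pcr_panel`.
#' @param dimer_threshold cross-dimer score at or above which a pair is
#'   flagged.
#' @param anneal_temp shared annealing temperature, degrees C.
#' @param tm_window allowed half-width around `anneal_temp`, degrees C.
#' @param min_size_gap minimum endpoint product-size spacing, bp.
#' @param channels channel table for dye assignment.
#' @return list of class `compatibility_report`: `dimer_matrix`,
#'   `dimer_flags`, `tm` (per-primer), `tm_ok`, `channel_assignment` (`NULL`
#'   for probe-less panels), `gel`, `findings` (character vector).
#' @export
compatibility_report <- function(panel, dimer_threshold = 12L,
                                 anneal_temp = 60, tm_window = 3,
                                 min_size_gap = 20L,
                                 channels = default_channels()) {
  oligos <- panel$oligos
  stopifnot(nrow(oligos) >= 1L)
  seqs <- stats::setNames(toupper(oligos$sequence), oligos$name)
  n <- length(seqs)
  mat <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in i:n) {
    sc <- if (i == j) self_any_score(seqs[i])
          else cross_dimer_score(seqs[i], seqs[j])
    mat[i, j] <- sc; mat[j, i] <- sc
  }
  idx <- which(mat >= dimer_threshold & upper.tri(mat, diag = TRUE),
               arr.ind = TRUE)
  dimer_flags <- data.frame(
    oligo1 = rownames(mat)[idx[, 1L]], oligo2 = colnames(mat)[idx[, 2L]],
    score = mat[idx], stringsAsFactors = FALSE)

  primers <- oligos[oligos$role != "probe", , drop = FALSE]
  tm <- vapply(stats::setNames(toupper(primers$sequence), primers$name),
               nn_tm, numeric(1L))
  tm_ok <- all(abs(tm - anneal_temp) <= tm_window)

  assignment <- NULL
  if (!is.null(panel$dyes) && nrow(panel$dyes) > 0L)
    assignment <- assign_channels(panel$dyes, channels)

  gel <- NULL
  if (!is.null(panel$assays) && "genomic_size" %in% names(panel$assays)) {
    ep <- assays_for_reaction(panel$assays, "endpoint")
    if (nrow(ep)) gel <- virtual_gel(ep$genomic_size, min_size_gap)
  }

  findings <- character()
  if (nrow(dimer_flags))
    findings <- c(findings, sprintf(
      "cross-dimer score >= %d for %s/%s (%d)", dimer_threshold,
      dimer_flags$oligo1, dimer_flags$oligo2, dimer_flags$score))
  if (!tm_ok)
    findings <- c(findings, sprintf(
      "primer Tm outside %.0f+/-%.0f C: %s", anneal_temp, tm_window,
      paste(names(tm)[abs(tm - anneal_temp) > tm_window], collapse = ", ")))
  if (!is.null(gel) && !all(gel$distinguishable))
    findings <- c(findings, "endpoint product sizes closer than the gel gap")
  structure(list(dimer_matrix = mat, dimer_flags = dimer_flags, tm = tm,
                 tm_ok = tm_ok, channel_assignment = assignment, gel = gel,
                 findings = findings),
            class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf("<compatibility_report> %d oligos, %d dimer flag(s), Tm %s\n",
              nrow(x$dimer_matrix), nrow(x$dimer_flags),
              if (x$tm_ok) "uniform" else "non-uniform"))
  if (length(x$findings)) cat(paste0("  - ", x$findings, "\n"), sep = "")
  else cat("  no findings\n")
  invisible(x)
}

#' Inclusivity/exclusivity check of a panel against templates
#'
#' Every assay must amplify each of its designated target templates
#' (inclusivity) and no assay may amplify any decoy, out-group or host
#' template (exclusivity). The verdict is monotone in the decoy set: adding
#' decoys can break but never create a pass.
#'
#' @param assays assay table (`assay`, `forward`, `reverse`, `target`).
#' @param panel `pcr_panel` or oligo data frame.
#' @param target_templates named list of [template()]s; names are assay
#'   names (every assay needs at least one).
#' @param decoy_templates list of non-target templates.
#' @param max_mismatch,clamp3,max_len stringency (defaults are the
#'   exact-match settings specificity claims are made at).
#' @return list: `matrix` (assay x template product counts), `verdict`
#'   (`TRUE`/`FALSE`), `failures` (data frame naming assay/template for
#'   missed targets or decoy cross-reactions).
#' @export
exclusivity_check <- function(assays, panel, target_templates,
                              decoy_templates = list(), max_mismatch = 0L,
                              clamp3 = 3L, max_len = 3000L) {
  missing_t <- setdiff(assays$assay, names(target_templates))
  if (length(missing_t))
    stop("assay(s) without a designated target template: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  templates <- c(unname(target_templates), decoy_templates)
  sim <- simulate_multiplex(assays, panel, templates,
                            max_mismatch = max_mismatch, clamp3 = clamp3,
                            max_len = max_len)
  mat <- sim$matrix
  fails <- list()
  for (i in seq_len(nrow(assays))) {
    tgt_id <- target_templates[[assays$assay[i]]]$id
    if (mat[assays$assay[i], tgt_id] < 1L)
      fails[[length(fails) + 1L]] <- data.frame(
        assay = assays$assay[i], template = tgt_id, kind = "missed_target")
    other <- setdiff(colnames(mat), tgt_id)
    bad <- other[mat[assays$assay[i], other] > 0L]
    for (b in bad)
      fails[[length(fails) + 1L]] <- data.frame(
        assay = assays$assay[i], template = b, kind = "cross_reaction")
  }
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(assay = character(), template = character(),
                              kind = character())
  list(matrix = mat, verdict = nrow(failures) == 0L, failures = failures,
       amplicons = sim$amplicons)
}
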