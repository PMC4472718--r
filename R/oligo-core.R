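#' @keywords internal
"_PACKAGE"

# ---- sequence primitives ----------------------------------------------------

.valid_dna <- function(seq) {
  is.character(seq) && length(seq) == 1L && !is.na(seq) && nzchar(seq) &&
    !grepl("[^ACGT]", seq)
}

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop(what, " is empty", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop(what, " contains non-DNA characters (alphabet is A/C/G/T): ",
         gsub("[ACGT]", "", seq), call. = FALSE)
  seq
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector of DNA strings (alphabet A/C/G/T, written
#'   5'->3').
#' @return character vector of the same length, each element the reverse
#'   complement of the input, again written 5'->3'.
#' @examples
#' revcomp("AAC")   # "GTT"
#' revcomp("ACGT")  # palindrome
#' @export
revcomp <- function(seq) {
  if (!is.character(seq) || any(is.na(seq)))
    stop("seq must be a character vector without NA", call. = FALSE)
  seq <- toupper(seq)
  bad <- grepl("[^ACGT]", seq)
  if (any(bad))
    stop("non-DNA character in sequence: ", seq[bad][1L], call. = FALSE)
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' GC content of a DNA string
#'
#' @param seq single DNA string.
#' @return percent G+C, rounded to 1 decimal (the precision oligo tables are
#'   printed at).
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq) {
  seq <- .check_dna(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  round(100 * sum(x %in% c("G", "C")) / length(x), 1L)
}

# ---- nearest-neighbor thermodynamics ----------------------------------------

# Unified NN duplex parameters (kcal/mol for dH, cal/(mol K) for dS).
# The ten unique stacks; a dinucleotide absent from the table is looked up as
# its reverse complement.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
.NN_INIT <- list(GC = c(dh = 0.1, ds = -2.8), AT = c(dh = 2.3, ds = 4.1))
.GAS_R <- 1.987 # cal/(mol K)

.nn_lookup <- function(dinuc, table) {
  v <- table[dinuc]
  miss <- is.na(v)
  if (any(miss)) v[miss] <- table[revcomp(dinuc[miss])]
  unname(v)
}

#' Nearest-neighbor thermodynamic parameters
#'
#' Exposes the unified duplex stacking table used by [nn_tm()] and
#' [hairpin_dg()], mainly so that independent re-summations (e.g. in tests or
#' audits) use identical constants.
#'
#' @return a list with elements `dh` (kcal/mol), `ds` (cal/mol/K), named by
#'   dinucleotide stack, plus `init` (duplex initiation terms by terminal
#'   pair class) and `dg37` (stack free energies at 37 C, kcal/mol).
#' @export
nn_parameters <- function() {
  list(dh = .NN_DH, ds = .NN_DS, init = .NN_INIT,
       dg37 = .NN_DH - 310.15 * .NN_DS / 1000)
}

#' Duplex melting temperature by the nearest-neighbor model
#'
#' Computes the melting temperature of the perfect duplex formed by an oligo
#' and its complement, using the unified nearest-neighbor dH/dS table with an
#' entropy salt correction (0.368 x (N-1) x ln[Na+]) and a
#' divalent-to-monovalent conversion of 120 x sqrt(mM divalent). Defaults
#' approximate common primer-design settings: 50 nM oligo, 50 mM monovalent
#' salt, no divalent.
#'
#' @param seq DNA string, length >= 8.
#' @param oligo_conc total oligo concentration, molar.
#' @param monovalent monovalent cation concentration, molar.
#' @param divalent divalent cation concentration, molar.
#' @return melting temperature, degrees Celsius.
#' @export
nn_tm <- function(seq, oligo_conc = 50e-9, monovalent = 0.05, divalent = 0) {
  seq <- .check_dna(seq)
  n <- nchar(seq)
  if (n < 8L)
    stop("nn_tm supports oligos of length >= 8 (got ", n, ")", call. = FALSE)
  stopifnot(oligo_conc > 0, monovalent > 0 || divalent > 0, divalent >= 0)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  dinuc <- paste0(x[-n], x[-1L])
  dh <- sum(.nn_lookup(dinuc, .NN_DH))
  ds <- sum(.nn_lookup(dinuc, .NN_DS))
  for (term in c(x[1L], x[n])) {
    cls <- if (term %in% c("G", "C")) "GC" else "AT"
    dh <- dh + .NN_INIT[[cls]]["dh"]
    ds <- ds + .NN_INIT[[cls]]["ds"]
  }
  selfcomp <- identical(seq, revcomp(seq))
  if (selfcomp) ds <- ds - 1.4
  ct_factor <- if (selfcomp) 1 else 4
  na_eff <- monovalent + 120 * sqrt(divalent * 1000) / 1000
  ds <- ds + 0.368 * (n - 1L) * log(na_eff)
  tm_k <- 1000 * dh / (ds + .GAS_R * log(oligo_conc / ct_factor))
  unname(tm_k - 273.15)
}

# ---- complementarity scores -------------------------------------------------

# Score of the best ungapped antiparallel alignment of a against b:
# a[i] pairs b[j] on the alignment diagonal i + j = d; a Watson-Crick pair
# contributes 1, G:T wobbles contribute nothing.
.align_scores <- function(a, b) {
  ca <- strsplit(chartr("ACGT", "TGCA", a), "", fixed = TRUE)[[1L]]
  xb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(ca); nb <- length(xb)
  vapply(2L:(na + nb), function(d) {
    i <- max(1L, d - nb):min(na, d - 1L)
    sum(ca[i] == xb[d - i])
  }, integer(1L))
}

#' Self-complementarity score ("any")
#'
#' Maximum number of Watson-Crick base pairs over all ungapped antiparallel
#' alignments of an oligo against a second copy of itself. This is a
#' transparent pair-count analogue of primer-design "ANY" self scores.
#'
#' @param seq DNA string.
#' @return integer score.
#' @examples
#' self_any_score("AAAAAA")  # 0: A cannot pair A
#' self_any_score("ATAT")    # 4
#' @export
self_any_score <- function(seq) {
  seq <- .check_dna(seq)
  max(.align_scores(seq, seq))
}

#' 3'-anchored self-complementarity score
#'
#' Like [self_any_score()] but restricted to alignments in which the
#' 3'-terminal base of one copy lies inside the paired window, i.e. the
#' configurations that can prime extension of a self-dimer. Always
#' less than or equal to the "any" score.
#'
#' @param seq DNA string.
#' @return integer score.
#' @export
self_end3_score <- function(seq) {
  seq <- .check_dna(seq)
  n <- nchar(seq)
  sc <- .align_scores(seq, seq)
  # diagonal d pairs position i of copy 1 with d - i of copy 2; the 3' end
  # (i = n) is paired when 1 <= d - n <= n
  anchored <- sc[(2L:(2L * n)) - n >= 1L]
  max(anchored)
}

#' Cross-dimer score between two oligos
#'
#' Maximum Watson-Crick pair count over all ungapped antiparallel alignments
#' of one oligo against another; symmetric in its arguments, and equal to
#' [self_any_score()] when both arguments are the same sequence.
#'
#' @param a,b DNA strings.
#' @return integer score.
#' @examples
#' cross_dimer_score("AAAA", "CCCC")   # 0
#' cross_dimer_score("ACGT", revcomp("ACGT"))  # 4: perfect duplex
#' @export
cross_dimer_score <- function(a, b) {
  a <- .check_dna(a, "a"); b <- .check_dna(b, "b")
  max(.align_scores(a, b))
}

# ---- hairpin surrogate ------------------------------------------------------

# Hairpin loop closure penalties, kcal/mol, loop sizes 3..9; larger loops by
# Jacobson-Stockmayer extrapolation from 9.
.LOOP_DG <- c(`3` = 3.5, `4` = 3.5, `5` = 3.3, `6` = 4.0, `7` = 4.2,
              `8` = 4.3, `9` = 4.5)

.loop_penalty <- function(n) {
  if (n <= 9L) return(unname(.LOOP_DG[as.character(n)]))
  unname(.LOOP_DG["9"]) + 1.75 * .GAS_R / 1000 * 310.15 * log(n / 9)
}

#' Single-stem hairpin free energy screen
#'
#' Enumerates every single stem-loop fold of the oligo (a stem of >= 2
#' contiguous Watson-Crick pairs closing a loop of at least `min_loop`
#' unpaired bases) and returns the most negative free energy, computed as the
#' sum of nearest-neighbor stack free energies at 37 C plus a loop-length
#' penalty. Returns `NA` when no stem of >= 2 pairs exists or when every fold
#' is destabilizing (energy > 0). This is a deliberately simple screening
#' surrogate: it considers one stem only, no bulges, mismatches or
#' multi-branch folds, and its values are not comparable to full
#' secondary-structure folding programs.
#'
#' @param seq DNA string.
#' @param min_loop minimum hairpin loop length, nucleotides (>= 3).
#' @return free energy in kcal/mol (<= 0), or `NA_real_`.
#' @export
hairpin_dg <- function(seq, min_loop = 3L) {
  seq <- .check_dna(seq)
  if (min_loop < 3L) stop("min_loop must be >= 3", call. = FALSE)
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  dg37 <- nn_parameters()$dg37
  best <- NA_real_
  if (n < 2L * 2L + min_loop) return(best)
  # stem arms x[p..p+k-1] and x[q..q+k-1]; pair t of the stem is
  # (p+t, q+k-1-t); loop runs from p+k to q-1
  for (p in 1L:(n - 3L)) {
    kmax <- floor((n - p - min_loop + 1L) / 2L)
    if (kmax < 2L) next
    for (k in 2L:kmax) {
      q_min <- p + k + min_loop
      if (q_min + k - 1L > n) next
      for (q in q_min:(n - k + 1L)) {
        i <- p:(p + k - 1L)
        j <- (q + k - 1L):q
        if (!all(comp[i] == x[j])) next
        stacks <- paste0(x[i[-k]], x[i[-1L]])
        e <- sum(.nn_lookup(stacks, dg37)) + .loop_penalty(q - (p + k))
        if (is.na(best) || e < best) best <- e
      }
    }
  }
  if (!is.na(best) && best > 0) best <- NA_real_
  best
}

# ---- oligo and dye objects --------------------------------------------------

#' Construct an oligo
#'
#' @param name short identifier.
#' @param sequence DNA string written 5'->3' (A/C/G/T only; panel oligos are
#'   non-degenerate).
#' @param role one of `"forward"`, `"reverse"`, `"probe"`. Probes are stored
#'   5'->3' exactly like primers; the role only affects placement rules
#'   downstream.
#' @return an object of class `oligo`.
#' @export
oligo <- function(name, sequence, role = c("forward", "reverse", "probe")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- .check_dna(sequence, paste0("oligo ", name))
  n <- nchar(sequence)
  if (n < 10L || n > 60L)
    stop("oligo ", name, " length ", n, " outside supported range 10-60",
         call. = FALSE)
  structure(list(name = name, sequence = sequence, role = role),
            class = "oligo")
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> %s (%s) %s [%d nt]\n", x$name, x$role, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' Per-oligo property report
#'
#' Computes the properties typically tabulated for panel oligos: length, GC%,
#' nearest-neighbor Tm, self-complementarity "any" and 3' scores, and the
#' single-stem hairpin free energy.
#'
#' @param oligos a data frame with columns `name` and `sequence` (a panel's
#'   `$oligos` table works), a list of [oligo()] objects, or a character
#'   vector of sequences (optionally named).
#' @param ... passed to [nn_tm()].
#' @return data frame with one row per oligo: `name`, `length`, `gc`, `tm`,
#'   `self_any`, `self_end3`, `hairpin_dg`.
#' @export
oligo_report <- function(oligos, ...) {
  if (is.data.frame(oligos)) {
    seqs <- stats::setNames(toupper(oligos$sequence), oligos$name)
  } else if (is.list(oligos)) {
    seqs <- stats::setNames(vapply(oligos, `[[`, "", "sequence"),
                            vapply(oligos, `[[`, "", "name"))
  } else {
    seqs <- toupper(oligos)
    if (is.null(names(seqs))) names(seqs) <- paste0("oligo", seq_along(seqs))
  }
  data.frame(
    name = names(seqs),
    length = nchar(seqs),
    gc = vapply(seqs, gc_content, numeric(1L)),
    tm = vapply(seqs, nn_tm, numeric(1L), ...),
    self_any = vapply(seqs, self_any_score, integer(1L)),
    self_end3 = vapply(seqs, self_end3_score, integer(1L)),
    hairpin_dg = vapply(seqs, hairpin_dg, numeric(1L)),
    row.names = NULL
  )
}

#' Construct a reporter-dye specification
#'
#' @param dye_name label, e.g. `"6-FAM"`.
#' @param excitation,emission band centers in nm; emission must exceed
#'   excitation (Stokes shift).
#' @param quencher quencher label (e.g. `"BHQ2"`), or `NA`.
#' @return an object of class `dye_spec` (a one-row data frame).
#' @export
dye_spec <- function(dye_name, excitation, emission, quencher = NA_character_) {
  stopifnot(is.character(dye_name), length(dye_name) == 1L,
            is.numeric(excitation), is.numeric(emission))
  if (emission <= excitation)
    stop("dye ", dye_name, ": emission (", emission,
         " nm) must exceed excitation (", excitation, " nm)", call. = FALSE)
  structure(data.frame(dye_name = dye_name, excitation = excitation,
                       emission = emission, quencher = quencher),
            class = c("dye_spec", "data.frame"))
}
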