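# Independent brute-force oracles. These deliberately re-derive everything
# with plain loops and literal constants so the implementations they check
# cannot share a defect with them.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.comp1 <- c(A = "T", C = "G", G = "C", T = "A")

# maximum WC pair count over ungapped antiparallel alignments; positions i of
# a and j of b pair on diagonal i + j = d
oracle_align_best <- function(a, b, anchor_end3 = FALSE) {
  ac <- strsplit(a, "")[[1L]]; bc <- strsplit(b, "")[[1L]]
  na <- length(ac); nb <- length(bc)
  best <- 0L
  for (d in 2L:(na + nb)) {
    if (anchor_end3 && (d - na < 1L || d - na > nb)) next
    sc <- 0L
    for (i in seq_len(na)) {
      j <- d - i
      if (j >= 1L && j <= nb && .comp1[[ac[i]]] == bc[j]) sc <- sc + 1L
    }
    best <- max(best, sc)
  }
  best
}

oracle_self_any <- function(s) oracle_align_best(s, s)
oracle_self_end3 <- function(s) oracle_align_best(s, s, anchor_end3 = TRUE)
oracle_cross <- function(a, b) oracle_align_best(a, b)

# naive sliding-window binding-site scan (linear templates)
oracle_scan <- function(oseq, tseq, max_mismatch = 0L, clamp3 = 3L) {
  m <- nchar(oseq); n <- nchar(tseq)
  oc <- strsplit(oseq, "")[[1L]]
  rc <- rev(vapply(oc, function(x) .comp1[[x]], ""))
  tc <- strsplit(tseq, "")[[1L]]
  hits <- data.frame(strand = character(), start = integer(),
                     mismatches = integer())
  if (n < m) return(hits)
  for (s in seq_len(n - m + 1L)) {
    w <- tc[s:(s + m - 1L)]
    mp <- which(w != oc)
    if (length(mp) <= max_mismatch && !any(mp > m - clamp3))
      hits <- rbind(hits, data.frame(strand = "+", start = s,
                                     mismatches = length(mp)))
    mm <- which(w != rc)
    if (length(mm) <= max_mismatch && !any(mm <= clamp3))
      hits <- rbind(hits, data.frame(strand = "-", start = s,
                                     mismatches = length(mm)))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# exhaustive single-stem hairpin enumeration with literal energy tables
oracle_hairpin <- function(seq, min_loop = 3L) {
  # stack free energies derived from the unified dH/dS table at 37 C
  # (dH - 310.15 * dS / 1000), written out literally
  dg37 <- c(AA = -7.9 + 310.15 * 22.2e-3, AT = -7.2 + 310.15 * 20.4e-3,
            TA = -7.2 + 310.15 * 21.3e-3, CA = -8.5 + 310.15 * 22.7e-3,
            GT = -8.4 + 310.15 * 22.4e-3, CT = -7.8 + 310.15 * 21.0e-3,
            GA = -8.2 + 310.15 * 22.2e-3, CG = -10.6 + 310.15 * 27.2e-3,
            GC = -9.8 + 310.15 * 24.4e-3, GG = -8.0 + 310.15 * 19.9e-3)
  look <- function(d) {
    if (d %in% names(dg37)) return(dg37[[d]])
    rcd <- paste(rev(vapply(strsplit(d, "")[[1L]],
                            function(x) .comp1[[x]], "")), collapse = "")
    dg37[[rcd]]
  }
  loop_pen <- function(l) {
    tab <- c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5)
    if (l <= 9L) tab[l - 2L]
    else 4.5 + 1.75 * 0.001987 * 310.15 * log(l / 9)
  }
  x <- strsplit(seq, "")[[1L]]
  n <- length(x)
  best <- NA_real_
  for (p in seq_len(n)) for (q in seq_len(n)) for (k in 2L:30L) {
    if (p + k - 1L >= q) next
    if (q - (p + k) < min_loop) next
    if (q + k - 1L > n) next
    pairs_ok <- TRUE
    for (t in 0L:(k - 1L)) {
      if (.comp1[[x[p + t]]] != x[q + k - 1L - t]) { pairs_ok <- FALSE; break }
    }
    if (!pairs_ok) next
    e <- loop_pen(q - (p + k))
    for (t in 0L:(k - 2L)) e <- e + look(paste0(x[p + t], x[p + t + 1L]))
    if (is.na(best) || e < best) best <- e
  }
  if (!is.na(best) && best > 0) best <- NA_real_
  best
}
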