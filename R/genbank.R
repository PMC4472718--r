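# Minimal GenBank flat-file writer/reader for annotated APC constructs:
# LOCUS / FEATURES / ORIGIN only, 1-based inclusive coordinates,
# complement() for minus-strand features.

#' Write an APC construct as a GenBank flat file
#'
#' Primers are written as `primer_bind` features, probes as `misc_binding`,
#' spacers/barcodes/adapters as `misc_feature`, each with a `/label`
#' qualifier. Coordinates are 1-based inclusive.
#'
#' @param construct an `apc_construct` (or a list with `sequence` and a
#'   `features` data frame: name, type, strand, start, end).
#' @param path output path.
#' @param name LOCUS name.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(construct, path, name = "APC") {
  seqc <- tolower(construct$sequence)
  n <- nchar(seqc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN %s",
                     name, n, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s synthetic multi-target positive control.",
                     name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  writeLines("                     /organism=\"synthetic DNA construct\"", con)
  ft <- construct$features
  if (!is.null(ft)) {
    for (i in seq_len(nrow(ft))) {
      loc <- sprintf("%d..%d", ft$start[i], ft$end[i])
      if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", ft$type[i], loc), con)
      writeLines(sprintf("                     /label=\"%s\"", ft$name[i]),
                 con)
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    line <- substr(seqc, s, min(s + 59L, n))
    chunks <- substring(line, seq(1L, nchar(line), 10L),
                        pmin(seq(10L, nchar(line) + 9L, 10L), nchar(line)))
    writeLines(sprintf("%9d %s", s, paste(chunks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path GenBank flat file.
#' @return list with `name`, `sequence` (uppercase), and `features` data
#'   frame (name, type, strand, start, end).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]
  ori <- which(lines == "ORIGIN")
  stopifnot(length(ori) == 1L)
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^acgtACGT]", "", paste(seq_lines,
                                                    collapse = "")))
  feats <- list()
  feat_block <- lines[(which(grepl("^FEATURES", lines)) + 1L):(ori - 1L)]
  i <- 1L
  while (i <= length(feat_block)) {
    ln <- feat_block[i]
    m <- regmatches(ln, regexec(
      "^     (\\S+)\\s+(complement\\()?(\\d+)\\.\\.(\\d+)\\)?\\s*$", ln))[[1L]]
    if (length(m)) {
      label <- NA_character_
      if (i < length(feat_block)) {
        lm <- regmatches(feat_block[i + 1L],
                         regexec("/label=\"([^\"]*)\"",
                                 feat_block[i + 1L]))[[1L]]
        if (length(lm)) label <- lm[2L]
      }
      feats[[length(feats) + 1L]] <- data.frame(
        name = label, type = m[2L],
        strand = if (nzchar(m[3L])) "-" else "+",
        start = as.integer(m[4L]), end = as.integer(m[5L]),
        stringsAsFactors = FALSE)
    }
    i <- i + 1L
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  if (!is.null(features))
    features <- features[features$type != "source", , drop = FALSE]
  list(name = name, sequence = sequence, features = features)
}

#' Export an APC construct as GenBank + FASTA
#'
#' @param construct a verified `apc_construct`.
#' @param prefix output path prefix; writes `<prefix>.gb` and
#'   `<prefix>.fasta`.
#' @param name construct name.
#' @return named character vector of the written paths, invisibly.
#' @export
export_annotated <- function(construct, prefix, name = "APC") {
  gb <- paste0(prefix, ".gb")
  fa <- paste0(prefix, ".fasta")
  write_genbank(construct, gb, name = name)
  write_fasta(template(name, construct$sequence,
                       description = "synthetic multi-target positive control insert"),
              fa)
  invisible(c(genbank = gb, fasta = fa))
}
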