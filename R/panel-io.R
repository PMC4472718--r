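# Panel and standard-format I/O: FASTA templates, panel TSV/JSON, shipped
# reference tables for the five-species Liposcelis diagnostic panel.

#' Read templates from a FASTA file
#'
#' @param path FASTA file (multi-record). Sequences are uppercased.
#' @param topology topology assigned to every record.
#' @return list of [template()] objects; an empty file gives an empty list.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L ||
      !any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(list())
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    template(id, toupper(as.character(set[[i]])), topology = topology,
             description = desc)
  })
}

#' Write templates to a FASTA file
#'
#' @param templates list of [template()] objects or a named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(templates, path) {
  if (is.character(templates))
    templates <- lapply(names(templates), function(nm)
      template(nm, templates[[nm]]))
  if (inherits(templates, "template")) templates <- list(templates)
  seqs <- Biostrings::DNAStringSet(vapply(templates, `[[`, "", "sequence"))
  names(seqs) <- vapply(templates, function(t) {
    if (nzchar(t$description)) paste(t$id, t$description) else t$id
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.req_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

.validate_oligo_table <- function(ol) {
  .req_cols(ol, c("target", "name", "role", "sequence"), "oligo table")
  if (anyDuplicated(ol$name))
    stop("duplicate oligo names: ",
         paste(unique(ol$name[duplicated(ol$name)]), collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(ol$role), c("forward", "reverse", "probe"))
  if (length(bad_role))
    stop("unknown oligo role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  ol$sequence <- toupper(ol$sequence)
  for (i in seq_len(nrow(ol))) {
    oligo(ol$name[i], ol$sequence[i], ol$role[i]) # runs the invariants
  }
  probes <- ol[ol$role == "probe", , drop = FALSE]
  if (nrow(probes) && all(c("ex", "em") %in% names(probes))) {
    ok <- is.na(probes$em) | is.na(probes$ex) | probes$em > probes$ex
    if (!all(ok))
      stop("probe dye emission must exceed excitation: ",
           paste(probes$name[!ok], collapse = ", "), call. = FALSE)
  }
  ol
}

.validate_assay_table <- function(as, ol) {
  .req_cols(as, c("assay", "target", "forward", "reverse", "use"),
            "assay table")
  if (!"probe" %in% names(as)) as$probe <- NA_character_
  as$probe[as$probe %in% c("", "NA")] <- NA_character_
  bad_use <- setdiff(unique(as$use), c("endpoint", "qpcr", "both", "single"))
  if (length(bad_use))
    stop("unknown assay use(s): ", paste(bad_use, collapse = ", "),
         call. = FALSE)
  refs <- c(as$forward, as$reverse, as$probe[!is.na(as$probe)])
  miss <- setdiff(refs, ol$name)
  if (length(miss))
    stop("assay table references unknown oligo(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  needs_probe <- as$use %in% c("qpcr", "both")
  if (any(needs_probe & is.na(as$probe)))
    stop("qPCR assay(s) without a probe: ",
         paste(as$assay[needs_probe & is.na(as$probe)], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(as$assay))
    stop("duplicate assay names", call. = FALSE)
  as
}

#' Read and validate an oligo panel
#'
#' A panel is the multiplex collection: an oligo table (columns `target`,
#' `name`, `role`, `sequence`, plus optional property/dye metadata) and
#' optionally an assay table grouping oligos into primer pairs with intended
#' use and expected product sizes (columns `assay`, `target`, `forward`,
#' `reverse`, `probe`, `use` in `endpoint|qpcr|both|single`, and optional
#' `genomic_size`, `apc_size`).
#'
#' Accepted formats: a TSV oligo table (with an optional second TSV of
#' assays), or a single JSON file with members `oligos` and `assays`.
#'
#' @param path panel TSV or JSON file.
#' @param assays_path optional assay TSV when `path` is a TSV.
#' @return object of class `pcr_panel`: list with `oligos`, `assays` (may be
#'   `NULL`), and `dyes` (the probe dye table).
#' @export
read_panel <- function(path, assays_path = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    ol <- as.data.frame(js$oligos)
    as <- if (!is.null(js$assays)) as.data.frame(js$assays) else NULL
  } else {
    ol <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    as <- if (!is.null(assays_path))
      utils::read.delim(assays_path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "")) else NULL
  }
  new_panel(ol, as)
}

#' Assemble a panel from in-memory tables
#'
#' @param oligos data frame of oligos (see [read_panel()]).
#' @param assays optional data frame of assays.
#' @return a `pcr_panel`.
#' @export
new_panel <- function(oligos, assays = NULL) {
  ol <- .validate_oligo_table(oligos)
  as <- if (!is.null(assays)) .validate_assay_table(assays, ol) else NULL
  dyes <- NULL
  if (all(c("dye", "ex", "em") %in% names(ol))) {
    pr <- ol[ol$role == "probe" & !is.na(ol$dye), , drop = FALSE]
    if (nrow(pr))
      dyes <- data.frame(dye_name = pr$dye, excitation = pr$ex,
                         emission = pr$em,
                         quencher = if ("quencher" %in% names(pr))
                           pr$quencher else NA_character_,
                         probe = pr$name,
                         channel = if ("channel" %in% names(pr)) pr$channel
                                   else NA_character_)
  }
  structure(list(oligos = ol, assays = as, dyes = dyes), class = "pcr_panel")
}

#' @export
print.pcr_panel <- function(x, ...) {
  cat(sprintf("<pcr_panel> %d oligos (%d primers, %d probes), %d targets",
              nrow(x$oligos), sum(x$oligos$role != "probe"),
              sum(x$oligos$role == "probe"),
              length(unique(x$oligos$target))))
  if (!is.null(x$assays)) cat(sprintf(", %d assays", nrow(x$assays)))
  cat("\n")
  invisible(x)
}

#' Subset a panel's assays by reaction type
#'
#' @param assays an assay table.
#' @param reaction `"endpoint"` or `"qpcr"`. Assays with use `"both"` belong
#'   to either reaction; `"single"`-use assays to neither.
#' @return the matching assay rows.
#' @export
assays_for_reaction <- function(assays, reaction = c("endpoint", "qpcr")) {
  reaction <- match.arg(reaction)
  assays[assays$use %in% c(reaction, "both"), , drop = FALSE]
}

#' Write an oligo property report as TSV
#'
#' @param report result of [oligo_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oligo_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "apctools")
  if (!nzchar(path)) stop("shipped data file not found: ", file,
                          call. = FALSE)
  path
}

#' The shipped Liposcelis identification panel
#'
#' The five-species psocid (booklouse) panel: 20 primers and 5 TaqMan probes
#' targeting the mitochondrial CO1 barcoding locus of *L. brunnea*,
#' *L. bostrychophila*, *L. decolor*, *L. obscura* and *L. pearmani*, with
#' printed property metadata (length, GC%, Tm, hairpin dG, self "any"/3'
#' scores) and probe reporter/quencher spectra.
#'
#' @return a `pcr_panel` with `oligos`, `assays` and `dyes`.
#' @export
liposcelis_panel <- function() {
  read_panel(.extdata("liposcelis_panel.tsv"),
             .extdata("liposcelis_assays.tsv"))
}

#' The shipped multiplex assay definitions
#'
#' @return data frame of the 8 multiplex assays (5 endpoint, 5 qPCR; two
#'   serve both reactions) with genomic and APC product sizes.
#' @export
liposcelis_assays <- function() liposcelis_panel()$assays

#' The shipped qPCR dilution-series reference table
#'
#' Mean and standard deviation of threshold cycles over three replicates for
#' 10-fold serial dilutions of the multi-target artificial positive control
#' (1 ng down to 1 fg per reaction) on two master mixes, per detection
#' channel, plus non-template controls.
#'
#' @param kit optional filter, `"rotorgene"` or `"ssofast"`.
#' @return data frame with columns `kit`, `channel`, `amount_ng`, `mean_ct`,
#'   `sd_ct`, `ntc`.
#' @export
liposcelis_dilution_series <- function(kit = NULL) {
  df <- read_ct_csv(.extdata("liposcelis_ct_series.csv"))
  if (!is.null(kit)) df <- df[df$kit == kit, , drop = FALSE]
  df
}

#' Default acquisition channels
#'
#' Excitation/detection band centers for the five standard acquisition
#' channels of a rotary real-time cycler. These are editable instrument
#' constants, shipped as data.
#'
#' @return data frame with `name`, `source_nm`, `detect_nm`, ordered by
#'   `detect_nm`.
#' @export
default_channels <- function() {
  utils::read.delim(.extdata("rotorgene_channels.tsv"),
                    stringsAsFactors = FALSE)
}
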