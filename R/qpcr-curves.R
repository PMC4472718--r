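# Standard-curve analytics: replicate statistics, Ct-vs-log10(amount)
# regression, amplification efficiency, detection limit.
#
# Template amounts are mass per reaction in ng throughout; unit helpers
# convert the pg/fg labels dilution series are usually written in.

#' Convert template amounts to ng
#'
#' @param amount numeric amounts.
#' @param unit one of `"ng"`, `"pg"`, `"fg"`.
#' @return amounts in ng.
#' @export
amount_to_ng <- function(amount, unit = c("ng", "pg", "fg")) {
  unit <- match.arg(unit)
  amount * switch(unit, ng = 1, pg = 1e-3, fg = 1e-6)
}

#' Per-dilution replicate statistics
#'
#' @param cts list of numeric replicate Ct vectors (one element per
#'   dilution), or a data frame with columns `amount_ng` and `ct`.
#' @return data frame with `amount_ng` (when available), `n`, `mean_ct`,
#'   `sd_ct` (sample SD, n-1 denominator; `NA` for single replicates).
#' @export
replicate_stats <- function(cts) {
  if (is.data.frame(cts)) {
    .req_cols(cts, c("amount_ng", "ct"), "replicate table")
    split_ct <- split(cts$ct, cts$amount_ng)
    amounts <- as.numeric(names(split_ct))
    o <- order(amounts, decreasing = TRUE)
    split_ct <- split_ct[o]; amounts <- amounts[o]
  } else if (is.list(cts)) {
    split_ct <- cts
    amounts <- rep(NA_real_, length(cts))
  } else stop("cts must be a list or a data frame", call. = FALSE)
  if (length(split_ct) == 0L || any(!lengths(split_ct)))
    stop("empty replicate list", call. = FALSE)
  data.frame(
    amount_ng = amounts,
    n = lengths(split_ct),
    mean_ct = vapply(split_ct, mean, numeric(1L)),
    sd_ct = vapply(split_ct, function(x)
      if (length(x) > 1L) stats::sd(x) else NA_real_, numeric(1L)),
    row.names = NULL)
}

#' Amplification efficiency from a standard-curve slope
#'
#' Efficiency as the per-cycle gain fraction, `10^(-1/slope) - 1`; a slope of
#' -3.32 cycles per 10-fold dilution corresponds to perfect doubling
#' (efficiency 1).
#'
#' @param slope cycles per log10 amount; must be negative.
#' @return efficiency fraction.
#' @examples
#' efficiency_from_slope(-1 / log10(2))  # exactly 1
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(is.na(slope)) || any(slope >= 0))
    stop("slope must be negative (Ct decreases with template amount)",
         call. = FALSE)
  10^(-1 / slope) - 1
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(template amount). By default the fit
#' is on per-dilution replicate means (the convention dilution tables are
#' printed in); `per_replicate = TRUE` fits all replicate Ct values instead.
#'
#' @param series data frame with column `amount_ng` and either `ct`
#'   (replicate-level rows) or `mean_ct`; non-template controls (rows with
#'   `NA` amount or a `ntc` flag) are ignored for fitting.
#' @param per_replicate fit replicate-level Ct values when available.
#' @return list of class `standard_curve_fit`: `slope`, `intercept`, `r2`,
#'   `efficiency`, `n_points`, and `points` (per-dilution mean/SD table).
#' @export
fit_standard_curve <- function(series, per_replicate = FALSE) {
  stopifnot(is.data.frame(series))
  .req_cols(series, "amount_ng", "standard-curve series")
  if ("ntc" %in% names(series)) series <- series[!series$ntc, , drop = FALSE]
  series <- series[!is.na(series$amount_ng), , drop = FALSE]
  if (any(series$amount_ng <= 0))
    stop("template amounts must be strictly positive", call. = FALSE)
  if ("ct" %in% names(series)) {
    if (any(!is.finite(series$ct)))
      stop("non-finite Ct value in series", call. = FALSE)
    pts <- replicate_stats(series[, c("amount_ng", "ct")])
  } else {
    .req_cols(series, "mean_ct", "standard-curve series")
    if (any(!is.finite(series$mean_ct)))
      stop("non-finite Ct value in series", call. = FALSE)
    pts <- data.frame(amount_ng = series$amount_ng, n = 1L,
                      mean_ct = series$mean_ct,
                      sd_ct = if ("sd_ct" %in% names(series)) series$sd_ct
                              else NA_real_)
    per_replicate <- FALSE
  }
  if (length(unique(pts$amount_ng)) < 3L)
    stop("need >= 3 distinct template amounts to fit a standard curve",
         call. = FALSE)
  if (per_replicate) {
    x <- log10(series$amount_ng); y <- series$ct
  } else {
    x <- log10(pts$amount_ng); y <- pts$mean_ct
  }
  fit <- stats::lm(y ~ x)
  # noiseless (e.g. simulated) series fit perfectly; summary()'s warning
  # about that is not informative here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    stop("fitted slope is non-negative; not a valid dilution series",
         call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2,
                 efficiency = efficiency_from_slope(slope),
                 n_points = length(unique(x)),
                 per_replicate = per_replicate,
                 points = pts),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<standard_curve_fit> slope %.3f cycles/log10, intercept %.2f, R2 %.4f, efficiency %.3f (%.0f%%), %d dilutions\n",
    x$slope, x$intercept, x$r2, x$efficiency, 100 * x$efficiency,
    x$n_points))
  invisible(x)
}

#' Detection limit of a dilution series
#'
#' @param series data frame with `amount_ng` and replicate detection calls:
#'   either a logical `detected` column or `ct` values where a finite Ct
#'   means detected (`NA` = no amplification). NTC rows (`NA` amount or
#'   `ntc` flag) are ignored.
#' @param criterion `"all"` (every replicate detected; default) or `"any"`.
#' @return the smallest amount (ng) satisfying the criterion, or `NA_real_`
#'   when nothing is detected.
#' @export
detection_limit <- function(series, criterion = c("all", "any")) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(series))
  if ("ntc" %in% names(series)) series <- series[!series$ntc, , drop = FALSE]
  series <- series[!is.na(series$amount_ng), , drop = FALSE]
  det <- if ("detected" %in% names(series)) series$detected
         else if ("ct" %in% names(series)) is.finite(series$ct)
         else if ("mean_ct" %in% names(series)) is.finite(series$mean_ct)
         else stop("series has no detection calls (detected/ct/mean_ct)",
                   call. = FALSE)
  agg <- tapply(det, series$amount_ng,
                if (criterion == "all") all else any)
  hits <- as.numeric(names(agg))[agg]
  if (length(hits) == 0L) return(NA_real_)
  min(hits)
}

#' Read a dilution-series Ct table from CSV
#'
#' Accepts either replicate-level columns (`kit`, `channel`, `amount_ng`,
#' `rep1`..`repN`) or a pre-averaged table (`mean_ct`, `sd_ct`). Rows with an
#' empty amount are non-template controls and get `ntc = TRUE`.
#'
#' @param path CSV file.
#' @return long-format data frame: `kit`, `channel`, `amount_ng`, `ntc`, and
#'   either `ct`/`replicate` or `mean_ct`/`sd_ct`.
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  .req_cols(df, c("channel", "amount_ng"), "Ct table")
  if (!"kit" %in% names(df)) df$kit <- "default"
  df$ntc <- is.na(df$amount_ng)
  reps <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (length(reps)) {
    long <- do.call(rbind, lapply(seq_along(reps), function(k) {
      data.frame(kit = df$kit, channel = df$channel,
                 amount_ng = df$amount_ng, ntc = df$ntc,
                 replicate = k, ct = df[[reps[k]]])
    }))
    rownames(long) <- NULL
    return(long[order(long$kit, long$channel, -xtfrm(long$amount_ng),
                      long$replicate), , drop = FALSE])
  }
  .req_cols(df, "mean_ct", "Ct table")
  df[, c("kit", "channel", "amount_ng", "mean_ct",
         intersect("sd_ct", names(df)), "ntc"), drop = FALSE]
}

#' Fit standard curves for every kit/channel in a Ct table
#'
#' @param ct_table result of [read_ct_csv()] (or any data frame with `kit`,
#'   `channel` and the columns [fit_standard_curve()] accepts).
#' @param per_replicate see [fit_standard_curve()].
#' @return data frame with one row per kit x channel: `kit`, `channel`,
#'   `slope`, `intercept`, `r2`, `efficiency`, `n_points`, plus the
#'   detection limit in ng.
#' @export
fit_all_curves <- function(ct_table, per_replicate = FALSE) {
  stopifnot(is.data.frame(ct_table))
  if (!"kit" %in% names(ct_table)) ct_table$kit <- "default"
  groups <- unique(ct_table[, c("kit", "channel")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sub <- ct_table[ct_table$kit == groups$kit[i] &
                    ct_table$channel == groups$channel[i], , drop = FALSE]
    f <- fit_standard_curve(sub, per_replicate = per_replicate)
    data.frame(kit = groups$kit[i], channel = groups$channel[i],
               slope = f$slope, intercept = f$intercept, r2 = f$r2,
               efficiency = f$efficiency, n_points = f$n_points,
               lod_ng = detection_limit(sub))
  }))
  rownames(out) <- NULL
  out
}
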