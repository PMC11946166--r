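## "Functional dissection": per-ROI averaging of source estimates and
## Student-t confidence intervals, assembled into per-concert trend
## tables.

#' Average a source estimate over a scout and time window
#'
#' The grand mean over (scout vertices x window samples) of each
#' chromophore matrix — the sum divided by
#' `n_vertices * n_samples`, equivalently a time average followed by a
#' vertex average.
#'
#' @param est a `source_estimate`.
#' @param scout a `nirs_scout`.
#' @param window optional `c(start_s, end_s)` relative to the
#'   estimate's first sample (half-open); default: all samples.
#' @return named numeric vector `c(hbo=, hbr=, hbt=)`.
#' @export
scout_average <- function(est, scout, window = NULL) {
  stopifnot(inherits(est, "source_estimate"), inherits(scout, "nirs_scout"))
  v <- scout$vertex_ids
  if (length(v) == 0L) stop_("empty scout")
  if (max(v) > est$n_vertices) stop_("scout vertex id outside estimate")
  idx <- if (is.null(window)) seq_len(est$n_samples)
         else sample_window(window[1], window[2], est$fs)
  if (length(idx) == 0L || max(idx) > est$n_samples)
    stop_("window outside estimate span")
  vapply(c(hbo = "hbo", hbr = "hbr", hbt = "hbt"),
         function(f) mean(est[[f]][v, idx]), 0)
}

#' Student-t confidence interval (mean + T * SEM rule)
#'
#' The interval rule used for the concert ROI summaries: the standard
#' error of the mean `SEM = sd(X)/sqrt(n)` (sample sd, n-1 denominator)
#' and the Student-t quantile `T = qt(1 - alpha/2, n - 1)` give
#' `CI = mean(X) +/- T * SEM`. The literal one-sided form
#' (`mean + T * SEM` only, no lower bound) is available with
#' `two_sided = FALSE`.
#'
#' @param X numeric sample vector, `n >= 2`.
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @param two_sided return the symmetric interval (default TRUE).
#' @return list with `mean`, `sem`, `t`, `ci_low`, `ci_high`, `n`.
#' @examples
#' ci_eq1(c(1, 2, 3))  # mean 2, sem 0.577, ci_high ~ 4.484
#' @export
ci_eq1 <- function(X, alpha = 0.05, two_sided = TRUE) {
  X <- as.numeric(X)
  n <- length(X)
  if (n < 2L) stop_("confidence interval needs n >= 2 (got %d)", n)
  m <- mean(X)
  sem <- stats::sd(X) / sqrt(n)
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  list(mean = m, sem = sem, t = tq,
       ci_low = if (two_sided) m - tq * sem else NA_real_,
       ci_high = m + tq * sem, n = n)
}

#' Per-concert ROI statistics from per-piece scout summaries
#'
#' The sample entering the interval rule is the set of per-piece
#' scout-averaged summaries within one concert (recorded in the output
#' so alternatives remain distinguishable).
#'
#' @param piece_values matrix `[n_pieces x 3]` with columns
#'   `hbo`, `hbr`, `hbt` (rows: pieces), as produced by stacking
#'   [scout_average()] results.
#' @param scout scout name.
#' @param concert_index integer concert number.
#' @param performer performer id.
#' @param alpha significance level.
#' @return data.frame, one row per chromophore, columns `performer`,
#'   `concert_index`, `scout`, `chromophore`, `mean`, `sem`, `ci_low`,
#'   `ci_high`, `n`, `sample_unit`.
#' @export
roi_stats <- function(piece_values, scout, concert_index, performer = "S1",
                      alpha = 0.05) {
  piece_values <- as.matrix(piece_values)
  labels <- c(hbo = "HbO", hbr = "HbR", hbt = "HbT")
  do.call(rbind, lapply(c("hbo", "hbr", "hbt"), function(f) {
    ci <- ci_eq1(piece_values[, f], alpha = alpha)
    data.frame(performer = performer, concert_index = concert_index,
               scout = scout, chromophore = labels[[f]],
               mean = ci$mean, sem = ci$sem, ci_low = ci$ci_low,
               ci_high = ci$ci_high, n = ci$n,
               sample_unit = "piece")
  }))
}

#' Assemble a cross-concert trend table with explicit gap rows
#'
#' Orders ROI statistics by concert within performer/scout/chromophore
#' and inserts explicit gap rows (`gap = TRUE`, NA statistics) for
#' concerts with no usable recording. Gaps are never interpolated:
#' missing data stays missing.
#'
#' @param stats data.frame of [roi_stats()] rows across concerts.
#' @param concerts full concert index set the table should span
#'   (default: `1:max(concert_index)`).
#' @return data.frame of class `trend_table` with an added `gap`
#'   column, sorted by performer, scout, chromophore, concert.
#' @export
trend_table <- function(stats, concerts = NULL) {
  if (nrow(stats) == 0L) stop_("need at least one analyzed concert")
  concerts <- concerts %||% seq_len(max(stats$concert_index))
  combos <- unique(stats[, c("performer", "scout", "chromophore")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    sub <- stats[stats$performer == cb$performer &
                 stats$scout == cb$scout &
                 stats$chromophore == cb$chromophore, ]
    miss <- setdiff(concerts, sub$concert_index)
    gaps <- if (length(miss))
      data.frame(performer = cb$performer, concert_index = miss,
                 scout = cb$scout, chromophore = cb$chromophore,
                 mean = NA_real_, sem = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n = 0L,
                 sample_unit = sub$sample_unit[1] %||% "piece")
      else NULL
    sub$gap <- FALSE
    if (!is.null(gaps)) gaps$gap <- TRUE
    out <- rbind(sub, gaps)
    out[order(out$concert_index), ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trend_table", class(out))
  out
}

#' Linear trend of ROI means across concerts
#'
#' Least-squares slope of the per-concert mean against concert index,
#' gap rows excluded.
#'
#' @param tt a [trend_table()].
#' @param scout,chromophore,performer which series to fit.
#' @return list with `slope`, `intercept`, `n`.
#' @export
trend_slope <- function(tt, scout, chromophore = "HbT", performer = NULL) {
  sub <- tt[tt$scout == scout & tt$chromophore == chromophore & !tt$gap, ]
  if (!is.null(performer)) sub <- sub[sub$performer == performer, ]
  if (nrow(sub) < 2L) stop_("need >= 2 non-gap concerts for a trend")
  fit <- stats::lm(mean ~ concert_index, data = sub)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = nrow(sub))
}

#' Write a trend table as TSV or JSON
#'
#' @param tt a [trend_table()].
#' @param path output path (`.tsv` or `.json` by extension).
#' @export
write_trend_table <- function(tt, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tt, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(tt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
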