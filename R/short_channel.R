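## Averaged short-separation-channel (SSC) subtraction on per-piece
## channel summaries, with negative zeroing, plus an SSC-dominance
## diagnostic. The correction operates on piece-level time means (the
## channel-summary analysis), not sample-wise; a sample-wise variant is
## provided separately as an extension.

#' Per-piece channel means of a concentration series
#'
#' Time-mean of one chromophore per source-detector pair within each
#' piece's `[start, end)` window.
#'
#' @param conc a `nirs_conc`.
#' @param pieces a [pieces_from_events()] table (or data.frame with
#'   `id`, `start`, `end`).
#' @param chromophore which chromophore to summarize (default `"hbt"`,
#'   the convention for the channel-level concert summaries).
#' @return object of class `piece_channel_means`: matrix
#'   `[n_pieces x n_pairs]` with piece ids as row names, plus attributes
#'   `ssc` (short pair ids), `chromophore`, `units`.
#' @export
piece_channel_means <- function(conc, pieces,
                                chromophore = c("hbt", "hbo", "hbr")) {
  stopifnot(inherits(conc, "nirs_conc"))
  chromophore <- match.arg(chromophore)
  X <- conc[[chromophore]]
  n <- nrow(X)
  vals <- t(vapply(seq_len(nrow(pieces)), function(i) {
    idx <- sample_window(pieces$start[i], pieces$end[i], conc$fs)
    if (min(idx) < 1L || max(idx) > n)
      stop_("piece '%s' window outside recording", pieces$id[i])
    colMeans(X[idx, , drop = FALSE])
  }, numeric(ncol(X))))
  rownames(vals) <- pieces$id
  ssc <- conc$pairs$pair[conc$pairs$is_short]
  if (length(ssc) == 0L)
    warn_("montage has no short-separation channels")
  structure(vals, ssc = ssc, chromophore = chromophore,
            units = conc$units, class = c("piece_channel_means", "matrix"))
}

#' Averaged SSC subtraction with negative zeroing
#'
#' For each piece, subtracts the mean of the short-separation-channel
#' values from every long channel's piece mean and clamps negative
#' results to exactly zero. A clamped (zeroed) channel is flagged
#' low-trust: its piece mean did not exceed the superficial signal
#' level, so it is likely dominated by extracerebral physiology or
#' noise. Short channels are excluded from the output.
#'
#' @param means a [piece_channel_means()] object.
#' @return data.frame of class `ssc_report` with one row per
#'   (piece, long pair): `piece`, `pair`, `raw_mean`, `ssc_mean`,
#'   `corrected`, `zeroed`.
#' @export
ssc_subtract <- function(means) {
  stopifnot(inherits(means, "piece_channel_means"))
  ssc <- attr(means, "ssc")
  if (length(ssc) == 0L)
    stop_("no short-separation channels in montage; cannot SSC-correct")
  pairs <- colnames(means)
  long <- setdiff(pairs, ssc)
  rows <- lapply(rownames(means), function(pid) {
    v <- means[pid, ]
    ssc_mean <- mean(v[ssc])
    raw <- v[long]
    corr <- pmax(0, raw - ssc_mean)
    data.frame(piece = pid, pair = long, raw_mean = unname(raw),
               ssc_mean = ssc_mean, corrected = unname(corr),
               zeroed = unname(raw - ssc_mean < 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "units") <- attr(means, "units")
  class(out) <- c("ssc_report", class(out))
  out
}

#' SSC dominance diagnostic
#'
#' Quantifies how large the superficial (short-channel) signal is
#' relative to the conventional channels: per piece and overall, the
#' ratio `mean(SSC) / mean(long)` of piece means, and the fraction of
#' long channels whose SSC-corrected mean clamps to zero. A zeroed
#' fraction near 1 reproduces the scenario where the recording is
#' predominantly superficial noise.
#'
#' @param means a [piece_channel_means()] object (>= 1 piece).
#' @return data.frame with rows per piece plus an `"overall"` row:
#'   `piece`, `ssc_mean`, `long_mean`, `ratio`, `zeroed_fraction`.
#' @export
ssc_dominance <- function(means) {
  stopifnot(inherits(means, "piece_channel_means"))
  if (nrow(means) < 1L) stop_("need at least one piece")
  rep_ <- ssc_subtract(means)
  ssc <- attr(means, "ssc")
  long <- setdiff(colnames(means), ssc)
  per_piece <- do.call(rbind, lapply(rownames(means), function(pid) {
    sm <- mean(means[pid, ssc]); lm <- mean(means[pid, long])
    data.frame(piece = pid, ssc_mean = sm, long_mean = lm,
               ratio = if (lm != 0) sm / lm else NA_real_,
               zeroed_fraction = mean(rep_$zeroed[rep_$piece == pid]))
  }))
  sm <- mean(means[, ssc]); lm <- mean(means[, long])
  overall <- data.frame(piece = "overall", ssc_mean = sm, long_mean = lm,
                        ratio = if (lm != 0) sm / lm else NA_real_,
                        zeroed_fraction = mean(rep_$zeroed))
  rbind(per_piece, overall)
}

#' Sample-wise SSC regression-free subtraction (extension)
#'
#' Extension beyond the piece-summary correction: subtracts the mean
#' short-channel time course from every long channel at each sample.
#' Not part of the channel-summary protocol; off by default everywhere
#' in the pipeline.
#'
#' @param conc a `nirs_conc`.
#' @param clamp clamp negative samples to zero (default FALSE; the
#'   piece-summary rule's zeroing is a trust indicator and is usually
#'   not meaningful sample-wise).
#' @return a `nirs_conc` containing long pairs only.
#' @export
ssc_subtract_samplewise <- function(conc, clamp = FALSE) {
  stopifnot(inherits(conc, "nirs_conc"))
  ssc <- conc$pairs$pair[conc$pairs$is_short]
  if (length(ssc) == 0L) stop_("no short-separation channels")
  long <- setdiff(conc$pairs$pair, ssc)
  for (f in c("hbo", "hbr", "hbt")) {
    ref <- rowMeans(conc[[f]][, ssc, drop = FALSE])
    M <- conc[[f]][, long, drop = FALSE] - ref
    if (clamp) M[M < 0] <- 0
    conc[[f]] <- M
  }
  conc$pairs <- conc$pairs[match(long, conc$pairs$pair), ]
  conc
}
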