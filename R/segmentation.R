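## Event-to-window bookkeeping for the three analysis protocols:
## whole-piece averaging, piece-onset (initial 20 s), and mid-piece
## (60-120 s into pieces longer than three minutes).

#' Convert a time in seconds to a sample index
#'
#' The sampling convention used throughout the package: a time `t`
#' maps to the zero-based cell `floor(t * fs)`, and a half-open interval
#' `[a, b)` maps to zero-based cells `[floor(a*fs), floor(b*fs))`.
#'
#' @param t time in seconds, `t >= 0`.
#' @param fs sampling frequency in Hz.
#' @return zero-based sample index (integer).
#' @examples
#' time_to_index(20, 75)    # 1500
#' time_to_index(12.5, 75)  # 937
#' @export
time_to_index <- function(t, fs) {
  if (any(t < 0)) stop_("negative time")
  as.integer(floor(t * fs))
}

#' 1-based sample indices of a half-open time window
#'
#' @param a,b window `[a, b)` in seconds.
#' @param fs sampling frequency, Hz.
#' @return integer vector of 1-based row indices
#'   (`floor(a*fs)+1 .. floor(b*fs)`), length `floor(b*fs) - floor(a*fs)`.
#' @export
sample_window <- function(a, b, fs) {
  if (b < a) stop_("window end before start")
  i0 <- time_to_index(a, fs); i1 <- time_to_index(b, fs)
  if (i1 <= i0) return(integer(0))
  seq.int(i0 + 1L, i1)
}

#' Extract musical pieces from labeled events
#'
#' Pieces are encoded as paired events `"<id>/start"` and `"<id>/end"`.
#' Matched pairs become `Piece` rows; unmatched start/end labels are
#' reported via attribute `unmatched` and a warning. Overlapping pieces
#' (attacca transitions) are allowed but flagged.
#'
#' @param events event data.frame (`label`, `onset`, `duration`).
#' @return data.frame of class `piece_table`, columns `id`, `start`,
#'   `end`, `duration`, `overlaps` (logical), sorted by start.
#' @export
pieces_from_events <- function(events) {
  events <- validate_events(events)
  is_start <- grepl("/start$", events$label)
  is_end <- grepl("/end$", events$label)
  sid <- sub("/start$", "", events$label[is_start])
  eid <- sub("/end$", "", events$label[is_end])
  ids <- intersect(sid, eid)
  unmatched <- c(setdiff(sid, eid), setdiff(eid, sid))
  if (length(unmatched))
    warn_("%d unmatched piece boundary label(s): %s", length(unmatched),
          paste(unmatched, collapse = ", "))
  rows <- lapply(ids, function(id) {
    s <- events$onset[events$label == paste0(id, "/start")][1]
    e <- events$onset[events$label == paste0(id, "/end")][1]
    if (e <= s)
      stop_("labeling error: piece '%s' ends (%.2f s) before it starts (%.2f s)",
            id, e, s)
    data.frame(id = id, start = s, end = e, duration = e - s)
  })
  p <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), start = numeric(), end = numeric(),
               duration = numeric())
  p <- p[order(p$start), ]
  p$overlaps <- FALSE
  if (nrow(p) > 1L)
    for (i in 2:nrow(p))
      if (p$start[i] < p$end[i - 1L]) p$overlaps[c(i - 1L, i)] <- TRUE
  rownames(p) <- NULL
  attr(p, "unmatched") <- unmatched
  class(p) <- c("piece_table", class(p))
  p
}

## Skip sentinel: a piece excluded from a protocol, with the reason.
protocol_skip <- function(reason) {
  structure(list(skip_reason = reason), class = "protocol_skip")
}

#' Was a piece skipped by a protocol?
#' @param w result of a `windows_*` function.
#' @return TRUE if the piece was excluded; the reason is in
#'   `attr(w, "skip_reason")` / `w$skip_reason`.
#' @export
is_skipped <- function(w) inherits(w, "protocol_skip")

protocol_windows <- function(protocol, baseline, analysis, model_span = NULL) {
  structure(list(protocol = protocol, baseline = baseline,
                 analysis = analysis, model_span = model_span),
            class = "protocol_windows")
}

#' @export
print.protocol_windows <- function(x, ...) {
  fmt <- function(w) if (is.null(w)) "none" else sprintf("[%g, %g)", w[1], w[2])
  cat(sprintf("<protocol_windows> %s: baseline %s, analysis %s%s\n",
              x$protocol, fmt(x$baseline), fmt(x$analysis),
              if (is.null(x$model_span)) ""
              else sprintf(", model span %s", fmt(x$model_span))))
  invisible(x)
}

#' Whole-piece analysis windows
#'
#' The purely averaging protocol: the analysis window is the full piece
#' and there is no baseline reference at all.
#'
#' @param piece one row of a [pieces_from_events()] table (or any list
#'   with `start` and `end` in seconds).
#' @return a `protocol_windows` object with `baseline = NULL`.
#' @export
windows_whole_piece <- function(piece) {
  if (piece$end <= piece$start) stop_("zero- or negative-length piece")
  protocol_windows("whole_piece", NULL, c(piece$start, piece$end))
}

#' Piece-onset analysis windows
#'
#' A 5 s baseline immediately before the piece and the first 20 s of
#' the piece. Pieces with insufficient pre-roll or shorter than 20 s are
#' skipped.
#'
#' @param piece as in [windows_whole_piece()].
#' @param baseline_s,analysis_s window lengths (defaults 5 and 20 s).
#' @return a `protocol_windows`, or a `protocol_skip` object carrying
#'   the reason if the piece does not qualify (test with [is_skipped()]).
#' @export
windows_initial <- function(piece, baseline_s = 5, analysis_s = 20) {
  if (piece$start < baseline_s)
    return(protocol_skip(sprintf(
      "piece '%s' starts %.1f s in; needs %g s pre-roll",
      piece$id %||% "?", piece$start, baseline_s)))
  if (piece$end - piece$start < analysis_s)
    return(protocol_skip(sprintf(
      "piece '%s' lasts %.1f s; needs >= %g s",
      piece$id %||% "?", piece$end - piece$start, analysis_s)))
  protocol_windows("initial",
                   c(piece$start - baseline_s, piece$start),
                   c(piece$start, piece$start + analysis_s))
}

#' Mid-piece analysis windows
#'
#' For pieces strictly longer than three minutes: a 20 s baseline before
#' the piece, a three-minute model span from piece start, and an
#' analysis window covering 60-120 s into the piece.
#'
#' @param piece as in [windows_whole_piece()].
#' @param min_duration_s strict duration threshold (default 180 s).
#' @param baseline_s baseline length (default 20 s).
#' @return a `protocol_windows` with `model_span`, or a `protocol_skip`
#'   if the piece is too short or lacks pre-roll.
#' @export
windows_mid <- function(piece, min_duration_s = 180, baseline_s = 20) {
  dur <- piece$end - piece$start
  if (!(dur > min_duration_s))
    return(protocol_skip(sprintf(
      "piece '%s' lasts %.1f s; needs > %g s", piece$id %||% "?",
      dur, min_duration_s)))
  if (piece$start < baseline_s)
    return(protocol_skip(sprintf(
      "piece '%s' needs %g s pre-roll", piece$id %||% "?", baseline_s)))
  protocol_windows("mid",
                   c(piece$start - baseline_s, piece$start),
                   c(piece$start + 60, piece$start + 120),
                   model_span = c(piece$start, piece$start + 180))
}

#' Windows for all pieces under one protocol
#'
#' @param pieces a [pieces_from_events()] table.
#' @param protocol one of `"whole_piece"`, `"initial"`, `"mid"`.
#' @param recording_duration_s optional total duration; windows
#'   extending beyond it cause the piece to be skipped.
#' @return named list of `protocol_windows` (qualifying pieces only);
#'   attribute `skipped` is a named character vector of reasons.
#' @export
protocol_windows_for <- function(pieces, protocol = c("whole_piece",
                                                      "initial", "mid"),
                                 recording_duration_s = NULL) {
  protocol <- match.arg(protocol)
  fn <- switch(protocol, whole_piece = windows_whole_piece,
               initial = windows_initial, mid = windows_mid)
  out <- list(); skipped <- character(0)
  for (i in seq_len(nrow(pieces))) {
    p <- pieces[i, ]
    w <- fn(p)
    if (is_skipped(w)) {
      skipped[p$id] <- w$skip_reason
      next
    }
    hi <- max(w$analysis[2], w$model_span[2] %||% -Inf)
    if (!is.null(recording_duration_s) && hi > recording_duration_s) {
      skipped[p$id] <- sprintf("piece '%s' window ends %.1f s, beyond recording (%.1f s)",
                               p$id, hi, recording_duration_s)
      next
    }
    out[[p$id]] <- w
  }
  attr(out, "skipped") <- skipped
  out
}
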