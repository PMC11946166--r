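#' Construct a continuous-wave fNIRS recording
#'
#' @param montage a `nirs_montage`; columns of `intensity` follow
#'   `montage$channels` row order.
#' @param fs sampling frequency, Hz.
#' @param intensity numeric matrix `[n_samples x n_channels]` of raw
#'   detector intensities (arbitrary units, strictly positive).
#' @param events data.frame with columns `label`, `onset` (s), `duration`
#'   (s); may be empty.
#' @param subject_id identifier string.
#' @return object of class `nirs_recording`.
#' @export
nirs_recording <- function(montage, fs, intensity,
                           events = empty_events(), subject_id = "S1") {
  stopifnot(inherits(montage, "nirs_montage"))
  assert_scalar_num(fs, "fs", positive = TRUE)
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != nrow(montage$channels))
    stop_("intensity has %d columns but montage has %d wavelength-channels",
          ncol(intensity), nrow(montage$channels))
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    bad <- which(apply(intensity, 2, function(x) any(!is.finite(x) | x <= 0)))
    stop_("nonpositive or non-finite intensity in channel(s): %s",
          paste(montage$channels$id[bad], collapse = ", "))
  }
  events <- validate_events(events, n_samples = nrow(intensity), fs = fs)
  colnames(intensity) <- montage$channels$id
  structure(
    list(montage = montage, fs = fs, intensity = intensity,
         events = events, subject_id = subject_id),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf(
    "<nirs_recording> subject %s: %d samples x %d channels @ %g Hz (%.1f s), %d events\n",
    x$subject_id, nrow(x$intensity), ncol(x$intensity), x$fs,
    nrow(x$intensity) / x$fs, nrow(x$events)
  ))
  invisible(x)
}

#' Empty event table
#' @return zero-row data.frame with the event columns.
#' @export
empty_events <- function() {
  data.frame(label = character(), onset = numeric(), duration = numeric())
}

validate_events <- function(events, n_samples = NULL, fs = NULL) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L) return(empty_events())
  need <- c("label", "onset", "duration")
  if (!all(need %in% names(events)))
    stop_("events must have columns %s", paste(need, collapse = ", "))
  if (any(events$onset < 0)) stop_("event onset < 0")
  if (any(events$duration < 0)) stop_("event duration < 0")
  if (!is.null(n_samples) && any(events$onset >= n_samples / fs))
    stop_("event onset beyond end of recording")
  events <- events[order(events$onset), need]
  rownames(events) <- NULL
  events
}

#' Read / write a tab-separated event table
#'
#' Plain-text exchange format: columns `label`, `onset`, `duration`
#' (seconds).
#'
#' @param path file path.
#' @return `read_events_tsv`: the event data.frame.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_events(ev)
}

#' @rdname read_events_tsv
#' @param events event data.frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(validate_events(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align two performers' recordings via shared event labels
#'
#' During dual-laptop acquisition the same trigger labels are streamed to
#' both machines; any residual clock offset between the recordings is
#' estimated as the mean onset difference over shared labels (a pure
#' translation, no drift term) and removed from the second recording's
#' events.
#'
#' @param recA,recB `nirs_recording` objects; `recB`'s clock is aligned
#'   to `recA`'s.
#' @param shared_labels labels to use; default: all labels occurring in
#'   both recordings.
#' @param tolerance maximum acceptable post-alignment residual (s) before
#'   a warning is issued; default 0.1 s.
#' @return a `hyperscan_session`: list with `recordings` (A and aligned
#'   B), `clock_offset` (s, B relative to A), and `residuals` per label.
#' @export
synchronize <- function(recA, recB, shared_labels = NULL, tolerance = 0.1) {
  stopifnot(inherits(recA, "nirs_recording"), inherits(recB, "nirs_recording"))
  if (!is.null(attr(recB, "sync_offset")))
    stop_("recording B has already been aligned (offset %.4f s); refusing to apply synchronization twice",
          attr(recB, "sync_offset"))
  labs <- shared_labels %||% intersect(recA$events$label, recB$events$label)
  labs <- labs[labs %in% recA$events$label & labs %in% recB$events$label]
  if (length(labs) == 0L) stop_("no shared event labels; cannot synchronize")
  dA <- vapply(labs, function(l) recA$events$onset[recA$events$label == l][1], 0)
  dB <- vapply(labs, function(l) recB$events$onset[recB$events$label == l][1], 0)
  clock_offset <- mean(dA - dB)          # add to B's clock to reach A's
  shifted <- recB$events
  shifted$onset <- shifted$onset + clock_offset
  if (any(shifted$onset < 0)) {
    warn_("alignment pushed %d event(s) before recording start; clipped to 0",
          sum(shifted$onset < 0))
    shifted$onset <- pmax(shifted$onset, 0)
  }
  recB$events <- shifted[order(shifted$onset), ]
  rownames(recB$events) <- NULL
  attr(recB, "sync_offset") <- clock_offset
  residuals <- (dB + clock_offset) - dA
  names(residuals) <- labs
  if (max(abs(residuals)) > tolerance)
    warn_("post-alignment residual %.3f s exceeds tolerance %.3f s",
          max(abs(residuals)), tolerance)
  structure(
    list(recordings = list(A = recA, B = recB),
         clock_offset = clock_offset, residuals = residuals,
         tolerance = tolerance),
    class = "hyperscan_session"
  )
}

#' @export
print.hyperscan_session <- function(x, ...) {
  cat(sprintf(
    "<hyperscan_session> subjects %s / %s, clock offset %.4f s, max residual %.4f s\n",
    x$recordings$A$subject_id, x$recordings$B$subject_id,
    x$clock_offset, if (length(x$residuals)) max(abs(x$residuals)) else 0
  ))
  invisible(x)
}
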