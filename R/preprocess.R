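## Homer-style continuous-wave processing chain:
## intensity -> delta-OD -> bad-channel screen -> bandpass -> MBLL -> block average.

#' Convert raw intensities to optical-density changes
#'
#' Per channel, `dOD(t) = -ln(I(t) / mean_t I)`; the reference is the
#' channel's temporal mean, so each dOD trace has (log-domain) zero mean
#' by construction and is invariant to rescaling the intensities.
#'
#' @param recording a `nirs_recording` with strictly positive intensity.
#' @return object of class `nirs_od`: list with `data`
#'   (`[n_samples x n_channels]` dimensionless dOD), `fs`, `channels`
#'   (the montage channel table), `montage`, and an optional `bad` mask.
#' @export
intensity_to_od <- function(recording) {
  stopifnot(inherits(recording, "nirs_recording"))
  I <- recording$intensity
  ref <- colMeans(I)
  od <- -log(sweep(I, 2, ref, "/"))
  structure(
    list(data = od, fs = recording$fs, channels = recording$montage$channels,
         montage = recording$montage, bad = character(0)),
    class = "nirs_od"
  )
}

#' @export
print.nirs_od <- function(x, ...) {
  cat(sprintf("<nirs_od> %d samples x %d channels @ %g Hz (%d flagged bad)\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$bad)))
  invisible(x)
}

#' Screen channels for flat or excessively variable raw signal
#'
#' Flags a wavelength-channel when its raw-intensity coefficient of
#' variation exceeds `cv_threshold` (loose coupling, motion-dominated
#' signal, dropouts) or its variance falls below `flat_threshold`
#' (dead channel). Flagged channels are masked downstream, not deleted,
#' so channel bookkeeping keeps its shape.
#'
#' @param recording a `nirs_recording` with at least 10 s of data.
#' @param cv_threshold coefficient-of-variation limit (default 0.15).
#' @param flat_threshold variance floor in squared intensity units
#'   (default 1e-12 relative to the squared channel mean).
#' @return data.frame of class `bad_channel_mask` with per-channel
#'   criterion values (`cv`, `rel_variance`) and a logical `flagged`
#'   column; thresholds are stored as attributes.
#' @export
detect_bad_channels <- function(recording, cv_threshold = 0.15,
                                flat_threshold = 1e-12) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (nrow(recording$intensity) < 10 * recording$fs)
    stop_("need at least 10 s of data to screen channels")
  I <- recording$intensity
  mu <- colMeans(I)
  v <- apply(I, 2, stats::var)
  cv <- sqrt(v) / mu
  relv <- v / mu^2
  out <- data.frame(channel = recording$montage$channels$id,
                    cv = cv, rel_variance = relv,
                    flagged = cv > cv_threshold | relv < flat_threshold,
                    row.names = NULL)
  attr(out, "cv_threshold") <- cv_threshold
  attr(out, "flat_threshold") <- flat_threshold
  class(out) <- c("bad_channel_mask", class(out))
  out
}

#' Zero-phase bandpass filter
#'
#' Cascaded 3rd-order Butterworth high-pass (at `low_hz`) and low-pass
#' (at `high_hz`), each applied forward-backward (`filtfilt`) for zero
#' phase. The defaults (0.01-0.5 Hz) retain the hemodynamic band while
#' rejecting drift and the cardiac pulsation around 1-1.5 Hz by well
#' over 20 dB. `low_hz = 0` degenerates to a pure low-pass.
#'
#' @param x a `nirs_od`, `nirs_conc`, or numeric matrix
#'   (`[n_samples x n_channels]`).
#' @param low_hz,high_hz band edges in Hz; `0 <= low_hz < high_hz < fs/2`.
#' @param fs sampling rate, required only for the matrix method.
#' @return filtered object of the same class.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.5, fs = NULL) {
  UseMethod("bandpass")
}

#' @export
bandpass.matrix <- function(x, low_hz = 0.01, high_hz = 0.5, fs = NULL) {
  if (is.null(fs)) stop_("`fs` is required for the matrix method")
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < fs / 2))
    stop_("invalid band: need 0 <= low_hz < high_hz < fs/2 (got %g, %g at fs %g)",
          low_hz, high_hz, fs)
  lp <- signal::butter(3, high_hz / (fs / 2), type = "low")
  y <- apply(x, 2, function(col) signal::filtfilt(lp, col))
  if (low_hz > 0) {
    hp <- signal::butter(3, low_hz / (fs / 2), type = "high")
    y <- apply(y, 2, function(col) signal::filtfilt(hp, col))
  }
  dimnames(y) <- dimnames(x)
  y
}

#' @export
bandpass.nirs_od <- function(x, low_hz = 0.01, high_hz = 0.5, fs = NULL) {
  x$data <- bandpass(x$data, low_hz, high_hz, fs = x$fs)
  x$band <- c(low_hz, high_hz)
  x
}

#' @export
bandpass.nirs_conc <- function(x, low_hz = 0.01, high_hz = 0.5, fs = NULL) {
  for (f in c("hbo", "hbr", "hbt"))
    x[[f]] <- bandpass(x[[f]], low_hz, high_hz, fs = x$fs)
  x$band <- c(low_hz, high_hz)
  x
}

#' Load the hemoglobin extinction-coefficient table
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin, units
#' 1/(Molar mm), sampled on a nanometre grid spanning the NIR window.
#' The shipped table holds nominal values interpolated from the commonly
#' used compiled hemoglobin absorption spectrum; supply your own CSV
#' (columns `wavelength_nm`, `eps_hbo`, `eps_hbr`) for calibrated work.
#'
#' @param path CSV path; default: table shipped with the package.
#' @return data.frame with columns `wavelength_nm`, `eps_hbo`, `eps_hbr`.
#' @export
extinction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "extinction_hb.csv",
                                package = "opusnirs", mustWork = TRUE)
  utils::read.csv(path)
}

#' Interpolate extinction coefficients at given wavelengths
#'
#' @param wavelengths wavelengths in nm (within the table's range).
#' @param table extinction table; see [extinction_table()].
#' @return matrix `[n_wavelengths x 2]`, columns `hbo`, `hbr`,
#'   units 1/(Molar mm).
#' @export
extinction_at <- function(wavelengths, table = extinction_table()) {
  rng <- range(table$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop_("wavelength outside extinction table range [%g, %g] nm",
          rng[1], rng[2])
  E <- cbind(
    hbo = stats::approx(table$wavelength_nm, table$eps_hbo, wavelengths)$y,
    hbr = stats::approx(table$wavelength_nm, table$eps_hbr, wavelengths)$y
  )
  rownames(E) <- as.character(wavelengths)
  E
}

#' Modified Beer-Lambert parameters for a montage
#'
#' Bundles the 2x2 extinction matrix at the montage's wavelengths, the
#' differential pathlength factors, and per-pair source-detector
#' distances. With `pathlength_scaling = FALSE` (the default) the
#' spectral inversion omits the `distance * DPF` factor, so recovered
#' concentration changes carry Molar-mm units (concentration times
#' effective path length) — the convention used for the channel-level
#' summaries in this package. Enable scaling for Molar units.
#'
#' @param montage a `nirs_montage`.
#' @param dpf differential pathlength factor(s); scalar or one per
#'   wavelength (default 6.0, a conventional adult-head value).
#' @param extinction extinction table (see [extinction_table()]).
#' @param pathlength_scaling divide by `distance * DPF` (default FALSE).
#' @return object of class `mbll_params`; the extinction matrix condition
#'   number is stored as attribute `kappa`.
#' @export
mbll_params <- function(montage, dpf = 6.0, extinction = extinction_table(),
                        pathlength_scaling = FALSE) {
  wl <- montage_wavelengths(montage)
  if (length(wl) != 2L) stop_("MBLL inversion needs exactly 2 wavelengths")
  E <- extinction_at(wl, extinction)
  kap <- kappa(E, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8) stop_("extinction matrix is singular")
  if (any(dpf <= 0)) stop_("dpf must be > 0")
  dpf <- rep_len(dpf, 2L); names(dpf) <- as.character(wl)
  pairs <- montage_pairs(montage)
  p <- structure(
    list(E = E, dpf = dpf, wavelengths = wl,
         distance_mm = stats::setNames(pairs$distance_mm, pairs$pair),
         pathlength_scaling = pathlength_scaling),
    class = "mbll_params"
  )
  attr(p, "kappa") <- kap
  p
}

#' Invert optical-density changes to hemoglobin concentration changes
#'
#' Per source-detector pair, solves the modified Beer-Lambert system
#' `dOD(lambda) = [eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR] * L(lambda)`
#' for the two chromophores, where `L` is `distance * DPF` if pathlength
#' scaling is enabled and 1 otherwise (Molar-mm convention). Total
#' hemoglobin is the sum `HbT = HbO + HbR`.
#'
#' @param od a `nirs_od` (both wavelengths present for every pair).
#' @param params an `mbll_params` for the same montage.
#' @return object of class `nirs_conc`: matrices `hbo`, `hbr`, `hbt`
#'   (`[n_samples x n_pairs]`), `fs`, `pairs` table, `units`.
#' @export
od_to_conc <- function(od, params) {
  stopifnot(inherits(od, "nirs_od"), inherits(params, "mbll_params"))
  ch <- od$channels
  wl <- params$wavelengths
  pairs <- unique(ch$pair)
  if (params$pathlength_scaling && any(params$distance_mm[pairs] <= 0))
    stop_("zero source-detector distance; cannot apply pathlength scaling")
  n <- nrow(od$data)
  hbo <- hbr <- matrix(NA_real_, n, length(pairs),
                       dimnames = list(NULL, pairs))
  for (p in pairs) {
    i1 <- which(ch$pair == p & ch$wavelength == wl[1])
    i2 <- which(ch$pair == p & ch$wavelength == wl[2])
    if (length(i1) != 1L || length(i2) != 1L)
      stop_("pair %s does not have both wavelengths", p)
    if (length(od$bad) && any(ch$id[c(i1, i2)] %in% od$bad)) next  # masked
    L <- if (params$pathlength_scaling)
      params$distance_mm[p] * params$dpf else c(1, 1)
    Es <- params$E * L           # rows scaled per wavelength
    Minv <- solve(Es)
    y1 <- od$data[, i1]; y2 <- od$data[, i2]
    hbo[, p] <- Minv[1, 1] * y1 + Minv[1, 2] * y2
    hbr[, p] <- Minv[2, 1] * y1 + Minv[2, 2] * y2
  }
  pt <- montage_pairs(od$montage)
  structure(
    list(hbo = hbo, hbr = hbr, hbt = hbo + hbr, fs = od$fs,
         pairs = pt[match(pairs, pt$pair), ],
         units = if (params$pathlength_scaling) "Molar" else "Molar mm"),
    class = "nirs_conc"
  )
}

#' @export
print.nirs_conc <- function(x, ...) {
  cat(sprintf("<nirs_conc> %d samples x %d pairs @ %g Hz [%s]\n",
              nrow(x$hbt), ncol(x$hbt), x$fs, x$units))
  invisible(x)
}

#' Block-average concentration epochs
#'
#' Extracts equal-length epochs `[start_s, end_s)` from a concentration
#' series, optionally subtracts each epoch's baseline-window mean, and
#' returns the pointwise mean across epochs with the across-epoch
#' standard deviation.
#'
#' @param conc a `nirs_conc`.
#' @param epochs list of `c(start_s, end_s)` half-open windows, equal
#'   lengths in samples.
#' @param baseline optional `c(rel_start_s, rel_end_s)` window relative
#'   to each epoch start (e.g. `c(-5, 0)`) whose mean is removed per
#'   epoch and pair.
#' @return object of class `nirs_block_average`: per chromophore a
#'   `mean` and `sd` matrix (`[epoch_samples x n_pairs]`), plus `n`
#'   (number of epochs), `time` (seconds relative to epoch start) and
#'   `fs`.
#' @export
block_average <- function(conc, epochs, baseline = NULL) {
  stopifnot(inherits(conc, "nirs_conc"))
  if (length(epochs) < 1L) stop_("need at least one epoch")
  n <- nrow(conc$hbt); fs <- conc$fs
  idx <- lapply(seq_along(epochs), function(k) {
    e <- epochs[[k]]
    i <- sample_window(e[1], e[2], fs)
    if (length(i) == 0L || min(i) < 1L || max(i) > n)
      stop_("epoch %d [%g, %g) is outside the recording", k, e[1], e[2])
    i
  })
  lens <- lengths(idx)
  if (length(unique(lens)) != 1L)
    stop_("epochs differ in length (samples: %s)",
          paste(unique(lens), collapse = ", "))
  bidx <- NULL
  if (!is.null(baseline)) {
    bidx <- lapply(seq_along(epochs), function(k) {
      e <- epochs[[k]]
      i <- sample_window(e[1] + baseline[1], e[1] + baseline[2], fs)
      if (length(i) == 0L || min(i) < 1L || max(i) > n)
        stop_("baseline of epoch %d is outside the recording", k)
      i
    })
  }
  out <- list(n = length(epochs), fs = fs,
              time = (seq_len(lens[1]) - 1L) / fs)
  for (f in c("hbo", "hbr", "hbt")) {
    X <- conc[[f]]
    stack <- vapply(seq_along(idx), function(k) {
      seg <- X[idx[[k]], , drop = FALSE]
      if (!is.null(bidx))
        seg <- sweep(seg, 2, colMeans(X[bidx[[k]], , drop = FALSE]), "-")
      seg
    }, matrix(0, lens[1], ncol(X)))
    out[[f]] <- list(
      mean = apply(stack, c(1, 2), mean),
      sd = if (length(idx) > 1L) apply(stack, c(1, 2), stats::sd)
           else matrix(NA_real_, lens[1], ncol(X))
    )
    dimnames(out[[f]]$mean) <- list(NULL, colnames(X))
    dimnames(out[[f]]$sd) <- list(NULL, colnames(X))
  }
  out$pairs <- conc$pairs
  class(out) <- "nirs_block_average"
  out
}
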