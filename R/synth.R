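## Synthetic two-performer concert sessions with known ground truth:
## piece-structured cortical activations (boxcar convolved with a
## canonical HRF) forward-projected into channel optical density,
## shared superficial physiology (undiluted on the short channels),
## drift, white noise, motion artifacts, and intensity synthesis by
## inverting the delta-OD transform around per-channel baselines.

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style double-gamma response normalized to unit peak: peak near
#' 5 s (within the physiological 4-6 s window after neuronal
#' activation), an undershoot around 16 s, `hrf(0) = 0`, and a positive
#' net integral over 30 s.
#'
#' @param t time(s) in seconds, `t >= 0`.
#' @param peak_shape,peak_scale gamma shape/scale of the main response
#'   (defaults 6 and 1: peak at 5 s).
#' @param under_shape,under_scale gamma shape/scale of the undershoot
#'   (defaults 16 and 1).
#' @param under_ratio undershoot amplitude ratio (default 1/6).
#' @return response values, unit peak amplitude.
#' @export
canonical_hrf <- function(t, peak_shape = 6, peak_scale = 1,
                          under_shape = 16, under_scale = 1,
                          under_ratio = 1 / 6) {
  if (any(t < 0)) stop_("t must be >= 0")
  h <- stats::dgamma(t, peak_shape, scale = peak_scale) -
    under_ratio * stats::dgamma(t, under_shape, scale = under_scale)
  peak <- stats::dgamma((peak_shape - 1) * peak_scale, peak_shape,
                        scale = peak_scale) -
    under_ratio * stats::dgamma((peak_shape - 1) * peak_scale, under_shape,
                                scale = under_scale)
  h / peak
}

#' Concert script: the piece programme of one concert
#'
#' @param pieces data.frame with columns `id`, `start` (s), `duration`
#'   (s); durations > 0, non-negative gaps allowed.
#' @param concert_index integer 1..7.
#' @param duration_s total recording length (default: 15 s past the
#'   last piece).
#' @return object of class `concert_script`.
#' @export
concert_script <- function(pieces, concert_index = 1L, duration_s = NULL) {
  stopifnot(all(pieces$duration > 0), all(diff(pieces$start) >= 0))
  duration_s <- duration_s %||% (max(pieces$start + pieces$duration) + 15)
  structure(list(pieces = pieces, concert_index = as.integer(concert_index),
                 duration_s = duration_s),
            class = "concert_script")
}

#' Default concert programme
#'
#' A nine-piece programme echoing an orchestral family-concert
#' repertoire, with exactly five pieces longer than three minutes
#' (the mid-piece protocol's selection), 30 s lead-in and 15 s gaps.
#'
#' @param concert_index integer 1..7.
#' @return a `concert_script`.
#' @export
default_concert_script <- function(concert_index = 1L) {
  ids <- c("traviata", "hedwig", "kjempevise", "schubert8", "firebird",
           "adagio", "william_tell", "grieg", "jegermarsj")
  dur <- c(200, 90, 240, 60, 210, 190, 75, 195, 45)
  start <- 30 + cumsum(c(0, dur[-length(dur)] + 15))
  concert_script(data.frame(id = ids, start = start, duration = dur),
                 concert_index)
}

#' Ground-truth parameters of the synthetic generator
#'
#' Defines the statistical structure the analysis chain assumes:
#' scout HRF amplitudes (Molar mm; micromolar-millimetre order of
#' magnitude, the conventional channel-level scale), shared superficial
#' physiology (Mayer waves ~0.1 Hz, respiration ~0.25 Hz, cardiac
#' ~1.2 Hz), slow drift, white measurement noise, a motion-artifact
#' rate, a per-concert amplitude trend (the rIFG amplitude decreases
#' linearly toward zero across seven concerts), and a per-performer
#' hair-attenuation factor (the "first" performer's optical coupling is
#' poorer: weaker cortical signal, more noise, so the short channels
#' dominate that recording).
#'
#' @param scout_amp_hbo named HbO amplitudes per scout (Molar mm).
#' @param hbr_ratio HbR amplitude as a (negative) fraction of HbO.
#' @param superficial list of `freq_hz` and `amp` vectors plus
#'   `coupling` (long-channel coupling coefficient, default 1.0).
#' @param drift_amp slow drift amplitude (delta-OD).
#' @param noise_sd white noise sd (delta-OD per sample).
#' @param motion_rate_hz expected motion artifacts per second.
#' @param concert_trend named list of per-concert amplitude multiplier
#'   functions (index -> factor); default: rIFG declining 1 -> 0.1.
#' @param hair_attenuation named per-performer factors in (0, 1].
#' @param label_jitter_sd sd (s) of Gaussian event-labeling jitter,
#'   default 0 (off).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(
    scout_amp_hbo = c(PRG = 1.0e-6, POG = 0.8e-6, STG = 0.6e-6,
                      rIFG = 1.0e-6),
    hbr_ratio = -0.35,
    superficial = list(freq_hz = c(mayer = 0.1, resp = 0.25, cardiac = 1.2),
                       amp = c(mayer = 5e-7, resp = 3e-7, cardiac = 2e-7),
                       coupling = 1.0),
    drift_amp = 2e-5,
    noise_sd = 2e-5,
    motion_rate_hz = 1 / 300,
    concert_trend = list(rIFG = function(i) 1 - 0.15 * (i - 1)),
    hair_attenuation = c(first = 0.35, second = 1.0),
    label_jitter_sd = 0) {
  structure(list(scout_amp_hbo = scout_amp_hbo, hbr_ratio = hbr_ratio,
                 superficial = superficial, drift_amp = drift_amp,
                 noise_sd = noise_sd, motion_rate_hz = motion_rate_hz,
                 concert_trend = concert_trend,
                 hair_attenuation = hair_attenuation,
                 label_jitter_sd = label_jitter_sd),
            class = "ground_truth")
}

## Summed sensitivity of each long channel to each scout, per wavelength:
## the forward weights for scout-level (spatially uniform) activations.
scout_forward_weights <- function(sens, scouts) {
  lapply(sens$A, function(M)
    vapply(scouts, function(s) rowSums(M[, s$vertex_ids, drop = FALSE]),
           numeric(nrow(M))))
}

#' Generate one synthetic concert session (two performers)
#'
#' Cortical scout activations are piece boxcars convolved with the
#' canonical HRF, scaled by the scout amplitudes, any per-concert trend
#' multipliers, and the performer's hair-attenuation factor; they are
#' forward-projected through the sensitivity matrix into long-channel
#' optical density. Shared superficial physiology is added to long
#' channels (scaled by the coupling coefficient) and, undiluted, to the
#' short channels. Drift, white noise and motion spikes/steps complete
#' the delta-OD, which is converted to strictly positive intensities
#' around per-channel baselines. Events carry piece boundaries as
#' `"<id>/start"` / `"<id>/end"` labels, with optional Gaussian jitter.
#' Deterministic given `seed`.
#'
#' @param script a [concert_script()].
#' @param montage a `nirs_montage`.
#' @param sens a [build_sensitivity()] for the montage/mesh.
#' @param scouts named list of `nirs_scout`s matching
#'   `truth$scout_amp_hbo` names.
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @param fs sampling rate (default 75 Hz).
#' @param performers performer role names (default first/second).
#' @return list of class `concert_session`: `recordings` (named list of
#'   `nirs_recording`), `script`, `truth`, and a `truth_report` with
#'   the realized scout amplitudes per performer.
#' @export
generate_session <- function(script, montage, sens, scouts,
                             truth = ground_truth(), seed = 1,
                             fs = 75, performers = c("first", "second")) {
  stopifnot(inherits(script, "concert_script"))
  missing_sc <- setdiff(names(truth$scout_amp_hbo), names(scouts))
  if (length(missing_sc))
    stop_("scout(s) %s not in mesh scout list",
          paste(missing_sc, collapse = ", "))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- round(script$duration_s * fs)
  tvec <- (seq_len(n) - 1L) / fs
  ch <- montage$channels
  nch <- nrow(ch)
  wl <- montage_wavelengths(montage)
  E <- extinction_at(wl)
  W <- scout_forward_weights(sens, scouts[names(truth$scout_amp_hbo)])

  ## piece boxcar convolved with HRF (shared across scouts up to scale)
  box <- numeric(n)
  for (i in seq_len(nrow(script$pieces))) {
    idx <- sample_window(script$pieces$start[i],
                         script$pieces$start[i] + script$pieces$duration[i],
                         fs)
    box[idx[idx <= n]] <- 1
  }
  hrf_k <- canonical_hrf(seq(0, 30, by = 1 / fs))
  act <- stats::convolve(box, rev(hrf_k), type = "open")[seq_len(n)] / fs

  recordings <- list(); report <- list()
  for (perf in performers) {
    hair <- truth$hair_attenuation[[perf]] %||% 1.0
    ## realized per-scout amplitudes this concert
    amps <- truth$scout_amp_hbo
    for (s in names(truth$concert_trend))
      if (s %in% names(amps))
        amps[s] <- amps[s] * truth$concert_trend[[s]](script$concert_index)
    dod <- matrix(0, n, nch, dimnames = list(NULL, ch$id))

    ## cortical contribution on long channels (attenuated by hair factor)
    for (w in as.character(wl)) {
      wmat <- W[[w]]                       # [n_long_pairs x n_scouts]
      spec <- E[w, "hbo"] + E[w, "hbr"] * truth$hbr_ratio
      chan_amp <- as.vector(wmat %*% amps) * spec * hair
      longp <- rownames(sens$A[[w]])
      cols <- match(paste0(longp, "@", w), ch$id)
      dod[, cols] <- dod[, cols] + outer(act, chan_amp)
    }

    ## shared superficial physiology (HbO-like spectrum)
    sup <- numeric(n)
    fr <- truth$superficial$freq_hz; am <- truth$superficial$amp
    for (k in seq_along(fr))
      sup <- sup + am[k] * sin(2 * pi * fr[k] * tvec + stats::runif(1, 0, 2 * pi))
    for (w in as.character(wl)) {
      sup_od <- E[w, "hbo"] * sup
      iw <- which(ch$wavelength == as.numeric(w))
      k <- ifelse(ch$is_short[iw], 1.0, truth$superficial$coupling)
      dod[, iw] <- dod[, iw] + outer(sup_od, k)
    }

    ## drift + noise (noise inflated as coupling degrades)
    drift <- truth$drift_amp * outer(tvec / max(tvec), stats::rnorm(nch))
    noise <- matrix(stats::rnorm(n * nch, sd = truth$noise_sd / sqrt(hair)),
                    n, nch)
    dod <- dod + drift + noise

    ## motion artifacts: half spikes, half steps, random channels
    n_art <- stats::rpois(1, truth$motion_rate_hz * script$duration_s)
    if (n_art > 0) for (a in seq_len(n_art)) {
      chn <- sample.int(nch, 1)
      at <- stats::runif(1, 5, script$duration_s - 5)
      if (stats::runif(1) < 0.5) {
        amp <- stats::runif(1, 2e-4, 1e-3) * sample(c(-1, 1), 1)
        dod[, chn] <- dod[, chn] +
          amp * exp(-((tvec - at)^2) / (2 * 0.15^2))
      } else {
        dod[tvec >= at, chn] <- dod[tvec >= at, chn] +
          stats::runif(1, -1e-4, 1e-4)
      }
    }

    ## intensity synthesis around per-channel baselines
    I0 <- 1e6 * hair
    intensity <- I0 * exp(-dod)

    ## events with optional labeling jitter
    jit <- function(k) if (truth$label_jitter_sd > 0)
      stats::rnorm(k, 0, truth$label_jitter_sd) else numeric(k)
    np <- nrow(script$pieces)
    ev <- data.frame(
      label = c(paste0(script$pieces$id, "/start"),
                paste0(script$pieces$id, "/end")),
      onset = pmax(0, c(script$pieces$start + jit(np),
                        script$pieces$start + script$pieces$duration +
                          jit(np))),
      duration = 0
    )
    recordings[[perf]] <- nirs_recording(montage, fs, intensity, ev,
                                         subject_id = perf)
    report[[perf]] <- list(hair_attenuation = hair,
                           scout_amp_hbo = amps,
                           scout_amp_hbr = amps * truth$hbr_ratio)
  }
  structure(list(recordings = recordings, script = script, truth = truth,
                 truth_report = report, seed = seed, fs = fs),
            class = "concert_session")
}

#' Default seven-concert fixture with the study's data losses
#'
#' Generates the default two-performer concert series: seven concerts
#' of the default programme (five pieces per concert longer than three
#' minutes) at 75 Hz with wavelengths 762/842 nm, an rIFG amplitude
#' declining across concerts, and the recording losses of the concert
#' study reproduced: the first performer's concert 4 and the second
#' performer's concerts 4 and 6 are absent.
#'
#' @param seed integer seed; per-concert seeds are derived from it.
#' @param concerts which concert indices to generate (default 1:7).
#' @param montage,mesh,scouts,sens optionally precomputed geometry
#'   (computed once from the defaults when omitted).
#' @param truth a [ground_truth()].
#' @return object of class `concert_fixture`: `sessions` (list indexed
#'   by concert, each a `concert_session` whose `recordings` omit lost
#'   performers), `missing` (named list of lost concert indices),
#'   `montage`, `mesh`, `scouts`, `sens`.
#' @export
default_fixture <- function(seed = 42, concerts = 1:7,
                            montage = default_brite_montage(),
                            mesh = default_cortex_mesh(montage),
                            scouts = default_scouts(mesh, montage),
                            sens = build_sensitivity(montage, mesh),
                            truth = ground_truth()) {
  missing <- list(first = 4L, second = c(4L, 6L))
  sessions <- list()
  for (ci in concerts) {
    perf <- c("first", "second")
    perf <- perf[!vapply(perf, function(p) ci %in% missing[[p]], TRUE)]
    script <- default_concert_script(ci)
    if (length(perf) == 0L) { sessions[[as.character(ci)]] <- NULL; next }
    sessions[[as.character(ci)]] <-
      generate_session(script, montage, sens, scouts, truth,
                       seed = (seed * 100 + ci) %% .Machine$integer.max,
                       performers = perf)
  }
  structure(list(sessions = sessions, missing = missing, montage = montage,
                 mesh = mesh, scouts = scouts, sens = sens, truth = truth,
                 concerts = concerts, seed = seed),
            class = "concert_fixture")
}

#' Concerts with a usable recording for one performer
#'
#' @param fixture a [default_fixture()] result.
#' @param performer `"first"` or `"second"`.
#' @return integer vector of concert indices.
#' @export
performer_concerts <- function(fixture, performer) {
  idx <- vapply(fixture$sessions, function(s)
    performer %in% names(s$recordings), TRUE)
  sort(as.integer(names(fixture$sessions)[idx]))
}
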