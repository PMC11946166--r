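## SNIRF (Shared Near Infrared Spectroscopy Format) read/write.
## One continuous-wave data block, measurementList-per-channel layout.

#' Write a recording to a SNIRF file
#'
#' Writes a SNIRF v1.1 file with one continuous-wave data block:
#' `/nirs/data1/dataTimeSeries`, an explicit time vector, one
#' `measurementList<i>` group per wavelength-channel, the probe geometry
#' (`sourcePos3D`, `detectorPos3D`, `wavelengths`, labels) and one stim
#' group per unique event label. Channel group names are preserved in a
#' custom metaDataTag.
#'
#' @param recording a `nirs_recording`.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_snirf <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.1", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")

  ## metadata
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  meta <- list(
    SubjectID = recording$subject_id,
    MeasurementDate = "unknown", MeasurementTime = "unknown",
    LengthUnit = "mm", TimeUnit = "s", FrequencyUnit = "Hz",
    channelGroups = jsonlite::toJSON(recording$montage$groups)
  )
  for (k in names(meta))
    rhdf5::h5write(as.character(meta[[k]]), path,
                   paste0("nirs/metaDataTags/", k))

  ## probe
  m <- recording$montage
  o <- m$optodes
  src <- o[o$kind == "source", ]; det <- o[o$kind == "detector", ]
  wl <- montage_wavelengths(m)
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(wl, path, "nirs/probe/wavelengths")
  rhdf5::h5write(as.matrix(src[, c("x", "y", "z")]), path,
                 "nirs/probe/sourcePos3D")
  rhdf5::h5write(as.matrix(det[, c("x", "y", "z")]), path,
                 "nirs/probe/detectorPos3D")
  rhdf5::h5write(src$id, path, "nirs/probe/sourceLabels")
  rhdf5::h5write(det$id, path, "nirs/probe/detectorLabels")

  ## data block (chunked so large series read back in slices efficiently)
  rhdf5::h5createGroup(path, "nirs/data1")
  n <- nrow(recording$intensity)
  rhdf5::h5createDataset(path, "nirs/data1/dataTimeSeries",
                         dims = dim(recording$intensity),
                         storage.mode = "double",
                         chunk = c(min(n, 8192L), ncol(recording$intensity)),
                         level = 4)
  rhdf5::h5write(recording$intensity, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write(seq(0, by = 1 / recording$fs, length.out = n), path,
                 "nirs/data1/time")
  ch <- m$channels
  for (i in seq_len(nrow(ch))) {
    g <- sprintf("nirs/data1/measurementList%d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(match(ch$source[i], src$id), path,
                   paste0(g, "/sourceIndex"))
    rhdf5::h5write(match(ch$detector[i], det$id), path,
                   paste0(g, "/detectorIndex"))
    rhdf5::h5write(match(ch$wavelength[i], wl), path,
                   paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(1L, path, paste0(g, "/dataType"))     # CW amplitude
    rhdf5::h5write(1L, path, paste0(g, "/dataTypeIndex"))
  }

  ## stim: one group per unique label
  ev <- recording$events
  if (nrow(ev)) {
    labs <- unique(ev$label)
    for (j in seq_along(labs)) {
      g <- sprintf("nirs/stim%d", j)
      rhdf5::h5createGroup(path, g)
      rhdf5::h5write(labs[j], path, paste0(g, "/name"))
      sub <- ev[ev$label == labs[j], ]
      rhdf5::h5write(cbind(sub$onset, sub$duration, rep(1, nrow(sub))),
                     path, paste0(g, "/data"))
    }
  }
  invisible(path)
}

#' Read a recording from a SNIRF file
#'
#' Expects a SNIRF v1.x file with one continuous-wave data block. The
#' sampling rate is inferred from the time vector (which must be uniform
#' within `time_tol`); events come from the stim groups; short-separation
#' channels are identified by source-detector distance below
#' `short_threshold_mm`.
#'
#' @param path SNIRF file path.
#' @param short_threshold_mm pairs closer than this are flagged short
#'   (default 15 mm).
#' @param time_tol maximum relative deviation of time steps from uniform
#'   (default 1e-6).
#' @return a `nirs_recording`.
#' @export
read_snirf <- function(path, short_threshold_mm = 15, time_tol = 1e-6) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  if (!any(ls$group == "/nirs" & ls$name == "probe"))
    stop_("SNIRF format error: missing /nirs/probe group")
  rd <- function(name) rhdf5::h5read(path, name)

  tvec <- as.numeric(rd("nirs/data1/time"))
  if (length(tvec) == 2L) {           # [start, dt] short form
    dt <- tvec[2]
  } else {
    dts <- diff(tvec)
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > time_tol * max(dt, 1)))
      stop_("SNIRF format error: non-uniform time vector (max dev %.3g s)",
            max(abs(dts - dt)))
  }
  fs <- 1 / dt

  wl <- as.numeric(rd("nirs/probe/wavelengths"))
  spos <- rd("nirs/probe/sourcePos3D"); dpos <- rd("nirs/probe/detectorPos3D")
  slab <- as.character(rd("nirs/probe/sourceLabels"))
  dlab <- as.character(rd("nirs/probe/detectorLabels"))
  optodes <- data.frame(
    id = c(slab, dlab),
    kind = rep(c("source", "detector"), c(length(slab), length(dlab))),
    x = c(spos[, 1], dpos[, 1]),
    y = c(spos[, 2], dpos[, 2]),
    z = c(spos[, 3], dpos[, 3])
  )

  dsets <- ls[ls$group == "/nirs/data1", "name"]
  mls <- sort(as.integer(sub("measurementList", "",
                             grep("^measurementList", dsets, value = TRUE))))
  ch <- do.call(rbind, lapply(mls, function(i) {
    g <- sprintf("nirs/data1/measurementList%d", i)
    data.frame(source = slab[as.integer(rd(paste0(g, "/sourceIndex")))],
               detector = dlab[as.integer(rd(paste0(g, "/detectorIndex")))],
               wavelength = wl[as.integer(rd(paste0(g, "/wavelengthIndex")))])
  }))
  ## short flag by geometric distance
  pos <- as.matrix(optodes[, c("x", "y", "z")]); rownames(pos) <- optodes$id
  dist <- sqrt(rowSums((pos[ch$source, , drop = FALSE] -
                        pos[ch$detector, , drop = FALSE])^2))
  ch$is_short <- dist < short_threshold_mm

  groups <- list()
  if (any(ls$group == "/nirs/metaDataTags" & ls$name == "channelGroups")) {
    gj <- as.character(rd("nirs/metaDataTags/channelGroups"))
    groups <- lapply(jsonlite::fromJSON(gj), as.character)
  }
  if (length(groups)) {
    pair <- paste0(ch$source, "-", ch$detector)
    ch$group <- NA_character_
    for (g in names(groups)) ch$group[pair %in% groups[[g]]] <- g
  }
  montage <- nirs_montage(optodes, ch, groups)

  intensity <- as.matrix(rd("nirs/data1/dataTimeSeries"))
  if (any(intensity <= 0))
    stop_("SNIRF validation error: nonpositive intensity values")

  stims <- grep("^stim[0-9]+$", ls[ls$group == "/nirs", "name"], value = TRUE)
  events <- empty_events()
  for (s in stims) {
    nm <- as.character(rd(paste0("nirs/", s, "/name")))
    d <- rd(paste0("nirs/", s, "/data"))
    d <- matrix(as.numeric(d), ncol = 3)
    events <- rbind(events,
                    data.frame(label = nm, onset = d[, 1], duration = d[, 2]))
  }

  subj <- "S1"
  if (any(ls$group == "/nirs/metaDataTags" & ls$name == "SubjectID"))
    subj <- as.character(rd("nirs/metaDataTags/SubjectID"))

  nirs_recording(montage, fs, intensity, events, subject_id = subj)
}

#' Read / write a montage as a YAML description
#'
#' Plain-text exchange format for custom layouts: `optodes` (id, kind,
#' position) and `channels` (source, detector, wavelength, is_short,
#' group) sections.
#'
#' @param path YAML file path.
#' @return `read_montage_yaml`: a `nirs_montage`.
#' @export
read_montage_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  optodes <- do.call(rbind, lapply(y$optodes, function(o)
    data.frame(id = o$id, kind = o$kind,
               x = o$position[[1]], y = o$position[[2]], z = o$position[[3]])))
  channels <- do.call(rbind, lapply(y$channels, function(ch)
    data.frame(source = ch$source, detector = ch$detector,
               wavelength = ch$wavelength, is_short = isTRUE(ch$is_short),
               group = ch$group %||% NA_character_)))
  nirs_montage(optodes, channels, y$groups %||% list())
}

#' @rdname read_montage_yaml
#' @param montage a `nirs_montage`.
#' @export
write_montage_yaml <- function(montage, path) {
  o <- montage$optodes; ch <- montage$channels
  y <- list(
    optodes = lapply(seq_len(nrow(o)), function(i)
      list(id = o$id[i], kind = o$kind[i],
           position = c(o$x[i], o$y[i], o$z[i]))),
    channels = lapply(seq_len(nrow(ch)), function(i)
      list(source = ch$source[i], detector = ch$detector[i],
           wavelength = ch$wavelength[i], is_short = ch$is_short[i],
           group = ch$group[i])),
    groups = montage$groups
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
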