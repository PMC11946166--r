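#' Construct an fNIRS montage
#'
#' A montage bundles optode positions with the channel table that wires
#' sources to detectors at each wavelength. Coordinates are in a
#' right-handed RAS head frame (x right, y anterior, z superior),
#' millimetres, origin at mid-head.
#'
#' @param optodes data.frame with columns `id`, `kind` ("source" or
#'   "detector"), `x`, `y`, `z` (mm).
#' @param channels data.frame with columns `source`, `detector`,
#'   `wavelength` (nm) and `is_short` (logical); optionally `group`.
#' @param groups optional named list mapping group names to pair ids
#'   (`"<source>-<detector>"`).
#' @return An object of class `nirs_montage`.
#' @seealso [default_brite_montage()], [channel_distances()]
#' @export
nirs_montage <- function(optodes, channels, groups = list()) {
  optodes <- as.data.frame(optodes)
  channels <- as.data.frame(channels)
  need_o <- c("id", "kind", "x", "y", "z")
  if (!all(need_o %in% names(optodes)))
    stop_("optodes must have columns %s", paste(need_o, collapse = ", "))
  need_c <- c("source", "detector", "wavelength", "is_short")
  if (!all(need_c %in% names(channels)))
    stop_("channels must have columns %s", paste(need_c, collapse = ", "))
  if (is.null(channels$group)) channels$group <- NA_character_
  channels$pair <- paste0(channels$source, "-", channels$detector)
  channels$id <- paste0(channels$pair, "@", channels$wavelength)
  m <- structure(
    list(optodes = optodes, channels = channels, groups = groups),
    class = "nirs_montage"
  )
  validate_montage(m)
  m
}

#' Validate montage invariants
#'
#' Checks id uniqueness, finite positions, source/detector resolution,
#' one channel per pair and wavelength, and a common wavelength set
#' across pairs.
#'
#' @param m a `nirs_montage`.
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_montage <- function(m) {
  o <- m$optodes; ch <- m$channels
  if (anyDuplicated(o$id))
    stop_("duplicate optode id: %s", o$id[duplicated(o$id)][1])
  if (!all(is.finite(as.matrix(o[, c("x", "y", "z")]))))
    stop_("non-finite optode position")
  if (!all(o$kind %in% c("source", "detector")))
    stop_("optode kind must be 'source' or 'detector'")
  src <- o$id[o$kind == "source"]; det <- o$id[o$kind == "detector"]
  bad <- setdiff(ch$source, src)
  if (length(bad)) stop_("channel source '%s' is not a source optode", bad[1])
  bad <- setdiff(ch$detector, det)
  if (length(bad)) stop_("channel detector '%s' is not a detector optode", bad[1])
  if (anyDuplicated(ch[, c("source", "detector", "wavelength")]))
    stop_("a source-detector pair appears twice at the same wavelength")
  wl_by_pair <- split(ch$wavelength, ch$pair)
  wl_sets <- unique(lapply(wl_by_pair, function(w) sort(unique(w))))
  if (length(wl_sets) != 1L)
    stop_("wavelength set differs between pairs")
  is_short <- tapply(ch$is_short, ch$pair, unique)
  if (any(lengths(is_short) != 1L))
    stop_("is_short flag differs between wavelengths of one pair")
  invisible(m)
}

#' @export
print.nirs_montage <- function(x, ...) {
  np <- length(unique(x$channels$pair))
  ns <- length(unique(x$channels$pair[x$channels$is_short]))
  wl <- sort(unique(x$channels$wavelength))
  cat(sprintf(
    "<nirs_montage> %d optodes, %d pairs (%d short), wavelengths %s nm, %d wavelength-channels\n",
    nrow(x$optodes), np, ns, paste(wl, collapse = "/"), nrow(x$channels)
  ))
  invisible(x)
}

#' Montage wavelengths
#' @param m a `nirs_montage`.
#' @return sorted unique wavelengths (nm).
#' @export
montage_wavelengths <- function(m) sort(unique(m$channels$wavelength))

#' Unique source-detector pair table of a montage
#'
#' One row per pair (collapsing wavelengths), with the geometric
#' source-detector distance in mm.
#'
#' @param m a `nirs_montage`.
#' @return data.frame with columns `pair`, `source`, `detector`,
#'   `is_short`, `group`, `distance_mm`.
#' @export
montage_pairs <- function(m) {
  ch <- m$channels
  keep <- !duplicated(ch$pair)
  p <- ch[keep, c("pair", "source", "detector", "is_short", "group")]
  d <- channel_distances(m)
  p$distance_mm <- d[match(paste0(p$pair, "@", ch$wavelength[keep]), names(d))]
  rownames(p) <- NULL
  p
}

#' Source-detector distances per wavelength-channel
#'
#' Euclidean distance between each channel's source and detector optode.
#' Both wavelengths of a pair share the same distance.
#'
#' @param m a `nirs_montage`.
#' @return named numeric vector (mm), one entry per wavelength-channel,
#'   names are channel ids (`"S-D@wavelength"`).
#' @export
channel_distances <- function(m) {
  o <- m$optodes
  pos <- as.matrix(o[, c("x", "y", "z")])
  rownames(pos) <- o$id
  ch <- m$channels
  if (!all(ch$source %in% rownames(pos)))
    stop_("unresolved source optode id")
  if (!all(ch$detector %in% rownames(pos)))
    stop_("unresolved detector optode id")
  d <- sqrt(rowSums((pos[ch$source, , drop = FALSE] -
                     pos[ch$detector, , drop = FALSE])^2))
  names(d) <- ch$id
  d
}

## Build one optode group on the scalp sphere. A "2 x 4" group is two
## sources and two detectors at the corners of a square (4 pairs of equal
## separation); a "2 x 5" group adds a short-separation detector next to
## the first source.
build_group <- function(center_dir, sep_mm, short_mm, radius,
                        src_ids, det_ids, short_det = NULL) {
  a <- sep_mm / sqrt(2)
  pos <- list(
    sphere_offset(center_dir, -a, 0, radius),  # source 1
    sphere_offset(center_dir,  a, 0, radius),  # source 2
    sphere_offset(center_dir, 0, -a, radius),  # detector 1
    sphere_offset(center_dir, 0,  a, radius)   # detector 2
  )
  ids <- c(src_ids, det_ids)
  kinds <- c("source", "source", "detector", "detector")
  pairs <- expand.grid(source = src_ids, detector = det_ids,
                       stringsAsFactors = FALSE)
  pairs$is_short <- FALSE
  if (!is.null(short_det)) {
    pos <- c(pos, list(sphere_offset(center_dir, -a + short_mm, 0, radius)))
    ids <- c(ids, short_det)
    kinds <- c(kinds, "detector")
    pairs <- rbind(pairs, data.frame(source = src_ids[1], detector = short_det,
                                     is_short = TRUE))
  }
  optodes <- data.frame(
    id = ids, kind = kinds,
    x = vapply(pos, `[`, 0, 1),
    y = vapply(pos, `[`, 0, 2),
    z = vapply(pos, `[`, 0, 3)
  )
  list(optodes = optodes, pairs = pairs)
}

#' Default right-hemisphere concert montage
#'
#' Builds the nominal dual-wavelength montage used throughout the package:
#' four optode groups over right sensorimotor (around C4), posterior
#' sensorimotor, superior temporal (around T8), and inferior frontal
#' (around F8) scalp sites — two groups of 4 pairs and two groups of
#' 5 pairs, the latter each containing one short-separation channel.
#' That yields 18 source-detector pairs (16 long + 2 short) and, at two
#' wavelengths, 36 wavelength-channels.
#'
#' Exact optode coordinates for this headcap layout are not standardized;
#' the coordinates here are idealized positions on a spherical scalp
#' (radius 85 mm) near the 10-10 landmarks named above and should be
#' treated as nominal geometry.
#'
#' @param wavelengths two wavelengths in nm; default `c(762, 842)`.
#' @param long_mm nominal long-channel separation (default 30 mm).
#' @param short_mm nominal short-channel separation (default 8 mm).
#' @param scalp_radius_mm scalp sphere radius (default 85 mm).
#' @return a `nirs_montage` with 36 wavelength-channels.
#' @examples
#' m <- default_brite_montage()
#' nrow(m$channels)            # 36
#' sum(montage_pairs(m)$is_short)  # 2
#' @export
default_brite_montage <- function(wavelengths = c(762, 842),
                                  long_mm = 30, short_mm = 8,
                                  scalp_radius_mm = 85) {
  stopifnot(length(wavelengths) == 2L, short_mm < long_mm)
  ## unit directions of the four group centres (RAS): C4-ish, posterior
  ## sensorimotor (CP4-ish), T8-ish, F8-ish
  dirs <- list(
    sensorimotor1 = c(sin(pi / 4), 0, cos(pi / 4)),
    sensorimotor2 = { v <- c(sin(pi / 4) * cos(-0.35),
                             sin(pi / 4) * sin(-0.35) - 0.15,
                             cos(pi / 4)); v / sqrt(sum(v^2)) },
    temporal = c(sin(1.40) * cos(-0.15), sin(1.40) * sin(-0.15), cos(1.40)),
    frontal  = c(sin(1.30) * cos(0.70),  sin(1.30) * sin(0.70),  cos(1.30))
  )
  specs <- list(
    list(dir = dirs$sensorimotor1, src = c("Tx1", "Tx2"), det = c("Rx1", "Rx2"),
         short = NULL, group = "Sensorimotor1"),
    list(dir = dirs$sensorimotor2, src = c("Tx3", "Tx4"), det = c("Rx3", "Rx4"),
         short = NULL, group = "Sensorimotor2"),
    list(dir = dirs$temporal, src = c("Tx5", "Tx6"), det = c("Rx5", "Rx6"),
         short = "Rx9", group = "Temporal"),
    list(dir = dirs$frontal, src = c("Tx7", "Tx8"), det = c("Rx7", "Rx8"),
         short = "Rx10", group = "Frontal")
  )
  optodes <- NULL; pairs <- NULL; groups <- list()
  for (s in specs) {
    g <- build_group(s$dir, long_mm, short_mm, scalp_radius_mm,
                     s$src, s$det, s$short)
    g$pairs$group <- s$group
    optodes <- rbind(optodes, g$optodes)
    pairs <- rbind(pairs, g$pairs)
    groups[[s$group]] <- paste0(g$pairs$source, "-", g$pairs$detector)
  }
  channels <- do.call(rbind, lapply(sort(wavelengths), function(wl) {
    cbind(pairs, wavelength = wl)
  }))
  ## order channels pair-major, wavelength-minor (stable channel ids)
  channels <- channels[order(match(paste0(channels$source, "-", channels$detector),
                                   paste0(pairs$source, "-", pairs$detector)),
                             channels$wavelength), ]
  rownames(channels) <- NULL
  nirs_montage(optodes, channels, groups)
}
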