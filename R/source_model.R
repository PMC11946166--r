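## Diffusion-approximation forward model (semi-infinite homogeneous
## medium) and depth-weighted minimum-norm inverse. A homogeneous
## closed-form fluence replaces Monte-Carlo template fluences; the
## optical properties are a per-wavelength configuration table, so both
## wavelengths get their own forward model.

#' Nominal tissue optical properties
#'
#' Absorption (`mu_a`) and reduced scattering (`mu_s_prime`)
#' coefficients, 1/mm, per wavelength. Defaults are conventional adult
#' head values in the NIR window.
#'
#' @param wavelengths wavelengths (nm).
#' @param mu_a,mu_s_prime vectors recycled to the wavelengths.
#' @return object of class `optical_props` (named lists by wavelength).
#' @export
optical_props <- function(wavelengths = c(762, 842),
                          mu_a = c(0.0170, 0.0190),
                          mu_s_prime = c(1.10, 1.00)) {
  mu_a <- rep_len(mu_a, length(wavelengths))
  mu_s_prime <- rep_len(mu_s_prime, length(wavelengths))
  if (any(mu_a <= 0) || any(mu_s_prime <= 0))
    stop_("optical properties must be > 0")
  structure(list(
    mu_a = stats::setNames(mu_a, wavelengths),
    mu_s_prime = stats::setNames(mu_s_prime, wavelengths),
    wavelengths = wavelengths
  ), class = "optical_props")
}

#' Photon fluence in a semi-infinite homogeneous medium
#'
#' Continuous-wave Green's-function fluence of the diffusion
#' approximation with the extrapolated-boundary condition: an isotropic
#' point source at depth `z0 = 1/(mu_a + mu_s')` below the surface
#' optode plus a negative image source above the extrapolated boundary.
#' `r` is the straight-line distance (mm) from the optode's surface
#' position to the field point; the source/image distances are
#' `sqrt(r^2 + z0^2)` and `sqrt(r^2 + (z0 + 2*zb)^2)` (exact for points
#' on the boundary, a controlled approximation at depth). Strictly
#' decreasing in `r`, symmetric under source/point exchange.
#'
#' @param r distance(s) from the optode, mm, `> 0`.
#' @param props an [optical_props()].
#' @param wavelength which wavelength's properties to use (nm).
#' @return fluence values (relative units, per mm^2).
#' @export
semi_infinite_fluence <- function(r, props = optical_props(),
                                  wavelength = props$wavelengths[1]) {
  if (any(r <= 0)) stop_("r must be > 0")
  wl <- as.character(wavelength)
  mua <- props$mu_a[[wl]]; musp <- props$mu_s_prime[[wl]]
  if (is.null(mua)) stop_("no optical properties for wavelength %s", wl)
  D <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / D)
  z0 <- 1 / (mua + musp)
  Reff <- 0.493                       # effective reflection, n ~ 1.4 tissue
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  r1 <- sqrt(r^2 + z0^2)
  r2 <- sqrt(r^2 + (z0 + 2 * zb)^2)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

#' Forward sensitivity of long channels to cortical vertices
#'
#' Adjoint (Rytov) sensitivity: for channel `(s, d)` and vertex `v`,
#' `entry = fluence(s -> v) * fluence(v -> d) / fluence(s -> d)`,
#' computed per wavelength from a tabulated radial fluence profile.
#' Vertices whose optode distance falls outside the tabulated range
#' take the fluence of the physically closest in-range vertex (ties
#' broken by lowest vertex index) — the nearest-vertex substitution
#' rule. Short channels are excluded: they inform the scalp, not the
#' cortex.
#'
#' @param montage a `nirs_montage`.
#' @param mesh a `nirs_mesh`.
#' @param props an [optical_props()] covering the montage wavelengths.
#' @param r_table_mm tabulated radial range `c(min, max)` in mm
#'   (default `c(0.5, 200)`); grid step 0.25 mm.
#' @return object of class `sensitivity_matrix`: `A` is a named list
#'   (one `[n_long_pairs x n_v]` matrix per wavelength, row names are
#'   pair ids), plus `pairs`, `props`, `n_vertices`. Rows that are all
#'   zero are recorded in `flat_rows`.
#' @export
build_sensitivity <- function(montage, mesh, props = optical_props(
                                montage_wavelengths(montage)),
                              r_table_mm = c(0.5, 200)) {
  V <- mesh$vertices
  if (is.null(V) || nrow(V) == 0L) stop_("empty mesh")
  pairs <- montage_pairs(montage)
  long <- pairs[!pairs$is_short, ]
  o <- montage$optodes
  pos <- as.matrix(o[, c("x", "y", "z")]); rownames(pos) <- o$id
  rgrid <- seq(r_table_mm[1], r_table_mm[2], by = 0.25)

  dist_to <- function(p) sqrt(colSums((t(V) - p)^2))

  A <- list()
  for (wl in montage_wavelengths(montage)) {
    tab <- semi_infinite_fluence(rgrid, props, wl)
    flu <- function(d) {
      ## tabulated lookup with nearest-vertex substitution out of range
      inr <- d >= r_table_mm[1] & d <= r_table_mm[2]
      out <- numeric(length(d))
      out[inr] <- stats::approx(rgrid, tab, d[inr])$y
      if (any(!inr)) {
        if (!any(inr)) stop_("all vertices outside tabulated fluence range")
        for (i in which(!inr)) {
          ## closest in-range vertex; which.min takes the lowest index on ties
          j <- which(inr)[which.min(abs(d[inr] - d[i]))]
          out[i] <- out[j]
        }
      }
      out
    }
    M <- matrix(0, nrow(long), nrow(V),
                dimnames = list(long$pair, NULL))
    for (k in seq_len(nrow(long))) {
      ps <- pos[long$source[k], ]; pd <- pos[long$detector[k], ]
      phi_sd <- semi_infinite_fluence(max(euclid(ps, pd), r_table_mm[1]),
                                      props, wl)
      M[k, ] <- flu(dist_to(ps)) * flu(dist_to(pd)) / phi_sd
    }
    A[[as.character(wl)]] <- M
  }
  flat <- lapply(A, function(M) rownames(M)[rowSums(M != 0) == 0])
  structure(list(A = A, pairs = long, props = props,
                 n_vertices = nrow(V), flat_rows = flat),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> %d long pairs x %d vertices, wavelengths %s nm\n",
              nrow(x$pairs), x$n_vertices, paste(names(x$A), collapse = "/")))
  invisible(x)
}

#' Depth-weighted minimum-norm source estimate
#'
#' Solves the underdetermined inverse problem per wavelength with a
#' depth-weighted Tikhonov (minimum-norm) estimator
#' `x = W A' (A W A' + alpha I)^{-1} y`, where
#' `W = diag(||a_v||^(-2*depth_exponent))` counteracts the superficial
#' bias of the unweighted minimum-norm solution, and the regularization
#' scale is `alpha = lambda * trace(A W A') / n_channels` with
#' `lambda = 1/SNR^2` (assumed amplitude SNR 3 by default). The depth
#' amplification is capped at `weight_limit` relative to the strongest
#' column (vertices weaker than `max ||a_v|| / weight_limit` are
#' treated as if at that floor), the usual guard against runaway
#' amplification of near-zero-sensitivity fringe vertices. The two
#' wavelength images are then converted per vertex to chromophore
#' changes by the 2x2 extinction-matrix inversion (Molar-mm
#' convention), and `hbt = hbo + hbr`.
#'
#' @param sens a [build_sensitivity()] result.
#' @param od a `nirs_od` whose window is already baseline-corrected;
#'   channels flagged in `od$bad` are excluded (a pair is dropped if
#'   either wavelength is bad).
#' @param lambda regularization factor (> 0); default `1/9`.
#' @param depth_exponent depth-weighting exponent (default 0.5).
#' @param weight_limit maximal depth amplification relative to the
#'   strongest column (default 10).
#' @param extinction extinction table for the spectral step.
#' @return object of class `source_estimate`: `hbo`, `hbr`, `hbt`
#'   matrices `[n_vertices x n_samples]`, `fs`, and regularization
#'   metadata.
#' @export
mne_inverse <- function(sens, od, lambda = 1 / 9, depth_exponent = 0.5,
                        weight_limit = 10, extinction = extinction_table()) {
  stopifnot(inherits(sens, "sensitivity_matrix"), inherits(od, "nirs_od"))
  if (!is.numeric(lambda) || lambda <= 0) stop_("lambda must be > 0")
  wls <- as.numeric(names(sens$A))
  ch <- od$channels
  bad_pairs <- unique(ch$pair[ch$id %in% od$bad])
  use <- setdiff(sens$pairs$pair, bad_pairs)
  if (length(use) == 0L) stop_("no usable long channels")
  nv <- sens$n_vertices
  nt <- nrow(od$data)
  ximg <- list()
  for (wl in wls) {
    cols <- match(paste0(use, "@", wl), ch$id)
    if (anyNA(cols)) stop_("missing wavelength-channels for pairs: %s",
                           paste(use[is.na(cols)], collapse = ", "))
    A <- sens$A[[as.character(wl)]][use, , drop = FALSE]
    if (all(A == 0)) stop_("all-zero sensitivity matrix at %g nm", wl)
    y <- t(od$data[, cols, drop = FALSE])       # [n_ch x n_t]
    s2 <- colSums(A^2)
    floor2 <- max(s2) / weight_limit^2
    w <- pmax(s2, floor2)^(-depth_exponent)
    w[!is.finite(w)] <- 0
    AW <- sweep(A, 2, w, "*")                   # A W
    G <- AW %*% t(A)                            # A W A'
    alpha <- lambda * sum(diag(G)) / nrow(A)
    x <- t(AW) %*% solve(G + alpha * diag(nrow(A)), y)  # [n_v x n_t]
    ximg[[as.character(wl)]] <- x
  }
  E <- extinction_at(wls, extinction)
  Minv <- solve(E)
  hbo <- Minv[1, 1] * ximg[[1]] + Minv[1, 2] * ximg[[2]]
  hbr <- Minv[2, 1] * ximg[[1]] + Minv[2, 2] * ximg[[2]]
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 fs = od$fs, n_vertices = nv, n_samples = nt,
                 lambda = lambda, depth_exponent = depth_exponent,
                 pairs_used = use),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d vertices x %d samples @ %g Hz (lambda %.3g, depth %.2g)\n",
              x$n_vertices, x$n_samples, x$fs, x$lambda, x$depth_exponent))
  invisible(x)
}

#' Forward-project vertex chromophore activity into channel dOD
#'
#' The adjoint of [mne_inverse()]'s linear chain: given vertex-wise
#' HbO/HbR time courses, produce the long-channel optical-density
#' changes `dOD(ch, wl, t) = sum_v A_wl[ch, v] (eps_hbo(wl) hbo_v +
#' eps_hbr(wl) hbr_v)`. Used by the synthetic generator and for
#' closed-loop validation.
#'
#' @param sens a [build_sensitivity()] result.
#' @param hbo,hbr matrices `[n_vertices x n_samples]` (Molar-mm) or
#'   sparse forms: a named list `list(vertex_ids=, series=)`.
#' @param extinction extinction table.
#' @return matrix `[n_samples x n_long_channels]` of dOD with columns
#'   named `"pair@wavelength"` (pair-major, wavelength-minor order).
#' @export
forward_project <- function(sens, hbo, hbr, extinction = extinction_table()) {
  wls <- as.numeric(names(sens$A))
  E <- extinction_at(wls, extinction)
  pairs <- sens$pairs$pair
  cols <- as.vector(t(outer(pairs, wls, function(p, w) paste0(p, "@", w))))
  nt <- ncol(hbo)
  out <- matrix(0, nt, length(cols), dimnames = list(NULL, cols))
  for (wl in wls) {
    A <- sens$A[[as.character(wl)]]
    mu <- E[as.character(wl), "hbo"] * hbo + E[as.character(wl), "hbr"] * hbr
    y <- A %*% mu                              # [n_pairs x n_t]
    out[, paste0(pairs, "@", wl)] <- t(y)
  }
  out
}
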