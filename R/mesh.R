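## Template cortex: a spherical-cap surface mesh beneath the montage,
## with named vertex-set scouts (ROIs). Stands in for an anatomical
## template so that source-space bookkeeping is reproducible without
## anatomical downloads; real atlas scouts can be supplied as files.

#' Spherical-cap cortex mesh
#'
#' Builds a structured triangulated spherical-cap surface of exactly
#' `n_rings * n_az` vertices (default 100 x 100 = 10,000) at cortical
#' depth, centred on a given outward direction.
#'
#' @param center_dir unit 3-vector: outward direction of the cap centre.
#' @param radius_mm cortical sphere radius (default 72 mm, i.e. 13 mm
#'   below an 85 mm scalp).
#' @param cap_angle_deg angular radius of the cap (default 55 degrees).
#' @param n_rings,n_az grid resolution; vertex count is their product.
#' @return object of class `nirs_mesh`: `vertices` `[n_v x 3]` (mm),
#'   `faces` `[n_f x 3]` (1-based vertex indices).
#' @export
spherical_cap_mesh <- function(center_dir = c(0.66, 0.21, 0.72),
                               radius_mm = 72, cap_angle_deg = 55,
                               n_rings = 100, n_az = 100) {
  b <- tangent_basis(center_dir)
  theta <- cap_angle_deg * pi / 180 * seq_len(n_rings) / n_rings
  phi <- 2 * pi * (seq_len(n_az) - 1L) / n_az
  g <- expand.grid(phi = phi, theta = theta)   # ring-major ordering
  dirs <- outer(cos(g$theta), b$n) +
    outer(sin(g$theta) * cos(g$phi), b$e1) +
    outer(sin(g$theta) * sin(g$phi), b$e2)
  vertices <- radius_mm * dirs
  colnames(vertices) <- c("x", "y", "z")
  ## triangulate the ring grid (wrap in azimuth)
  vid <- function(i, j) (i - 1L) * n_az + ((j - 1L) %% n_az) + 1L
  faces <- matrix(0L, 2L * (n_rings - 1L) * n_az, 3L)
  k <- 0L
  for (i in seq_len(n_rings - 1L)) for (j in seq_len(n_az)) {
    a <- vid(i, j); bb <- vid(i, j + 1L)
    cc <- vid(i + 1L, j); dd <- vid(i + 1L, j + 1L)
    faces[k + 1L, ] <- c(a, bb, cc)
    faces[k + 2L, ] <- c(bb, dd, cc)
    k <- k + 2L
  }
  structure(list(vertices = vertices, faces = faces,
                 radius_mm = radius_mm, center_dir = b$n),
            class = "nirs_mesh")
}

#' @export
print.nirs_mesh <- function(x, ...) {
  cat(sprintf("<nirs_mesh> %d vertices, %d faces, radius %g mm\n",
              nrow(x$vertices), nrow(x$faces), x$radius_mm %||% NA))
  invisible(x)
}

#' Default template cortex under a montage
#'
#' A 10,000-vertex spherical-cap mesh centred beneath the montage's mean
#' optode direction, at 13 mm below the scalp sphere.
#'
#' @param montage a `nirs_montage` (default: [default_brite_montage()]).
#' @param depth_mm cortical depth below the scalp sphere (default 13 mm).
#' @return a `nirs_mesh` with exactly 10,000 vertices.
#' @export
default_cortex_mesh <- function(montage = default_brite_montage(),
                                depth_mm = 13) {
  pos <- as.matrix(montage$optodes[, c("x", "y", "z")])
  scalp_r <- mean(sqrt(rowSums(pos^2)))
  ctr <- colMeans(pos / sqrt(rowSums(pos^2)))
  spherical_cap_mesh(ctr / sqrt(sum(ctr^2)), radius_mm = scalp_r - depth_mm)
}

#' Read / write a mesh as ASCII OFF
#'
#' @param path file path.
#' @return `read_mesh_off`: a `nirs_mesh`.
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop_("not an OFF file: %s", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  colnames(verts) <- c("x", "y", "z")
  fl <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)],
                                 collapse = "\n"), quiet = TRUE),
               ncol = 4, byrow = TRUE)
  structure(list(vertices = verts, faces = fl[, 2:4, drop = FALSE] + 1L),
            class = "nirs_mesh")
}

#' @rdname read_mesh_off
#' @param mesh a `nirs_mesh`.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a scout (ROI vertex set)
#'
#' @param name scout name (e.g. `"PRG"`).
#' @param vertex_ids 1-based vertex indices into the mesh.
#' @param mesh optional mesh for index validation.
#' @return object of class `nirs_scout`.
#' @export
nirs_scout <- function(name, vertex_ids, mesh = NULL) {
  vertex_ids <- as.integer(vertex_ids)
  if (length(vertex_ids) == 0L) stop_("scout '%s' is empty", name)
  if (!is.null(mesh) && (min(vertex_ids) < 1L ||
                         max(vertex_ids) > nrow(mesh$vertices)))
    stop_("scout '%s' has vertex ids outside the mesh", name)
  structure(list(name = name, vertex_ids = vertex_ids),
            class = "nirs_scout")
}

#' Geodesic-patch scout around a surface point
#'
#' The `n` mesh vertices nearest to `seed_point` (straight-line
#' distance; on a cap surface this matches the geodesic ordering).
#'
#' @param mesh a `nirs_mesh`.
#' @param name scout name.
#' @param seed_point 3-vector (mm) or a vertex index.
#' @param n number of vertices in the patch.
#' @return a `nirs_scout` of exactly `n` vertices.
#' @export
scout_patch <- function(mesh, name, seed_point, n) {
  if (length(seed_point) == 1L)
    seed_point <- mesh$vertices[as.integer(seed_point), ]
  d2 <- rowSums(sweep(mesh$vertices, 2, seed_point, "-")^2)
  nirs_scout(name, order(d2)[seq_len(n)], mesh)
}

#' Default scouts mirroring the concert ROIs
#'
#' Four geodesic patches on the template cap sized to the vertex counts
#' of the concert head model's atlas ROIs: precentral gyrus (PRG, 107),
#' postcentral gyrus (POG, 97), superior temporal gyrus (STG, 92), and
#' the combined right inferior frontal gyrus (rIFG, 144). Seeds sit at
#' the cortical projections of the montage's sensorimotor, temporal and
#' frontal group centres, so each scout lies under its channels.
#'
#' @param mesh a `nirs_mesh`.
#' @param montage the montage the mesh was built for.
#' @return named list of `nirs_scout`s (`PRG`, `POG`, `STG`, `rIFG`).
#' @export
default_scouts <- function(mesh, montage = default_brite_montage()) {
  r <- mesh$radius_mm %||% mean(sqrt(rowSums(mesh$vertices^2)))
  proj <- function(group, shift = c(0, 0, 0)) {
    pairs <- montage$groups[[group]]
    ch <- montage$channels
    ids <- unique(unlist(strsplit(pairs, "-")))
    o <- montage$optodes[montage$optodes$id %in% ids, c("x", "y", "z")]
    ctr <- colMeans(as.matrix(o)) + shift
    r * ctr / sqrt(sum(ctr^2))
  }
  list(
    PRG = scout_patch(mesh, "PRG", proj("Sensorimotor1", c(0, 6, 0)), 107),
    POG = scout_patch(mesh, "POG", proj("Sensorimotor2", c(0, -6, 0)), 97),
    STG = scout_patch(mesh, "STG", proj("Temporal"), 92),
    rIFG = scout_patch(mesh, "rIFG", proj("Frontal"), 144)
  )
}

#' Read / write scouts as two-column TSV or JSON
#'
#' TSV columns: `scout_name`, `vertex_id` (1-based). JSON: object
#' mapping scout names to vertex-id arrays. Format chosen by file
#' extension.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @param mesh optional mesh for validation.
#' @return `read_scouts`: named list of `nirs_scout`s.
#' @export
read_scouts <- function(path, mesh = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    return(stats::setNames(
      lapply(names(obj), function(nm) nirs_scout(nm, obj[[nm]], mesh)),
      names(obj)))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("scout_name", "vertex_id") %in% names(d)))
    stop_("scout TSV needs columns scout_name, vertex_id")
  sp <- split(d$vertex_id, d$scout_name)
  stats::setNames(lapply(names(sp), function(nm) nirs_scout(nm, sp[[nm]], mesh)),
                  names(sp))
}

#' @rdname read_scouts
#' @param scouts named list of `nirs_scout`s.
#' @export
write_scouts <- function(scouts, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(scouts, function(s) s$vertex_ids), path)
  } else {
    d <- do.call(rbind, lapply(scouts, function(s)
      data.frame(scout_name = s$name, vertex_id = s$vertex_ids)))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
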