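# Core triangle-mesh container and primitives. Units are mm throughout.
# Convention: tooth axis = z, apex at z = -RL, CEJ plane at z = 0,
# mesiodistal = x, buccolingual = y.

#' Construct a tooth mesh
#'
#' A `tooth_mesh` is a triangle mesh in mm with optional named anatomical
#' landmarks and an optional cemento-enamel junction (CEJ) plane. Landmarks
#' used by the morphometry layer are `apex`, `cej_buccal`, `cej_lingual`,
#' `cej_mesial`, `cej_distal` and (optionally) `crown_tip`.
#'
#' @param vertices numeric matrix, one 3D point (mm) per row.
#' @param faces integer matrix, one triangle per row as 1-based vertex indices.
#' @param landmarks named list of length-3 numeric vectors, or `NULL`.
#' @param cej_plane a plane from [make_plane()], or `NULL`.
#' @param validate check index bounds and basic sanity.
#' @return An object of class `tooth_mesh`.
#' @export
tooth_mesh <- function(vertices, faces, landmarks = NULL, cej_plane = NULL,
                       validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (validate) {
    if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
    if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
    if (nrow(faces) < 1L || nrow(vertices) < 3L) stop("empty mesh")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (!is.null(landmarks)) {
      ok <- vapply(landmarks, function(p) is.numeric(p) && length(p) == 3L,
                   logical(1))
      if (!all(ok)) stop("landmarks must be length-3 numeric vectors")
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 landmarks = landmarks, cej_plane = cej_plane),
            class = "tooth_mesh")
}

#' @export
print.tooth_mesh <- function(x, ...) {
  cat(sprintf("<tooth_mesh> %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (!is.null(x$landmarks))
    cat(sprintf(", landmarks: %s", paste(names(x$landmarks), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Construct a plane from a point and a normal
#'
#' @param point numeric length 3, a point on the plane (mm).
#' @param normal numeric length 3, plane normal (normalised internally).
#' @return list with components `point` and unit `normal`.
#' @export
make_plane <- function(point, normal) {
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("zero-length plane normal")
  list(point = as.numeric(point), normal = as.numeric(normal) / nrm)
}

#' Least-squares plane through a set of points
#'
#' Total-least-squares fit: the plane passes through the centroid with normal
#' given by the singular vector of the smallest singular value. Used to define
#' the CEJ plane from the four CEJ landmarks.
#'
#' @param pts numeric matrix of 3D points (>= 3, non-collinear).
#' @return a plane as from [make_plane()].
#' @export
fit_plane <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) stop("points are collinear")
  make_plane(ctr, sv$v[, 3])
}

# Per-face un-normalised normals (cross product), n_faces x 3.
face_cross <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Total surface area of a triangle mesh
#'
#' Sum of triangle areas; does not require a closed mesh and is independent of
#' face orientation. Degenerate (collinear) triangles contribute zero.
#'
#' @param mesh a [tooth_mesh()] (or any list with `vertices` and `faces`).
#' @return surface area in mm^2.
#' @export
surface_area <- function(mesh) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L) stop("empty mesh")
  cr <- face_cross(mesh$vertices, mesh$faces)
  sum(0.5 * sqrt(rowSums(cr^2)))
}

# Count edges that are not shared by exactly two faces. 0 for a closed mesh.
open_edge_count <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) != 2L)
}

#' Is the mesh closed (watertight)?
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param mesh a [tooth_mesh()].
#' @return logical.
#' @export
is_closed_mesh <- function(mesh) open_edge_count(mesh) == 0L

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem volume: sum of signed tetrahedra spanned by each face
#' and the origin. The result is reported positive regardless of global
#' orientation and is translation-invariant for closed meshes.
#'
#' @param mesh a closed, consistently oriented [tooth_mesh()].
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  oe <- open_edge_count(mesh)
  if (oe > 0L)
    stop(sprintf("mesh is not closed: %d open edge(s); volume undefined", oe))
  f <- mesh$faces
  de <- paste(rbind(f[, 1], f[, 2], f[, 3]),
              rbind(f[, 2], f[, 3], f[, 1]))
  if (anyDuplicated(de))
    stop("mesh faces are not consistently oriented; volume undefined")
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  # scalar triple product a . (b x c) / 6
  s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
       a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
       a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(s)) / 6
}

#' Trivial mesh repair
#'
#' Merges vertices closer than `tol` (grid rounding), drops faces with
#' repeated vertices and exactly duplicated faces. This mirrors the minimal
#' clean-up a mesh tool applies before volume computation; anything still
#' open after repair is reported as an error by [enclosed_volume()].
#'
#' @param mesh a [tooth_mesh()].
#' @param tol merge tolerance in mm.
#' @return a repaired [tooth_mesh()].
#' @export
repair_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  fkey <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  f <- f[!duplicated(fkey), , drop = FALSE]
  tooth_mesh(newv, f, landmarks = mesh$landmarks, cej_plane = mesh$cej_plane)
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x a [tooth_mesh()] or an n x 3 point matrix.
#' @param transform a `rigid_transform` from [rigid_align()].
#' @return the transformed object.
#' @export
transform_points <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "tooth_mesh")) {
    out <- x
    out$vertices <- transform_points(x$vertices, transform)
    if (!is.null(x$landmarks))
      out$landmarks <- lapply(x$landmarks, function(p)
        as.numeric(transform$rotation %*% p + transform$translation))
    if (!is.null(x$cej_plane))
      out$cej_plane <- make_plane(
        as.numeric(transform$rotation %*% x$cej_plane$point +
                     transform$translation),
        as.numeric(transform$rotation %*% x$cej_plane$normal))
    return(out)
  }
  x <- as.matrix(x)
  sweep(x %*% t(transform$rotation), 2, -transform$translation)
}
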