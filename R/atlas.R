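# Shape atlas: rigid landmark registration, mean models, signed
# surface-distance colour maps on the standardised +/-1.145 mm scale.

#' Rigid landmark registration (orthogonal Procrustes, no scaling)
#'
#' Finds the rotation + translation minimising the sum of squared distances
#' between corresponding landmarks (Kabsch algorithm); reflections are
#' excluded, so the result is a proper rigid motion in mm.
#'
#' @param moving_landmarks,fixed_landmarks n x 3 matrices (or named lists of
#'   length-3 points with matching names), n >= 3, non-collinear.
#' @return object of class `rigid_transform` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmse`, the residual root-mean-square
#'   landmark distance after alignment.
#' @export
rigid_align <- function(moving_landmarks, fixed_landmarks) {
  as_mat <- function(x, other = NULL) {
    if (is.list(x) && !is.matrix(x)) {
      if (!is.null(names(x)) && !is.null(other) && !is.null(names(other)))
        x <- x[names(other)]
      x <- do.call(rbind, x)
    }
    as.matrix(x)
  }
  M <- as_mat(moving_landmarks, fixed_landmarks)
  X <- as_mat(fixed_landmarks, moving_landmarks)
  if (!all(dim(M) == dim(X)) || ncol(M) != 3L || nrow(M) < 3L)
    stop("need >= 3 corresponding 3D landmark pairs")
  cm <- colMeans(M)
  cx <- colMeans(X)
  Mc <- sweep(M, 2, cm)
  Xc <- sweep(X, 2, cx)
  H <- t(Mc) %*% Xc
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("landmarks are collinear: rotation is not identifiable")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cx - R %*% cm)
  rmse <- sqrt(mean(rowSums(((Mc %*% t(R)) - Xc)^2)))
  structure(list(rotation = R, translation = tr, rmse = rmse),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> residual RMS", format(x$rmse, digits = 4), "mm\n")
  print(x$rotation)
  cat("translation:", format(x$translation, digits = 6), "\n")
  invisible(x)
}

#' Closest points on a mesh surface
#'
#' For each query point, the nearest point on any triangle of the mesh, the
#' Euclidean distance, and the index of the supporting face.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a [tooth_mesh()].
#' @return list with `points` (n x 3), `distance` (n), `face` (n).
#' @export
closest_on_mesh <- function(points, mesh) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L) stop("empty mesh")
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  cpp_closest_on_mesh(points, mesh$vertices, mesh$faces)
}

#' Mean shape model over aligned meshes
#'
#' Template-based correspondence: each template vertex is matched to its
#' closest surface point on every mesh (the template included), and the mean
#' of those points becomes the new vertex. The output keeps the template
#' connectivity, so averaging N copies of one mesh reproduces it exactly and
#' the result is invariant to the input order.
#'
#' @param meshes list of >= 2 aligned [tooth_mesh()] objects.
#' @param template index into `meshes` of the template (default 1).
#' @return the mean [tooth_mesh()].
#' @export
mean_model <- function(meshes, template = 1L) {
  if (length(meshes) < 2L) stop("need at least 2 meshes to average")
  tm <- meshes[[template]]
  acc <- matrix(0, nrow(tm$vertices), 3L)
  for (m in meshes) {
    cp <- closest_on_mesh(tm$vertices, m)
    acc <- acc + cp$points
  }
  out <- tm
  out$vertices <- acc / length(meshes)
  out$ground_truth <- NULL
  out
}

#' Angle-weighted outward vertex pseudo-normals
#'
#' @param mesh a consistently outward-oriented [tooth_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  N <- matrix(0, nrow(V), 3L)
  fn <- face_cross(V, F)
  fn_len <- sqrt(rowSums(fn^2))
  fn_unit <- fn / pmax(fn_len, 1e-300)
  for (k in 1:3) {
    i0 <- F[, k]
    i1 <- F[, if (k < 3) k + 1 else 1]
    i2 <- F[, if (k > 1) k - 1 else 3]
    e1 <- V[i1, , drop = FALSE] - V[i0, , drop = FALSE]
    e2 <- V[i2, , drop = FALSE] - V[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)), 1e-300)
    ang <- acos(pmin(1, pmax(-1, cosang)))
    w <- ang * fn_unit
    for (j in 1:3) {
      acc <- numeric(nrow(V))
      tmp <- rowsum(w[, j], i0)
      acc[as.integer(rownames(tmp))] <- tmp
      N[, j] <- N[, j] + acc
    }
  }
  N / pmax(sqrt(rowSums(N^2)), 1e-300)
}

#' Signed surface-distance colour map
#'
#' For each vertex of the reference mesh, the distance to the model surface,
#' signed positive where the model lies outside the reference along its
#' outward vertex normal. Colours follow a piecewise-linear
#' blue-green-red ramp: pure blue at `-bound` mm, pure green at 0, pure red
#' at `+bound` mm, clamped outside.
#'
#' @param model the mesh being compared (e.g. the normal-root mean model).
#' @param reference the reference mesh (e.g. the conical mean model); both
#'   must already be in the common frame.
#' @param bound colour-scale bound in mm (default 1.145, the standardised
#'   display scale).
#' @return object of class `colour_map`: list with `distance` (mm, one per
#'   reference vertex), `rgb` (n x 3 integer, 0-255), `bound`, `reference`.
#' @export
distance_colour_map <- function(model, reference, bound = 1.145) {
  if (nrow(reference$vertices) == 0L || nrow(model$faces) == 0L)
    stop("empty mesh")
  cp <- closest_on_mesh(reference$vertices, model)
  nrm <- vertex_normals(reference)
  dir <- cp$points - reference$vertices
  sgn <- sign(rowSums(dir * nrm))
  sgn[sgn == 0] <- 1
  d <- sgn * cp$distance
  structure(list(distance = d, rgb = distance_colours(d, bound),
                 bound = bound, reference = reference),
            class = "colour_map")
}

#' Map signed distances to the blue-green-red ramp
#'
#' @param d signed distances (mm).
#' @param bound scale bound (mm).
#' @return n x 3 integer matrix of RGB values in 0-255.
#' @export
distance_colours <- function(d, bound = 1.145) {
  x <- pmin(1, pmax(-1, d / bound))
  r <- ifelse(x > 0, x * 255, 0)
  g <- (1 - abs(x)) * 255
  b <- ifelse(x < 0, -x * 255, 0)
  m <- round(cbind(red = r, green = g, blue = b))
  storage.mode(m) <- "integer"
  m
}

#' Build the group mean models and their colour map
#'
#' Aligns every mesh to a fixed reference via landmark Procrustes, averages
#' each group, and computes the signed-distance map of the normal mean
#' against the conical mean (conical as reference, matching the published
#' display convention).
#'
#' @param nrt_meshes,crt_meshes lists of landmark-annotated meshes.
#' @param bound colour-scale bound in mm.
#' @return list with `mean_nrt`, `mean_crt` (aligned mean meshes) and `map`
#'   (a `colour_map`).
#' @export
shape_atlas <- function(nrt_meshes, crt_meshes, bound = 1.145) {
  if (length(crt_meshes) < 2L || length(nrt_meshes) < 2L)
    stop("need at least 2 meshes per group")
  ref_lm <- crt_meshes[[1]]$landmarks
  align_all <- function(ms) lapply(ms, function(m) {
    tf <- rigid_align(m$landmarks, ref_lm)
    transform_points(m, tf)
  })
  nrt_al <- align_all(nrt_meshes)
  crt_al <- align_all(crt_meshes)
  mean_nrt <- mean_model(nrt_al, 1L)
  mean_crt <- mean_model(crt_al, 1L)
  list(mean_nrt = mean_nrt, mean_crt = mean_crt,
       map = distance_colour_map(mean_nrt, mean_crt, bound = bound))
}
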