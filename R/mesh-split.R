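# Splitting a closed mesh by a plane with planar cap accounting.
#
# The crown/root segmentation at the CEJ needs both halves closed so that
# surface areas and volumes obey the bookkeeping identity behind
# RSA = (S_MT + S_MR - S_MC)/2: each half receives a planar cap (area S_S1)
# over every intersection curve, so
#   area(crown) + area(root)     = area(tooth) + 2 * S_S1
#   volume(crown) + volume(root) = volume(tooth)
# hold exactly up to floating point.

#' Split a closed mesh by a plane, capping both halves
#'
#' Triangles crossing the plane are subdivided along the intersection; the
#' intersection segments are chained into closed curves, and each curve is
#' capped on both halves by a planar triangle fan from the curve centroid.
#' Vertices lying exactly on the plane are assigned to the positive side.
#'
#' @param mesh a closed [tooth_mesh()].
#' @param plane a plane from [make_plane()].
#' @return list with `positive` and `negative` closed meshes (sides by the
#'   sign of the plane's signed distance), the total cap area `cap_area`
#'   (S_S1, mm^2) and `n_loops`, the number of intersection curves.
#' @export
split_by_plane <- function(mesh, plane) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- as.numeric(sweep(V, 2, plane$point) %*% plane$normal)
  eps <- 1e-9 * max(1, max(abs(V)))
  d[abs(d) < eps] <- 0
  if (!any(d > 0) || !any(d < 0))
    stop("plane is tangent to or misses the mesh: no interior on both sides")
  pos <- d >= 0
  fpos <- matrix(pos[F], ncol = 3)
  np <- rowSums(fpos)
  all_pos <- np == 3L
  all_neg <- np == 0L
  mixed <- which(!all_pos & !all_neg)
  if (length(mixed) == 0L)
    stop("plane does not intersect the mesh interior (no crossing triangles)")

  # intersection points, cached per mesh edge so shared edges reuse the
  # exact same coordinates (required for loop chaining and conservation)
  pt_env <- new.env(parent = emptyenv())
  new_pts <- list()
  inter <- function(i, j) {
    if (d[i] == 0) return(list(key = paste0("v", i), p = V[i, ]))
    if (d[j] == 0) return(list(key = paste0("v", j), p = V[j, ]))
    ii <- min(i, j); jj <- max(i, j)
    key <- paste0("e", ii, "_", jj)
    if (!is.null(pt_env[[key]])) return(list(key = key, p = pt_env[[key]]))
    t <- d[ii] / (d[ii] - d[jj])
    p <- V[ii, ] + t * (V[jj, ] - V[ii, ])
    pt_env[[key]] <- p
    list(key = key, p = p)
  }

  pos_faces <- list()   # triangles as 3 x 3 coordinate matrices or index rows
  neg_faces <- list()
  segs <- list()        # intersection segments as pairs of keys
  key_pts <- new.env(parent = emptyenv())

  add_seg <- function(a, b) {
    if (a$key == b$key) return(invisible())
    key_pts[[a$key]] <- a$p
    key_pts[[b$key]] <- b$p
    segs[[length(segs) + 1L]] <<- c(a$key, b$key)
  }

  # collect split sub-triangles using point keys; original vertices keep
  # their index-based key "v<i>"
  vkey <- function(i) list(key = paste0("v", i), p = V[i, ])
  tri_list_pos <- list()
  tri_list_neg <- list()
  for (fi in mixed) {
    idx <- F[fi, ]
    s <- pos[idx]
    lone_on_pos <- sum(s) == 1L
    lone <- which(s == lone_on_pos)  # position (1..3) of the lone vertex
    # rotate so lone vertex is C, preserving winding
    ord <- switch(lone, c(2L, 3L, 1L), c(3L, 1L, 2L), c(1L, 2L, 3L))
    A <- idx[ord[1]]; B <- idx[ord[2]]; C <- idx[ord[3]]
    pAC <- inter(A, C)
    pBC <- inter(B, C)
    add_seg(pAC, pBC)
    side_ab <- list(list(vkey(A), vkey(B), pBC), list(vkey(A), pBC, pAC))
    side_c <- list(list(pAC, pBC, vkey(C)))
    if (lone_on_pos) {
      tri_list_pos <- c(tri_list_pos, side_c)
      tri_list_neg <- c(tri_list_neg, side_ab)
    } else {
      tri_list_pos <- c(tri_list_pos, side_ab)
      tri_list_neg <- c(tri_list_neg, side_c)
    }
  }
  if (length(segs) == 0L)
    stop("plane is tangent to the mesh: no closed intersection curve")

  # chain segments into closed loops; every key must have degree exactly 2
  keys <- unique(unlist(segs))
  adj <- new.env(parent = emptyenv())
  for (sgm in segs) {
    adj[[sgm[1]]] <- c(adj[[sgm[1]]], sgm[2])
    adj[[sgm[2]]] <- c(adj[[sgm[2]]], sgm[1])
  }
  deg <- vapply(keys, function(k) length(adj[[k]]), integer(1))
  if (any(deg != 2L))
    stop("non-simple plane intersection (tangency or self-touching curve)")
  visited <- new.env(parent = emptyenv())
  loops <- list()
  for (k0 in keys) {
    if (!is.null(visited[[k0]])) next
    loop <- character(0)
    prev <- ""
    cur <- k0
    repeat {
      loop <- c(loop, cur)
      visited[[cur]] <- TRUE
      nbrs <- adj[[cur]]
      nxt <- if (nbrs[1] != prev) nbrs[1] else nbrs[2]
      prev <- cur
      cur <- nxt
      if (cur == k0) break
    }
    if (length(loop) < 3L)
      stop("degenerate intersection curve with fewer than 3 points")
    loops[[length(loops) + 1L]] <- loop
  }

  # assemble vertex table: original vertices first, then intersection points
  ikeys <- keys
  ipts <- do.call(rbind, lapply(ikeys, function(k) key_pts[[k]]))
  # keys of form "v<i>" refer to original vertices
  key_index <- function(k) {
    isv <- startsWith(k, "v")
    out <- integer(length(k))
    out[isv] <- as.integer(substring(k[isv], 2))
    out[!isv] <- nrow(V) + match(k[!isv], ikeys_e)
    out
  }
  ikeys_e <- ikeys[!startsWith(ikeys, "v")]
  epts <- do.call(rbind, lapply(ikeys_e, function(k) key_pts[[k]]))
  if (is.null(epts)) epts <- matrix(0, 0, 3)
  allV <- rbind(V, epts)

  tri_to_rows <- function(tris) {
    if (length(tris) == 0L) return(matrix(0L, 0, 3))
    m <- t(vapply(tris, function(tr)
      key_index(c(tr[[1]]$key, tr[[2]]$key, tr[[3]]$key)), integer(3)))
    # drop degenerate sub-triangles (two corners collapsed onto the same point)
    m[m[, 1] != m[, 2] & m[, 2] != m[, 3] & m[, 1] != m[, 3], , drop = FALSE]
  }
  posF <- rbind(F[all_pos, , drop = FALSE], tri_to_rows(tri_list_pos))
  negF <- rbind(F[all_neg, , drop = FALSE], tri_to_rows(tri_list_neg))

  # planar caps: fan from the loop centroid; orientation from the signed
  # area of the loop projected into an in-plane basis (u, v) with u x v = n
  n <- plane$normal
  u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])

  cap_area <- 0
  cap_pos <- list()
  cap_neg <- list()
  for (loop in loops) {
    li <- key_index(loop)
    P <- allV[li, , drop = FALSE]
    x <- as.numeric(sweep(P, 2, plane$point) %*% u)
    y <- as.numeric(sweep(P, 2, plane$point) %*% v)
    m <- length(x)
    nxt <- c(2:m, 1)
    a2 <- sum(x * y[nxt] - x[nxt] * y)  # 2 * signed area, CCW about n if > 0
    if (abs(a2) < 1e-14)
      stop("degenerate (zero-area) intersection curve")
    cap_area <- cap_area + abs(a2) / 2
    if (a2 < 0) li <- rev(li)          # make loop CCW about n
    ctr_idx <- nrow(allV) + 1L
    allV <- rbind(allV, colMeans(P))
    m <- length(li)
    nxt <- c(2:m, 1)
    # CCW fan has normal +n: outward for the negative half (below the plane)
    cap_neg[[length(cap_neg) + 1L]] <- cbind(ctr_idx, li, li[nxt])
    cap_pos[[length(cap_pos) + 1L]] <- cbind(ctr_idx, li[nxt], li)
  }
  posF <- rbind(posF, do.call(rbind, cap_pos))
  negF <- rbind(negF, do.call(rbind, cap_neg))

  compact <- function(faces) {
    used <- sort(unique(as.integer(faces)))
    tooth_mesh(allV[used, , drop = FALSE],
               matrix(match(as.integer(faces), used), ncol = 3))
  }
  positive <- compact(posF)
  negative <- compact(negF)
  if (!is_closed_mesh(positive) || !is_closed_mesh(negative))
    stop("internal error: split produced a non-closed half")
  list(positive = positive, negative = negative,
       cap_area = cap_area, n_loops = length(loops))
}

#' Split an annotated tooth at its CEJ plane into crown and root
#'
#' Orients the CEJ plane so the apex landmark falls on the root side and
#' calls [split_by_plane()].
#'
#' @param mesh a [tooth_mesh()] with an `apex` landmark and either a stored
#'   `cej_plane` or the four CEJ landmarks to fit one.
#' @return list with closed `crown` and `root` meshes and the truncation cap
#'   area `S_S1` (mm^2).
#' @export
split_tooth <- function(mesh) {
  plane <- mesh$cej_plane
  if (is.null(plane)) {
    lm <- mesh$landmarks
    need <- c("cej_buccal", "cej_lingual", "cej_mesial", "cej_distal")
    if (!all(need %in% names(lm)))
      stop("no CEJ plane and missing CEJ landmarks to fit one")
    plane <- fit_plane(do.call(rbind, lm[need]))
  }
  apex <- mesh$landmarks$apex
  if (is.null(apex)) stop("missing landmark: apex")
  d_apex <- sum((apex - plane$point) * plane$normal)
  if (abs(d_apex) < 1e-9)
    stop("apex lies on the CEJ plane; crown/root split undefined")
  if (d_apex > 0) plane$normal <- -plane$normal  # root on the negative side
  sp <- split_by_plane(mesh, plane)
  list(crown = sp$positive, root = sp$negative, S_S1 = sp$cap_area,
       cej_plane = plane)
}
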