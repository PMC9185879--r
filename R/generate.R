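# Synthetic data generators: tooth meshes, scalar cohorts, projections.

#' Generate a watertight tooth mesh from a profile
#'
#' Builds the closed surface (apex cap, root wall, crown dome or flat CEJ
#' disc), places the six anatomical landmarks, stores the CEJ plane, and
#' attaches quadrature ground-truth metrics (see [profile_ground_truth()]).
#'
#' @param profile a [tooth_profile()].
#' @return a closed [tooth_mesh()] with a `ground_truth` element.
#' @export
generate_tooth <- function(profile) {
  stopifnot(inherits(profile, "tooth_profile"))
  L <- profile$root_length
  a <- profile$cervical_halfwidth_md
  b <- profile$cervical_halfwidth_bl
  H <- profile$crown_height
  ra <- profile$apex_radius
  n_ax <- profile$mesh_resolution[1]
  nc <- profile$mesh_resolution[2]
  zc <- -(L - ra)

  # axial stations bottom -> top (z, g); poles handled separately
  zs <- numeric(0)
  if (ra > 0) {
    n_cap <- max(4L, ceiling(n_ax * ra / L))
    phi <- seq(pi / 2, 0, length.out = n_cap + 1L)[-1L]  # drop apex pole
    zs <- c(zs, zc - ra * sin(phi))
    zs <- c(zs, seq(zc, 0, length.out = n_ax)[-1L])
  } else {
    zs <- c(zs, seq(-L, 0, length.out = n_ax + 1L)[-1L])
  }
  if (H > 0) {
    n_crown <- max(4L, ceiling(n_ax * H / L))
    phi <- seq(0, pi / 2, length.out = n_crown + 1L)
    phi <- phi[-c(1L, length(phi))]                      # drop CEJ ring, pole
    zs <- c(zs, H * sin(phi))
  }
  gs <- profile_g(profile, zs)

  theta <- 2 * pi * (seq_len(nc) - 1) / nc
  nring <- length(zs)
  V <- matrix(0, 1L + nring * nc + 1L, 3)
  V[1, ] <- c(0, 0, -L)                                  # apex pole
  for (i in seq_len(nring)) {
    rows <- 1L + (i - 1L) * nc + seq_len(nc)
    V[rows, 1] <- a * gs[i] * cos(theta)
    V[rows, 2] <- b * gs[i] * sin(theta)
    V[rows, 3] <- zs[i]
  }
  top <- nrow(V)
  V[top, ] <- c(0, 0, if (H > 0) H else 0)               # crown tip / disc ctr

  ring <- function(i) 1L + (i - 1L) * nc + seq_len(nc)
  nxt <- c(2:nc, 1L)
  faces <- vector("list", nring + 1L)
  r1 <- ring(1L)
  faces[[1]] <- cbind(1L, r1[nxt], r1)                   # apex fan
  for (i in seq_len(nring - 1L)) {
    lo <- ring(i); up <- ring(i + 1L)
    faces[[i + 1L]] <- rbind(cbind(lo, lo[nxt], up[nxt]),
                             cbind(lo, up[nxt], up))
  }
  rt <- ring(nring)
  faces[[nring + 1L]] <- cbind(top, rt, rt[nxt])         # top fan / CEJ disc
  F <- do.call(rbind, faces)

  # enforce outward orientation (positive signed volume)
  av <- V[F[, 1], , drop = FALSE]
  bv <- V[F[, 2], , drop = FALSE]
  cv <- V[F[, 3], , drop = FALSE]
  s <- sum(av[, 1] * (bv[, 2] * cv[, 3] - bv[, 3] * cv[, 2]) +
           av[, 2] * (bv[, 3] * cv[, 1] - bv[, 1] * cv[, 3]) +
           av[, 3] * (bv[, 1] * cv[, 2] - bv[, 2] * cv[, 1]))
  if (s < 0) F <- F[, c(1L, 3L, 2L)]

  landmarks <- list(apex = c(0, 0, -L),
                    cej_mesial = c(a, 0, 0),
                    cej_distal = c(-a, 0, 0),
                    cej_buccal = c(0, b, 0),
                    cej_lingual = c(0, -b, 0))
  if (H > 0) landmarks$crown_tip <- c(0, 0, H)

  mesh <- tooth_mesh(V, F, landmarks = landmarks,
                     cej_plane = make_plane(c(0, 0, 0), c(0, 0, 1)))
  if (!is_closed_mesh(mesh))
    stop("internal error: generated mesh is not watertight")
  mesh$ground_truth <- profile_ground_truth(profile)
  mesh$profile <- profile
  mesh
}

#' Population specification for scalar cohorts
#'
#' Per-parameter normal distributions for the two diagnostic groups. The
#' defaults are the published maxillary-premolar reference values
#' (mean +/- SD) for normal-rooted (NRT, n = 54) and cone-rooted (CRT,
#' n = 41) teeth:
#' RL 11.62+/-1.19 / 11.65+/-1.54 mm, PRW 0.48+/-0.12 / 0.33+/-0.16 mm,
#' RSA 236.88+/-27.93 / 207.98+/-27.80 mm^2, RV 316.93+/-49.89 /
#' 253.40+/-41.98 mm^3, RSA/RL 20.42+/-1.86 / 17.88+/-1.31,
#' RV/RL 27.34+/-3.87 / 21.76+/-2.43.
#'
#' @param n_nrt,n_crt group sizes (> 1).
#' @param nrt_mean,nrt_sd,crt_mean,crt_sd named numeric vectors over the six
#'   parameters `RL, PRW, RSA, RV, RSA_RL, RV_RL`; SDs must be >= 0.
#' @param correlation optional 6 x 6 cross-parameter correlation matrix
#'   (default: independence).
#' @param seed integer RNG seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_nrt = 54L, n_crt = 41L,
                            nrt_mean = c(RL = 11.62, PRW = 0.48, RSA = 236.88,
                                         RV = 316.93, RSA_RL = 20.42,
                                         RV_RL = 27.34),
                            nrt_sd = c(RL = 1.19, PRW = 0.12, RSA = 27.93,
                                       RV = 49.89, RSA_RL = 1.86,
                                       RV_RL = 3.87),
                            crt_mean = c(RL = 11.65, PRW = 0.33, RSA = 207.98,
                                         RV = 253.40, RSA_RL = 17.88,
                                         RV_RL = 21.76),
                            crt_sd = c(RL = 1.54, PRW = 0.16, RSA = 27.80,
                                       RV = 41.98, RSA_RL = 1.31,
                                       RV_RL = 2.43),
                            correlation = NULL,
                            seed = 1L) {
  pars <- c("RL", "PRW", "RSA", "RV", "RSA_RL", "RV_RL")
  for (v in list(nrt_mean, nrt_sd, crt_mean, crt_sd))
    if (!all(pars %in% names(v)))
      stop("mean/sd vectors must be named over ", paste(pars, collapse = ", "))
  if (any(c(nrt_sd, crt_sd) < 0)) stop("SDs must be >= 0")
  if (n_nrt <= 1L || n_crt <= 1L) stop("group sizes must be > 1")
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!all(dim(correlation) == c(6L, 6L)) ||
        max(abs(correlation - t(correlation))) > 1e-12)
      stop("correlation must be a symmetric 6 x 6 matrix")
  }
  structure(list(n_nrt = as.integer(n_nrt), n_crt = as.integer(n_crt),
                 nrt_mean = nrt_mean[pars], nrt_sd = nrt_sd[pars],
                 crt_mean = crt_mean[pars], crt_sd = crt_sd[pars],
                 correlation = correlation, seed = as.integer(seed),
                 parameters = pars),
            class = "population_spec")
}

#' Draw a labelled scalar cohort
#'
#' Independent (or optionally correlated) normal draws per parameter and
#' group; reproducible under a fixed seed.
#'
#' @param spec a [population_spec()].
#' @return data.frame with columns `tooth_id`, `group` (NRT/CRT) and the six
#'   metric columns.
#' @export
generate_cohort <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  draw <- function(n, mu, sigma) {
    z <- matrix(rnorm(n * 6L), n, 6L)
    if (!is.null(spec$correlation)) {
      ch <- chol(spec$correlation)
      z <- z %*% ch
    }
    sweep(sweep(z, 2, sigma, `*`), 2, mu, `+`)
  }
  x_nrt <- draw(spec$n_nrt, spec$nrt_mean, spec$nrt_sd)
  x_crt <- draw(spec$n_crt, spec$crt_mean, spec$crt_sd)
  x <- rbind(x_nrt, x_crt)
  colnames(x) <- spec$parameters
  out <- data.frame(
    tooth_id = sprintf("T%03d", seq_len(spec$n_nrt + spec$n_crt)),
    group = rep(c("NRT", "CRT"), c(spec$n_nrt, spec$n_crt)),
    x, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Jittered tooth profiles for a mesh cohort
#'
#' Samples per-tooth profiles around the class defaults (length SD from the
#' published group SDs, ~4% coefficient of variation on the cervical
#' halfwidths) for end-to-end mesh pipelines.
#'
#' @param n number of teeth.
#' @param taper_class `"normal"` or `"conical"`.
#' @param seed integer seed.
#' @param mesh_resolution passed to [tooth_profile()].
#' @return list of [tooth_profile()] objects.
#' @export
sample_tooth_profiles <- function(n, taper_class = c("normal", "conical"),
                                  seed = 1L,
                                  mesh_resolution = c(48L, 48L)) {
  taper_class <- match.arg(taper_class)
  base <- tooth_profile(taper_class, mesh_resolution = mesh_resolution)
  sd_L <- if (taper_class == "normal") 1.19 else 1.54
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tooth_profile(taper_class,
                  root_length = max(6, rnorm(1, base$root_length, sd_L)),
                  cervical_halfwidth_md =
                    base$cervical_halfwidth_md * exp(rnorm(1, 0, 0.04)),
                  cervical_halfwidth_bl =
                    base$cervical_halfwidth_bl * exp(rnorm(1, 0, 0.04)),
                  crown_height = base$crown_height,
                  mesh_resolution = mesh_resolution,
                  seed = seed + i)
  })
}

#' Orthographic silhouette of a tooth mesh
#'
#' Projects the mesh along a viewing direction onto the perpendicular plane
#' and returns the silhouette polygon with the projected apex (G) and
#' mesial/distal CEJ (F, E) landmarks — the input the periapical root-width
#' construction [prw()] expects. The silhouette is taken as the convex hull
#' of the projected vertices, exact for the convex-profiled teeth produced
#' by [generate_tooth()].
#'
#' @param mesh a [tooth_mesh()] with landmarks.
#' @param direction viewing direction (default buccolingual, the periapical
#'   view); must not be parallel to the mesiodistal (x) axis.
#' @return a [radiograph_outline()].
#' @export
project_to_radiograph <- function(mesh, direction = c(0, 1, 0)) {
  if (is.null(mesh$landmarks)) stop("mesh has no landmarks")
  v <- direction / sqrt(sum(direction^2))
  u1 <- c(1, 0, 0) - sum(c(1, 0, 0) * v) * v
  if (sqrt(sum(u1^2)) < 1e-6)
    stop("viewing direction is parallel to the mesiodistal axis")
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(0, 0, 1) - sum(c(0, 0, 1) * v) * v - sum(c(0, 0, 1) * u1) * u1
  if (sqrt(sum(u2^2)) < 1e-6) {
    u2 <- c(0, 1, 0) - sum(c(0, 1, 0) * v) * v - sum(c(0, 1, 0) * u1) * u1
  }
  u2 <- u2 / sqrt(sum(u2^2))
  P <- cbind(mesh$vertices %*% u1, mesh$vertices %*% u2)
  hull <- grDevices::chull(P[, 1], P[, 2])
  if (length(hull) < 3L) stop("empty silhouette")
  proj <- function(p) c(sum(p * u1), sum(p * u2))
  lm <- mesh$landmarks
  for (nm in c("apex", "cej_mesial", "cej_distal"))
    if (is.null(lm[[nm]])) stop("missing landmark: ", nm)
  radiograph_outline(P[hull, , drop = FALSE],
                     G = proj(lm$apex),
                     F_ = proj(lm$cej_mesial),
                     E = proj(lm$cej_distal))
}
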