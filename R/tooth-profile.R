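# Parametric single-root tooth model.
#
# The root is a surface of "elliptical revolution" about the tooth axis (z):
# the cross-section at height z is an ellipse with semi-axes a*g(z)
# (mesiodistal, x) and b*g(z) (buccolingual, y), where g is a dimensionless
# taper profile with g(0) = 1 at the CEJ and g(-L) = 0 at the apex:
#
#   root  (-L+ra <= z <= 0):  g(z) = (1 + z/L)^p
#   apex cap (-L <= z < -L+ra): ellipsoidal cap of axial depth ra blending
#                                the profile smoothly to the apex point
#   crown (0 < z <= H):       g(z) = sqrt(1 - (z/H)^2)  (half-ellipsoid)
#
# p = 0.5 gives the convex, cervically parallel-walled "normal" root;
# p = 1 gives the straight-tapered "conical" root. With equal cervical
# halfwidths the conical profile is strictly narrower than the normal one at
# every interior height, which is the defining contrast between the classes.

#' Parametric tooth profile
#'
#' Describes a synthetic single-root tooth. Default dimensions are chosen so
#' the quadrature ground-truth root volume and surface area fall in the range
#' reported for human maxillary premolars (roughly 200-320 mm^3 and
#' 200-240 mm^2).
#'
#' @param taper_class `"normal"` (p = 0.5) or `"conical"` (p = 1).
#' @param root_length root length L in mm (apex at z = -L).
#' @param cervical_halfwidth_md mesiodistal semi-axis a at the CEJ, mm.
#' @param cervical_halfwidth_bl buccolingual semi-axis b at the CEJ, mm.
#' @param taper_exponent overrides the class default p.
#' @param crown_height crown height H in mm; 0 gives a flat-capped root-only
#'   solid (useful for closed-form oracles).
#' @param apex_radius axial depth of the rounded apex cap, mm; 0 gives a
#'   sharp apex (exact cone for p = 1).
#' @param mesh_resolution integer c(n_axial, n_circumferential), both >= 8.
#' @param seed optional integer recorded with the profile.
#' @return object of class `tooth_profile`.
#' @export
tooth_profile <- function(taper_class = c("normal", "conical"),
                          root_length = NULL,
                          cervical_halfwidth_md = NULL,
                          cervical_halfwidth_bl = NULL,
                          taper_exponent = NULL,
                          crown_height = 6,
                          apex_radius = 0.3,
                          mesh_resolution = c(64L, 64L),
                          seed = NULL) {
  taper_class <- match.arg(taper_class)
  defaults <- switch(taper_class,
    normal  = list(L = 11.62, a = 3.6, b = 4.8, p = 0.5),
    conical = list(L = 11.65, a = 3.75, b = 5.0, p = 1.0))
  if (is.null(root_length)) root_length <- defaults$L
  if (is.null(cervical_halfwidth_md)) cervical_halfwidth_md <- defaults$a
  if (is.null(cervical_halfwidth_bl)) cervical_halfwidth_bl <- defaults$b
  if (is.null(taper_exponent)) taper_exponent <- defaults$p
  if (root_length <= 0) stop("root_length must be > 0")
  if (cervical_halfwidth_md <= 0 || cervical_halfwidth_bl <= 0)
    stop("cervical halfwidths must be > 0")
  if (taper_exponent <= 0) stop("taper_exponent must be > 0")
  if (crown_height < 0 || apex_radius < 0)
    stop("crown_height and apex_radius must be >= 0")
  if (apex_radius >= root_length) stop("apex_radius must be < root_length")
  mesh_resolution <- as.integer(mesh_resolution)
  if (length(mesh_resolution) != 2L || any(mesh_resolution < 8L))
    stop("mesh_resolution must be two integers >= 8")
  structure(list(root_length = root_length,
                 cervical_halfwidth_md = cervical_halfwidth_md,
                 cervical_halfwidth_bl = cervical_halfwidth_bl,
                 taper_class = taper_class,
                 taper_exponent = taper_exponent,
                 crown_height = crown_height,
                 apex_radius = apex_radius,
                 mesh_resolution = mesh_resolution,
                 seed = seed),
            class = "tooth_profile")
}

# taper profile g(z) on [-L, H], vectorised
profile_g <- function(profile, z) {
  L <- profile$root_length; ra <- profile$apex_radius
  H <- profile$crown_height; p <- profile$taper_exponent
  zc <- -(L - ra)
  fc <- if (ra > 0) (ra / L)^p else 0
  g <- numeric(length(z))
  i_cap <- z < zc
  i_root <- z >= zc & z <= 0
  i_crown <- z > 0
  if (any(i_cap))
    g[i_cap] <- fc * sqrt(pmax(0, 1 - ((zc - z[i_cap]) / ra)^2))
  if (any(i_root)) g[i_root] <- (1 + z[i_root] / L)^p
  if (any(i_crown)) {
    if (H <= 0) stop("z above CEJ but crown_height is 0")
    g[i_crown] <- sqrt(pmax(0, 1 - (z[i_crown] / H)^2))
  }
  g
}

# g(z) * g'(z), analytic per region (finite everywhere, unlike g' alone)
profile_gg1 <- function(profile, z) {
  L <- profile$root_length; ra <- profile$apex_radius
  H <- profile$crown_height; p <- profile$taper_exponent
  zc <- -(L - ra)
  fc <- if (ra > 0) (ra / L)^p else 0
  out <- numeric(length(z))
  i_cap <- z < zc
  i_root <- z >= zc & z <= 0
  i_crown <- z > 0
  if (any(i_cap)) out[i_cap] <- fc^2 * (zc - z[i_cap]) / ra^2
  if (any(i_root)) out[i_root] <- (p / L) * (1 + z[i_root] / L)^(2 * p - 1)
  if (any(i_crown)) out[i_crown] <- -z[i_crown] / H^2
  out
}

# lateral surface area of the profile solid between z0 and z1 by 1D (adaptive)
# x 2D (periodic trapezoid) quadrature of the parametric surface integral
profile_lateral_area <- function(profile, z0, z1, n_theta = 720L) {
  a <- profile$cervical_halfwidth_md
  b <- profile$cervical_halfwidth_bl
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  B <- b^2 * cos(theta)^2 + a^2 * sin(theta)^2
  integrand <- function(z) {
    g <- profile_g(profile, z)
    gg1 <- profile_gg1(profile, z)
    # |S_z x S_theta| = sqrt(g^2 (b^2 cos^2 + a^2 sin^2) + (a b g g')^2)
    m <- sqrt(outer(g^2, B) + (a * b * gg1)^2)
    rowSums(m) * (2 * pi / n_theta)
  }
  # integrate per smooth region to keep the adaptive rule efficient
  L <- profile$root_length; ra <- profile$apex_radius
  brk <- sort(unique(pmax(z0, pmin(z1, c(z0, -(L - ra), 0, z1)))))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    if (brk[i + 1] - brk[i] < 1e-12) next
    total <- total + integrate(integrand, brk[i], brk[i + 1],
                               rel.tol = 1e-9, subdivisions = 500L)$value
  }
  total
}

# enclosed volume of the profile solid between z0 and z1 (cross-section is an
# ellipse of area pi * a * b * g(z)^2)
profile_volume <- function(profile, z0, z1) {
  a <- profile$cervical_halfwidth_md
  b <- profile$cervical_halfwidth_bl
  L <- profile$root_length; ra <- profile$apex_radius
  brk <- sort(unique(pmax(z0, pmin(z1, c(z0, -(L - ra), 0, z1)))))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    if (brk[i + 1] - brk[i] < 1e-12) next
    total <- total + integrate(function(z) pi * a * b *
                                 profile_g(profile, z)^2,
                               brk[i], brk[i + 1],
                               rel.tol = 1e-10, subdivisions = 500L)$value
  }
  total
}

#' Ground-truth root metrics of a tooth profile
#'
#' Quadrature reference values for the root portion (below the CEJ plane):
#' lateral surface area (the root surface excluding the CEJ truncation cap,
#' i.e. the quantity RSA estimates) and enclosed volume (RV), plus the exact
#' root length RL.
#'
#' @param profile a [tooth_profile()].
#' @return list with `RL` (mm), `root_lateral_area` (mm^2), `root_volume`
#'   (mm^3).
#' @export
profile_ground_truth <- function(profile) {
  L <- profile$root_length
  list(RL = L,
       root_lateral_area = profile_lateral_area(profile, -L, 0),
       root_volume = profile_volume(profile, -L, 0))
}
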