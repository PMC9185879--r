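# Fixture builders and independent oracles, all constructed in code.

# unit cube [0,1]^3, outward orientation
make_cube <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  F <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(1, 5, 8), c(1, 8, 4),   # left (-x)
             c(2, 3, 7), c(2, 7, 6))   # right (+x)
  tooth_mesh(V, F)
}

# UV sphere of radius r, consistent outward orientation
make_sphere <- function(r, n = 40, center = c(0, 0, 0)) {
  th <- seq(0, pi, length.out = n + 1)
  nc <- 2L * n
  ph <- 2 * pi * (0:(nc - 1)) / nc
  V <- rbind(c(0, 0, -r))
  for (i in n:2)
    V <- rbind(V, cbind(r * sin(th[i]) * cos(ph), r * sin(th[i]) * sin(ph),
                        r * cos(th[i])))
  V <- rbind(V, c(0, 0, r))
  ring <- function(i) 1L + (i - 1L) * nc + 1:nc
  nx <- c(2:nc, 1)
  r1 <- ring(1)
  Fs <- cbind(1, r1[nx], r1)
  for (i in 1:(n - 2)) {
    lo <- ring(i); up <- ring(i + 1)
    Fs <- rbind(Fs, cbind(lo, lo[nx], up[nx]), cbind(lo, up[nx], up))
  }
  rt <- ring(n - 1)
  Fs <- rbind(Fs, cbind(nrow(V), rt, rt[nx]))
  tooth_mesh(sweep(V, 2, center, `+`), Fs)
}

# closed cone (lateral + base), apex at z = -h, base disc at z = 0
make_cone <- function(r, h, n = 128) {
  generate_tooth(tooth_profile("conical", root_length = h,
                               cervical_halfwidth_md = r,
                               cervical_halfwidth_bl = r,
                               crown_height = 0, apex_radius = 0,
                               mesh_resolution = c(max(n %/% 2, 8), n)))
}

# Independent midpoint-Riemann oracle for the lateral area and volume of the
# elliptical power-profile solid r(z) = (a, b) * (1 + z/L)^p on [-L, 0];
# numeric partial derivatives, no shared code with the package quadrature.
riemann_profile_oracle <- function(a, b, L, p, nz = 1200, nth = 1200) {
  zm <- -L + (seq_len(nz) - 0.5) * (L / nz)
  th <- (seq_len(nth) - 0.5) * (2 * pi / nth)
  g <- function(z) (1 + z / L)^p
  hz <- L / nz * 1e-3
  S <- function(z, th) list(x = outer(g(z), cos(th)) * a,
                            y = outer(g(z), sin(th)) * b,
                            z = matrix(z, length(z), length(th)))
  s1 <- S(zm + hz, th); s0 <- S(zm - hz, th)
  dz <- list(x = (s1$x - s0$x) / (2 * hz), y = (s1$y - s0$y) / (2 * hz),
             z = (s1$z - s0$z) / (2 * hz))
  hth <- 2 * pi / nth * 1e-3
  t1 <- S(zm, th + hth); t0 <- S(zm, th - hth)
  dt <- list(x = (t1$x - t0$x) / (2 * hth), y = (t1$y - t0$y) / (2 * hth),
             z = (t1$z - t0$z) / (2 * hth))
  cx <- dz$y * dt$z - dz$z * dt$y
  cy <- dz$z * dt$x - dz$x * dt$z
  cz <- dz$x * dt$y - dz$y * dt$x
  area <- sum(sqrt(cx^2 + cy^2 + cz^2)) * (L / nz) * (2 * pi / nth)
  vol <- sum(pi * a * b * g(zm)^2) * (L / nz)
  list(area = area, volume = vol)
}

# brute-force pairwise Mann-Whitney AUC (lower value => CRT positive)
brute_auc <- function(crt, nrt) {
  mean(outer(crt, nrt, `<`) + 0.5 * outer(crt, nrt, `==`))
}

# exhaustive Youden search over midpoint thresholds (value < cutoff => CRT)
brute_youden <- function(crt, nrt) {
  v <- sort(unique(c(crt, nrt)))
  cand <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  yi <- vapply(cand, function(cc)
    mean(crt < cc) + mean(nrt >= cc) - 1, numeric(1))
  best <- which(yi >= max(yi) - 1e-12)[1]
  list(cutoff = cand[best], yi = yi[best])
}

# trapezoidal area under an roc_auc() curve
trapezoid_auc <- function(roc) {
  cv <- roc$curve
  sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
}

# random rigid transform (uniform rotation via QR, bounded translation)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  structure(list(rotation = q, translation = runif(3, -10, 10), rmse = 0),
            class = "rigid_transform")
}
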