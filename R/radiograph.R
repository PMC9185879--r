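# Periapical root-width parameter (PRW).
#
# On a 2D root silhouette with apex G and mesial/distal CEJ points F, E:
# B and C are the midpoints of chords GF and GE; the line through B and C,
# extended both ways, meets the mesial margin at A and the distal margin at
# D; PRW = (|AD| - |BC|)/2. Straight (conical) margins give PRW = 0; margins
# bulging outward beyond the chords give PRW > 0.

#' Construct a radiograph outline
#'
#' @param polygon ordered 2D vertices (mm) of the closed silhouette (closing
#'   edge implicit).
#' @param G apex point.
#' @param F_ mesial CEJ point (named `F_` to avoid the `F`/`FALSE` clash).
#' @param E distal CEJ point.
#' @param validate check that G, F, E lie within 0.5 mm of the polygon.
#' @return object of class `radiograph_outline`.
#' @export
radiograph_outline <- function(polygon, G, F_, E, validate = TRUE) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon must be an n x 2 matrix with n >= 3")
  G <- as.numeric(G); F_ <- as.numeric(F_); E <- as.numeric(E)
  if (validate) {
    for (nm in c("G", "F_", "E")) {
      p <- get(nm)
      if (point_polygon_distance(p, polygon) > 0.5)
        stop(sprintf("landmark %s is more than 0.5 mm from the outline",
                     sub("_$", "", nm)))
    }
  }
  structure(list(polygon = polygon, G = G, F_ = F_, E = E),
            class = "radiograph_outline")
}

# distance from a point to the closed polyline of a polygon
point_polygon_distance <- function(p, poly) {
  n <- nrow(poly)
  q1 <- poly
  q2 <- poly[c(2:n, 1), , drop = FALSE]
  e <- q2 - q1
  w <- cbind(p[1] - q1[, 1], p[2] - q1[, 2])
  len2 <- rowSums(e^2)
  t <- pmin(1, pmax(0, ifelse(len2 > 0, rowSums(w * e) / len2, 0)))
  dx <- w[, 1] - t * e[, 1]
  dy <- w[, 2] - t * e[, 2]
  sqrt(min(dx^2 + dy^2))
}

#' Root-width parameter from a silhouette
#'
#' Implements the periapical construction: `B = midpoint(G, F)`,
#' `C = midpoint(G, E)`; the line through B and C is extended until it meets
#' the root margins at A (mesial) and D (distal);
#' `PRW = (|AD| - |BC|)/2`. If the line crosses a margin more than once the
#' crossing nearest to B (mesial side) / C (distal side) is used. Concave
#' margins can give a small negative PRW, which is reported as computed.
#'
#' @param outline a [radiograph_outline()].
#' @return list with `prw` (mm), the construction points `A`, `B`, `C`, `D`,
#'   and the chord lengths `AD`, `BC`.
#' @export
prw <- function(outline) {
  stopifnot(inherits(outline, "radiograph_outline"))
  G <- outline$G; F_ <- outline$F_; E <- outline$E
  B <- (G + F_) / 2
  C <- (G + E) / 2
  r <- C - B
  bc <- sqrt(sum(r^2))
  if (bc < 1e-9) stop("degenerate construction: B and C coincide")

  poly <- outline$polygon
  n <- nrow(poly)
  q1 <- poly
  q2 <- poly[c(2:n, 1), , drop = FALSE]
  e <- q2 - q1
  qb <- cbind(q1[, 1] - B[1], q1[, 2] - B[2])
  denom <- r[1] * e[, 2] - r[2] * e[, 1]
  s <- (qb[, 1] * e[, 2] - qb[, 2] * e[, 1]) / denom
  t <- (qb[, 1] * r[2] - qb[, 2] * r[1]) / denom
  hit <- is.finite(s) & is.finite(t) & t >= 0 & t < 1
  s <- s[hit]
  if (length(s) == 0L) stop("line BC does not intersect the outline")
  s_a <- s[s < 0.5]
  s_d <- s[s >= 0.5]
  if (length(s_a) == 0L || length(s_d) == 0L)
    stop("line BC fails to intersect both root margins")
  sA <- max(s_a)   # crossing nearest B on the mesial side
  sD <- min(s_d)   # crossing nearest C on the distal side
  A <- B + sA * r
  D <- B + sD * r
  ad <- (sD - sA) * bc
  list(prw = (ad - bc) / 2, A = A, B = B, C = C, D = D, AD = ad, BC = bc)
}
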