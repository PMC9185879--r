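# Per-tooth 3D metrics: RL, RSA, RV and the length-normalised indices.

#' Root length from landmarks
#'
#' Euclidean distance from the apex to the midpoint of the chord joining the
#' buccal and lingual CEJ landmarks.
#'
#' @param mesh a [tooth_mesh()] with `apex`, `cej_buccal`, `cej_lingual`
#'   landmarks (a bare named list of landmarks is also accepted).
#' @return RL in mm.
#' @export
root_length <- function(mesh) {
  lm <- if (inherits(mesh, "tooth_mesh")) mesh$landmarks else mesh
  for (nm in c("apex", "cej_buccal", "cej_lingual"))
    if (is.null(lm[[nm]])) stop("missing landmark: ", nm)
  mid <- (lm$cej_buccal + lm$cej_lingual) / 2
  sqrt(sum((lm$apex - mid)^2))
}

#' Root surface area from the three closed-object areas
#'
#' `RSA = (S_MT + S_MR - S_MC) / 2`: with `S_MT = S_R + S_C`,
#' `S_MR = S_R + S_S1` and `S_MC = S_C + S_S1` (outer root area S_R, outer
#' crown area S_C, shared truncation cap S_S1), the half-sum isolates the
#' root's outer surface S_R exactly.
#'
#' @param s_mt,s_mr,s_mc surface areas (mm^2) of the closed whole-tooth,
#'   root and crown objects.
#' @return RSA in mm^2.
#' @export
root_surface_area <- function(s_mt, s_mr, s_mc) {
  if (any(c(s_mt, s_mr, s_mc) < 0)) stop("areas must be >= 0")
  rsa <- (s_mt + s_mr - s_mc) / 2
  if (rsa < 0)
    stop("inconsistent areas: (S_MT + S_MR - S_MC)/2 is negative")
  rsa
}

#' Full metric record for an annotated tooth mesh
#'
#' Fits/uses the CEJ plane, splits the tooth into closed crown and root
#' objects, and assembles RL, RSA, RV, RSA/RL and RV/RL. Ratios are computed
#' at full precision; use [format_metrics()] for 2-decimal reporting.
#'
#' @param mesh a closed, landmark-annotated [tooth_mesh()].
#' @param label optional group label (`"NRT"`, `"CRT"` or `"unknown"`).
#' @return object of class `root_metrics`: list with `RL`, `RSA`, `RV`,
#'   `RSA_RL`, `RV_RL`, the intermediate areas `S_MT`, `S_MR`, `S_MC`,
#'   `S_S1`, and `label`.
#' @export
compute_metrics <- function(mesh, label = "unknown") {
  stopifnot(inherits(mesh, "tooth_mesh"))
  if (!is_closed_mesh(mesh)) {
    mesh <- repair_mesh(mesh)
    if (!is_closed_mesh(mesh))
      stop(sprintf("mesh is not closed after repair (%d open edges)",
                   open_edge_count(mesh)))
  }
  rl <- root_length(mesh)
  if (rl < 1e-9) stop("root length is zero: apex coincides with the CEJ chord")
  sp <- split_tooth(mesh)
  s_mt <- surface_area(mesh)
  s_mr <- surface_area(sp$root)
  s_mc <- surface_area(sp$crown)
  rsa <- root_surface_area(s_mt, s_mr, s_mc)
  rv <- enclosed_volume(sp$root)
  structure(list(RL = rl, PRW = NA_real_, RSA = rsa, RV = rv,
                 RSA_RL = rsa / rl, RV_RL = rv / rl,
                 S_MT = s_mt, S_MR = s_mr, S_MC = s_mc, S_S1 = sp$S_S1,
                 label = label),
            class = "root_metrics")
}

#' @export
print.root_metrics <- function(x, ...) {
  cat(sprintf(
    "<root_metrics> [%s] RL %.2f mm, RSA %.2f mm^2, RV %.2f mm^3, RSA/RL %.2f, RV/RL %.2f\n",
    x$label, x$RL, x$RSA, x$RV, x$RSA_RL, x$RV_RL))
  invisible(x)
}

#' Format a metric record at reporting precision
#'
#' @param x a `root_metrics` object or data.frame of metrics.
#' @param digits decimal places (default 2, the reporting convention).
#' @return data.frame of rounded values.
#' @export
format_metrics <- function(x, digits = 2) {
  if (inherits(x, "root_metrics"))
    x <- as.data.frame(x[c("RL", "PRW", "RSA", "RV", "RSA_RL", "RV_RL",
                           "label")])
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], round, digits = digits)
  x
}
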