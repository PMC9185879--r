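# File formats: STL (binary/ASCII), PLY with per-vertex colour, landmark
# JSON sidecars, cohort / outline / distance CSVs. All coordinates in mm.

#' Write a mesh to STL
#'
#' @param mesh a [tooth_mesh()].
#' @param path output file.
#' @param binary write binary STL (default) or ASCII.
#' @param name solid name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE, name = "rootmorph") {
  V <- mesh$vertices
  F <- mesh$faces
  n <- face_cross(V, F)
  len <- sqrt(rowSums(n^2))
  n <- n / pmax(len, 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste0("binary STL ", name)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    # 12 floats per facet + attribute byte count
    tri <- cbind(n,
                 V[F[, 1], , drop = FALSE],
                 V[F[, 2], , drop = FALSE],
                 V[F[, 3], , drop = FALSE])
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    fmt_v <- function(p) sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3])
    lines <- character(0)
    out <- vector("list", nrow(F))
    for (i in seq_len(nrow(F))) {
      out[[i]] <- c(sprintf("  facet normal %.9g %.9g %.9g",
                            n[i, 1], n[i, 2], n[i, 3]),
                    "    outer loop",
                    fmt_v(V[F[i, 1], ]), fmt_v(V[F[i, 2], ]),
                    fmt_v(V[F[i, 3], ]),
                    "    endloop", "  endfacet")
    }
    writeLines(c(paste("solid", name), unlist(out), paste("endsolid", name)),
               con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII, auto-detected)
#'
#' Coincident facet corners are merged into shared vertices so the result is
#' a connected mesh suitable for closedness checks and volume computation.
#'
#' @param path STL file.
#' @param merge_tol vertex merge tolerance in mm.
#' @return a [tooth_mesh()] (without landmarks).
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid") && {
    # binary files may also start with "solid"; check facet count coherence
    sz <- file.info(path)$size
    con <- file(path, "rb")
    seek(con, 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    close(con)
    !is.finite(nf) || sz != 84 + nf * 50
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    raw_all <- readBin(con, "raw", n = nf * 50)
    m <- matrix(raw_all, nrow = 50)
    fl <- readBin(as.raw(m[1:48, ]), "numeric", n = 12L * nf, size = 4,
                  endian = "little")
    tri <- matrix(fl, ncol = 12, byrow = TRUE)
    xyz <- rbind(tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE],
                 tri[, 10:12, drop = FALSE])
    # interleave back to per-facet order
    ord <- as.vector(t(matrix(seq_len(3 * nf), nrow = nf)))
    xyz <- xyz[ord, , drop = FALSE]
  }
  if (is.null(xyz) || nrow(xyz) %% 3L != 0L) stop("malformed STL: ", path)
  nfac <- nrow(xyz) / 3L
  key <- paste(round(xyz[, 1] / merge_tol), round(xyz[, 2] / merge_tol),
               round(xyz[, 3] / merge_tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  tooth_mesh(xyz[first, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write landmarks as a JSON sidecar
#'
#' Format: an object mapping landmark names to `[x, y, z]` in mm.
#'
#' @param landmarks named list of length-3 points.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, function(p) round(unname(p), 9)),
                       path, digits = NA)
  invisible(path)
}

#' Read a landmark JSON sidecar
#'
#' @param path JSON file from [write_landmarks()].
#' @return named list of length-3 numeric points.
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, as.numeric)
}

#' Write a cohort table as CSV
#'
#' Header comment lines record the seed and configuration hash so every
#' artifact is traceable to its run.
#'
#' @param cohort data.frame from [generate_cohort()] or measured metrics.
#' @param path output file.
#' @param seed integer seed to record (optional).
#' @param config_hash configuration hash to record (optional).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config_hash)) writeLines(paste("# config:", config_hash), con)
  write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV (skipping `#` comment headers)
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a 2D outline as CSV (x,y per row, closed implicitly)
#'
#' @param outline a [radiograph_outline()] or n x 2 matrix.
#' @param path output CSV; landmarks (if present) go to a JSON sidecar named
#'   `<path>.landmarks.json` with keys G, F, E.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(outline, path) {
  poly <- if (inherits(outline, "radiograph_outline")) outline$polygon
          else as.matrix(outline)
  df <- data.frame(x = poly[, 1], y = poly[, 2])
  write.csv(df, path, row.names = FALSE)
  if (inherits(outline, "radiograph_outline"))
    jsonlite::write_json(list(G = unname(outline$G), F = unname(outline$F_),
                              E = unname(outline$E)),
                         paste0(path, ".landmarks.json"), digits = NA)
  invisible(path)
}

#' Read a 2D outline CSV (+ optional landmark sidecar)
#'
#' @param path CSV from [write_outline_csv()].
#' @return a [radiograph_outline()] if the landmark sidecar exists, else a
#'   plain matrix.
#' @export
read_outline_csv <- function(path) {
  df <- read.csv(path)
  poly <- as.matrix(df[, c("x", "y")])
  lm_path <- paste0(path, ".landmarks.json")
  if (file.exists(lm_path)) {
    lm <- jsonlite::read_json(lm_path, simplifyVector = TRUE)
    radiograph_outline(poly, G = as.numeric(lm$G), F_ = as.numeric(lm$F),
                       E = as.numeric(lm$E))
  } else poly
}

#' Write a colour-mapped mesh as ASCII PLY
#'
#' @param mesh a [tooth_mesh()] (typically the colour map's reference).
#' @param path output file.
#' @param colours n x 3 integer RGB matrix (0-255), one row per vertex.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, colours = NULL) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  has_col <- !is.null(colours)
  hdr <- c("ply", "format ascii 1.0", "comment rootmorph colour map",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (has_col) {
    writeLines(sprintf("%.9g %.9g %.9g %d %d %d", V[, 1], V[, 2], V[, 3],
                       colours[, 1], colours[, 2], colours[, 3]), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  }
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
             con)
  invisible(path)
}

#' Write signed distances as CSV
#'
#' @param map a `colour_map` from [distance_colour_map()].
#' @param path output CSV with columns `vertex_id`, `signed_distance_mm`.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(map, path) {
  write.csv(data.frame(vertex_id = seq_along(map$distance),
                       signed_distance_mm = map$distance),
            path, row.names = FALSE)
  invisible(path)
}
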