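# STL reading and writing (binary and ASCII), with vertex welding.
#
# STL stores each facet's three corners as independent float32 triples, so a
# shared edge appears as duplicated coordinates; on read we merge vertices
# whose coordinates agree within a tolerance so that edges become
# topological, not just coincident.

STL_MERGE_TOL <- 1e-6  # mm; STL is float32, clinical scale is ~1-10 mm

# quantised merge of duplicated vertex coordinates
weld_vertices <- function(coords, faces_raw, tol = STL_MERGE_TOL) {
  q <- round(coords / tol)
  key <- paste(q[, 1L], q[, 2L], q[, 3L], sep = "/")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  vertices <- coords[first, , drop = FALSE]
  faces <- matrix(idx[faces_raw], ncol = 3L)
  # facets collapsed to a line or point by welding are dropped
  keep <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
    faces[, 1L] != faces[, 3L]
  triangle_mesh(vertices, faces[keep, , drop = FALSE])
}

#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (auto-detected) and welds duplicated facet
#' corners into shared vertices (exact-coordinate merge within 1e-6 mm).
#' Units are taken as millimetres; STL carries no unit metadata.
#'
#' @param path path to an `.stl` file
#' @return a [triangle_mesh()]
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) abort_io("STL file not found: %s", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 15) {
    abort_io("file too short to be STL (%s bytes): %s", format(size), path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 84))
  is_binary <- FALSE
  if (size >= 84) {
    count <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(count) && count >= 0 && size == 84 + 50 * as.numeric(count)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    count <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (count == 0L) abort_io("empty STL (0 facets): %s", path)
    body <- readBin(con, "raw", n = 50 * as.numeric(count))
    if (length(body) != 50 * count) {
      abort_io("malformed binary STL: truncated at byte %d of %s",
               84 + length(body), path)
    }
    # 12 float32 per facet (normal + 3 corners), then 2 attribute bytes
    float_idx <- as.vector(outer(1:48, (0:(count - 1)) * 50, "+"))
    vals <- readBin(body[float_idx], "numeric", size = 4,
                    n = 12 * count, endian = "little")
    m <- matrix(vals, ncol = 12, byrow = TRUE)
    coords <- rbind(m[, 4:6, drop = FALSE],
                    m[, 7:9, drop = FALSE],
                    m[, 10:12, drop = FALSE])
    # corner order: facet i occupies rows i, i+count, i+2*count
    faces_raw <- cbind(seq_len(count), seq_len(count) + count,
                       seq_len(count) + 2L * count)
  } else {
    txt <- readLines(path, warn = FALSE)
    if (length(txt) == 0L || !grepl("^\\s*solid", txt[1L])) {
      abort_io("malformed STL: neither valid binary layout nor 'solid' header (line 1) in %s",
               path)
    }
    vlines <- grep("^\\s*vertex\\s", txt)
    if (length(vlines) == 0L) abort_io("empty STL (no vertices): %s", path)
    if (length(vlines) %% 3L != 0L) {
      abort_io("malformed ASCII STL: vertex count %d not a multiple of 3 (near line %d) in %s",
               length(vlines), vlines[length(vlines)], path)
    }
    parts <- strsplit(trimws(txt[vlines]), "\\s+")
    nums <- suppressWarnings(
      vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(nums)) {
      bad <- vlines[which(apply(is.na(nums), 2L, any))[1L]]
      abort_io("malformed ASCII STL: unparseable vertex at line %d of %s",
               bad, path)
    }
    coords <- t(nums)
    nf <- nrow(coords) / 3L
    faces_raw <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  }
  mesh <- weld_vertices(coords, faces_raw)
  if (n_faces(mesh) == 0L) abort_io("empty STL (no usable facets): %s", path)
  mesh
}

#' Write a mesh to STL
#'
#' @param mesh a nonempty [triangle_mesh()]
#' @param path output path
#' @param dialect `"binary"` (default; bit-stable for identical input) or
#'   `"ascii"`
#' @return `path`, invisibly
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (!inherits(mesh, "triangle_mesh") || n_faces(mesh) == 0L) {
    abort_validation("cannot write an empty mesh to STL")
  }
  fc <- face_corners(mesh)
  nrm <- face_normals(mesh)
  nf <- n_faces(mesh)
  if (dialect == "binary") {
    con <- tryCatch(file(path, "wb"),
                    error = function(e) abort_io("cannot open %s for writing", path))
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "aneumorph binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # interleave normal + corners per facet: nf x 12 float matrix
    block <- cbind(nrm, fc$a, fc$b, fc$c)
    floats <- as.vector(t(block))
    fr <- writeBin(floats, raw(), size = 4, endian = "little")
    fr <- matrix(fr, ncol = 48, byrow = TRUE)
    attr2 <- matrix(as.raw(0L), nrow = nf, ncol = 2)
    writeBin(as.vector(t(cbind(fr, attr2))), con)
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1L], m[, 2L], m[, 3L])
    lines <- c("solid aneumorph",
               as.vector(rbind(paste("  facet normal", fmt(nrm)),
                               "    outer loop",
                               paste("      vertex", fmt(fc$a)),
                               paste("      vertex", fmt(fc$b)),
                               paste("      vertex", fmt(fc$c)),
                               "    endloop",
                               "  endfacet")),
               "endsolid aneumorph")
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort_io("cannot write ASCII STL to %s", path)
  }
  invisible(path)
}
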