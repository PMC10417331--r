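#' Construct a triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates, mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param clean Drop degenerate (zero-area or repeated-index) triangles
#'   instead of failing; used by the file readers as load cleanup.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, clean = FALSE) {
  vertices <- as_points_matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices))) {
    stop("triangle vertex indices out of range", call. = FALSE)
  }
  degen <- triangles[, 1L] == triangles[, 2L] | triangles[, 2L] == triangles[, 3L] |
    triangles[, 1L] == triangles[, 3L]
  if (nrow(triangles) > 0L && !any(is.na(degen))) {
    a <- vertices[triangles[, 2L], , drop = FALSE] - vertices[triangles[, 1L], , drop = FALSE]
    b <- vertices[triangles[, 3L], , drop = FALSE] - vertices[triangles[, 1L], , drop = FALSE]
    cr <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
    degen <- degen | sqrt(rowSums(cr^2)) < 1e-12
  }
  if (any(degen)) {
    if (!clean) stop(sprintf("%d degenerate (zero-area) triangle(s)", sum(degen)),
                     call. = FALSE)
    triangles <- triangles[!degen, , drop = FALSE]
  }
  structure(list(vertices = vertices, triangles = triangles), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Total triangle area of a mesh
#'
#' @param mesh A `surface_mesh`.
#' @param triangles Optional triangle indices to restrict to (e.g. a region
#'   from [generate_cup_mesh()]).
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh, triangles = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tri <- mesh$triangles
  if (!is.null(triangles)) tri <- tri[triangles, , drop = FALSE]
  a <- mesh$vertices[tri[, 2L], , drop = FALSE] - mesh$vertices[tri[, 1L], , drop = FALSE]
  b <- mesh$vertices[tri[, 3L], , drop = FALSE] - mesh$vertices[tri[, 1L], , drop = FALSE]
  cr <- cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
              a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
              a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

parse_coordinate_system <- function(token, path) {
  token <- toupper(trimws(token))
  if (token %in% c("RAS", "0")) return("RAS")
  if (token %in% c("LPS", "1")) return("LPS")
  stop(sprintf("unknown coordinate system '%s' in %s (expected RAS/LPS/0/1)", token, path),
       call. = FALSE)
}

head_point_label <- function(nm) grepl("^head(_point)?_?[0-9]*$", nm)

#' Read anatomical landmarks from a markups file
#'
#' Supports the two common markups dialects exported by segmentation
#' software: fiducial CSV (`.fcsv`, with a `# CoordinateSystem` header) and
#' markups JSON (`.mrk.json` / `.json`). Labels are matched
#' case-insensitively against the [landmark_aliases()] table; labels of the
#' form `head`, `head_12` or `head_point_3` are collected into the femoral
#' head point cloud; all other unknown labels are kept as free-form extras.
#' Coordinates are normalized to RAS at this boundary.
#'
#' @param path Input file path.
#' @param format `"fcsv"`, `"markups_json"`, or `"auto"` (by file extension,
#'   falling back to content sniffing).
#' @param case_id Case identifier recorded in the result (defaults to the
#'   file base name).
#' @param intact_side `"left"` or `"right"`.
#' @return A `landmark_set` in RAS millimetres.
#' @export
read_landmarks <- function(path, format = c("auto", "fcsv", "markups_json"),
                           case_id = NULL, intact_side = c("left", "right")) {
  format <- match.arg(format)
  intact_side <- match.arg(intact_side)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    lower <- tolower(path)
    format <- if (grepl("\\.fcsv$", lower)) "fcsv"
    else if (grepl("\\.json$", lower)) "markups_json"
    else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) > 0L && grepl("^\\s*\\{", first)) "markups_json" else "fcsv"
    }
  }
  case_id <- case_id %||% sub("\\.(mrk\\.)?(fcsv|json)$", "", basename(path))
  parsed <- switch(format,
                   fcsv = read_fcsv_points(path),
                   markups_json = read_markups_json_points(path))
  labels <- vapply(parsed$labels, normalize_landmark_name, character(1L), USE.NAMES = FALSE)
  is_head <- head_point_label(labels)
  lm <- parsed$points[!is_head, , drop = FALSE]
  rownames(lm) <- labels[!is_head]
  head_points <- if (any(is_head)) parsed$points[is_head, , drop = FALSE] else NULL
  landmark_set(lm, case_id = case_id, coordinate_system = parsed$coordinate_system,
               head_points = head_points, intact_side = intact_side)
}

read_fcsv_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("empty fcsv file: %s", path), call. = FALSE)
  header <- grep("^#", lines, value = TRUE)
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  coordinate_system <- if (length(cs_line) == 0L) "LPS"  # modern default
  else parse_coordinate_system(sub(".*=", "", cs_line[1L]), path)
  rows <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(rows) == 0L) stop(sprintf("no fiducial rows in %s", path), call. = FALSE)
  fields <- strsplit(rows, ",")
  pts <- t(vapply(fields, function(f) {
    if (length(f) < 4L) stop(sprintf("malformed fcsv row in %s: '%s'", path,
                                     paste(f, collapse = ",")), call. = FALSE)
    as.numeric(f[2:4])
  }, numeric(3L)))
  if (!all(is.finite(pts))) stop(sprintf("non-numeric coordinates in %s", path), call. = FALSE)
  labels <- vapply(fields, function(f) {
    lbl <- if (length(f) >= 12L) trimws(f[[12L]]) else ""
    if (lbl == "") f[[1L]] else lbl
  }, character(1L))
  list(points = pts, labels = labels, coordinate_system = coordinate_system)
}

read_markups_json_points <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop(sprintf("cannot parse markups JSON %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (is.null(doc$markups)) stop(sprintf("missing 'markups' field in %s", path), call. = FALSE)
  labels <- character(0L)
  pts <- matrix(0, 0L, 3L)
  cs <- NULL
  for (mk in doc$markups) {
    cs <- cs %||% mk$coordinateSystem
    for (cp in mk$controlPoints) {
      if (is.null(cp$position)) stop(sprintf("control point without 'position' in %s", path),
                                     call. = FALSE)
      labels <- c(labels, cp$label %||% sprintf("point_%d", length(labels) + 1L))
      pts <- rbind(pts, as.numeric(unlist(cp$position)))
    }
  }
  if (nrow(pts) == 0L) stop(sprintf("no control points in %s", path), call. = FALSE)
  list(points = pts, labels = labels,
       coordinate_system = parse_coordinate_system(cs %||% "LPS", path))
}

#' Write a landmark set to a markups file
#'
#' Coordinates are written in RAS with an explicit coordinate-system header
#' (fcsv) or field (JSON). Head points are written with labels `head_001`,
#' `head_002`, ... so [read_landmarks()] recovers them.
#'
#' @param x A `landmark_set`.
#' @param path Output path.
#' @param format `"fcsv"` or `"markups_json"`.
#' @return Invisibly `path`.
#' @export
write_landmarks <- function(x, path, format = c("fcsv", "markups_json")) {
  stopifnot(inherits(x, "landmark_set"))
  format <- match.arg(format)
  labels <- rownames(x$landmarks)
  pts <- x$landmarks
  if (!is.null(x$head_points)) {
    labels <- c(labels, sprintf("head_%03d", seq_len(nrow(x$head_points))))
    pts <- rbind(pts, x$head_points)
  }
  if (format == "fcsv") {
    lines <- c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = RAS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
    rows <- sprintf("%s,%.9g,%.9g,%.9g,0,0,0,1,1,1,0,%s,,",
                    paste0("F_", seq_len(nrow(pts))),
                    pts[, 1L], pts[, 2L], pts[, 3L], labels)
    writeLines(c(lines, rows), path)
  } else {
    cps <- lapply(seq_len(nrow(pts)), function(i) {
      list(id = as.character(i), label = labels[i],
           position = as.numeric(pts[i, ]))
    })
    doc <- list(markups = list(list(type = "Fiducial", coordinateSystem = "RAS",
                                    controlPoints = cps)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a surface mesh from an STL file
#'
#' Both binary and ASCII STL encodings are detected automatically. Duplicate
#' vertices shared between facets are merged exactly, and degenerate
#' (zero-area) triangles are dropped as load cleanup. Coordinates are assumed
#' to be millimetres (no unit autodetection).
#'
#' @param path STL file path.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  size <- file.size(path)
  if (size == 0L) stop(sprintf("STL parse error in %s: empty file (byte offset 0)", path),
                       call. = FALSE)
  head_raw <- readBin(path, "raw", n = min(size, 512L))
  # keep printable ASCII only: binary headers may hold arbitrary bytes
  head_txt <- rawToChar(head_raw[head_raw >= as.raw(0x20) & head_raw <= as.raw(0x7e)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  size <- file.size(path)
  if (size < 84) {
    stop(sprintf("STL parse error in %s: truncated header (byte offset %d of 84)", path, size),
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * n
  if (n < 0 || size < expected) {
    stop(sprintf("STL parse error in %s: %d facets declared but file ends at byte %d (expected %d)",
                 path, n, size, expected), call. = FALSE)
  }
  body <- readBin(con, "raw", n = 50L * n)
  rec_off <- rep((seq_len(n) - 1L) * 50L, each = 48L)
  float_bytes <- body[rec_off + rep(1:48, times = n)]
  vals <- readBin(float_bytes, "numeric", n = 12L * n, size = 4L, endian = "little")
  vals <- matrix(vals, ncol = 12L, byrow = TRUE)   # nx ny nz v1 v2 v3
  tri_verts <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
                     vals[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * n), ncol = 3L)))  # interleave v1 v2 v3 per facet
  index_mesh(tri_verts[ord, , drop = FALSE])
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    stop(sprintf("STL parse error in %s: %d vertex lines (need a positive multiple of 3)",
                 path, length(vlines)), call. = FALSE)
  }
  vals <- lapply(strsplit(trimws(vlines), "\\s+"), function(f) as.numeric(f[2:4]))
  tri_verts <- do.call(rbind, vals)
  if (!all(is.finite(tri_verts))) {
    stop(sprintf("STL parse error in %s: non-numeric vertex coordinates", path), call. = FALSE)
  }
  index_mesh(tri_verts)
}

# merge exactly-equal vertices of a flat (3 rows per facet) vertex soup
index_mesh <- function(tri_verts) {
  key <- paste(tri_verts[, 1L], tri_verts[, 2L], tri_verts[, 3L])
  idx <- match(key, unique(key))
  verts <- tri_verts[!duplicated(key), , drop = FALSE]
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, tris, clean = TRUE)
}

#' Write a surface mesh to an STL file
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @param encoding `"binary"` (default) or `"ascii"`.
#' @return Invisibly `path`.
#' @export
write_mesh <- function(mesh, path, encoding = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  encoding <- match.arg(encoding)
  v1 <- mesh$vertices[mesh$triangles[, 1L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 2L], , drop = FALSE]
  v3 <- mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
  n <- nrow(mesh$triangles)
  if (encoding == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "hipplan surface mesh"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    rec <- cbind(nrm, v1, v2, v3)   # 12 floats per facet
    flat <- as.numeric(t(rec))
    body <- writeBin(flat, raw(), size = 4L, endian = "little")
    body <- matrix(body, nrow = 48L)
    out <- rbind(body, matrix(as.raw(0L), nrow = 2L, ncol = n))
    writeBin(as.vector(out), con)
  } else {
    fmt_v <- function(m) sprintf("      vertex %.9g %.9g %.9g", m[, 1L], m[, 2L], m[, 3L])
    body <- character(7L * n)
    body[seq(1L, by = 7L, length.out = n)] <-
      sprintf("  facet normal %.9g %.9g %.9g", nrm[, 1L], nrm[, 2L], nrm[, 3L])
    body[seq(2L, by = 7L, length.out = n)] <- "    outer loop"
    body[seq(3L, by = 7L, length.out = n)] <- fmt_v(v1)
    body[seq(4L, by = 7L, length.out = n)] <- fmt_v(v2)
    body[seq(5L, by = 7L, length.out = n)] <- fmt_v(v3)
    body[seq(6L, by = 7L, length.out = n)] <- "    endloop"
    body[seq(7L, by = 7L, length.out = n)] <- "  endfacet"
    writeLines(c("solid hipplan", body, "endsolid hipplan"), path)
  }
  invisible(path)
}

#' Read a caliper measurement table
#'
#' CSV with header `case_id,comparison,reference_mm,measured_mm` (a
#' `defect_label` column is carried through if present). Lengths must be
#' positive numbers; offending rows are named in the error.
#'
#' @param path CSV path.
#' @return A data.frame with typed, validated columns.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "comparison", "reference_mm", "measured_mm")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("measurement table %s missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("reference_mm", "measured_mm")) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(vals) | vals <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("invalid %s in %s at row(s) %s: lengths must be positive numbers",
                   col, path, paste(bad, collapse = ", ")), call. = FALSE)
    }
    tab[[col]] <- vals
  }
  tab
}

#' Write a caliper measurement table
#'
#' @param tab Data.frame with at least `case_id`, `comparison`,
#'   `reference_mm`, `measured_mm`.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_measurement_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
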