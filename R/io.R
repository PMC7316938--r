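# File formats: pose tables (CSV/JSON), implant surface clouds (STL ascii
# and binary, XYZ, ascii PLY), the packaged cohort deviation fixture, and
# the Table-1-style report writer. All readers validate and reject rather
# than coerce; every parse error names its location. CSV dialect: comma
# separator, period decimal, mandatory header, UTF-8 (comma-decimal
# exports are rejected with a clear message).

.POSE_COLS <- c("patient_id", "implant_id", "location_fdi", "role",
                "shoulder_x", "shoulder_y", "shoulder_z",
                "apex_x", "apex_y", "apex_z", "length_mm", "diameter_mm")
.POSE_NUM_COLS <- .POSE_COLS[5:12]

.check_pose_numeric <- function(raw, col) {
  v <- raw[[col]]
  if (is.numeric(v)) return(as.numeric(v))
  vc <- trimws(as.character(v))
  out <- suppressWarnings(as.numeric(vc))
  bad <- which(!is.na(vc) & vc != "" & vc != "NA" & is.na(out))
  if (length(bad)) {
    hint <- if (any(grepl(",", vc[bad]))) {
      " (comma decimal separator? this reader requires period decimals)"
    } else ""
    stop(sprintf("non-numeric value '%s' in column '%s', row %d%s",
                 vc[bad[1]], col, bad[1], hint), call. = FALSE)
  }
  out
}

.validate_pose_table <- function(tab, where = "pose table") {
  missing_cols <- setdiff(setdiff(.POSE_COLS, c("length_mm", "diameter_mm")),
                          names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing column(s): %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("length_mm", "diameter_mm")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_real_
  }
  tab <- tab[, .POSE_COLS]
  for (col in .POSE_NUM_COLS) tab[[col]] <- .check_pose_numeric(tab, col)
  coord_cols <- .POSE_NUM_COLS[1:6]
  for (col in coord_cols) {
    bad <- which(is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("missing coordinate in column '%s', row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  for (col in c("patient_id", "implant_id", "location_fdi", "role")) {
    tab[[col]] <- as.character(tab[[col]])
  }
  bad_role <- which(!tab$role %in% c("planned", "placed"))
  if (length(bad_role)) {
    stop(sprintf("invalid role '%s' in row %d (must be planned or placed)",
                 tab$role[bad_role[1]], bad_role[1]), call. = FALSE)
  }
  key <- paste(tab$patient_id, tab$location_fdi, tab$role)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate key (patient_id, location_fdi, role) = (%s, %s, %s) in row %d",
                 tab$patient_id[dup[1]], tab$location_fdi[dup[1]],
                 tab$role[dup[1]], dup[1]), call. = FALSE)
  }
  tab
}

#' Read and write pose tables
#'
#' A pose table holds one implant pose per row: identifiers, role (planned
#' or placed), shoulder and apex coordinates in mm, and optional nominal
#' length and diameter. Supported formats are CSV (comma separator, period
#' decimal, header row mandatory) and JSON (array of objects). Readers
#' validate the schema and reject malformed files with errors naming the
#' offending row and column.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return `read_pose_table()` returns a validated data frame with columns
#'   `r paste(.POSE_COLS, collapse = ", ")`.
#' @export
read_pose_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, check.names = TRUE,
             fileEncoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0L) stop(sprintf("empty pose table: %s", path), call. = FALSE)
  .validate_pose_table(raw, where = path)
}

#' @rdname read_pose_table
#' @param table A pose-table data frame, or a list of [implant_pose()]
#'   objects (converted with [poses_to_table()]).
#' @export
write_pose_table <- function(table, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!is.data.frame(table)) table <- poses_to_table(table)
  table <- .validate_pose_table(table, where = "pose table to write")
  if (format == "csv") {
    write.csv(table, path, row.names = FALSE, quote = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Convert between pose lists and pose tables
#'
#' @param poses List of [implant_pose()] objects.
#' @return `poses_to_table()` gives a pose-table data frame;
#'   `table_to_poses()` gives a list of `implant_pose` objects.
#' @export
poses_to_table <- function(poses) {
  if (inherits(poses, "implant_pose")) poses <- list(poses)
  do.call(rbind, lapply(poses, function(p) {
    data.frame(patient_id = p$patient_id, implant_id = p$implant_id,
               location_fdi = p$location, role = p$role,
               shoulder_x = p$shoulder[1], shoulder_y = p$shoulder[2],
               shoulder_z = p$shoulder[3],
               apex_x = p$apex[1], apex_y = p$apex[2], apex_z = p$apex[3],
               length_mm = if (is.null(p$length_mm)) NA_real_ else p$length_mm,
               diameter_mm = if (is.null(p$diameter_mm)) NA_real_ else p$diameter_mm,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname poses_to_table
#' @param table A validated pose-table data frame.
#' @export
table_to_poses <- function(table) {
  table <- .validate_pose_table(table)
  lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    implant_pose(r$patient_id, r$location_fdi, r$role,
                 shoulder = c(r$shoulder_x, r$shoulder_y, r$shoulder_z),
                 apex = c(r$apex_x, r$apex_y, r$apex_z),
                 implant_id = r$implant_id,
                 length_mm = if (is.na(r$length_mm)) NULL else r$length_mm,
                 diameter_mm = if (is.na(r$diameter_mm)) NULL else r$diameter_mm)
  })
}

# ---- point cloud / mesh formats ---------------------------------------------

.infer_cloud_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         stl = "stl",
         xyz = "xyz",
         ply = "ply",
         stop(sprintf("cannot infer cloud format from extension of %s", path),
              call. = FALSE))
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vlines)) {
    stop(sprintf("malformed ascii STL (no vertex records): %s", path), call. = FALSE)
  }
  parts <- strsplit(trimws(vlines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed vertex record in %s: '%s'", path, vlines[bad[1]]),
         call. = FALSE)
  }
  m <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(v)) stop(sprintf("non-numeric vertex coordinates in %s", path),
                       call. = FALSE)
    v
  }, numeric(3)))
  if (nrow(m) %% 3L != 0L) {
    stop(sprintf("ascii STL vertex count not a multiple of 3: %s", path),
         call. = FALSE)
  }
  m
}

.read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  if (length(header) < 80L) stop(sprintf("truncated binary STL header: %s", path),
                                 call. = FALSE)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n_tri) != 1L || is.na(n_tri) || n_tri < 0L) {
    stop(sprintf("malformed binary STL facet count: %s", path), call. = FALSE)
  }
  # each facet: normal (3 float) + 3 vertices (9 float) + attribute (uint16)
  body <- readBin(con, "raw", n = n_tri * 50L)
  if (length(body) != n_tri * 50L) {
    stop(sprintf("binary STL facet count mismatch (%d facets declared, file truncated): %s",
                 n_tri, path), call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = 3L * n_tri, ncol = 3L)
  for (i in seq_len(n_tri)) {
    chunk <- body[((i - 1L) * 50L + 1L):((i - 1L) * 50L + 48L)]
    vals <- readBin(chunk, "double", n = 12L, size = 4L, endian = "little")
    m[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], nrow = 3L, byrow = TRUE)
  }
  m
}

#' Read a surface point cloud
#'
#' Reads STL (ascii or binary, autodetected), XYZ (whitespace-separated
#' coordinates) or ascii PLY files. For triangulated formats the vertices
#' are de-duplicated into a point set and connectivity is discarded:
#' registration here is point-based.
#'
#' @param path File path.
#' @param format `"stl"`, `"xyz"`, `"ply"`, or `"auto"` (from extension).
#' @return An n x 3 numeric matrix of unique points, mm, in first-occurrence
#'   order.
#' @export
read_cloud <- function(path, format = c("auto", "stl", "xyz", "ply")) {
  format <- .infer_cloud_format(path, match.arg(format))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  m <- switch(format,
    stl = {
      head_bytes <- readBin(path, "raw", n = 5L)
      is_ascii <- identical(rawToChar(head_bytes), "solid") &&
        .looks_like_ascii_stl(path)
      if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path)
    },
    xyz = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines)) stop(sprintf("empty file: %s", path), call. = FALSE)
      parts <- strsplit(trimws(lines), "\\s+")
      t(vapply(seq_along(parts), function(i) {
        p <- parts[[i]]
        if (length(p) < 3L) stop(sprintf("malformed XYZ line %d in %s", i, path),
                                 call. = FALSE)
        v <- suppressWarnings(as.numeric(p[1:3]))
        if (anyNA(v)) stop(sprintf("non-numeric coordinates on line %d of %s", i, path),
                           call. = FALSE)
        v
      }, numeric(3)))
    },
    ply = .read_ply_ascii(path))
  unique(m)
}

# Binary STLs may also begin with "solid": require an endsolid/facet token.
.looks_like_ascii_stl <- function(path) {
  txt <- tryCatch(readLines(path, n = 50L, warn = FALSE), error = function(e) "")
  any(grepl("facet|endsolid", txt))
}

.read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") {
    stop(sprintf("malformed PLY header (missing 'ply' magic): %s", path), call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop(sprintf("malformed PLY (no end_header): %s", path), call. = FALSE)
  header <- trimws(lines[1:end])
  if (any(grepl("^format\\s+binary", header))) {
    stop(sprintf("binary PLY is not supported: %s", path), call. = FALSE)
  }
  vline <- grep("^element\\s+vertex\\s+\\d+$", header, value = TRUE)
  if (length(vline) != 1L) {
    stop(sprintf("malformed PLY (vertex element not found): %s", path), call. = FALSE)
  }
  n_vert <- as.integer(sub(".*\\s", "", vline))
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_vert) {
    stop(sprintf("PLY vertex count mismatch (%d declared, %d found): %s",
                 n_vert, length(body), path), call. = FALSE)
  }
  parts <- strsplit(trimws(body[seq_len(n_vert)]), "\\s+")
  t(vapply(seq_len(n_vert), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][1:3]))
    if (anyNA(v)) stop(sprintf("non-numeric vertex on line %d of %s", end + i, path),
                       call. = FALSE)
    v
  }, numeric(3)))
}

#' Write point clouds and triangle meshes
#'
#' `write_cloud()` writes a bare point set as XYZ or ascii PLY.
#' `write_stl()` writes a triangle soup (consecutive vertex triples) as
#' ascii or binary STL. [cylinder_mesh()] builds a capped-cylinder triangle
#' soup from an implant pose, handy for producing STL fixtures.
#'
#' @param points n x 3 point matrix (for `write_stl`, 3t x 3 with rows
#'   grouped in vertex triples).
#' @param path Output path.
#' @param format Output dialect.
#' @return The path, invisibly.
#' @export
write_cloud <- function(points, path, format = c("auto", "xyz", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  }
  m <- .as_cloud(points)
  if (format == "xyz") {
    writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = " ")),
               path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(m)),
                 "property float x", "property float y", "property float z",
                 "end_header"), con)
    writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_cloud
#' @export
write_stl <- function(points, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  m <- .as_cloud(points, "triangle vertices")
  if (nrow(m) %% 3L != 0L) {
    stop("write_stl needs rows in vertex triples (one triangle per 3 rows)",
         call. = FALSE)
  }
  n_tri <- nrow(m) %/% 3L
  normals <- t(vapply(seq_len(n_tri), function(i) {
    a <- m[3L * i - 2L, ]; bb <- m[3L * i - 1L, ]; cc <- m[3L * i, ]
    nrm <- .cross3(bb - a, cc - a)
    nl <- .norm3(nrm)
    if (nl > 0) nrm / nl else c(0, 0, 0)
  }, numeric(3)))
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid implantdev", con)
    for (i in seq_len(n_tri)) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         normals[i, 1], normals[i, 2], normals[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in (3L * i - 2L):(3L * i)) {
        writeLines(sprintf("      vertex %.9g %.9g %.9g", m[j, 1], m[j, 2], m[j, 3]),
                   con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid implantdev", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-80s", "implantdev binary stl"))[1:80]), con)
    writeBin(as.integer(n_tri), con, size = 4L, endian = "little")
    for (i in seq_len(n_tri)) {
      writeBin(as.numeric(normals[i, ]), con, size = 4L, endian = "little")
      writeBin(as.numeric(t(m[(3L * i - 2L):(3L * i), ])), con, size = 4L,
               endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_cloud
#' @param pose An [implant_pose()].
#' @param radius_mm Cylinder radius, mm.
#' @param n_segments Circumferential facets (default 36).
#' @export
cylinder_mesh <- function(pose, radius_mm = 1.75, n_segments = 36L) {
  .assert_pose(pose)
  axis <- implant_axis(pose)
  len <- .norm3(pose$apex - pose$shoulder)
  b <- .perp_basis(axis)
  ang <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  rim <- function(t) t(vapply(ang, function(a) {
    pose$shoulder + t * axis + radius_mm * (cos(a) * b$e1 + sin(a) * b$e2)
  }, numeric(3)))
  lo <- rim(0); hi <- rim(len)
  tris <- list()
  for (i in seq_len(n_segments)) {
    j <- if (i == n_segments) 1L else i + 1L
    tris[[length(tris) + 1L]] <- rbind(lo[i, ], lo[j, ], hi[i, ])
    tris[[length(tris) + 1L]] <- rbind(lo[j, ], hi[j, ], hi[i, ])
    tris[[length(tris) + 1L]] <- rbind(pose$shoulder, lo[j, ], lo[i, ])
    tris[[length(tris) + 1L]] <- rbind(pose$apex, hi[i, ], hi[j, ])
  }
  do.call(rbind, tris)
}

# ---- packaged cohort fixture and report writer ------------------------------

#' Packaged per-implant deviation table of the source cohort
#'
#' The published per-implant accuracy table of an 11-patient prospective
#' cohort (24 implants, semi-guided bone-supported templates in the
#' severely atrophied maxilla): template fit, implant site (FDI), implant
#' length, and the four deviation metrics at the implant shoulder. One
#' implant (patient 6, site 23) could not be measured because the template
#' did not fit and carries NA throughout; 23 complete rows enter every
#' summary.
#'
#' @return Data frame with 24 rows and columns `patient_no`, `template_fit`,
#'   `location_fdi`, `implant_length_mm`, `angular_deg`, `global_mm`,
#'   `lateral_mm`, `depth_mm`.
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "cohort_deviations.csv", package = "implantdev",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("integer", "character", "character",
                                 "numeric", "numeric", "numeric", "numeric",
                                 "numeric"))
  tab
}

.fmt_cell <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

#' Write a per-implant or summary deviation report
#'
#' Renders deviation records in the layout of the published accuracy table:
#' one row per implant at 1-decimal precision plus a "Mean (SD)" footer
#' (angular deviation at 2 decimals, other metrics at 1). Missing metrics
#' print as NA and are excluded from the footer per metric. This writer is
#' the only place values are rounded; all internal pipelines carry full
#' precision.
#'
#' @param records A list of `deviation_record`s or a deviation data frame
#'   (see [summarise_cohort()]).
#' @param path Output CSV path, or `""` to return lines invisibly without
#'   writing.
#' @param style `"per_implant_csv"` (rows + footer) or `"summary_csv"`
#'   (four summary rows only).
#' @param divisor SD divisor for the footer, as in [describe()].
#' @return Character vector of report lines, invisibly.
#' @export
write_report <- function(records, path, style = c("per_implant_csv", "summary_csv"),
                         divisor = c("population", "sample")) {
  style <- match.arg(style)
  divisor <- match.arg(divisor)
  tab <- if (is.data.frame(records)) records else deviations_table(records)
  if (nrow(tab) < 1L) stop("write_report needs at least one record", call. = FALSE)
  summ <- summarise_cohort(tab, divisor = divisor)
  if (style == "per_implant_csv") {
    id_cols <- intersect(c("patient_id", "patient_no", "location", "location_fdi"),
                         names(tab))
    header <- paste(c(id_cols, "angular_deg", "global_mm", "lateral_mm", "depth_mm"),
                    collapse = ",")
    rows <- vapply(seq_len(nrow(tab)), function(i) {
      paste(c(as.character(unlist(tab[i, id_cols])),
              .fmt_cell(tab$angular_deg[i], 1L), .fmt_cell(tab$global_mm[i], 1L),
              .fmt_cell(tab$lateral_mm[i], 1L), .fmt_cell(tab$depth_mm[i], 1L)),
            collapse = ",")
    }, character(1))
    footer <- paste(c("Mean (SD)", rep("", length(id_cols) - 1L),
                      sprintf("%s (%s)", .fmt_cell(summ$mean[1], 2L), .fmt_cell(summ$sd[1], 2L)),
                      sprintf("%s (%s)", .fmt_cell(summ$mean[2], 1L), .fmt_cell(summ$sd[2], 1L)),
                      sprintf("%s (%s)", .fmt_cell(summ$mean[3], 1L), .fmt_cell(summ$sd[3], 1L)),
                      sprintf("%s (%s)", .fmt_cell(summ$mean[4], 1L), .fmt_cell(summ$sd[4], 1L))),
                    collapse = ",")
    lines <- c(header, rows, footer)
  } else {
    lines <- c("metric,n,mean,sd,min,max",
               vapply(seq_len(nrow(summ)), function(i) {
                 digits <- if (summ$metric[i] == "angular_deg") 2L else 1L
                 paste(c(summ$metric[i], summ$n[i],
                         .fmt_cell(summ$mean[i], digits), .fmt_cell(summ$sd[i], digits),
                         .fmt_cell(summ$min[i], digits), .fmt_cell(summ$max[i], digits)),
                       collapse = ",")
               }, character(1)))
  }
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}
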