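# PLY reading/writing (ascii and binary_little_endian), limited to the
# elements this pipeline touches: vertices (xyz float32, optional uchar RGB)
# and triangular faces. Other elements are skipped with a notice.

.ply_scalar_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                      short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                      int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                      float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw, off, type) {
  sz <- .ply_scalar_size[[type]]
  val <- switch(type,
    char = , int8 = readBin(raw[off + 1], "integer", size = 1, signed = TRUE),
    uchar = , uint8 = as.integer(raw[off + 1]),
    short = , int16 = readBin(raw[off + (1:2)], "integer", size = 2,
                              endian = "little"),
    ushort = , uint16 = readBin(raw[off + (1:2)], "integer", size = 2,
                                signed = FALSE, endian = "little"),
    int = , int32 = readBin(raw[off + (1:4)], "integer", size = 4,
                            endian = "little"),
    uint = , uint32 = readBin(raw[off + (1:4)], "integer", size = 4,
                              endian = "little"),
    float = , float32 = readBin(raw[off + (1:4)], "double", size = 4,
                                endian = "little"),
    double = , float64 = readBin(raw[off + (1:8)], "double", size = 8,
                                 endian = "little"),
    stop("unsupported PLY scalar type: ", type))
  list(value = val, off = off + sz)
}

.parse_ply_header <- function(lines) {
  stopifnot(lines[1] == "ply")
  fmt_line <- grep("^format ", lines, value = TRUE)[1]
  fmt <- strsplit(fmt_line, " +")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }
  elements <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), " +")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(kind = "list", count_type = tok[3],
                                    value_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(kind = "scalar", type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = fmt, elements = elements)
}

#' Read a triangle mesh (or point cloud) from a PLY file
#'
#' Handles ascii and binary_little_endian PLY with `vertex` (x, y, z and
#' optional red/green/blue) and `face` elements; triangular faces only.
#' Elements other than vertex/face are skipped with a notice. Declared
#' element counts must match the data actually present.
#'
#' @param path Path to a `.ply` file.
#' @return A [triangle_mesh()]; a point cloud yields a mesh with 0 faces.
#' @export
read_ply_mesh <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # locate end_header byte-wise (the body may be binary), tolerant of \r\n
  pos <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(pos) == 0) stop("not a PLY file: no end_header found")
  header_end <- pos[1] + 9L
  if (header_end < length(raw) && raw[header_end + 1] == as.raw(0x0d)) {
    header_end <- header_end + 1L
  }
  if (header_end < length(raw) && raw[header_end + 1] == as.raw(0x0a)) {
    header_end <- header_end + 1L
  }
  header <- strsplit(rawToChar(raw[seq_len(pos[1] + 9L)]), "\r?\n")[[1]]
  hdr <- .parse_ply_header(header)
  extra <- setdiff(names(hdr$elements), c("vertex", "face"))
  if (length(extra) > 0) {
    message("ignoring PLY element(s): ", paste(extra, collapse = ", "))
  }
  if (hdr$format == "ascii") {
    body <- strsplit(rawToChar(raw[(header_end + 1):length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    out <- .read_ply_ascii(hdr, body)
  } else {
    out <- .read_ply_binary(hdr, raw, header_end)
  }
  triangle_mesh(out$vertices, out$faces, out$color)
}

.empty_mesh_parts <- function() {
  list(vertices = matrix(numeric(0), ncol = 3),
       faces = matrix(integer(0), ncol = 3), color = NULL)
}

.read_ply_ascii <- function(hdr, body) {
  out <- .empty_mesh_parts()
  row <- 0
  for (el in hdr$elements) {
    if (el$count > 0 && row + el$count > length(body)) {
      stop("PLY declares ", el$count, " '", el$name, "' rows but file has fewer")
    }
    rows <- body[row + seq_len(el$count)]
    row <- row + el$count
    if (el$name == "vertex") {
      tok_list <- lapply(strsplit(trimws(rows), " +"), as.numeric)
      if (any(lengths(tok_list) != length(el$props))) {
        stop("PLY element 'vertex': row width mismatch - fewer rows than ",
             "declared, or malformed rows")
      }
      toks <- do.call(rbind, tok_list)
      if (el$count == 0) toks <- matrix(numeric(0), ncol = length(el$props))
      pn <- names(el$props)
      out$vertices <- toks[, match(c("x", "y", "z"), pn), drop = FALSE]
      if (all(c("red", "green", "blue") %in% pn)) {
        out$color <- toks[, match(c("red", "green", "blue"), pn), drop = FALSE]
      }
    } else if (el$name == "face") {
      f <- lapply(strsplit(trimws(rows), " +"), as.numeric)
      if (any(vapply(f, function(x) x[1] != 3, TRUE))) {
        stop("non-triangular PLY face encountered")
      }
      out$faces <- if (el$count == 0) matrix(integer(0), ncol = 3) else
        do.call(rbind, lapply(f, function(x) x[2:4] + 1))
    }
  }
  out
}

.read_ply_binary <- function(hdr, raw, off) {
  out <- .empty_mesh_parts()
  for (el in hdr$elements) {
    if (el$name == "vertex") {
      pn <- names(el$props)
      types <- vapply(el$props, function(p) p$type, "")
      sizes <- .ply_scalar_size[types]
      stride <- sum(sizes)
      need <- el$count * stride
      if (off + need > length(raw)) {
        stop("PLY declares ", el$count, " vertices but file is too short")
      }
      vals <- matrix(NA_real_, nrow = el$count, ncol = length(pn))
      col_off <- cumsum(c(0, sizes))[seq_along(sizes)]
      for (j in seq_along(pn)) {
        idx_raw <- as.vector(outer(seq_len(sizes[j]),
                                   off + (seq_len(el$count) - 1) * stride + col_off[j],
                                   `+`))
        sub <- raw[idx_raw]
        vals[, j] <- switch(types[j],
          float = , float32 = readBin(sub, "double", el$count, size = 4,
                                      endian = "little"),
          double = , float64 = readBin(sub, "double", el$count, size = 8,
                                       endian = "little"),
          uchar = , uint8 = as.numeric(readBin(sub, "integer", el$count,
                                               size = 1, signed = FALSE)),
          readBin(sub, "integer", el$count, size = sizes[j], endian = "little"))
      }
      off <- off + need
      out$vertices <- vals[, match(c("x", "y", "z"), pn), drop = FALSE]
      if (all(c("red", "green", "blue") %in% pn)) {
        out$color <- vals[, match(c("red", "green", "blue"), pn), drop = FALSE]
      }
    } else if (el$name == "face") {
      faces <- matrix(NA_integer_, nrow = el$count, ncol = 3)
      p <- el$props[["vertex_indices"]] %||% el$props[["vertex_index"]] %||%
        el$props[[1]]
      for (i in seq_len(el$count)) {
        cnt <- .ply_read_scalar(raw, off, p$count_type)
        if (cnt$value != 3) stop("non-triangular PLY face encountered")
        off <- cnt$off
        for (j in 1:3) {
          v <- .ply_read_scalar(raw, off, p$value_type)
          faces[i, j] <- v$value + 1L
          off <- v$off
        }
      }
      out$faces <- faces
    } else {
      # skip unknown fixed-stride element; list properties unsupported here
      if (any(vapply(el$props, function(p) p$kind == "list", TRUE))) {
        stop("cannot skip binary PLY element '", el$name, "' with list properties")
      }
      stride <- sum(.ply_scalar_size[vapply(el$props, function(p) p$type, "")])
      off <- off + el$count * stride
    }
  }
  out
}

#' Write a triangle mesh to PLY
#'
#' `binary_little_endian` by default (coordinates as float32, colour as
#' uchar) for portability into mesh viewers; `ascii` on request. Round trips
#' through [read_ply_mesh()] within float32 precision (about 1e-6 relative).
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param format `"binary_little_endian"` or `"ascii"`.
#' @param comment Optional header comment line(s).
#' @return `path`, invisibly.
#' @export
write_ply_mesh <- function(mesh, path,
                           format = c("binary_little_endian", "ascii"),
                           comment = NULL) {
  format <- match.arg(format)
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  has_color <- !is.null(mesh$color)
  header <- c("ply", paste("format", format, "1.0"),
              if (!is.null(comment)) paste("comment", comment),
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              if (has_color) c("property uchar red", "property uchar green",
                               "property uchar blue"),
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    if (nv > 0) {
      vtx <- apply(mesh$vertices, 1, function(r) paste(sprintf("%.9g", r),
                                                       collapse = " "))
      if (has_color) {
        vtx <- paste(vtx, apply(mesh$color, 1, paste, collapse = " "))
      }
      writeLines(vtx, con, sep = "\n")
    }
    if (nf > 0) {
      writeLines(apply(mesh$faces - 1L, 1, function(r)
        paste(c(3, r), collapse = " ")), con, sep = "\n")
    }
  } else {
    if (nv > 0) {
      for (i in seq_len(nv)) {
        writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4,
                 endian = "little")
        if (has_color) {
          writeBin(as.raw(mesh$color[i, ]), con)
        }
      }
    }
    if (nf > 0) {
      for (i in seq_len(nf)) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
                 endian = "little")
      }
    }
  }
  invisible(path)
}

#' Write mapped fixations as a PLY point cloud
#'
#' One vertex per projection row with status `"mapped"`, in row order;
#' non-mapped rows contribute no vertex. An all-miss table still yields a
#' valid zero-vertex PLY (with a warning).
#'
#' @param projections A projection table from [project_fixations()].
#' @param path Output path.
#' @param format See [write_ply_mesh()].
#' @return `path`, invisibly.
#' @export
write_fixation_ply <- function(projections, path,
                               format = c("binary_little_endian", "ascii")) {
  mapped <- projections[projections$status == "mapped", , drop = FALSE]
  if (nrow(mapped) == 0) {
    warning("no mapped fixations: writing an empty point cloud")
  }
  verts <- cbind(mapped$intersection_x, mapped$intersection_y,
                 mapped$intersection_z)
  if (nrow(mapped) == 0) verts <- matrix(numeric(0), ncol = 3)
  cloud <- triangle_mesh(verts, matrix(integer(0), ncol = 3))
  write_ply_mesh(cloud, path, format = match.arg(format),
                 comment = "fixation intersection points")
}
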