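# Readers/writers for meshes (OFF, PLY ascii/binary little-endian, OBJ) and
# the package's JSON formats.  JSON payloads carry a "format" field; writers
# emit stable key order so files diff cleanly.

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Read and write triangular meshes
#'
#' Supported formats by extension: OFF (ascii), PLY (ascii and binary
#' little-endian; vertex `x/y/z` float or double properties, triangular
#' faces) and OBJ (geometry only; `v`/`f` records, polygonal faces are
#' fan-triangulated).  Coordinates are assumed millimeters; `scale` allows
#' unit conversion on read (e.g. `scale = 1000` for meter-based files).
#'
#' @param path File path; format chosen by extension.
#' @param scale Multiplier applied to vertex coordinates on read (default 1).
#' @return `read_mesh()`: a [tri_mesh()].
#' @export
read_mesh <- function(path, scale = 1) {
  ext <- file_ext(path)
  mesh <- switch(ext,
    off = read_off(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop(sprintf("unsupported mesh format '.%s' (use .off/.ply/.obj)", ext),
         call. = FALSE))
  if (scale != 1) mesh <- tri_mesh(mesh$vertices * scale, mesh$faces)
  mesh
}

#' @rdname read_mesh
#' @param mesh A [tri_mesh()].
#' @param format For PLY: `"ascii"` (default; exact round-trip) or
#'   `"binary"` (binary little-endian, float32 vertices).
#' @return `write_mesh()`: the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ascii", "binary")) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- match.arg(format)
  ext <- file_ext(path)
  switch(ext,
    off = write_off(mesh, path),
    ply = write_ply(mesh, path, binary = format == "binary"),
    obj = write_obj(mesh, path),
    stop(sprintf("unsupported mesh format '.%s'", ext), call. = FALSE))
  invisible(path)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L || toupper(lines[1L]) != "OFF") {
    stop(sprintf("%s: not an OFF file", path), call. = FALSE)
  }
  counts <- suppressWarnings(as.integer(strsplit(lines[2L], "\\s+")[[1L]]))
  if (length(counts) < 2L || anyNA(counts[1:2])) {
    stop(sprintf("%s: malformed OFF count line", path), call. = FALSE)
  }
  nv <- counts[1L]; nf <- counts[2L]
  if (length(lines) < 2L + nv + nf) {
    stop(sprintf("%s: truncated OFF file", path), call. = FALSE)
  }
  vtx <- do.call(rbind, lapply(lines[3:(2L + nv)], function(l) {
    as.numeric(strsplit(l, "\\s+")[[1L]][1:3])
  }))
  faces <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    tok <- suppressWarnings(as.integer(strsplit(lines[2L + nv + i], "\\s+")[[1L]]))
    if (anyNA(tok) || tok[1L] != 3L || length(tok) < 4L) {
      stop(sprintf("%s: face %d is not a triangle record", path, i), call. = FALSE)
    }
    faces[i, ] <- tok[2:4] + 1L
  }
  if (any(faces < 1L) || any(faces > nv)) {
    bad <- which(rowSums(faces < 1L | faces > nv) > 0)[1L]
    stop(sprintf("%s: face %d references a vertex index out of range",
                 path, bad), call. = FALSE)
  }
  tri_mesh(vtx, faces)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  f0 <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f0[, 1L], f0[, 2L], f0[, 3L]), con)
}

read_ply_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file", call. = FALSE)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("PLY header truncated", call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      cur <- tok[2L]
      elements[[cur]] <- list(count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop("PLY property before element", call. = FALSE)
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1L]] <- tok[-1L]
    } else if (tok[1L] == "end_header") {
      break
    }
  }
  if (is.null(fmt) || !(fmt %in% c("ascii", "binary_little_endian"))) {
    stop(sprintf("unsupported PLY format '%s'", fmt %||% "<missing>"),
         call. = FALSE)
  }
  list(format = fmt, elements = elements)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ply_scalar_size <- function(type) {
  switch(type,
    char = , int8 = , uchar = , uint8 = 1L,
    short = , int16 = , ushort = , uint16 = 2L,
    int = , int32 = , uint = , uint32 = , float = , float32 = 4L,
    double = , float64 = 8L,
    stop(sprintf("unsupported PLY scalar type '%s'", type), call. = FALSE))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_ply_header(con)
  vel <- hdr$elements$vertex
  fel <- hdr$elements$face
  if (is.null(vel) || is.null(fel)) {
    stop(sprintf("%s: PLY file lacks vertex/face elements", path), call. = FALSE)
  }
  vprops <- vapply(vel$props, function(p) p[2L], character(1L))
  xyz <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz)) stop(sprintf("%s: PLY vertex element lacks x/y/z", path),
                       call. = FALSE)
  if (hdr$format == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- trimws(txt)
    txt <- txt[nzchar(txt)]
    if (length(txt) < vel$count + fel$count) {
      stop(sprintf("%s: truncated PLY body", path), call. = FALSE)
    }
    vtx <- do.call(rbind, lapply(txt[seq_len(vel$count)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1L]][xyz])
    }))
    faces <- matrix(0L, fel$count, 3L)
    for (i in seq_len(fel$count)) {
      tok <- suppressWarnings(as.integer(
        strsplit(txt[vel$count + i], "\\s+")[[1L]]))
      if (anyNA(tok[1L]) || tok[1L] != 3L) {
        stop(sprintf("%s: PLY face %d is not a triangle", path, i), call. = FALSE)
      }
      faces[i, ] <- tok[2:4] + 1L
    }
  } else {
    # Binary little-endian: read vertex records property by property.
    types <- vapply(vel$props, function(p) p[1L], character(1L))
    if (any(types == "list")) {
      stop("list-typed vertex properties are not supported", call. = FALSE)
    }
    sizes <- vapply(types, ply_scalar_size, integer(1L))
    rec_size <- sum(sizes)
    rawv <- readBin(con, "raw", n = rec_size * vel$count)
    if (length(rawv) < rec_size * vel$count) {
      stop(sprintf("%s: truncated PLY vertex block", path), call. = FALSE)
    }
    vtx <- matrix(0, vel$count, 3L)
    offs <- cumsum(c(0L, sizes))
    for (k in seq_along(xyz)) {
      pidx <- xyz[k]
      type <- types[pidx]
      sz <- sizes[pidx]
      starts <- (seq_len(vel$count) - 1L) * rec_size + offs[pidx]
      bytes <- rawv[as.vector(outer(seq_len(sz), starts, "+"))]
      what <- if (type %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      vtx[, k] <- readBin(bytes, what, n = vel$count, size = sz,
                          endian = "little")
    }
    # Faces: list property (count type + index type).
    fprop <- fel$props[[1L]]
    if (fprop[1L] != "list") stop("PLY face element must be a list property",
                                  call. = FALSE)
    csz <- ply_scalar_size(fprop[2L])
    isz <- ply_scalar_size(fprop[3L])
    faces <- matrix(0L, fel$count, 3L)
    for (i in seq_len(fel$count)) {
      cnt <- readBin(con, "integer", n = 1L, size = csz, signed = csz > 1L,
                     endian = "little")
      if (length(cnt) == 0L || cnt != 3L) {
        stop(sprintf("%s: PLY face %d is not a triangle", path, i), call. = FALSE)
      }
      idx <- readBin(con, "integer", n = 3L, size = isz, endian = "little")
      faces[i, ] <- idx + 1L
    }
  }
  tri_mesh(vtx, faces)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nv),
           sprintf("property %s x", if (binary) "float" else "double"),
           sprintf("property %s y", if (binary) "float" else "double"),
           sprintf("property %s z", if (binary) "float" else "double"),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1L],
                       mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    f0 <- mesh$faces - 1L
    writeLines(sprintf("3 %d %d %d", f0[, 1L], f0[, 2L], f0[, 3L]), con)
  }
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vtx <- list(); faces <- list()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "v") {
      vtx[[length(vtx) + 1L]] <- as.numeric(tok[2:4])
    } else if (tok[1L] == "f") {
      idx <- as.integer(vapply(tok[-1L], function(t) strsplit(t, "/")[[1L]][1L],
                               character(1L)))
      if (length(idx) < 3L || anyNA(idx)) {
        stop(sprintf("%s: malformed OBJ face '%s'", path, ln), call. = FALSE)
      }
      for (k in 2:(length(idx) - 1L)) {
        faces[[length(faces) + 1L]] <- c(idx[1L], idx[k], idx[k + 1L])
      }
    }
  }
  if (!length(vtx) || !length(faces)) {
    stop(sprintf("%s: OBJ file lacks geometry", path), call. = FALSE)
  }
  tri_mesh(do.call(rbind, vtx), do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
}

# ---- JSON formats ----

write_json_file <- function(x, path) {
  # 17 significant digits round-trips IEEE doubles exactly.
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

check_format <- function(obj, expected, path) {
  if (!identical(obj$format, expected)) {
    stop(sprintf("%s: expected format '%s', found '%s'", path, expected,
                 obj$format %||% "<missing>"), call. = FALSE)
  }
}

#' Read and write cranial landmark files
#'
#' JSON schema `cranioguide/cranial@1`: `frame`, `method` and a `points`
#' object mapping each of Nz/Iz/LPA/RPA/Cz to an `[x, y, z]` triplet.
#'
#' @param path File path.
#' @return `read_landmarks()`: a [cranial_landmarks()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_format(obj, "cranioguide/cranial@1", path)
  if (is.null(obj$points)) stop(sprintf("%s: missing 'points'", path),
                                call. = FALSE)
  pts <- lapply(obj$points, function(p) as.numeric(unlist(p)))
  cranial_landmarks(pts, frame = obj$frame %||% "head-mm",
                    method = obj$method %||% "five-point")
}

#' @rdname read_landmarks
#' @param cranial A [cranial_landmarks()].
#' @export
write_landmarks <- function(cranial, path) {
  stopifnot(inherits(cranial, "cranial_landmarks"))
  pts <- lapply(stats::setNames(CRANIAL_NAMES, CRANIAL_NAMES),
                function(nm) unname(cranial$points[nm, ]))
  write_json_file(list(format = "cranioguide/cranial@1",
                       frame = cranial$frame, method = cranial$method,
                       points = pts), path)
}

#' Read and write layout files
#'
#' JSON schema `cranioguide/layout@1`: `density`, `source`, `frame`, an
#' `entries` object label -> `[x, y, z]`, and a `region` object label ->
#' tag.  Duplicate labels are rejected.
#'
#' @param path File path.
#' @return `read_layout()`: a [tentwenty_layout()].
#' @export
read_layout <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_format(obj, "cranioguide/layout@1", path)
  labels <- names(obj$entries)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop(sprintf("%s: layout entries must have unique labels", path),
         call. = FALSE)
  }
  entries <- do.call(rbind, lapply(obj$entries, function(p) as.numeric(unlist(p))))
  rownames(entries) <- labels
  region <- unlist(obj$region)
  tentwenty_layout(entries, density = obj$density, source = obj$source,
                   region = if (length(region)) region else NULL,
                   frame = obj$frame %||% "head-mm")
}

#' @rdname read_layout
#' @param layout A [tentwenty_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "tentwenty_layout"))
  labels <- rownames(layout$entries)
  ord <- order(labels)
  entries <- lapply(stats::setNames(labels[ord], labels[ord]),
                    function(l) unname(layout$entries[l, ]))
  write_json_file(list(format = "cranioguide/layout@1",
                       density = layout$density, source = layout$source,
                       frame = layout$frame, entries = entries,
                       region = as.list(layout$region[labels[ord]])), path)
}

#' Read and write fitted head maps
#'
#' JSON schema `cranioguide/headmap@1`: the subset spec (with an explicit
#' `index_base` field), ridge, metadata, and per-target `A` (row-major
#' nested array, `3Nf x 3`) and `b`.  Round-trips preserve coefficients
#' exactly (numbers are written at full precision).
#'
#' @param path File path.
#' @return `read_headmap()`: a `linear_headmap`.
#' @export
read_headmap <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_format(obj, "cranioguide/headmap@1", path)
  idx <- as.integer(unlist(obj$subset$indices))
  base <- obj$subset$index_base %||% 1L
  if (base == 0L) idx <- idx + 1L
  spec <- subset_spec(obj$subset$name, idx, obj$subset$convention)
  targets <- lapply(obj$targets, function(tg) {
    list(A = do.call(rbind, lapply(tg$A, function(r) as.numeric(unlist(r)))),
         b = as.numeric(unlist(tg$b)))
  })
  meta <- list(n_rows = obj$meta$n_rows %||% NA_integer_,
               ridge = obj$meta$ridge %||% 0)
  linear_headmap(targets, spec, meta)
}

#' @rdname read_headmap
#' @param map A `linear_headmap`.
#' @export
write_headmap <- function(map, path) {
  stopifnot(inherits(map, "linear_headmap"))
  targets <- lapply(map$targets, function(tg) {
    list(A = apply(tg$A, 1L, function(r) r, simplify = FALSE),
         b = unname(tg$b))
  })
  write_json_file(list(
    format = "cranioguide/headmap@1",
    subset = list(name = map$subset$name,
                  indices = map$subset$indices,
                  convention = map$subset$convention,
                  index_base = 1L),
    meta = list(n_rows = map$meta$n_rows, ridge = map$meta$ridge),
    targets = targets), path)
}

#' Read and write facial-landmark streams
#'
#' JSON-lines, one record per frame: `{"t": <time>, "convention": "...",
#' "points": [[x, y, z], ...]}`.  A record with an empty `points` array
#' denotes a frame with no detected face and reads back as `NULL`.
#'
#' @param path File path.
#' @return `read_stream()`: a list of [facial_landmarks()] (or `NULL`)
#'   frames.
#' @export
read_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    if (is.null(obj$points)) {
      stop(sprintf("%s: stream record %d lacks 'points'", path, i),
           call. = FALSE)
    }
    if (length(obj$points) == 0L) return(NULL)
    pts <- do.call(rbind, lapply(obj$points, function(p) as.numeric(unlist(p))))
    facial_landmarks(pts, convention = obj$convention %||% "camera468",
                     frame = "normalized-camera")
  })
}

#' @rdname read_stream
#' @param frames List of [facial_landmarks()] or `NULL` entries.
#' @export
write_stream <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    rec <- if (is.null(fr)) {
      list(t = i - 1L, convention = NA, points = list())
    } else {
      list(t = i - 1L, convention = fr$convention,
           points = apply(fr$points, 1L, function(r) r, simplify = FALSE))
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                                null = "null"), con)
  }
  invisible(path)
}

#' Read and write atlas bundles
#'
#' An atlas bundle directory holds `mesh.ply` (or `.off`/`.obj`),
#' `cranial.json` and one `layout_<density>.json` per precomputed density.
#'
#' @param dir Directory path.
#' @return `read_atlas_bundle()`: an [atlas_bundle()].
#' @export
read_atlas_bundle <- function(dir) {
  mesh_file <- Filter(file.exists,
                      file.path(dir, c("mesh.ply", "mesh.off", "mesh.obj")))
  if (!length(mesh_file)) stop(sprintf("%s: no mesh.{ply,off,obj}", dir),
                               call. = FALSE)
  mesh <- read_mesh(mesh_file[[1L]])
  cranial <- read_landmarks(file.path(dir, "cranial.json"))
  layout_files <- list.files(dir, "^layout_.*\\.json$", full.names = TRUE)
  if (!length(layout_files)) stop(sprintf("%s: no layout files", dir),
                                  call. = FALSE)
  layouts <- lapply(layout_files, read_layout)
  names(layouts) <- vapply(layouts, `[[`, character(1L), "density")
  atlas_bundle(mesh, cranial, layouts)
}

#' @rdname read_atlas_bundle
#' @param bundle An [atlas_bundle()].
#' @export
write_atlas_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(bundle$mesh, file.path(dir, "mesh.ply"))
  write_landmarks(bundle$cranial, file.path(dir, "cranial.json"))
  for (d in names(bundle$layouts)) {
    write_layout(bundle$layouts[[d]],
                 file.path(dir, paste0("layout_", gsub("-", "", d), ".json")))
  }
  invisible(dir)
}
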