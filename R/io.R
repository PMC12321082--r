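#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Supports ASCII OBJ (`v`/`f` records, quads and larger polygons are
#' fan-triangulated), PLY in ASCII and binary little-endian form, and STL
#' in ASCII and binary form. STL files carry no vertex indexing, so
#' coincident vertices are merged on load. Coordinates are taken as
#' millimetres. Degenerate (zero-area) triangles are dropped with a
#' warning.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"obj"`, `"ply"`, `"stl"`.
#' @return A [trimesh].
#' @seealso [save_mesh()]
#' @export
load_mesh <- function(path, format = c("auto", "obj", "ply", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  m <- switch(format,
              obj = read_obj(path),
              ply = read_ply(path),
              stl = read_stl(path))
  drop_degenerate_triangles(m)
}

#' Write a triangle mesh to OBJ, PLY or STL
#'
#' @param m a [trimesh].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"obj"`, `"ply"`, `"stl"`.
#' @param binary for PLY/STL, write the binary variant (default `TRUE`).
#'   PLY binary stores double precision; STL is always 32-bit float.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(m, path, format = c("auto", "obj", "ply", "stl"),
                      binary = TRUE) {
  format <- match.arg(format)
  validate_trimesh(m)
  if (n_triangles(m) == 0)
    stop("refusing to write a mesh with no triangles", call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         obj = write_obj(m, path),
         ply = write_ply(m, path, binary = binary),
         stl = write_stl(m, path, binary = binary))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("obj", "ply", "stl"))
    stop("cannot infer mesh format from extension: ", path, call. = FALSE)
  ext
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines)
  flines <- grep("^f\\s", lines)
  if (length(vlines) == 0) stop("OBJ has no vertices: ", path, call. = FALSE)
  vparts <- strsplit(trimws(sub("^v", "", lines[vlines])), "\\s+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  if (anyNA(verts)) stop("OBJ vertex record not numeric", call. = FALSE)
  tris <- list()
  for (i in seq_along(flines)) {
    ln <- flines[i]
    toks <- strsplit(trimws(sub("^f", "", lines[ln])), "\\s+")[[1]]
    idx <- suppressWarnings(as.integer(sub("/.*", "", toks)))
    if (anyNA(idx) || length(idx) < 3)
      stop("OBJ face record invalid at line ", ln, call. = FALSE)
    idx <- ifelse(idx < 0, nrow(verts) + idx + 1L, idx)
    if (any(idx < 1 | idx > nrow(verts)))
      stop("OBJ face index out of range at line ", ln, call. = FALSE)
    # fan triangulation for quads and larger polygons
    tris[[i]] <- cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
  }
  trimesh(verts, do.call(rbind, tris))
}

write_obj <- function(m, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# facegauge OBJ export", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     m$triangles[, 1], m$triangles[, 2], m$triangles[, 3]),
             con)
}

# ---- PLY ------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, n = 1L) {
  switch(type,
         char = , int8 = readBin(con, integer(), n, size = 1, signed = TRUE,
                                 endian = "little"),
         uchar = , uint8 = readBin(con, integer(), n, size = 1,
                                   signed = FALSE, endian = "little"),
         short = , int16 = readBin(con, integer(), n, size = 2,
                                   signed = TRUE, endian = "little"),
         ushort = , uint16 = readBin(con, integer(), n, size = 2,
                                     signed = FALSE, endian = "little"),
         int = , int32 = , uint = , uint32 =
           readBin(con, integer(), n, size = 4, endian = "little"),
         float = , float32 = readBin(con, numeric(), n, size = 4,
                                     endian = "little"),
         double = , float64 = readBin(con, numeric(), n, size = 8,
                                      endian = "little"),
         stop("unsupported PLY type: ", type, call. = FALSE))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply"))
    stop("not a PLY file: ", path, call. = FALSE)
  fmt <- NULL
  elements <- list()  # list of list(name, count, props = list(name,type,list))
  repeat {
    ln <- trimws(readLines(con, n = 1))
    if (length(ln) == 0) stop("PLY header truncated", call. = FALSE)
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "end_header") break
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element")
      elements[[length(elements) + 1]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
    if (tok[1] == "property") {
      i <- length(elements)
      if (tok[2] == "list") {
        elements[[i]]$props[[length(elements[[i]]$props) + 1]] <-
          list(name = tok[5], type = tok[4], count_type = tok[3],
               is_list = TRUE)
      } else {
        elements[[i]]$props[[length(elements[[i]]$props) + 1]] <-
          list(name = tok[3], type = tok[2], is_list = FALSE)
      }
    }
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt, call. = FALSE)

  verts <- NULL
  tris <- NULL
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    row <- 1L
    for (el in elements) {
      if (el$count == 0) next
      chunk <- body[row:(row + el$count - 1L)]
      row <- row + el$count
      toks <- strsplit(trimws(chunk), "\\s+")
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        ix <- match(c("x", "y", "z"), pn)
        if (anyNA(ix)) stop("PLY vertex element lacks x/y/z", call. = FALSE)
        verts <- t(vapply(toks, function(p) as.numeric(p[ix]), numeric(3)))
      } else if (el$name == "face") {
        tris <- do.call(rbind, lapply(seq_along(toks), function(i) {
          p <- as.integer(toks[[i]])
          k <- p[1]
          if (length(p) < k + 1)
            stop("PLY face record truncated at record ", i, call. = FALSE)
          idx <- p[2:(k + 1)] + 1L  # PLY is 0-based
          cbind(idx[1], idx[2:(k - 1)], idx[3:k])
        }))
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        ptypes <- vapply(el$props, `[[`, "", "type")
        vals <- matrix(NA_real_, el$count, length(el$props))
        # uniform scalar types let us read the element in one block
        if (length(unique(ptypes)) == 1 && !any(vapply(el$props, `[[`,
                                                       TRUE, "is_list"))) {
          raw <- ply_read_scalar(con, ptypes[1],
                                 el$count * length(el$props))
          vals <- matrix(raw, el$count, length(el$props), byrow = TRUE)
        } else {
          for (r in seq_len(el$count))
            for (c_ in seq_along(el$props))
              vals[r, c_] <- ply_read_scalar(con, ptypes[c_])
        }
        ix <- match(c("x", "y", "z"), pn)
        if (anyNA(ix)) stop("PLY vertex element lacks x/y/z", call. = FALSE)
        verts <- vals[, ix, drop = FALSE]
      } else if (el$name == "face") {
        lp <- el$props[[1]]
        rows <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          k <- ply_read_scalar(con, lp$count_type)
          idx <- ply_read_scalar(con, lp$type, k) + 1L
          rows[[r]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
        }
        tris <- do.call(rbind, rows)
      } else {
        # skip unknown fixed-size element
        sz <- sum(ply_type_size[vapply(el$props, `[[`, "", "type")])
        invisible(readBin(con, raw(), el$count * sz))
      }
    }
  }
  if (is.null(verts)) stop("PLY has no vertex element", call. = FALSE)
  if (is.null(tris)) stop("PLY has no face element", call. = FALSE)
  trimesh(verts, tris)
}

write_ply <- function(m, path, binary = TRUE) {
  nv <- n_vertices(m); nt <- n_triangles(m)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0"
              else "format ascii 1.0",
              "comment facegauge PLY export",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nt),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.numeric(t(m$vertices)), con, size = 8, endian = "little")
    f0 <- m$triangles - 1L
    for (i in seq_len(nt)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.17g %.17g %.17g",
                       m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]),
               con)
    f0 <- m$triangles - 1L
    writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  }
}

# ---- STL ------------------------------------------------------------------

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 count + 50-byte records; an ASCII
  # file starts with "solid" and its size does not match the binary layout
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, raw(), 80)
  looks_ascii <- identical(rawToChar(head80[1:5]), "solid")
  is_binary <- FALSE
  if (sz >= 84) {
    n <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (!is.na(n) && sz == 84 + 50 * n) is_binary <- TRUE
  }
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, raw(), 80))
    n <- readBin(con, integer(), 1, size = 4, endian = "little")
    # each 50-byte record: 12 little-endian floats + uint16 attribute count
    body <- readBin(con, raw(), 50 * n)
    keep <- rep(c(rep(TRUE, 48), FALSE, FALSE), n)
    vals <- readBin(body[keep], numeric(), n * 12, size = 4,
                    endian = "little")
    rec <- matrix(vals, nrow = n, ncol = 12, byrow = TRUE)
    tri_pts <- matrix(t(rec[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  } else if (looks_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("ASCII STL vertex records not a multiple of 3", call. = FALSE)
    parts <- strsplit(trimws(sub("^\\s*vertex", "", lines[vl])), "\\s+")
    tri_pts <- t(vapply(parts, function(p) as.numeric(p[1:3]), numeric(3)))
  } else {
    stop("unrecognized STL layout: ", path, call. = FALSE)
  }
  # de-index: merge coincident vertices (exact duplicates from the soup)
  key <- paste(tri_pts[, 1], tri_pts[, 2], tri_pts[, 3], sep = "|")
  uniq <- !duplicated(key)
  vid <- match(key, key[uniq])
  verts <- tri_pts[uniq, , drop = FALSE]
  tris <- matrix(vid, ncol = 3, byrow = TRUE)
  ok <- tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] &
    tris[, 1] != tris[, 3]
  trimesh(verts, tris[ok, , drop = FALSE])
}

write_stl <- function(m, path, binary = TRUE) {
  f <- m$triangles
  v <- m$vertices
  tn <- triangle_normals_raw(m)
  tn <- tn / pmax(sqrt(rowSums(tn^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("facegauge STL export"), raw(60)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(tn[i, ], v[f[i, 1], ], v[f[i, 2], ],
                            v[f[i, 3], ])), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines("solid facegauge", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         tn[i, 1], tn[i, 2], tn[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, k], 1], v[f[i, k], 2], v[f[i, k], 3]),
                   con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid facegauge", con)
  }
}
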