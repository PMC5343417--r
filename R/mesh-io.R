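#' Read a triangulated surface mesh from file
#'
#' Supports PLY (ascii and binary little/big endian), STL (ascii and binary)
#' and OBJ.  PLY faces with four vertices are fan-triangulated; faces with
#' more vertices are rejected.  STL files carry no connectivity, so vertices
#' with bit-identical coordinates are merged on read.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"stl"`, `"obj"`; guessed from the file
#'   extension when missing.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0) stop("corrupt mesh file (empty): ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj"))
      stop("unknown mesh format for extension '", ext, "'")
    format <- ext
  }
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path))
}

#' Write a triangulated surface mesh to file
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"stl"` or `"obj"`; guessed from the extension
#'   when missing.
#' @param binary write binary PLY (little-endian, double-precision
#'   coordinates) or binary STL; ignored for OBJ.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "stl", "obj"),
                       binary = TRUE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj"))
      stop("unknown mesh format for extension '", ext, "'")
    format <- ext
  }
  switch(format,
         ply = write_ply(mesh, path, binary = binary),
         stl = write_stl(mesh, path, binary = binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

## ---- PLY ----

ply_type_info <- function(type) {
  # returns list(size, what, signed)
  switch(type,
         char = , int8 = list(size = 1L, what = "integer"),
         uchar = , uint8 = list(size = 1L, what = "integer"),
         short = , int16 = list(size = 2L, what = "integer"),
         ushort = , uint16 = list(size = 2L, what = "integer"),
         int = , int32 = list(size = 4L, what = "integer"),
         uint = , uint32 = list(size = 4L, what = "integer"),
         float = , float32 = list(size = 4L, what = "numeric"),
         double = , float64 = list(size = 8L, what = "numeric"),
         stop("unsupported PLY property type: ", type))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) == 0 || tolower(trimws(magic)) != "ply")
    stop("corrupt PLY file (missing 'ply' magic): ", path)
  fmt <- NULL
  elements <- list()   # each: list(name, count, props = list(name,type,list,count_type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) stop("corrupt PLY header (no end_header): ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    } else if (tok[1] == "end_header") break
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(fmt)) stop("corrupt PLY header (no format line): ", path)
  if (!all(c("vertex", "face") %in% names(elements)))
    stop("PLY file lacks vertex/face elements: ", path)

  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 0L
    get_lines <- function(k) {
      out <- txt[(pos + 1L):(pos + k)]
      pos <<- pos + k
      out
    }
    data <- list()
    for (el in elements) {
      lines <- get_lines(el$count)
      data[[el$name]] <- strsplit(trimws(lines), "\\s+")
    }
    vprops <- vapply(elements$vertex$props, `[[`, "", "name")
    vl <- data$vertex
    vm <- t(vapply(vl, function(s) as.numeric(s), numeric(length(vprops))))
    colnames(vm) <- vprops
    verts <- vm[, c("x", "y", "z"), drop = FALSE]
    faces <- lapply(data$face, function(s) {
      n <- as.integer(s[1])
      as.integer(s[2:(1 + n)])
    })
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    vprops <- elements$vertex$props
    nv <- elements$vertex$count
    # vertices: fixed record; read property-by-property interleaved
    sizes <- vapply(vprops, function(p) ply_type_info(p$type)$size, 0L)
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * nv)
    if (length(raw) < rec * nv) stop("corrupt PLY file (truncated): ", path)
    offs <- cumsum(c(0L, sizes))
    vm <- matrix(NA_real_, nv, length(vprops))
    for (j in seq_along(vprops)) {
      ti <- ply_type_info(vprops[[j]]$type)
      idx <- as.vector(outer(seq_len(ti$size) + offs[j],
                             (seq_len(nv) - 1L) * rec, `+`))
      vm[, j] <- readBin(raw[idx], ti$what, n = nv, size = ti$size,
                         endian = endian,
                         signed = !grepl("^u", vprops[[j]]$type))
    }
    colnames(vm) <- vapply(vprops, `[[`, "", "name")
    verts <- vm[, c("x", "y", "z"), drop = FALSE]
    fp <- elements$face$props[[1]]
    cti <- ply_type_info(fp$count_type)
    iti <- ply_type_info(fp$type)
    faces <- vector("list", elements$face$count)
    for (i in seq_len(elements$face$count)) {
      k <- readBin(con, cti$what, n = 1L, size = cti$size, endian = endian,
                   signed = !grepl("^u", fp$count_type))
      faces[[i]] <- as.integer(
        readBin(con, iti$what, n = k, size = iti$size, endian = endian,
                signed = !grepl("^u", fp$type)))
    }
  }
  tri <- triangulate_polys(faces)
  tri_mesh(verts, tri + 1L, provenance = paste("read:", basename(path)))
}

# fan-triangulate polygon faces (0-based index input, 0-based output)
triangulate_polys <- function(faces) {
  ns <- lengths(faces)
  if (any(ns < 3)) stop("corrupt face with fewer than 3 vertices")
  if (any(ns > 4)) stop("polygonal faces with more than 4 vertices are not supported")
  out <- matrix(0L, nrow = sum(ns - 2L), ncol = 3L)
  r <- 1L
  for (f in faces) {
    for (k in seq_len(length(f) - 2L)) {
      out[r, ] <- c(f[1], f[1 + k], f[2 + k])
      r <- r + 1L
    }
  }
  out
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    fm <- t(cbind(3L, mesh$faces - 1L))
    # counts as uchar, indices as int32
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fm[2:4, i]), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
    writeLines(apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " ")), con)
  }
  invisible(path)
}

## ---- STL ----

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = min(80L, sz))
  is_binary <- FALSE
  if (sz > 84) {
    ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    tris <- matrix(NA_real_, ntri, 9)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)  # attribute byte count
      tris[i, ] <- rec[4:12]
    }
  } else {
    close(con)
    on.exit(NULL)
    txt <- readLines(path, warn = FALSE)
    if (!any(grepl("^\\s*solid", txt)))
      stop("corrupt STL file: ", path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    if (length(vl) %% 3 != 0) stop("corrupt ASCII STL (vertex count not multiple of 3): ", path)
    vm <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(s) as.numeric(s[2:4]), numeric(3)))
    tris <- matrix(t(vm), ncol = 9, byrow = TRUE)
  }
  if (nrow(tris) == 0) stop("corrupt STL file (no facets): ", path)
  # merge identical vertices
  pts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  nt <- nrow(tris)
  faces <- cbind(idx[seq_len(nt)], idx[nt + seq_len(nt)], idx[2 * nt + seq_len(nt)])
  tri_mesh(pts[uk, , drop = FALSE], faces,
           provenance = paste("read:", basename(path)))
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(nrm[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]),
               con, size = 4, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("    vertex %.9g %.9g %.9g",
                           v[f[i, k], 1], v[f[i, k], 2], v[f[i, k], 3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

## ---- OBJ ----

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop("corrupt OBJ file (no vertices/faces): ", path)
  vm <- t(vapply(strsplit(trimws(vl), "\\s+"),
                 function(s) as.numeric(s[2:4]), numeric(3)))
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(s) {
    as.integer(vapply(strsplit(s[-1], "/"), `[[`, "", 1L)) - 1L
  })
  tri <- triangulate_polys(faces)
  tri_mesh(vm, tri + 1L, provenance = paste("read:", basename(path)))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " "))), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste("f", paste(r, collapse = " "))), con)
  invisible(path)
}
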