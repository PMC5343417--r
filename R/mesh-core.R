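#' Triangulated surface mesh
#'
#' Constructs the basic surface representation used throughout the package:
#' a triangulated mesh with vertex coordinates in millimetres, in a
#' right-handed frame.  Pipeline inputs are expected to be watertight,
#' single-component and consistently oriented (see [validate_mesh()]).
#'
#' @param vertices numeric matrix with one row per vertex and columns x, y, z
#'   (mm).
#' @param faces integer matrix with one row per triangle, holding 1-based
#'   vertex indices.
#' @param provenance free-text note on where the mesh came from.
#' @return an object of class `tri_mesh` with elements `vertices`, `faces`
#'   and `provenance`.
#' @export
tri_mesh <- function(vertices, faces, provenance = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
  }
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces,
                 provenance = as.character(provenance)[1L]),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# undirected edge list, one row per face edge (3 per face)
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  list(directed = e, key = key)
}

#' Edge lengths of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return numeric vector of unique-edge lengths in mm.
#' @export
edge_lengths <- function(mesh) {
  et <- mesh_edge_table(mesh)
  ek <- unique(et$key)
  d <- mesh$vertices[ek[, 1], , drop = FALSE] -
    mesh$vertices[ek[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

# per-face doubled area vectors (cross products); rowwise
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total surface area of a mesh
#' @param mesh a [tri_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(sqrt(rowSums(face_cross(mesh)^2))) / 2
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume; positive for outward-oriented watertight
#' meshes.
#' @param mesh a [tri_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- face_cross(mesh)
  sum(rowSums(v[f[, 1], , drop = FALSE] * cr)) / 6
}

#' Validate a mesh and report its integrity
#'
#' Reports watertightness (every edge shared by exactly two faces),
#' orientation consistency (shared edges traversed in opposite directions),
#' connected component count, minimum/median edge length and degenerate-face
#' count.  The pipeline entry point rejects meshes that are not watertight
#' single components.
#'
#' @param mesh a [tri_mesh()].
#' @return an object of class `mesh_report`: a list with fields
#'   `watertight`, `oriented`, `n_components`, `min_edge`, `median_edge`,
#'   `n_degenerate_faces`, `n_vertices`, `n_faces`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  et <- mesh_edge_table(mesh)
  id <- paste(et$key[, 1], et$key[, 2])
  cnt <- table(id)
  watertight <- nrow(mesh$faces) > 0 && all(cnt == 2L)
  # orientation: for each undirected edge seen twice, the two directed copies
  # must be opposite
  oriented <- FALSE
  if (watertight) {
    dir_id <- paste(et$directed[, 1], et$directed[, 2])
    oriented <- !any(duplicated(dir_id))
  }
  # connected components over vertices used by faces (union-find)
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(et$key) > 0) {
    for (r in seq_len(nrow(et$key))) {
      a <- find(et$key[r, 1]); b <- find(et$key[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  used <- unique(as.vector(mesh$faces))
  comps <- length(unique(vapply(used, find, integer(1))))
  el <- edge_lengths(mesh)
  areas <- sqrt(rowSums(face_cross(mesh)^2)) / 2
  rep <- list(watertight = watertight,
              oriented = oriented,
              n_components = comps,
              min_edge = if (length(el)) min(el) else NA_real_,
              median_edge = if (length(el)) stats::median(el) else NA_real_,
              n_degenerate_faces = sum(areas <= 1e-12),
              n_vertices = n,
              n_faces = nrow(mesh$faces))
  class(rep) <- "mesh_report"
  rep
}

#' @export
print.mesh_report <- function(x, ...) {
  cat("mesh report\n")
  cat(sprintf("  watertight: %s   oriented: %s   components: %d\n",
              x$watertight, x$oriented, x$n_components))
  cat(sprintf("  edges [mm]: min %.4g, median %.4g; degenerate faces: %d\n",
              x$min_edge, x$median_edge, x$n_degenerate_faces))
  cat(sprintf("  %d vertices, %d faces\n", x$n_vertices, x$n_faces))
  invisible(x)
}

# assert a mesh is fit for pipeline entry
assert_pipeline_mesh <- function(mesh, id = "mesh") {
  rep <- validate_mesh(mesh)
  if (!rep$watertight || rep$n_components != 1L)
    stop(sprintf(
      "%s rejected: watertight=%s, components=%d (pipeline requires a watertight single-component surface)",
      id, rep$watertight, rep$n_components))
  invisible(rep)
}

#' Apply a rigid transform (or any affine map) to a mesh
#' @param mesh a [tri_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, transform) {
  tri_mesh(apply_transform(transform, mesh$vertices), mesh$faces,
           mesh$provenance)
}

#' Mirror a mesh across the sagittal (x = 0) plane
#'
#' Negates the x (medio-lateral) coordinate and flips face winding so the
#' surface stays outward-oriented.
#' @param mesh a [tri_mesh()].
#' @return the mirrored mesh.
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  tri_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE], mesh$provenance)
}
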