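#' Corresponded shape: ordered dense landmarks on one specimen
#'
#' A fixed-length ordered set of surface landmarks; index i refers to the
#' same anatomical location on every specimen of a population.
#'
#' @param points n x 3 matrix of landmark coordinates (mm).
#' @param id specimen identifier.
#' @return an object of class `corresponded_shape`.
#' @export
corresponded_shape <- function(points, id = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L)
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, id = as.character(id)[1L]),
            class = "corresponded_shape")
}

#' @export
print.corresponded_shape <- function(x, ...) {
  cat(sprintf("corresponded_shape '%s': %d landmarks\n", x$id,
              nrow(x$points)))
  invisible(x)
}

# exact closest point of one query point on K triangles simultaneously.
# p: length-3 point; A, B, C: K x 3 triangle vertex matrices.
# Ericson-style region classification, vectorized over triangles.
# Returns K x 3 closest points.
closest_point_on_triangles <- function(p, A, B, C) {
  AB <- B - A; AC <- C - A
  AP <- -sweep(A, 2, p)
  d1 <- rowSums(AB * AP); d2 <- rowSums(AC * AP)
  BP <- -sweep(B, 2, p)
  d3 <- rowSums(AB * BP); d4 <- rowSums(AC * BP)
  CP <- -sweep(C, 2, p)
  d5 <- rowSums(AB * CP); d6 <- rowSums(AC * CP)
  k <- nrow(A)
  out <- matrix(NA_real_, k, 3)
  done <- rep(FALSE, k)
  # vertex regions
  i <- !done & d1 <= 0 & d2 <= 0
  out[i, ] <- A[i, ]; done <- done | i
  i <- !done & d3 >= 0 & d4 <= d3
  out[i, ] <- B[i, ]; done <- done | i
  i <- !done & d6 >= 0 & d5 <= d6
  out[i, ] <- C[i, ]; done <- done | i
  vc <- d1 * d4 - d3 * d2
  i <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(i)) {
    v <- d1[i] / (d1[i] - d3[i])
    out[i, ] <- A[i, , drop = FALSE] + v * AB[i, , drop = FALSE]
    done <- done | i
  }
  vb <- d5 * d2 - d1 * d6
  i <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(i)) {
    w <- d2[i] / (d2[i] - d6[i])
    out[i, ] <- A[i, , drop = FALSE] + w * AC[i, , drop = FALSE]
    done <- done | i
  }
  va <- d3 * d6 - d5 * d4
  i <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(i)) {
    w <- (d4[i] - d3[i]) / ((d4[i] - d3[i]) + (d5[i] - d6[i]))
    out[i, ] <- B[i, , drop = FALSE] +
      w * (C[i, , drop = FALSE] - B[i, , drop = FALSE])
    done <- done | i
  }
  i <- !done
  if (any(i)) {
    denom <- va[i] + vb[i] + vc[i]
    denom[denom == 0] <- 1
    v <- vb[i] / denom
    w <- vc[i] / denom
    out[i, ] <- A[i, , drop = FALSE] + v * AB[i, , drop = FALSE] +
      w * AC[i, , drop = FALSE]
  }
  out
}

#' Closest points on a mesh surface
#'
#' Exact projection of query points onto the surface of a triangulated mesh
#' (any point of any triangle, not just vertices).  Candidate triangles are
#' pre-filtered by a centroid-distance bound, then tested exactly.
#'
#' @param points m x 3 query points.
#' @param mesh a [tri_mesh()].
#' @return list with `points` (m x 3 projected points), `distance`
#'   (m-vector, mm) and `face` (index of the triangle carrying each
#'   projection).
#' @export
closest_point_on_mesh <- function(points, mesh) {
  points <- as.matrix(points)
  if (nrow(mesh$faces) == 0) stop("target mesh is empty")
  v <- mesh$vertices
  f <- mesh$faces
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  # circumscribing radius bound per triangle (max centroid-vertex distance)
  rad <- sqrt(pmax(
    rowSums((v[f[, 1], , drop = FALSE] - cen)^2),
    rowSums((v[f[, 2], , drop = FALSE] - cen)^2),
    rowSums((v[f[, 3], , drop = FALSE] - cen)^2)))
  m <- nrow(points)
  out_p <- matrix(NA_real_, m, 3)
  out_d <- numeric(m)
  out_f <- integer(m)
  c2 <- rowSums(cen^2)
  chunk <- max(1L, floor(2e6 / nrow(f)))
  for (s in seq(1, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    p <- points[s:e, , drop = FALSE]
    dc <- sqrt(pmax(outer(rowSums(p^2), c2, `+`) - 2 * p %*% t(cen), 0))
    for (ii in seq_len(e - s + 1L)) {
      di <- dc[ii, ]
      ub <- min(di + rad)           # distance to best centroid's triangle
      cand <- which(di - rad <= ub) # triangles possibly closer
      pt <- p[ii, ]
      cp <- closest_point_on_triangles(pt, v[f[cand, 1], , drop = FALSE],
                                       v[f[cand, 2], , drop = FALSE],
                                       v[f[cand, 3], , drop = FALSE])
      d2 <- (cp[, 1] - pt[1])^2 + (cp[, 2] - pt[2])^2 + (cp[, 3] - pt[3])^2
      j <- which.min(d2)
      out_p[s + ii - 1L, ] <- cp[j, ]
      out_d[s + ii - 1L] <- sqrt(d2[j])
      out_f[s + ii - 1L] <- cand[j]
    }
  }
  list(points = out_p, distance = out_d, face = out_f)
}

#' Farthest-point subsampling of mesh vertices
#'
#' Deterministic greedy farthest-point sampling used to build the
#' correspondence template: gives near-uniform surface coverage.
#'
#' @param mesh a [tri_mesh()].
#' @param n number of points to select.
#' @param seed integer seed choosing the (otherwise arbitrary) start vertex.
#' @return integer vector of `n` vertex indices.
#' @export
farthest_point_sample <- function(mesh, n, seed = 1L) {
  v <- mesh$vertices
  nv <- nrow(v)
  n <- min(n, nv)
  start <- (as.integer(seed) %% nv) + 1L
  sel <- integer(n)
  sel[1] <- start
  d <- rowSums(sweep(v, 2, v[start, ])^2)
  if (n > 1) for (k in 2:n) {
    i <- which.max(d)
    sel[k] <- i
    d <- pmin(d, rowSums(sweep(v, 2, v[i, ])^2))
  }
  sel
}

#' Build a correspondence template from a reference mesh
#'
#' @param reference the reference specimen's [tri_mesh()] (in the
#'   standardized frame).
#' @param n number of template landmarks; `n = NULL` uses every vertex of
#'   the reference (the mean shape then inherits the reference
#'   connectivity, see [mean_mesh()]).
#' @param seed seed for the farthest-point start vertex.
#' @return a [corresponded_shape()] with attribute `"vertex_index"` (indices
#'   into the reference vertices).
#' @export
make_template <- function(reference, n = 2000L, seed = 1L) {
  stopifnot(inherits(reference, "tri_mesh"))
  idx <- if (is.null(n)) seq_len(nrow(reference$vertices))
         else farthest_point_sample(reference, n, seed)
  out <- corresponded_shape(reference$vertices[idx, , drop = FALSE],
                            id = "template")
  attr(out, "vertex_index") <- idx
  out
}

#' Project a template onto a target surface to obtain correspondence
#'
#' Landmark i of the output is the exact closest point on the target surface
#' to landmark i of the template, after the target has been brought into the
#' template frame by `transform`.  This template-projection rule is exact
#' when specimens are smooth deformations of the template; it deliberately
#' replaces heavier correspondence optimization while keeping the same
#' interface.
#'
#' @param template a [corresponded_shape()].
#' @param target the specimen [tri_mesh()].
#' @param transform [rigid_transform()] mapping the target into the template
#'   frame (identity if already registered).
#' @param id specimen id for the output.
#' @param guard maximal allowed projection distance (mm); larger distances
#'   signal gross misregistration and raise an error.
#' @return a [corresponded_shape()] in the template frame.
#' @export
correspond_to_template <- function(template, target,
                                   transform = rigid_transform(),
                                   id = "", guard = 10) {
  stopifnot(inherits(template, "corresponded_shape"),
            inherits(target, "tri_mesh"))
  tgt <- transform_mesh(target, transform)
  pr <- closest_point_on_mesh(template$points, tgt)
  if (any(pr$distance > guard))
    stop(sprintf(
      "projection distance %.2f mm exceeds guard %.2f mm: target appears misregistered",
      max(pr$distance), guard))
  corresponded_shape(pr$points, id = id)
}

#' Write / read a population of corresponded shapes as CSV
#'
#' Long format: id, point index, x, y, z.
#' @param shapes list of [corresponded_shape()] objects.
#' @param path CSV path.
#' @return `path` (write) or a list of shapes (read).
#' @export
write_shapes_csv <- function(shapes, path) {
  rows <- do.call(rbind, lapply(shapes, function(s) {
    data.frame(id = s$id, point = seq_len(nrow(s$points)),
               x = s$points[, 1], y = s$points[, 2], z = s$points[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shapes_csv
#' @export
read_shapes_csv <- function(path) {
  d <- utils::read.csv(path)
  ids <- unique(d$id)
  lapply(ids, function(i) {
    di <- d[d$id == i, ]
    di <- di[order(di$point), ]
    corresponded_shape(cbind(di$x, di$y, di$z), id = i)
  })
}
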