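#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 translation vector (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation has negative determinant (reflection)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  m <- as_matrix4(x)
  print(round(m, 6))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix (or length-3 vector).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) {
    return(as.numeric(transform$rotation %*% points + transform$translation))
  }
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' Compose two rigid transforms: apply `b` first, then `a`
#' @param a,b [rigid_transform()] objects.
#' @return the composed transform.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation + a$translation))
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' Convert a rigid transform to / from a 4x4 homogeneous matrix
#' @param transform a [rigid_transform()].
#' @return a 4x4 matrix.
#' @export
as_matrix4 <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname as_matrix4
#' @param m a 4x4 homogeneous matrix.
#' @export
from_matrix4 <- function(m) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Serialize / deserialize rigid transforms as JSON 4x4 matrices
#' @param transform a [rigid_transform()].
#' @param path JSON file path.
#' @return `path` (write) or a [rigid_transform()] (read).
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(as_matrix4(transform), path, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  from_matrix4(matrix(unlist(jsonlite::read_json(path)), 4, 4, byrow = TRUE))
}

# Kabsch: least-squares rotation (+ optional scale) mapping x onto y.
# Returns list(rotation, translation, scale) with y ~ scale * R x + t.
kabsch <- function(x, y, scaling = FALSE) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  h <- crossprod(x0, y0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s3 <- diag(c(1, 1, d))
  r <- sv$v %*% s3 %*% t(sv$u)
  s <- 1
  if (scaling) {
    s <- sum(sv$d * c(1, 1, d)) / sum(x0^2)
  }
  t <- as.numeric(cy - s * r %*% cx)
  list(rotation = r, translation = t, scale = s)
}

#' Rigid registration of a point set or mesh onto a target mesh (ICP)
#'
#' Point-to-point iterative closest point with surface correspondence:
#' source points are matched to their exact closest point on the target
#' surface (any point of any triangle) and the optimal rigid motion
#' (Kabsch/SVD) is applied, until the RMS residual change falls below `tol`
#' or `max_iter` is reached.  A cheap nearest-vertex matching phase warms
#' up the alignment before the exact surface projections take over;
#' vertex-only matching alone is not used because its tangential snapping
#' creates spurious fixed points well above the true minimum on densely
#' sampled meshes.  The reported RMS residual (point-to-surface) is
#' non-increasing across iterations.
#'
#' @param source a [tri_mesh()] or an n x 3 point matrix.
#' @param target a [tri_mesh()].
#' @param init initial [rigid_transform()] mapping source into the target
#'   frame; `"principal_axes"` requests a coarse initialization aligning
#'   centroids and principal axes (sign-disambiguated to the rotation closest
#'   to identity).
#' @param max_iter maximum surface-correspondence iterations.
#' @param tol convergence tolerance on the RMS residual change (mm).
#' @param max_points source points are subsampled to at most this many for
#'   speed.
#' @return list with `transform` (a [rigid_transform()]), `rms` (final RMS
#'   residual, mm), `residuals` (per-iteration point-to-surface RMS trace)
#'   and `iterations`.
#' @export
rigid_icp <- function(source, target, init = rigid_transform(),
                      max_iter = 50L, tol = 1e-8, max_points = 500L) {
  src <- if (inherits(source, "tri_mesh")) source$vertices else as.matrix(source)
  stopifnot(inherits(target, "tri_mesh"), max_iter >= 1L)
  tgt <- target$vertices
  if (any(!is.finite(src)) || any(!is.finite(tgt)))
    stop("non-finite coordinates")
  if (nrow(src) == 0 || nrow(tgt) == 0) stop("empty source or target")
  if (nrow(src) > max_points) {
    keep <- round(seq(1, nrow(src), length.out = max_points))
    src <- src[keep, , drop = FALSE]
  }
  if (identical(init, "principal_axes")) init <- principal_axes_init(src, tgt)
  cur <- init
  p <- apply_transform(cur, src)
  # warm start: nearest-vertex matching until it stalls (cheap)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    q <- tgt[nearest_vertex(p, tgt), , drop = FALSE]
    rms <- sqrt(mean(rowSums((p - q)^2)))
    if (prev - rms < max(tol, 1e-6)) break
    prev <- rms
    k <- kabsch(p, q)
    step <- rigid_transform(k$rotation, k$translation)
    cur <- compose_transform(step, cur)
    p <- apply_transform(step, p)
  }
  # exact surface-projection phase
  trace <- numeric(0)
  prev <- Inf
  it <- 0L
  has_faces <- nrow(target$faces) > 0
  surface_rms <- function(pts) {
    if (has_faces) {
      pr <- closest_point_on_mesh(pts, target)
      list(q = pr$points, rms = sqrt(mean(pr$distance^2)))
    } else {
      q <- tgt[nearest_vertex(pts, tgt), , drop = FALSE]
      list(q = q, rms = sqrt(mean(rowSums((pts - q)^2))))
    }
  }
  # cheap nearest-vertex polish from a given state; near the optimum the
  # vertex matching is the true correspondence and converges in a few steps
  # (exactly so when source and target share vertices)
  vertex_polish <- function(cur0, p0) {
    prev0 <- Inf
    for (k2 in seq_len(10L)) {
      q <- tgt[nearest_vertex(p0, tgt), , drop = FALSE]
      rms0 <- sqrt(mean(rowSums((p0 - q)^2)))
      if (prev0 - rms0 < tol) break
      prev0 <- rms0
      k <- kabsch(p0, q)
      step <- rigid_transform(k$rotation, k$translation)
      cur0 <- compose_transform(step, cur0)
      p0 <- apply_transform(step, p0)
    }
    list(cur = cur0, p = p0)
  }
  repeat {
    it <- it + 1L
    sr <- surface_rms(p)
    rms <- sr$rms
    # a polish attempt is adopted only if it strictly improves the
    # point-to-surface residual (keeps the trace monotone)
    pol <- vertex_polish(cur, p)
    sr2 <- surface_rms(pol$p)
    if (sr2$rms < rms - 1e-15) {
      cur <- pol$cur
      p <- pol$p
      sr <- sr2
      rms <- sr2$rms
    }
    trace <- c(trace, rms)
    if (rms < 1e-9 || prev - rms < tol || it >= max_iter) break
    prev <- rms
    k <- kabsch(p, sr$q)
    step <- rigid_transform(k$rotation, k$translation)
    cur <- compose_transform(step, cur)
    p <- apply_transform(step, p)
  }
  list(transform = cur, rms = trace[length(trace)], residuals = trace,
       iterations = it)
}

# nearest target vertex index for each query point (chunked brute force)
nearest_vertex <- function(points, vertices, chunk = 512L) {
  n <- nrow(points)
  out <- integer(n)
  v2 <- rowSums(vertices^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- points[s:e, , drop = FALSE]
    d <- outer(rowSums(p^2), v2, `+`) - 2 * p %*% t(vertices)
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

# coarse init: centroid + principal axes, choosing axis signs that give the
# rotation closest to identity among the four proper sign flips
principal_axes_init <- function(src, tgt) {
  es <- eigen(stats::cov(src), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(tgt), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  best <- NULL
  besttr <- -Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    sgn <- diag(c(s1, s2, s1 * s2))
    r <- et %*% sgn %*% t(es)
    if (sum(diag(r)) > besttr) {
      besttr <- sum(diag(r))
      best <- r
    }
  }
  rigid_transform(best, colMeans(tgt) - as.numeric(best %*% colMeans(src)))
}

#' Generalized Procrustes alignment of corresponded shapes
#'
#' Iteratively superimposes every shape on the evolving mean by optimal
#' rigid motion (Gower/Kabsch) until the mean stabilizes.  With
#' `allow_scaling = FALSE` (the default) each shape's centroid size is
#' preserved exactly, so size differences remain in the aligned data.
#'
#' @param shapes list of [corresponded_shape()] objects (or n x 3 matrices)
#'   with identical landmark counts.
#' @param allow_scaling also fit a per-shape scale factor.
#' @param tol convergence tolerance on the mean shape change.
#' @param max_iter iteration cap.
#' @return list with `aligned` (list of shapes, input order), `mean` (n x 3
#'   matrix), `residuals` (per-shape RMS distance to the mean, mm).
#' @export
generalized_procrustes <- function(shapes, allow_scaling = FALSE,
                                   tol = 1e-9, max_iter = 200L) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  mats <- lapply(shapes, function(s)
    if (inherits(s, "corresponded_shape")) s$points else as.matrix(s))
  ns <- vapply(mats, nrow, 0L)
  if (length(unique(ns)) != 1L) stop("mismatched landmark counts")
  # center all
  mats <- lapply(mats, function(m) sweep(m, 2, colMeans(m)))
  mean_shape <- mats[[1]]
  repeat_count <- 0L
  repeat {
    repeat_count <- repeat_count + 1L
    aligned <- lapply(mats, function(m) {
      k <- kabsch(m, mean_shape, scaling = allow_scaling)
      k$scale * m %*% t(k$rotation) + rep(1, nrow(m)) %o% k$translation
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    if (allow_scaling) {
      # keep mean centroid size fixed to avoid global shrink
      cs0 <- sqrt(sum(mean_shape^2))
      cs1 <- sqrt(sum(new_mean^2))
      if (cs1 > 0) new_mean <- new_mean * (cs0 / cs1)
    }
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    mats <- aligned
    if (delta < tol || repeat_count >= max_iter) break
  }
  res <- vapply(mats, function(m) sqrt(mean(rowSums((m - mean_shape)^2))),
                0)
  out_shapes <- mats
  for (i in seq_along(shapes)) {
    if (inherits(shapes[[i]], "corresponded_shape")) {
      out_shapes[[i]] <- corresponded_shape(mats[[i]], shapes[[i]]$id)
    }
  }
  list(aligned = out_shapes, mean = mean_shape, residuals = res)
}

#' Centroid size of a shape
#' @param shape an n x 3 matrix or [corresponded_shape()].
#' @return square root of the summed squared distances to the centroid.
#' @export
centroid_size <- function(shape) {
  m <- if (inherits(shape, "corresponded_shape")) shape$points else as.matrix(shape)
  m <- sweep(m, 2, colMeans(m))
  sqrt(sum(m^2))
}
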