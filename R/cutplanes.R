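#' Detect the styloid and dorsal-tubercle landmarks
#'
#' On a mesh in the standardized frame (+z distal, +y dorsal), the styloid
#' tip is the surface point with the greatest axial (+z) coordinate and the
#' dorsal tubercle is the most dorsal (+y) surface point within the distal
#' quarter of the bone's axial extent (restricting the search prevents the
#' dorsal bow of the shaft from capturing the maximum).  Both are returned
#' as mesh vertices.  If the candidate maximum is a near-tie across a wide
#' region (e.g. the flat end cap of a featureless cylinder) the landmark is
#' declared unidentifiable.
#'
#' @param mesh a [tri_mesh()] in the standardized frame.
#' @param distal_fraction fraction of the axial extent (from the distal
#'   end) searched for the tubercle.
#' @param tie_tol vertices within this distance (mm) of the extreme value
#'   count as candidates for the uniqueness check.
#' @param spread_tol maximal allowed candidate spread, as a fraction of the
#'   bounding-box diagonal, before the landmark is declared unidentifiable.
#' @return an object of class `landmarks`: list with `styloid_tip`,
#'   `tubercle_dorsal` (3-vectors, mm) and `frame` (unit axis, dorsal and
#'   lateral vectors).
#' @export
detect_landmarks <- function(mesh, distal_fraction = 0.25, tie_tol = 0.5,
                             spread_tol = 0.25) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  diag_len <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  pick <- function(vals, sub, what) {
    mx <- max(vals[sub])
    cand <- sub[vals[sub] > mx - tie_tol]
    spread <- max(stats::dist(v[cand, c(1, 2, 3) , drop = FALSE]))
    if (length(cand) > 1 && spread > spread_tol * diag_len)
      stop(sprintf(
        "landmarks not identifiable: %s maximum is tied across a %.1f mm region",
        what, spread))
    cand[which.max(vals[cand])]
  }
  i_sty <- pick(v[, 3], seq_len(nrow(v)), "axial (styloid)")
  zr <- range(v[, 3])
  window <- which(v[, 3] >= zr[2] - distal_fraction * diff(zr))
  i_tub <- pick(v[, 2], window, "dorsal (tubercle)")
  sty <- v[i_sty, ]
  tub <- v[i_tub, ]
  if (sty[3] <= tub[3])
    stop("landmarks not identifiable: styloid is not distal to the tubercle")
  structure(list(styloid_tip = sty, tubercle_dorsal = tub,
                 frame = list(axis = c(0, 0, 1), dorsal = c(0, 1, 0),
                              lateral = c(1, 0, 0))),
            class = "landmarks")
}

#' @export
print.landmarks <- function(x, ...) {
  cat(sprintf("landmarks: styloid tip (%.2f, %.2f, %.2f), dorsal tubercle (%.2f, %.2f, %.2f)\n",
              x$styloid_tip[1], x$styloid_tip[2], x$styloid_tip[3],
              x$tubercle_dorsal[1], x$tubercle_dorsal[2], x$tubercle_dorsal[3]))
  invisible(x)
}

#' A standardized cut plane
#' @param label `"distal"`, `"middle"` or `"proximal"`.
#' @param origin a point on the plane (mm).
#' @param normal unit normal (parallel to the main axis).
#' @return an object of class `cut_plane`.
#' @export
cut_plane <- function(label, origin, normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(label = label, origin = as.numeric(origin),
                 normal = as.numeric(normal)),
            class = "cut_plane")
}

#' Define the three standardized cut planes from the landmarks
#'
#' All planes are perpendicular to the main axis.  With z_s and z_t the
#' axial coordinates of the styloid tip and the dorsal tubercle point and
#' d = z_s - z_t > 0: the distal plane lies at z_t, the proximal plane at
#' z_t - d/2 (half the styloid-tubercle axial distance further proximal),
#' and the middle plane halfway between the two, at z_t - d/4.  The two
#' plane gaps are therefore equal (d/4).
#'
#' @param landmarks a [landmarks()] object.
#' @return named list of three [cut_plane()] objects
#'   (`distal`, `middle`, `proximal`).
#' @export
define_cut_planes <- function(landmarks) {
  z_s <- landmarks$styloid_tip[3]
  z_t <- landmarks$tubercle_dorsal[3]
  d <- z_s - z_t
  if (d <= 0) stop("styloid-tubercle axial distance is not positive")
  mk <- function(label, z) cut_plane(label, c(0, 0, z), c(0, 0, 1))
  list(distal = mk("distal", z_t),
       middle = mk("middle", z_t - d / 4),
       proximal = mk("proximal", z_t - d / 2))
}

#' Planar cross-section contour of a mesh
#'
#' Intersects every triangle with the plane, chains the resulting segments
#' into closed loops by their shared mesh edges, and returns the loop with
#' the largest enclosed area as a counter-clockwise polygon in plane
#' coordinates (x = lateral, y = dorsal for an axis-perpendicular plane).
#' An open chain indicates a non-watertight mesh and is an error; a plane
#' missing the mesh is an error.
#'
#' @param mesh a [tri_mesh()].
#' @param plane a [cut_plane()].
#' @return an object of class `section_contour`: list with `vertices`
#'   (n x 2 CCW polygon, mm), `plane`, and `n_loops` (number of closed
#'   loops found at this height).
#' @export
cross_section <- function(mesh, plane) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(plane, "cut_plane"))
  v <- mesh$vertices
  n <- plane$normal
  h <- as.numeric(v %*% n) - sum(plane$origin * n)
  # avoid exact vertex-on-plane degeneracies by a deterministic tiny nudge
  tol <- 1e-9 * max(1, max(abs(h)))
  if (any(abs(h) < tol)) h <- h - 3.1415 * tol
  f <- mesh$faces
  hs <- matrix(h[f], ncol = 3)
  straddle <- (apply(hs, 1, min) < 0) & (apply(hs, 1, max) > 0)
  if (!any(straddle)) stop("plane misses mesh")
  ff <- f[straddle, , drop = FALSE]
  hh <- hs[straddle, , drop = FALSE]
  # per triangle, the two crossing edges; identify each crossing point by
  # its (sorted) mesh edge so chaining is exact
  seg_pts <- list(); seg_keys <- list()
  edge_pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  for (i in seq_len(nrow(ff))) {
    pts <- matrix(NA_real_, 0, 3)
    keys <- character(0)
    for (ep in edge_pairs) {
      ha <- hh[i, ep[1]]; hb <- hh[i, ep[2]]
      if ((ha < 0) != (hb < 0)) {
        a <- ff[i, ep[1]]; b <- ff[i, ep[2]]
        t <- ha / (ha - hb)
        pts <- rbind(pts, v[a, ] + t * (v[b, ] - v[a, ]))
        keys <- c(keys, paste(min(a, b), max(a, b)))
      }
    }
    seg_pts[[length(seg_pts) + 1L]] <- pts
    seg_keys[[length(seg_keys) + 1L]] <- keys
  }
  # chain segments: each segment joins two edge keys
  k1 <- vapply(seg_keys, `[`, "", 1L)
  k2 <- vapply(seg_keys, `[`, "", 2L)
  nseg <- length(k1)
  used <- rep(FALSE, nseg)
  # adjacency: for every edge key, the (up to 2) segments touching it
  keymap <- split(rep(seq_len(nseg), 2L), c(k1, k2))
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    loop_keys <- character(0)
    cur <- start
    enter_key <- k1[start]
    repeat {
      used[cur] <- TRUE
      exit_key <- if (k1[cur] == enter_key) k2[cur] else k1[cur]
      loop_keys <- c(loop_keys, exit_key)
      nxt <- setdiff(keymap[[exit_key]], cur)
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      cur <- nxt[1]
      enter_key <- exit_key
    }
    # a loop is closed iff its last exit key equals the start's entry key
    if (loop_keys[length(loop_keys)] != k1[start])
      stop(sprintf("open section chain at mesh edge %s: mesh is not watertight",
                   loop_keys[length(loop_keys)]))
    loops[[length(loops) + 1L]] <- loop_keys
  }
  # crossing point for each edge key (same point whichever triangle computed
  # it, because the interpolation is along the shared mesh edge)
  all_pts <- do.call(rbind, seg_pts)
  all_keys <- unlist(seg_keys)
  first <- !duplicated(all_keys)
  pt_of <- all_pts[first, , drop = FALSE]
  rownames(pt_of) <- all_keys[first]
  # plane coordinate frame
  u1 <- if (abs(n[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  ex <- u1 - sum(u1 * n) * n
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(n[2] * ex[3] - n[3] * ex[2],
          n[3] * ex[1] - n[1] * ex[3],
          n[1] * ex[2] - n[2] * ex[1])
  to2d <- function(keys) {
    p <- pt_of[keys, , drop = FALSE]
    p0 <- sweep(p, 2, plane$origin)
    cbind(as.numeric(p0 %*% ex), as.numeric(p0 %*% ey))
  }
  polys <- lapply(loops, to2d)
  areas <- vapply(polys, function(p) abs(polygon_signed_area(p)), 0)
  if (max(areas) < 1e-12) stop("degenerate contour: plane is tangent to the mesh")
  best <- polys[[which.max(areas)]]
  if (polygon_signed_area(best) < 0) best <- best[rev(seq_len(nrow(best))), ]
  colnames(best) <- c("x", "y")
  structure(list(vertices = best, plane = plane, n_loops = length(loops)),
            class = "section_contour")
}

#' @export
print.section_contour <- function(x, ...) {
  cat(sprintf("section_contour (%s): %d vertices, area %.2f mm^2\n",
              x$plane$label, nrow(x$vertices),
              polygon_signed_area(x$vertices)))
  invisible(x)
}

#' Morphometric parameters of a section contour
#'
#' Width is the contour extent along the lateral (x) axis, depth the extent
#' along the dorsal (y) axis, the perimeter is the polygon edge-length sum
#' and the area the absolute shoelace area.
#'
#' @param contour a [section_contour()] or an n x 2 polygon matrix.
#' @return an object of class `morphometrics`: list with `width`, `depth`,
#'   `perimeter` (mm) and `area` (mm^2).
#' @export
section_morphometrics <- function(contour) {
  xy <- if (inherits(contour, "section_contour")) contour$vertices
        else as.matrix(contour)
  if (nrow(xy) < 3L) stop("contour needs at least 3 vertices")
  out <- list(width = diff(range(xy[, 1])),
              depth = diff(range(xy[, 2])),
              perimeter = polygon_perimeter(xy),
              area = abs(polygon_signed_area(xy)))
  class(out) <- "morphometrics"
  out
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf("width %.2f mm, depth %.2f mm, perimeter %.2f mm, area %.2f mm^2\n",
              x$width, x$depth, x$perimeter, x$area))
  invisible(x)
}

#' Morphometrics of one specimen at the three standardized planes
#'
#' Convenience wrapper: landmark detection, plane construction, sectioning
#' and morphometrics in one call.
#'
#' @param mesh a [tri_mesh()] in the standardized frame.
#' @param id,gender,side metadata copied into the output rows.
#' @return data.frame with one row per plane: id, gender, side, plane,
#'   width, depth, perimeter, area, plane_z.
#' @export
specimen_morphometrics <- function(mesh, id = "", gender = NA, side = NA) {
  lm <- detect_landmarks(mesh)
  planes <- define_cut_planes(lm)
  do.call(rbind, lapply(planes, function(pl) {
    m <- section_morphometrics(cross_section(mesh, pl))
    data.frame(id = id, gender = gender, side = side, plane = pl$label,
               width = m$width, depth = m$depth, perimeter = m$perimeter,
               area = m$area, plane_z = pl$origin[3])
  }))
}
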