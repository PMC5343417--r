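# geometric fixtures built in code

icosphere <- function(r = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    mids <- new.env()
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (is.null(mids[[k]])) {
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        mids[[k]] <- nrow(v)
      }
      mids[[k]]
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c0 <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c0); ca <- getmid(c0, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(ab, b, bc),
                                         c(ca, bc, c0), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  tri_mesh(v, f)
}

unit_cube <- function() {
  tri_mesh(as.matrix(expand.grid(0:1, 0:1, 0:1)),
           rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
                 c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
                 c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6)))
}

unit_tetrahedron <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

ball_mask <- function(r = 10, spacing = c(0.5, 0.5, 0.5), pad = 2) {
  gx <- seq(-r - pad, r + pad, by = spacing[1])
  gy <- seq(-r - pad, r + pad, by = spacing[2])
  gz <- seq(-r - pad, r + pad, by = spacing[3])
  arr <- array(FALSE, c(length(gx), length(gy), length(gz)))
  for (k in seq_along(gz))
    arr[, , k] <- outer(gx^2, gy^2, `+`) + gz[k]^2 <= r^2
  voxel_mask(arr, spacing = spacing, origin = c(gx[1], gy[1], gz[1]))
}

# independent point-to-surface oracle: min distance over a dense
# barycentric sampling of every triangle (slow, brute force)
oracle_point_to_mesh <- function(p, mesh, grid = 12L) {
  u <- seq(0, 1, length.out = grid)
  bc <- expand.grid(a = u, b = u)
  bc <- bc[bc$a + bc$b <= 1, ]
  best <- Inf
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], ]
    pts <- outer(1 - bc$a - bc$b, tri[1, ]) + outer(bc$a, tri[2, ]) +
      outer(bc$b, tri[3, ])
    best <- min(best, sqrt(min(rowSums(sweep(pts, 2, p)^2))))
  }
  best
}
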