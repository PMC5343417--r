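# shoelace signed area of a closed polygon (n x 2, implicit closure)
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(xy) {
  d <- xy - xy[c(seq_len(nrow(xy))[-1], 1L), ]
  sum(sqrt(rowSums(d^2)))
}

#' Reference morphometric statistics of the adult distal radius
#'
#' Published CT-based reference values (mean and SD in mm / mm^2) of the
#' four morphometric parameters at the three standardized cross-sectional
#' cut planes, by gender.  These anchor the calibration of the synthetic
#' population defaults: the female distal-plane width/depth/area are matched
#' exactly by the default bone, the other planes set the fixed taper, and
#' the male/female width ratio sets the default gender size factor.
#'
#' @return data.frame with columns `plane`, `parameter`, `gender`, `mean`,
#'   `sd`.
#' @export
reference_morphometrics <- function() {
  g <- function(plane, gender, w, d, p, a) {
    data.frame(plane = plane,
               parameter = c("width", "depth", "perimeter", "area"),
               gender = gender,
               mean = c(w[1], d[1], p[1], a[1]),
               sd = c(w[2], d[2], p[2], a[2]))
  }
  rbind(
    g("distal",   "F", c(29.0, 2.1), c(21.0, 1.7), c(86.1, 6.1), c(472.6, 70.2)),
    g("middle",   "F", c(28.2, 2.3), c(19.5, 1.8), c(81.5, 7.0), c(427.5, 69.3)),
    g("proximal", "F", c(26.3, 2.4), c(17.2, 1.7), c(73.4, 7.4), c(353.2, 66.0)),
    g("distal",   "M", c(33.0, 2.1), c(23.8, 1.4), c(96.5, 6.0), c(593.1, 62.1)),
    g("middle",   "M", c(31.2, 2.2), c(21.6, 1.7), c(90.4, 6.7), c(516.9, 67.7)),
    g("proximal", "M", c(28.6, 2.4), c(18.6, 1.9), c(79.7, 7.7), c(416.0, 71.4)))
}

ref_value <- function(tab, plane, parameter, gender = "F") {
  tab$mean[tab$plane == plane & tab$parameter == parameter &
             tab$gender == gender]
}

# analytic cut contour of a calibration candidate (one plane), without
# needing a full bone_params object: superellipse plus the dorsal bump tail
calib_contour <- function(a, b, p, bump_amp, bump_theta, bump_sig_theta,
                          n = 2000L) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  se <- superellipse_xy(theta, p)
  cbind(a * se[, 1],
        b * se[, 2] + bump_amp * exp(-(theta - bump_theta)^2 /
                                       (2 * bump_sig_theta^2)))
}

#' Calibrate station profiles to target plane morphometrics
#'
#' Solves the swept-profile parameters so that the analytic cross-sections
#' of the mean bone at the three standardized plane heights reproduce the
#' requested width, depth and area: the half-width comes directly from the
#' width, the half-depth from the depth (minus the tubercle prominence at
#' the distal plane, where the plane passes through the bump apex), and the
#' superellipse exponent is found by root-finding on the exact polygon area
#' of the resulting contour.  One station is placed at each plane height;
#' further stations extend the taper into the shaft and round the articular
#' end.
#'
#' @param targets data.frame like [reference_morphometrics()] restricted to
#'   one gender; defaults to the bundled female reference values.
#' @param axis_length,styloid_height,tubercle_z_fraction,tubercle_prominence
#'   mean-geometry constants of the bone the stations are solved for.
#' @param tubercle_theta angular bump position (radians).
#' @param tubercle_sigma_theta,tubercle_sigma_z bump widths (radians, mm).
#' @return data.frame of station profiles for [bone_params()].
#' @export
calibrate_station_profiles <- function(targets = NULL,
                                       axis_length = 70,
                                       styloid_height = 6,
                                       tubercle_z_fraction = 62 / 70,
                                       tubercle_prominence = 1.2,
                                       tubercle_theta = pi / 2 - 0.3,
                                       tubercle_sigma_theta = 0.30,
                                       tubercle_sigma_z = 1.2) {
  if (is.null(targets)) {
    tab <- reference_morphometrics()
    targets <- tab[tab$gender == "F", ]
  }
  L <- axis_length
  zt <- tubercle_z_fraction * L
  d <- (L + styloid_height) - zt      # styloid-tubercle axial distance
  plane_z <- c(proximal = zt - d / 2, middle = zt - d / 4, distal = zt)
  if (plane_z["proximal"] <= 0)
    stop("geometry places the proximal plane outside the bone")

  solve_station <- function(plane) {
    w <- ref_value(targets, plane, "width")
    dp <- ref_value(targets, plane, "depth")
    ar <- ref_value(targets, plane, "area")
    dz <- zt - plane_z[[plane]]
    amp <- tubercle_prominence * exp(-dz^2 / (2 * tubercle_sigma_z^2))
    a <- w / 2
    # the off-midline bump makes both the depth and the area relations
    # implicit; alternate the two one-dimensional solves (weak coupling)
    b <- (dp - amp) / 2
    p <- 2
    for (pass in 1:4) {
      depth_of <- function(bb) {
        cc <- calib_contour(a, bb, p, amp, tubercle_theta,
                            tubercle_sigma_theta)
        diff(range(cc[, 2])) - dp
      }
      b <- stats::uniroot(depth_of, c(0.05 * dp, 0.75 * dp),
                          tol = 1e-10)$root
      area_of <- function(pp) {
        abs(polygon_signed_area(
          calib_contour(a, b, pp, amp, tubercle_theta,
                        tubercle_sigma_theta))) - ar
      }
      p <- stats::uniroot(area_of, c(1.05, 12), tol = 1e-10)$root
    }
    c(a = a, b = b, p = p)
  }
  st <- vapply(c("proximal", "middle", "distal"), solve_station, numeric(3))
  zf <- plane_z / L
  out <- data.frame(
    zf = c(0, zf[["proximal"]], zf[["middle"]], zf[["distal"]], 1),
    half_width = c(0.80 * st["a", "proximal"], st["a", ],
                   st["a", "distal"]),
    half_depth = c(0.80 * st["b", "proximal"], st["b", ],
                   0.95 * st["b", "distal"]),
    squareness = c(st["p", "proximal"], st["p", ], st["p", "distal"]))
  rownames(out) <- NULL
  out
}

# lazily computed package defaults (calibration involves root finding)
.radius_defaults <- new.env(parent = emptyenv())

get_radius_default <- function(name) {
  if (!exists(name, envir = .radius_defaults)) {
    if (name == "station_profiles") {
      assign("station_profiles", calibrate_station_profiles(),
             envir = .radius_defaults)
    } else stop("unknown default: ", name)
  }
  get(name, envir = .radius_defaults)
}
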