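#' Fit a Point Distribution Model
#'
#' The Point Distribution Model (PDM) is the statistical core of the
#' package: principal-component analysis of aligned, corresponded landmark
#' sets.  Shapes are flattened to 3n-vectors (x1,y1,z1,x2,...), the mean is
#' the arithmetic mean, and modes/eigenvalues come from the sample
#' covariance (divisor n_samples - 1) via an SVD of the centered data matrix
#' -- rank-safe when the landmark dimension vastly exceeds the sample count.
#' Eigenvalues are sorted in decreasing order; each mode's entry of largest
#' magnitude is made positive so the decomposition is deterministic across
#' platforms.
#'
#' @param shapes list of [corresponded_shape()] objects (or n x 3 matrices)
#'   with identical landmark counts, already aligned (see
#'   [generalized_procrustes()]).
#' @return an object of class `pdm` with elements `mean` (3n-vector, mm),
#'   `modes` (3n x k orthonormal matrix), `eigenvalues` (k-vector, mm^2,
#'   decreasing), `n_samples`, `n_landmarks`.
#' @seealso [num_modes()], [project_shape()], [synthesize_shape()],
#'   [mode_deviation()], [mean_mesh()]
#' @export
pdm <- function(shapes) {
  if (length(shapes) < 2L) stop("need at least 2 shapes to fit a PDM")
  mats <- lapply(shapes, function(s)
    if (inherits(s, "corresponded_shape")) s$points else as.matrix(s))
  nl <- vapply(mats, nrow, 0L)
  if (length(unique(nl)) != 1L) stop("mismatched landmark counts")
  x <- t(vapply(mats, function(m) as.vector(t(m)), numeric(3L * nl[1])))
  if (any(!is.finite(x))) stop("NaN or infinite coordinates in shapes")
  m <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = min(m - 1L, ncol(xc)))
  ev <- (sv$d[seq_len(ncol(sv$v))]^2) / (m - 1)
  modes <- sv$v
  # deterministic sign: largest-magnitude entry of each mode positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  structure(list(mean = mu, modes = modes, eigenvalues = ev,
                 n_samples = m, n_landmarks = nl[1]),
            class = "pdm")
}

#' @export
print.pdm <- function(x, ...) {
  cat(sprintf("Point Distribution Model: %d samples, %d landmarks, %d modes\n",
              x$n_samples, x$n_landmarks, length(x$eigenvalues)))
  tot <- sum(x$eigenvalues)
  if (tot > 0) {
    k <- min(5L, length(x$eigenvalues))
    cat(sprintf("  first %d modes explain %.1f%% of variance (95%% at %d modes)\n",
                k, 100 * sum(x$eigenvalues[seq_len(k)]) / tot,
                num_modes(x, 0.95)))
  } else {
    cat("  zero shape variance\n")
  }
  invisible(x)
}

#' @export
summary.pdm <- function(object, threshold = 0.95, ...) {
  ev <- object$eigenvalues
  tot <- sum(ev)
  frac <- if (tot > 0) ev / tot else rep(0, length(ev))
  out <- list(
    n_samples = object$n_samples,
    n_landmarks = object$n_landmarks,
    eigenvalues = ev,
    explained = frac,
    cumulative = cumsum(frac),
    threshold = threshold,
    n_modes = num_modes(object, threshold))
  class(out) <- "summary.pdm"
  out
}

#' @export
print.summary.pdm <- function(x, ...) {
  cat(sprintf("PDM summary: %d samples, %d landmarks\n", x$n_samples,
              x$n_landmarks))
  k <- min(10L, length(x$eigenvalues))
  if (k > 0) {
    df <- data.frame(mode = seq_len(k),
                     eigenvalue = signif(x$eigenvalues[seq_len(k)], 4),
                     explained = sprintf("%.1f%%", 100 * x$explained[seq_len(k)]),
                     cumulative = sprintf("%.1f%%", 100 * x$cumulative[seq_len(k)]))
    print(df, row.names = FALSE)
  }
  cat(sprintf("modes for %.0f%% explained variance: %d\n",
              100 * x$threshold, x$n_modes))
  invisible(x)
}

#' @export
#' @importFrom graphics barplot abline
plot.pdm <- function(x, threshold = 0.95, ...) {
  ev <- x$eigenvalues
  tot <- sum(ev)
  if (tot <= 0) stop("zero-variance model has no spectrum to plot")
  graphics::barplot(100 * ev / tot, names.arg = seq_along(ev),
                    xlab = "mode", ylab = "% variance explained", ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Number of modes at an explained-variance threshold
#'
#' The smallest m such that the first m eigenvalues account for at least
#' `threshold` of the total variance (inclusive rule: a cumulative fraction
#' exactly at the threshold counts).  A zero-variance model has 0 modes.
#'
#' @param model a [pdm()].
#' @param threshold fraction in (0, 1].
#' @return integer mode count.
#' @export
num_modes <- function(model, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  ev <- model$eigenvalues
  tot <- sum(ev)
  if (tot <= 0) return(0L)
  cum <- cumsum(ev) / tot
  which(cum >= threshold - 1e-12)[1]
}

# flatten a shape to the model's 3n coordinate vector (x1,y1,z1,x2,...)
as_shape_vector <- function(model, shape) {
  if (inherits(shape, "corresponded_shape")) shape <- shape$points
  if (is.null(dim(shape))) {
    if (length(shape) != length(model$mean))
      stop("shape vector length does not match model")
    return(as.numeric(shape))
  }
  m <- as.matrix(shape)
  if (nrow(m) != model$n_landmarks || ncol(m) != 3L)
    stop("landmark count does not match model")
  as.vector(t(m))
}

vector_as_shape <- function(model, vec, id = "") {
  corresponded_shape(matrix(vec, ncol = 3, byrow = TRUE), id = id)
}

#' Project a shape into model coefficient space
#'
#' Coefficients are modes' inner products with the mean-centered shape
#' vector; `synthesize_shape(project_shape(x))` with all modes reproduces a
#' training shape exactly.
#'
#' @param model a [pdm()].
#' @param shape a [corresponded_shape()], n x 3 matrix or 3n-vector.
#' @param n_modes number of leading modes to use (default: all).
#' @return numeric coefficient vector.
#' @export
project_shape <- function(model, shape, n_modes = NULL) {
  v <- as_shape_vector(model, shape)
  k <- if (is.null(n_modes)) ncol(model$modes) else n_modes
  if (k > ncol(model$modes)) stop("mode index out of range")
  as.numeric(crossprod(model$modes[, seq_len(k), drop = FALSE],
                       v - model$mean))
}

#' @export
predict.pdm <- function(object, shape, n_modes = NULL, ...) {
  project_shape(object, shape, n_modes)
}

#' Synthesize a shape from model coefficients
#'
#' @param model a [pdm()].
#' @param coefficients coefficient vector (length at most the mode count).
#' @param id id for the returned shape.
#' @return a [corresponded_shape()].
#' @export
synthesize_shape <- function(model, coefficients, id = "synthesized") {
  k <- length(coefficients)
  if (k > ncol(model$modes)) stop("mode index out of range")
  v <- model$mean
  if (k > 0)
    v <- v + as.numeric(model$modes[, seq_len(k), drop = FALSE] %*% coefficients)
  vector_as_shape(model, v, id = id)
}

#' Shape at k standard deviations along one mode
#'
#' mean + k * sqrt(eigenvalue_i) * mode_i; the conventional rendering of a
#' model's variation (e.g. -3...+3 SD along the first mode).
#'
#' @param model a [pdm()].
#' @param mode mode index.
#' @param k deviation in SD units.
#' @return a [corresponded_shape()].
#' @export
mode_deviation <- function(model, mode, k) {
  if (mode < 1 || mode > length(model$eigenvalues))
    stop("mode index out of range")
  v <- model$mean + k * sqrt(model$eigenvalues[mode]) * model$modes[, mode]
  vector_as_shape(model, v, id = sprintf("mode%d_%+gSD", mode, k))
}

#' Mesh for a model-space shape
#'
#' When the model was built on full-vertex correspondences of a reference
#' mesh (see [make_template()] with `n = NULL`), any synthesized shape --
#' in particular the mean -- inherits the reference connectivity and can be
#' rendered and cut like a specimen mesh.
#'
#' @param model a [pdm()].
#' @param reference the reference [tri_mesh()] providing connectivity.
#' @param shape a shape vector/object; default is the model mean.
#' @return a [tri_mesh()].
#' @export
mean_mesh <- function(model, reference, shape = NULL) {
  stopifnot(inherits(reference, "tri_mesh"))
  if (model$n_landmarks != nrow(reference$vertices))
    stop("model landmarks do not match reference vertices; build the template with n = NULL")
  v <- if (is.null(shape)) model$mean else as_shape_vector(model, shape)
  tri_mesh(matrix(v, ncol = 3, byrow = TRUE), reference$faces,
           provenance = "pdm mean shape")
}

#' Export mode-deviation meshes
#'
#' Writes the mean and +/- k SD surfaces of one mode as PLY files for visual
#' inspection.
#'
#' @param model a [pdm()] built on full-vertex correspondence.
#' @param reference reference [tri_mesh()] (connectivity).
#' @param mode mode index.
#' @param k_values SD offsets to export.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
export_mode_meshes <- function(model, reference, mode = 1L,
                               k_values = c(-3, -2, -1, 1, 2, 3),
                               dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p0 <- file.path(dir, "mean.ply")
  write_mesh(mean_mesh(model, reference), p0)
  paths <- c(paths, p0)
  for (k in k_values) {
    sh <- mode_deviation(model, mode, k)
    p <- file.path(dir, sprintf("mode%d_%+gSD.ply", mode, k))
    write_mesh(mean_mesh(model, reference, sh), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Serialize / load a PDM as JSON
#'
#' One self-contained JSON file: counts, eigenvalues, mean and mode arrays.
#' @param model a [pdm()].
#' @param path file path.
#' @return `path` (write) or a [pdm()] (read).
#' @export
write_pdm_json <- function(model, path) {
  obj <- list(n_samples = model$n_samples, n_landmarks = model$n_landmarks,
              eigenvalues = model$eigenvalues, mean = model$mean,
              modes = model$modes)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pdm_json
#' @export
read_pdm_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  structure(list(mean = as.numeric(o$mean),
                 modes = as.matrix(o$modes),
                 eigenvalues = as.numeric(o$eigenvalues),
                 n_samples = as.integer(o$n_samples),
                 n_landmarks = as.integer(o$n_landmarks)),
            class = "pdm")
}
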