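#' Construct a path of images
#'
#' A path is an ordered set of conformations ("images") of one system,
#' stored as a matrix with one flattened conformation per row, together with
#' its arc-length parameterization and endpoint-fixing flags.
#'
#' @param images Either a numeric matrix (`n_images x ndof`) or a list of
#'   conformation matrices with identical shapes.
#' @param fixed_endpoints Logical; when `TRUE` the first and last images are
#'   never moved by path operations that respect the flag. Default `TRUE`.
#' @param n_particles,ndim Geometry of each image; inferred from list input.
#' @return Object of class `tpath`: the image matrix with attributes
#'   `arc` (normalized arc-length values in `[0, 1]`), `fixed_endpoints`,
#'   `n_particles`, `ndim`.
#' @export
make_path <- function(images, fixed_endpoints = TRUE,
                      n_particles = NULL, ndim = NULL) {
  if (is.list(images)) {
    n_particles <- nrow(as.matrix(images[[1]]))
    ndim <- ncol(as.matrix(images[[1]]))
    images <- do.call(rbind, lapply(images, function(m) as.numeric(t(m))))
  }
  images <- as.matrix(images)
  if (nrow(images) < 2) stop("a path needs at least 2 images")
  if (is.null(n_particles)) n_particles <- 1L
  if (is.null(ndim)) ndim <- ncol(images)
  structure(images, arc = .arc_values(images),
            fixed_endpoints = fixed_endpoints,
            n_particles = as.integer(n_particles), ndim = as.integer(ndim),
            class = c("tpath", "matrix", "array"))
}

# normalized cumulative arc length of a polyline (rows = points)
.arc_values <- function(mat) {
  seg <- sqrt(rowSums((mat[-1, , drop = FALSE] -
                         mat[-nrow(mat), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(seq(0, 1, length.out = nrow(mat)))
  s / s[length(s)]
}

#' Total polyline length of a path
#' @param path A [make_path()] object or plain matrix of row-images.
#' @return Scalar length in the image coordinate norm.
#' @export
path_length <- function(path) {
  mat <- unclass(path)
  sum(sqrt(rowSums((mat[-1, , drop = FALSE] -
                      mat[-nrow(mat), , drop = FALSE])^2)))
}

# Place points at prescribed normalized arc lengths on a polyline.
.interp_polyline <- function(mat, s_out) {
  seg <- sqrt(rowSums((mat[-1, , drop = FALSE] -
                         mat[-nrow(mat), , drop = FALSE])^2))
  total <- sum(seg)
  if (total == 0) stop("zero-length path: all images identical")
  s <- c(0, cumsum(seg)) / total
  out <- matrix(NA_real_, length(s_out), ncol(mat))
  for (q in seq_along(s_out)) {
    t0 <- min(max(s_out[q], 0), 1)
    k <- findInterval(t0, s, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(seg))
    denom <- s[k + 1] - s[k]
    frac <- if (denom > 0) (t0 - s[k]) / denom else 0
    out[q, ] <- mat[k, ] + frac * (mat[k + 1, ] - mat[k, ])
  }
  out
}

.repath <- function(mat, template) {
  structure(mat, arc = .arc_values(mat),
            fixed_endpoints = attr(template, "fixed_endpoints"),
            n_particles = attr(template, "n_particles"),
            ndim = attr(template, "ndim"),
            class = c("tpath", "matrix", "array"))
}

#' Reparametrize a path to equal inter-image spacing
#'
#' Images are redistributed along the piecewise-linear polyline through the
#' current images so that consecutive inter-image distances are equal
#' (within 1e-8 relative); endpoints are unchanged.
#'
#' @param path A [make_path()] object (>= 3 images).
#' @return The reparametrized path.
#' @export
reparametrize <- function(path) {
  mat <- unclass(path)
  if (nrow(mat) < 3) stop("reparametrization needs at least 3 images")
  out <- .interp_polyline(mat, seq(0, 1, length.out = nrow(mat)))
  out[1, ] <- mat[1, ]
  out[nrow(out), ] <- mat[nrow(mat), ]
  .repath(out, path)
}

#' Resample a path to a new image count
#'
#' Output images lie on the input polyline at equally spaced arc lengths.
#'
#' @param path A [make_path()] object.
#' @param n_out Number of output images (>= 2).
#' @return Resampled path with `n_out` images.
#' @export
resample_images <- function(path, n_out) {
  if (n_out < 2) stop("n_out must be >= 2")
  mat <- unclass(path)
  out <- .interp_polyline(mat, seq(0, 1, length.out = n_out))
  out[1, ] <- mat[1, ]
  out[n_out, ] <- mat[nrow(mat), ]
  .repath(out, path)
}

#' Double the images of a path by midpoint insertion
#'
#' Inserts one linearly interpolated image between each pair of successive
#' images; optionally inserts two images in the central interval (an
#' off-by-one bookkeeping variant of the doubling step), giving
#' `2n` rather than `2n - 1` images.
#'
#' @param path A [make_path()] object.
#' @param middle_double Insert two images in the middle interval. Default
#'   `FALSE`.
#' @return The doubled path.
#' @export
double_images <- function(path, middle_double = FALSE) {
  mat <- unclass(path)
  n <- nrow(mat)
  mid <- if (middle_double) floor(n / 2) else 0L
  rows <- list()
  for (i in seq_len(n - 1)) {
    rows[[length(rows) + 1]] <- mat[i, ]
    if (middle_double && i == mid) {
      rows[[length(rows) + 1]] <- mat[i, ] + (mat[i + 1, ] - mat[i, ]) / 3
      rows[[length(rows) + 1]] <- mat[i, ] + 2 * (mat[i + 1, ] - mat[i, ]) / 3
    } else {
      rows[[length(rows) + 1]] <- (mat[i, ] + mat[i + 1, ]) / 2
    }
  }
  rows[[length(rows) + 1]] <- mat[n, ]
  .repath(do.call(rbind, rows), path)
}

#' Extract images by index
#'
#' @param path A [make_path()] object.
#' @param idx 1-based image indices (e.g. the stride-8 extraction
#'   `seq(8, 256, by = 8)` picks 32 images from a 256-image path, the
#'   classic "start at image 7 (0-based), end at the last image" rule).
#' @return Path containing the selected images in order.
#' @export
extract_images <- function(path, idx) {
  mat <- unclass(path)
  if (any(idx < 1 | idx > nrow(mat))) stop("image index out of range")
  .repath(mat[idx, , drop = FALSE], path)
}

#' Minimum distance from a path polyline to a point
#'
#' Distance from the piecewise-linear curve through the images to an
#' arbitrary point, minimizing over all segments.
#'
#' @param path A [make_path()] object.
#' @param point Numeric vector in image space.
#' @return Scalar distance.
#' @export
path_distance_to_point <- function(path, point) {
  mat <- unclass(path)
  point <- as.numeric(point)
  best <- Inf
  for (i in seq_len(nrow(mat) - 1)) {
    a <- mat[i, ]; b <- mat[i + 1, ]
    ab <- b - a
    denom <- sum(ab^2)
    t0 <- if (denom > 0) sum((point - a) * ab) / denom else 0
    t0 <- min(max(t0, 0), 1)
    d <- sqrt(sum((a + t0 * ab - point)^2))
    best <- min(best, d)
  }
  best
}

#' Per-image coordinates of a path
#' @param path A [make_path()] object.
#' @param i Image index.
#' @return Conformation matrix `n_particles x ndim`.
#' @export
path_image <- function(path, i) {
  matrix(unclass(path)[i, ], nrow = attr(path, "n_particles"),
         ncol = attr(path, "ndim"), byrow = TRUE)
}
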