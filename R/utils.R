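# Small vector helpers shared across the geometry code. All coordinates are
# RAS millimetres; points are length-3 numeric vectors or n x 3 matrices.

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x))) {
    stop("expected a finite length-3 coordinate vector", call. = FALSE)
  }
  unname(x)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, context = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop(sprintf("cannot normalize near-zero %s", context), call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# n x 3 coordinate matrix from a list of points or a matrix
as_points_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    m <- points
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, vec3))
  } else {
    m <- matrix(vec3(points), ncol = 3L)
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("points contain non-finite coordinates", call. = FALSE)
  m
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a
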