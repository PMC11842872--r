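# Polygons are closed, simple, and stored as n x 2 matrices (x, y in µm)
# without a repeated closing vertex.

#' Resample a polygon to a fixed vertex count by arc length
#'
#' @param poly n x 2 matrix of vertices.
#' @param n_vertices Target vertex count (default 64).
#' @return `n_vertices` x 2 matrix.
#' @export
resample_polygon <- function(poly, n_vertices = 64L) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_vertices + 1L)[seq_len(n_vertices)]
  x <- stats::approx(s, closed[, 1], xout = target)$y
  y <- stats::approx(s, closed[, 2], xout = target)$y
  cbind(x, y)
}

# cyclic-shift alignment minimizing summed vertex distance to the reference
align_polygon <- function(ref, poly) {
  n <- nrow(ref)
  stopifnot(nrow(poly) == n)
  costs <- vapply(seq_len(n) - 1L, function(sh) {
    idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
    sum(sqrt(rowSums((ref - poly[idx, , drop = FALSE])^2)))
  }, numeric(1))
  sh <- which.min(costs) - 1L
  idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
  poly[idx, , drop = FALSE]
}

#' Nuclear outline interpolated between keyframes
#'
#' Stores manually traced outline polygons at the first, middle and last
#' frame of a movie; the outline at any frame is obtained by vertex-wise
#' linear interpolation between the bracketing keyframes. Keyframe polygons
#' are resampled to a common vertex count by arc length and rotationally
#' aligned (cyclic shift minimizing summed vertex distance) so that vertex
#' correspondence is well defined.
#'
#' @param polys List of keyframe polygons (n x 2 matrices), in frame order.
#' @param keyframes Integer frames of the keyframes (same length as `polys`),
#'   e.g. first, middle and last frame.
#' @param n_vertices Common vertex count after resampling (default 64).
#' @return Object of class `nuclear_outline`.
#' @export
nuclear_outline <- function(polys, keyframes, n_vertices = 64L) {
  stopifnot(length(polys) == length(keyframes), length(polys) >= 1,
            !is.unsorted(keyframes))
  rs <- lapply(polys, resample_polygon, n_vertices = n_vertices)
  for (i in seq_along(rs)[-1]) rs[[i]] <- align_polygon(rs[[i - 1]], rs[[i]])
  structure(list(polys = rs, keyframes = as.integer(keyframes),
                 n_vertices = as.integer(n_vertices)),
            class = "nuclear_outline")
}

#' Outline polygon at a given frame
#'
#' @param outline A [nuclear_outline()].
#' @param frame Frame index within the keyframe range.
#' @return Interpolated polygon (matrix).
#' @export
interpolate_outline <- function(outline, frame) {
  stopifnot(inherits(outline, "nuclear_outline"))
  kf <- outline$keyframes
  if (frame < kf[1] || frame > kf[length(kf)]) {
    stop("frame outside the movie's keyframe range")
  }
  i <- findInterval(frame, kf)
  if (i == length(kf) || frame == kf[i]) return(outline$polys[[i]])
  a <- (frame - kf[i]) / (kf[i + 1] - kf[i])
  (1 - a) * outline$polys[[i]] + a * outline$polys[[i + 1]]
}

#' Area centroid of a polygon
#'
#' Center of mass of the enclosed region (shoelace formula).
#'
#' @param poly n x 2 matrix.
#' @return Length-2 numeric vector.
#' @export
polygon_centroid <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Center-border distance of a point in a nuclear outline
#'
#' The CBD is the distance of the point from the outline centroid divided by
#' the distance from the centroid to the border along the same ray: 0 at the
#' center, 1 on the border. For non-convex outlines the outermost border
#' crossing along the ray is used. Points marginally outside the outline
#' (CBD in `(1, clamp]`, segmentation noise) are clamped to 1; points
#' further outside return their raw CBD `> 1` so callers can exclude them.
#'
#' @param point Length-2 numeric (x, y in µm).
#' @param poly Outline polygon.
#' @param centroid Optional precomputed centroid.
#' @param clamp Clamping limit for marginally outside points (default 1.02).
#' @return CBD value.
#' @export
compute_cbd <- function(point, poly, centroid = NULL, clamp = 1.02) {
  if (is.null(centroid)) centroid <- polygon_centroid(poly)
  v <- point - centroid
  rp <- sqrt(sum(v^2))
  if (rp < 1e-12) return(0)
  u <- v / rp
  # ray-segment intersections: centroid + t*u = a + s*(b - a)
  a <- poly
  b <- poly[c(seq_len(nrow(poly))[-1], 1L), , drop = FALSE]
  e <- b - a
  denom <- u[1] * (-e[, 2]) - u[2] * (-e[, 1])
  w <- cbind(a[, 1] - centroid[1], a[, 2] - centroid[2])
  t_ray <- (w[, 1] * (-e[, 2]) - w[, 2] * (-e[, 1])) / denom
  s_seg <- (u[1] * w[, 2] - u[2] * w[, 1]) / denom
  hit <- is.finite(t_ray) & t_ray > 1e-12 & s_seg >= -1e-9 & s_seg <= 1 + 1e-9
  if (!any(hit)) return(Inf)
  r_border <- max(t_ray[hit])
  cbd <- rp / r_border
  if (cbd > 1 && cbd <= clamp) cbd <- 1
  cbd
}

#' Area-normalized radial histogram of CBD values
#'
#' Counts CBD values into `n_bins` equal-width rings, divides each count by
#' the ring's area fraction (ring `i` of the unit disk has area proportional
#' to \eqn{i^2 - (i-1)^2}) and normalizes the densities to a maximum of 1.
#' The counting error \eqn{\sqrt{N}} per bin is propagated through both
#' normalizations. Values in `(1, 1.02]` are clamped to the border bin;
#' values beyond are excluded with a message.
#'
#' @param cbds Numeric CBD values.
#' @param n_bins Number of ring bins (default 5).
#' @return Object of class `cbd_histogram` with `counts`, `density`
#'   (max-normalized), `error`, and bin edges.
#' @export
radial_histogram <- function(cbds, n_bins = 5L) {
  out_of_range <- cbds > 1.02 | cbds < 0
  if (any(out_of_range)) {
    message(sum(out_of_range), " CBD value(s) outside [0, 1.02] excluded")
    cbds <- cbds[!out_of_range]
  }
  cbds <- pmin(cbds, 1)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(cbds, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  i <- seq_len(n_bins)
  area <- (i^2 - (i - 1)^2) / n_bins^2      # ring area fraction of unit disk
  dens <- counts / area
  err <- sqrt(counts) / area
  m <- max(dens)
  if (m > 0) {
    dens <- dens / m
    err <- err / m
  }
  structure(list(counts = counts, density = dens, error = err,
                 edges = edges, n = sum(counts)),
            class = "cbd_histogram")
}

#' @export
print.cbd_histogram <- function(x, ...) {
  cat(sprintf("CBD histogram (%d tracks, %d bins):\n", x$n, length(x$counts)))
  print(data.frame(bin = sprintf("[%.1f,%.1f)", x$edges[-length(x$edges)],
                                 x$edges[-1]),
                   count = x$counts, density = round(x$density, 3),
                   error = round(x$error, 3)), row.names = FALSE)
  invisible(x)
}

#' CBD values of track origins within a moving nuclear outline
#'
#' Convenience wrapper: computes the CBD of each track's initial position in
#' the outline interpolated to the track's first frame.
#'
#' @param tracks Track table.
#' @param outline A [nuclear_outline()].
#' @return Numeric CBD per track (may exceed 1 for points outside).
#' @export
track_cbds <- function(tracks, outline) {
  vapply(split(tracks, tracks$track_id), function(tr) {
    i <- which.min(tr$frame)
    poly <- interpolate_outline(outline, tr$frame[i])
    compute_cbd(c(tr$x_um[i], tr$y_um[i]), poly)
  }, numeric(1))
}
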