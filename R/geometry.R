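# polygon geometry for cell contours
#
# Contours are two-column (x, y) matrices in microns, image coordinates
# (x right, y down), vertices stored open (last vertex != first). All
# quantities are closed-form polygon integrals, so analytic fixtures (circles,
# ellipses) have exact expectations.

close_ring <- function(p) rbind(p, p[1, , drop = FALSE])

validate_contour <- function(contour) {
  if (is.data.frame(contour)) contour <- as.matrix(contour[, 1:2])
  if (!is.matrix(contour) || ncol(contour) < 2) {
    stop_data("contour must be a two-column matrix of vertices")
  }
  contour <- contour[, 1:2, drop = FALSE]
  storage.mode(contour) <- "double"
  # drop a repeated closing vertex if present
  n <- nrow(contour)
  if (n >= 2 && all(contour[n, ] == contour[1, ])) contour <- contour[-n, , drop = FALSE]
  if (nrow(contour) < 3) stop_data("contour needs at least 3 distinct vertices")
  if (!all(is.finite(contour))) stop_data("contour contains non-finite vertices")
  contour
}

polygon_area <- function(p) {
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  abs(sum(p[, 1] * q[, 2] - q[, 1] * p[, 2])) / 2
}

polygon_perimeter <- function(p) {
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

# second central moments of the uniform lamina bounded by the polygon,
# returned as the 2x2 covariance matrix entries
polygon_moments <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  a_signed <- sum(cross) / 2
  if (abs(a_signed) < .Machine$double.eps) stop_data("degenerate polygon (zero area)")
  cx <- sum((x + x2) * cross) / (6 * a_signed)
  cy <- sum((y + y2) * cross) / (6 * a_signed)
  ixx <- sum(cross * (y^2 + y * y2 + y2^2)) / 12      # integral of y^2 dA
  iyy <- sum(cross * (x^2 + x * x2 + x2^2)) / 12      # integral of x^2 dA
  ixy <- sum(cross * (x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y)) / 24
  # central moments, normalized by area -> variances of the lamina
  list(
    centroid = c(cx, cy),
    var_x = iyy / a_signed - cx^2,
    var_y = ixx / a_signed - cy^2,
    cov_xy = ixy / a_signed - cx * cy,
    area_signed = a_signed
  )
}

convex_hull_area <- function(p) {
  h <- grDevices::chull(p)
  polygon_area(p[h, , drop = FALSE])
}

# serialize / parse contours as WKT POLYGON strings for tidy CSV round trips
wkt_polygon <- function(p) {
  ring <- close_ring(p)
  coords <- paste(formatC(ring[, 1], format = "g", digits = 17),
                  formatC(ring[, 2], format = "g", digits = 17))
  paste0("POLYGON ((", paste(coords, collapse = ", "), "))")
}

parse_wkt_polygon <- function(s) {
  body <- regmatches(s, regexpr("\\(\\(.*\\)\\)", s))
  if (length(body) == 0) stop_format(sprintf("not a WKT POLYGON: '%s'", substr(s, 1, 40)))
  body <- gsub("^\\(\\(|\\)\\)$", "", body)
  parts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  xy <- do.call(rbind, lapply(parts, function(v) as.numeric(v[nzchar(v)])))
  validate_contour(xy)
}
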