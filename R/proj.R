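# Transverse Mercator (WGS84 UTM) forward/inverse, Krueger n-series.
# Series truncated at n^6: worse-case error well below 1 mm inside a UTM zone,
# far tighter than the 1e-6 degree round-trip contract used elsewhere.

.WGS84_A <- 6378137
.WGS84_F <- 1 / 298.257223563
.UTM_K0 <- 0.9996
.UTM_FE <- 500000

.tm_constants <- local({
  f <- .WGS84_F
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  list(
    n = n,
    A = .WGS84_A / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256),
    alpha = c(
      n / 2 - 2 * n2 / 3 + 5 * n3 / 16 + 41 * n4 / 180 - 127 * n5 / 288 + 7891 * n6 / 37800,
      13 * n2 / 48 - 3 * n3 / 5 + 557 * n4 / 1440 + 281 * n5 / 630 - 1983433 * n6 / 1935360,
      61 * n3 / 240 - 103 * n4 / 140 + 15061 * n5 / 26880 + 167603 * n6 / 181440,
      49561 * n4 / 161280 - 179 * n5 / 168 + 6601661 * n6 / 7257600,
      34729 * n5 / 80640 - 3418889 * n6 / 1995840,
      212378941 * n6 / 319334400),
    beta = c(
      n / 2 - 2 * n2 / 3 + 37 * n3 / 96 - n4 / 360 - 81 * n5 / 512 + 96199 * n6 / 604800,
      n2 / 48 + n3 / 15 - 437 * n4 / 1440 + 46 * n5 / 105 - 1118711 * n6 / 3870720,
      17 * n3 / 480 - 37 * n4 / 840 - 209 * n5 / 4480 + 5569 * n6 / 90720,
      4397 * n4 / 161280 - 11 * n5 / 504 - 830251 * n6 / 7257600,
      4583 * n5 / 161280 - 108847 * n6 / 3991680,
      20648693 * n6 / 638668800),
    e = sqrt(f * (2 - f)))
})

#' Interpret a UTM EPSG code
#'
#' Decodes EPSG codes of the WGS84 UTM families 326xx (northern hemisphere)
#' and 327xx (southern hemisphere). Any other projected CRS can still be used
#' for clustering (distances are planar in whatever meter-unit CRS the input
#' is in), but geographic coordinates cannot be derived from it.
#'
#' @param crs_epsg integer EPSG code.
#' @return A list with `zone`, `south`, `lon0` (central meridian, degrees) and
#'   `false_northing`, or `NULL` when the code is not a WGS84 UTM code.
#' @export
#' @examples
#' utm_epsg_info(32633)
utm_epsg_info <- function(crs_epsg) {
  crs_epsg <- as.integer(crs_epsg)
  if (length(crs_epsg) != 1L || is.na(crs_epsg)) return(NULL)
  south <- crs_epsg %/% 100L == 327L
  north <- crs_epsg %/% 100L == 326L
  if (!south && !north) return(NULL)
  zone <- crs_epsg %% 100L
  if (zone < 1L || zone > 60L) return(NULL)
  list(zone = zone, south = south, lon0 = -183 + 6 * zone,
       false_northing = if (south) 1e7 else 0)
}

#' Project geographic coordinates to UTM
#'
#' Forward WGS84 transverse Mercator projection for one UTM zone.
#'
#' @param lon,lat numeric vectors, degrees (WGS84).
#' @param crs_epsg EPSG code of the target UTM CRS (326xx or 327xx).
#' @return A data.frame with columns `x` (easting) and `y` (northing), meters.
#' @export
#' @examples
#' utm_project(15, 60, 32633)  # on the central meridian of zone 33N
utm_project <- function(lon, lat, crs_epsg) {
  info <- utm_epsg_info(crs_epsg)
  if (is.null(info)) stop("crs_epsg ", crs_epsg, " is not a WGS84 UTM code (326xx/327xx)")
  stopifnot(length(lon) == length(lat))
  if (any(abs(lat) > 84, na.rm = TRUE))
    stop("latitude outside the UTM domain (|lat| <= 84)")
  k <- .tm_constants
  phi <- lat * pi / 180
  lam <- (lon - info$lon0) * pi / 180
  s <- sin(phi)
  con <- 2 * sqrt(k$n) / (1 + k$n)
  t <- sinh(atanh(s) - con * atanh(con * s))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:6) {
    xi <- xi + k$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + k$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  data.frame(x = .UTM_FE + .UTM_K0 * k$A * eta,
             y = info$false_northing + .UTM_K0 * k$A * xi)
}

#' Inverse-project UTM coordinates to longitude/latitude
#'
#' @param x,y numeric vectors: easting/northing in meters.
#' @param crs_epsg EPSG code of the source UTM CRS (326xx or 327xx).
#' @return A data.frame with columns `lon` and `lat` (degrees, WGS84).
#' @export
#' @examples
#' utm_inverse(500000, 6651411, 32633)
utm_inverse <- function(x, y, crs_epsg) {
  info <- utm_epsg_info(crs_epsg)
  if (is.null(info)) stop("crs_epsg ", crs_epsg, " is not a WGS84 UTM code (326xx/327xx)")
  stopifnot(length(x) == length(y))
  k <- .tm_constants
  xi <- (y - info$false_northing) / (.UTM_K0 * k$A)
  eta <- (x - .UTM_FE) / (.UTM_K0 * k$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  lam <- atan2(sinh(eta_p), cos(xi_p))
  chi <- asin(sin(xi_p) / cosh(eta_p))  # conformal latitude
  e2 <- k$e^2; e4 <- e2^2; e6 <- e2^3; e8 <- e2^4
  d <- c(e2 / 2 + 5 * e4 / 24 + e6 / 12 + 13 * e8 / 360,
         7 * e4 / 48 + 29 * e6 / 240 + 811 * e8 / 11520,
         7 * e6 / 120 + 81 * e8 / 1120,
         4279 * e8 / 161280)
  phi <- chi
  for (j in 1:4) phi <- phi + d[j] * sin(2 * j * chi)
  data.frame(lon = info$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}
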