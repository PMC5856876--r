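#' Distance-band parameters for walker stepping
#'
#' A walker step between two anchorages is assigned to a distance band
#' (short / medium / long) by the lattice Euclidean distance between their
#' grid positions, and the band determines the stepping rate: the base rate
#' \code{k_s} for short steps, \code{k_s / medium_divisor} for medium steps
#' and \code{k_s / long_divisor} for long steps.  Pairs beyond \code{dL}
#' grid units cannot interact.
#'
#' The defaults (\code{dS = 3}, \code{dM = 5}, \code{dL = 8} grid units,
#' \code{k_s = 0.009} per second, divisors 50 and 100) discretise the
#' experimentally motivated piecewise rate function: with one grid unit
#' equal to half the average anchorage spacing of 6.2 nm (3.1 nm), the
#' short and medium cutoffs land exactly on 1.5 and 2.5 times the average
#' spacing, and \code{dL = 8} corresponds to 24.8 nm, close to the 24 nm
#' maximum interaction distance.
#'
#' @param dS short-band threshold in grid units.
#' @param dM medium-band threshold in grid units.
#' @param dL long-band threshold in grid units.
#' @param k_s base stepping rate in s^-1 (short-band rate).
#' @param medium_divisor rate divisor for medium steps.
#' @param long_divisor rate divisor for long steps.
#' @return An object of class \code{distance_params}.
#' @export
#' @examples
#' p <- distance_params()
#' step_rate("SHORT", p)
distance_params <- function(dS = 3, dM = 5, dL = 8, k_s = 0.009,
                            medium_divisor = 50, long_divisor = 100) {
  stopifnot(dS > 0, dS < dM, dM < dL, k_s > 0,
            medium_divisor > 1, long_divisor > 1)
  structure(list(dS = dS, dM = dM, dL = dL, k_s = k_s,
                 medium_divisor = medium_divisor,
                 long_divisor = long_divisor),
            class = "distance_params")
}

#' Physical banding parameters
#'
#' Alternative specification of the distance bands in physical units:
#' the average anchorage spacing \code{d_a} (nm), the maximum
#' interaction distance \code{d_M} (nm) and the lattice resolution
#' \code{grid_unit} (nm per grid unit, default half the average
#' spacing).  \code{as_distance_params()} converts to grid-unit
#' thresholds by rounding \code{1.5 d_a}, \code{2.5 d_a} and \code{d_M}
#' to the nearest whole grid unit; at the default resolution this
#' reproduces the standard bands 3 / 5 / 8 exactly.
#'
#' @param d_a average anchorage distance in nm.
#' @param d_M maximum interaction distance in nm.
#' @param grid_unit nm per grid unit.
#' @param k_s,medium_divisor,long_divisor rate parameters, as in
#'   \code{\link{distance_params}}.
#' @return \code{physical_params}: an object of class
#'   \code{physical_params}; \code{as_distance_params}: the equivalent
#'   \code{\link{distance_params}}.
#' @export
physical_params <- function(d_a = 6.2, d_M = 24, grid_unit = d_a / 2,
                            k_s = 0.009, medium_divisor = 50,
                            long_divisor = 100) {
  stopifnot(d_a > 0, d_M > 1.5 * d_a, grid_unit > 0)
  structure(list(d_a = d_a, d_M = d_M, grid_unit = grid_unit,
                 k_s = k_s, medium_divisor = medium_divisor,
                 long_divisor = long_divisor),
            class = "physical_params")
}

#' @rdname physical_params
#' @param p a \code{physical_params} object.
#' @export
as_distance_params <- function(p) {
  stopifnot(inherits(p, "physical_params"))
  distance_params(dS = round(1.5 * p$d_a / p$grid_unit),
                  dM = round(2.5 * p$d_a / p$grid_unit),
                  dL = round(p$d_M / p$grid_unit),
                  k_s = p$k_s, medium_divisor = p$medium_divisor,
                  long_divisor = p$long_divisor)
}

#' Squared Euclidean distance between grid points
#'
#' All band classification in the package is done on squared distances in
#' exact integer arithmetic (\code{d <= r} iff \code{d^2 <= r^2} for
#' non-negative \code{d}, \code{r}), so no floating point enters the
#' decision which pairs of anchorages may interact.
#'
#' @param x1,y1,x2,y2 integer grid coordinates (vectorised).
#' @return integer vector of squared distances.
#' @export
squared_distance <- function(x1, y1, x2, y2) {
  (x1 - x2)^2 + (y1 - y2)^2
}

#' Minkowski, Manhattan and Chebyshev distances on the grid
#'
#' The generalised L_m distance; \code{m = 1} gives the rectilinear
#' (Manhattan) distance, \code{m = 2} the Euclidean distance, and the limit
#' m -> infinity the chessboard (Chebyshev) distance.  Manhattan and
#' Chebyshev distances are exact integers on an integer grid.
#'
#' @param x1,y1,x2,y2 grid coordinates (vectorised).
#' @param m order of the norm, \code{m >= 1}.
#' @return numeric (Minkowski) or integer (Manhattan/Chebyshev) distances.
#' @export
minkowski_distance <- function(x1, y1, x2, y2, m) {
  if (m < 1) stop("Minkowski order m must be >= 1")
  (abs(x1 - x2)^m + abs(y1 - y2)^m)^(1 / m)
}

#' @rdname minkowski_distance
#' @export
manhattan_distance <- function(x1, y1, x2, y2) {
  abs(x1 - x2) + abs(y1 - y2)
}

#' @rdname minkowski_distance
#' @export
chebyshev_distance <- function(x1, y1, x2, y2) {
  pmax(abs(x1 - x2), abs(y1 - y2))
}

#' Distance band of an anchorage pair
#'
#' Classifies an ordered pair of distinct grid points into one of the bands
#' \code{SHORT} (0 < d <= dS), \code{MEDIUM} (dS < d <= dM),
#' \code{LONG} (dM < d <= dL) or \code{NONE} (out of interaction range).
#' Comparisons use exact integer squared distances.
#'
#' @param x1,y1,x2,y2 grid coordinates (vectorised).
#' @param params a \code{\link{distance_params}} object.
#' @return character vector in \code{c("SHORT","MEDIUM","LONG","NONE")}.
#' @export
step_category <- function(x1, y1, x2, y2, params = distance_params()) {
  d2 <- squared_distance(x1, y1, x2, y2)
  if (any(d2 == 0)) stop("step_category: identical points (no self-steps)")
  out <- rep("NONE", length(d2))
  out[d2 <= params$dL^2] <- "LONG"
  out[d2 <= params$dM^2] <- "MEDIUM"
  out[d2 <= params$dS^2] <- "SHORT"
  out
}

#' Stepping rate for a distance band
#'
#' @param cat character vector of band names.
#' @param params a \code{\link{distance_params}} object.
#' @return rates in s^-1; \code{NONE} maps to 0.
#' @export
step_rate <- function(cat, params = distance_params()) {
  rates <- c(SHORT = params$k_s,
             MEDIUM = params$k_s / params$medium_divisor,
             LONG = params$k_s / params$long_divisor,
             NONE = 0)
  bad <- setdiff(unique(cat), names(rates))
  if (length(bad)) stop("unknown step category: ", paste(bad, collapse = ", "))
  unname(rates[cat])
}

#' Short-band neighbourhood stencil
#'
#' All nonzero integer offsets (dx, dy) with dx^2 + dy^2 <= dS^2.  For the
#' default dS = 3 this set equals the union of the Manhattan ball of radius
#' 3 and the Chebyshev ball of radius 2 (minus the origin), the discrete
#' construction commonly used to realise lattice-L2 membership.
#'
#' @param params a \code{\link{distance_params}} object.
#' @return data.frame with integer columns \code{dx}, \code{dy}.
#' @export
short_neighbourhood_stencil <- function(params = distance_params()) {
  r <- params$dS
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r^2 & !(g$dx == 0 & g$dy == 0), , drop = FALSE]
  g <- g[order(g$dx, g$dy), ]
  rownames(g) <- NULL
  g
}
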