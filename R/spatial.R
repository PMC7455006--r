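#' Wrap positions onto the torus
#'
#' Reduces coordinates modulo the area dimensions into `[0, size)`.
#'
#' @param x,y Numeric coordinate vectors.
#' @param sizeX,sizeY Area dimensions.
#' @return Data frame with wrapped `x`, `y`.
#' @export
wrap_position <- function(x, y, sizeX, sizeY) {
  data.frame(x = x %% sizeX, y = y %% sizeY)
}

#' One Brownian diffusion step
#'
#' Each agent is displaced by a random vector of magnitude
#' `sqrt(6 * dt * D * p)` with `p ~ Uniform[0, 1]` and direction uniform on
#' the circle, then wrapped onto the torus. The per-step mean squared
#' displacement is `3 * dt * D`.
#'
#' @param x,y Coordinate vectors.
#' @param D Diffusion constant (>= 0).
#' @param dt Step length (> 0).
#' @param sizeX,sizeY Area dimensions.
#' @return Data frame with updated `x`, `y`.
#' @export
diffusion_step <- function(x, y, D, dt, sizeX, sizeY) {
  stopifnot(D >= 0, dt > 0)
  n <- length(x)
  w <- sqrt(6 * dt * D * stats::runif(n))
  theta <- stats::runif(n, 0, 2 * pi)
  wrap_position(x + w * cos(theta), y + w * sin(theta), sizeX, sizeY)
}

#' Toroidal distance between points
#'
#' @param x1,y1,x2,y2 Coordinates (vectors recycle).
#' @param sizeX,sizeY Area dimensions.
#' @return Numeric vector of distances.
#' @export
torus_distance <- function(x1, y1, x2, y2, sizeX, sizeY) {
  dx <- abs(x1 - x2); dx <- pmin(dx, sizeX - dx)
  dy <- abs(y1 - y2); dy <- pmin(dy, sizeY - dy)
  sqrt(dx^2 + dy^2)
}

#' Radius neighbour query over a uniform grid index
#'
#' For every agent, returns the indices of all other agents at toroidal
#' Euclidean distance strictly less than `radius` ("closer than the
#' interaction radius"); an agent at exactly `radius` is not a neighbour.
#' Backed by a uniform grid with cell size at least `radius`, so each query
#' inspects at most 9 cells.
#'
#' @param x,y Agent coordinate vectors.
#' @param sizeX,sizeY Area dimensions.
#' @param radius Query radius.
#' @return List (one element per agent) of sorted integer neighbour indices.
#' @export
neighbors_within <- function(x, y, sizeX, sizeY, radius) {
  stopifnot(length(x) == length(y), radius > 0)
  grid_neighbors_cpp(as.numeric(x), as.numeric(y),
                     as.numeric(sizeX), as.numeric(sizeY),
                     as.numeric(radius))
}
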