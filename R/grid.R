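#' Cell-centered rectangular grid for the state plane
#'
#' Builds the finite-volume grid on which densities, potentials and flux
#' fields are represented. Cells are uniform; values live at cell centers
#' \eqn{x_i = x_{min} + (i - 1/2) h_x}.
#'
#' @param n number of cells per axis (used for both unless `nx`/`ny` given).
#' @param xlim,ylim axis ranges.
#' @param frame coordinate frame tag: `"gating"` (the \eqn{(S_1, S_2)}
#'   unit square) or `"current"` (total-current plane, nA).
#' @param nx,ny cell counts per axis.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(n = 200, xlim = c(0, 1), ylim = c(0, 1),
                   frame = c("gating", "current"), nx = n, ny = n) {
  frame <- match.arg(frame)
  stopifnot(nx >= 3, ny >= 3, diff(xlim) > 0, diff(ylim) > 0)
  hx <- diff(xlim) / nx
  hy <- diff(ylim) / ny
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny),
    xlim = xlim, ylim = ylim, hx = hx, hy = hy,
    xc = xlim[1] + (seq_len(nx) - 0.5) * hx,
    yc = ylim[1] + (seq_len(ny) - 0.5) * hy,
    frame = frame), class = "grid2d")
}

#' @exportS3Method base::print
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d cells, x in [%g, %g], y in [%g, %g], frame = %s\n",
              x$nx, x$ny, x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2], x$frame))
  invisible(x)
}

#' Current-frame grid covering the image of the gating square
#'
#' The affine map \eqn{I = M S + c} sends the gating square to a
#' parallelogram in the current plane; this helper returns a rectangular
#' grid over its (optionally padded) bounding box.
#'
#' @param params a [circuit_params()] object.
#' @param n cells per axis.
#' @param pad fractional padding added around the bounding box.
#' @return A `grid2d` in the `"current"` frame.
#' @export
current_grid <- function(params, n = 200, pad = 0.02) {
  cm <- coupling_map(params)
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)) %*% t(cm$M)
  corners <- sweep(corners, 2, cm$c, "+")
  xl <- range(corners[, 1]); yl <- range(corners[, 2])
  xl <- xl + c(-1, 1) * pad * diff(xl)
  yl <- yl + c(-1, 1) * pad * diff(yl)
  grid2d(n, xlim = xl, ylim = yl, frame = "current")
}

#' Cell-center coordinates of a grid
#'
#' All cell centers as an n-by-2 matrix, cells in column-major order
#' (x fastest), matching the vector layout used by the solvers.
#'
#' @param grid a [grid2d()] object.
#' @return An `(nx*ny)`-by-2 matrix of coordinates.
#' @export
grid_points <- function(grid) {
  cbind(rep(grid$xc, times = grid$ny), rep(grid$yc, each = grid$nx))
}

grid_index <- function(grid, i, j) i + (j - 1L) * grid$nx

#' Bilinear interpolation of a gridded field at arbitrary points
#'
#' @param grid a [grid2d()] object.
#' @param Z an `nx`-by-`ny` matrix of cell-center values.
#' @param points a length-2 vector or n-by-2 matrix of coordinates.
#' @return Interpolated values (constant extrapolation outside the
#'   outermost cell centers).
#' @export
interp_field <- function(grid, Z, points) {
  pts <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  fx <- (pts[, 1] - grid$xc[1]) / grid$hx
  fy <- (pts[, 2] - grid$yc[1]) / grid$hy
  fx <- pmin(pmax(fx, 0), grid$nx - 1L)
  fy <- pmin(pmax(fy, 0), grid$ny - 1L)
  i0 <- pmin(floor(fx), grid$nx - 2L); tx <- fx - i0
  j0 <- pmin(floor(fy), grid$ny - 2L); ty <- fy - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  z00 <- Z[cbind(i0, j0)];     z10 <- Z[cbind(i0 + 1L, j0)]
  z01 <- Z[cbind(i0, j0 + 1L)]; z11 <- Z[cbind(i0 + 1L, j0 + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

#' Diffusion tensor of the circuit in a given frame
#'
#' Noise enters the dynamics as an isotropic fluctuation of the total
#' currents with diffusion coefficient `D`. In the current frame the
#' tensor is therefore \eqn{D\,\mathrm{Id}}; conjugating by the inverse
#' coupling map gives the constant anisotropic gating-frame tensor
#' \eqn{D\,M^{-1} M^{-T}}.
#'
#' @param params a [circuit_params()] object.
#' @param D scalar diffusion coefficient in current space
#'   (nA^2/s; default 1.4e-2).
#' @param frame `"gating"` or `"current"`.
#' @return A symmetric 2-by-2 matrix.
#' @export
diffusion_tensor <- function(params, D = 1.4e-2,
                             frame = c("gating", "current")) {
  frame <- match.arg(frame)
  if (D < 0) stop("diffusion coefficient must be non-negative")
  if (frame == "current") return(D * diag(2))
  cm <- coupling_map(params)
  D * (cm$Minv %*% t(cm$Minv))
}
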