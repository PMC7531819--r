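# Peak detection on solved landscapes and conversion of current-frame
# solutions into gating coordinates.

#' Local maxima of a steady-state density
#'
#' Finds local maxima of the density field with plateau merging: cells
#' that are >= all 8 neighbors are grouped into connected components
#' (ties across adjacent cells count as one peak) and each component
#' reports its probability-weighted center.
#'
#' @param landscape a `landscape` object.
#' @param min_rel discard peaks below `min_rel * max(P)` (default 1e-4).
#' @return A data.frame with columns `x`, `y`, `P` (peak density) sorted
#'   by decreasing density.
#' @export
landscape_maxima <- function(landscape, min_rel = 1e-4) {
  P <- landscape$P
  g <- landscape$grid
  nx <- g$nx; ny <- g$ny
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- P
  is_max <- TRUE
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (P >= pad[2:(nx + 1) + di, 2:(ny + 1) + dj])
  }
  is_max <- is_max & (P >= min_rel * max(P))
  if (!any(is_max)) return(data.frame(x = numeric(0), y = numeric(0),
                                      P = numeric(0)))
  # merge adjacent flagged cells (plateaus) into components
  idx <- which(is_max, arr.ind = TRUE)
  n <- nrow(idx)
  comp <- seq_len(n)
  find <- function(a) { while (comp[a] != a) a <- comp[a]; a }
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u < v && abs(idx[u, 1] - idx[v, 1]) <= 1 &&
        abs(idx[u, 2] - idx[v, 2]) <= 1)
      comp[find(u)] <- find(v)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    m <- idx[roots == r, , drop = FALSE]
    w <- P[m]
    data.frame(x = sum(g$xc[m[, 1]] * w) / sum(w),
               y = sum(g$yc[m[, 2]] * w) / sum(w),
               P = max(w))
  }))
  out[order(-out$P), , drop = FALSE]
}

#' Convert a current-frame landscape to gating coordinates
#'
#' Pulls a landscape solved in the current plane back to the gating
#' square through the exact affine change of variables: densities pick up
#' the constant Jacobian \eqn{|\det M|}, the potential shifts by
#' \eqn{\ln|\det M|}, and the flux transforms as a vector density,
#' \eqn{J_S = |\det M|\, M^{-1} J_I}.
#'
#' @param landscape a `landscape` solved with `frame = "current"` and
#'   `params` attached.
#' @param grid a gating-frame [grid2d()] to evaluate on.
#' @return A `landscape` object in the gating frame (interpolated fields;
#'   `residual` and solver diagnostics carried over).
#' @export
landscape_to_gating <- function(landscape, grid = grid2d(200)) {
  stopifnot(inherits(landscape, "landscape"),
            landscape$frame == "current", !is.null(landscape$params),
            grid$frame == "gating")
  params <- landscape$params
  cm <- coupling_map(params)
  gI <- landscape$grid
  ptsS <- grid_points(grid)
  ptsI <- sweep(ptsS %*% t(cm$M), 2, cm$c, "+")
  jac <- abs(cm$detM)
  P <- interp_field(gI, landscape$P, ptsI) * jac
  P <- matrix(pmax(P, 0), grid$nx, grid$ny)
  P <- P / (sum(P) * grid$hx * grid$hy)
  JxI <- interp_field(gI, landscape$Jx, ptsI)
  JyI <- interp_field(gI, landscape$Jy, ptsI)
  JS <- cbind(JxI, JyI) %*% t(cm$Minv) * jac
  out <- structure(list(
    P = P, grid = grid, Dt = diffusion_tensor(params, landscape$D, "gating"),
    residual = landscape$residual, iterations = landscape$iterations,
    used_direct = landscape$used_direct, neg_clamped = landscape$neg_clamped,
    floor = landscape$floor, frame = "gating",
    U = potential_from_density(P * grid$hx * grid$hy, landscape$floor),
    Jx = matrix(JS[, 1], grid$nx, grid$ny),
    Jy = matrix(JS[, 2], grid$nx, grid$ny),
    params = params, D = landscape$D,
    drift_fn = circuit_drift_fn(params, "gating")), class = "landscape")
  out
}
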