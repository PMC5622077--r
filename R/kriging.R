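#' Ordinary-kriging surface over a pathway map
#'
#' Interpolates the association color (-log10 p) of projected gene-sets
#' onto a regular grid over `[-1, 1]^2`.  An exponential variogram
#' `gamma(h) = nugget + sill (1 - exp(-h / range))` is fitted to the
#' empirical semivariogram by weighted least squares (weights N_k / h_k^2);
#' when the fit fails or is degenerate the surface falls back to
#' inverse-distance weighting, recorded in the output `method`.  With zero
#' nugget the surface honors the data exactly at the observation points.
#'
#' @param projection data frame with x, y and a value column (`neglog10p`
#'   or `value`); duplicated coordinates are averaged.
#' @param grid_resolution grid points per axis.
#' @return list with grid_x, grid_y, surface (resolution x resolution
#'   matrix), method ("kriging", "idw" or "constant") and variogram
#'   parameters (when kriged).
#' @export
krige_surface <- function(projection, grid_resolution = 100) {
  v <- projection$neglog10p %||% projection$value
  if (is.null(v)) stop("projection needs a 'neglog10p' or 'value' column")
  pts <- aggregate(list(v = v), list(x = projection$x, y = projection$y),
                   mean)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 distinct points")
  gx <- seq(-1, 1, length.out = grid_resolution)
  grid <- as.matrix(expand.grid(x = gx, y = gx))
  if (var(pts$v) < .Machine$double.eps) {
    return(list(grid_x = gx, grid_y = gx,
                surface = matrix(pts$v[1], grid_resolution, grid_resolution),
                method = "constant", variogram = NULL))
  }
  P <- as.matrix(pts[, c("x", "y")])
  dmat <- as.matrix(dist(P))
  vg <- fit_exponential_variogram(dmat, pts$v)
  if (is.null(vg)) {
    surface <- idw_interpolate(P, pts$v, grid)
    return(list(grid_x = gx, grid_y = gx,
                surface = matrix(surface, grid_resolution, grid_resolution),
                method = "idw", variogram = NULL))
  }
  gam <- function(h) vg$nugget + vg$sill * (1 - exp(-h / vg$range))
  # ordinary-kriging system in semivariogram form (gamma(0) = 0 on the
  # diagonal => exact interpolation at the data points)
  A <- rbind(cbind(gam(dmat), 1), c(rep(1, n), 0))
  diag(A)[seq_len(n)] <- 0
  d0sq <- outer(rowSums(P^2), rowSums(grid^2), "+") - 2 * P %*% t(grid)
  d0 <- sqrt(pmax(d0sq, 0))
  G0 <- gam(d0)
  G0[d0 < 1e-9] <- 0  # the semivariogram is 0 at zero lag: honor the data
  B <- rbind(G0, 1)
  lambda <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(lambda)) {
    surface <- idw_interpolate(P, pts$v, grid)
    return(list(grid_x = gx, grid_y = gx,
                surface = matrix(surface, grid_resolution, grid_resolution),
                method = "idw", variogram = NULL))
  }
  pred <- as.numeric(crossprod(lambda[seq_len(n), , drop = FALSE], pts$v))
  list(grid_x = gx, grid_y = gx,
       surface = matrix(pred, grid_resolution, grid_resolution),
       method = "kriging", variogram = vg)
}

# WLS fit of an exponential variogram to binned empirical semivariances.
# Returns NULL when the fit fails or collapses to zero sill.
fit_exponential_variogram <- function(dmat, values, n_bins = 12) {
  d <- dmat[upper.tri(dmat)]
  g <- 0.5 * outer(values, values, "-")[upper.tri(dmat)]^2
  pos <- d > 0
  d <- d[pos]
  g <- g[pos]
  if (length(d) < 3) return(NULL)
  breaks <- seq(0, max(d), length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE)
  h_k <- tapply(d, bin, mean)
  g_k <- tapply(g, bin, mean)
  n_k <- tapply(d, bin, length)
  ok <- !is.na(h_k) & !is.na(g_k) & h_k > 0
  h_k <- h_k[ok]; g_k <- g_k[ok]; n_k <- n_k[ok]
  if (length(h_k) < 3) return(NULL)
  wls <- function(par) {
    fit <- par[1] + par[2] * (1 - exp(-h_k / par[3]))
    sum(n_k / h_k^2 * (g_k - fit)^2)
  }
  init <- c(nugget = 0, sill = max(g_k), range = max(h_k) / 3)
  res <- tryCatch(
    optim(init, wls, method = "L-BFGS-B",
          lower = c(0, 1e-10, 1e-6 * max(h_k))),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) return(NULL)
  par <- res$par
  if (par[2] <= 1e-10) return(NULL)
  list(nugget = unname(par[1]), sill = unname(par[2]),
       range = unname(par[3]))
}

idw_interpolate <- function(P, values, grid, power = 2) {
  d2 <- outer(rowSums(P^2), rowSums(grid^2), "+") - 2 * P %*% t(grid)
  d2[d2 < 0] <- 0
  w <- 1 / pmax(d2, .Machine$double.eps)^(power / 2)
  pred <- as.numeric(crossprod(w, values) / colSums(w))
  # exact at (numerically) coincident points
  hit <- apply(d2, 2, which.min)
  at_point <- d2[cbind(hit, seq_len(ncol(d2)))] < 1e-24
  pred[at_point] <- values[hit[at_point]]
  pred
}
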