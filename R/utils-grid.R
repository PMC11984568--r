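# Internal grid helpers shared by the phantom generator, ray tracer and
# error-field machinery. All are dimension-agnostic (2-D or 3-D) unless noted.

#' @importFrom stats rnorm runif sd median setNames dnorm
NULL

.HU_MIN <- -1024
.HU_MAX <- 3071

clampHU <- function(x) pmin(pmax(x, .HU_MIN), .HU_MAX)

# voxel-centre physical coordinate along axis k for 1-based index i
axisCoords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# default origin placing the grid centre at 0
centredOrigin <- function(dim, spacing) -(dim - 1) / 2 * spacing

# matrix (nvox x ndim) of voxel-centre coordinates in array order
voxelCoords <- function(dim, spacing, origin) {
  ax <- lapply(seq_along(dim), function(k) axisCoords(dim[k], spacing[k], origin[k]))
  as.matrix(do.call(expand.grid, ax))
}

# translate a logical mask by an integer number of voxels per axis (zero fill)
shiftMask <- function(mask, shift) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) {
      src[[k]] <- seq_len(d[k] - s); dst[[k]] <- (s + 1):d[k]
    } else {
      src[[k]] <- (1 - s):d[k]; dst[[k]] <- seq_len(d[k] + s)
    }
  }
  out[matrixIndex(dst, d)] <- mask[matrixIndex(src, d)]
  out
}

# index grid expansion: list of per-axis index vectors -> linear indices
matrixIndex <- function(idx, d) {
  g <- as.matrix(do.call(expand.grid, idx))
  as.vector(g %*% cumprod(c(1, d[-length(d)])) - sum(cumprod(c(1, d[-length(d)]))) + 1)
}

# binary dilation by a Euclidean ball of `radius` voxels (shift-union)
dilateMask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- dim(mask)
  r <- ceiling(radius)
  offs <- as.matrix(do.call(expand.grid, rep(list(-r:r), length(d))))
  offs <- offs[sqrt(rowSums(offs^2)) <= radius + 1e-9, , drop = FALSE]
  out <- array(FALSE, d)
  for (i in seq_len(nrow(offs))) out <- out | shiftMask(mask, offs[i, ])
  out
}

# separable Gaussian smoothing, sigma in voxels per axis (recycled)
smoothGauss <- function(x, sigma) {
  d <- dim(x)
  sigma <- rep(sigma, length.out = length(d))
  for (k in seq_along(d)) {
    s <- sigma[k]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- dnorm(-r:r, sd = s)
    kern <- kern / sum(kern)
    x <- applyAlong(x, k, function(v) convPad(v, kern, r))
  }
  x
}

# 1-D convolution with replicate padding
convPad <- function(v, kern, r) {
  vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
  stats::convolve(vp, rev(kern), type = "filter")
}

# apply a length-preserving function along axis k of an array
applyAlong <- function(x, k, f) {
  d <- dim(x)
  perm <- c(k, seq_along(d)[-k])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[k])
  m <- apply(m, 2, f)
  xp <- array(m, dim = d[perm])
  aperm(xp, order(perm))
}

# solid ellipse/ellipsoid mask; centre and semi-axes in mm (grid coordinates)
ellipseMask <- function(dim, spacing, origin, centre, semi, theta = 0) {
  co <- voxelCoords(dim, spacing, origin)
  p <- sweep(co[, seq_along(centre), drop = FALSE], 2, centre)
  if (length(centre) == 2 && theta != 0) {
    ct <- cos(theta); st <- sin(theta)
    p <- cbind(ct * p[, 1] + st * p[, 2], -st * p[, 1] + ct * p[, 2])
  }
  q <- sweep(p, 2, semi, "/")
  array(rowSums(q^2) <= 1, dim)
}

# bilinear (2-D) sample of a matrix at physical points; zero outside the grid
bilinearSample <- function(values, spacing, origin, px, py) {
  d <- dim(values)
  fx <- (px - origin[1]) / spacing[1] + 1
  fy <- (py - origin[2]) / spacing[2] + 1
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  out <- numeric(length(px))
  val <- function(i, j) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    v <- numeric(length(i))
    v[ok] <- values[cbind(i[ok], j[ok])]
    v
  }
  out <- (1 - tx) * (1 - ty) * val(i0, j0) +
    tx * (1 - ty) * val(i0 + 1, j0) +
    (1 - tx) * ty * val(i0, j0 + 1) +
    tx * ty * val(i0 + 1, j0 + 1)
  out
}

# nearest-neighbour sample at physical points (any dimension); zero outside
nearestSample <- function(values, spacing, origin, pts) {
  d <- dim(values)
  idx <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1
  idx <- round(idx)
  ok <- rep(TRUE, nrow(idx))
  for (k in seq_along(d)) ok <- ok & idx[, k] >= 1 & idx[, k] <= d[k]
  out <- numeric(nrow(idx))
  if (any(ok)) out[ok] <- values[idx[ok, , drop = FALSE]]
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
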