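# Low-level gridded-array numerics shared by the phantom generator,
# the registration backend and the Jacobian analysis.

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates.  Points outside the grid return `background`.
.interpTrilinear <- function(arr, idx, background = 0) {
  d <- dim(arr)
  idx <- rbind(idx)
  inb <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
         idx[, 2] >= 1 & idx[, 2] <= d[2] &
         idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(background, nrow(idx))
  if (!any(inb)) return(out)
  p <- idx[inb, , drop = FALSE]
  i0 <- pmin(pmax(floor(p[, 1]), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(p[, 2]), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(p[, 3]), 1), d[3] - 1)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- i0 + s1 * (j0 - 1) + s2 * (k0 - 1)
  v000 <- arr[base];            v100 <- arr[base + 1]
  v010 <- arr[base + s1];       v110 <- arr[base + 1 + s1]
  v001 <- arr[base + s2];       v101 <- arr[base + 1 + s2]
  v011 <- arr[base + s1 + s2];  v111 <- arr[base + 1 + s1 + s2]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inb] <- c0 * (1 - fz) + c1 * fz
  out
}

# Central-difference gradient of a 3D array along one axis (one-sided at the
# borders), divided by the spacing so units are value / mm.
.gradientAxis <- function(arr, axis, spacing) {
  d <- dim(arr)
  n <- d[axis]
  idx <- function(r) switch(axis,
    arr[r, , , drop = FALSE], arr[, r, , drop = FALSE], arr[, , r, drop = FALSE])
  g <- array(0, d)
  assign_g <- function(r, val) {
    if (axis == 1) g[r, , ] <<- val
    else if (axis == 2) g[, r, ] <<- val
    else g[, , r] <<- val
  }
  if (n < 2) return(g)
  assign_g(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * spacing))
  assign_g(1, (idx(2) - idx(1)) / spacing)
  assign_g(n, (idx(n) - idx(n - 1)) / spacing)
  g
}

# FFT-based Gaussian smoothing of a 3D array; sigma per axis in voxels.
# Precomputed transfer function makes repeated calls (demons iterations) cheap.
.gaussianTransfer <- function(dims, sigma) {
  k1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  ka <- k1(dims[1], sigma[1]); kb <- k1(dims[2], sigma[2]); kc <- k1(dims[3], sigma[3])
  kern <- outer(outer(ka, kb), kc)
  dim(kern) <- dims
  stats::fft(kern)
}

.smoothFFT <- function(x, transfer) {
  Re(stats::fft(stats::fft(x) * transfer, inverse = TRUE)) / length(x)
}

# Global-histogram Otsu threshold (between-class variance maximisation).
.otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stop("image is constant: no bimodal contrast to threshold")
  b <- pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins))
  h <- tabulate(b, nbins = nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  t <- which.max(sb)
  rng[1] + t / nbins * diff(rng)
}

# 6-connected component labelling of a logical 3D array (igraph backend).
.labelComponents <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  vid <- integer(prod(d))
  vid[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  from <- integer(0); to <- integer(0)
  for (axis in 1:3) {
    ok <- ai[, axis] < d[axis]
    nb <- idx[ok] + strides[axis]
    keep <- mask[nb]
    from <- c(from, vid[idx[ok][keep]])
    to <- c(to, vid[nb[keep]])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Components of `mask` that do not touch the grid border.
.interiorComponents <- function(mask) {
  lab <- .labelComponents(mask)
  ncomp <- max(lab)
  if (ncomp == 0L) return(list(label = lab, interior = integer(0), sizes = integer(0)))
  d <- dim(lab)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  interior <- setdiff(seq_len(ncomp), border)
  sizes <- tabulate(lab, nbins = ncomp)
  list(label = lab, interior = interior, sizes = sizes)
}

# Fill interior cavities: background components not connected to the border.
.fillHoles <- function(mask) {
  comp <- .interiorComponents(!mask)
  if (length(comp$interior)) mask[comp$label %in% comp$interior] <- TRUE
  mask
}

# Euclidean-ball binary dilation via FFT convolution (exact on the voxel grid).
.dilateBall <- function(mask, radius) {
  if (radius == 0) return(mask)
  r <- as.integer(radius)
  d <- dim(mask)
  pd <- d + 2L * r
  off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  off <- off[rowSums(off^2) <= r^2 + 1e-9, , drop = FALSE]
  kern <- array(0, pd)
  kern[cbind((off[, 1] %% pd[1]) + 1L,
             (off[, 2] %% pd[2]) + 1L,
             (off[, 3] %% pd[3]) + 1L)] <- 1
  a <- array(0, pd)
  a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- as.numeric(mask)
  conv <- Re(stats::fft(stats::fft(a) * stats::fft(kern), inverse = TRUE)) / prod(pd)
  conv[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] > 0.5
}

# Block-average downsampling by 2 along every axis (multiresolution pyramid).
.downsample2 <- function(arr) {
  d <- dim(arr)
  nd <- pmax(1L, d %/% 2L)
  i <- pmin(2L * seq_len(nd[1]) - 1L, d[1]); i2 <- pmin(i + 1L, d[1])
  j <- pmin(2L * seq_len(nd[2]) - 1L, d[2]); j2 <- pmin(j + 1L, d[2])
  k <- pmin(2L * seq_len(nd[3]) - 1L, d[3]); k2 <- pmin(k + 1L, d[3])
  (arr[i, j, k] + arr[i2, j, k] + arr[i, j2, k] + arr[i, j, k2] +
   arr[i2, j2, k] + arr[i2, j, k2] + arr[i, j2, k2] + arr[i2, j2, k2]) / 8
}
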