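# Independent oracles, kept deliberately separate from the package
# implementations they check.

# Pratt circle fit solved as a generalized eigenproblem on the algebraic
# parameterization A(x^2+y^2) + Bx + Cy + D = 0 with constraint
# B^2 + C^2 - 4AD = 1 (no Newton iteration involved).
pratt_eigen_oracle <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  Z <- cbind(x^2 + y^2, x, y, 1)
  M <- crossprod(Z) / nrow(Z)
  Cmat <- matrix(c(0, 0, 0, -2,
                   0, 1, 0, 0,
                   0, 0, 1, 0,
                   -2, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- eigen(solve(Cmat, M))
  vals <- Re(ev$values)
  vals[abs(Im(ev$values)) > 1e-8] <- Inf
  vals[vals < -1e-10] <- Inf
  v <- Re(ev$vectors[, which.min(vals)])
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]
  cx <- -B / (2 * A); cy <- -C / (2 * A)
  r <- sqrt(B^2 + C^2 - 4 * A * D) / (2 * abs(A))
  list(center = c(cx, cy), radius = r)
}

# Monte-Carlo area of a convex polygon by point-in-bounding-box sampling.
mc_polygon_area <- function(poly, n = 2e5, seed = 42) {
  set.seed(seed)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  # even-odd test written independently of the package helper
  inside <- rep(FALSE, n)
  m <- nrow(poly)
  j <- m
  for (i in seq_len(m)) {
    cond <- ((poly[i, 2] > py) != (poly[j, 2] > py)) &
      (px < poly[i, 1] + (poly[j, 1] - poly[i, 1]) *
         (py - poly[i, 2]) / (poly[j, 2] - poly[i, 2]))
    inside <- xor(inside, cond)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

# Brute-force local mean/sd in a circular window at one pixel.
phansalkar_point_oracle <- function(px, r, row, col) {
  nr <- nrow(px); nc <- ncol(px)
  vals <- c()
  for (i in -r:r) for (j in -r:r) {
    if (i^2 + j^2 > r^2) next
    ri <- row + i; ci <- col + j
    if (ri < 1 || ri > nr || ci < 1 || ci > nc) next
    vals <- c(vals, px[ri, ci])
  }
  x <- vals / 255
  m <- mean(x); s <- sqrt(mean(x^2) - m^2)
  m * (1 + 2 * exp(-10 * m) + 0.25 * ((s / 0.5) - 1))
}
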