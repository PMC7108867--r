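#' Phansalkar local threshold
#'
#' Adaptive local thresholding for bright structures on dark, low-contrast
#' background. On intensities normalized to `[0, 1]`, the per-pixel
#' threshold is `t = m (1 + p exp(-q m) + k ((s / r) - 1))` with `m`, `s`
#' the mean and standard deviation in a circular window, and the reference
#' constants p = 2, q = 10, k = 0.25, r = 0.5. A pixel is
#' foreground when its normalized intensity exceeds `t`. Bright-on-dark
#' polarity is assumed: on an inverted (dark-fiber) image the method
#' returns an essentially empty foreground.
#'
#' @param img `lj_image` or matrix (8-bit convention).
#' @param radius_px window radius in pixels.
#' @return `lj_mask`.
#' @export
local_threshold_phansalkar <- function(img, radius_px = 15) {
  px <- as_pixel_matrix(img)
  if (2 * radius_px + 1 > min(dim(px)))
    stop("window larger than image")
  x <- px / 255
  k <- disc_kernel(radius_px)
  n <- conv2_same(matrix(1, nrow(x), ncol(x)), k)
  m <- conv2_same(x, k) / n
  s2 <- conv2_same(x^2, k) / n - m^2
  s <- sqrt(pmax(0, s2))
  t <- m * (1 + 2 * exp(-10 * m) + 0.25 * ((s / 0.5) - 1))
  binary_mask(x > t, ppu_of(img))
}

#' Global threshold at a fraction above the minimum
#'
#' Foreground where `intensity > min + frac * (max - min)`; the fractional
#' form keeps "20 percent above the minimum" meaningful when the minimum
#' is zero.
#'
#' @param img `lj_image` or matrix.
#' @param frac fraction of the dynamic range above the minimum.
#' @return `lj_mask`.
#' @export
global_threshold_minfrac <- function(img, frac = 0.20) {
  px <- as_pixel_matrix(img)
  rng <- range(px)
  if (rng[1] == rng[2]) stop("constant image: no dynamic range")
  binary_mask(px > rng[1] + frac * diff(rng), ppu_of(img))
}

#' Size-sort matrix elements
#'
#' Labels 8-connected components of a binary mask and classifies each by
#' its maximal Feret diameter in micrometers: noise below 4 um (removed as
#' background), small fibrils in 4-40 um, large assembled networks above
#' 40 um.
#'
#' @param mask `lj_mask` (or logical matrix plus `pixels_per_um`).
#' @param pixels_per_um pixel scale when `mask` is a bare matrix.
#' @param cutoffs_um the two class boundaries.
#' @return list with masks `noise`, `small`, `large` (`lj_mask`), the label
#'   matrix, and a `components` data.frame (`id`, `n_px`, `feret_um`,
#'   `class`).
#' @export
size_sort <- function(mask, pixels_per_um = NULL, cutoffs_um = c(4, 40)) {
  m <- as_mask_matrix(mask)
  ppu <- if (is.null(pixels_per_um)) ppu_of(mask) else pixels_per_um
  lab <- lj_label_components(m, 8L)
  n_comp <- max(lab)
  cls <- character(n_comp)
  feret <- numeric(n_comp)
  npx <- tabulate(lab[lab > 0], n_comp)
  if (n_comp > 0) {
    idx <- which(lab > 0)
    rows <- (idx - 1L) %% nrow(m) + 1L
    cols <- (idx - 1L) %/% nrow(m) + 1L
    ids <- lab[idx]
    ord <- order(ids)
    rows <- rows[ord]; cols <- cols[ord]; ids <- ids[ord]
    ends <- cumsum(npx)
    starts <- c(1, head(ends, -1) + 1)
    for (i in seq_len(n_comp)) {
      r <- rows[starts[i]:ends[i]]; c <- cols[starts[i]:ends[i]]
      if (length(r) == 1) {
        f <- 1
      } else {
        h <- unique(cbind(r, c))
        hull <- if (nrow(h) > 2) h[grDevices::chull(h), , drop = FALSE] else h
        f <- max(dist(hull)) + 1  # +1: pixel extent, not center distance
      }
      feret[i] <- f / ppu
      cls[i] <- if (feret[i] < cutoffs_um[1]) "noise"
        else if (feret[i] <= cutoffs_um[2]) "small" else "large"
    }
  }
  pick <- function(what) {
    keep <- which(cls == what)
    binary_mask(matrix(lab %in% keep, nrow(m), ncol(m)), ppu)
  }
  list(noise = pick("noise"), small = pick("small"), large = pick("large"),
       labels = lab,
       components = data.frame(id = seq_len(n_comp), n_px = npx,
                               feret_um = feret, class = cls))
}

#' Medial-lateral distribution of a binary signal along an interface
#'
#' The interface is cut into consecutive anterior-posterior sectors
#' (columns); within each sector every signal pixel's relative ML position
#' is computed against the local tissue extent, with 0 at the reference
#' (notochord) side at the maximal row: `|row - max tissue row| / (max -
#' min tissue row)`. Relative positions are pooled over sectors into a
#' histogram normalized by the total signal pixel count.
#'
#' @param signal,tissue `lj_mask`s of equal shape (tissue = full interface
#'   footprint).
#' @param sector_um AP sector width.
#' @param nbins number of histogram bins on `[0, 1]`.
#' @return list with `bin_centers`, `frequency` (sums to the analyzed
#'   fraction), `counts`, and the pooled relative positions `ml_rel`.
#' @export
ml_distribution <- function(signal, tissue, sector_um = 10, nbins = 30) {
  sg <- as_mask_matrix(signal); ts <- as_mask_matrix(tissue)
  stopifnot(identical(dim(sg), dim(ts)))
  ppu <- ppu_of(signal)
  dx <- max(1L, round(sector_um * ppu))
  nc <- ncol(sg)
  edges <- seq(1L, nc + 1L, by = dx)
  if (tail(edges, 1) <= nc) edges <- c(edges, nc + 1L)
  pooled <- numeric(0)
  total <- sum(sg)
  for (k in seq_len(length(edges) - 1)) {
    cols <- edges[k]:(edges[k + 1] - 1)
    trows <- which(rowSums(ts[, cols, drop = FALSE]) > 0)
    if (!length(trows)) {
      warning("sector ", k, " has an empty tissue mask; skipped")
      next
    }
    ref <- max(trows)
    ml <- max(trows) - min(trows)
    if (ml == 0) next
    srows <- which(sg[, cols, drop = FALSE], arr.ind = TRUE)[, 1]
    if (!length(srows)) next
    pooled <- c(pooled, abs(srows - ref) / ml)
  }
  h <- graphics::hist(pooled, breaks = seq(0, 1.0000001, length.out = nbins + 1),
                      plot = FALSE)
  list(bin_centers = h$mids, counts = h$counts,
       frequency = if (total > 0) h$counts / total else h$counts,
       ml_rel = pooled)
}

#' Anterior-posterior density profile of a binary signal
#'
#' Signal density (signal pixels over tissue pixels) in consecutive AP
#' sectors, with sector centers reported in micrometers from the anterior
#' edge (first center at half a sector).
#'
#' @inheritParams ml_distribution
#' @param sector_um AP sector width (50 um convention).
#' @return data.frame with `position_um`, `density`, `n_signal`,
#'   `n_tissue`; sectors with empty tissue get `NA` density.
#' @export
ap_density <- function(signal, tissue, sector_um = 50) {
  sg <- as_mask_matrix(signal); ts <- as_mask_matrix(tissue)
  stopifnot(identical(dim(sg), dim(ts)))
  ppu <- ppu_of(signal)
  dx <- max(1L, round(sector_um * ppu))
  nc <- ncol(sg)
  n_sec <- max(1L, round(nc / dx))
  out <- data.frame(position_um = sector_um / 2 + sector_um * (seq_len(n_sec) - 1),
                    density = NA_real_, n_signal = NA_integer_,
                    n_tissue = NA_integer_)
  for (k in seq_len(n_sec)) {
    cols <- (1 + (k - 1) * dx):min(nc, k * dx)
    nsig <- sum(sg[, cols]); ntis <- sum(ts[, cols])
    out$n_signal[k] <- nsig; out$n_tissue[k] <- ntis
    out$density[k] <- if (ntis > 0) nsig / ntis else NA_real_
  }
  out
}

#' Photoconverted-spot deformation metrics
#'
#' Width and height of a binary spot, per frame, as the standard deviation
#' of the foreground pixel coordinates: width over columns (the ML axis in
#' the dorsal-view spot convention) and height over rows (AP). The
#' population standard deviation is used, so a filled rectangle of `w`
#' columns has width `sqrt((w^2 - 1) / 12)` exactly. Metrics are also
#' normalized to the first frame.
#'
#' @param series either an `lj_spot_series` (frames are thresholded with
#'   [otsu_threshold()] or `fixed_threshold`), or a list of `lj_mask` /
#'   logical matrices.
#' @param fixed_threshold optional intensity threshold overriding Otsu.
#' @return data.frame with per-frame `width`, `height`, `width_norm`,
#'   `height_norm`, `n_px`.
#' @export
spot_metrics <- function(series, fixed_threshold = NULL) {
  masks <- if (inherits(series, "lj_spot_series")) {
    lapply(series$frames, function(fr) {
      th <- if (is.null(fixed_threshold)) otsu_threshold(fr) else fixed_threshold
      fr$pixels > th
    })
  } else {
    lapply(series, as_mask_matrix)
  }
  if (!length(masks)) stop("empty series")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  rows <- lapply(seq_along(masks), function(k) {
    w <- which(masks[[k]], arr.ind = TRUE)
    if (nrow(w) == 0) stop("frame ", k, " has no foreground pixels")
    data.frame(frame = k, width = pop_sd(w[, 2]), height = pop_sd(w[, 1]),
               n_px = nrow(w))
  })
  out <- do.call(rbind, rows)
  out$width_norm <- out$width / out$width[1]
  out$height_norm <- out$height / out$height[1]
  out
}

#' @noRd
xcorr_valid <- function(image, template) {
  # valid-mode cross-correlation sum_{ij} image[u+i, v+j] * template[i, j]
  nr <- nrow(image); nc <- ncol(image)
  tr <- nrow(template); tc <- ncol(template)
  fr <- stats::nextn(nr + tr - 1, c(2, 3, 5))
  fc <- stats::nextn(nc + tc - 1, c(2, 3, 5))
  A <- matrix(0, fr, fc); A[1:nr, 1:nc] <- image
  B <- matrix(0, fr, fc)
  B[1:tr, 1:tc] <- template[tr:1, tc:1]
  full <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / (fr * fc)
  full[tr:nr, tc:nc, drop = FALSE]
}

#' @noRd
ncc_peak <- function(template, search) {
  # normalized cross-correlation of template against all valid placements
  # in search; returns integer offset of the peak (relative to centered
  # placement) plus parabolic sub-pixel refinement and the peak score
  tm <- template - mean(template)
  denT <- sqrt(sum(tm^2))
  if (denT < 1e-9) return(NULL)
  n <- length(template)
  num <- xcorr_valid(search, tm)
  ones <- matrix(1, nrow(template), ncol(template))
  s1 <- xcorr_valid(search, ones)
  s2 <- xcorr_valid(search^2, ones)
  denS <- sqrt(pmax(0, s2 - s1^2 / n))
  ncc <- num / (denS * denT)
  ncc[denS < 1e-9] <- -Inf
  pk <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
  # parabolic sub-pixel fit along each axis
  sub <- c(0, 0)
  for (ax in 1:2) {
    i <- pk[ax]
    if (i > 1 && i < dim(ncc)[ax]) {
      trip <- if (ax == 1) ncc[(i - 1):(i + 1), pk[2]]
        else ncc[pk[1], (i - 1):(i + 1)]
      den <- trip[1] - 2 * trip[2] + trip[3]
      if (is.finite(den) && abs(den) > 1e-12)
        sub[ax] <- 0.5 * (trip[1] - trip[3]) / den
    }
  }
  center <- (dim(ncc) + 1) / 2
  list(dy = pk[1] - center[1] + sub[1],
       dx = pk[2] - center[2] + sub[2],
       score = max(ncc))
}

#' Multi-pass block-matching displacement field
#'
#' Estimates the displacement of `frameB` relative to `frameA` on a regular
#' grid by maximizing normalized cross-correlation of an interrogation
#' window (side `IW`) within a search window (side `SW`), with vectors every
#' `VS` pixels. Passes run coarse to fine; each pass pre-shifts its search
#' windows by the previous pass's field (bilinearly interpolated) and adds
#' parabolic sub-pixel refinement. Default schedule: 60/120/15, 50/120/12,
#' 40/80/10. Vectors are bounded by `(SW - IW) / 2` per pass; flat
#' (zero-variance) interrogation windows are flagged invalid.
#'
#' @param frameA,frameB equal-size grayscale images (`lj_image` or matrix).
#' @param IW,SW,VS equal-length vectors giving the pass schedule.
#' @return data.frame with node coordinates (`x` = column, `y` = row),
#'   displacement (`u` = column shift, `v` = row shift), correlation
#'   `score` and `valid` flag, for the final pass.
#' @export
displacement_field <- function(frameA, frameB,
                               IW = c(60, 50, 40),
                               SW = c(120, 120, 80),
                               VS = c(15, 12, 10)) {
  A <- as_pixel_matrix(frameA); B <- as_pixel_matrix(frameB)
  stopifnot(identical(dim(A), dim(B)), length(IW) == length(SW),
            length(SW) == length(VS), all(IW < SW))
  nr <- nrow(A); nc <- ncol(A)
  prev <- NULL
  for (p in seq_along(IW)) {
    iw <- IW[p]; sw <- SW[p]; vs <- VS[p]
    hw <- iw %/% 2
    xs <- seq(hw + 1, nc - hw, by = vs)
    ys <- seq(hw + 1, nr - hw, by = vs)
    grid <- expand.grid(y = ys, x = xs)
    grid$u <- NA_real_; grid$v <- NA_real_
    grid$score <- NA_real_; grid$valid <- FALSE
    for (g in seq_len(nrow(grid))) {
      cx <- grid$x[g]; cy <- grid$y[g]
      u0 <- 0; v0 <- 0
      if (!is.null(prev)) {
        u0 <- round(interp_field(prev, cx, cy, "u"))
        v0 <- round(interp_field(prev, cx, cy, "v"))
        if (!is.finite(u0) || !is.finite(v0)) { u0 <- 0; v0 <- 0 }
      }
      tr <- (cy - hw):(cy + hw - (1 - iw %% 2))
      tc <- (cx - hw):(cx + hw - (1 - iw %% 2))
      sh <- sw %/% 2
      sr <- (cy + v0 - sh):(cy + v0 + sh - (1 - sw %% 2))
      sc <- (cx + u0 - sh):(cx + u0 + sh - (1 - sw %% 2))
      if (min(sr) < 1 || max(sr) > nr || min(sc) < 1 || max(sc) > nc) next
      res <- ncc_peak(A[tr, tc], B[sr, sc])
      if (is.null(res)) next
      grid$u[g] <- u0 + res$dx
      grid$v[g] <- v0 + res$dy
      grid$score[g] <- res$score
      grid$valid[g] <- TRUE
    }
    prev <- grid
  }
  prev
}

#' @noRd
interp_field <- function(field, x, y, comp) {
  # bilinear interpolation of a gridded field component at (x, y)
  xs <- sort(unique(field$x)); ys <- sort(unique(field$y))
  xi <- findInterval(x, xs, all.inside = TRUE)
  yi <- findInterval(y, ys, all.inside = TRUE)
  x0 <- xs[xi]; x1 <- xs[min(xi + 1, length(xs))]
  y0 <- ys[yi]; y1 <- ys[min(yi + 1, length(ys))]
  val <- function(px, py) {
    v <- field[[comp]][field$x == px & field$y == py]
    if (length(v)) v[1] else NA_real_
  }
  tx <- if (x1 > x0) (x - x0) / (x1 - x0) else 0
  ty <- if (y1 > y0) (y - y0) / (y1 - y0) else 0
  v00 <- val(x0, y0); v10 <- val(x1, y0)
  v01 <- val(x0, y1); v11 <- val(x1, y1)
  if (anyNA(c(v00, v10, v01, v11))) return(mean(c(v00, v10, v01, v11),
                                                na.rm = TRUE))
  (1 - ty) * ((1 - tx) * v00 + tx * v10) + ty * ((1 - tx) * v01 + tx * v11)
}

#' Pooled angular histogram of displacement vectors
#'
#' Pools the valid vectors of one or more displacement fields (typically
#' the consecutive-frame correlations 1-2, 2-3, 3-4 of a spot series) into
#' an angular histogram (rose plot data). Angles follow image convention:
#' 0 = increasing column (lateral when medial is to the left), pi/2 =
#' increasing row.
#'
#' @param fields a displacement field data.frame or list of them.
#' @param nbins_angle number of angular bins over `(-pi, pi]`.
#' @param min_magnitude vectors shorter than this are excluded.
#' @return list with `breaks`, `mids`, `counts`, and pooled `angles`.
#' @export
rose_histogram <- function(fields, nbins_angle = 24, min_magnitude = 1e-3) {
  if (is.data.frame(fields)) fields <- list(fields)
  ang <- unlist(lapply(fields, function(f) {
    f <- f[f$valid & sqrt(f$u^2 + f$v^2) >= min_magnitude, , drop = FALSE]
    atan2(f$v, f$u)
  }))
  breaks <- seq(-pi, pi, length.out = nbins_angle + 1)
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE)
  list(breaks = breaks, mids = h$mids, counts = h$counts, angles = ang)
}

#' Pratt algebraic circle fit
#'
#' Moment-based Pratt fit: centered second/third/fourth moments, the
#' characteristic polynomial `A0 + x (A1 + x (A2 + 4 x^2))`, a Newton
#' root-find from `x = 0` (at most 20 iterations, eps = 1e-12), and the
#' closed-form center and radius.
#'
#' @param points n x 2 matrix of point coordinates (n >= 3).
#' @return list with `center` (length 2) and `radius`.
#' @export
pratt_circle_fit <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("At least 3 points are required to fit a circle.")
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  X <- points[, 1] - mx; Y <- points[, 2] - my
  Z <- X^2 + Y^2
  Mxx <- mean(X * X); Myy <- mean(Y * Y); Mxy <- mean(X * Y)
  Mxz <- mean(X * Z); Myz <- mean(Y * Z); Mzz <- mean(Z * Z)
  Mz <- Mxx + Myy
  Cov_xy <- Mxx * Myy - Mxy * Mxy
  A2 <- 4 * Cov_xy - 3 * Mz * Mz - Mzz
  A1 <- Mzz * Mz + 4 * Cov_xy * Mz - Mxz^2 - Myz^2 - Mz^3
  A0 <- Mxz^2 * Myy + Myz^2 * Mxx - Mzz * Cov_xy - 2 * Mxz * Myz * Mxy +
    Mz * Mz * Cov_xy
  A22 <- A2 + A2
  xnew <- 0
  ynew <- 1e20
  for (iter in 1:20) {
    yold <- ynew
    ynew <- A0 + xnew * (A1 + xnew * (A2 + 4 * xnew * xnew))
    if (abs(ynew) > abs(yold)) { xnew <- 0; break }
    Dy <- A1 + xnew * (A22 + 16 * xnew * xnew)
    xold <- xnew
    xnew <- xold - ynew / Dy
    if (!is.finite(xnew)) { xnew <- 0; break }
    if (abs((xnew - xold) / max(abs(xnew), 1e-300)) < 1e-12) break
    if (xnew < 0) { xnew <- 0; break }
  }
  DET <- xnew * xnew - xnew * Mz + Cov_xy
  cx <- (Mxz * (Myy - xnew) - Myz * Mxy) / (2 * DET)
  cy <- (Myz * (Mxx - xnew) - Mxz * Mxy) / (2 * DET)
  radius <- sqrt(cx * cx + cy * cy + Mz + 2 * xnew)
  if (!is.finite(radius)) stop("Points selected are collinear.")
  list(center = c(cx + mx, cy + my), radius = radius)
}

#' Ratiometric medial-lateral gradient
#'
#' Pixelwise channel ratio and per-channel level profiles across ML bins,
#' reproducing the ratio-quantification procedure: zero pixels (outside the
#' tissue) and saturated pixels (255) are excluded everywhere; pixels below
#' the per-channel threshold count as zero in the level profiles (tissue-
#' scale averages) but are excluded from the ratio profile (matrix-only
#' average). The image is cut into `nbins` equal column bins along ML and
#' every profile is normalized to its most-lateral (last) bin.
#'
#' @param imgA,imgB equal-size 8-bit images (`lj_image` or matrix).
#' @param thA,thB per-channel background thresholds.
#' @param nbins number of ML bins.
#' @return list of data.frames `A`, `B`, `ratio`, each with `position`
#'   (relative ML bin center), `mean`, `mean_norm`.
#' @export
ratio_gradient <- function(imgA, imgB, thA = 33, thB = 30, nbins = 10) {
  A <- as_pixel_matrix(imgA); B <- as_pixel_matrix(imgB)
  stopifnot(identical(dim(A), dim(B)))
  Aex <- A == 0 | A == 255
  Bex <- B == 0 | B == 255
  # level images: out-of-tissue/saturated excluded, sub-threshold as zero
  Alev <- A; Alev[A < thA] <- 0; Alev[Aex] <- NA
  Blev <- B; Blev[B < thB] <- 0; Blev[Bex] <- NA
  # matrix-only images for the ratio
  Am <- A; Am[A < thA | Aex] <- NA
  Bm <- B; Bm[B < thB | Bex] <- NA
  R <- Am / Bm
  R[!is.finite(R) | R == 0] <- NA
  if (all(is.na(Am))) stop("channel A has no usable foreground")
  if (all(is.na(Bm))) stop("channel B has no usable foreground")
  nc <- ncol(A)
  binsize <- floor(nc / nbins)
  if (binsize < 1) stop("more bins than columns")
  profile <- function(M) {
    means <- vapply(seq_len(nbins), function(k) {
      cols <- if (k < nbins) ((k - 1) * binsize + 1):(k * binsize)
        else ((nbins - 1) * binsize + 1):nc
      mean(M[, cols], na.rm = TRUE)
    }, 1.0)
    if (!is.finite(means[nbins]) || means[nbins] == 0)
      stop("most-lateral bin is empty or zero; cannot normalize")
    data.frame(position = (seq_len(nbins) - 0.5) / nbins,
               mean = means, mean_norm = means / means[nbins])
  }
  list(A = profile(Alev), B = profile(Blev), ratio = profile(R))
}

#' Mean intensity inside polygonal regions
#'
#' @param img `lj_image` or matrix.
#' @param regions list of polygons (n x 2 matrices, columns = (x = column,
#'   y = row) pixel coordinates); regions may overlap.
#' @return numeric vector of per-region means.
#' @export
region_means <- function(img, regions) {
  px <- as_pixel_matrix(img)
  nr <- nrow(px); nc <- ncol(px)
  vapply(seq_along(regions), function(i) {
    poly <- regions[[i]]
    if (min(poly[, 1]) < 0.5 || max(poly[, 1]) > nc + 0.5 ||
        min(poly[, 2]) < 0.5 || max(poly[, 2]) > nr + 0.5)
      stop("region ", i, " extends outside the image")
    cr <- max(1, floor(min(poly[, 2]))):min(nr, ceiling(max(poly[, 2])))
    cc <- max(1, floor(min(poly[, 1]))):min(nc, ceiling(max(poly[, 1])))
    gx <- rep(cc, each = length(cr))
    gy <- rep(cr, length(cc))
    inside <- point_in_polygon(gx, gy, poly)
    if (!any(inside)) stop("region ", i, " contains no pixels")
    mean(px[cbind(gy[inside], gx[inside])])
  }, 1.0)
}

#' @noRd
point_in_polygon <- function(px, py, poly) {
  # even-odd rule, vectorized over points
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
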