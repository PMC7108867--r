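#' Seeded synthetic fibrous-matrix image
#'
#' Renders bright curvilinear elements (smoothed random walks with a
#' Gaussian cross-section, sigma ~ 2 px) on a dark noisy background,
#' emulating an en-face view of fibronectin matrix at a tissue interface.
#' Element sizes are drawn per class — "small" fibrils with maximal extent
#' in (4, 40) um, "large" assembled networks in (40, 150) um — and element
#' placement along the medial-lateral (ML) axis follows a linear density
#' gradient. Rows run along ML with the reference (notochord) side at the
#' maximal row; columns run along anterior-posterior (AP).
#'
#' @param width_um,height_um canvas size (AP x ML), default 300 x 60 um.
#' @param n_small,n_large element counts per size class.
#' @param ml_gradient_slope slope of the linear placement density across
#'   relative ML position in `[0, 1]` (0 = reference side); density is
#'   proportional to `1 + slope * (m - 0.5)`, so `|slope| <= 2`.
#' @param seed integer seed; identical seeds give identical images.
#' @param pixels_per_um pixel scale.
#' @return `lj_image` whose `truth` holds per-element class and realized
#'   extent, the element label map, the noiseless foreground mask and the
#'   programmed slope.
#' @export
gen_matrix_image <- function(width_um = 300, height_um = 60,
                             n_small = 60, n_large = 6,
                             ml_gradient_slope = 0, seed = 1,
                             pixels_per_um = 17.4) {
  stopifnot(n_small >= 0, n_large >= 0, abs(ml_gradient_slope) <= 2)
  set.seed(as.integer(seed))
  nr <- round(height_um * pixels_per_um)
  nc <- round(width_um * pixels_per_um)
  acc <- matrix(0, nr, nc)       # stamped fiber amplitude
  labels <- matrix(0L, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  sigma <- 2
  half <- 4L                     # stamp half-width (2 sigma)
  off <- seq(-half, half)
  gauss1 <- function(d) exp(-d^2 / (2 * sigma^2))

  sample_ml <- function() {
    # inverse-CDF of the linear density on relative ML position
    s <- ml_gradient_slope
    u <- runif(1)
    m <- if (abs(s) < 1e-12) u else {
      a <- s / 2; b <- 1 - s / 2
      (-b + sqrt(b^2 + 4 * a * u)) / (2 * a)
    }
    m
  }

  elements <- list()
  # long elements are placed first: on a partially occupied canvas a long
  # collision-free path quickly becomes improbable
  classes <- c(rep("large", n_large), rep("small", n_small))
  for (id in seq_along(classes)) {
    cls <- classes[id]
    lim <- if (cls == "small") c(4, 40) else c(40, 150)
    # cap draws at what the canvas can hold (large networks on small
    # canvases); the class lower bound always stands
    cap <- min(lim[2], 0.8 * sqrt(width_um^2 + height_um^2))
    if (cap <= lim[1])
      stop("canvas too small for class ", cls)
    placed <- FALSE
    for (try in 1:60) {
      target <- runif(1, lim[1], cap)
      len_px <- target * pixels_per_um
      step <- 1.5
      n_pts <- max(3L, ceiling(len_px / step))
      heading <- runif(1, 0, 2 * pi)
      dth <- rnorm(n_pts - 1, 0, 0.04)
      th <- heading + cumsum(c(0, dth))
      px <- cumsum(c(0, step * cos(th[-n_pts])))
      py <- cumsum(c(0, step * sin(th[-n_pts])))
      feret_px <- max(dist(cbind(px, py)[unique(c(
        grDevices::chull(px, py))), , drop = FALSE]))
      if (feret_px / pixels_per_um < lim[1] ||
          feret_px / pixels_per_um > lim[2]) next
      m <- sample_ml()
      ry <- py - mean(py); rx <- px - mean(px)
      r_lo <- half + 1 - min(ry); r_hi <- nr - half - max(ry)
      c_lo <- half + 1 - min(rx); c_hi <- nc - half - max(rx)
      if (r_lo > r_hi || c_lo > c_hi) next
      # clamp the center into the feasible band (extended elements near
      # the canvas edge); truth records the sampled ML position
      row0 <- round(min(max(nr - m * (nr - 1), r_lo), r_hi))
      col0 <- round(runif(1, c_lo, c_hi))
      rows <- row0 + ry
      cols <- col0 + rx
      ri <- round(rows); ci <- round(cols)
      if (any(occupied[cbind(ri, ci)])) next
      # stamp
      for (k in seq_len(n_pts)) {
        rs <- ri[k] + off; cs <- ci[k] + off
        w <- outer(gauss1(rs - rows[k]), gauss1(cs - cols[k]))
        sub <- acc[rs, cs]
        acc[rs, cs] <- pmax(sub, w)
        lab <- labels[rs, cs]
        lab[w > 0.4 & lab == 0L] <- id
        labels[rs, cs] <- lab
      }
      # block out a neighbourhood so elements stay separable
      for (k in seq_len(n_pts)) {
        rr <- pmax(1L, pmin(nr, ri[k] + seq(-6L, 6L)))
        cc <- pmax(1L, pmin(nc, ci[k] + seq(-6L, 6L)))
        occupied[rr, cc] <- TRUE
      }
      elements[[id]] <- data.frame(id = id, class = cls,
                                   feret_um = feret_px / pixels_per_um,
                                   ml_rel = m)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place element ", id,
           " without exceeding the density cap")
  }
  fg_mask <- acc > 0.4
  img <- 20 + 200 * acc + matrix(rnorm(nr * nc, 0, 5), nr, nc)
  img <- pmin(pmax(img, 0), 255)
  truth <- list(
    elements = if (length(elements)) do.call(rbind, elements) else
      data.frame(id = integer(), class = character(),
                 feret_um = numeric(), ml_rel = numeric()),
    labels = labels, foreground = fg_mask,
    ml_gradient_slope = ml_gradient_slope, seed = seed
  )
  labeled_image(img, pixels_per_um, truth = truth)
}

#' Seeded synthetic photoconverted-spot time series
#'
#' Renders a bright elliptical spot whose medial-lateral extent shrinks by a
#' programmed fraction over the series while the anterior-posterior extent
#' changes independently, with multiplicative photobleaching per frame.
#' For spot images, columns run along ML (medial to the left) and rows
#' along AP, matching the dorsal-view convention of the photoconversion
#' assay.
#'
#' @param spot_um ML x AP half-axes of the initial spot, in um.
#' @param ml_shrink_fraction total ML shrink over the series, in `[0, 1)`;
#'   the final frame has ML extent `(1 - ml_shrink_fraction)` times the
#'   first.
#' @param ap_change_fraction total AP change (positive shrinks).
#' @param bleach_per_frame intensity multiplier applied per frame.
#' @param n_frames number of frames (15-min sampling convention).
#' @param seed integer seed.
#' @param pixels_per_um pixel scale.
#' @return object of class `lj_spot_series`: list of `lj_image` frames plus
#'   a `truth` record of programmed per-frame extents.
#' @export
gen_spot_series <- function(spot_um = c(8, 6), ml_shrink_fraction = 0,
                            ap_change_fraction = 0, bleach_per_frame = 1,
                            n_frames = 5, seed = 1, pixels_per_um = 17.4) {
  stopifnot(n_frames >= 2,
            ml_shrink_fraction >= 0, ml_shrink_fraction < 1,
            ap_change_fraction >= 0, ap_change_fraction < 1,
            bleach_per_frame > 0, bleach_per_frame <= 1)
  set.seed(as.integer(seed))
  a0 <- spot_um[1] * pixels_per_um   # ML half-axis, px (columns)
  b0 <- spot_um[2] * pixels_per_um   # AP half-axis, px (rows)
  if ((1 - ml_shrink_fraction) * 2 * a0 < 3 ||
      (1 - ap_change_fraction) * 2 * b0 < 3)
    stop("spot smaller than 3 px in final frame")
  nc <- ceiling(2 * a0) + 40
  nr <- ceiling(2 * b0) + 40
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  col_d <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  row_d <- matrix(rep(seq_len(nr), nc), nr, nc) - cy
  frames <- vector("list", n_frames)
  ext <- data.frame(frame = seq_len(n_frames), ml_px = NA_real_,
                    ap_px = NA_real_, intensity = NA_real_)
  for (t in seq_len(n_frames)) {
    f <- (t - 1) / (n_frames - 1)
    a <- a0 * (1 - ml_shrink_fraction)^f
    b <- b0 * (1 - ap_change_fraction)^f
    inten <- 200 * bleach_per_frame^(t - 1)
    r2 <- (col_d / a)^2 + (row_d / b)^2
    core <- inten * pmin(1, pmax(0, (1.05 - r2) / 0.1))
    img <- 8 + core + matrix(rnorm(nr * nc, 0, 3), nr, nc)
    frames[[t]] <- labeled_image(pmin(pmax(img, 0), 255), pixels_per_um)
    ext$ml_px[t] <- 2 * a; ext$ap_px[t] <- 2 * b; ext$intensity[t] <- inten
  }
  structure(list(frames = frames,
                 truth = list(extents = ext,
                              ml_shrink_fraction = ml_shrink_fraction,
                              ap_change_fraction = ap_change_fraction,
                              bleach_per_frame = bleach_per_frame,
                              seed = seed),
                 pixels_per_um = pixels_per_um),
            class = "lj_spot_series")
}

#' @export
print.lj_spot_series <- function(x, ...) {
  cat(sprintf("Spot series: %d frames, programmed ML shrink %.0f%%\n",
              length(x$frames), 100 * x$truth$ml_shrink_fraction))
  invisible(x)
}

#' Seeded points on a noisy circular arc
#'
#' Fixture generator for the Pratt circle fit.
#'
#' @param center length-2 circle center.
#' @param radius circle radius.
#' @param n number of points (>= 3).
#' @param angular_span arc length in radians (> 0).
#' @param noise_sd isotropic Gaussian noise added to each point.
#' @param seed integer seed.
#' @return list with `points` (n x 2) and `truth` (center, radius).
#' @export
gen_circle_points <- function(center = c(0, 0), radius = 1, n = 20,
                              angular_span = 2 * pi, noise_sd = 0,
                              seed = 1) {
  stopifnot(n >= 3, radius > 0)
  if (angular_span <= 0) stop("angular_span must be positive")
  set.seed(as.integer(seed))
  th <- seq(0, angular_span, length.out = n)
  pts <- cbind(center[1] + radius * cos(th),
               center[2] + radius * sin(th))
  if (noise_sd > 0) pts <- pts + matrix(rnorm(2 * n, 0, noise_sd), n, 2)
  list(points = pts, truth = list(center = center, radius = radius,
                                  noise_sd = noise_sd, seed = seed))
}

#' Seeded dual-channel ratio image pair
#'
#' Emulates a tension-probe / total-matrix channel pair: channel B is a
#' smooth positive base pattern; channel A equals B times a medial-lateral
#' ratio profile, with an optional seeded fraction of A pixels clipped to
#' 255 (saturation). For ratio pairs, the ML axis runs along columns with
#' the most-lateral side at the maximal column, matching the binning of the
#' ratio-quantification code.
#'
#' @param base_pattern optional matrix for channel B; default is a smooth
#'   seeded random texture spanning sub-threshold background and bright
#'   matrix, values in `[10, 200]`.
#' @param ratio_profile_ml function of relative ML position in `[0, 1]`
#'   (1 = most lateral) returning the per-column A/B ratio, or a constant.
#' @param saturation_fraction fraction of A pixels clipped to 255
#'   (`[0, 0.05]`).
#' @param seed integer seed.
#' @param nr,nc canvas size if `base_pattern` is not supplied.
#' @param pixels_per_um pixel scale.
#' @return list with `A`, `B` (`lj_image`) and `truth` (per-column ratio).
#' @export
gen_ratio_pair <- function(base_pattern = NULL,
                           ratio_profile_ml = function(m) 1 + m,
                           saturation_fraction = 0, seed = 1,
                           nr = 200, nc = 400, pixels_per_um = 17.4) {
  stopifnot(saturation_fraction >= 0, saturation_fraction <= 0.05)
  set.seed(as.integer(seed))
  if (is.null(base_pattern)) {
    noise <- matrix(rnorm(nr * nc), nr, nc)
    smooth <- conv2_same(noise, outer(stats::dnorm(-8:8, sd = 3),
                                      stats::dnorm(-8:8, sd = 3)))
    f <- (smooth - min(smooth)) / diff(range(smooth))
    base_pattern <- 10 + 190 * f^1.5
  } else {
    nr <- nrow(base_pattern); nc <- ncol(base_pattern)
  }
  if (is.numeric(ratio_profile_ml)) {
    val <- ratio_profile_ml
    ratio_profile_ml <- function(m) rep(val, length(m))
  }
  mrel <- (seq_len(nc) - 0.5) / nc
  rcol <- ratio_profile_ml(mrel)
  if (any(rcol <= 0)) stop("ratio profile must be positive")
  A <- sweep(base_pattern, 2, rcol, "*")
  A <- pmin(A, 255)
  if (saturation_fraction > 0) {
    n_sat <- round(saturation_fraction * nr * nc)
    idx <- sample(nr * nc, n_sat)
    A[idx] <- 255
  }
  list(A = labeled_image(round(A), pixels_per_um),
       B = labeled_image(round(base_pattern), pixels_per_um),
       truth = list(ratio_by_col = rcol, ml_rel = mrel, seed = seed))
}
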