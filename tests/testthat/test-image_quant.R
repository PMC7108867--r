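test_that("Phansalkar threshold matches a brute-force window oracle", {
  set.seed(5)
  px <- matrix(round(runif(40 * 50, 0, 255)), 40, 50)
  mask <- local_threshold_phansalkar(labeled_image(px), radius_px = 5)
  for (rc in list(c(15, 20), c(8, 40), c(30, 9))) {
    t_oracle <- phansalkar_point_oracle(px, 5, rc[1], rc[2])
    expect_identical(mask$mask[rc[1], rc[2]], px[rc[1], rc[2]] / 255 > t_oracle)
  }
})

test_that("Phansalkar edge cases behave per contract", {
  # at s = 0 the threshold is m (0.75 + 2 exp(-10 m)): above m for dark
  # constants (m < ln(8)/10 ~ 0.208, empty mask), below m for bright ones
  const <- labeled_image(matrix(30, 50, 50))
  m <- local_threshold_phansalkar(const, radius_px = 5)
  expect_equal(sum(m$mask), 0)
  bright <- labeled_image(matrix(200, 50, 50))
  mb <- local_threshold_phansalkar(bright, radius_px = 5)
  expect_equal(mean(mb$mask), 1)
  expect_error(local_threshold_phansalkar(labeled_image(matrix(1, 10, 10)),
                                          radius_px = 15), "window")
  # polarity: dark fibers on bright background yield (nearly) no foreground
  img <- gen_matrix_image(40, 20, n_small = 4, n_large = 0, seed = 2)
  inv <- labeled_image(255 - img$pixels, img$pixels_per_um)
  m_inv <- local_threshold_phansalkar(inv)
  expect_lt(sum(m_inv$mask & img$truth$foreground) /
              sum(img$truth$foreground), 0.05)
})

test_that("segmentation recovers the generator truth (IoU)", {
  img <- gen_matrix_image(100, 40, n_small = 15, n_large = 2,
                          ml_gradient_slope = 1, seed = 3)
  mask <- local_threshold_phansalkar(img)
  ss <- size_sort(mask)
  total_matrix <- ss$small$mask | ss$large$mask   # noise removed, per pipeline
  iou <- sum(total_matrix & img$truth$foreground) /
    sum(total_matrix | img$truth$foreground)
  expect_gte(iou, 0.7)
})

test_that("global min-fraction threshold follows its formula", {
  px <- matrix(0, 10, 10); px[5, 5] <- 255; px[2, 2] <- 60
  m <- global_threshold_minfrac(labeled_image(px), frac = 0.2)
  expect_identical(m$mask, px > 51)
  m0 <- global_threshold_minfrac(labeled_image(px), frac = 0)
  expect_identical(m0$mask, px > 0)
  m1 <- global_threshold_minfrac(labeled_image(px), frac = 0.999)
  expect_equal(sum(m1$mask), 1)
  expect_error(global_threshold_minfrac(labeled_image(matrix(7, 5, 5))),
               "constant")
})

test_that("size_sort classifies by Feret diameter in micrometers", {
  ppu <- 17.4
  m <- matrix(FALSE, 100, 1200)
  m[10, 1:round(3 * ppu)] <- TRUE                 # ~3 um -> noise
  m[40, 1:round(20 * ppu)] <- TRUE                # ~20 um -> small
  m[80, 1:round(60 * ppu)] <- TRUE                # ~60 um -> large
  ss <- size_sort(binary_mask(m, ppu))
  expect_equal(as.integer(table(ss$components$class)[c("noise", "small",
                                                       "large")]),
               c(1L, 1L, 1L))
  expect_equal(sum(ss$noise$mask) + sum(ss$small$mask) + sum(ss$large$mask),
               sum(m))  # partition covers all foreground
  empty <- size_sort(binary_mask(matrix(FALSE, 5, 5), ppu))
  expect_equal(nrow(empty$components), 0)
  expect_equal(sum(empty$noise$mask | empty$small$mask | empty$large$mask), 0)
})

test_that("size classes partition components disjointly", {
  img <- gen_matrix_image(80, 40, n_small = 10, n_large = 1, seed = 6)
  ss <- size_sort(binary_mask(img$truth$foreground, img$pixels_per_um))
  overlap <- (ss$noise$mask & ss$small$mask) |
    (ss$noise$mask & ss$large$mask) | (ss$small$mask & ss$large$mask)
  expect_equal(sum(overlap), 0)
  expect_identical(ss$noise$mask | ss$small$mask | ss$large$mask,
                   img$truth$foreground)
})

test_that("size-sort recovers generator classes on noiseless masks", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    img <- gen_matrix_image(120, 50, n_small = 12, n_large = 2, seed = s)
    ss <- size_sort(binary_mask(img$truth$foreground, img$pixels_per_um))
    truth <- img$truth$elements
    comp <- ss$components[ss$components$class != "noise", ]
    # match components to truth elements via the label map
    for (i in seq_len(nrow(comp))) {
      px <- which(ss$labels == comp$id[i], arr.ind = TRUE)[1, ]
      tid <- img$truth$labels[px[1], px[2]]
      if (tid > 0) {
        total <- total + 1
        if (comp$class[i] == truth$class[truth$id == tid]) hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("ml_distribution recovers uniformity and gradients", {
  ppu <- 17.4
  tissue <- binary_mask(matrix(TRUE, 300, 800), ppu)
  set.seed(3)
  sig <- matrix(runif(300 * 800) < 0.1, 300, 800)
  d <- ml_distribution(binary_mask(sig, ppu), tissue)
  expect_equal(sum(d$frequency), 1, tolerance = 1e-12)
  expect_lt(max(d$counts) / min(d$counts), 1.5)
  # all signal on the reference row -> all mass in the first bin
  sig0 <- matrix(FALSE, 300, 800); sig0[300, ] <- TRUE
  d0 <- ml_distribution(binary_mask(sig0, ppu), tissue)
  expect_equal(d0$counts[1], sum(sig0))
  expect_equal(sum(d0$counts[-1]), 0)
  # generated gradient: rank correlation of bin counts against position
  img <- gen_matrix_image(200, 60, n_small = 40, n_large = 0,
                          ml_gradient_slope = 1.5, seed = 5)
  full <- binary_mask(matrix(TRUE, nrow(img$pixels), ncol(img$pixels)), ppu)
  dg <- ml_distribution(binary_mask(img$truth$foreground, ppu), full)
  expect_gt(cor(dg$bin_centers, dg$counts, method = "spearman"), 0)
})

test_that("ap_density measures per-sector coverage at stated positions", {
  ppu <- 17.4
  nc <- round(150 * ppu)
  tissue <- binary_mask(matrix(TRUE, 100, nc), ppu)
  set.seed(8)
  sig <- matrix(runif(100 * nc) < 0.3, 100, nc)
  d <- ap_density(binary_mask(sig, ppu), tissue)
  expect_equal(d$position_um, c(25, 75, 125))
  expect_true(all(abs(d$density - 0.3) < 0.01))
  # zero signal -> zero densities
  d0 <- ap_density(binary_mask(matrix(FALSE, 100, nc), ppu), tissue)
  expect_true(all(d0$density == 0))
  # AP ramp: recovered density increases
  ramp <- matrix(rep(seq(0, 1, length.out = nc), each = 100) >
                   matrix(runif(100 * nc), 100, nc), 100, nc)
  dr <- ap_density(binary_mask(ramp, ppu), tissue)
  expect_true(all(diff(dr$density) > 0))
})

test_that("spot metrics match closed forms and programmed deformations", {
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  sm1 <- spot_metrics(list(one))
  expect_equal(sm1$width, 0); expect_equal(sm1$height, 0)
  # filled rectangle: population sd of a discrete uniform
  rect <- matrix(FALSE, 20, 20); rect[6:15, 4:10] <- TRUE
  smr <- spot_metrics(list(rect))
  expect_equal(smr$width, sqrt((7^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(smr$height, sqrt((10^2 - 1) / 12), tolerance = 1e-12)
  expect_error(spot_metrics(list(matrix(FALSE, 3, 3))), "frame 1")
  # programmed 40% ML shrink, 0% AP change, with bleaching, Otsu default
  sp <- gen_spot_series(ml_shrink_fraction = 0.4, ap_change_fraction = 0,
                        bleach_per_frame = 0.9, n_frames = 5, seed = 2)
  sm <- spot_metrics(sp)
  expect_equal(sm$width_norm[5], 0.6, tolerance = 0.05)
  expect_equal(sm$height_norm[5], 1.0, tolerance = 0.05)
  # normalized metrics are insensitive to bleaching under the default
  sp_nb <- gen_spot_series(ml_shrink_fraction = 0.4, ap_change_fraction = 0,
                           bleach_per_frame = 1, n_frames = 5, seed = 2)
  sm_nb <- spot_metrics(sp_nb)
  expect_equal(sm$width_norm[5], sm_nb$width_norm[5], tolerance = 0.05)
})

test_that("displacement field recovers translations and flags flat patches", {
  set.seed(9)
  A <- matrix(0, 200, 200)
  A[60:140, 60:140] <- matrix(runif(81 * 81, 0, 255), 81, 81)
  df0 <- displacement_field(A, A)
  expect_s3_class(df0, "data.frame")
  # integer peak is exact at zero; parabolic sub-pixel refinement adds
  # jitter below a quarter pixel at perfect-score peaks
  expect_equal(median(df0$u[df0$valid]), 0, tolerance = 0.05)
  expect_equal(median(df0$v[df0$valid]), 0, tolerance = 0.05)
  expect_lt(max(abs(df0$u[df0$valid])), 0.25)
  expect_lt(max(abs(df0$v[df0$valid])), 0.25)
  B <- matrix(0, 200, 200)
  B[60:140, 65:145] <- A[60:140, 60:140]   # shift +5 columns
  df <- displacement_field(A, B)
  expect_equal(median(df$u[df$valid]), 5, tolerance = 0.05)
  expect_equal(median(df$v[df$valid]), 0, tolerance = 0.05)
  # a completely flat pair yields no valid vectors
  flat <- displacement_field(matrix(3, 150, 150), matrix(3, 150, 150))
  expect_equal(sum(flat$valid), 0)
})

test_that("rose histogram shows the lateral bias of a shrinking spot", {
  sp <- gen_spot_series(spot_um = c(10, 7), ml_shrink_fraction = 0.5,
                        n_frames = 4, seed = 6)
  fields <- lapply(1:3, function(k)
    displacement_field(sp$frames[[k]]$pixels, sp$frames[[k + 1]]$pixels,
                       IW = c(40, 30), SW = c(80, 60), VS = c(12, 10)))
  rh <- rose_histogram(fields)
  # ML motion dominates: |u| mass exceeds |v| mass
  horiz <- mean(abs(cos(rh$angles)) > abs(sin(rh$angles)))
  expect_gt(horiz, 0.6)
  # isotropic control: no such dominance
  sp0 <- gen_spot_series(spot_um = c(10, 7), ml_shrink_fraction = 0,
                         n_frames = 4, seed = 6)
  f0 <- lapply(1:3, function(k)
    displacement_field(sp0$frames[[k]]$pixels, sp0$frames[[k + 1]]$pixels,
                       IW = c(40, 30), SW = c(80, 60), VS = c(12, 10)))
  rh0 <- rose_histogram(f0)
  expect_lt(length(rh0$angles), length(rh$angles))
})

test_that("Pratt fit is exact on circles and matches the eigen oracle", {
  th <- c(0.3, 1.2, 2.5, 4.0)
  pts <- cbind(cos(th), sin(th))
  f <- pratt_circle_fit(pts)
  expect_equal(f$radius, 1, tolerance = 1e-9)
  expect_equal(f$center, c(0, 0), tolerance = 1e-9)
  expect_error(pratt_circle_fit(rbind(c(0, 0), c(1, 1))), "At least 3")
  expect_error(pratt_circle_fit(cbind(1:5, 2 * (1:5) + 3)), "collinear")
  # noisy arcs: against truth (2%) and the independent eigen solver (1e-6)
  for (s in 1:3) {
    cp <- gen_circle_points(c(120, 80), 100, 30, angular_span = pi,
                            noise_sd = 0.5, seed = s)
    f <- pratt_circle_fit(cp$points)
    o <- pratt_eigen_oracle(cp$points)
    expect_equal(f$radius, 100, tolerance = 0.02)
    expect_equal(f$radius, o$radius, tolerance = 1e-6)
    expect_equal(f$center, o$center, tolerance = 1e-4)
  }
})

test_that("Pratt fit is rigid-motion invariant/equivariant", {
  cp <- gen_circle_points(c(0, 0), 50, 20, angular_span = 2, noise_sd = 1,
                          seed = 4)
  f0 <- pratt_circle_fit(cp$points)
  th <- 0.9; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- cp$points %*% R + rep(c(10, -7), each = 20)
  f1 <- pratt_circle_fit(moved)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-9)
  expect_equal(f1$center, drop(f0$center %*% R) + c(10, -7),
               tolerance = 1e-6)
})

test_that("ratio gradient reproduces constant and linear profiles", {
  rp <- gen_ratio_pair(ratio_profile_ml = 2, saturation_fraction = 0,
                       seed = 4)
  rg <- ratio_gradient(rp$A, rp$B)
  expect_true(all(abs(rg$ratio$mean - 2) < 0.02))
  expect_true(all(abs(rg$ratio$mean_norm - 1) < 0.02))
  # linear profile: per-bin recovery within 5% of binwise truth
  rp2 <- gen_ratio_pair(ratio_profile_ml = function(m) 1 + m,
                        saturation_fraction = 0, seed = 5)
  rg2 <- ratio_gradient(rp2$A, rp2$B)
  truth_bin <- vapply(1:10, function(k)
    mean(rp2$truth$ratio_by_col[(40 * (k - 1) + 1):(40 * k)]), 1.0)
  expect_true(all(abs(rg2$ratio$mean / truth_bin - 1) < 0.05))
  # saturated-out channel: error path
  sat <- labeled_image(matrix(255, 50, 100))
  expect_error(ratio_gradient(sat, rp$B$pixels[1:50, 1:100]),
               "no usable foreground")
})

test_that("region means average exactly inside polygons", {
  px <- matrix(7, 40, 60)
  sq <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))
  expect_equal(region_means(labeled_image(px), list(sq)), 7)
  half <- px; half[, 31:60] <- 200
  regions <- list(rbind(c(5, 5), c(25, 5), c(25, 35), c(5, 35)),
                  rbind(c(35, 5), c(55, 5), c(55, 35), c(5 + 30, 35)))
  mv <- region_means(labeled_image(half), regions)
  expect_equal(mv, c(7, 200))
  # overlapping regions are computed independently
  ov <- region_means(labeled_image(half), list(sq, sq))
  expect_equal(ov[1], ov[2])
  expect_error(region_means(labeled_image(px), list(sq + 1000)), "outside")
})
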