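test_that("model_params validates and carries the published constants", {
  p <- model_params()
  expect_equal(p$l0, 0.1)
  expect_equal(p$K_rep, 30000)
  expect_equal(p$c, 10)
  expect_equal(p$R_rep, 0.1)
  expect_equal(p$R_adh, 0.2)
  expect_equal(p$P, 5)
  expect_equal(p$dt, 0.001)
  expect_equal(p$N, 50L)
  expect_error(model_params(K_S = -1), "positive")
  expect_error(model_params(R_rep = 0.3, R_adh = 0.2), "R_rep")
})

test_that("canonical cross-section geometry is valid and symmetric", {
  p <- model_params()
  cs <- build_cross_section(canonical_layout(), p)
  expect_named(cs$tissues, c("NT", "PSM_L", "PSM_R", "NC"))
  for (t in cs$tissues) expect_equal(nrow(t$pos), 50)
  # mirror symmetry: PSM_R is PSM_L reflected; NT and NC self-mirror
  expect_equal(sort(cs$tissues$PSM_R$pos[, 1]),
               sort(-cs$tissues$PSM_L$pos[, 1]), tolerance = 1e-12)
  expect_equal(sort(cs$tissues$NT$pos[, 1]), sort(-cs$tissues$NT$pos[, 1]),
               tolerance = 1e-9)
  # construction constraint: no inter-tissue pair closer than R_rep
  nms <- names(cs$tissues)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- min(lapjoint:::cross_dist(cs$tissues[[nms[i]]]$pos,
                                   cs$tissues[[nms[j]]]$pos))
    expect_gte(d, p$R_rep)
  }
})

test_that("scaling the layout scales all pairwise distances", {
  p <- model_params()
  cs1 <- build_cross_section(canonical_layout(), p)
  cs2 <- build_cross_section(canonical_layout(scale = 2), p)
  all1 <- do.call(rbind, lapply(cs1$tissues, `[[`, "pos"))
  all2 <- do.call(rbind, lapply(cs2$tissues, `[[`, "pos"))
  i <- c(1, 30, 77, 120, 160); j <- c(20, 90, 140, 180, 199)
  d1 <- sqrt(rowSums((all1[i, ] - all1[j, ])^2))
  d2 <- sqrt(rowSums((all2[i, ] - all2[j, ])^2))
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("tissue_forces matches hand-evaluated cases", {
  # unstretched, (essentially) unpressurized regular 50-gon: forces vanish
  p0 <- model_params(P = 1e-12)
  r0 <- p0$l0 / (2 * sin(pi / 50))
  f <- tissue_forces(regular_polygon(50, r0), p0)
  expect_lt(max(abs(f)), 1e-10)
  # spring tension magnitude K_S (l - l0)
  p <- model_params(K_S = 100)
  expect_equal(p$K_S * (0.15 - p$l0), 5.0)
  # stretched polygon: net force points inward when tension beats pressure
  f2 <- tissue_forces(regular_polygon(50, 2 * r0), p)
  expect_true(all(rowSums(f2 * regular_polygon(50, 2 * r0)) < 0))
  expect_error(tissue_forces(rbind(c(0, 0), c(0, 0), c(1, 0)), p),
               "degenerate")
})

test_that("interaction force follows the piecewise law", {
  p <- model_params(K_adh = 10)
  # branch continuity at r = R_rep: both branches vanish
  eps <- 1e-9
  f_in <- interaction_force(c(p$R_rep - eps, 0), p)
  f_out <- interaction_force(c(p$R_rep + eps, 0), p)
  expect_lt(abs(f_in[1]), 1e-4)
  expect_lt(abs(f_out[1]), 1e-4)
  expect_equal(interaction_force(c(p$R_rep, 0), p), c(0, 0))
  # adhesive magnitude at the outer range boundary
  f_adh <- interaction_force(c(p$R_adh, 0), p)
  expect_equal(sqrt(sum(f_adh^2)), 10 * (0.2 - 0.1), tolerance = 1e-12)
  expect_lt(f_adh[1], 0)  # attractive: force on i points toward j
  # beyond range: zero
  expect_equal(interaction_force(c(0.25, 0), p), c(0, 0))
  # repulsive branch pushes i away from j
  f_rep <- interaction_force(c(0.05, 0), p)
  expect_gt(f_rep[1], 0)
  expect_equal(f_rep[1], p$K_rep * (p$R_rep - 0.05), tolerance = 1e-12)
  expect_error(interaction_force(c(0, 0), p), "zero separation")
})

test_that("interaction continuity at R_rep holds across parameter sets", {
  for (ka in c(4, 6.5, 10, 12)) {
    p <- model_params(K_adh = ka)
    for (eps in 10^(-c(3, 5, 7))) {
      lo <- sqrt(sum(interaction_force(c(p$R_rep - eps, 0), p)^2))
      hi <- sqrt(sum(interaction_force(c(p$R_rep + eps, 0), p)^2))
      expect_lt(lo, p$K_rep * eps * 1.01)
      expect_lt(hi, ka * eps * 1.01)
    }
  }
})

test_that("explicit Euler step is x + (dt/c) F and respects fixed points", {
  p <- model_params(K_S = 100)
  cs <- build_cross_section(canonical_layout(), p)
  f <- net_forces(cs, p)
  st1 <- step(cs, p, n_steps = 1)
  moved <- do.call(rbind, lapply(st1$cross_section$tissues, `[[`, "pos"))
  orig <- do.call(rbind, lapply(cs$tissues, `[[`, "pos"))
  n_mobile <- nrow(orig)
  expect_equal(moved - orig, (p$dt / p$c) * f[seq_len(n_mobile), ],
               tolerance = 1e-12)
  # yolk never moves
  expect_identical(st1$cross_section$yolk, cs$yolk)
  # equilibrium polygon is a fixed point (isolated tissue, far yolk)
  pe <- model_params(K_S = 100)
  r_eq <- polygon_equilibrium_length(pe) / (2 * sin(pi / pe$N))
  cse <- single_loop_cs(regular_polygon(pe$N, r_eq), pe)
  ste <- step(cse, pe, n_steps = 10)
  expect_equal(ste$cross_section$tissues$NT$pos,
               regular_polygon(pe$N, r_eq), tolerance = 1e-6)
})

test_that("a mirror-symmetric state stays mirror-symmetric under stepping", {
  p <- model_params(K_S = 100, dt = 2e-4)
  cs <- build_cross_section(canonical_layout(), p)
  st <- step(cs, p, n_steps = 500)
  for (nm in c("NT", "NC")) {
    x <- st$cross_section$tissues[[nm]]$pos[, 1]
    expect_equal(sort(x), sort(-x), tolerance = 1e-9)
  }
  l <- st$cross_section$tissues$PSM_L$pos
  r <- st$cross_section$tissues$PSM_R$pos
  expect_equal(sort(r[, 1]), sort(-l[, 1]), tolerance = 1e-9)
})

test_that("overdamped trajectory of a stretched pair follows exp decay", {
  # two-point loop = two springs; relative coordinate relaxes with rate
  # 2 * (2 K_S) / c; explicit Euler must match within O(dt)
  p <- model_params(K_S = 5, P = 1e-12, dt = 1e-3)
  x0 <- 0.3
  pos <- rbind(c(-x0 / 2, 0), c(x0 / 2, 0))
  cs <- single_loop_cs(pos, p)
  n <- 200
  st <- step(cs, p, n_steps = n)
  gap <- diff(st$cross_section$tissues$NT$pos[, 1])
  rate <- 2 * 2 * p$K_S / p$c   # both points move, two parallel springs
  expected <- p$l0 + (x0 - p$l0) * exp(-rate * n * p$dt)
  expect_equal(gap, expected, tolerance = 0.01)
})

test_that("isolated loops relax to the closed-form polygon equilibrium", {
  for (ks in c(50, 100, 200)) {
    p <- model_params(K_S = ks)
    cs <- single_loop_cs(lapjoint:::circle_points(c(0, 5), 0.8, p$N), p)
    st <- run_to_steady_state(cs, p, tol = 1e-4, max_steps = 5e5)
    expect_true(st$converged)
    pos <- st$cross_section$tissues$NT$pos
    l <- sqrt(rowSums((pos[c(2:p$N, 1), ] - pos)^2))
    lstar <- polygon_equilibrium_length(p)
    expect_lt(max(abs(l - lstar)) / lstar, 0.005)
  }
  # the N = 50, K_S = 100 value quoted in the examples
  expect_equal(polygon_equilibrium_length(model_params(K_S = 100)),
               0.1397, tolerance = 1e-3)
})

test_that("divergent integration aborts with a diagnostic", {
  # a stretched loop at a spring-unstable time step (2 K_S dt / c >> 2)
  p <- model_params(K_S = 100, dt = 0.5)
  cs <- single_loop_cs(lapjoint:::circle_points(c(0, 5), 5, p$N), p)
  expect_error(run_to_steady_state(cs, p, tol = 1e-6, max_steps = 1e5),
               "diverging|non-finite")
})

test_that("tension field is zero at rest length and uniform at equilibrium", {
  p <- model_params(K_S = 100)
  r0 <- p$l0 / (2 * sin(pi / p$N))
  st0 <- make_state(list(NT = regular_polygon(p$N, r0)), p)
  tf0 <- tension_field(st0, p)
  expect_lt(max(abs(tf0$tension)), 1e-10)
  # relaxed isolated polygon: uniform tension K_S (l* - l0) ~ 3.97
  cs <- single_loop_cs(lapjoint:::circle_points(c(0, 5), 0.8, p$N), p)
  st <- run_to_steady_state(cs, p, tol = 1e-4, max_steps = 5e5)
  tf <- tension_field(st, p)
  expect_equal(mean(tf$tension),
               p$K_S * (polygon_equilibrium_length(p) - p$l0),
               tolerance = 0.005)
  expect_lt(stats::sd(tf$tension), 0.01)
  expect_equal(mean(tf$tension), 3.97, tolerance = 0.01)
})

test_that("compiled and plain-R force paths agree", {
  p <- model_params(K_S = 80, K_adh = 9)
  cs <- build_cross_section(canonical_layout(), p)
  f_cpp <- net_forces(cs, p)
  # plain-R recomputation: intra-tissue forces + pairwise interactions
  pos_all <- do.call(rbind, c(lapply(cs$tissues, `[[`, "pos"),
                              list(cs$yolk)))
  grp <- rep(seq_along(cs$tissues), each = 50)
  grp <- c(grp, rep(0L, nrow(cs$yolk)))
  f_r <- matrix(0, nrow(pos_all), 2)
  off <- 0
  for (t in cs$tissues) {
    f_r[off + 1:50, ] <- tissue_forces(t$pos, p, t$ks)
    off <- off + 50
  }
  for (i in seq_len(nrow(pos_all))) {
    d <- pos_all[rep(i, nrow(pos_all)), , drop = FALSE] - pos_all
    r <- sqrt(rowSums(d^2))
    near <- which(r < p$R_adh & grp != grp[i] &
                    !(grp == 0 & grp[i] == 0) & r > 0)
    for (j in near) f_r[i, ] <- f_r[i, ] + interaction_force(d[j, ], p)
  }
  expect_equal(f_cpp, f_r, tolerance = 1e-10)
})

test_that("steady states respect volume exclusion", {
  st <- steady(100, 10)
  cs <- st$cross_section
  nms <- names(cs$tissues)
  dmin <- Inf
  for (i in 1:3) for (j in (i + 1):4) {
    dmin <- min(dmin, lapjoint:::cross_dist(cs$tissues[[nms[i]]]$pos,
                                            cs$tissues[[nms[j]]]$pos))
  }
  p <- st$params
  expect_gt(dmin, p$R_rep - 0.2 * p$R_rep)
})

test_that("steady-state metrics are stable under 10% more steps", {
  st <- steady(100, 10)
  L0 <- mean_L(morphometrics(st))
  st2 <- run_to_steady_state(st$cross_section, st$params, tol = 1e-9,
                             max_steps = 0.1 * st$step_count)
  L1 <- mean_L(morphometrics(st2))
  expect_lt(abs(L1 - L0) / L0, 0.001)
})
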