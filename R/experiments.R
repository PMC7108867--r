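#' Simulate one (K_S, K_adh) condition to steady state
#'
#' Builds the canonical cross-section, applies any per-interface adhesion or
#' per-spring surface-stiffness overrides, and relaxes to steady state.
#'
#' @param K_S,K_adh condition parameters.
#' @param layout layout list, see [canonical_layout()].
#' @param base `lj_params` supplying the fixed constants.
#' @param kadh_pairs named list of per-interface adhesion overrides, e.g.
#'   `list("PSM_L|NT" = 5)`.
#' @param nt_left_ks_factor multiply the stiffness of NT surface springs
#'   whose initial midpoint lies left of the midline by this factor.
#' @param tol,max_steps convergence control, see [run_to_steady_state()].
#' @param jitter,jitter_seed seeded initial-position noise, see
#'   [build_cross_section()].
#' @param dt integration step. The default is smaller than the legacy
#'   `0.001` of [model_params()]: explicit Euler with `K_rep = 30000` and
#'   `c = 10` is only contact-stable for `dt <= c / K_rep`, and `2e-4`
#'   makes the relaxation deterministic and exactly mirror-symmetric (see
#'   the methods vignette).
#' @return `lj_state` (with `$params` attached).
#' @export
simulate_condition <- function(K_S, K_adh, layout = canonical_layout(),
                               base = model_params(),
                               kadh_pairs = list(),
                               nt_left_ks_factor = 1,
                               tol = 1e-4, max_steps = 4e6, dt = 2e-4,
                               jitter = 0, jitter_seed = 1) {
  params <- model_params(K_S = K_S, K_adh = K_adh, K_rep = base$K_rep,
                         P = base$P, l0 = base$l0, R_rep = base$R_rep,
                         R_adh = base$R_adh, c = base$c, dt = dt,
                         N = base$N)
  cs <- build_cross_section(layout, params, jitter = jitter,
                            jitter_seed = jitter_seed)
  cs$kadh_pairs <- kadh_pairs
  if (nt_left_ks_factor != 1) {
    p <- cs$tissues$NT$pos
    nxt <- c(2:nrow(p), 1)
    midx <- (p[, 1] + p[nxt, 1]) / 2
    cs$tissues$NT$ks[midx < 0] <- params$K_S * nt_left_ks_factor
  }
  st <- run_to_steady_state(cs, params, tol = tol, max_steps = max_steps)
  st$params <- params
  st
}

#' @noRd
mean_interface_length <- function(m) (m$L_psm_nt_L + m$L_psm_nt_R) / 2

#' Sweep surface stiffness at fixed adhesion
#'
#' Runs the model over a grid of `K_S` values, measures the PSM|NT
#' interfacial length at steady state (mean of the two sides) and
#' normalizes it to the sweep maximum. Increasing surface stiffness
#' shrinks and stiffens the tissues, so the interfacial length decreases.
#'
#' @param ks_grid ascending grid of `K_S` values (>= 4 values).
#' @param K_adh fixed adhesion stiffness.
#' @param ... passed to [simulate_condition()].
#' @return data.frame with one row per grid point, metric columns and a
#'   `norm_L` column (value / max over converged runs).
#' @export
sweep_surface_stiffness <- function(ks_grid, K_adh = 10, ...) {
  stopifnot(length(ks_grid) >= 4, !is.unsorted(ks_grid))
  rows <- lapply(ks_grid, function(ks) {
    st <- simulate_condition(ks, K_adh, ...)
    m <- morphometrics(st)
    data.frame(K_S = ks, K_adh = K_adh, L = mean_interface_length(m), m)
  })
  out <- do.call(rbind, rows)
  finish_sweep(out, "L")
}

#' Sweep adhesion stiffness at fixed surface stiffness
#'
#' Metric: NT medial-lateral width relative to the PSM|NT interfacial
#' length, which saturates once adhesion is strong enough to keep the
#' interface fully engaged.
#'
#' @param kadh_grid ascending grid of `K_adh` values.
#' @param K_S fixed surface stiffness.
#' @param ... passed to [simulate_condition()].
#' @return data.frame with metric columns, the `ratio` column
#'   (NT ML width / L PSM|NT) and a detachment flag.
#' @export
sweep_adhesion_stiffness <- function(kadh_grid, K_S = 100, ...) {
  stopifnot(length(kadh_grid) >= 2, !is.unsorted(kadh_grid))
  rows <- lapply(kadh_grid, function(ka) {
    st <- simulate_condition(K_S, ka, ...)
    m <- morphometrics(st)
    data.frame(K_S = K_S, K_adh = ka, L = mean_interface_length(m),
               ratio = m$nt_ml / mean_interface_length(m),
               detached = (m$gaps_L + m$gaps_R > 0) |
                 m$detached_L | m$detached_R, m)
    })
  out <- do.call(rbind, rows)
  out <- finish_sweep(out, "L")
  # in this geometry weak adhesion expresses itself as continuous peeling
  # of the interface rather than enclosed gaps; flag rows whose contact
  # has collapsed well below the saturated length as detachment-regime
  shrunk <- out$L / max(out$L) < 0.6
  out$detached <- out$detached | shrunk
  out
}

#' @noRd
finish_sweep <- function(out, metric) {
  ok <- out$converged
  if (mean(!ok) > 0.2)
    stop("more than 20% of sweep runs failed to converge")
  out$norm_L <- NA_real_
  out$norm_L[ok] <- out[[metric]][ok] / max(out[[metric]][ok])
  out
}

#' Genotype panel
#'
#' Simulates the four genotype presets and reports interfacial length and
#' angle relative to the wild-type run.
#'
#' @param presets data.frame with `name`, `K_S`, `K_adh` (must contain a
#'   `WT` row); defaults to the four genotypes of [genotype_presets()].
#' @param ... passed to [simulate_condition()].
#' @return data.frame with absolute and WT-relative metrics per genotype.
#' @export
genotype_panel <- function(presets = NULL, ...) {
  if (is.null(presets)) {
    presets <- genotype_presets()
    presets <- presets[presets$name %in% c("WT", "cdh2", "itga5",
                                           "cdh2_itga5"), ]
  }
  if (!"WT" %in% presets$name) stop("presets must include a WT row")
  rows <- lapply(seq_len(nrow(presets)), function(i) {
    st <- simulate_condition(presets$K_S[i], presets$K_adh[i], ...)
    m <- morphometrics(st)
    data.frame(name = presets$name[i], K_S = presets$K_S[i],
               K_adh = presets$K_adh[i],
               L = mean_interface_length(m),
               theta = mean(c(m$theta_L, m$theta_R), na.rm = TRUE), m)
  })
  out <- do.call(rbind, rows)
  wt <- out[out$name == "WT", ]
  out$rel_L <- out$L / wt$L
  out$rel_theta <- out$theta / wt$theta
  out
}

#' Unilateral (contralateral) perturbation experiment
#'
#' Compares a symmetric run against a run in which either the adhesion
#' stiffness of the left PSM|NT interface or the surface stiffness of the
#' left half of the neural tube is reduced. Reports the tension-gradient
#' slope on the *right* (unperturbed) neural-tube side of the interface and
#' the left-right PSM area asymmetry for both runs.
#'
#' @param mode `"left_adhesion"` or `"left_NT_halfsurface"`.
#' @param factor reduction factor in (0, 1]; 1 reproduces the symmetric run.
#' @param K_S,K_adh baseline condition (defaults to the tension-map preset).
#' @param ... passed to [simulate_condition()].
#' @return list with the two states, `slope_right_sym`,
#'   `slope_right_pert`, `dA_sym`, `dA_pert`.
#' @export
asymmetric_perturbation <- function(mode = c("left_adhesion",
                                             "left_NT_halfsurface"),
                                    factor = 0.5, K_S = 200, K_adh = 10,
                                    ...) {
  mode <- match.arg(mode)
  stopifnot(factor > 0, factor <= 1)
  sym <- simulate_condition(K_S, K_adh, ...)
  pert <- switch(mode,
    left_adhesion = simulate_condition(
      K_S, K_adh, kadh_pairs = list("PSM_L|NT" = factor * K_adh), ...),
    left_NT_halfsurface = simulate_condition(
      K_S, K_adh, nt_left_ks_factor = factor, ...)
  )
  right_slope <- function(st) {
    rec <- extract_interface(st, "PSM_R", "NT", st$params)
    tension_profile(rec, tension_field(st, st$params), "NT")$slope
  }
  msym <- morphometrics(sym); mpert <- morphometrics(pert)
  list(symmetric = sym, perturbed = pert, mode = mode, factor = factor,
       slope_right_sym = right_slope(sym),
       slope_right_pert = right_slope(pert),
       dA_sym = msym$dA, dA_pert = mpert$dA)
}
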