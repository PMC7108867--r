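#' Model parameters for the cross-section simulation
#'
#' Bundles all constants of the coarse-grained mechanical model. Forces,
#' lengths and times are in dimensionless model units. The fixed parameters
#' (`l0`, `K_rep`, `c`, `R_rep`, `R_adh`, `P`, `dt`) are kept constant in all
#' experiments; `K_S` (surface stiffness, the proxy for cadherin-dependent
#' tissue surface tension) and `K_adh` (adhesion stiffness, the proxy for
#' integrin-fibronectin inter-tissue adhesion) are the two biological dials.
#'
#' @param K_S surface-spring stiffness (per unit length).
#' @param K_adh inter-tissue adhesion-spring stiffness.
#' @param K_rep inter-tissue repulsion stiffness (volume exclusion).
#' @param P internal pressure, acting outward along surface normals.
#' @param l0 rest length of surface springs.
#' @param R_rep distance below which point pairs of different tissues repel.
#' @param R_adh distance up to which point pairs of different tissues adhere.
#' @param c drag coefficient of the overdamped dynamics (c v = F).
#' @param dt explicit-Euler time step.
#' @param N number of mass points per tissue loop.
#' @return object of class `lj_params` (a validated list).
#' @export
#' @examples
#' p <- model_params(K_S = 100, K_adh = 10)
model_params <- function(K_S = 100, K_adh = 10, K_rep = 30000, P = 5,
                         l0 = 0.1, R_rep = 0.1, R_adh = 0.2, c = 10,
                         dt = 0.001, N = 50) {
  p <- list(K_S = K_S, K_adh = K_adh, K_rep = K_rep, P = P, l0 = l0,
            R_rep = R_rep, R_adh = R_adh, c = c, dt = dt, N = as.integer(N))
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all model parameters must be finite and strictly positive")
  if (p$R_rep >= p$R_adh)
    stop("R_rep must be smaller than R_adh")
  if (p$N < 3)
    stop("N must be at least 3")
  class(p) <- "lj_params"
  p
}

#' @export
print.lj_params <- function(x, ...) {
  cat("Cross-section model parameters:\n")
  cat(sprintf("  K_S = %g, K_adh = %g, K_rep = %g, P = %g\n",
              x$K_S, x$K_adh, x$K_rep, x$P))
  cat(sprintf("  l0 = %g, R_rep = %g, R_adh = %g, c = %g, dt = %g, N = %d\n",
              x$l0, x$R_rep, x$R_adh, x$c, x$dt, x$N))
  invisible(x)
}

#' Genotype parameter presets
#'
#' The (K_S, K_adh) pairs used to mimic wild-type and mutant embryos, the
#' exploratory corner points, and the high-stiffness preset used for
#' tension-map figures. The double mutant combines the surface stiffness of
#' the cadherin mutant with the adhesion stiffness of the integrin mutant.
#'
#' @return data.frame with columns `name`, `K_S`, `K_adh`.
#' @export
genotype_presets <- function() {
  data.frame(
    name  = c("WT", "cdh2", "itga5", "cdh2_itga5",
              "explore_lowadh", "explore_highadh",
              "explore_lowKs", "explore_highKs", "tension_map"),
    K_S   = c(100, 55, 100, 55, 50, 50, 35, 100, 200),
    K_adh = c(10, 12, 6.5, 6.5, 4, 12, 8, 8, 10),
    stringsAsFactors = FALSE
  )
}

#' Closed-form equilibrium spring length of an isolated tissue
#'
#' For an isolated pressurized loop relaxing to a regular N-gon, force
#' balance between spring tension and pressure gives the equilibrium spring
#' length `l* = l0 (1 + (P / (2 K_S)) cot(pi / N))`. Used as an analytic
#' oracle for the dynamics.
#'
#' @param params `lj_params`.
#' @return equilibrium spring length (model units).
#' @export
polygon_equilibrium_length <- function(params) {
  params$l0 * (1 + (params$P / (2 * params$K_S)) / tan(pi / params$N))
}
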