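#' Intra-tissue forces on one loop
#'
#' Net surface-spring and pressure force on each mass point of a closed
#' loop: `F_i = T_i - T_{i+1} + (P l0 / 2)(n_i + n_{i+1})`, where the
#' tension along a spring of current length `l` is `K_S (l - l0)` directed
#' along the spring, and `n` are outward unit normals of the two edges
#' adjacent to the point (counterclockwise orientation assumed).
#'
#' This is the plain-R reference implementation; the simulation engine
#' evaluates the identical law in compiled code.
#'
#' @param pos N x 2 matrix of loop points, counterclockwise.
#' @param params `lj_params`.
#' @param ks optional per-spring stiffness vector (spring `i` connects point
#'   `i` to `i+1`); defaults to `params$K_S`.
#' @return N x 2 matrix of force vectors.
#' @export
tissue_forces <- function(pos, params, ks = NULL) {
  n <- nrow(pos)
  if (is.null(ks)) ks <- rep(params$K_S, n)
  nxt <- c(2:n, 1)
  e <- pos[nxt, , drop = FALSE] - pos     # edge i: point i -> i+1
  l <- sqrt(rowSums(e^2))
  if (any(l <= 0)) stop("degenerate spring (zero length)")
  hhat <- e / l
  tension <- ks * (l - l0_of(params))     # signed magnitude along hhat
  Tv <- hhat * tension                    # vector tension of spring i
  prv <- c(n, 1:(n - 1))
  # force on point i: spring i pulls toward i+1, spring i-1 pulls toward i-1
  f <- Tv - Tv[prv, , drop = FALSE]
  nrm <- cbind(hhat[, 2], -hhat[, 1])     # outward normal of CCW edge
  f + (params$P * params$l0 / 2) * (nrm + nrm[prv, , drop = FALSE])
}

#' @noRd
l0_of <- function(params) params$l0

#' Piecewise inter-tissue interaction force
#'
#' Force on point i exerted by point j of a different tissue (or the yolk),
#' as a function of the separation vector r_ij = x_i - x_j: repulsive
#' K_rep (R_rep - r) rhat below R_rep, adhesive -K_adh (r - R_rep) rhat
#' between R_rep and R_adh, zero beyond R_adh. Both branches vanish at
#' r = R_rep, making the law continuous there.
#'
#' @param rij separation vector (length-2) or n x 2 matrix of separations.
#' @param params `lj_params`.
#' @param K_adh adhesion stiffness override (pair-specific perturbations).
#' @return force vector(s) on point i, same shape as `rij`.
#' @export
interaction_force <- function(rij, params, K_adh = params$K_adh) {
  v <- if (is.matrix(rij)) rij else matrix(rij, ncol = 2)
  r <- sqrt(rowSums(v^2))
  if (any(r == 0)) stop("zero separation: interaction direction undefined")
  mag <- numeric(length(r))
  rep_i <- r < params$R_rep
  adh_i <- !rep_i & r <= params$R_adh
  mag[rep_i] <- params$K_rep * (params$R_rep - r[rep_i])
  mag[adh_i] <- -K_adh * (r[adh_i] - params$R_rep)
  out <- v * (mag / r)
  if (is.matrix(rij)) out else drop(out)
}
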