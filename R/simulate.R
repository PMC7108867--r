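#' Net forces on every point of a cross-section
#'
#' Sum of intra-tissue (spring + pressure) and inter-tissue (piecewise
#' repulsion/adhesion) forces, evaluated by the compiled engine. Yolk points
#' exert forces but never move.
#'
#' @param cs `lj_cross_section`.
#' @param params `lj_params`.
#' @return matrix (total points x 2), tissues first then yolk.
#' @export
net_forces <- function(cs, params) {
  pk <- pack_state(cs, params)
  lj_net_forces(pk$pos, pk$grp, pk$start, pk$len, pk$ks, pk$kadh,
                unclass(params))
}

#' Advance the cross-section by explicit-Euler steps
#'
#' Overdamped update `x <- x + (dt / c) F` applied to every mobile point.
#'
#' @param state an `lj_state` (or an `lj_cross_section`, which is promoted
#'   to a fresh state).
#' @param params `lj_params`.
#' @param n_steps number of Euler steps to take.
#' @return updated `lj_state`.
#' @export
step <- function(state, params, n_steps = 1) {
  state <- as_lj_state(state, params)
  pk <- pack_state(state$cross_section, params)
  res <- lj_run(pk$pos, pk$grp, pk$start, pk$len, pk$ks, pk$kadh,
                unclass(params), pk$mobile,
                tol = 0, max_steps = n_steps,
                window = n_steps, check_every = max(1L, as.integer(n_steps)))
  state$cross_section <- unpack_state(state$cross_section, pk, res$pos)
  state$step_count <- state$step_count + res$steps
  state$max_residual_force <- res$resid_inst
  state$converged <- FALSE
  state
}

#' @noRd
as_lj_state <- function(x, params) {
  if (inherits(x, "lj_state")) return(x)
  if (!inherits(x, "lj_cross_section"))
    stop("expected an lj_state or lj_cross_section")
  structure(list(cross_section = x, params = params, step_count = 0,
                 converged = FALSE, max_residual_force = Inf),
            class = "lj_state")
}

#' @export
print.lj_state <- function(x, ...) {
  cat(sprintf("Simulation state: %d steps, converged = %s, residual = %.3g\n",
              as.integer(x$step_count), x$converged, x$max_residual_force))
  invisible(x)
}

#' Relax a cross-section to steady state
#'
#' Integrates the overdamped dynamics until the residual force drops below
#' `tol` or `max_steps` is reached. Because the stiff repulsion springs give
#' the explicit scheme a small-amplitude limit cycle at pressed contacts,
#' the convergence criterion uses the window-averaged force
#' `c * max_i |mean velocity over the last window steps|`, which measures
#' true drift rather than contact jitter; the instantaneous maximal net
#' force is also recorded. Divergence (a tenfold residual increase at large
#' amplitude) aborts with a diagnostic.
#'
#' @param cross_section `lj_cross_section` (or an existing state to resume).
#' @param params `lj_params`.
#' @param tol residual-force tolerance (model force units).
#' @param max_steps step budget.
#' @param window number of steps over which the residual is averaged;
#'   defaults to 20 time units worth of steps.
#' @param freeze_tissues names of tissues held immobile during this run
#'   (used by staged settling protocols).
#' @return `lj_state` with `converged` and `max_residual_force` filled in.
#' @export
#' @examples
#' \donttest{
#' p <- model_params()
#' st <- run_to_steady_state(build_cross_section(canonical_layout(), p), p)
#' }
run_to_steady_state <- function(cross_section, params, tol = 1e-4,
                                max_steps = 2e6, window = NULL,
                                freeze_tissues = character(0)) {
  stopifnot(tol > 0, max_steps >= 1)
  if (is.null(window)) window <- max(1000L, as.integer(round(20 / params$dt)))
  state <- as_lj_state(cross_section, params)
  pk <- pack_state(state$cross_section, params)
  if (length(freeze_tissues)) {
    idx <- match(freeze_tissues, pk$names)
    if (anyNA(idx)) stop("unknown tissue in freeze_tissues")
    pk$mobile[pk$grp %in% (idx - 1L)] <- FALSE
  }
  res <- lj_run(pk$pos, pk$grp, pk$start, pk$len, pk$ks, pk$kadh,
                unclass(params), pk$mobile,
                tol = tol, max_steps = max_steps,
                window = as.integer(window), check_every = 50L)
  state$cross_section <- unpack_state(state$cross_section, pk, res$pos)
  state$step_count <- state$step_count + res$steps
  state$converged <- res$converged
  state$max_residual_force <- res$resid_window
  state$resid_inst <- res$resid_inst
  state
}

#' Per-spring tension field
#'
#' Signed tension `K_S (l_i - l0)` of every surface spring together with the
#' spring midpoint, per tissue. Uses per-spring stiffness overrides where
#' present (asymmetric perturbations).
#'
#' @param state `lj_state`.
#' @param params `lj_params`.
#' @return data.frame with columns `tissue`, `spring`, `mx`, `my`, `tension`.
#' @export
tension_field <- function(state, params) {
  cs <- state$cross_section
  out <- lapply(names(cs$tissues), function(nm) {
    t <- cs$tissues[[nm]]
    n <- nrow(t$pos)
    nxt <- c(2:n, 1)
    e <- t$pos[nxt, , drop = FALSE] - t$pos
    l <- sqrt(rowSums(e^2))
    mid <- (t$pos + t$pos[nxt, , drop = FALSE]) / 2
    data.frame(tissue = nm, spring = seq_len(n),
               mx = mid[, 1], my = mid[, 2],
               tension = t$ks * (l - params$l0))
  })
  do.call(rbind, out)
}
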