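# Constructed tissue states for morphometric unit tests.

square_loop <- function(x0, y0, side, spacing = 0.1) {
  n_side <- round(side / spacing)
  s <- seq(0, side, length.out = n_side + 1)[-(n_side + 1)]
  p <- rbind(
    cbind(x0 + s, y0),              # bottom, left -> right
    cbind(x0 + side, y0 + s),       # right, up
    cbind(x0 + side - s, y0 + side),# top, right -> left
    cbind(x0, y0 + side - s)        # left, down
  )
  p  # counterclockwise
}

make_state <- function(loops, params = model_params(),
                       yolk = cbind(1000, 0)) {
  cs <- structure(list(
    tissues = lapply(loops, function(p) list(pos = p,
                                             ks = rep(params$K_S, nrow(p)))),
    yolk = yolk, kadh_pairs = list()), class = "lj_cross_section")
  st <- structure(list(cross_section = cs, params = params, step_count = 0,
                       converged = TRUE, max_residual_force = 0),
                  class = "lj_state")
  st
}

single_loop_cs <- function(pos, params) {
  structure(list(
    tissues = list(NT = list(pos = pos, ks = rep(params$K_S, nrow(pos)))),
    yolk = cbind(1000, 0), kadh_pairs = list()),
    class = "lj_cross_section")
}

regular_polygon <- function(n, radius, center = c(0, 0)) {
  th <- 2 * pi * seq(0, n - 1) / n - pi / 2
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
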