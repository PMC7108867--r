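#' @noRd
resample_closed <- function(path, n) {
  # resample a dense closed polyline to n points at equal arclength
  d <- sqrt(rowSums((path - path[c(2:nrow(path), 1), ])^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  closed <- rbind(path, path[1, ])
  x <- stats::approx(s, closed[, 1], xout = target)$y
  y <- stats::approx(s, closed[, 2], xout = target)$y
  cbind(x, y)
}

#' @noRd
circle_points <- function(center, radius, n, start_angle = -pi / 2) {
  th <- start_angle + 2 * pi * seq(0, n - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' @noRd
rounded_rect_points <- function(center, width, height, n, corner_frac = 0.35) {
  # dense CCW outline of an axis-aligned rounded rectangle, resampled;
  # starts at the bottom to keep the sampling mirror symmetric about x=center
  rc <- corner_frac * min(width, height) / 2
  hw <- width / 2 - rc
  hh <- height / 2 - rc
  arc <- function(cx, cy, a0, a1) {
    th <- seq(a0, a1, length.out = 24)
    cbind(cx + rc * cos(th), cy + rc * sin(th))
  }
  seg <- function(x0, y0, x1, y1) {
    t <- seq(0, 1, length.out = 24)[-1]
    cbind(x0 + t * (x1 - x0), y0 + t * (y1 - y0))
  }
  p <- rbind(
    cbind(0, -height / 2),
    seg(0, -height / 2, hw, -height / 2),
    arc(hw, -hh, -pi / 2, 0),
    seg(width / 2, -hh, width / 2, hh),
    arc(hw, hh, 0, pi / 2),
    seg(hw, height / 2, -hw, height / 2),
    arc(-hw, hh, pi / 2, pi),
    seg(-width / 2, hh, -width / 2, -hh),
    arc(-hw, -hh, pi, 3 * pi / 2),
    seg(-hw, -height / 2, 0, -height / 2)
  )
  p <- p[!duplicated(round(p, 12)), , drop = FALSE]
  q <- resample_closed(p, n)
  cbind(q[, 1] + center[1], q[, 2] + center[2])
}

#' @noRd
polygon_is_simple <- function(p) {
  n <- nrow(p)
  seg_int <- function(a, b, c, d) {
    o <- function(p1, p2, p3)
      sign((p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
    (o1 != o2) && (o3 != o4)
  }
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(p[idx[i, 1], ], p[idx[i, 2], ], p[idx[j, 1], ], p[idx[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' @noRd
ensure_ccw <- function(p) {
  a <- sum(p[, 1] * p[c(2:nrow(p), 1), 2] - p[c(2:nrow(p), 1), 1] * p[, 2]) / 2
  if (a < 0) p[c(1, nrow(p):2), , drop = FALSE] else p
}

#' Canonical cross-section layout
#'
#' Geometry of the initial condition, mimicking a transverse section of the
#' posterior trunk: the neural tube (NT) as a tall rounded rectangle at the
#' dorsal midline, the notochord (NC) beneath it, the left and right
#' presomitic mesoderm (PSM) flanking both, and a rigid horizontal yolk
#' surface below. Distances are in model units (the surface-spring rest
#' length is 0.1). The free dimensions were calibrated once against the
#' wild-type shape anchors and then frozen for all genotypes; see the
#' methods vignette.
#'
#' @param nt_width,nt_height NT rounded-rectangle dimensions.
#' @param nc_radius initial notochord radius.
#' @param psm_radius initial PSM radius.
#' @param gap initial clearance between adjacent tissues (kept within the
#'   adhesion range so interfaces engage at t = 0).
#' @param yolk_gap initial clearance between ventral tissue and yolk.
#' @param yolk_halfwidth half-extent of the yolk chain.
#' @param yolk_spacing spacing of yolk points (at most `R_rep` so tissues
#'   cannot slip between them).
#' @param psm_x optional explicit PSM center offset from the midline;
#'   `NULL` places the PSMs adjacent to the notochord.
#' @param nt_y optional explicit NT center height; `NULL` stacks the NT
#'   directly above the notochord.
#' @param scale overall scale factor applied to every dimension.
#' @return a list describing the layout, to pass to [build_cross_section()].
#' @export
canonical_layout <- function(nt_width = 1.15, nt_height = 2.1,
                             nc_radius = 0.48, psm_radius = 0.80,
                             gap = 0.16, yolk_gap = 0.15,
                             yolk_halfwidth = 4.5, yolk_spacing = 0.05,
                             psm_x = NULL, nt_y = NULL, scale = 1) {
  l <- list(nt_width = nt_width, nt_height = nt_height,
            nc_radius = nc_radius, psm_radius = psm_radius,
            gap = gap, yolk_gap = yolk_gap,
            yolk_halfwidth = yolk_halfwidth, yolk_spacing = yolk_spacing)
  l <- lapply(l, function(v) v * scale)
  if (!is.null(psm_x)) l$psm_x <- psm_x * scale
  if (!is.null(nt_y)) l$nt_y <- nt_y * scale
  l
}

#' Build the initial cross-section
#'
#' Discretizes the four tissue loops to `params$N` points each (counter-
#' clockwise, mirror-symmetric about the vertical midline) and the fixed
#' yolk chain, then validates the geometry: every loop must be simple and
#' no inter-tissue point pair may start closer than `R_rep`.
#'
#' @param layout a layout list from [canonical_layout()].
#' @param params `lj_params` from [model_params()].
#' @param jitter half-width of uniform positional noise added to every
#'   initial tissue point (0 disables; the default). Used to break exact
#'   mirror symmetry and probe basin robustness.
#' @param jitter_seed seed controlling the jitter (reproducible).
#' @param prestretch if `TRUE`, tissue dimensions are scaled by
#'   `l*(K_S) / l0` (the isolated-loop equilibrium stretch) so that loops
#'   start near their mechanical size and relaxation probes shape rather
#'   than inflation; initial clearances are kept as drawn so every intended
#'   interface starts inside the adhesion range.
#' @return object of class `lj_cross_section`: a named list of tissues
#'   (`NT`, `PSM_L`, `PSM_R`, `NC`), each with a `pos` matrix and per-spring
#'   stiffness `ks`, plus the `yolk` point matrix.
#' @export
#' @examples
#' cs <- build_cross_section(canonical_layout(), model_params())
build_cross_section <- function(layout = canonical_layout(),
                                params = model_params(),
                                prestretch = FALSE,
                                jitter = 0, jitter_seed = 1) {
  N <- params$N
  if (prestretch) {
    s <- polygon_equilibrium_length(params) / params$l0
    for (f in c("nt_width", "nt_height", "nc_radius", "psm_radius",
                "psm_x", "nt_y", "yolk_halfwidth"))
      if (!is.null(layout[[f]])) layout[[f]] <- layout[[f]] * s
  }
  g <- layout$gap
  nc_c <- c(0, layout$yolk_gap + layout$nc_radius)
  psm_y <- layout$yolk_gap + layout$psm_radius
  psm_x <- if (!is.null(layout$psm_x)) layout$psm_x else
    layout$nc_radius + g + layout$psm_radius
  nc <- circle_points(nc_c, layout$nc_radius, N)
  psm_r <- circle_points(c(psm_x, psm_y), layout$psm_radius, N)
  nt_at <- function(y) rounded_rect_points(c(0, y), layout$nt_width,
                                           layout$nt_height, N)
  nt_c_y <- if (!is.null(layout$nt_y)) layout$nt_y else {
    # stack the NT a gap above the notochord; if that would overlap the
    # PSMs, raise it until every clearance reaches the layout gap
    stack <- nc_c[2] + layout$nc_radius + g + layout$nt_height / 2
    if (min(cross_dist(nt_at(stack), psm_r)) >= params$R_rep) stack else {
      clear <- function(y) {
        p <- nt_at(y)
        min(min(cross_dist(p, nc)), min(cross_dist(p, psm_r))) - g
      }
      hi <- psm_y + layout$psm_radius + layout$nt_height / 2 + g + 0.5
      stats::uniroot(clear, c(stack - layout$nt_height, hi))$root
    }
  }
  tissues <- list(
    NT = nt_at(nt_c_y),
    PSM_L = circle_points(c(-psm_x, psm_y), layout$psm_radius, N),
    PSM_R = psm_r,
    NC = nc
  )
  tissues <- lapply(tissues, ensure_ccw)
  if (jitter > 0) {
    # seed-controlled symmetry-breaking noise on the initial points,
    # used to probe basin sensitivity (off by default: jitter = 0)
    rng <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    set.seed(as.integer(jitter_seed))
    tissues <- lapply(tissues, function(p)
      p + matrix(runif(2 * nrow(p), -jitter, jitter), nrow(p), 2))
    if (!is.null(rng)) assign(".Random.seed", rng, globalenv())
  }
  for (nm in names(tissues)) {
    if (!polygon_is_simple(tissues[[nm]]))
      stop("initial loop for ", nm, " is self-intersecting")
  }
  nms <- names(tissues)
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      dmin <- min(cross_dist(tissues[[i]], tissues[[j]]))
      if (dmin < params$R_rep)
        stop(sprintf("initial loops %s and %s overlap (min distance %.3f < R_rep)",
                     nms[i], nms[j], dmin))
    }
  }
  yx <- seq(-layout$yolk_halfwidth, layout$yolk_halfwidth,
            by = layout$yolk_spacing)
  yolk <- cbind(yx, rep(0, length(yx)))
  cs <- list(
    tissues = lapply(tissues, function(p)
      list(pos = p, ks = rep(params$K_S, nrow(p)))),
    yolk = yolk,
    kadh_pairs = list()
  )
  class(cs) <- "lj_cross_section"
  cs
}

#' @noRd
cross_dist <- function(a, b) {
  # full distance matrix between two point sets (small n)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

#' @export
print.lj_cross_section <- function(x, ...) {
  cat("Cross-section with tissues:",
      paste(sprintf("%s (%d pts)", names(x$tissues),
                    vapply(x$tissues, function(t) nrow(t$pos), 1L)),
            collapse = ", "),
      sprintf("; yolk %d pts\n", nrow(x$yolk)))
  invisible(x)
}

#' @noRd
pack_state <- function(cs, params) {
  # flatten a cross-section into the engine arrays
  nm <- names(cs$tissues)
  G <- length(nm)
  lens <- vapply(cs$tissues, function(t) nrow(t$pos), 1L)
  start <- cumsum(c(0L, lens[-G]))
  pos <- do.call(rbind, c(lapply(cs$tissues, function(t) t$pos),
                          list(cs$yolk)))
  grp <- rep(seq(0L, G), times = c(lens, nrow(cs$yolk)))
  ks <- unlist(lapply(cs$tissues, function(t) t$ks), use.names = FALSE)
  kadh <- matrix(params$K_adh, G + 1, G + 1)
  rownames(kadh) <- colnames(kadh) <- c(nm, "yolk")
  for (key in names(cs$kadh_pairs)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(ab) != 2 || !all(ab %in% rownames(kadh)))
      stop("bad kadh_pairs key: ", key)
    kadh[ab[1], ab[2]] <- kadh[ab[2], ab[1]] <- cs$kadh_pairs[[key]]
  }
  list(pos = pos, grp = grp, start = start, len = lens, ks = ks,
       kadh = kadh, mobile = grp < G, names = nm)
}

#' @noRd
unpack_state <- function(cs, packed, pos) {
  out <- cs
  for (i in seq_along(cs$tissues)) {
    idx <- (packed$start[i] + 1):(packed$start[i] + packed$len[i])
    out$tissues[[i]]$pos <- pos[idx, , drop = FALSE]
  }
  out
}
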