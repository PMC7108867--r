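#' Extract the contact interface between two tissues
#'
#' Walks the surface loop of `tissueA` and finds the maximal consecutive run
#' of points whose nearest `tissueB` point (or yolk point) lies within
#' `range`. Out-of-range runs enclosed in the span are recorded as
#' detachment gaps. The default `range` is the model's own adhesion range,
#' so a "gap" is exactly a stretch of surface outside adhesive reach.
#'
#' @param state `lj_state`.
#' @param tissueA,tissueB tissue names (`tissueB` may be `"yolk"`).
#' @param range contact distance threshold.
#' @param params `lj_params` (used for the default range).
#' @return object of class `lj_interface`: indices along the source loop,
#'   point coordinates, in-range flags, gap index runs and a
#'   `full_detachment` flag.
#' @export
extract_interface <- function(state, tissueA, tissueB,
                              params = state$params,
                              range = params$R_adh) {
  cs <- state$cross_section
  a <- cs$tissues[[tissueA]]$pos
  b <- if (identical(tissueB, "yolk")) cs$yolk else cs$tissues[[tissueB]]$pos
  if (is.null(a) || is.null(b)) stop("unknown tissue name")
  nearest <- apply(cross_dist(a, b), 1, min)
  in_range <- nearest <= range
  rec <- list(tissue = tissueA, partner = tissueB, range = range,
              indices = integer(0), points = a[0, , drop = FALSE],
              in_range = logical(0), gaps = list(),
              full_detachment = !any(in_range), loop = a)
  class(rec) <- "lj_interface"
  if (rec$full_detachment) return(rec)
  n <- length(in_range)
  if (all(in_range)) {
    rec$indices <- seq_len(n)
  } else {
    # rotate so index 1 sits inside the longest out-of-range run
    r <- rle(rep(in_range, 2))
    ends <- cumsum(r$lengths)
    pick <- which(!r$values)[which.max(r$lengths[!r$values])]
    rot <- ends[pick] %% n  # first element after that run becomes index 1
    idx <- ((seq_len(n) + rot - 1) %% n) + 1
    flags <- in_range[idx]
    span <- range(which(flags))
    rec$indices <- idx[span[1]:span[2]]
    inner <- flags[span[1]:span[2]]
    rr <- rle(inner)
    pos <- cumsum(c(1, rr$lengths))
    for (k in which(!rr$values)) {
      rec$gaps <- c(rec$gaps,
                    list(rec$indices[pos[k]:(pos[k + 1] - 1)]))
    }
  }
  rec$points <- a[rec$indices, , drop = FALSE]
  rec$in_range <- in_range[rec$indices]
  rec
}

#' @export
print.lj_interface <- function(x, ...) {
  cat(sprintf("Interface %s|%s: %d points, %d gap(s)%s\n",
              x$tissue, x$partner, length(x$indices), length(x$gaps),
              if (x$full_detachment) " [fully detached]" else ""))
  invisible(x)
}

#' Interfacial length
#'
#' Length of the interface polyline: the sum of consecutive point distances
#' along the extracted interface span (the in-silico analogue of a
#' segmented-line measurement).
#'
#' @param rec `lj_interface`.
#' @return length in model units.
#' @export
interfacial_length <- function(rec) {
  p <- rec$points
  if (nrow(p) < 2) stop("interface has fewer than 2 points")
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Interfacial angle at the lateral edge
#'
#' The angle formed between the PSM|NT interface and the PSM surface
#' continuing laterally past it, evaluated at the lateral end of the
#' interface: the angle at the end point between a chord through the last
#' `k` interface points and a chord through the first `k` points of the
#' continuing free surface.
#'
#' @param state `lj_state`.
#' @param side `"L"` or `"R"`.
#' @param k chord length in points.
#' @param params `lj_params`.
#' @return angle in degrees.
#' @export
interfacial_angle <- function(state, side = c("L", "R"), k = 3,
                              params = state$params) {
  side <- match.arg(side)
  psm <- paste0("PSM_", side)
  rec <- extract_interface(state, psm, "NT", params)
  if (length(rec$indices) <= k) stop("interface shorter than k points")
  loop <- rec$loop
  n <- nrow(loop)
  ends <- c(1L, length(rec$indices))
  lat <- ends[which.max(abs(rec$points[ends, 1]))]
  corner_idx <- rec$indices[lat]
  dir <- if (lat == 1L) -1L else 1L  # loop direction of the continuation
  back <- rec$indices[lat - dir * k] # k points back into the interface
  fwd <- ((corner_idx - 1 + dir * k) %% n) + 1  # k points past the end
  a <- loop[corner_idx, ]
  u <- loop[back, ] - a
  v <- loop[fwd, ] - a
  ang <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  ang * 180 / pi
}

#' Axis-aligned bounding extents of a closed outline
#'
#' @param outline n x 2 matrix (medial-lateral along x, dorsal-ventral
#'   along y).
#' @return named vector `c(ML = width, DV = height)`.
#' @export
bounding_extents <- function(outline) {
  if (nrow(outline) < 3) stop("outline needs at least 3 vertices")
  c(ML = diff(range(outline[, 1])), DV = diff(range(outline[, 2])))
}

#' Shoelace area of a simple polygon
#'
#' @param outline n x 2 matrix of vertices (either orientation).
#' @return area (non-negative).
#' @export
polygon_area <- function(outline) {
  if (nrow(outline) < 3) stop("polygon needs at least 3 vertices")
  if (!polygon_is_simple(outline)) stop("polygon is self-intersecting")
  nxt <- c(2:nrow(outline), 1)
  abs(sum(outline[, 1] * outline[nxt, 2] -
          outline[nxt, 1] * outline[, 2])) / 2
}

#' @noRd
shoelace_area <- function(outline) {
  # tolerant variant used on raw simulated loops, whose strongly compressed
  # surfaces (notochord in a tight cage) can carry microscopic wrinkles
  nxt <- c(2:nrow(outline), 1)
  abs(sum(outline[, 1] * outline[nxt, 2] -
          outline[nxt, 1] * outline[, 2])) / 2
}

#' Left-right area asymmetry
#'
#' @param area_L,area_R tissue cross-sectional areas.
#' @return `|area_L - area_R|`.
#' @export
lr_asymmetry <- function(area_L, area_R) abs(area_L - area_R)

#' Tension profile along an interface
#'
#' Restricts a [tension_field()] to the springs of one side of an interface
#' (the neural-tube side or the PSM side), ordered medial to lateral by
#' horizontal distance from the midline, and fits a least-squares slope.
#'
#' @param rec `lj_interface` (a PSM|NT interface).
#' @param field data.frame from [tension_field()].
#' @param side_of `"NT"` or `"PSM"`: whose surface springs to read.
#' @param max_dist springs whose midpoints lie farther than this from the
#'   interface polyline are excluded.
#' @return list with `profile` (data.frame `position`, `mx`, `my`,
#'   `tension`, medial to lateral) and `slope` (tension per unit
#'   medial-lateral distance).
#' @export
tension_profile <- function(rec, field, side_of = c("NT", "PSM"),
                            max_dist = 0.3) {
  side_of <- match.arg(side_of)
  tiss <- if (side_of == "NT") "NT" else rec$tissue
  f <- field[field$tissue == tiss, , drop = FALSE]
  if (nrow(rec$points) == 0) stop("empty interface")
  d <- apply(cross_dist(cbind(f$mx, f$my), rec$points), 1, min)
  f <- f[d <= max_dist, , drop = FALSE]
  if (nrow(f) == 0) stop("no springs project onto the interface span")
  f$position <- abs(f$mx)
  f <- f[order(f$position), , drop = FALSE]
  slope <- if (nrow(f) >= 2)
    unname(coef(lm(tension ~ position, data = f))[2]) else NA_real_
  list(profile = f[, c("position", "mx", "my", "tension")], slope = slope)
}

#' Free (uncontacted) surface of a tissue
#'
#' The maximal consecutive run of a tissue's surface points that lie beyond
#' `range` of every other tissue and the yolk. For the PSM this is the
#' lateral surface facing the epidermis, i.e. the model's PSM|E interface.
#'
#' @inheritParams extract_interface
#' @param tissue tissue name.
#' @return `lj_interface` with partner `"free"`.
#' @export
free_surface <- function(state, tissue, params = state$params,
                         range = params$R_adh) {
  cs <- state$cross_section
  a <- cs$tissues[[tissue]]$pos
  others <- c(lapply(cs$tissues[setdiff(names(cs$tissues), tissue)],
                     function(t) t$pos),
              list(cs$yolk))
  nearest <- do.call(pmin, lapply(others, function(b)
    apply(cross_dist(a, b), 1, min)))
  free <- nearest > range
  rec <- list(tissue = tissue, partner = "free", range = range,
              indices = integer(0), points = a[0, , drop = FALSE],
              in_range = logical(0), gaps = list(),
              full_detachment = !any(free), loop = a)
  class(rec) <- "lj_interface"
  if (!any(free)) return(rec)
  n <- length(free)
  if (all(free)) {
    rec$indices <- seq_len(n)
  } else {
    r <- rle(rep(!free, 2))
    ends <- cumsum(r$lengths)
    pick <- which(r$values)[which.max(r$lengths[r$values])]
    rot <- ends[pick] %% n
    idx <- ((seq_len(n) + rot - 1) %% n) + 1
    flags <- free[idx]
    span <- range(which(flags))
    rec$indices <- idx[span[1]:span[2]]
  }
  rec$points <- a[rec$indices, , drop = FALSE]
  rec$in_range <- free[rec$indices]
  rec
}

#' Radius of curvature of an interface
#'
#' Pratt circle fit through the interface points; see [pratt_circle_fit()].
#'
#' @param rec `lj_interface`.
#' @return fitted radius (model units).
#' @export
interface_curvature <- function(rec) {
  pratt_circle_fit(rec$points)$radius
}

#' Full morphometric summary of a steady state
#'
#' One call computing the standard shape metrics: per-side interfacial
#' length and angle, NT bounding extents, per-tissue areas, left-right PSM
#' area asymmetry, detachment gap counts and interface curvature radii.
#'
#' @param state `lj_state`.
#' @param params `lj_params`.
#' @return a one-row data.frame.
#' @export
morphometrics <- function(state, params = state$params) {
  cs <- state$cross_section
  recL <- extract_interface(state, "PSM_L", "NT", params)
  recR <- extract_interface(state, "PSM_R", "NT", params)
  ext <- bounding_extents(cs$tissues$NT$pos)
  areas <- vapply(cs$tissues, function(t) shoelace_area(t$pos), 1.0)
  ang <- function(side) tryCatch(interfacial_angle(state, side, params = params),
                                 error = function(e) NA_real_)
  ilen <- function(r) if (nrow(r$points) >= 2) interfacial_length(r) else 0
  curv <- function(r) tryCatch(interface_curvature(r),
                               error = function(e) NA_real_)
  freeL <- free_surface(state, "PSM_L", params)
  freeR <- free_surface(state, "PSM_R", params)
  data.frame(
    L_psm_nt_L = ilen(recL), L_psm_nt_R = ilen(recR),
    theta_L = ang("L"), theta_R = ang("R"),
    nt_ml = unname(ext["ML"]), nt_dv = unname(ext["DV"]),
    area_NT = unname(areas["NT"]), area_PSM_L = unname(areas["PSM_L"]),
    area_PSM_R = unname(areas["PSM_R"]), area_NC = unname(areas["NC"]),
    dA = lr_asymmetry(areas[["PSM_L"]], areas[["PSM_R"]]),
    gaps_L = length(recL$gaps), gaps_R = length(recR$gaps),
    detached_L = recL$full_detachment, detached_R = recR$full_detachment,
    curv_psm_nt_L = curv(recL), curv_psm_nt_R = curv(recR),
    curv_psm_e_L = curv(freeL), curv_psm_e_R = curv(freeR),
    converged = state$converged
  )
}
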