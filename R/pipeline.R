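#' Default pipeline configuration
#'
#' Nested list controlling the end-to-end pipeline; amenable to JSON
#' round-tripping. `scale = "desk"` uses the full grids of the in-silico
#' campaigns; `scale = "smoke"` shrinks every stage for fast smoke tests.
#'
#' @param scale `"desk"` or `"smoke"`.
#' @return configuration list.
#' @export
default_config <- function(scale = c("desk", "smoke")) {
  scale <- match.arg(scale)
  smoke <- scale == "smoke"
  list(
    scale = scale,
    seed = 1,
    simulate = list(K_S = 100, K_adh = 10, max_steps = 4e6),
    sweep = list(
      ks_grid = if (smoke) c(100, 140, 170, 200) else
        c(35, 50, 70, 100, 140, 200),
      kadh_grid = if (smoke) c(8, 12) else c(4, 5, 6.5, 8, 10, 12),
      ks_fixed = if (smoke) 100 else c(55, 100), kadh_fixed = 10
    ),
    genotypes = list(subset = if (smoke) c("WT", "itga5") else NULL),
    perturb = list(adhesion_factor = 0.75, nt_ks_factor = 0.25),
    synth = list(
      matrix = list(width_um = if (smoke) 60 else 300,
                    height_um = if (smoke) 30 else 60,
                    n_small = if (smoke) 8 else 60,
                    n_large = if (smoke) 1 else 6,
                    ml_gradient_slope = 1),
      spots = list(ml_shrink_fraction = 0.4, n_frames = if (smoke) 3 else 5,
                   bleach_per_frame = 0.95),
      circle = list(radius = 100, n = 30, noise_sd = 0.5),
      ratio = list(nr = if (smoke) 80 else 200,
                   nc = if (smoke) 160 else 400,
                   saturation_fraction = 0.005)
    )
  )
}

#' Read a JSON pipeline configuration
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path JSON file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(if (!is.null(user$scale)) user$scale else "desk")
  modifyList(base, user)
}

#' Write steady-state point coordinates as CSV
#'
#' One row per point: `tissue`, `index`, `x`, `y` (yolk included with
#' tissue `"yolk"`).
#'
#' @param state `lj_state`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_state_csv <- function(state, path) {
  cs <- state$cross_section
  rows <- lapply(names(cs$tissues), function(nm) {
    p <- cs$tissues[[nm]]$pos
    data.frame(tissue = nm, index = seq_len(nrow(p)), x = p[, 1], y = p[, 2])
  })
  rows <- c(rows, list(data.frame(tissue = "yolk",
                                  index = seq_len(nrow(cs$yolk)),
                                  x = cs$yolk[, 1], y = cs$yolk[, 2])))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a steady-state CSV back into a cross-section
#'
#' @param path CSV written by [write_state_csv()].
#' @param params `lj_params` (for per-spring stiffness defaults).
#' @return `lj_state`.
#' @export
read_state_csv <- function(path, params = model_params()) {
  df <- read.csv(path)
  nms <- setdiff(unique(df$tissue), "yolk")
  tissues <- lapply(nms, function(nm) {
    d <- df[df$tissue == nm, ]
    d <- d[order(d$index), ]
    list(pos = cbind(d$x, d$y), ks = rep(params$K_S, nrow(d)))
  })
  names(tissues) <- nms
  yd <- df[df$tissue == "yolk", ]
  cs <- structure(list(tissues = tissues,
                       yolk = cbind(yd$x, yd$y)[order(yd$index), ],
                       kadh_pairs = list()),
                  class = "lj_cross_section")
  st <- as_lj_state(cs, params)
  st$params <- params
  st
}

#' Run the full in-silico and synthetic-imaging pipeline
#'
#' Executes simulate, measure, both sweeps, the genotype panel, the two
#' unilateral perturbations, then synthetic-image generation and every
#' image quantification, writing CSV/JSON (and PGM images) under `out_dir`
#' and returning a manifest with per-file checksums.
#'
#' @param config list from [default_config()] or [read_config()].
#' @param out_dir output directory (created if missing).
#' @param stages which stages to execute (the `quantify` stage requires
#'   `synth` in the same call).
#' @return manifest list (also written to `manifest.json`).
#' @export
run_all <- function(config = default_config("smoke"), out_dir = tempfile(),
                    stages = c("simulate", "sweep", "genotypes", "perturb",
                               "synth", "quantify")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  done <- list()
  note <- function(stage, files) {
    done[[stage]] <<- lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  }
  ms <- config$simulate$max_steps

  if ("simulate" %in% stages) {
    st <- simulate_condition(config$simulate$K_S, config$simulate$K_adh,
                             max_steps = ms)
    write_state_csv(st, pth("state_wt.csv"))
    write.csv(tension_field(st, st$params), pth("tension_wt.csv"),
              row.names = FALSE)
    write.csv(morphometrics(st), pth("morphometrics_wt.csv"),
              row.names = FALSE)
    note("simulate", c(pth("state_wt.csv"), pth("tension_wt.csv"),
                       pth("morphometrics_wt.csv")))
  }

  if ("sweep" %in% stages) {
    sw1 <- sweep_surface_stiffness(config$sweep$ks_grid,
                                   K_adh = config$sweep$kadh_fixed,
                                   max_steps = ms)
    write.csv(sw1, pth("sweep_ks.csv"), row.names = FALSE)
    sw2 <- do.call(rbind, lapply(config$sweep$ks_fixed, function(ks)
      sweep_adhesion_stiffness(config$sweep$kadh_grid, K_S = ks,
                               max_steps = ms)))
    write.csv(sw2, pth("sweep_kadh.csv"), row.names = FALSE)
    note("sweep", c(pth("sweep_ks.csv"), pth("sweep_kadh.csv")))
  }

  if ("genotypes" %in% stages) {
    presets <- NULL
    if (!is.null(config$genotypes$subset)) {
      presets <- genotype_presets()
      presets <- presets[presets$name %in% config$genotypes$subset, ]
    }
    gp <- genotype_panel(presets, max_steps = ms)
    write.csv(gp, pth("genotypes.csv"), row.names = FALSE)
    note("genotypes", pth("genotypes.csv"))
  }

  if ("perturb" %in% stages) pt_run(config, pth, note, ms)

  if ("synth" %in% stages) {
    res <- synth_run(config, pth, note)
    if ("quantify" %in% stages) quantify_run(res, pth, note)
  }

  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("lapjoint")),
                   stages = done)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = 10)
  invisible(manifest)
}

#' @noRd
pt_run <- function(config, pth, note, ms) {
  pt <- lapply(list(
    c("left_adhesion", config$perturb$adhesion_factor),
    c("left_NT_halfsurface", config$perturb$nt_ks_factor)
  ), function(mp) {
    ap <- asymmetric_perturbation(mp[1], factor = as.numeric(mp[2]),
                                  max_steps = ms)
    data.frame(mode = mp[1], factor = as.numeric(mp[2]),
               slope_right_sym = ap$slope_right_sym,
               slope_right_pert = ap$slope_right_pert,
               dA_sym = ap$dA_sym, dA_pert = ap$dA_pert)
  })
  write.csv(do.call(rbind, pt), pth("perturbations.csv"), row.names = FALSE)
  note("perturb", pth("perturbations.csv"))
  invisible(NULL)
}

#' @noRd
synth_run <- function(config, pth, note) {
  seed <- config$seed
  mi <- do.call(gen_matrix_image, c(config$synth$matrix, list(seed = seed)))
  write_pgm(mi, pth("matrix.pgm"))
  sp <- do.call(gen_spot_series, c(config$synth$spots, list(seed = seed)))
  for (i in seq_along(sp$frames))
    write_pgm(sp$frames[[i]], pth(sprintf("spot_%02d.pgm", i)))
  cp <- do.call(gen_circle_points, c(config$synth$circle, list(seed = seed)))
  write.csv(data.frame(x = cp$points[, 1], y = cp$points[, 2]),
            pth("circle_points.csv"), row.names = FALSE)
  rp <- do.call(gen_ratio_pair, c(config$synth$ratio, list(seed = seed)))
  write_pgm(rp$A, pth("ratio_A.pgm")); write_pgm(rp$B, pth("ratio_B.pgm"))
  note("synth", c(pth("matrix.pgm"), pth("spot_01.pgm"),
                  pth("circle_points.csv"), pth("ratio_A.pgm"),
                  pth("ratio_B.pgm")))
  list(mi = mi, sp = sp, cp = cp, rp = rp)
}

#' @noRd
quantify_run <- function(res, pth, note) {
  mi <- res$mi; sp <- res$sp; cp <- res$cp; rp <- res$rp
  mask <- local_threshold_phansalkar(mi)
  sizes <- size_sort(mask)
  write.csv(sizes$components, pth("matrix_components.csv"),
            row.names = FALSE)
  tissue <- binary_mask(matrix(TRUE, nrow(mi$pixels), ncol(mi$pixels)),
                        mi$pixels_per_um)
  mlp <- ml_distribution(sizes$small, tissue)
  write.csv(data.frame(bin = mlp$bin_centers, frequency = mlp$frequency),
            pth("ml_distribution.csv"), row.names = FALSE)
  apd <- ap_density(sizes$small, tissue)
  write.csv(apd, pth("ap_density.csv"), row.names = FALSE)
  sm <- spot_metrics(sp)
  write.csv(sm, pth("spot_metrics.csv"), row.names = FALSE)
  fit <- pratt_circle_fit(cp$points)
  rg <- ratio_gradient(rp$A, rp$B)
  jsonlite::write_json(
    list(circle_fit = fit,
         ratio_profile = rg$ratio,
         spot_final_width_norm = sm$width_norm[nrow(sm)]),
    pth("quantify.json"), auto_unbox = TRUE, digits = 10)
  note("quantify", c(pth("matrix_components.csv"),
                     pth("ml_distribution.csv"), pth("ap_density.csv"),
                     pth("spot_metrics.csv"), pth("quantify.json")))
  invisible(NULL)
}
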