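#' Labeled image container
#'
#' A 2D 8-bit-convention intensity image together with its physical pixel
#' scale and axis convention. Following the convention of the quantification
#' code this package mirrors, columns run along the anterior-posterior (AP)
#' axis, rows along the medial-lateral (ML) axis, and the notochord /
#' neural-tube reference side sits at the maximal row index.
#'
#' @param pixels numeric matrix, intensities in `[0, 255]`.
#' @param pixels_per_um pixel scale (default 17.4 px/um).
#' @param truth optional ground-truth payload (generator-dependent).
#' @return object of class `lj_image`.
#' @export
labeled_image <- function(pixels, pixels_per_um = 17.4, truth = NULL) {
  stopifnot(is.matrix(pixels), pixels_per_um > 0)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  structure(list(pixels = pixels, pixels_per_um = pixels_per_um,
                 truth = truth),
            class = "lj_image")
}

#' @export
print.lj_image <- function(x, ...) {
  cat(sprintf("Image %d x %d px (%.1f x %.1f um at %.1f px/um)%s\n",
              nrow(x$pixels), ncol(x$pixels),
              nrow(x$pixels) / x$pixels_per_um,
              ncol(x$pixels) / x$pixels_per_um, x$pixels_per_um,
              if (!is.null(x$truth)) " + ground truth" else ""))
  invisible(x)
}

#' Binary mask container
#'
#' @param mask logical matrix, `TRUE` = signal.
#' @param pixels_per_um pixel scale.
#' @return object of class `lj_mask`.
#' @export
binary_mask <- function(mask, pixels_per_um = 17.4) {
  stopifnot(is.matrix(mask), is.logical(mask), pixels_per_um > 0)
  structure(list(mask = mask, pixels_per_um = pixels_per_um),
            class = "lj_mask")
}

#' @export
print.lj_mask <- function(x, ...) {
  cat(sprintf("Binary mask %d x %d px, %.1f%% foreground\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Read and write portable graymap (PGM, plain P2) images
#'
#' Text-based image interchange used by this package in place of TIFF
#' (no TIFF codec is assumed to be installed); any ImageJ-compatible tool
#' reads P2 PGM.
#'
#' @param img `lj_image` or plain matrix.
#' @param path file path.
#' @param pixels_per_um scale recorded in a comment line and restored by
#'   [read_pgm()].
#' @return `write_pgm()` returns the path invisibly; `read_pgm()` returns an
#'   `lj_image`.
#' @export
write_pgm <- function(img, path, pixels_per_um = NULL) {
  if (inherits(img, "lj_image")) {
    if (is.null(pixels_per_um)) pixels_per_um <- img$pixels_per_um
    img <- img$pixels
  }
  if (is.null(pixels_per_um)) pixels_per_um <- 17.4
  m <- round(pmin(pmax(img, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# pixels_per_um %.6g", pixels_per_um),
               paste(ncol(m), nrow(m)), "255"), con)
  write(t(m), file = con, ncolumns = 16)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  ppu <- 17.4
  cm <- grep("^#", lines, value = TRUE)
  hit <- regmatches(cm, regexpr("pixels_per_um [0-9.eE+-]+", cm))
  if (length(hit)) ppu <- as.numeric(sub("pixels_per_um ", "", hit[1]))
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("not a plain (P2) PGM file")
  vals <- scan(text = paste(lines[-1], collapse = " "), quiet = TRUE)
  nc <- vals[1]; nr <- vals[2]
  px <- matrix(vals[-(1:3)], nrow = nr, ncol = nc, byrow = TRUE)
  labeled_image(px, ppu)
}

#' @noRd
as_pixel_matrix <- function(img) {
  if (inherits(img, "lj_image")) img$pixels else img
}

#' @noRd
as_mask_matrix <- function(mask) {
  if (inherits(mask, "lj_mask")) mask$mask else mask
}

#' @noRd
ppu_of <- function(x, default = 17.4) {
  if (inherits(x, "lj_image") || inherits(x, "lj_mask")) x$pixels_per_um
  else default
}

#' Otsu threshold of an 8-bit image
#'
#' Maximizes between-class variance on a 256-bin histogram. Used as the
#' default per-frame threshold for photoconverted-spot series, standing in
#' for the manual per-frame thresholds of interactive analysis.
#'
#' @param img `lj_image` or matrix.
#' @return threshold value; foreground is `intensity > threshold`.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(as_pixel_matrix(img))
  h <- tabulate(pmin(255L, pmax(0L, as.integer(round(v)))) + 1L, 256L)
  w <- h / sum(h)
  omega <- cumsum(w)
  mu <- cumsum(w * (0:255))
  mu_t <- mu[256]
  sigma2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- 0
  which.max(sigma2) - 1
}

#' @noRd
conv2_same <- function(x, kernel) {
  # zero-padded FFT convolution, result cropped to the size of x with the
  # kernel centered; pad to 2-3-5-smooth sizes for the mixed-radix FFT
  nr <- stats::nextn(nrow(x) + nrow(kernel) - 1, c(2, 3, 5))
  nc <- stats::nextn(ncol(x) + ncol(kernel) - 1, c(2, 3, 5))
  X <- matrix(0, nr, nc); X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K <- matrix(0, nr, nc); K[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  out <- Re(fft(fft(X) * fft(K), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(kernel) - 1) %/% 2
  c0 <- (ncol(kernel) - 1) %/% 2
  out[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
}

#' @noRd
disc_kernel <- function(radius) {
  d <- 2 * radius + 1
  idx <- seq(-radius, radius)
  k <- outer(idx, idx, function(i, j) (i^2 + j^2) <= radius^2)
  k * 1
}
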