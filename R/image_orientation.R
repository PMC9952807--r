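# Synthetic fluorescence-style cell images and orientation quantification.
#
# The generator renders elongated capsule-shaped cells whose axial angles
# follow a von Mises distribution on doubled angles (the natural axial
# analogue of a unimodal circular distribution); quantification uses the
# structure tensor — smoothed outer products of intensity gradients — whose
# minor eigenvector gives the local texture orientation and whose
# eigenvalue contrast gives a coherence weight.
#
# Image convention: a numeric matrix in [0, 1]; the first index runs along
# the x axis (stretch direction, angle 0), the second along y. Angles are
# measured from x toward y and are axial (theta and theta + 180 identical).

#' Specification of a synthetic cell image
#'
#' @param image_size image side length (pixels).
#' @param n_cells number of cells to draw (>= 0).
#' @param cell_length,cell_width cell capsule dimensions (pixels).
#' @param mean_angle mean axial orientation (degrees from the stretch
#'   axis).
#' @param concentration von Mises concentration of the doubled-angle
#'   distribution; 0 = isotropic, larger = tighter alignment.
#' @param noise_level additive Gaussian noise, relative to full scale.
#' @param seed RNG seed; identical spec + seed gives identical images.
#' @return an object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(image_size = 256, n_cells = 150,
                                 cell_length = 24, cell_width = 6,
                                 mean_angle = 0, concentration = 6,
                                 noise_level = 0.05, seed = 1) {
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (concentration < 0) stopf("concentration must be >= 0")
  if (cell_length < 2 || cell_width < 1 || cell_width > cell_length)
    stopf("degenerate cell dimensions")
  structure(as.list(environment()), class = "synthetic_image_spec")
}

# Best-Fisher von Mises sampler (mean mu, concentration kappa), radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Generate a synthetic fluorescence-style cell image
#'
#' Renders `n_cells` elongated capsules at random positions with axial
#' angles drawn from a von Mises distribution on doubled angles about
#' `mean_angle`, plus additive Gaussian noise. Deterministic for a fixed
#' spec and seed.
#'
#' @param spec a [synthetic_image_spec()].
#' @return numeric matrix in [0, 1] (first index x, second y).
#' @examples
#' img <- generate_cell_image(synthetic_image_spec(n_cells = 50,
#'                                                 mean_angle = 30))
#' @export
generate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  s <- spec
  with_seed(s$seed, {
    img <- matrix(0, s$image_size, s$image_size)
    if (s$n_cells > 0) {
      # axial sampling: von Mises on doubled angles, halved back
      ang2 <- rvonmises(s$n_cells, 2 * s$mean_angle * pi / 180,
                        s$concentration)
      theta <- ang2 / 2
      cx <- stats::runif(s$n_cells, 1, s$image_size)
      cy <- stats::runif(s$n_cells, 1, s$image_size)
      half <- (s$cell_length - s$cell_width) / 2
      sig <- s$cell_width / 3
      reach <- ceiling(s$cell_length / 2 + 3 * sig)
      for (i in seq_len(s$n_cells)) {
        d <- c(cos(theta[i]), sin(theta[i]))
        xr <- max(1, floor(cx[i] - reach)):min(s$image_size,
                                               ceiling(cx[i] + reach))
        yr <- max(1, floor(cy[i] - reach)):min(s$image_size,
                                               ceiling(cy[i] + reach))
        px <- outer(xr, rep(1, length(yr))) - cx[i]
        py <- outer(rep(1, length(xr)), yr) - cy[i]
        # distance to the capsule spine segment
        t_ <- pmin(pmax(px * d[1] + py * d[2], -half), half)
        dx <- px - t_ * d[1]; dy <- py - t_ * d[2]
        val <- exp(-(dx^2 + dy^2) / (2 * sig^2))
        img[xr, yr] <- pmax(img[xr, yr], val)
      }
    }
    if (s$noise_level > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, s$noise_level),
                          nrow(img))
    pmin(pmax(img, 0), 1)
  })
}

# Separable Gaussian smoothing (matrix in, matrix out); reflective edges.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(v, r) c(v[r:1], v, v[length(v) - 0:(r - 1)])
  conv1 <- function(v) stats::filter(pad(v, r), k, sides = 2)[(r + 1):(r + length(v))]
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}

#' Quantify the axial orientation distribution of an image
#'
#' Structure-tensor orientation analysis: intensity gradients are computed
#' at `gradient_scale`, the tensor components are smoothed at twice that
#' scale, and each pixel contributes its local texture orientation (the
#' tensor's minor eigenvector) weighted by gradient energy times coherence.
#' Pixels with coherence below `coherence_floor` are discarded. All
#' statistics use the doubled-angle transform appropriate for axial data.
#'
#' @param image 2D numeric matrix (grayscale).
#' @param gradient_scale Gaussian derivative scale (pixels).
#' @param coherence_floor minimum coherence in [0, 1] for a pixel to
#'   contribute.
#' @param nbins number of histogram bins over [0, 180).
#' @return an object of class `orientation_distribution`: normalised
#'   histogram, circular `mean_angle` folded to [0, 90] (degrees from the
#'   stretch axis), unfolded `mean_axis` in [0, 180), and the
#'   `order_parameter` (resultant length of doubled angles, 0 = isotropic,
#'   1 = perfectly aligned). A constant image yields a `no_orientation`
#'   flag rather than an angle.
#' @export
quantify_orientation <- function(image, gradient_scale = 2,
                                 coherence_floor = 0.2, nbins = 36) {
  img <- as.matrix(image)
  if (length(dim(img)) != 2 || !is.numeric(img))
    stopf("image must be a 2D numeric matrix")
  sm <- gauss_smooth(img, gradient_scale)
  n1 <- nrow(sm); n2 <- ncol(sm)
  gx <- (sm[c(2:n1, n1), ] - sm[c(1, 1:(n1 - 1)), ]) / 2
  gy <- (sm[, c(2:n2, n2)] - sm[, c(1, 1:(n2 - 1))]) / 2
  jxx <- gauss_smooth(gx * gx, 2 * gradient_scale)
  jyy <- gauss_smooth(gy * gy, 2 * gradient_scale)
  jxy <- gauss_smooth(gx * gy, 2 * gradient_scale)
  tr <- jxx + jyy
  if (max(tr) < 1e-12) {
    return(structure(list(histogram = NULL, mean_angle = NA_real_,
                          mean_axis = NA_real_, order_parameter = NA_real_,
                          no_orientation = TRUE),
                     class = "orientation_distribution"))
  }
  coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / (tr + 1e-12 * max(tr))
  # gradient direction = major eigenvector; texture runs perpendicular
  theta_tex <- 0.5 * atan2(2 * jxy, jxx - jyy) + pi / 2
  w <- tr * coh
  w[coh < coherence_floor] <- 0
  if (sum(w) <= 0) {
    return(structure(list(histogram = NULL, mean_angle = NA_real_,
                          mean_axis = NA_real_, order_parameter = NA_real_,
                          no_orientation = TRUE),
                     class = "orientation_distribution"))
  }
  th <- (theta_tex * 180 / pi) %% 180
  bins <- seq(0, 180, length.out = nbins + 1)
  idx <- pmin(findInterval(th, bins), nbins)
  hist_w <- vapply(seq_len(nbins), function(b) sum(w[idx == b]), 0)
  hist_w <- hist_w / sum(hist_w)
  C <- sum(w * cos(2 * theta_tex)); S <- sum(w * sin(2 * theta_tex))
  mean_axis <- (0.5 * atan2(S, C) * 180 / pi) %% 180
  op <- sqrt(C^2 + S^2) / sum(w)
  structure(list(
    histogram = data.frame(bin_lo = bins[-(nbins + 1)], bin_hi = bins[-1],
                           weight = hist_w),
    mean_angle = fold_angle(mean_axis), mean_axis = mean_axis,
    order_parameter = op, no_orientation = FALSE),
    class = "orientation_distribution")
}

#' @export
print.orientation_distribution <- function(x, ...) {
  cat("Axial orientation distribution\n")
  if (x$no_orientation) {
    cat("  no orientation detected (constant or incoherent image)\n")
  } else {
    cat(sprintf("  mean angle: %.1f deg (axis %.1f deg), order parameter %.3f\n",
                x$mean_angle, x$mean_axis, x$order_parameter))
  }
  invisible(x)
}

#' Marker-positive area fraction of a fluorescence image
#'
#' Percentage of the image area covered by marker-expressing pixels:
#' `100 * (pixels >= threshold) / total`. With `threshold = NULL` the Otsu
#' threshold of the image is used.
#'
#' @param image 2D numeric matrix (grayscale, values in [0, 1]).
#' @param threshold intensity threshold, or `NULL` for Otsu.
#' @return area fraction in percent.
#' @export
quantify_area_fraction <- function(image, threshold = NULL) {
  img <- as.matrix(image)
  if (length(img) == 0) stopf("empty image")
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  100 * mean(img >= threshold)
}

#' Read and write images
#'
#' Thin wrappers over EBImage I/O: 16-bit TIFF or PNG depending on the
#' file extension.
#'
#' @param image 2D numeric matrix in [0, 1].
#' @param file path ending in .tif/.tiff or .png.
#' @return `read_image` returns a numeric matrix.
#' @export
write_image <- function(image, file) {
  EBImage::writeImage(EBImage::Image(as.matrix(image)), file,
                      bits.per.sample = 16L)
  invisible(file)
}

#' @rdname write_image
#' @export
read_image <- function(file) {
  as.matrix(EBImage::imageData(EBImage::readImage(file)))
}
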