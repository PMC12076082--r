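# Ground-truth-known generators for the assay pipelines: droplet phase
# scans with a planted phase boundary, dilution series following the
# piecewise C_sat model with gel-band calibration, and two-channel
# condensate images with planted intensity ratios.

#' Parameters for the synthetic droplet phase scan
#'
#' Droplet compositions are sampled uniformly over the scanned window:
#' protein over `protein_range` and a shared dilution signal in `[0, 1]`
#' that maps to urea and NaCl through the fixed 3 M / 1 M stock ratio (see
#' [barcode_to_composition()]). The phase class is Bernoulli with
#' probability `plogis(signed distance to the boundary / noise_width)` in
#' normalised composition space (positive below the boundary, the
#' two-phase side); `noise_width = 0` gives a hard boundary with on-boundary
#' droplets classed two-phase.
#'
#' @param n_droplets Number of droplets, > 0.
#' @param boundary Either `list(intercept =, slope =)` for the line
#'   `dilution = intercept + slope * protein` in normalised coordinates, or
#'   `list(vertical = x0)` for a vertical boundary at normalised protein
#'   `x0`.
#' @param noise_width Non-negative logistic decision-noise width in
#'   normalised distance units.
#' @param protein_range Protein axis range (uM).
#' @param urea_max,nacl_max Stock concentrations mapped by the barcode
#'   (default 3 M urea, 1 M NaCl).
#' @param seed RNG seed.
#' @return A `scan_gen_params` list.
#' @export
scan_gen_params <- function(n_droplets = 5000L,
                            boundary = list(intercept = 0.2, slope = 0.6),
                            noise_width = 0.02,
                            protein_range = c(0, 10),
                            urea_max = 3, nacl_max = 1, seed = 1L) {
  stopifnot(n_droplets > 0, noise_width >= 0,
            length(protein_range) == 2L,
            protein_range[2L] > protein_range[1L])
  if (is.null(boundary$vertical)) {
    stopifnot(!is.null(boundary$intercept), !is.null(boundary$slope))
  }
  structure(
    list(n_droplets = as.integer(n_droplets), boundary = boundary,
         noise_width = noise_width, protein_range = protein_range,
         urea_max = urea_max, nacl_max = nacl_max, seed = seed),
    class = "scan_gen_params"
  )
}

# Signed distance (positive on the two-phase side, below the boundary /
# beyond the vertical line) in normalised (protein, dilution) coordinates.
.boundary_signed_distance <- function(boundary, x, y) {
  if (!is.null(boundary$vertical)) {
    x - boundary$vertical
  } else {
    (boundary$intercept + boundary$slope * x - y) /
      sqrt(1 + boundary$slope^2)
  }
}

#' Generate a synthetic droplet phase scan
#'
#' @param params A [scan_gen_params()] object.
#' @return Data.frame of droplet records: `droplet_id`, `protein_uM`,
#'   `signal` (normalised dilution barcode), `urea_M`, `nacl_M`, `class`
#'   (1 = phase-separated, 0 = mixed).
#' @export
#' @examples
#' rec <- gen_phasescan(scan_gen_params(n_droplets = 200, seed = 3))
#' table(rec$class)
gen_phasescan <- function(params) {
  stopifnot(inherits(params, "scan_gen_params"))
  with_seed(params$seed, {
    n <- params$n_droplets
    protein <- stats::runif(n, params$protein_range[1L],
                            params$protein_range[2L])
    signal <- stats::runif(n)
    x <- (protein - params$protein_range[1L]) /
      diff(params$protein_range)
    d <- .boundary_signed_distance(params$boundary, x, signal)
    p <- if (params$noise_width == 0) {
      as.numeric(d >= 0)
    } else {
      stats::plogis(d / params$noise_width)
    }
    cls <- stats::rbinom(n, 1L, p)
    comp <- barcode_to_composition(signal, urea_max = params$urea_max,
                                   nacl_max = params$nacl_max)
    data.frame(droplet_id = seq_len(n), protein_uM = protein,
               signal = signal, urea_M = comp$urea_M,
               nacl_M = comp$nacl_M, class = cls)
  })
}

#' Parameters for the synthetic C_sat dilution series
#'
#' @param m True sub-saturation slope (dimensionless), > 0.
#' @param c True saturation concentration (uM), > 0.
#' @param x_grid Total-concentration grid (uM); must span both sides of the
#'   breakpoint `c / m`.
#' @param calibration_slope Band density per uM of the paired gel
#'   calibration.
#' @param calibration_conc Known concentrations of the calibration lane
#'   (uM).
#' @param noise_sd Relative measurement noise (multiplicative, sd as a
#'   fraction of the signal) applied to dilute-phase values and band
#'   densities; 0 for noiseless.
#' @param seed RNG seed.
#' @return A `csat_gen_params` list.
#' @export
csat_gen_params <- function(m = 1, c = 0.38,
                            x_grid = seq(0.05, 5, length.out = 12L),
                            calibration_slope = 1.7,
                            calibration_conc = c(0.25, 0.5, 1, 2, 4, 8),
                            noise_sd = 0, seed = 1L) {
  stopifnot(m > 0, c > 0, noise_sd >= 0, length(x_grid) >= 4L)
  bp <- c / m
  if (!(min(x_grid) < bp && max(x_grid) > bp)) {
    stop("x_grid must span both sides of the breakpoint c/m = ", bp)
  }
  structure(
    list(m = m, c = c, x_grid = as.numeric(x_grid),
         calibration_slope = calibration_slope,
         calibration_conc = as.numeric(calibration_conc),
         noise_sd = noise_sd, seed = seed),
    class = "csat_gen_params"
  )
}

#' Generate a synthetic C_sat dilution series with calibration table
#'
#' Dilute-phase concentrations follow `y = min(m x, c)` with optional
#' multiplicative Gaussian noise; the paired calibration table maps known
#' concentrations to band densities through `calibration_slope` with the
#' same relative noise.
#'
#' @param params A [csat_gen_params()] object.
#' @return List with `series` (data.frame `x`, `y` in uM), `calibration`
#'   (data.frame `concentration`, `band_density`) and the planted `truth`.
#' @export
#' @examples
#' s <- gen_csat_series(csat_gen_params(m = 1, c = 0.38,
#'   x_grid = seq(0.05, 2, length.out = 12)))
#' fit_csat(s$series$x, s$series$y)$c
gen_csat_series <- function(params) {
  stopifnot(inherits(params, "csat_gen_params"))
  with_seed(params$seed, {
    x <- params$x_grid
    y0 <- pmin(params$m * x, params$c)
    y <- y0 * (1 + stats::rnorm(length(x), 0, params$noise_sd))
    y <- pmax(y, 0)
    dens0 <- params$calibration_slope * params$calibration_conc
    dens <- dens0 * (1 + stats::rnorm(length(dens0), 0, params$noise_sd))
    list(
      series = data.frame(x = x, y = y),
      calibration = data.frame(concentration = params$calibration_conc,
                               band_density = dens),
      truth = list(m = params$m, c = params$c,
                   calibration_slope = params$calibration_slope)
    )
  })
}

#' Parameters for the synthetic condensate image generator
#'
#' @param shape Image size in pixels (rows, cols).
#' @param pixel_size Pixel edge (um/pixel), > 0.
#' @param centres n x 2 matrix of disk centres (um; x = column direction,
#'   y = row direction). Disks must lie fully inside the frame.
#' @param radii Disk radii (um), > 0.
#' @param intensity_in,intensity_bg Green-channel mean intensities inside
#'   disks and in the background.
#' @param red_in,red_bg Red-channel mean intensities (same geometry).
#' @param noise_sd Additive Gaussian noise sd (both channels).
#' @param seed RNG seed.
#' @return An `image_gen_params` list.
#' @export
image_gen_params <- function(shape = c(128L, 128L), pixel_size = 0.1,
                             centres, radii, intensity_in = 500,
                             intensity_bg = 100, red_in = 100,
                             red_bg = 100, noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 2L, pixel_size > 0, noise_sd >= 0,
            all(radii > 0), all(intensity_in >= 0), all(intensity_bg >= 0))
  centres <- if (is.null(dim(centres))) matrix(centres, ncol = 2L)
             else as.matrix(centres)
  stopifnot(nrow(centres) == length(radii))
  wx <- shape[2L] * pixel_size
  wy <- shape[1L] * pixel_size
  inside <- centres[, 1L] - radii >= 0 & centres[, 1L] + radii <= wx &
            centres[, 2L] - radii >= 0 & centres[, 2L] + radii <= wy
  if (length(radii) > 0L && !all(inside)) {
    stop("all disks must lie inside the frame")
  }
  structure(
    list(shape = as.integer(shape), pixel_size = pixel_size,
         centres = centres, radii = as.numeric(radii),
         intensity_in = intensity_in, intensity_bg = intensity_bg,
         red_in = red_in, red_bg = red_bg, noise_sd = noise_sd,
         seed = seed),
    class = "image_gen_params"
  )
}

#' Generate a synthetic two-channel condensate image
#'
#' Background pixels at the background intensity, disk pixels at the
#' in-disk intensity, plus additive Gaussian noise; the red channel shares
#' the disk geometry with independently chosen intensities.
#'
#' @param params An [image_gen_params()] object (zero disks give flat
#'   images).
#' @return An `image_pair`: `green`, `red` (matrices), `pixel_size`, and
#'   `truth` (disk mask and planted intensity parameters).
#' @export
#' @examples
#' p <- image_gen_params(centres = cbind(6.4, 6.4), radii = 2,
#'                       intensity_in = 500, intensity_bg = 100)
#' img <- gen_condensate_image(p)
gen_condensate_image <- function(params) {
  stopifnot(inherits(params, "image_gen_params"))
  nr <- params$shape[1L]; ncl <- params$shape[2L]
  px <- params$pixel_size
  xc <- (col(matrix(0, nr, ncl)) - 0.5) * px
  yc <- (row(matrix(0, nr, ncl)) - 0.5) * px
  in_disk <- matrix(FALSE, nr, ncl)
  for (i in seq_along(params$radii)) {
    in_disk <- in_disk |
      ((xc - params$centres[i, 1L])^2 + (yc - params$centres[i, 2L])^2 <=
         params$radii[i]^2)
  }
  with_seed(params$seed, {
    green <- matrix(params$intensity_bg, nr, ncl)
    green[in_disk] <- params$intensity_in
    red <- matrix(params$red_bg, nr, ncl)
    red[in_disk] <- params$red_in
    if (params$noise_sd > 0) {
      green <- green + matrix(stats::rnorm(nr * ncl, 0, params$noise_sd),
                              nr, ncl)
      red <- red + matrix(stats::rnorm(nr * ncl, 0, params$noise_sd),
                          nr, ncl)
    }
    structure(
      list(green = green, red = red, pixel_size = px,
           truth = list(mask = in_disk,
                        ratio_green = params$intensity_in /
                          max(params$intensity_bg, .Machine$double.eps),
                        ratio_red = params$red_in /
                          max(params$red_bg, .Machine$double.eps))),
      class = "image_pair"
    )
  })
}
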