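# Condensate image analysis: Triangle thresholding, size-filtered
# segmentation, partition coefficients and co-localisation.

#' Triangle threshold of an intensity image
#'
#' Builds a 256-bin histogram over the observed intensity range, draws the
#' line from the histogram peak to the farthest non-empty tail bin, and
#' returns the intensity (bin centre) maximising the perpendicular distance
#' from the histogram to that line. Deterministic; preserves low-intensity
#' edge pixels better than variance-based thresholds, which is why it is
#' the method of choice for condensate masks.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold intensity (pixels strictly above it are foreground).
#' @export
triangle_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: no threshold exists")
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  idx <- pmin(n_bins, pmax(1L, findInterval(v, breaks, rightmost.closed = TRUE)))
  counts <- tabulate(idx, nbins = n_bins)
  centres <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  peak <- which.max(counts)
  nonempty <- which(counts > 0L)
  first <- nonempty[1L]
  last <- nonempty[length(nonempty)]
  tail_bin <- if ((last - peak) >= (peak - first)) last else first
  if (tail_bin == peak) stop("degenerate histogram: peak is the only bin")
  # perpendicular distance of each bin (b, h[b]) to the peak-tail line,
  # with bin index and count on comparable scales
  b1 <- peak; h1 <- counts[peak]
  b2 <- tail_bin; h2 <- counts[tail_bin]
  span <- seq(min(b1, b2), max(b1, b2))
  num <- abs((h2 - h1) * (span - b1) - (b2 - b1) * (counts[span] - h1))
  best <- span[which.max(num)]
  centres[best]
}

#' Segment condensates with Triangle threshold and size filter
#'
#' Mask = pixels above the Triangle threshold; connected components
#' (8-connected by default) with area below `min_area` um^2 are removed.
#' No circularity criterion is applied.
#'
#' @param image Numeric intensity matrix.
#' @param pixel_size Pixel edge (um/pixel), > 0.
#' @param min_area Minimum component area (um^2, default 0.5).
#' @param connectivity 8 (default) or 4.
#' @return A `condensate_mask`: `mask` (logical matrix), `labels` (integer
#'   matrix), `areas` (um^2 of retained components), `threshold`,
#'   `pixel_size`.
#' @export
#' @examples
#' p <- image_gen_params(centres = cbind(6.4, 6.4), radii = 2)
#' img <- gen_condensate_image(p)
#' m <- segment_condensates(img$green, img$pixel_size)
#' length(m$areas)
segment_condensates <- function(image, pixel_size, min_area = 0.5,
                                connectivity = 8L) {
  stopifnot(is.matrix(image), pixel_size > 0, min_area >= 0,
            connectivity %in% c(4L, 8L))
  thr <- triangle_threshold(image)
  mask <- image > thr
  labels <- cpp_label_components(mask, as.integer(connectivity))
  px_area <- pixel_size^2
  areas <- table(labels[labels > 0L]) * px_area
  keep <- as.integer(names(areas)[areas >= min_area])
  mask_f <- matrix(labels %in% keep, nrow = nrow(image))
  labels[!mask_f] <- 0L
  # renumber retained components consecutively
  if (length(keep) > 0L) {
    labels <- matrix(match(labels, keep, nomatch = 0L), nrow = nrow(image))
  }
  structure(
    list(mask = mask_f, labels = labels,
         areas = as.numeric(areas[areas >= min_area]),
         threshold = thr, pixel_size = pixel_size),
    class = "condensate_mask"
  )
}

#' Partition coefficient of an image given a condensate mask
#'
#' Ratio of the mean intensity inside the condensate mask to the mean
#' intensity of the surrounding dilute phase (all non-mask pixels). An
#' empty or full mask yields an undefined result flagged for exclusion
#' from replicate aggregation.
#'
#' @param image Numeric intensity matrix.
#' @param mask A `condensate_mask` or logical matrix of the same shape.
#' @return A `partition_result`: `value`, `undefined`, `mean_in`,
#'   `mean_out`, `n_in`.
#' @export
partition_coefficient <- function(image, mask) {
  m <- if (inherits(mask, "condensate_mask")) mask$mask else mask
  stopifnot(is.matrix(image), is.logical(m), all(dim(m) == dim(image)))
  n_in <- sum(m)
  if (n_in == 0L || n_in == length(m)) {
    return(structure(list(value = NA_real_, undefined = TRUE,
                          mean_in = NA_real_, mean_out = NA_real_,
                          n_in = n_in),
                     class = "partition_result"))
  }
  mi <- mean(image[m])
  mo <- mean(image[!m])
  structure(
    list(value = mi / mo, undefined = FALSE, mean_in = mi, mean_out = mo,
         n_in = n_in),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  if (x$undefined) cat("partition coefficient: undefined (empty/full mask)\n")
  else cat(sprintf("partition coefficient: %.4g (in %.4g / out %.4g)\n",
                   x$value, x$mean_in, x$mean_out))
  invisible(x)
}

#' Co-localisation partition coefficient of the red channel
#'
#' Segments condensates on the green (scaffold) channel and measures the
#' red (client) channel's partition coefficient inside that green-derived
#' mask — the recruitment readout: ~1 means no recruitment.
#'
#' @param pair An `image_pair` (see [gen_condensate_image()]) or a list
#'   with `green`, `red`, `pixel_size`.
#' @param min_area Minimum component area (um^2).
#' @return List with `green` and `red` `partition_result`s and the shared
#'   `mask`.
#' @export
colocalisation <- function(pair, min_area = 0.5) {
  stopifnot(all(c("green", "red", "pixel_size") %in% names(pair)))
  mask <- segment_condensates(pair$green, pair$pixel_size,
                              min_area = min_area)
  list(green = partition_coefficient(pair$green, mask),
       red = partition_coefficient(pair$red, mask),
       mask = mask)
}

#' Replicate aggregation of partition coefficients
#'
#' Mean and standard deviation over per-image partition coefficients,
#' excluding undefined (empty/full mask) results.
#'
#' @param results List of `partition_result` objects.
#' @return Data.frame `mean`, `sd`, `n`, `n_excluded`.
#' @export
partition_summary <- function(results) {
  vals <- vapply(results, function(r) {
    if (isTRUE(r$undefined)) NA_real_ else r$value
  }, numeric(1L))
  ok <- !is.na(vals)
  data.frame(mean = mean(vals[ok]), sd = stats::sd(vals[ok]),
             n = sum(ok), n_excluded = sum(!ok))
}

#' One-way ANOVA across variants' partition coefficients
#'
#' Convenience wrapper comparing per-image partition coefficients between
#' construct variants (reporting aid, not a condensate-specific algorithm).
#'
#' @param value Numeric partition coefficients.
#' @param group Factor of variant labels.
#' @return The fitted `aov` object.
#' @export
compare_partition <- function(value, group) {
  stats::aov(value ~ factor(group))
}

#' Read a greyscale image (TIFF or PNG) as a matrix
#'
#' @param path Image file; `.tif`/`.tiff` read via the tiff package,
#'   `.png` via the png package.
#' @return Numeric matrix (first channel if multi-channel).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("package 'tiff' required for TIFF input")
    }
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("package 'png' required for PNG input")
    }
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
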