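# Droplet-microfluidic phase-diagram construction: barcode-to-composition
# mapping, neighbourhood-averaged phase-separation probability maps, and
# extraction of the 0.5-probability phase boundary.

#' Map a normalised barcode signal to urea and NaCl concentrations
#'
#' The dilution barcode co-varies urea and NaCl from shared stock
#' solutions: `[urea] = 3 M x signal` and `[NaCl] = 1 M x signal`, so their
#' ratio is fixed at 3:1 and the two axes collapse onto one dilution
#' coordinate.
#'
#' @param signal Normalised combined fluorescence signal in `[0, 1]`.
#' @param urea_max,nacl_max Stock concentrations (default 3 M and 1 M).
#' @return Data.frame `urea_M`, `nacl_M`.
#' @export
#' @examples
#' barcode_to_composition(c(0, 0.5, 1))
barcode_to_composition <- function(signal, urea_max = 3, nacl_max = 1) {
  if (any(signal < 0 | signal > 1)) {
    stop("normalised signal must lie in [0, 1]")
  }
  data.frame(urea_M = urea_max * signal, nacl_M = nacl_max * signal)
}

#' Phase-separation probability map from droplet records
#'
#' Normalises the protein and dilution axes to `[0, 1]` by their data
#' range, then assigns each droplet the mean phase class over all droplets
#' (including itself) within a Euclidean neighbourhood of radius
#' `radius_frac` in normalised space. The same rule evaluated on a regular
#' grid gives the probability map. As the radius grows beyond the data
#' extent every probability tends to the global class mean.
#'
#' @param records Droplet records: data.frame with `protein_uM`, `class`,
#'   and a dilution coordinate (`nacl_M`, `urea_M` or `signal`).
#' @param radius_frac Neighbourhood radius as a fraction of the normalised
#'   data range (default 0.05), > 0.
#' @param grid_n Grid resolution per axis for the probability map.
#' @return A `phase_diagram`: `records` (with a `probability` column),
#'   `grid` (data.frame `x`, `y`, `p` in normalised coordinates),
#'   `radius_frac`, `ranges` (axis ranges used for normalisation).
#' @export
probability_map <- function(records, radius_frac = 0.05, grid_n = 60L) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L,
            radius_frac > 0, "class" %in% names(records),
            "protein_uM" %in% names(records))
  ycol <- intersect(c("nacl_M", "urea_M", "signal"), names(records))[1L]
  if (is.na(ycol)) {
    stop("records need a dilution coordinate (nacl_M, urea_M or signal)")
  }
  px <- records$protein_uM
  py <- records[[ycol]]
  rx <- range(px); ry <- range(py)
  if (diff(rx) == 0 || diff(ry) == 0) {
    stop("zero data range on an axis; cannot normalise")
  }
  x <- (px - rx[1L]) / diff(rx)
  y <- (py - ry[1L]) / diff(ry)
  cls <- records$class
  n <- length(x)
  prob <- numeric(n)
  r2 <- radius_frac^2
  chunk <- 1000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dx <- outer(x[s:e], x, "-")
    dy <- outer(y[s:e], y, "-")
    nb <- dx * dx + dy * dy <= r2
    prob[s:e] <- (nb %*% cls) / rowSums(nb)
  }
  gx <- seq(0, 1, length.out = grid_n)
  gy <- seq(0, 1, length.out = grid_n)
  grid <- expand.grid(x = gx, y = gy)
  gp <- numeric(nrow(grid))
  for (s in seq(1L, nrow(grid), by = chunk)) {
    e <- min(nrow(grid), s + chunk - 1L)
    dx <- outer(grid$x[s:e], x, "-")
    dy <- outer(grid$y[s:e], y, "-")
    nb <- dx * dx + dy * dy <= r2
    cnt <- rowSums(nb)
    gp[s:e] <- ifelse(cnt > 0, (nb %*% cls) / pmax(cnt, 1L), NA_real_)
  }
  grid$p <- gp
  records$probability <- prob
  structure(
    list(records = records, grid = grid, radius_frac = radius_frac,
         ranges = list(protein = rx, dilution = ry, dilution_axis = ycol)),
    class = "phase_diagram"
  )
}

#' Fit the 0.5-probability phase boundary
#'
#' Collects grid nodes whose probability lies within `tol` of 0.5 and fits
#' a total-least-squares line through them (first principal component of
#' the node coordinates) in normalised space, reported both in normalised
#' and physical units. Nodes closer than one neighbourhood radius to the
#' window edge are excluded: their truncated neighbourhoods bias the
#' estimated probability and bend the level set. Near-vertical boundaries
#' are reported as a constant protein concentration.
#'
#' @param diagram A [probability_map()] result.
#' @param tol Half-width of the probability band around 0.5 (default
#'   0.05).
#' @return A `boundary_fit`: `vertical`, `slope`, `intercept` (normalised),
#'   `x0` (normalised protein position if vertical), physical-unit
#'   counterparts (`slope_phys`, `intercept_phys`, `protein_uM`),
#'   `n_nodes`, `residuals` (signed per-droplet distance to the line,
#'   normalised), `orientation` (mean class below minus above the line).
#' @export
fit_boundary <- function(diagram, tol = 0.05) {
  stopifnot(inherits(diagram, "phase_diagram"), tol > 0)
  g <- diagram$grid
  r <- diagram$radius_frac
  interior <- g$x >= r & g$x <= 1 - r & g$y >= r & g$y <= 1 - r
  sel <- !is.na(g$p) & abs(g$p - 0.5) <= tol & interior
  if (!any(sel)) {
    # fall back to the full window when the level set only touches edges
    sel <- !is.na(g$p) & abs(g$p - 0.5) <= tol
  }
  if (!any(sel)) {
    stop("no boundary in scanned window: probability map never crosses 0.5")
  }
  pts <- cbind(g$x[sel], g$y[sel])
  ctr <- colMeans(pts)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1L]
  rec <- diagram$records
  x <- (rec$protein_uM - diagram$ranges$protein[1L]) /
    diff(diagram$ranges$protein)
  ycol <- diagram$ranges$dilution_axis
  y <- (rec[[ycol]] - diagram$ranges$dilution[1L]) /
    diff(diagram$ranges$dilution)
  nvec <- c(-v[2L], v[1L])  # unit normal
  resid <- (cbind(x, y) - matrix(ctr, nrow = length(x), ncol = 2L,
                                 byrow = TRUE)) %*% nvec
  vertical <- abs(v[1L]) < 1e-6
  rx <- diagram$ranges$protein
  ry <- diagram$ranges$dilution
  if (vertical) {
    x0 <- ctr[1L]
    slope <- NA_real_; intercept <- NA_real_
    slope_phys <- NA_real_; intercept_phys <- NA_real_
    protein_uM <- rx[1L] + x0 * diff(rx)
  } else {
    slope <- v[2L] / v[1L]
    intercept <- ctr[2L] - slope * ctr[1L]
    x0 <- NA_real_
    slope_phys <- slope * diff(ry) / diff(rx)
    intercept_phys <- ry[1L] + diff(ry) *
      (intercept - slope * rx[1L] / diff(rx))
    protein_uM <- NA_real_
  }
  below <- if (vertical) x > ctr[1L] else y < intercept + slope * x
  orientation <- mean(rec$class[below]) - mean(rec$class[!below])
  structure(
    list(vertical = vertical, slope = unname(slope),
         intercept = unname(intercept), x0 = unname(x0),
         slope_phys = unname(slope_phys),
         intercept_phys = unname(intercept_phys),
         protein_uM = unname(protein_uM),
         n_nodes = sum(sel), tol = tol,
         residuals = drop(resid), orientation = unname(orientation)),
    class = "boundary_fit"
  )
}

#' @export
print.boundary_fit <- function(x, ...) {
  if (x$vertical) {
    cat(sprintf("boundary_fit: vertical at protein = %.4g uM (%d nodes)\n",
                x$protein_uM, x$n_nodes))
  } else {
    cat(sprintf("boundary_fit: dilution = %.4g + %.4g x protein (normalised; %d nodes)\n",
                x$intercept, x$slope, x$n_nodes))
  }
  invisible(x)
}
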