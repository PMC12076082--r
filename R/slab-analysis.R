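# Direct-coexistence slab analysis: z density profiles, coexisting-phase
# densities via a symmetric tanh interface fit, and critical-point fitting
# with the law of coexisting densities plus the law of rectilinear diameters.

#' Mass-density profile along the slab axis
#'
#' Bins bead masses along z. Each retained frame is first recentred so that
#' the slab centre of mass (mass-weighted circular mean over the periodic z
#' axis) sits at the box centre, then per-frame profiles are averaged.
#' Binning conserves total mass exactly per frame.
#'
#' @param traj A [slab_trajectory()].
#' @param bin_width Bin width (Angstrom); must not exceed box z / 10.
#' @param discard_frac Fraction of initial frames discarded as equilibration
#'   (default 0.5); at least one frame is always retained.
#' @param recentre Recentre each frame on the slab centre of mass.
#' @return A `density_profile`: `z` (bin centres, Angstrom), `rho` (mg/mL),
#'   `n_frames`, `bin_width`, `box`, `temperature`, `total_mass`.
#' @export
density_profile <- function(traj, bin_width = 10, discard_frac = 0.5,
                            recentre = TRUE) {
  stopifnot(inherits(traj, "slab_trajectory"))
  if (length(traj$frames) == 0L) stop("empty trajectory")
  Lz <- traj$box[3L]
  stopifnot(bin_width > 0)
  if (bin_width > Lz / 10) {
    stop("bin_width must be at most box z / 10")
  }
  stopifnot(discard_frac >= 0, discard_frac < 1)
  n_frames <- length(traj$frames)
  first <- min(n_frames, floor(discard_frac * n_frames) + 1L)
  keep <- seq.int(first, n_frames)
  n_bins <- max(10L, as.integer(round(Lz / bin_width)))
  eff_width <- Lz / n_bins
  xsec <- traj$box[1L] * traj$box[2L]
  acc <- numeric(n_bins)
  for (fi in keep) {
    z <- traj$frames[[fi]][, 3L] %% Lz
    if (recentre) {
      zcm <- circular_mean(z, Lz, w = traj$mass)
      z <- (z - zcm + Lz / 2) %% Lz
    }
    bin <- pmin(n_bins, floor(z / eff_width) + 1L)
    m <- vapply(split(traj$mass, factor(bin, levels = seq_len(n_bins))),
                sum, numeric(1L))
    acc <- acc + m
  }
  acc <- acc / length(keep)
  rho <- acc / (xsec * eff_width) * .DA_PER_A3_IN_MG_ML
  structure(
    list(z = (seq_len(n_bins) - 0.5) * eff_width, rho = rho,
         n_frames = length(keep), bin_width = eff_width, box = traj$box,
         temperature = traj$temperature, total_mass = sum(traj$mass)),
    class = "density_profile"
  )
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$z, x$rho, type = "l", xlab = "z (\u00c5)",
                 ylab = "density (mg/mL)", ...)
  invisible(x)
}

#' Coexisting-phase densities from a density profile
#'
#' Fits the symmetric interface model
#' `rho(z) = (rho_h + rho_l)/2 - (rho_h - rho_l)/2 *
#'   tanh((|z - z0| - w) / delta)`
#' and reports the dilute and dense plateau densities. A one-phase verdict is
#' returned when the fitted contrast `(rho_h - rho_l)/max(rho_h, eps)` falls
#' below `contrast_threshold` or the fit cannot be performed; a
#' plateau-average fallback (top/bottom quartile bands of the profile) is
#' used if the tanh fit does not converge.
#'
#' @param profile A [density_profile()].
#' @param contrast_threshold One-phase criterion on the relative density
#'   contrast (default 0.1).
#' @return A `coexistence_point`: `T`, `rho_l`, `rho_h`, `one_phase`, and
#'   interface parameters `z0`, `w`, `delta` when fitted.
#' @export
coexisting_densities <- function(profile, contrast_threshold = 0.1) {
  stopifnot(inherits(profile, "density_profile"))
  rho <- profile$rho
  z <- profile$z
  if (any(!is.finite(rho))) stop("non-finite densities in profile")
  hi <- mean(rho[rho >= stats::quantile(rho, 0.9)])
  lo <- mean(rho[rho <= stats::quantile(rho, 0.1)])
  mk <- function(rl, rh, one_phase, z0 = NA, w = NA, delta = NA) {
    structure(list(T = profile$temperature, rho_l = rl, rho_h = rh,
                   one_phase = one_phase, z0 = z0, w = w, delta = delta),
              class = "coexistence_point")
  }
  contrast0 <- (hi - lo) / max(hi, .Machine$double.eps)
  if (contrast0 < contrast_threshold) {
    return(mk(mean(rho), mean(rho), TRUE))
  }
  mid <- (hi + lo) / 2
  w0 <- max(profile$bin_width, sum(rho > mid) * profile$bin_width / 2)
  start <- list(rh = hi, rl = max(lo, 0), z0 = profile$box[3L] / 2,
                w = w0, delta = 2 * profile$bin_width)
  dat <- data.frame(z = z, rho = rho)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rho ~ (rh + rl) / 2 - (rh - rl) / 2 * tanh((abs(z - z0) - w) / delta),
      data = dat, start = start,
      lower = c(rh = 0, rl = 0, z0 = 0, w = profile$bin_width / 2,
                delta = profile$bin_width / 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # plateau-average fallback
    band <- hi - lo
    dense <- rho[rho > lo + 0.75 * band]
    dilute <- rho[rho < lo + 0.25 * band]
    if (length(dense) == 0L || length(dilute) == 0L) {
      return(mk(mean(rho), mean(rho), TRUE))
    }
    rl <- mean(dilute); rh <- mean(dense)
    contrast <- (rh - rl) / max(rh, .Machine$double.eps)
    return(mk(rl, rh, contrast < contrast_threshold))
  }
  cf <- stats::coef(fit)
  rl <- unname(cf["rl"]); rh <- unname(cf["rh"])
  if (rh < rl) { tmp <- rl; rl <- rh; rh <- tmp }
  contrast <- (rh - rl) / max(rh, .Machine$double.eps)
  mk(rl, rh, contrast < contrast_threshold,
     z0 = unname(cf["z0"]), w = unname(cf["w"]), delta = unname(cf["delta"]))
}

#' @export
print.coexistence_point <- function(x, ...) {
  if (isTRUE(x$one_phase)) {
    cat(sprintf("one phase at T = %g K (density %.4g mg/mL)\n",
                x$T, x$rho_h))
  } else {
    cat(sprintf("T = %g K: rho_l = %.4g, rho_h = %.4g mg/mL\n",
                x$T, x$rho_l, x$rho_h))
  }
  invisible(x)
}

#' Collect coexistence points from several trajectories
#'
#' Runs [density_profile()] and [coexisting_densities()] on each trajectory
#' and assembles the two-phase results into a table ready for
#' [fit_binodal()]. One-phase verdicts are dropped with a message.
#'
#' @param trajs List of `slab_trajectory` objects at distinct temperatures.
#' @inheritParams density_profile
#' @inheritParams coexisting_densities
#' @return A `coexistence_points` data.frame (`T`, `rho_l`, `rho_h`).
#' @export
slab_coexistence <- function(trajs, bin_width = 10, discard_frac = 0.5,
                             contrast_threshold = 0.1) {
  pts <- lapply(trajs, function(tr) {
    pr <- density_profile(tr, bin_width = bin_width,
                          discard_frac = discard_frac)
    coexisting_densities(pr, contrast_threshold = contrast_threshold)
  })
  two <- Filter(function(p) !isTRUE(p$one_phase), pts)
  if (length(two) < length(pts)) {
    message(length(pts) - length(two), " trajectory(ies) were one-phase ",
            "and were dropped")
  }
  structure(
    data.frame(T = vapply(two, `[[`, numeric(1L), "T"),
               rho_l = vapply(two, `[[`, numeric(1L), "rho_l"),
               rho_h = vapply(two, `[[`, numeric(1L), "rho_h")),
    class = c("coexistence_points", "data.frame")
  )
}

#' Fit the binodal and critical point
#'
#' Two-stage fit of coexisting densities versus temperature. Stage 1 fits
#' the law of coexisting densities,
#' `(rho_h - rho_l)^nu = d (1 - T/T_c)` (`nu = 3.06`, the Ising critical
#' exponent), by ordinary least squares in its linearised form
#' `(rho_h - rho_l)^nu` versus `T` (linear in `d` and `d/T_c`). Stage 2 fits
#' the law of rectilinear diameters,
#' `rho_h + rho_l = 2 rho_c + 2 A (T - T_c)`, with `T_c` held fixed.
#' Noiseless input generated from these laws is recovered to machine
#' precision. An optional joint nonlinear refinement of all four parameters
#' is available.
#'
#' @param points Data.frame with columns `T`, `rho_l`, `rho_h`; at least 3
#'   distinct temperatures, all two-phase.
#' @param exponent Critical exponent (default 3.06).
#' @param method `"sequential"` (default) or `"joint"` (nonlinear refinement
#'   of the sequential solution, minimising squared density residuals).
#' @return A `binodal_fit`: `tc`, `rho_c`, `d`, `A`, `exponent`, `se`
#'   (named vector of standard errors), `method`, `points`.
#' @export
#' @examples
#' pts <- gen_binodal_points(346, 300, 1e7, -0.5,
#'                           temperatures = seq(295, 342, length.out = 10))
#' fit_binodal(pts)$tc
fit_binodal <- function(points, exponent = 3.06,
                        method = c("sequential", "joint")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(points),
            all(c("T", "rho_l", "rho_h") %in% names(points)))
  Tv <- points$T
  if (length(Tv) < 3L || length(unique(Tv)) < 3L) {
    stop("need at least 3 coexistence points at distinct temperatures")
  }
  if (any(points$rho_h <= points$rho_l)) {
    stop("all points must be two-phase (rho_h > rho_l)")
  }
  y <- (points$rho_h - points$rho_l)^exponent
  lm1 <- stats::lm(y ~ Tv)
  a <- unname(stats::coef(lm1)[1L])
  b <- unname(stats::coef(lm1)[2L])
  if (!is.finite(b) || b >= 0) {
    stop("density difference does not decrease with temperature; ",
         "cannot locate a critical point")
  }
  tc <- -a / b
  d <- a
  if (tc <= max(Tv)) {
    stop("fitted critical temperature does not exceed the largest fitted ",
         "temperature; data are inconsistent with the coexistence law")
  }
  V1 <- suppressWarnings(stats::vcov(lm1))  # noiseless input fits exactly
  g <- c(-1 / b, a / b^2)
  se_tc <- sqrt(drop(t(g) %*% V1 %*% g))
  se_d <- sqrt(V1[1L, 1L])
  s <- points$rho_l + points$rho_h
  dT <- Tv - tc
  lm2 <- stats::lm(s ~ dT)
  rho_c <- unname(stats::coef(lm2)[1L]) / 2
  A <- unname(stats::coef(lm2)[2L]) / 2
  se2 <- sqrt(diag(suppressWarnings(stats::vcov(lm2)))) / 2
  se <- c(tc = se_tc, rho_c = unname(se2[1L]), d = se_d,
          A = unname(se2[2L]))
  if (method == "joint") {
    obj <- function(th) {
      tc_ <- th[1L]; d_ <- th[2L]; rc_ <- th[3L]; A_ <- th[4L]
      if (tc_ <= max(Tv) || d_ <= 0) return(1e30)
      diff <- (d_ * (1 - Tv / tc_))^(1 / exponent)
      sm <- 2 * rc_ + 2 * A_ * (Tv - tc_)
      sum((points$rho_l - (sm - diff) / 2)^2 +
          (points$rho_h - (sm + diff) / 2)^2)
    }
    op <- stats::optim(c(tc, d, rho_c, A), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    tc <- op$par[1L]; d <- op$par[2L]; rho_c <- op$par[3L]; A <- op$par[4L]
    n_res <- 2L * length(Tv)
    sigma2 <- op$value / max(1L, n_res - 4L)
    H <- tryCatch(stats::optimHess(op$par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
      if (!is.null(cv) && all(diag(cv) >= 0)) {
        se <- sqrt(diag(cv))
        names(se) <- c("tc", "d", "rho_c", "A")
        se <- se[c("tc", "rho_c", "d", "A")]
      }
    }
  }
  structure(
    list(tc = tc, rho_c = rho_c, d = d, A = A, exponent = exponent,
         se = se, method = method, points = points),
    class = "binodal_fit"
  )
}

#' @export
print.binodal_fit <- function(x, ...) {
  cat(sprintf("binodal_fit (%s): T_c = %.4g +/- %.3g K, rho_c = %.4g +/- %.3g mg/mL\n",
              x$method, x$tc, x$se["tc"], x$rho_c, x$se["rho_c"]))
  cat(sprintf("  d = %.6g, A = %.4g, exponent = %g\n", x$d, x$A, x$exponent))
  invisible(x)
}

#' Predicted coexistence points of a fitted binodal
#'
#' @param object A `binodal_fit`.
#' @param temperatures Temperatures (K) below the fitted `tc`.
#' @param ... Unused.
#' @return A `coexistence_points` data.frame.
#' @export
predict.binodal_fit <- function(object, temperatures, ...) {
  gen_binodal_points(object$tc, object$rho_c, object$d, object$A,
                     temperatures, exponent = object$exponent)
}

#' Binodal curve on a reduced temperature scale
#'
#' Rescales temperatures by a reference critical temperature (e.g. that of a
#' reference variant) so that binodals of different constructs can be
#' compared on one axis; the curve apex sits at `tc / reference_tc`. The
#' rescaling is a positive linear map, so the ordering of variants' critical
#' temperatures is preserved.
#'
#' @param fit A `binodal_fit`.
#' @param reference_tc Reference critical temperature (K), > 0.
#' @param temperatures Temperatures (K) at which to evaluate the curve;
#'   default: 60 points from the lowest fitted temperature (or `0.8 tc`) up
#'   to just below `tc`.
#' @return Data.frame `T`, `T_norm`, `rho_l`, `rho_h`; attribute `apex`
#'   holds `tc / reference_tc`.
#' @export
normalised_binodal <- function(fit, reference_tc, temperatures = NULL) {
  stopifnot(inherits(fit, "binodal_fit"), reference_tc > 0)
  if (is.null(temperatures)) {
    lo <- if (nrow(fit$points) > 0L) min(fit$points$T) else 0.8 * fit$tc
    temperatures <- seq(lo, fit$tc * (1 - 1e-9), length.out = 60L)
  }
  pts <- stats::predict(fit, temperatures)
  out <- data.frame(T = pts$T, T_norm = pts$T / reference_tc,
                    rho_l = pts$rho_l, rho_h = pts$rho_h)
  attr(out, "apex") <- fit$tc / reference_tc
  out
}
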