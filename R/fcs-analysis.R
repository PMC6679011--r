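#' Fluorescence autocorrelation curve
#'
#' Lag-time / G(tau) pairs in the "+1" convention: G decays to 1 at large
#' lag and `G(0+) - 1 = 1/N` for pure diffusion of N molecules in the
#' detection volume.
#'
#' @param lags Strictly increasing lag times in seconds, all `> 0`.
#' @param g G(tau) values, dimensionless, finite.
#' @param sd Optional per-point standard deviation (e.g. across replicate
#'   measurements), used as weights in fitting.
#' @return A `faf_curve` list.
#' @export
faf_curve <- function(lags, g, sd = NULL) {
  lags <- as.numeric(lags); g <- as.numeric(g)
  if (length(lags) != length(g)) stop("`lags` and `g` must have equal length")
  if (any(lags <= 0)) stop("lags must be > 0")
  if (any(diff(lags) <= 0)) stop("lags must be strictly increasing")
  if (!all(is.finite(g))) stop("G values must be finite")
  if (!is.null(sd) && length(sd) != length(g))
    stop("`sd` must match the curve length")
  structure(list(lags = lags, g = g, sd = sd), class = "faf_curve")
}

#' @export
print.faf_curve <- function(x, ...) {
  cat(sprintf("<faf_curve> %d points, lags [%.3g, %.3g] s, G(first) = %.4f\n",
              length(x$lags), min(x$lags), max(x$lags), x$g[1]))
  invisible(x)
}

# G at integer sample lags `ks` of series `x`, normalised by global mean `mu`
raw_acf <- function(x, ks, mu) {
  n <- length(x)
  d <- x - mu
  vapply(ks, function(k) {
    sum(d[seq_len(n - k)] * d[(k + 1):n]) / (n - k) / mu^2 + 1
  }, numeric(1))
}

# pairwise binning (mean of consecutive pairs), odd tail dropped
bin_pairs <- function(x) {
  n <- 2L * (length(x) %/% 2L)
  x <- x[seq_len(n)]
  (x[seq(1L, n, 2L)] + x[seq(2L, n, 2L)]) / 2
}

#' Autocorrelate an intensity trace
#'
#' Computes `G(tau) = <dF(t) dF(t+tau)> / <F>^2 + 1` with `dF = F - <F>`.
#' The `multi_tau` scheme uses the standard quasi-logarithmic correlator:
#' lags `1..m` samples at full resolution, then lags `m/2+1..m` on a series
#' binned pairwise at each successive level, doubling the lag spacing per
#' level. The `direct` scheme is the O(n k) plain summation oracle at every
#' sample lag up to the truncation (or at user-supplied lags).
#'
#' @param trace An [intensity_trace()].
#' @param scheme `"multi_tau"` (default) or `"direct"`.
#' @param m Multi-tau block size (lags per level doubling); default 16.
#' @param max_lag Truncation lag in seconds; default a quarter of the trace
#'   duration.
#' @param lags Optional explicit lag times in seconds (`direct` only),
#'   rounded to sample multiples.
#' @param errors If `TRUE` (`multi_tau` only; default `FALSE`), attach per-point
#'   standard errors estimated by splitting the trace into 8 contiguous
#'   blocks, running the correlator on each, and taking the SD of the block
#'   estimates over `sqrt(8)`. Block SEs respect the correlation structure
#'   of the signal at every lag (unlike an i.i.d. sample-count model, which
#'   understates the noise of short lags whose products are serially
#'   correlated). Lags too deep to be estimated within one block inherit
#'   the last empirical SE scaled by the sample-count model
#'   `sqrt(2^level / (n_level - k))`. Used as weights in [fit_faf()]. The
#'   default leaves weighting to replicate SDs from [average_fafs()]
#'   (uniform when absent), matching the replicate-driven protocol.
#' @return A [faf_curve()].
#' @export
autocorrelate <- function(trace, scheme = c("multi_tau", "direct"), m = 16L,
                          max_lag = NULL, lags = NULL, errors = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  scheme <- match.arg(scheme)
  x <- trace$counts
  n <- length(x)
  if (n < 2L * m) stop("trace too short: need at least 2*m samples")
  mu <- mean(x)
  if (mu == 0) stop("constant-zero trace: autocorrelation normalisation undefined")
  dt <- trace$dt
  if (is.null(max_lag)) max_lag <- n * dt / 4

  if (scheme == "direct") {
    ks <- if (is.null(lags)) seq_len(floor(max_lag / dt))
          else unique(pmax(1L, round(lags / dt)))
    ks <- ks[ks < n]
    return(faf_curve(ks * dt, raw_acf(x, ks, mu)))
  }

  main <- mt_pass(x, dt, m, max_lag, mu)
  sdv <- NULL
  n_blocks <- 8L
  bl <- n %/% n_blocks
  if (errors && bl >= 4L * m) {
    block_max <- bl * dt / 4
    bg <- vapply(seq_len(n_blocks), function(b) {
      xs <- x[((b - 1L) * bl + 1L):(b * bl)]
      bc <- mt_pass(xs, dt, m, block_max, mean(xs))
      out <- rep(NA_real_, length(main$lag))
      idx <- match(round(bc$lag / dt), round(main$lag / dt))
      out[idx[!is.na(idx)]] <- bc$g[!is.na(idx)]
      out
    }, numeric(length(main$lag)))
    sdv <- apply(bg, 1L, sd) / sqrt(n_blocks)
    covered <- !is.na(sdv)
    if (!any(covered)) {
      sdv <- NULL
    } else {
      # deeper lags: extrapolate from the last block-covered SE with the
      # sample-count scaling of the estimator variance
      iid <- main$iid_se
      last <- max(which(covered))
      if (last < length(sdv))
        sdv[(last + 1L):length(sdv)] <-
          sdv[last] * iid[(last + 1L):length(iid)] / iid[last]
      sdv <- pmax(sdv, max(sdv, na.rm = TRUE) * 1e-6)
    }
  }
  faf_curve(main$lag, main$g, sd = sdv)
}

# one multi-tau pass: quasi-log lags, pairwise binning per level
mt_pass <- function(x, dt, m, max_lag, mu) {
  out_lag <- numeric(0); out_g <- numeric(0); out_iid <- numeric(0)
  level <- 0L
  xb <- x
  width <- 1L
  repeat {
    ks <- if (level == 0L) seq_len(m) else (m %/% 2L + 1L):m
    ks <- ks[ks * width * dt <= max_lag & ks < length(xb)]
    if (length(ks) > 0L) {
      out_lag <- c(out_lag, ks * width * dt)
      out_g <- c(out_g, raw_acf(xb, ks, mu))
      out_iid <- c(out_iid, sqrt(width / (length(xb) - ks)))
    }
    xb <- bin_pairs(xb)
    width <- width * 2L
    level <- level + 1L
    if (length(xb) <= m || (m %/% 2L + 1L) * width * dt > max_lag) break
  }
  if (length(out_lag) == 0L) stop("no lags below `max_lag`; increase it")
  ord <- order(out_lag)
  list(lag = out_lag[ord], g = out_g[ord], iid_se = out_iid[ord])
}

#' Average replicate autocorrelation curves
#'
#' Pointwise mean of curves measured on an identical lag grid, with the
#' per-point standard deviation across replicates attached for weighted
#' fitting. Averaging replicate short acquisitions is the standard guard
#' against non-stationary fluctuations (drift, slow bleaching).
#'
#' @param curves List of [faf_curve()] objects on identical lag grids.
#' @return A [faf_curve()] with `sd` set (0 when a single curve is given).
#' @export
average_fafs <- function(curves) {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, logical(1), "faf_curve")))
  lag0 <- curves[[1]]$lags
  same <- vapply(curves, function(cv)
    length(cv$lags) == length(lag0) && all(abs(cv$lags - lag0) <= 1e-12 + 1e-9 * lag0),
    logical(1))
  if (!all(same)) stop("curves must share an identical lag grid")
  G <- do.call(cbind, lapply(curves, `[[`, "g"))
  sdv <- if (ncol(G) > 1) apply(G, 1, sd) else rep(0, nrow(G))
  faf_curve(lag0, rowMeans(G), sd = sdv)
}

triplet_factor <- function(lags, T, tau_T) {
  (1 - T + T * exp(-lags / tau_T)) / (1 - T)
}

#' Evaluate the FCS diffusion model
#'
#' The one- or two-component 3D free-diffusion autocorrelation model
#' \deqn{G(\tau) = 1 + \frac{1}{N} \sum_i y_i
#'   \left(1 + \tau/\tau_{D,i}\right)^{-1}
#'   \left(1 + \frac{1}{s^2}\,\tau/\tau_{D,i}\right)^{-1/2}}
#' optionally multiplied (on the 1/N term) by the triplet factor
#' `(1 - T + T exp(-tau/tau_T)) / (1 - T)` accounting for dark-state
#' blinking.
#'
#' @param lags Lag times in seconds.
#' @param N Mean number of molecules in the detection volume; `> 0`.
#' @param tau_D Per-component diffusion times in seconds (length 1 or 2).
#' @param y Component fractions summing to 1; default `1` for one component.
#' @param s Structure parameter (axial/lateral ratio); `> 0`.
#' @param triplet Optional `list(T = , tau_T = )`.
#' @return A [faf_curve()].
#' @export
model_gtau <- function(lags, N, tau_D, y = NULL, s = 5, triplet = NULL) {
  if (N <= 0) stop("`N` must be > 0")
  if (s <= 0) stop("`s` must be > 0")
  if (any(tau_D <= 0)) stop("diffusion times must be > 0")
  if (is.null(y)) y <- rep(1 / length(tau_D), length(tau_D))
  if (length(y) != length(tau_D)) stop("`y` and `tau_D` lengths differ")
  if (abs(sum(y) - 1) > 1e-8) stop("fractions `y` must sum to 1")
  comp <- vapply(seq_along(tau_D), function(i) {
    r <- lags / tau_D[i]
    y[i] / ((1 + r) * sqrt(1 + r / s^2))
  }, numeric(length(lags)))
  g <- 1 + rowSums(matrix(comp, nrow = length(lags))) / N
  if (!is.null(triplet))
    g <- 1 + (g - 1) * triplet_factor(lags, triplet$T, triplet$tau_T)
  faf_curve(lags, g)
}

# parameter packing for the optimiser: positivity via log, fractions via logit
pack_params <- function(N, tau_D, y, s, triplet, s_free, trip_free, base_free) {
  p <- c(logN = log(N), setNames(log(tau_D), paste0("ltau", seq_along(tau_D))))
  if (length(tau_D) == 2L) p <- c(p, zy = stats::qlogis(min(max(y[1], 1e-4), 1 - 1e-4)))
  if (trip_free) p <- c(p, zT = stats::qlogis(min(max(triplet$T, 1e-4), 1 - 1e-4)),
                        ltauT = log(triplet$tau_T))
  if (s_free) p <- c(p, ls = log(s))
  if (base_free) p <- c(p, b = 0)
  p
}

unpack_params <- function(p, n_components, s_fixed, s_free, trip_free, base_free) {
  N <- exp(p[["logN"]])
  tau_D <- exp(unname(p[grep("^ltau[0-9]", names(p))]))
  y <- if (n_components == 2L) {
    y1 <- stats::plogis(p[["zy"]]); c(y1, 1 - y1)
  } else 1
  triplet <- if (trip_free)
    list(T = stats::plogis(p[["zT"]]), tau_T = exp(p[["ltauT"]])) else NULL
  s <- if (s_free) exp(p[["ls"]]) else s_fixed
  baseline <- if (base_free) p[["b"]] else 0
  list(N = N, tau_D = tau_D, y = y, s = s, triplet = triplet,
       baseline = baseline)
}

#' Fit the diffusion model to an autocorrelation curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of [model_gtau()]
#' against a measured curve, multi-started from a coarse grid of candidate
#' diffusion times to avoid local optima. Weights are `1/sd` when the curve
#' carries per-point replicate SDs (all positive), else uniform.
#'
#' @param curve A [faf_curve()] with at least 10 points, decaying toward 1.
#' @param n_components 1 or 2 diffusing components.
#' @param triplet If `TRUE`, fit the triplet dark-state factor too.
#' @param s_policy `"fixed"` (default; the conventional choice when no
#'   calibration measurement is available) or `"free"`.
#' @param s Structure parameter value used when `s_policy = "fixed"`, and the
#'   starting value when free. Default 5.
#' @param baseline `"free"` (default) fits an additive offset on G alongside
#'   the diffusion model, the conventional guard against correlation
#'   pedestals (detector afterpulsing, drift, and the small negative
#'   pedestal that particle-number conservation imposes on closed-volume
#'   simulations); `"fixed"` pins the large-lag limit at exactly 1.
#' @param window `"adaptive"` (default) first fits the full curve, then
#'   refits on lags up to `window_factor` times the largest fitted
#'   diffusion time and reports that fit. Lags far beyond the slowest
#'   diffusion time carry no information about the diffusion parameters
#'   (the model is flat there to within a fraction of a percent of the
#'   amplitude) while residual instrumental or finite-volume correlations
#'   concentrate there, so excluding them is the conventional safeguard.
#'   `"full"` fits every lag.
#' @param window_factor Fit-window length in units of the largest fitted
#'   diffusion time; default 50 (the lateral model term has decayed to 2
#'   percent of the amplitude by then).
#' @param w Optional lateral beam radius in um; when given, per-component
#'   diffusion coefficients `D = w^2 / (4 tau_D)` are filled in.
#' @return A `fit_result` list: `n_components`, `N`, `y`, `tau_D` (sorted
#'   ascending, i.e. fast component first), `s`, `triplet`, `D` (or `NULL`),
#'   and `goodness` (`rss`, `red_chisq`, `n_points`, `n_par`).
#'   Non-convergence from every start raises an error; no silent defaults.
#' @export
fit_faf <- function(curve, n_components = 1L, triplet = FALSE,
                    s_policy = c("fixed", "free"), s = 5,
                    baseline = c("free", "fixed"),
                    window = c("adaptive", "full"), window_factor = 50,
                    w = NULL) {
  window <- match.arg(window)
  fit <- fit_faf_once(curve, n_components, triplet, s_policy, s, baseline, w)
  if (window == "adaptive") {
    win <- window_factor * max(fit$tau_D)
    keep <- curve$lags <= win
    if (sum(keep) >= 10L && sum(keep) < length(curve$lags)) {
      sub <- faf_curve(curve$lags[keep], curve$g[keep],
                       sd = if (!is.null(curve$sd)) curve$sd[keep])
      fit <- fit_faf_once(sub, n_components, triplet, s_policy, s, baseline, w)
      fit$window <- win
    }
  }
  fit
}

fit_faf_once <- function(curve, n_components = 1L, triplet = FALSE,
                         s_policy = c("fixed", "free"), s = 5,
                         baseline = c("free", "fixed"), w = NULL) {
  stopifnot(inherits(curve, "faf_curve"))
  s_policy <- match.arg(s_policy)
  base_free <- match.arg(baseline) == "free"
  n_components <- as.integer(n_components)
  if (!n_components %in% c(1L, 2L)) stop("`n_components` must be 1 or 2")
  lags <- curve$lags; g <- curve$g
  if (length(lags) < 10L) stop("need at least 10 lag points to fit")
  amp <- max(g) - 1
  if (amp <= 0) stop("curve does not decay toward 1 from above; nothing to fit")

  wts <- if (!is.null(curve$sd) && all(curve$sd > 0)) 1 / curve$sd
         else rep(1, length(g))
  s_free <- s_policy == "free"

  resid_fn <- function(p) {
    u <- unpack_params(p, n_components, s, s_free, triplet, base_free)
    gm <- tryCatch(
      u$baseline + model_gtau(lags, u$N, u$tau_D,
                              if (n_components == 2L) u$y else NULL,
                              u$s, u$triplet)$g,
      error = function(e) rep(NA_real_, length(g)))
    if (!all(is.finite(gm))) return(rep(1e6, length(g)))
    (gm - g) * wts
  }

  N0 <- 1 / amp
  tau_grid <- 10^seq(log10(min(lags) * 2), log10(max(lags) / 2),
                     length.out = if (n_components == 1L) 8 else 6)
  starts <- if (n_components == 1L) {
    lapply(tau_grid, function(tau) list(tau_D = tau, y = 1))
  } else {
    idx <- utils::combn(seq_along(tau_grid), 2)
    lapply(seq_len(ncol(idx)), function(j)
      list(tau_D = tau_grid[idx[, j]], y = c(0.5, 0.5)))
  }

  best <- NULL
  for (st in starts) {
    p0 <- pack_params(N0, st$tau_D, st$y, s,
                      list(T = 0.1, tau_T = min(lags) * 5), s_free, triplet,
                      base_free)
    res <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(res) || !res$info %in% 1:3) next
    rss <- sum(resid_fn(res$par)^2)
    if (is.null(best) || rss < best$rss) best <- list(res = res, rss = rss)
  }
  if (is.null(best))
    stop("fit_faf: no start converged; the curve may not match the model ",
         "(components = ", n_components, ", triplet = ", triplet, ")")

  u <- unpack_params(best$res$par, n_components, s, s_free, triplet, base_free)
  ord <- order(u$tau_D)
  tau_D <- unname(u$tau_D[ord])
  y <- if (n_components == 2L) unname(u$y[ord]) else 1
  raw_res <- (u$baseline +
              model_gtau(lags, u$N, tau_D, if (n_components == 2L) y else NULL,
                         u$s, u$triplet)$g - g)
  n_par <- length(best$res$par)
  rss <- sum(raw_res^2)
  wrss <- sum((raw_res * wts)^2)
  red_chisq <- wrss / max(length(g) - n_par, 1)
  out <- structure(list(
    n_components = n_components, N = unname(u$N), y = y, tau_D = tau_D,
    s = unname(u$s), triplet = u$triplet, baseline = unname(u$baseline),
    D = if (!is.null(w)) tau_to_D(tau_D, w) else NULL,
    goodness = list(rss = rss, wrss = wrss, red_chisq = red_chisq,
                    n_points = length(g), n_par = n_par),
    converged = TRUE), class = "fit_result")
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d-component, N = %.4g, s = %.3g\n",
              x$n_components, x$N, x$s))
  for (i in seq_along(x$tau_D))
    cat(sprintf("  component %d: y = %.3f, tau_D = %.4g s%s\n", i,
                if (x$n_components == 2) x$y[i] else 1, x$tau_D[i],
                if (!is.null(x$D)) sprintf(", D = %.4g um2/s", x$D[i]) else ""))
  cat(sprintf("  RSS = %.4g, reduced chi-square = %.4g\n",
              x$goodness$rss, x$goodness$red_chisq))
  invisible(x)
}

#' Choose between one- and two-component fits
#'
#' Fits each candidate model and accepts the two-component model only when
#' the nested F-test on residual sums of squares rejects the one-component
#' model at level `alpha`. Ties, numerically zero one-component residuals,
#' or a two-component fit that does not reduce the residual all fall back to
#' the one-component model.
#'
#' @param curve A [faf_curve()].
#' @param candidates Subset of `c(1, 2)`.
#' @param alpha Significance level of the nested F-test; default 0.05.
#' @param ... Passed to [fit_faf()] (`triplet`, `s_policy`, `s`, `w`).
#' @return The chosen `fit_result`, with attribute `"selection"` recording
#'   RSS values, the F statistic and its p-value (when both were fitted).
#' @export
select_model <- function(curve, candidates = c(1L, 2L), alpha = 0.05, ...) {
  candidates <- sort(unique(as.integer(candidates)))
  if (!all(candidates %in% c(1L, 2L)) || length(candidates) == 0)
    stop("`candidates` must be a subset of {1, 2}")
  if (length(candidates) == 1L)
    return(fit_faf(curve, n_components = candidates, ...))

  # candidates are compared on the full lag grid (a common fit window),
  # then the chosen model is refit with its own adaptive window
  fit1 <- fit_faf(curve, n_components = 1L, window = "full", ...)
  fit2 <- fit_faf(curve, n_components = 2L, window = "full", ...)
  # compare on the weighted objective the fits actually minimised
  rss1 <- fit1$goodness$wrss; rss2 <- fit2$goodness$wrss
  n <- fit1$goodness$n_points
  p1 <- fit1$goodness$n_par; p2 <- fit2$goodness$n_par
  scale <- sum((curve$g - 1)^2)
  sel <- list(rss1 = rss1, rss2 = rss2, f = NA_real_, p = NA_real_)
  choose2 <- FALSE
  if (rss1 > 1e-14 * max(scale, .Machine$double.eps) && rss2 < rss1 &&
      n > p2) {
    f <- ((rss1 - rss2) / (p2 - p1)) / (rss2 / (n - p2))
    p <- pf(f, p2 - p1, n - p2, lower.tail = FALSE)
    sel$f <- f; sel$p <- p
    choose2 <- is.finite(p) && p < alpha
  }
  out <- fit_faf(curve, n_components = if (choose2) 2L else 1L, ...)
  attr(out, "selection") <- sel
  out
}

#' Convert diffusion time to diffusion coefficient
#'
#' `D = w^2 / (4 tau_D)`: the residence time of a Brownian particle in a
#' Gaussian detection volume of lateral radius `w`.
#'
#' @param tau_D Diffusion time(s) in seconds; `> 0`.
#' @param w Lateral 1/e^2 beam radius in um; `> 0`.
#' @return Diffusion coefficient(s) in um^2/s.
#' @export
tau_to_D <- function(tau_D, w) {
  if (any(tau_D <= 0)) stop("`tau_D` must be > 0")
  if (w <= 0) stop("`w` must be > 0")
  w^2 / (4 * tau_D)
}

#' @rdname tau_to_D
#' @param D Diffusion coefficient(s) in um^2/s; `> 0`.
#' @export
D_to_tau <- function(D, w) {
  if (any(D <= 0)) stop("`D` must be > 0")
  if (w <= 0) stop("`w` must be > 0")
  w^2 / (4 * D)
}

#' Reference-dye calibrated diffusion coefficient
#'
#' Converts a measured diffusion time into a diffusion coefficient by ratio
#' to a reference dye measured in the same detection volume:
#' `D_probe = D_ref * tau_ref / tau_probe`. The default reference is
#' rhodamine 6G with its literature value `D = 280 um^2/s`, the conventional
#' FCS calibration standard.
#'
#' @param tau_probe Measured diffusion time of the probe in seconds.
#' @param tau_ref Measured diffusion time of the reference dye in seconds.
#' @param D_ref Reference diffusion coefficient in um^2/s; default 280
#'   (rhodamine 6G).
#' @return Diffusion coefficient of the probe in um^2/s.
#' @export
calibrate_D <- function(tau_probe, tau_ref, D_ref = 280) {
  if (any(c(tau_probe, tau_ref, D_ref) <= 0))
    stop("all calibration inputs must be > 0")
  D_ref * tau_ref / tau_probe
}

#' Characteristic diffusion coefficient of a compartment
#'
#' Reduces a fit to the single D value characterising a compartment's fluid
#' phase. In the nucleolus, two-component fits arise because part of the
#' probe population diffuses fast in interstitial fluid; the slow component
#' (smaller D) is taken as characteristic of the nucleolar matrix and the
#' fast component is set aside. Outside the nucleolus a fraction-weighted
#' mean is reported, with both components retained in the
#' `"components"` attribute.
#'
#' @param fit A converged `fit_result` with `D` filled (fit with `w`, or
#'   assign via [tau_to_D()] / [calibrate_D()]).
#' @param compartment `"nucleolus"`, `"nucleoplasm"` or `"cytoplasm"`.
#' @return A single D in um^2/s.
#' @export
characteristic_D <- function(fit, compartment = c("nucleolus", "nucleoplasm",
                                                  "cytoplasm")) {
  stopifnot(inherits(fit, "fit_result"))
  compartment <- match.arg(compartment)
  if (is.null(fit$D))
    stop("fit has no D values: fit with `w`, or fill via tau_to_D()/calibrate_D()")
  if (fit$n_components == 1L) return(fit$D)
  if (compartment == "nucleolus") return(min(fit$D))
  out <- sum(fit$y * fit$D)
  attr(out, "components") <- data.frame(y = fit$y, D = fit$D)
  out
}
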