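#' Axial detection-slice description
#'
#' Parameters of the microscope's axial detection slice and of the empirical
#' correction that replaces the nominal slice thickness by an effective one
#' before evaluating the defocus-loss factor [z_corr()]. The absorbing-
#' boundary loss model overestimates how many free molecules leave the
#' slice (molecules can blink out and return); the effective thickness
#' `dz_eff = dz_nominal + corr_sqrt_coeff * sqrt(D) + corr_intercept_b`
#' compensates for this, with the published calibration constants
#' (0.700 um, 0.15716 um s^(1/2), 0.20811 um) as defaults. The printed form
#' of the calibration is typographically ambiguous (sqrt(D) vs D); the
#' sqrt(D) reading is used here, consistent with the diffusion length scale,
#' and the constants are configurable.
#'
#' @param dz_nominal nominal axial detection thickness dz (um).
#' @param corr_sqrt_coeff coefficient of `sqrt(D)` in the corrected
#'   thickness (um per sqrt(um^2/s)).
#' @param corr_intercept_b additive correction constant (um).
#' @param series_tolerance truncation tolerance for the image-series sum.
#' @param quadrature_points number of Gauss-Legendre nodes (>= 64).
#' @return A `detection_slice` object.
#' @export
detection_slice <- function(dz_nominal = 0.700, corr_sqrt_coeff = 0.15716,
                            corr_intercept_b = 0.20811,
                            series_tolerance = 1e-10, quadrature_points = 64) {
  if (dz_nominal <= 0) stop_mk("dz_nominal must be > 0")
  if (quadrature_points < 64) stop_mk("quadrature_points must be >= 64")
  if (series_tolerance <= 0) stop_mk("series_tolerance must be > 0")
  structure(list(dz_nominal = dz_nominal, corr_sqrt_coeff = corr_sqrt_coeff,
                 corr_intercept_b = corr_intercept_b,
                 series_tolerance = series_tolerance,
                 quadrature_points = as.integer(quadrature_points)),
            class = "detection_slice")
}

#' Corrected axial detection thickness
#'
#' `dz_eff = dz_nominal + corr_sqrt_coeff * sqrt(d_free) + corr_intercept_b`;
#' monotone non-decreasing in `d_free`.
#'
#' @param d_free free diffusion coefficient (um^2/s, >= 0).
#' @param slice a [detection_slice()].
#' @return effective thickness (um).
#' @export
#' @examples
#' corrected_dz(0)  # 0.90811
#' corrected_dz(4)  # 1.22243
corrected_dz <- function(d_free, slice = detection_slice()) {
  if (any(d_free < 0)) stop_mk("d_free must be >= 0")
  slice$dz_nominal + slice$corr_sqrt_coeff * sqrt(d_free) + slice$corr_intercept_b
}

# Survival probability of Brownian z-motion between absorbing walls at +/- a,
# started at z, after time t (method of images; alternating erfc series).
z_survival_series <- function(z, a, d, t, tol = 1e-10, nmax = 100) {
  if (d * t <= 0) return(rep(1, length(z)))
  s <- sqrt(4 * d * t)
  total <- rep(0, length(z))
  for (n in 0:nmax) {
    term <- (-1)^n * (erfc(((2 * n + 1) * a - z) / s) +
                        erfc(((2 * n + 1) * a + z) / s))
    total <- total + term
    if (max(abs(term)) < tol) break
  }
  pmin(pmax(1 - total, 0), 1)
}

#' Axial defocus-loss correction factor Z_CORR
#'
#' Fraction of free molecules (diffusion coefficient `d_free`) still inside
#' the axial detection slice after a lag `delta_tau`, under an absorbing-
#' boundary model with the corrected effective thickness
#' (see [corrected_dz()]):
#' the slice-average, over a uniform start position, of the image-method
#' survival probability between absorbing walls. Evaluated by fixed-order
#' Gauss-Legendre quadrature over the slice with the alternating erfc series
#' truncated at `series_tolerance`. Bound molecules barely move axially, so
#' this factor multiplies only the free component of the two-state
#' jump-length model; without it the apparent bound fraction is inflated.
#'
#' @param d_free free diffusion coefficient (um^2/s, >= 0).
#' @param delta_tau lag time (s, > 0).
#' @param slice a [detection_slice()].
#' @param corrected use the effective thickness from [corrected_dz()]
#'   (default); `FALSE` evaluates the raw absorbing-slab model at the nominal
#'   thickness. Note that with the correction the slab width grows like
#'   `sqrt(d_free)` — the same scaling as the diffusion length — so the
#'   corrected factor tends to a small positive constant as `d_free` grows,
#'   whereas the uncorrected factor tends to 0.
#' @return a fraction in `[0, 1]`; 1 when `d_free = 0`.
#' @export
z_corr <- function(d_free, delta_tau, slice = detection_slice(),
                   corrected = TRUE) {
  if (d_free < 0) stop_mk("d_free must be >= 0")
  if (delta_tau <= 0) stop_mk("delta_tau must be > 0")
  if (d_free == 0) return(1)
  a <- if (corrected) corrected_dz(d_free, slice) / 2 else slice$dz_nominal / 2
  gl <- pracma::gaussLegendre(slice$quadrature_points, -a, a)
  surv <- z_survival_series(gl$x, a, d_free, delta_tau,
                            tol = slice$series_tolerance)
  val <- sum(gl$w * surv) / (2 * a)
  min(max(val, 0), 1)
}

#' Discrete-frame in-slice survival probabilities
#'
#' Exact defocus weights for discrete-frame detection: the probability that
#' a molecule diffusing with coefficient `d`, inside the axial slice at one
#' frame, is inside the slice at each of the next `n_lags` frame checks
#' (free motion in between, uniform stationary start). Computed by iterating
#' the Gaussian transfer operator restricted to the slice on a trapezoid
#' grid. Unlike the absorbing-boundary factor [z_corr()], which compensates
#' discrete checking through an enlarged effective thickness, this is the
#' exact quantity for frame-sampled data; the two agree to a few percent
#' over the usual lag range.
#'
#' @param d diffusion coefficient (um^2/s, >= 0).
#' @param frame_interval time between frame checks (s).
#' @param n_lags number of consecutive checks.
#' @param slice a [detection_slice()]; the nominal (physical) thickness is
#'   used.
#' @param m grid points across the slice.
#' @return numeric vector of length `n_lags`: survival after 1..n_lags
#'   frames.
#' @export
defocus_survival <- function(d, frame_interval, n_lags,
                             slice = detection_slice(), m = 151) {
  a <- slice$dz_nominal / 2
  if (d <= 0) return(rep(1, n_lags))
  z <- seq(-a, a, length.out = m)
  h <- z[2] - z[1]
  w <- rep(h, m); w[c(1, m)] <- h / 2
  s <- sqrt(2 * d * frame_interval)
  M <- outer(z, z, function(zi, zj) dnorm(zj - zi, sd = s)) * rep(w, each = m)
  p0 <- w / (2 * a)
  v <- rep(1, m)
  out <- numeric(n_lags)
  for (k in seq_len(n_lags)) {
    v <- M %*% v
    out[k] <- sum(p0 * v)
  }
  pmin(pmax(out, 0), 1)
}

#' Jump-length histograms over multiple lag times
#'
#' Pools, for each lag `k` in `lags`, the Euclidean displacements between
#' localizations exactly `k` frames apart within each trajectory. Pairs that
#' span a blink gap (any missing intermediate frame) are skipped, so only
#' uninterrupted runs of consecutive detections contribute. Counts are
#' normalized to an empirical probability density over the bins.
#'
#' @param tracks a [trajectory_set()].
#' @param lags integer frame multiples (subset of 1..7 by default).
#' @param bin_width histogram bin width (um).
#' @param r_max histogram upper edge (um).
#' @return A `jump_length_histogram`: list of per-lag entries
#'   (`lag_frames`, `delta_tau`, `edges`, `mid`, `counts`, `density`,
#'   `n_jumps`), with attributes `frame_interval`, `bin_width`.
#' @export
jump_histogram <- function(tracks, lags = 1:7, bin_width = 0.01, r_max = 1.2) {
  stopifnot(inherits(tracks, "trajectory_set"))
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1)) stop_mk("lags must be >= 1 frame")
  dt <- frame_interval(tracks)
  edges <- seq(0, r_max, by = bin_width)
  ord <- order(tracks$trajectory_id, tracks$frame)
  id <- tracks$trajectory_id[ord]; fr <- tracks$frame[ord]
  x <- tracks$x_um[ord]; y <- tracks$y_um[ord]
  n <- length(id)
  # maximal runs of consecutive frames within a trajectory
  newrun <- c(TRUE, id[-1] != id[-n] | diff(fr) != 1L)
  run <- cumsum(newrun)
  out <- list()
  for (k in lags) {
    if (n > k) {
      i <- seq_len(n - k)
      ok <- run[i] == run[i + k]
      r <- sqrt((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)[ok]
    } else r <- numeric(0)
    if (!length(r)) {
      warning(sprintf("no jump pairs at lag %d; lag omitted", k))
      next
    }
    r <- pmin(r, r_max - 1e-12)  # clamp rare overshoots into the last bin
    counts <- tabulate(findInterval(r, edges, rightmost.closed = TRUE),
                       nbins = length(edges) - 1)
    out[[as.character(k)]] <- list(
      lag_frames = k, delta_tau = k * dt, edges = edges,
      mid = (edges[-1] + edges[-length(edges)]) / 2,
      counts = counts, density = counts / (sum(counts) * bin_width),
      n_jumps = sum(counts))
  }
  if (!length(out)) stop_mk("no jump pairs at any requested lag")
  structure(out, frame_interval = dt, bin_width = bin_width,
            class = "jump_length_histogram")
}

#' @export
print.jump_length_histogram <- function(x, ...) {
  cat("Jump-length histograms\n")
  for (h in x)
    cat(sprintf("  lag %d (%.1f ms): %d jumps\n",
                h$lag_frames, 1000 * h$delta_tau, h$n_jumps))
  invisible(x)
}

#' Two-state jump-length model density
#'
#' The steady-state two-state model for the distribution of 2D jump lengths
#' `r` at lag `delta_tau`: a bound Rayleigh component with scale
#' `2 (D_bound dtau + sigma^2)` plus a free Rayleigh component with scale
#' `2 (D_free dtau + sigma^2)` weighted by the defocus-loss factor
#' [z_corr()]:
#' \deqn{P(r) = F_B \frac{r}{2 (D_B \Delta\tau + \sigma^2)}
#'   e^{-r^2 / (4 (D_B \Delta\tau + \sigma^2))} +
#'   Z_{CORR} (1 - F_B) \frac{r}{2 (D_F \Delta\tau + \sigma^2)}
#'   e^{-r^2 / (4 (D_F \Delta\tau + \sigma^2))}}
#' The raw model is unnormalized (it integrates to
#' `F_B + Z_CORR (1 - F_B)`); set `normalize = TRUE` to divide by that mass
#' so the result is a proper density comparable with empirical histograms.
#'
#' @param r jump length(s), um (>= 0).
#' @param delta_tau lag time (s).
#' @param f_bound bound fraction in `[0, 1]`.
#' @param d_free,d_bound diffusion coefficients (um^2/s).
#' @param sigma localization error (um).
#' @param slice a [detection_slice()].
#' @param normalize divide by the model mass so the density integrates to 1.
#' @param zc optional precomputed `z_corr` value (avoids re-evaluation in
#'   fitting loops).
#' @return density values (1/um).
#' @export
two_state_density <- function(r, delta_tau, f_bound, d_free, d_bound,
                              sigma = 0.035, slice = detection_slice(),
                              normalize = FALSE, zc = NULL) {
  if (any(r < 0)) stop_mk("r must be >= 0")
  vb <- d_bound * delta_tau + sigma^2
  vf <- d_free * delta_tau + sigma^2
  if (is.null(zc)) zc <- z_corr(d_free, delta_tau, slice)
  dens <- f_bound * r / (2 * vb) * exp(-r^2 / (4 * vb)) +
    zc * (1 - f_bound) * r / (2 * vf) * exp(-r^2 / (4 * vf))
  if (normalize) dens <- dens / (f_bound + zc * (1 - f_bound))
  dens
}

#' Fit the two-state model to jump-length histograms
#'
#' Joint nonlinear least squares across all lags: minimizes the summed
#' squared difference between the per-lag empirical densities and the
#' per-lag normalized model density, over `(f_bound, d_free, d_bound)` with
#' the localization error fixed (default 0.035 um) or fitted. Both sides of
#' the comparison are proper densities: the model carries the
#' defocus-loss factor [z_corr()] on its free component and is then
#' renormalized per lag, mirroring how the empirical histograms are
#' conditioned on molecules remaining detectable. Optimization is
#' box-constrained L-BFGS-B with a Latin-hypercube multi-start (fixed
#' sub-seeds), keeping the best converged run.
#'
#' @param hist a `jump_length_histogram` with >= 2 lags.
#' @param slice a [detection_slice()].
#' @param defocus how the out-of-focus loss of moving molecules is modelled:
#'   `"discrete"` (default) uses the exact frame-sampled in-slice survival
#'   ([defocus_survival()]) for both components; `"corrected_dz"` uses the
#'   absorbing-boundary factor [z_corr()] with the corrected effective
#'   thickness on the free component only.
#' @param sigma_fixed localization error (um) to hold fixed, or `"fit"` to
#'   estimate it within `[0.02, 0.06]` um.
#' @param bounds list with `d_free`, `d_bound`, `f_bound` ranges; defaults
#'   `d_free` in `[0.15, 20]` (upper limit matching the tracking setting of a
#'   maximal expected diffusion constant of 20 um^2/s), `d_bound` in
#'   `[5e-4, 0.1]`, `f_bound` in `[0, 1]`.
#' @param n_restarts number of Latin-hypercube starting points (>= 5).
#' @param restart_seed seed for the Latin-hypercube draw.
#' @return A `two_state_fit`: list with `f_bound`, `d_free`, `d_bound`,
#'   `sigma`, `sigma_fitted`, `residual`, `converged`, `zc` (per-lag
#'   defocus factors), `hist`, `slice`.
#' @export
fit_two_state <- function(hist, slice = detection_slice(),
                          defocus = c("discrete", "corrected_dz"),
                          sigma_fixed = 0.035,
                          bounds = list(d_free = c(0.15, 20),
                                        d_bound = c(5e-4, 0.1),
                                        f_bound = c(0, 1)),
                          n_restarts = 6, restart_seed = 1L) {
  stopifnot(inherits(hist, "jump_length_histogram"))
  if (length(hist) < 2) stop_mk("need >= 2 lags, got %d", length(hist))
  defocus <- match.arg(defocus)
  fit_sigma <- identical(sigma_fixed, "fit")
  sig_range <- c(0.02, 0.06)

  dt1 <- attr(hist, "frame_interval")
  lag_tau <- vapply(hist, function(h) h$delta_tau, numeric(1))
  lag_frames <- vapply(hist, function(h) h$lag_frames, numeric(1))
  kmax <- max(lag_frames)
  mids <- lapply(hist, function(h) h$mid)
  emp <- lapply(hist, function(h) h$density)

  if (defocus == "discrete") {
    sf_at <- surv_interpolator(bounds$d_free, dt1, kmax, slice)
    sb_at <- surv_interpolator(bounds$d_bound, dt1, kmax, slice)
  }
  weights_at <- function(df, db) {
    if (defocus == "discrete") {
      list(sf = sf_at(df)[lag_frames], sb = sb_at(db)[lag_frames])
    } else {
      list(sf = vapply(lag_tau, function(tau) z_corr(df, tau, slice),
                       numeric(1)),
           sb = rep(1, length(lag_tau)))
    }
  }

  obj <- function(p) {
    f <- p[1]; df <- p[2]; db <- p[3]
    sg <- if (fit_sigma) p[4] else sigma_fixed
    wts <- weights_at(df, db)
    tot <- 0
    for (j in seq_along(hist)) {
      vb <- db * lag_tau[j] + sg^2
      vf <- df * lag_tau[j] + sg^2
      r <- mids[[j]]
      dens <- f * wts$sb[j] * r / (2 * vb) * exp(-r^2 / (4 * vb)) +
        (1 - f) * wts$sf[j] * r / (2 * vf) * exp(-r^2 / (4 * vf))
      dens <- dens / (f * wts$sb[j] + (1 - f) * wts$sf[j])
      tot <- tot + sum((dens - emp[[j]])^2)
    }
    tot
  }

  lo <- c(bounds$f_bound[1], bounds$d_free[1], bounds$d_bound[1])
  hi <- c(bounds$f_bound[2], bounds$d_free[2], bounds$d_bound[2])
  if (fit_sigma) { lo <- c(lo, sig_range[1]); hi <- c(hi, sig_range[2]) }

  n_restarts <- max(5L, as.integer(n_restarts))
  lh <- withr_seed(restart_seed, lhs::randomLHS(n_restarts, length(lo)))
  # the parameters live on very different scales (f ~ 0.1, D_free ~ 1,
  # D_bound ~ 0.01): scale the search accordingly
  pscale <- pmax((hi - lo) / 10, 1e-4)
  fits <- vector("list", n_restarts)
  best <- NULL
  for (i in seq_len(n_restarts)) {
    p0 <- lo + lh[i, ] * (hi - lo)
    res <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 1000, parscale = pscale)),
      error = function(e) NULL)
    fits[[i]] <- res
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  # converged: the best run terminated cleanly, or at least two independent
  # restarts agree on the optimum (a line-search stall at the solution)
  converged <- FALSE
  if (!is.null(best)) {
    agree <- sum(vapply(fits, function(r) {
      !is.null(r) && abs(r$value - best$value) <= 1e-6 * (1 + abs(best$value))
    }, logical(1)))
    converged <- best$convergence %in% c(0L, 1L) || agree >= 2
  }
  if (is.null(best)) {
    warning("all two-state fit restarts failed")
    best <- list(par = (lo + hi) / 2, value = NA_real_)
  }
  p <- best$par
  sg <- if (fit_sigma) p[4] else sigma_fixed
  wts <- weights_at(p[2], p[3])
  structure(list(f_bound = p[1], d_free = p[2], d_bound = p[3], sigma = sg,
                 sigma_fitted = fit_sigma, residual = best$value,
                 converged = converged, defocus = defocus,
                 zc = setNames(wts$sf, names(hist)),
                 zc_bound = setNames(wts$sb, names(hist)),
                 hist = hist, slice = slice),
            class = "two_state_fit")
}

# interpolator for discrete in-slice survival over a diffusion range:
# precomputes survival curves on a log grid of D and interpolates per lag
surv_interpolator <- function(d_range, dt1, kmax, slice, n_grid = 30) {
  a <- slice$dz_nominal / 2
  dg <- exp(seq(log(max(d_range[1], 1e-6)), log(d_range[2]),
                length.out = n_grid))
  S <- vapply(dg, function(d) {
    s <- sqrt(2 * d * dt1)
    m <- min(901, max(151, ceiling(6 * a / max(s, 1e-6))))
    defocus_survival(d, dt1, kmax, slice, m = m)
  }, numeric(kmax))
  S <- matrix(S, nrow = kmax)
  function(d) {
    d <- min(max(d, dg[1]), dg[length(dg)])
    vapply(seq_len(kmax), function(k) {
      approx(log(dg), S[k, ], xout = log(d), rule = 2)$y
    }, numeric(1))
  }
}

# evaluate expr after set.seed(seed), restoring the RNG state afterwards
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state jump-length model fit\n")
  cat(sprintf("  F_bound = %.3f\n", x$f_bound))
  cat(sprintf("  D_free  = %.3g um^2/s   D_bound = %.3g um^2/s   sigma = %g um%s\n",
              x$d_free, x$d_bound, x$sigma,
              if (x$sigma_fitted) " (fitted)" else " (fixed)"))
  cat(sprintf("  residual = %.4g (%s), %d lags, defocus model: %s\n",
              x$residual, if (x$converged) "converged" else "NOT converged",
              length(x$hist), x$defocus))
  invisible(x)
}

#' @export
coef.two_state_fit <- function(object, ...) {
  c(f_bound = object$f_bound, d_free = object$d_free,
    d_bound = object$d_bound, sigma = object$sigma)
}

#' @export
predict.two_state_fit <- function(object, r, delta_tau, ...) {
  lag_tau <- vapply(object$hist, function(h) h$delta_tau, numeric(1))
  j <- which.min(abs(lag_tau - delta_tau))
  sf <- object$zc[j]; sb <- object$zc_bound[j]
  vb <- object$d_bound * delta_tau + object$sigma^2
  vf <- object$d_free * delta_tau + object$sigma^2
  dens <- object$f_bound * sb * r / (2 * vb) * exp(-r^2 / (4 * vb)) +
    (1 - object$f_bound) * sf * r / (2 * vf) * exp(-r^2 / (4 * vf))
  unname(dens / (object$f_bound * sb + (1 - object$f_bound) * sf))
}

#' @export
plot.two_state_fit <- function(x, lags = names(x$hist), ...) {
  old <- par(mfrow = c(1, length(lags)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (nm in lags) {
    h <- x$hist[[nm]]
    plot(h$mid, h$density, type = "h", col = "grey60",
         xlab = "jump length (um)", ylab = "density",
         main = sprintf("lag %.1f ms", 1000 * h$delta_tau), ...)
    lines(h$mid, predict(x, h$mid, h$delta_tau), col = 2, lwd = 2)
  }
  invisible(x)
}

#' Monte-Carlo oracle for the axial defocus loss
#'
#' Independent brute-force estimate of the quantity [z_corr()] computes:
#' simulates Brownian z-paths from a uniform start inside the slice,
#' absorbing them at the effective slice boundaries (with a Brownian-bridge
#' crossing correction between steps so discretization does not bias the
#' absorption probability), and returns the surviving fraction at
#' `delta_tau`. Used to validate the series-plus-quadrature evaluation; not
#' part of the fitting path.
#'
#' @param d_free diffusion coefficient (um^2/s).
#' @param delta_tau lag time (s).
#' @param slice a [detection_slice()].
#' @param n_paths number of simulated paths.
#' @param n_steps time steps per path.
#' @param seed RNG seed.
#' @return surviving fraction in `[0, 1]`.
#' @export
z_corr_mc <- function(d_free, delta_tau, slice = detection_slice(),
                      n_paths = 1e5, n_steps = 200, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  a <- corrected_dz(d_free, slice) / 2
  dt <- delta_tau / n_steps
  sd_step <- sqrt(2 * d_free * dt)
  z <- runif(n_paths, -a, a)
  alive <- rep(TRUE, n_paths)
  for (i in seq_len(n_steps)) {
    zn <- z + rnorm(n_paths, 0, sd_step)
    hit <- abs(zn) >= a
    # Brownian-bridge probability of touching a wall between the endpoints
    up <- exp(-pmax(0, (a - z) * (a - zn)) / (d_free * dt))
    dn <- exp(-pmax(0, (a + z) * (a + zn)) / (d_free * dt))
    cross <- runif(n_paths) < pmin(1, up + dn - up * dn)
    dead <- alive & (hit | cross)
    alive <- alive & !dead
    z <- ifelse(alive, zn, z)
  }
  mean(alive)
}
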