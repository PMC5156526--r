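#' Configuration of the fixation-artifact particle model
#'
#' Parameters of a stochastic particle model of chemical fixation acting on
#' a dynamically bound TF in a mitotic cell: a 2D cell disc of radius
#' `r_cell` containing a concentric chromosome disc of radius `r_chr`;
#' free particles diffuse with `d_free` (reflecting at the cell boundary),
#' bind with hazard `k_on_star` while inside the chromosome disc, and
#' unbind with hazard `k_off`. From `t = 0` the fixative enters through the
#' membrane and diffuses inward, producing a concentration front
#' `C(radius, t)` (see [pfa_concentration()]); every non-crosslinked
#' particle acquires crosslinks with hazard `k_x * C` and is then frozen at
#' its position forever. Mode `"uniform_instant"` instead freezes all
#' particles simultaneously at `t = 0`, emulating uniform cryofixation
#' (high-pressure freezing / freeze substitution).
#'
#' Geometry and rate constants are modelling choices, not measured values:
#' the published description of the artifact is verbal/schematic, so the 2D
#' concentric-disc geometry, the erfc inward-diffusion front and the linear
#' crosslink hazard are this package's concrete rendering of it. Only
#' directional predictions (dose dependence, k_off dependence, uniform-
#' fixation rescue) are quantitative claims. The default `d_pfa` and `k_x`
#' place the model in the front-limited regime the artifact requires:
#' effective fixative penetration is slow (the membrane and crowded
#' cytoplasm limit transport far below the free-solution diffusivity of
#' formaldehyde), so the cytoplasmic pool near the membrane is captured
#' while the chromosome interior is still unfixed, and at low dose fixation
#' is still incomplete a minute after addition.
#'
#' @param r_cell cell radius (um).
#' @param r_chr chromosome-disc radius (um), `0 < r_chr < r_cell`.
#' @param d_free free diffusion coefficient (um^2/s).
#' @param k_on_star binding hazard inside the chromosome disc (1/s).
#' @param k_off unbinding hazard (1/s).
#' @param c0 fixative dose in relative units (1 = "1% PFA").
#' @param d_pfa fixative diffusivity (um^2/s).
#' @param k_x crosslinking rate constant (1/(s * dose unit)).
#' @param n_particles number of simulated TF molecules.
#' @param duration_s simulated time (s).
#' @param dt time step (s); must satisfy
#'   `dt <= 0.1 / max(k_off, k_on_star, k_x * c0)`.
#' @param mode `"gradient"` (diffusing fixative front) or
#'   `"uniform_instant"` (all particles frozen at t = 0).
#' @param record_every trace recording interval (s).
#' @return A `fixation_config` object.
#' @export
fixation_config <- function(r_cell = 8, r_chr = 4, d_free = 2,
                            k_on_star = 2, k_off = 0.5, c0 = 1,
                            d_pfa = 0.3, k_x = 0.05, n_particles = 2000,
                            duration_s = 70, dt = 0.02,
                            mode = c("gradient", "uniform_instant"),
                            record_every = 1) {
  mode <- match.arg(mode)
  if (!(r_chr > 0 && r_chr < r_cell)) stop_mk("need 0 < r_chr < r_cell")
  if (any(c(d_free, k_on_star, k_off, c0, d_pfa, k_x) < 0))
    stop_mk("all rates and coefficients must be >= 0")
  lim <- 0.1 / max(k_off, k_on_star, k_x * c0, 1e-12)
  if (dt > lim)
    stop_mk("time step %g s violates stability limit %.3g s (0.1 / fastest hazard)",
            dt, lim)
  structure(list(r_cell = r_cell, r_chr = r_chr, d_free = d_free,
                 k_on_star = k_on_star, k_off = k_off, c0 = c0,
                 d_pfa = d_pfa, k_x = k_x,
                 n_particles = as.integer(n_particles),
                 duration_s = duration_s, dt = dt, mode = mode,
                 record_every = record_every),
            class = "fixation_config")
}

#' Fixative concentration at a point of the cell
#'
#' Inward-diffusion approximation of the fixative front: treating the
#' membrane as a planar source along the radial depth coordinate, the
#' concentration at depth `r_cell - radius` after time `t` is
#' `C = c0 * erfc((r_cell - radius) / sqrt(4 * d_pfa * t))` — full dose at
#' the membrane immediately, a wave of crosslinking potential moving inward,
#' and `C -> c0` everywhere as `t -> Inf`. At `t = 0` interior points see
#' zero concentration.
#'
#' @param radius_from_center radial position(s), um, in `[0, r_cell]`.
#' @param t time since fixative addition (s, >= 0).
#' @param cfg a [fixation_config()].
#' @return concentration(s) in dose units.
#' @export
pfa_concentration <- function(radius_from_center, t, cfg) {
  if (any(radius_from_center < 0 | radius_from_center > cfg$r_cell))
    stop_mk("radius must lie in [0, r_cell]")
  if (t < 0) stop_mk("t must be >= 0")
  depth <- cfg$r_cell - radius_from_center
  if (t == 0) return(ifelse(depth > 0, 0, cfg$c0))
  cfg$c0 * erfc(depth / sqrt(4 * cfg$d_pfa * t))
}

# stationary initial state: bound particles inside the chromosome disc at
# density u * k_on_star / k_off, free particles uniform at density u
init_fixation_state <- function(cfg) {
  n <- cfg$n_particles
  a_cell <- pi * cfg$r_cell^2
  a_chr <- pi * cfg$r_chr^2
  ratio <- if (cfg$k_off > 0) cfg$k_on_star / cfg$k_off else
    if (cfg$k_on_star > 0) Inf else 0
  p_bound <- if (is.infinite(ratio)) 1 else
    (a_chr * ratio) / (a_cell + a_chr * ratio)
  bound <- runif(n) < p_bound
  r <- ifelse(bound, cfg$r_chr * sqrt(runif(n)), cfg$r_cell * sqrt(runif(n)))
  th <- runif(n, 0, 2 * pi)
  list(x = r * cos(th), y = r * sin(th), bound = bound)
}

enrichment_stat <- function(x, y, cfg) {
  r2 <- x^2 + y^2
  n_chr <- sum(r2 <= cfg$r_chr^2)
  dens_chr <- n_chr / (pi * cfg$r_chr^2)
  dens_cell <- length(x) / (pi * cfg$r_cell^2)
  dens_chr / dens_cell
}

#' Simulate the fixation-artifact particle model
#'
#' Runs the model described in [fixation_config()]: particles are
#' initialized at the kinetic stationary state, then stepped on a grid of
#' `dt`. Per step, non-crosslinked free particles take Gaussian diffusion
#' steps (reflected at the cell boundary), bind with probability
#' `1 - exp(-k_on_star dt)` while inside the chromosome disc, bound
#' particles unbind likewise, and every non-crosslinked particle becomes
#' crosslinked with probability `1 - exp(-k_x C(r, t) dt)`, freezing it in
#' place and state forever. In mode `"uniform_instant"` all particles are
#' frozen at `t = 0` and the trace is flat by construction.
#'
#' @param cfg a [fixation_config()].
#' @param seed integer RNG seed.
#' @return A `fixation_trace`: data frame with `time_s`, `enrichment`
#'   (mean particle density in the chromosome disc over mean density in the
#'   cell — the particle analogue of the normalized chromosome intensity),
#'   `frac_crosslinked` and `frac_bound` (among non-crosslinked particles;
#'   `NA` once all are crosslinked), with the config attached.
#' @export
simulate_fixation <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "fixation_config"))
  lim <- 0.1 / max(cfg$k_off, cfg$k_on_star, cfg$k_x * cfg$c0, 1e-12)
  if (cfg$dt > lim)
    stop_mk("time step %g s violates stability limit %.3g s", cfg$dt, lim)
  if (!is.null(seed)) set.seed(seed)
  st <- init_fixation_state(cfg)
  x <- st$x; y <- st$y; bound <- st$bound
  n <- cfg$n_particles
  xl <- rep(cfg$mode == "uniform_instant", n)
  steps <- ceiling(cfg$duration_s / cfg$dt)
  rec_every <- max(1L, round(cfg$record_every / cfg$dt))
  sd_step <- sqrt(2 * cfg$d_free * cfg$dt)
  p_on <- 1 - exp(-cfg$k_on_star * cfg$dt)
  p_off <- 1 - exp(-cfg$k_off * cfg$dt)

  rec_t <- rec_e <- rec_x <- rec_b <- numeric(0)
  record <- function(t) {
    rec_t <<- c(rec_t, t)
    rec_e <<- c(rec_e, enrichment_stat(x, y, cfg))
    rec_x <<- c(rec_x, mean(xl))
    rec_b <<- c(rec_b, if (all(xl)) NA_real_ else mean(bound[!xl]))
  }
  record(0)
  for (s in seq_len(steps)) {
    t <- s * cfg$dt
    mob <- !xl & !bound
    if (any(mob)) {
      xn <- x[mob] + rnorm(sum(mob), 0, sd_step)
      yn <- y[mob] + rnorm(sum(mob), 0, sd_step)
      rn <- sqrt(xn^2 + yn^2)
      out <- rn > cfg$r_cell
      if (any(out)) { # radial reflection at the membrane
        fac <- (2 * cfg$r_cell - rn[out]) / rn[out]
        xn[out] <- xn[out] * fac
        yn[out] <- yn[out] * fac
      }
      x[mob] <- xn; y[mob] <- yn
    }
    live <- !xl
    r2 <- x^2 + y^2
    # binding / unbinding among non-crosslinked particles
    can_bind <- live & !bound & (r2 <= cfg$r_chr^2)
    if (any(can_bind))
      bound[can_bind] <- runif(sum(can_bind)) < p_on
    can_unbind <- live & bound
    if (any(can_unbind)) {
      ub <- runif(sum(can_unbind)) < p_off
      bound[which(can_unbind)[ub]] <- FALSE
    }
    if (cfg$mode == "gradient" && cfg$k_x * cfg$c0 > 0 && any(live)) {
      conc <- pfa_concentration(pmin(sqrt(r2[live]), cfg$r_cell), t, cfg)
      hit <- runif(sum(live)) < 1 - exp(-cfg$k_x * conc * cfg$dt)
      xl[which(live)[hit]] <- TRUE
    }
    if (s %% rec_every == 0) record(t)
  }
  structure(data.frame(time_s = rec_t, enrichment = rec_e,
                       frac_crosslinked = rec_x, frac_bound = rec_b),
            config = cfg, class = c("fixation_trace", "data.frame"))
}

#' @export
print.fixation_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Fixation trace (%s mode, dose %g): %d time points over %g s\n",
              cfg$mode, cfg$c0, nrow(x), max(x$time_s)))
  cat(sprintf("  enrichment %.2f -> %.2f; crosslinked %.0f%% at end\n",
              x$enrichment[1], tail(x$enrichment, 1),
              100 * tail(x$frac_crosslinked, 1)))
  invisible(x)
}

#' @export
plot.fixation_trace <- function(x, ...) {
  plot(x$time_s, x$enrichment, type = "l", xlab = "time since fixative (s)",
       ylab = "apparent chromosome enrichment", ...)
  invisible(x)
}

#' Dose-response of the fixation artifact
#'
#' Runs [simulate_fixation()] for each dose and replicate seed and reports
#' the apparent enrichment at `at_time` (default 60 s) after fixative
#' addition, the model analogue of a fixative titration experiment.
#'
#' @param cfg a [fixation_config()]; its `c0` is replaced by each dose.
#' @param doses numeric vector of >= 2 doses (relative units).
#' @param replicates replicate simulations per dose (>= 10 recommended).
#' @param at_time readout time after addition (s).
#' @param seed base seed; replicate `i` at dose `j` uses
#'   `seed + 1000 * j + i`.
#' @return data frame with `dose`, `mean_enrichment`, `se`, `n`; attribute
#'   `per_run` holds the full dose x replicate matrix.
#' @export
dose_response <- function(cfg, doses, replicates = 20, at_time = 60, seed = 1) {
  if (length(doses) < 2) stop_mk("need >= 2 doses")
  per <- matrix(NA_real_, length(doses), replicates,
                dimnames = list(dose = doses, NULL))
  for (j in seq_along(doses)) {
    cfg_j <- cfg
    cfg_j$c0 <- doses[j]
    for (i in seq_len(replicates)) {
      tr <- simulate_fixation(cfg_j, seed = seed + 1000 * j + i)
      per[j, i] <- approx(tr$time_s, tr$enrichment, xout = at_time, rule = 2)$y
    }
  }
  structure(data.frame(dose = doses,
                       mean_enrichment = rowMeans(per),
                       se = apply(per, 1, sd) / sqrt(replicates),
                       n = replicates),
            per_run = per, class = c("dose_response", "data.frame"))
}
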