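## Mitchell-Schaeffer two-current action potential model: single-cell
## simulation, APD <-> tau_close calibration, physical-voltage templates
## and the UVC-weighted APD field that shapes repolarization.

.cell_cache <- new.env(parent = emptyenv())

.ms_key <- function(params) {
  paste(format(unlist(params[c("V_gate", "tau_in", "tau_out", "tau_open")]),
               digits = 12), collapse = "|")
}

#' Simulate the Mitchell-Schaeffer two-current model
#'
#' Explicit integration of the normalized two-variable model
#' `dv/dt = h v^2 (1 - v)/tau_in - v/tau_out + J_stim`,
#' `dh/dt = (1 - h)/tau_open` below the gate voltage and `-h/tau_close`
#' above it. Rest is `v = 0, h = 1`; a suprathreshold stimulus produces a
#' single action potential.
#'
#' @param params Named list with `V_gate`, `tau_in`, `tau_out`,
#'   `tau_open`, `tau_close` (model time units are ms).
#' @param duration Total simulated time, ms.
#' @param dt Time step, ms; must satisfy `dt <= 0.1 * tau_in`.
#' @param stim_time Stimulus onset, ms (`NA` for no stimulus).
#' @param stim_amp,stim_dur Stimulus current amplitude and duration.
#' @return List with `t`, `v`, `h` sampled every step.
#' @export
ms_simulate <- function(params, duration = 500, dt = 0.025, stim_time = 1,
                        stim_amp = 0.6, stim_dur = 1) {
  if (dt > 0.1 * params$tau_in + 1e-12) {
    stop("dt = ", dt, " exceeds stability bound 0.1 * tau_in = ",
         0.1 * params$tau_in)
  }
  out <- .ms_run(params, params$tau_close, duration, dt, stim_time,
                 stim_amp, stim_dur)
  list(t = out$t, v = drop(out$v), h = drop(out$h))
}

## Core integrator, vectorized over a tau_close vector (columns).
.ms_run <- function(params, tau_close, duration, dt, stim_time,
                    stim_amp = 0.6, stim_dur = 1) {
  nt <- ceiling(duration / dt) + 1L
  m <- length(tau_close)
  v <- matrix(0, nt, m); h <- matrix(1, nt, m)
  vv <- rep(0, m); hh <- rep(1, m)
  tg <- (seq_len(nt) - 1L) * dt
  with_stim <- !is.na(stim_time)
  for (i in 2:nt) {
    t_now <- tg[i - 1]
    J <- if (with_stim && t_now >= stim_time && t_now < stim_time + stim_dur)
      stim_amp else 0
    dv <- hh * vv^2 * (1 - vv) / params$tau_in - vv / params$tau_out + J
    dh <- ifelse(vv < params$V_gate, (1 - hh) / params$tau_open,
                 -hh / tau_close)
    vv <- pmin(pmax(vv + dt * dv, 0), 1.000001)
    hh <- pmin(pmax(hh + dt * dh, 0), 1)
    v[i, ] <- vv; h[i, ] <- hh
  }
  list(t = tg, v = v, h = h)
}

## APD per column: time from maximum upstroke slope to the downstroke
## crossing of V_gate. NA when no action potential was elicited.
.measure_apd <- function(t, v, v_gate) {
  if (!is.matrix(v)) v <- cbind(v)
  apply(v, 2, function(col) {
    if (max(col) < 0.5) return(NA_real_)
    dv <- diff(col)
    iu <- which.max(dv)
    after <- which(col[-seq_len(iu)] < v_gate)
    if (!length(after)) return(NA_real_)
    t[iu + after[1]] - t[iu]
  })
}

## Monotone tau_close -> APD relation for a parameter set (cached).
.apd_relation <- function(params, dt = 0.025) {
  key <- .ms_key(params)
  rel <- .cell_cache[[paste0("rel|", key)]]
  if (!is.null(rel)) return(rel)
  taus <- exp(seq(log(5), log(700), length.out = 36))
  run <- .ms_run(params, taus, duration = 1100, dt = dt, stim_time = 1)
  apds <- .measure_apd(run$t, run$v, params$V_gate)
  ok <- !is.na(apds)
  rel <- list(tau = taus[ok], apd = apds[ok])
  o <- order(rel$apd)
  rel$tau <- rel$tau[o]; rel$apd <- rel$apd[o]
  .cell_cache[[paste0("rel|", key)]] <- rel
  rel
}

#' Calibrate tau_close against a target action potential duration
#'
#' Uses the monotone numeric relation between `tau_close` and the measured
#' APD (cached per parameter set), with secant refinement so the returned
#' value reproduces the target within 1 ms.
#'
#' @inheritParams ms_simulate
#' @param apd_target Target APD, ms.
#' @param tol Acceptable |measured - target|, ms.
#' @return The calibrated `tau_close`.
#' @export
calibrate_tau_close <- function(params, apd_target, dt = 0.025, tol = 1) {
  rel <- .apd_relation(params, dt)
  if (apd_target < min(rel$apd) || apd_target > max(rel$apd)) {
    stop(sprintf("APD target %.1f ms outside achievable range [%.1f, %.1f] ms",
                 apd_target, min(rel$apd), max(rel$apd)))
  }
  tau <- stats::approx(rel$apd, rel$tau, xout = apd_target)$y
  for (i in 1:6) {
    run <- .ms_run(params, tau, duration = apd_target + 300, dt = dt,
                   stim_time = 1)
    apd <- .measure_apd(run$t, run$v, params$V_gate)
    if (abs(apd - apd_target) <= tol * 0.5) break
    slope <- (max(rel$tau) - min(rel$tau)) / (max(rel$apd) - min(rel$apd))
    i2 <- findInterval(apd_target, rel$apd)
    if (i2 >= 1 && i2 < length(rel$apd)) {
      slope <- (rel$tau[i2 + 1] - rel$tau[i2]) / (rel$apd[i2 + 1] - rel$apd[i2])
    }
    tau <- tau + (apd_target - apd) * slope
  }
  tau
}

#' Generate a physical-voltage action potential template
#'
#' Runs the cell model with `tau_close` calibrated to the target APD and
#' maps the normalized trace to physical voltage
#' `V = V_min + v (V_max - V_min)`; the resting value is `V_min` exactly.
#'
#' @inheritParams calibrate_tau_close
#' @param dt_out Output sampling interval, ms.
#' @return List of class `ap_template`: `trace` (mV), `dt` (ms), `apd`
#'   (ms, measured), `upstroke_offset` (ms from trace start to the
#'   maximum-slope sample), `V_min`, `V_max`.
#' @export
make_template <- function(params, apd_target, dt = 0.025, dt_out = 1) {
  tau <- calibrate_tau_close(params, apd_target, dt)
  run <- .ms_run(params, tau, duration = apd_target + 280, dt = dt,
                 stim_time = 1)
  v <- drop(run$v)
  stride <- max(round(dt_out / dt), 1L)
  idx <- seq(1, length(v), by = stride)
  vs <- v[idx]
  trace <- params$V_min + vs * (params$V_max - params$V_min)
  apd <- .measure_apd(run$t, run$v, params$V_gate)
  structure(list(trace = trace, dt = dt_out, apd = apd,
                 upstroke_offset = (which.max(diff(vs)) - 1) * dt_out,
                 V_min = params$V_min, V_max = params$V_max,
                 tau_close = tau),
            class = "ap_template")
}

#' Build a template bank over a grid of APDs
#'
#' Calibrates `tau_close` across an APD grid (1 ms spacing by default),
#' simulates all cells in one vectorized pass, and stores the physical
#' traces aligned so the maximum-upstroke sample sits at index
#' `align + 1`. Banks are cached per cell-parameter set and grid.
#'
#' @inheritParams make_template
#' @param apd_grid Numeric vector of APDs, ms (regular grid).
#' @param align Number of resting samples kept before the upstroke.
#' @return List of class `template_bank`: `V` (levels x samples, mV),
#'   `apd` (grid), `dt`, `align`, `dur` (per-level ms until the trace
#'   returns to within 1 percent of rest after the upstroke).
#' @export
template_bank <- function(params, apd_grid = seq(140, 260, by = 1),
                          dt = 0.025, dt_out = 1, align = 2) {
  key <- paste0("bank|", .ms_key(params), "|",
                paste(range(apd_grid), collapse = "-"), "|",
                length(apd_grid), "|", dt_out)
  bk <- .cell_cache[[key]]
  if (!is.null(bk)) return(bk)
  rel <- .apd_relation(params, dt)
  grid <- apd_grid[apd_grid >= min(rel$apd) & apd_grid <= max(rel$apd)]
  if (!length(grid)) stop("APD grid entirely outside achievable range")
  taus <- stats::approx(rel$apd, rel$tau, xout = grid)$y
  run <- .ms_run(params, taus, duration = max(grid) + 280, dt = dt,
                 stim_time = 1)
  apds <- .measure_apd(run$t, run$v, params$V_gate)
  ## one secant correction toward the grid targets
  slope <- diff(range(rel$tau)) / diff(range(rel$apd))
  taus <- taus + (grid - apds) * slope
  run <- .ms_run(params, taus, duration = max(grid) + 280, dt = dt,
                 stim_time = 1)
  apds <- .measure_apd(run$t, run$v, params$V_gate)
  stride <- max(round(dt_out / dt), 1L)
  vsub <- run$v[seq(1, nrow(run$v), by = stride), , drop = FALSE]
  ns <- nrow(vsub)
  V <- matrix(params$V_min, length(grid), ns + align)
  dur <- numeric(length(grid))
  amp <- params$V_max - params$V_min
  for (j in seq_along(grid)) {
    iu <- which.max(diff(vsub[, j]))
    tail_v <- vsub[iu:ns, j]
    shifted <- c(rep(0, align), tail_v)
    V[j, seq_along(shifted)] <- params$V_min + shifted * amp
    ip <- which.max(tail_v)
    below <- which(tail_v[ip:length(tail_v)] < 0.10)
    dur[j] <- if (length(below)) (ip - 1 + below[1] - 1) * dt_out else
      (ns - iu) * dt_out
  }
  bk <- structure(list(V = V, apd = grid, apd_measured = apds, dt = dt_out,
                       align = align, dur = dur, V_min = params$V_min,
                       V_max = params$V_max),
                  class = "template_bank")
  .cell_cache[[key]] <- bk
  bk
}

#' Compute the UVC-weighted APD field
#'
#' Evaluates the weighted linear combination
#' `s = q_rho * rho + q_v * vtil + q_phi * (phi/pi) + q_z * z` at every
#' myocardial node (`vtil` is -1 in the LV and +1 in the RV), then min-max
#' normalizes `s` onto `[apd_min, apd_max]`. A spatially constant `s`
#' yields the midpoint everywhere.
#'
#' @param mesh Ventricular `cardiac_mesh` with UVCs.
#' @param tw List with `apd_min`, `apd_max` (ms) and weights `q_rho`,
#'   `q_v`, `q_phi`, `q_z`.
#' @return Numeric per-node APD vector (ms), class `apd_field`.
#' @export
compute_apd_field <- function(mesh, tw) {
  if (is.null(mesh$uvc)) stop("mesh has no universal coordinates")
  if (nrow(mesh$uvc) == 0) stop("empty myocardium")
  stopifnot(tw$apd_min < tw$apd_max)
  vtil <- ifelse(mesh$uvc$v == "rv", 1, -1)
  s <- tw$q_rho * mesh$uvc$rho + tw$q_v * vtil +
    tw$q_phi * (mesh$uvc$phi / pi) + tw$q_z * mesh$uvc$z
  rng <- range(s)
  apd <- if (diff(rng) < 1e-12) {
    rep((tw$apd_min + tw$apd_max) / 2, length(s))
  } else {
    tw$apd_min + (s - rng[1]) / diff(rng) * (tw$apd_max - tw$apd_min)
  }
  structure(apd, class = "apd_field")
}

#' Atrial action potential template
#'
#' Parameterized surrogate template with atrial resting and peak voltages;
#' the fibrotic variant carries a reduced upstroke amplitude and a
#' shortened APD to represent cytokine-remodeled tissue.
#'
#' @param region_kind `"healthy"` or `"fibrotic"`.
#' @param apd_target Target APD for the healthy tissue, ms.
#' @param params Parameter registry (see [default_params()]).
#' @return An `ap_template` (see [make_template()]).
#' @export
make_atrial_template <- function(region_kind = c("healthy", "fibrotic"),
                                 apd_target = 250, params = default_params()) {
  region_kind <- match.arg(region_kind)
  p <- params$ms_atrial
  fb <- params$fibrosis
  if (region_kind == "fibrotic") {
    tpl <- make_template(p, apd_target * fb$apd_factor)
    tpl$trace <- p$V_min + (tpl$trace - p$V_min) * fb$amp_factor
    tpl$V_max <- p$V_min + (p$V_max - p$V_min) * fb$amp_factor
  } else {
    tpl <- make_template(p, apd_target)
  }
  tpl
}

#' Atrial template bank for a region kind
#'
#' @inheritParams make_atrial_template
#' @param apd_grid APD grid, ms.
#' @return A `template_bank`; fibrotic banks have scaled amplitude and the
#'   grid interpreted as pre-remodeling APD.
#' @export
atrial_template_bank <- function(region_kind = c("healthy", "fibrotic"),
                                 apd_grid = seq(200, 300, by = 2),
                                 params = default_params()) {
  region_kind <- match.arg(region_kind)
  p <- params$ms_atrial
  fb <- params$fibrosis
  if (region_kind == "fibrotic") {
    bk <- template_bank(p, apd_grid * fb$apd_factor)
    bk$V <- p$V_min + (bk$V - p$V_min) * fb$amp_factor
    bk$apd <- apd_grid[seq_len(nrow(bk$V))]
  } else {
    bk <- template_bank(p, apd_grid)
  }
  bk
}
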