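## Reaction-Eikonal transmembrane voltage construction and the infinite
## volume conductor forward projection to electrode potentials and the
## twelve standard leads.

#' Standard 12-lead output order
#' @export
LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

#' Conductivity set
#'
#' Intracellular, extracellular and volume-conductor conductivities (S/m).
#' The dipole operator uses the scalar `sigma_i_bulk` (default the
#' longitudinal intracellular value) in a homogeneous medium of
#' `sigma_medium` (default the torso value); the remaining entries are
#' recorded metadata.
#'
#' @param params Parameter registry.
#' @param sigma_i_bulk,sigma_medium Overrides for the operator scalars.
#' @return Named list of class `conductivity_set`.
#' @export
conductivity_set <- function(params = default_params(),
                             sigma_i_bulk = NULL, sigma_medium = NULL) {
  cs <- params$conductivity
  cs$sigma_i_bulk <- if (is.null(sigma_i_bulk)) cs$sigma_il else sigma_i_bulk
  cs$sigma_medium <- if (is.null(sigma_medium)) cs$sigma_torso else sigma_medium
  structure(cs, class = "conductivity_set")
}

#' Evaluate the reaction-Eikonal transmembrane voltage field
#'
#' `V_m(x, t) = template(t - LAT(x); APD(x))`: each node plays its
#' action-potential template time-shifted by its local activation time,
#' with the template chosen from the bank level nearest its APD. Nodes
#' with infinite LAT (inert tissue) stay at the resting voltage.
#'
#' @param lat `activation_map` (per-node ms; `+Inf` = inert).
#' @param apd Per-node APD vector (ms), or a scalar.
#' @param banks A `template_bank` or list of banks.
#' @param t_grid Output times, ms (regular grid at the bank's `dt`).
#' @param bank_id Per-node bank index (when `banks` is a list).
#' @return Matrix `V_m` (nodes x times, mV).
#' @export
evaluate_tmv <- function(lat, apd, banks, t_grid, bank_id = NULL) {
  if (inherits(banks, "template_bank")) banks <- list(banks)
  nn <- length(lat)
  if (length(apd) == 1) apd <- rep(apd, nn)
  if (is.null(bank_id)) bank_id <- rep(1L, nn)
  nt <- length(t_grid)
  V <- matrix(0, nn, nt)
  for (b in seq_along(banks)) {
    bk <- banks[[b]]
    sel <- which(bank_id == b)
    if (!length(sel)) next
    step <- bk$apd[2] - bk$apd[1]
    lev <- round((apd[sel] - bk$apd[1]) / step) + 1L
    if (any(lev < 1 | lev > nrow(bk$V), na.rm = TRUE)) {
      stop("APD outside template bank range [", min(bk$apd), ", ",
           max(bk$apd), "] ms")
    }
    ns <- ncol(bk$V)
    latl <- lat[sel]
    inert <- !is.finite(latl)
    latl[inert] <- 0
    for (it in seq_len(nt)) {
      k <- round((t_grid[it] - latl) / bk$dt) + bk$align + 1L
      k <- pmin(pmax(k, 1L), ns)
      V[sel, it] <- bk$V[cbind(lev, k)]
    }
    if (any(inert)) V[sel[inert], ] <- bk$V_min
  }
  V
}

#' Precompute the infinite-volume-conductor forward operator
#'
#' Builds the linear map from nodal transmembrane voltages to electrode
#' potentials: per element, the equivalent current dipole is
#' `-sigma_i_bulk * grad(V_m) * Vol_e` (gradient by face-averaged finite
#' differences on the voxel), and the potential at electrode `y` in the
#' homogeneous unbounded medium is the dipole-field sum divided by
#' `4 pi sigma_medium`. Inert elements are excluded.
#'
#' @param mesh A `cardiac_mesh`.
#' @param electrodes Electrode position matrix (rows named, mm).
#' @param sigma A `conductivity_set`.
#' @param exclude_elems Optional integer element indices to exclude
#'   (electrically inert, e.g. infarct core).
#' @return Dense matrix (electrodes x nodes); potentials in mV when
#'   `V_m` is in mV.
#' @export
forward_operator <- function(mesh, electrodes, sigma = conductivity_set(),
                             exclude_elems = integer(0)) {
  ne <- nrow(mesh$elems)
  nn <- nrow(mesh$nodes)
  h <- mesh$res
  kconst <- -sigma$sigma_i_bulk / (4 * pi * sigma$sigma_medium)
  keep <- rep(TRUE, ne)
  keep[exclude_elems] <- FALSE
  ## the finite-difference gradient lives in the voxel lattice frame; a
  ## rigidly placed mesh carries its rotation so axis a points along R[,a]
  R <- if (is.null(mesh$rot)) diag(3) else mesh$rot
  Cs <- vector("list", 3)
  for (a in 1:3) {
    C <- matrix(0, nrow(electrodes), ne)
    for (ei in seq_len(nrow(electrodes))) {
      rvec <- sweep(mesh$elem_center, 2, electrodes[ei, ], "-") * -1
      r2 <- rowSums(rvec^2)
      if (any(r2 < (h / 2)^2)) stop("electrode inside an element")
      C[ei, ] <- kconst * mesh$elem_vol * drop(rvec %*% R[, a]) / r2^1.5
    }
    C[, !keep] <- 0
    Cs[[a]] <- C
  }
  A <- matrix(0, nrow(electrodes), nn)
  for (a in 1:3) {
    signs <- ifelse(.hex_corners[, a] == 1, 1, -1) / (4 * h)
    G <- Matrix::sparseMatrix(
      i = rep(seq_len(ne), 8), j = as.vector(mesh$elems),
      x = rep(signs, each = ne), dims = c(ne, nn)
    )
    A <- A + as.matrix(Cs[[a]] %*% G)
  }
  rownames(A) <- rownames(electrodes)
  A
}

#' Project transmembrane voltages to electrode potentials
#'
#' @param mesh A `cardiac_mesh`.
#' @param tmv Matrix (nodes x times, mV) from [evaluate_tmv()].
#' @param electrodes Electrode matrix (rows named).
#' @param sigma `conductivity_set`.
#' @param A Optional precomputed operator from [forward_operator()].
#' @param exclude_elems Inert elements to exclude.
#' @return Matrix (electrodes x times, mV).
#' @export
forward_ecg <- function(mesh, tmv, electrodes, sigma = conductivity_set(),
                        A = NULL, exclude_elems = integer(0)) {
  if (is.null(A)) {
    A <- forward_operator(mesh, electrodes, sigma, exclude_elems)
  }
  A %*% tmv
}

#' Derive the 12 standard leads from electrode potentials
#'
#' Einthoven limb leads, Goldberger augmented leads and Wilson precordial
#' leads from the nine potentials RA, LA, LL, V1..V6, in the published
#' output order I, II, III, aVR, aVL, aVF, V1-V6.
#'
#' @param potentials Matrix (>= 9 x T) with rownames including RA, LA,
#'   LL, V1..V6.
#' @param fs Sampling rate, Hz.
#' @param fiducials Optional named list of ground-truth fiducials (ms).
#' @return A `beat_ecg12`: `signal` (12 x T, mV), `fs`, `fiducials`.
#' @export
derive_leads <- function(potentials, fs = 1000, fiducials = list()) {
  need <- c("RA", "LA", "LL", paste0("V", 1:6))
  miss <- setdiff(need, rownames(potentials))
  if (length(miss)) stop("missing electrodes: ", paste(miss, collapse = ", "))
  ra <- potentials["RA", ]; la <- potentials["LA", ]; ll <- potentials["LL", ]
  wct <- (ra + la + ll) / 3
  sig <- rbind(
    I = la - ra, II = ll - ra, III = ll - la,
    aVR = ra - (la + ll) / 2, aVL = la - (ra + ll) / 2,
    aVF = ll - (ra + la) / 2,
    potentials[paste0("V", 1:6), , drop = FALSE] -
      matrix(wct, 6, length(wct), byrow = TRUE)
  )
  rownames(sig) <- LEAD_NAMES
  structure(list(signal = sig, fs = fs, fiducials = fiducials),
            class = "beat_ecg12")
}

#' @export
print.beat_ecg12 <- function(x, ...) {
  cat(sprintf("<beat_ecg12: 12 x %d samples @ %g Hz>\n", ncol(x$signal), x$fs))
  if (length(x$fiducials)) {
    cat("  fiducials:", paste(names(x$fiducials),
                              sprintf("%.1f", unlist(x$fiducials)),
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a single ventricular beat (QRST complex)
#'
#' Runs the Eikonal activation, evaluates the reaction-Eikonal voltage
#' field over a 450 ms beat at 1 ms, projects to electrode potentials,
#' derives the 12 leads and resamples to 500 Hz. Ground-truth fiducials
#' (QRS onset/offset, T-wave end) are taken from the activation and
#' repolarization fields.
#'
#' @param setup List with `mesh`, `cond`, `sources`, `apd` (per-node ms),
#'   `banks`, `bank_id` (optional), `electrodes`, `sigma`, optional
#'   precomputed `A` and `exclude_elems`.
#' @param beat_ms Beat duration, ms.
#' @param fs_out Output sampling rate, Hz.
#' @return A `beat_ecg12` with fiducials `QRS_on`, `QRS_off`, `T_off`.
#' @export
simulate_qrst <- function(setup, beat_ms = 450, fs_out = 500) {
  lat <- solve_eikonal(setup$mesh, setup$cond, setup$sources)
  banks <- if (inherits(setup$banks, "template_bank")) list(setup$banks) else
    setup$banks
  bank_id <- if (is.null(setup$bank_id)) rep(1L, length(lat)) else
    setup$bank_id
  fin <- is.finite(lat)
  qrs_on <- min(lat[fin])
  qrs_off <- max(lat[fin]) + 2
  dur <- numeric(length(lat))
  for (b in seq_along(banks)) {
    sel <- bank_id == b & fin
    if (!any(sel)) next
    bk <- banks[[b]]
    step <- bk$apd[2] - bk$apd[1]
    lev <- pmin(pmax(round((setup$apd[sel] - bk$apd[1]) / step) + 1L, 1L),
                length(bk$dur))
    dur[sel] <- bk$dur[lev]
  }
  t_off <- min(max(lat[fin] + dur[fin]), beat_ms - 1)
  t_grid <- seq(0, beat_ms - 1, by = 1)
  V <- evaluate_tmv(lat, setup$apd, banks, t_grid, bank_id)
  phi <- forward_ecg(setup$mesh, V, setup$electrodes, setup$sigma,
                     A = setup$A, exclude_elems = setup$exclude_elems)
  beat <- derive_leads(phi, fs = 1000,
                       fiducials = list(QRS_on = qrs_on, QRS_off = qrs_off,
                                        T_off = t_off))
  resample_beat(beat, fs_out)
}

#' Simulate a single atrial beat (P wave)
#'
#' Eikonal activation from the sinoatrial exit site, atrial template
#' voltage field, dipole projection and lead derivation. The window is
#' auto-sized to the depolarization extent, clamped to 150-200 ms.
#'
#' @param setup List with `mesh`, `cond`, `sources`, `apd`, `banks`,
#'   `bank_id`, `electrodes`, `sigma`, optional `A`, `exclude_elems`.
#' @param fs_out Output sampling rate, Hz.
#' @return A `beat_ecg12` with fiducials `P_on`, `P_off`.
#' @export
simulate_pwave <- function(setup, fs_out = 500) {
  lat <- solve_eikonal(setup$mesh, setup$cond, setup$sources)
  fin <- is.finite(lat)
  p_on <- min(lat[fin])
  p_off <- max(lat[fin]) + 2
  window <- min(max(150, p_off + 30), 200)
  t_grid <- seq(0, window - 1, by = 1)
  banks <- if (inherits(setup$banks, "template_bank")) list(setup$banks) else
    setup$banks
  bank_id <- if (is.null(setup$bank_id)) rep(1L, length(lat)) else
    setup$bank_id
  V <- evaluate_tmv(lat, setup$apd, banks, t_grid, bank_id)
  phi <- forward_ecg(setup$mesh, V, setup$electrodes, setup$sigma,
                     A = setup$A, exclude_elems = setup$exclude_elems)
  beat <- derive_leads(phi, fs = 1000,
                       fiducials = list(P_on = p_on, P_off = p_off))
  resample_beat(beat, fs_out)
}

#' Resample a beat to a target sampling rate
#'
#' @param beat A `beat_ecg12`.
#' @param fs_out Target rate, Hz (must divide the current rate).
#' @return The resampled `beat_ecg12`.
#' @export
resample_beat <- function(beat, fs_out) {
  if (fs_out == beat$fs) return(beat)
  stride <- beat$fs / fs_out
  stopifnot(abs(stride - round(stride)) < 1e-9)
  beat$signal <- beat$signal[, seq(1, ncol(beat$signal), by = round(stride)),
                             drop = FALSE]
  beat$fs <- fs_out
  beat
}

#' Plot a 12-lead beat or record
#'
#' @param x A `beat_ecg12` or `ecg_record`.
#' @param variant For records: which signal variant to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot_ecg <- function(x, variant = "filtered", ...) {
  sig <- if (inherits(x, "ecg_record")) x[[variant]] else x$signal
  fs <- x$fs
  t <- (seq_len(ncol(sig)) - 1) / fs
  old <- graphics::par(mfrow = c(6, 2), mar = c(1.5, 3, 1, 0.5))
  on.exit(graphics::par(old))
  for (i in 1:12) {
    graphics::plot(t, sig[i, ], type = "l", xlab = "", ylab = LEAD_NAMES[i],
                   ...)
  }
  invisible(x)
}
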