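## End-to-end record generation: Latin-hypercube case sampling, cached
## anatomy bundles (meshes, template banks, forward operators), single
## beat simulation per chamber, and the synthesis stage producing the
## raw / noisy / filtered record triple with ground-truth fiducials.

#' Latin-hypercube sample of per-record simulation parameters
#'
#' Draws `n` stratified parameter rows covering the fascicular-site,
#' repolarization, atrial conduction, pose, infarct, fibrosis, left
#' atrial enlargement and noise quantities over their configured ranges.
#' All columns are sampled for every row; a case configuration consumes
#' the subset its label needs.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param params Parameter registry.
#' @return Data frame with one row per record (`seed` column included).
#' @export
sample_case <- function(n, seed, params = default_params()) {
  fs <- params$fascicular_sites
  rg <- list()
  for (nm in names(fs)) {
    st <- fs[[nm]]
    rg[[paste0(nm, "_phi")]] <- st$phi
    rg[[paste0(nm, "_z")]] <- st$z
    rg[[paste0(nm, "_r")]] <- st$r
  }
  rg$t_mod <- fs$rv_mod$t
  rp <- params$repolarization
  rg$apd_min <- rp$apd_min; rg$apd_max <- rp$apd_max
  rg$q_rho <- rp$q_rho; rg$q_v <- rp$q_v; rg$q_z <- rp$q_z
  for (reg in names(params$atrial_cv)) {
    rg[[paste0("cv_", reg)]] <- params$atrial_cv[[reg]]$cv
  }
  rg$pose_ax <- params$pose$rot; rg$pose_ay <- params$pose$rot
  rg$pose_az <- params$pose$rot
  rg$pose_tx <- params$pose$trans; rg$pose_ty <- params$pose$trans
  rg$pose_tz <- params$pose$trans
  rg$torso_l1 <- params$shape$torso_coeff
  rg$torso_l2 <- params$shape$torso_coeff
  rg$mi_d_co <- params$infarct$d_co
  rg$mi_u <- c(0, 1)          # mapped to the artery-specific phi range
  rg$mi_z <- c(0, 1)          # mapped likewise
  rg$fam_u <- c(0, 1)         # mapped to the nine fibrosis levels
  rg$lae_scale <- params$lae$volume_scale
  rg$snr_db <- c(15, 20)
  out <- lhs_sample(rg, n, seed)
  out$seed <- as.integer(seed) + seq_len(n)
  out
}

#' Map a sampled row to the five fascicular site definitions
#'
#' @param row One row of [sample_case()].
#' @param params Parameter registry.
#' @return Named list of sites for [fascicular_sources()].
#' @export
sample_fascicular_sites <- function(row, params = default_params()) {
  fs <- params$fascicular_sites
  out <- lapply(names(fs), function(nm) {
    st <- fs[[nm]]
    list(chamber = st$chamber, rho = st$rho,
         phi = row[[paste0(nm, "_phi")]],
         z = row[[paste0(nm, "_z")]],
         r = row[[paste0(nm, "_r")]],
         t = if (nm == "rv_mod") row$t_mod else range_or_fixed(st$t)[1])
  })
  names(out) <- names(fs)
  out
}

## Map the unit infarct-center coordinates onto the artery-specific
## phi/z bounds (LCX occupies the two lateral intervals).
.mi_center <- function(artery, u, z_u, params) {
  ct <- params$infarct$centers
  if (artery == "RAD") artery <- "RCA"
  if (artery == "LCX") {
    half <- pi - ct$LCX$phi_abs[1]
    phi <- if (u < 0.5) ct$LCX$phi_abs[1] + u * 2 * half else
      -pi + (u - 0.5) * 2 * half
    zr <- ct$LCX$z
  } else {
    b <- ct[[artery]]
    phi <- b$phi[1] + u * (b$phi[2] - b$phi[1])
    zr <- b$z
  }
  list(phi = phi, z = zr[1] + z_u * (zr[2] - zr[1]))
}

#' Build the cached per-anatomy simulation bundle
#'
#' Heavy per-anatomy state reused across records: ventricular mesh with
#' fibers and cached lattice edges, atrial mesh, template banks (sinus,
#' border zone, healthy and fibrotic atrial), default electrodes and the
#' ventricular forward operator.
#'
#' @param shape_coeffs Bounded anatomy shape coefficients.
#' @param params Parameter registry.
#' @param resolution,atrial_resolution Mesh resolutions, mm.
#' @return A named list (`anatomy_bundle`).
#' @export
build_anatomy_bundle <- function(shape_coeffs = numeric(6),
                                 params = default_params(),
                                 resolution = 2, atrial_resolution = 1.5) {
  an <- default_anatomy(resolution = resolution,
                        atrial_resolution = atrial_resolution,
                        shape_coeffs = shape_coeffs)
  vmesh <- cache_edges(assign_ventricular_fibers(
    build_ventricular_mesh(an, params),
    params$fibers$alpha_endo, params$fibers$alpha_epi,
    params$fibers$beta_endo, params$fibers$beta_epi
  ))
  amesh <- cache_edges(build_atrial_mesh(an, params))
  electrodes <- default_pose()$electrode_positions
  ## ventricular attitude: electrodes seen from the idealized heart frame
  R_att <- rotation_xyz(an$attitude[1], an$attitude[2], an$attitude[3])
  el_v <- t(solve(R_att) %*% t(electrodes))
  rownames(el_v) <- rownames(electrodes)
  sigma <- conductivity_set(params)
  list(
    anatomy = an, vmesh = vmesh, amesh = amesh,
    electrodes = electrodes, el_v = el_v, sigma = sigma,
    vbank = template_bank(params$ms_sinus, seq(145, 255, by = 1)),
    bzbank = template_bank(params$ms_bz, seq(145, 255, by = 1)),
    abank = atrial_template_bank("healthy", seq(200, 300, by = 2), params),
    fbank = atrial_template_bank("fibrotic", seq(200, 300, by = 2), params),
    A_vent = forward_operator(vmesh, el_v, sigma)
  )
}

## Electrodes seen from the (unposed) heart frame: the inverse rigid
## transform of the heart pose, plus the torso-shape surrogate scaling.
.pose_electrodes <- function(electrodes, row) {
  el <- electrodes
  sc <- 1 + 0.05 * row$torso_l1 / 2
  el[, 1:2] <- el[, 1:2] * sc
  el[, 3] <- el[, 3] + 10 * row$torso_l2 / 2
  R <- rotation_xyz(row$pose_ax, row$pose_ay, row$pose_az)
  tr <- c(row$pose_tx, row$pose_ty, row$pose_tz)
  t(solve(R) %*% t(sweep(el, 2, tr, "-")))
}

#' Simulate the single-beat pair (P wave and QRST) for one case record
#'
#' @param cfg `case_config` from [make_case_config()].
#' @param anat `anatomy_bundle`.
#' @param params Parameter registry.
#' @return List with `pwave`, `qrst` (`beat_ecg12`) and bookkeeping
#'   (`sources`, infarct / fibrosis element sets).
#' @export
simulate_beat_pair <- function(cfg, anat, params = default_params()) {
  row <- cfg$sample
  ## --- ventricles -----------------------------------------------------
  vmesh <- anat$vmesh
  sites <- sample_fascicular_sites(row, params)
  sources <- fascicular_sources(vmesh, sites)
  if (!is.null(cfg$bbb)) sources <- apply_bbb(sources, cfg$bbb, sites)
  cond <- build_conduction_field_ventricular(
    vmesh, params$conduction$cv_myo, params$conduction$cv_myo_ratio,
    params$conduction$cv_endo, params$conduction$endo_band_z,
    params$conduction$rho_endo
  )
  exclude <- integer(0)
  bank_id <- rep(1L, nrow(vmesh$nodes))
  banks <- list(anat$vbank, anat$bzbank)
  mi_info <- NULL
  if (!is.null(cfg$mi)) {
    mi_info <- apply_mi(vmesh, cond, cfg$mi, params)
    cond <- mi_info$cond
    exclude <- mi_info$core
    if (length(mi_info$bz)) {
      bank_id[unique(as.vector(vmesh$elems[mi_info$bz, ]))] <- 2L
    }
    ## sources must not sit in inert tissue
    dead <- unique(as.vector(vmesh$elems[mi_info$core, ]))
    sources <- structure(lapply(sources, function(s) {
      s$nodes <- setdiff(s$nodes, dead); s
    }), class = "source_set")
    sources <- structure(Filter(function(s) length(s$nodes) > 0, sources),
                         class = "source_set")
  }
  tw <- list(apd_min = row$apd_min, apd_max = row$apd_max,
             q_rho = row$q_rho, q_v = row$q_v, q_phi = 0, q_z = row$q_z)
  apd <- compute_apd_field(vmesh, tw)
  apd <- pmin(pmax(apd, min(anat$vbank$apd)), max(anat$vbank$apd))
  A_v <- if (length(exclude)) {
    forward_operator(vmesh, anat$el_v, anat$sigma, exclude)
  } else anat$A_vent
  qrst <- simulate_qrst(list(
    mesh = vmesh, cond = cond, sources = sources, apd = apd,
    banks = banks, bank_id = bank_id, electrodes = anat$el_v,
    sigma = anat$sigma, A = A_v, exclude_elems = exclude
  ))
  ## --- atria ----------------------------------------------------------
  if (cfg$la_volume_scale > 1) {
    an2 <- anat$anatomy
    an2$la_volume_scale <- cfg$la_volume_scale
    amesh <- cache_edges(build_atrial_mesh(an2, params))
  } else {
    amesh <- anat$amesh
  }
  cvs <- c(bulk_tissue = row$cv_bulk_tissue,
           interatrial_connections = row$cv_interatrial_connections,
           crista_terminalis = row$cv_crista_terminalis,
           pectinate_muscles = row$cv_pectinate_muscles,
           inferior_isthmus = row$cv_inferior_isthmus)
  acond <- build_conduction_field_atrial(amesh, cvs, params)
  a_bank_id <- rep(1L, nrow(amesh$nodes))
  a_exclude <- integer(0)
  fib_info <- NULL
  if (!is.null(cfg$fibrosis)) {
    fib_info <- apply_fibrosis(amesh, acond, cfg$fibrosis, params)
    acond <- fib_info$cond
    a_exclude <- fib_info$removed
    if (length(fib_info$surviving)) {
      a_bank_id[unique(as.vector(amesh$elems[fib_info$surviving, ]))] <- 2L
    }
  }
  if (cfg$iab) acond <- apply_iab(amesh, acond)
  el_a <- .pose_electrodes(anat$electrodes, row)
  pwave <- simulate_pwave(list(
    mesh = amesh, cond = acond, sources = sa_node_sources(amesh),
    apd = rep(250, nrow(amesh$nodes)), banks = list(anat$abank, anat$fbank),
    bank_id = a_bank_id, electrodes = el_a, sigma = anat$sigma,
    A = NULL, exclude_elems = a_exclude
  ))
  list(pwave = pwave, qrst = qrst, sources = sources, mi = mi_info,
       fibrosis = fib_info)
}

#' Generate one complete labeled 10 s record
#'
#' Full pipeline for a single record: beat-pair simulation per the case
#' configuration, clinical-scale P amplitude assignment, conditional
#' QRST scaling and PQ sampling (AV block enforces PQ > 200 ms), sigmoid
#' concatenation, heart-rate-variability RR series, per-beat QT warping,
#' TP assembly, noise superposition at the drawn SNR and zero-phase
#' bandpass filtering.
#'
#' @param cfg `case_config`.
#' @param anat `anatomy_bundle`.
#' @param config `synth_config`.
#' @param params Parameter registry.
#' @param beats Optional precomputed result of [simulate_beat_pair()]
#'   (reused when synthesizing several records from one beat pair).
#' @return An `ecg_record`: `raw`, `noisy`, `filtered` (12 x 5000 mV at
#'   500 Hz), `fiducials`, `label`, `snr_db`, `pq`, `meta`.
#' @export
generate_record <- function(cfg, anat, config = default_synth_config(),
                            params = default_params(), beats = NULL) {
  row <- cfg$sample
  set.seed(as.integer(row$seed))
  if (is.null(beats)) beats <- simulate_beat_pair(cfg, anat, params)
  pwave <- beats$pwave; qrst <- beats$qrst
  ## clinical-scale P amplitude (truncated marginal draw)
  p_target <- -Inf
  for (i in 1:100) {
    p_target <- stats::rnorm(1, config$mvn$A$mean["P_amp"],
                             config$mvn$A$sd[1])
    if (p_target >= config$p_amp_floor) break
  }
  p_target <- max(p_target, config$p_amp_floor)
  p_now <- max(abs(pwave$signal["II", ]))
  if (p_now <= 0) stop("flat P wave")
  pwave$signal <- pwave$signal * (p_target / p_now)
  qrst <- scale_qrst(qrst, pwave, config)
  p_dur <- pwave$fiducials$P_off - pwave$fiducials$P_on
  pq <- sample_pq(p_dur, config, avb = cfg$avb)
  beat <- concat_beat(pwave, qrst, pq)
  ## mean heart rate from the QT interval via the interval block
  qt <- beat$fiducials$T_off - beat$fiducials$QRS_on
  cg <- conditional_gaussian(config$mvn$C, c(QT_int = qt), "RR_int")
  rr_mean <- .draw_gaussian(cg$mean, cg$cov)
  hr <- min(max(60000 / rr_mean, config$hr_range_bpm[1]),
            config$hr_range_bpm[2])
  min_rr <- ncol(beat$signal) * 1000 / beat$fs + 40
  n_beats <- ceiling(1000 * (config$record_s + 1.5) / max(60000 / hr, min_rr))
  rr <- generate_rr_series(hr, n_beats, config$hrv$beta, config$hrv$sdnn)
  rr <- pmax(rr, min_rr)
  warped <- lapply(rr, function(r) stretch_beat(beat, r, config))
  asm <- assemble_record(warped, rr, config)
  snr <- row$snr_db
  nz <- add_noise(asm$signal, snr, config$fs)
  filt <- bandpass_filter(nz$noisy, config$fs)
  rownames(asm$signal) <- rownames(nz$noisy) <- rownames(filt) <- LEAD_NAMES
  structure(list(
    raw = asm$signal, noisy = nz$noisy, filtered = filt, fs = config$fs,
    label = cfg$label, fiducials = asm$fiducials, snr_db = snr, pq = pq,
    meta = list(sample = row, mi_subclass = cfg$mi_subclass,
                la_volume_scale = cfg$la_volume_scale)
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record: %s, 12 x %d @ %g Hz, %d beats, SNR %.1f dB>\n",
              x$label, ncol(x$raw), x$fs, nrow(x$fiducials), x$snr_db))
  invisible(x)
}

#' Generate a batch of labeled records
#'
#' Samples `n` parameter rows, assigns them round-robin to a small pool
#' of anatomies (anatomy bundles are built once and reused), and runs
#' the full pipeline per record.
#'
#' @param label One of [case_labels()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @param n_anatomies Size of the anatomy pool.
#' @param config `synth_config`.
#' @param params Parameter registry.
#' @param resolution,atrial_resolution Mesh resolutions, mm.
#' @param anatomies Optional prebuilt list of `anatomy_bundle`s.
#' @return List of `ecg_record` with an `anatomy_id` entry in each
#'   record's `meta`.
#' @export
generate_records <- function(label, n, seed, n_anatomies = 3,
                             config = default_synth_config(),
                             params = default_params(),
                             resolution = 2, atrial_resolution = 1.5,
                             anatomies = NULL) {
  rows <- sample_case(n, seed, params)
  if (is.null(anatomies)) {
    shapes <- lhs_sample(stats::setNames(
      rep(list(params$shape$atrial_coeff), 6),
      paste0("c", 1:6)
    ), max(n_anatomies, 2), seed + 7919)[seq_len(n_anatomies), , drop = FALSE]
    anatomies <- lapply(seq_len(n_anatomies), function(i) {
      build_anatomy_bundle(as.numeric(shapes[i, ]), params,
                           resolution, atrial_resolution)
    })
  }
  lapply(seq_len(n), function(i) {
    cfg <- make_case_config(label, rows[i, ], params)
    aid <- ((i - 1) %% length(anatomies)) + 1
    rec <- generate_record(cfg, anatomies[[aid]], config, params)
    rec$meta$anatomy_id <- aid
    rec
  })
}
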