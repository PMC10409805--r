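#' Default electrophysiology parameters and sampling ranges
#'
#' Central registry of the fixed values and sampling ranges that drive the
#' simulations: fascicular site placement, conduction velocities, fiber
#' angles, tissue conductivities, Mitchell-Schaeffer cell parameters,
#' repolarization-gradient ranges, infarct sizing, atrial regional
#' conduction, pose variability, and the synthesis-stage distributions.
#'
#' A range is a length-2 numeric `c(lo, hi)`; a fixed value is a scalar.
#' Conduction velocities are in m/s (1 m/s == 1 mm/ms), angles in degrees
#' unless noted, times in ms, conductivities in S/m.
#'
#' @return A nested named list of parameter values and ranges.
#' @export
default_params <- function() {
  list(
    ## Fascicular breakthrough sites of the His-Purkinje surrogate (UVC).
    ## rho: transmural depth (0 = endo); phi: rotational (0 = mid-septum);
    ## z: apico-basal (0 = apex); r: endocardial extent fraction; t: delay ms.
    fascicular_sites = list(
      rv_mod  = list(chamber = "rv", rho = 0.2, phi = c(0, 1.0),
                     z = c(0.1, 0.6), r = c(0.2, 0.8), t = c(0, 10)),
      rv_sept = list(chamber = "rv", rho = 0.8, phi = c(-1.5, 1.5),
                     z = c(0.2, 0.4), r = 0.4, t = 10),
      lv_sept = list(chamber = "lv", rho = 0.2, phi = c(-1.5, 1.5),
                     z = c(0.3, 0.7), r = c(0.05, 0.4), t = 10),
      lv_ant  = list(chamber = "lv", rho = 0.2, phi = c(1.0, pi),
                     z = c(0.2, 0.8), r = c(0.05, 0.4), t = 10),
      lv_post = list(chamber = "lv", rho = 0.2, phi = c(-pi, -1.0),
                     z = c(0.2, 0.7), r = c(0.05, 0.4), t = 10)
    ),
    conduction = list(
      cv_endo = 2.0,            # isotropic fast-conducting endocardium
      cv_endo_ratio = 1.0,
      cv_myo = 0.6,             # along fiber
      cv_myo_ratio = c(4, 2, 1),# fiber : sheet : normal
      endo_band_z = c(0.1, 0.9),# apico-basal extent of fast endo layer
      rho_endo = 0.1            # transmural extent of fast endo layer
    ),
    fibers = list(alpha_endo = 60, alpha_epi = -60,
                  beta_endo = -65, beta_epi = 25),
    conductivity = list(
      sigma_il = 0.34, sigma_in = 0.06, sigma_it = 0.06,
      sigma_el = 0.12, sigma_en = 0.08, sigma_et = 0.08,
      sigma_torso = 0.22, sigma_atria = 0.0537,
      sigma_lungs = 0.0389, sigma_blood = 0.7
    ),
    ## Mitchell-Schaeffer two-current model, sinus ventricular myocyte.
    ms_sinus = list(V_gate = 0.13, V_min = -86.2, V_max = 40.0,
                    tau_in = 0.3, tau_out = 5.4, tau_open = 80.0,
                    tau_close = 150.0),
    ## Border-zone variant (infarct).
    ms_bz = list(V_gate = 0.13, V_min = -73.1, V_max = 12.5,
                 tau_in = 0.45, tau_out = 3.6, tau_open = 44.0,
                 tau_close = 120.0),
    ## Atrial surrogate template voltages.
    ms_atrial = list(V_gate = 0.13, V_min = -80.0, V_max = 20.0,
                     tau_in = 0.3, tau_out = 5.4, tau_open = 80.0,
                     tau_close = 160.0),
    repolarization = list(
      apd_min = c(150, 175), apd_max = c(225, 250),
      q_rho = c(-0.6, 0.0), q_v = c(0.1, 0.15), q_phi = 0,
      q_z = c(0.9, 1.0)
    ),
    infarct = list(
      d_co = c(0, 1.0),
      centers = list(
        LAD = list(phi = c(0.0, 2.0), z = c(0.1, 1.0)),
        RCA = list(phi = c(-2.0, 0.0), z = c(0.2, 1.0)),
        LCX = list(phi_abs = c(2.0, pi), z = c(0.2, 1.0))
      ),
      rho_n = c(0.3, 1.0),       # the two modeled transmural extents
      cv_bz = 0.15, cv_bz_ratio = 1.0,
      bz_fraction = 0.05
    ),
    ## Atrial regional transversal conduction velocities and anisotropy.
    atrial_cv = list(
      bulk_tissue            = list(cv = c(0.57, 0.85), ar = 1.94),
      interatrial_connections = list(cv = c(0.46, 0.70), ar = 3.0),
      crista_terminalis      = list(cv = c(0.57, 0.85), ar = 2.56),
      pectinate_muscles      = list(cv = c(0.62, 0.92), ar = 3.24),
      inferior_isthmus       = list(cv = c(0.57, 0.85), ar = 1.0)
    ),
    pose = list(rot = c(-20, 20), trans = c(-10, 10)),
    shape = list(atrial_coeff = c(-3, 3), torso_coeff = c(-2, 2),
                 axis_scale_max = 0.15),
    fibrosis = list(
      fractions = seq(0.05, 0.45, by = 0.05),
      removal_fraction = 0.5,
      cv_factor_long = 0.5, cv_factor_trans = 0.2,
      apd_factor = 0.85, amp_factor = 0.7
    ),
    lae = list(volume_scale = c(1.1, 1.6)),
    avb = list(pq_min = 200)
  )
}

#' Default anatomy parameters for the parametric idealized geometries
#'
#' Semi-axes and wall thicknesses for the two-chamber truncated-ellipsoid
#' ventricles and the two-shell atria, plus mesh resolution and bounded
#' shape coefficients standing in for statistical-shape-model eigenmodes.
#'
#' @param resolution Voxel edge length in mm for the ventricular mesh.
#' @param atrial_resolution Voxel edge length in mm for the atrial mesh.
#' @param shape_coeffs Numeric vector of bounded shape coefficients
#'   (anatomical variability surrogate); values in \[-3, 3\] perturb the
#'   ellipsoid axes by up to `axis_scale_max` (15 percent) at the bound.
#' @param la_volume_scale Left-atrial volume scale factor (>= 1; values
#'   above 1 encode left atrial enlargement).
#' @return A named list of class `anatomy_params`.
#' @export
default_anatomy <- function(resolution = 2, atrial_resolution = 1.5,
                            shape_coeffs = numeric(6), la_volume_scale = 1) {
  stopifnot(resolution > 0, atrial_resolution > 0, la_volume_scale >= 1)
  structure(list(
    lv_endo_axes = c(20, 20, 44),  # mm semi-axes of the LV cavity
    lv_wall = 12,                  # mm LV wall thickness
    rv_offset = c(-16, 10, 6),     # mm RV center offset (right-anterior)
    rv_endo_axes = c(32, 26, 46),  # mm semi-axes of the RV cavity
    rv_wall = 4,                   # mm RV free wall thickness
    base_frac = 0.72,              # fraction of the full ellipsoid kept (apex up to base)
    attitude = c(-15, -40, 0),     # deg; tilts the apex left-anterior-inferior
    ra_center = c(-28, 0, 0), ra_radius = 24,  # mm (right atrium on -x)
    la_center = c(28, 0, 0), la_radius = 22,   # mm
    atrial_wall = 3,               # mm, homogeneous
    la_volume_scale = la_volume_scale,
    shape_coeffs = shape_coeffs,
    resolution = resolution,
    atrial_resolution = atrial_resolution
  ), class = "anatomy_params")
}

#' Default torso pose and electrode positions
#'
#' Rigid pose of the heart inside the torso frame (rotations applied in
#' x, y, z order, then translation) and the ten standard electrode
#' positions on a cylindrical torso surrogate. The heart frame origin sits
#' between the chambers; +x points to the subject's left, +y anterior,
#' +z cranial.
#'
#' @param alpha_x,alpha_y,alpha_z Rotations in degrees.
#' @param t_x,t_y,t_z Translations in mm.
#' @return A list of class `torso_pose` with an `electrode_positions`
#'   matrix (10 x 3, rows RA, LA, LL, RL, V1..V6, mm).
#' @export
default_pose <- function(alpha_x = 0, alpha_y = 0, alpha_z = 0,
                         t_x = 0, t_y = 0, t_z = 0) {
  el <- rbind(
    RA = c(-180,  20, 240), LA = c(180,  20, 240),
    LL = c( 100,  10, -520), RL = c(-100, 10, -520),
    V1 = c(-25, 100,  20), V2 = c( 25, 100,  20),
    V3 = c( 60,  95, -10), V4 = c( 95,  85, -40),
    V5 = c(125,  60, -40), V6 = c(150,  25, -40)
  )
  colnames(el) <- c("x", "y", "z")
  structure(list(alpha_x = alpha_x, alpha_y = alpha_y, alpha_z = alpha_z,
                 t_x = t_x, t_y = t_y, t_z = t_z,
                 electrode_positions = el), class = "torso_pose")
}

#' Default synthesis-stage configuration
#'
#' Multivariate-normal feature blocks (means and standard deviations from
#' published lead-II clinical values; correlations are configurable
#' calibration knobs), the heart-rate-variability model, noise model, and
#' output format settings.
#'
#' Blocks: A couples P-wave and R-peak amplitude (mV); B couples P-wave
#' duration and PQ interval (ms); C couples QRS duration, QT interval and
#' RR interval (ms).
#'
#' @return A nested named list of class `synth_config`.
#' @export
default_synth_config <- function() {
  structure(list(
    mvn = list(
      A = list(mean = c(P_amp = 0.05, R_amp = 0.79),
               sd = c(0.06, 0.38),
               cor = matrix(c(1, 0.5, 0.5, 1), 2)),
      B = list(mean = c(P_dur = 136.44, PQ_int = 158.80),
               sd = c(11.51, 24.16),
               cor = matrix(c(1, 0.4, 0.4, 1), 2)),
      C = list(mean = c(QRS_dur = 122.15, QT_int = 420.29, RR_int = 879.82),
               sd = c(16.04, 62.68, 143.73),
               cor = matrix(c(1, 0.4, 0, 0.4, 1, 0.6, 0, 0.6, 1), 3))
    ),
    hr_range_bpm = c(50, 90),
    hrv = list(beta = 1.0, sdnn = 30),
    snr_db = c(15, 20),
    p_amp_floor = 0.02,  # mV; lower truncation of the sampled P amplitude
    r_amp_floor = 0.10,  # mV; lower truncation of the sampled R target
    fs = 500, record_s = 10,
    avb_pq_min = 200
  ), class = "synth_config")
}

#' The thirteen labeled pathology cases
#'
#' Eight classes (healthy sinus control plus seven pathologies); the
#' myocardial-infarction class carries six sub-classes, one per
#' artery-transmurality pair, for thirteen labeled cases in total.
#'
#' @return Character vector of the 13 case identifiers.
#' @export
case_labels <- function() {
  c("sinus", "avblock", "lbbb", "rbbb", "lae", "fam", "iab",
    "mi_LAD_0.3", "mi_LAD_1.0", "mi_LCX_0.3", "mi_LCX_1.0",
    "mi_RCA_0.3", "mi_RCA_1.0")
}

range_or_fixed <- function(x) if (length(x) == 2L) x else c(x, x)

#' Write / read the run configuration file
#'
#' Serializes the parameter registry, anatomy parameters and synthesis
#' configuration to a YAML file so a run is fully described by one
#' human-readable document, and reads it back.
#'
#' @param path YAML file path.
#' @param params Parameter registry ([default_params()]).
#' @param anatomy Anatomy parameters ([default_anatomy()]).
#' @param synth Synthesis configuration ([default_synth_config()]).
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns a list with `params`, `anatomy`, `synth`.
#' @export
write_config <- function(path, params = default_params(),
                         anatomy = default_anatomy(),
                         synth = default_synth_config()) {
  strip <- function(x) {
    if (is.matrix(x)) return(list(.matrix = as.vector(x), .nrow = nrow(x)))
    if (is.list(x)) return(lapply(x, strip))
    unclass(x)
  }
  yaml::write_yaml(list(params = strip(unclass(params)),
                        anatomy = strip(unclass(anatomy)),
                        synth = strip(unclass(synth))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  restore <- function(x) {
    if (is.list(x) && !is.null(x$.matrix)) {
      return(matrix(unlist(x$.matrix), nrow = x$.nrow))
    }
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  cfg <- yaml::read_yaml(path)
  list(params = restore(cfg$params),
       anatomy = structure(restore(cfg$anatomy), class = "anatomy_params"),
       synth = structure(restore(cfg$synth), class = "synth_config"))
}
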