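## Parametric idealized cardiac geometry: voxelized two-chamber truncated
## ellipsoids for the ventricles, two spheroidal shells with interatrial
## bridges for the atria, analytic universal coordinates and rule-based
## fibers. The voxel lattice is shared by all meshes so edges, elements and
## gradients have one code path.

# VTK hexahedron corner offsets (lattice units), VTK ordering.
.hex_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
)

.lattice_key <- function(ijk, K = 4096) {
  (ijk[, 1] * K + ijk[, 2]) * K + ijk[, 3]
}

## Assemble a cardiac_mesh from kept voxel centers (integer lattice coords of
## the voxel's low corner) and an origin so that corner position =
## origin + res * lattice.
.make_voxel_mesh <- function(vox_ijk, region, res, origin, kind) {
  stopifnot(nrow(vox_ijk) > 0)
  corners <- do.call(rbind, lapply(seq_len(8), function(j) {
    sweep(vox_ijk, 2, .hex_corners[j, ], "+")
  }))
  key <- .lattice_key(corners)
  ukey <- sort(unique(key))
  node_idx <- match(key, ukey)
  nn <- length(ukey)
  lattice <- matrix(0L, nn, 3)
  first <- match(ukey, key)
  lattice <- corners[first, , drop = FALSE]
  dimnames(lattice) <- NULL
  nodes <- sweep(lattice * res, 2, origin, "+")
  ne <- nrow(vox_ijk)
  elems <- matrix(node_idx, ne, 8)
  centers <- sweep((vox_ijk + 0.5) * res, 2, origin, "+")
  structure(list(
    nodes = nodes, lattice = lattice, elems = elems,
    elem_lattice = vox_ijk,
    elem_region = region, elem_center = centers,
    elem_vol = rep(res^3, ne), res = res, kind = kind,
    chamber = rep(NA_character_, nn), uvc = NULL,
    fib_f = NULL, fib_s = NULL, fib_n = NULL,
    elem_f = NULL, elem_s = NULL, elem_n = NULL
  ), class = "cardiac_mesh")
}

#' @export
print.cardiac_mesh <- function(x, ...) {
  cat(sprintf("<cardiac_mesh: %s, %d nodes, %d elements, res %.2g mm>\n",
              x$kind, nrow(x$nodes), nrow(x$elems), x$res))
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$elem_region)),
                                  table(x$elem_region)), collapse = ", "), "\n")
  invisible(x)
}

## Normalized ellipsoid radius ||(p - c) / a||.
.ell_m <- function(p, center, axes) {
  q <- sweep(p, 2, center, "-")
  sqrt((q[, 1] / axes[1])^2 + (q[, 2] / axes[2])^2 + (q[, 3] / axes[3])^2)
}

## Solve, per point, the transmural coordinate rho such that p lies on the
## ellipsoid with semi-axes (a_endo + rho * w); monotone, bisection.
.ell_rho <- function(p, center, a_endo, w, lo = -1, hi = 2, iter = 40) {
  q <- sweep(p, 2, center, "-")
  f <- function(rho) {
    sqrt((q[, 1] / (a_endo[1] + rho * w))^2 +
         (q[, 2] / (a_endo[2] + rho * w))^2 +
         (q[, 3] / (a_endo[3] + rho * w))^2) - 1
  }
  lo <- rep(lo, nrow(p)); hi <- rep(hi, nrow(p))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    smaller <- v > 0     # outside the mid surface -> rho larger
    lo[smaller] <- mid[smaller]
    hi[!smaller] <- mid[!smaller]
  }
  (lo + hi) / 2
}

.apply_shape_coeffs <- function(an, p) {
  cf <- an$shape_coeffs
  if (length(cf) < 6) cf <- c(cf, numeric(6 - length(cf)))
  cf <- pmin(pmax(cf, -3), 3)
  s <- 1 + p$shape$axis_scale_max * cf / 3
  an$lv_endo_axes <- an$lv_endo_axes * s[1:3]
  an$rv_endo_axes <- an$rv_endo_axes * s[1:3]
  an$rv_offset <- an$rv_offset * s[1:3]
  an$lv_wall <- an$lv_wall * s[4]
  an$rv_wall <- an$rv_wall * s[5]
  an$base_frac <- min(max(an$base_frac + 0.05 * cf[6] / 3, 0.55), 0.9)
  an$ra_radius <- an$ra_radius * s[1]
  an$la_radius <- an$la_radius * s[2]
  an
}

#' Build the parametric idealized ventricular mesh
#'
#' Voxelizes a two-chamber geometry: a thick-walled truncated prolate
#' ellipsoid for the left ventricle and a thin crescent shell for the
#' right ventricle, on a regular lattice. Every node carries analytic
#' universal ventricular coordinates: transmural `rho` (0 endocardium,
#' 1 epicardium), rotational `phi` (0 at mid-septum, anterior positive,
#' radians), apico-basal `z` (0 apex, 1 base) and chamber label `v`.
#'
#' @param anatomy An `anatomy_params` list from [default_anatomy()].
#' @param params Parameter registry, see [default_params()].
#' @return A `cardiac_mesh` with UVCs (no fibers yet; see
#'   [assign_ventricular_fibers()]).
#' @export
build_ventricular_mesh <- function(anatomy = default_anatomy(),
                                   params = default_params()) {
  an <- .apply_shape_coeffs(anatomy, params)
  res <- an$resolution
  stopifnot(res >= 0.5)
  if (an$lv_wall / res < 3) {
    stop("resolution ", res, " mm too coarse: fewer than 3 elements across ",
         "the ", an$lv_wall, " mm LV wall")
  }
  lv_epi <- an$lv_endo_axes + an$lv_wall
  rv_epi <- an$rv_endo_axes + an$rv_wall
  z_base <- (2 * an$base_frac - 1) * lv_epi[3]
  lim <- rbind(
    lo = c(-max(lv_epi[1], -an$rv_offset[1] + rv_epi[1]) - res,
           -max(lv_epi[2], rv_epi[2] - an$rv_offset[2]) - res,
           -lv_epi[3] - res),
    hi = c(max(lv_epi[1], an$rv_offset[1] + rv_epi[1]) + res,
           max(lv_epi[2], rv_epi[2] + an$rv_offset[2]) + res,
           z_base + res)
  )
  origin <- floor(lim["lo", ] / res) * res
  n_vox <- ceiling((lim["hi", ] - origin) / res)
  g <- as.matrix(expand.grid(i = 0:(n_vox[1] - 1), j = 0:(n_vox[2] - 1),
                             k = 0:(n_vox[3] - 1)))
  ctr <- sweep((g + 0.5) * res, 2, origin, "+")
  keep_z <- ctr[, 3] <= z_base
  m_lv_en <- .ell_m(ctr, c(0, 0, 0), an$lv_endo_axes)
  m_lv_ep <- .ell_m(ctr, c(0, 0, 0), lv_epi)
  in_lv <- m_lv_en >= 1 & m_lv_ep <= 1 & keep_z
  m_rv_en <- .ell_m(ctr, an$rv_offset, an$rv_endo_axes)
  m_rv_ep <- .ell_m(ctr, an$rv_offset, rv_epi)
  in_rv <- m_rv_en >= 1 & m_rv_ep <= 1 & m_lv_ep > 1 & keep_z &
    ctr[, 3] >= -lv_epi[3]
  region <- ifelse(in_lv, "lv_myo", ifelse(in_rv, "rv_myo", NA))
  keep <- !is.na(region)
  mesh <- .make_voxel_mesh(g[keep, , drop = FALSE], region[keep], res,
                           origin, "ventricular")
  ## Node chamber: RV only when clearly outside the LV epicardial surface.
  nm_lv_ep <- .ell_m(mesh$nodes, c(0, 0, 0), lv_epi)
  mesh$chamber <- ifelse(nm_lv_ep > 1 + 1e-9, "rv", "lv")
  rho <- numeric(nrow(mesh$nodes))
  is_rv <- mesh$chamber == "rv"
  if (any(!is_rv)) {
    rho[!is_rv] <- .ell_rho(mesh$nodes[!is_rv, , drop = FALSE], c(0, 0, 0),
                            an$lv_endo_axes, an$lv_wall)
  }
  if (any(is_rv)) {
    rho[is_rv] <- .ell_rho(mesh$nodes[is_rv, , drop = FALSE], an$rv_offset,
                           an$rv_endo_axes, an$rv_wall)
  }
  rho <- pmin(pmax(rho, 0), 1)
  ## rotational coordinate: 0 at mid-septum (direction of the RV center),
  ## anterior positive, lateral LV free wall at +/- pi
  alpha0 <- atan2(an$rv_offset[2], an$rv_offset[1])
  raw_phi <- atan2(mesh$nodes[, 2], mesh$nodes[, 1]) - alpha0
  phi <- -atan2(sin(raw_phi), cos(raw_phi))
  zc <- pmin(pmax((mesh$nodes[, 3] + lv_epi[3]) / (z_base + lv_epi[3]), 0), 1)
  mesh$uvc <- data.frame(rho = rho, phi = phi, z = zc,
                         v = ifelse(is_rv, "rv", "lv"))
  mesh$anatomy <- an
  mesh$lv_long_axis <- z_base + lv_epi[3]
  mesh
}

## Local ellipsoid frame: transmural (outward), circumferential,
## apico-basal directions per point.
.ell_frame <- function(p, center, axes) {
  q <- sweep(p, 2, center, "-")
  et <- cbind(q[, 1] / axes[1]^2, q[, 2] / axes[2]^2, q[, 3] / axes[3]^2)
  et <- et / pmax(sqrt(rowSums(et^2)), 1e-12)
  ## circumferential = z_hat x e_t, with an x_hat fallback near the apex
  ec <- cbind(-et[, 2], et[, 1], 0)
  nec <- sqrt(rowSums(ec^2))
  bad <- nec < 1e-6
  if (any(bad)) ec[bad, ] <- matrix(c(0, 1, 0), sum(bad), 3, byrow = TRUE)
  ec <- ec / pmax(sqrt(rowSums(ec^2)), 1e-12)
  el <- cbind(et[, 2] * ec[, 3] - et[, 3] * ec[, 2],
              et[, 3] * ec[, 1] - et[, 1] * ec[, 3],
              et[, 1] * ec[, 2] - et[, 2] * ec[, 1])
  el <- el / pmax(sqrt(rowSums(el^2)), 1e-12)
  list(et = et, ec = ec, el = el)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.renorm <- function(v) v / pmax(sqrt(rowSums(v^2)), 1e-12)

#' Assign rule-based myocardial fibers
#'
#' Helix angle interpolates linearly in the transmural coordinate from
#' `alpha_endo` at the endocardium to `alpha_epi` at the epicardium
#' (defaults 60 to -60 degrees); the sheet angle likewise (-65 to 25
#' degrees). Produces orthonormal per-node and per-element (fiber, sheet,
#' normal) triads.
#'
#' @param mesh Ventricular `cardiac_mesh` with UVCs.
#' @param alpha_endo,alpha_epi Helix angle at endo-/epicardium, degrees.
#' @param beta_endo,beta_epi Sheet angle at endo-/epicardium, degrees.
#' @return The mesh with `fib_f`, `fib_s`, `fib_n` (per node) and
#'   `elem_f`, `elem_s`, `elem_n` (per element) unit-vector matrices.
#' @export
assign_ventricular_fibers <- function(mesh, alpha_endo = 60, alpha_epi = -60,
                                      beta_endo = -65, beta_epi = 25) {
  if (is.null(mesh$uvc)) stop("mesh has no universal coordinates")
  an <- mesh$anatomy
  rho <- mesh$uvc$rho
  alpha <- (alpha_endo + rho * (alpha_epi - alpha_endo)) * pi / 180
  beta <- (beta_endo + rho * (beta_epi - beta_endo)) * pi / 180
  is_rv <- mesh$uvc$v == "rv"
  fr <- .ell_frame(mesh$nodes, c(0, 0, 0), an$lv_endo_axes + an$lv_wall)
  if (any(is_rv)) {
    fr_rv <- .ell_frame(mesh$nodes[is_rv, , drop = FALSE], an$rv_offset,
                        an$rv_endo_axes + an$rv_wall)
    fr$et[is_rv, ] <- fr_rv$et; fr$ec[is_rv, ] <- fr_rv$ec
    fr$el[is_rv, ] <- fr_rv$el
  }
  f <- .renorm(cos(alpha) * fr$ec + sin(alpha) * fr$el)
  ## transmural direction projected orthogonal to f, then sheet by beta
  tperp <- .renorm(fr$et - rowSums(fr$et * f) * f)
  bperp <- .cross3(f, tperp)
  s <- .renorm(cos(beta) * tperp + sin(beta) * bperp)
  n <- .cross3(f, s)
  mesh$fib_f <- f; mesh$fib_s <- s; mesh$fib_n <- n
  mesh$node_alpha <- alpha_endo + rho * (alpha_epi - alpha_endo)
  ## element triads: average corner vectors, re-orthonormalized
  avg8 <- function(v) {
    out <- matrix(0, nrow(mesh$elems), 3)
    for (j in 1:8) out <- out + v[mesh$elems[, j], , drop = FALSE]
    out / 8
  }
  ef <- .renorm(avg8(f))
  es <- avg8(s)
  es <- .renorm(es - rowSums(es * ef) * ef)
  mesh$elem_f <- ef; mesh$elem_s <- es; mesh$elem_n <- .cross3(ef, es)
  mesh
}

#' Build the parametric idealized atrial mesh
#'
#' Two spheroidal shells of homogeneous 3 mm wall thickness (right and
#' left atrium) connected by an anterior-superior Bachmann's-bundle bridge
#' and a posterior interatrial connection, with band-shaped region tags
#' for the crista terminalis, pectinate muscles and inferior isthmus, and
#' a sinoatrial-node exit site marked at the crista-terminalis / superior
#' vena cava junction surrogate on the right atrium. The left-atrial
#' radius scales with `la_volume_scale^(1/3)`.
#'
#' @inheritParams build_ventricular_mesh
#' @return A `cardiac_mesh` of kind `"atrial"` with tangential rule-based
#'   fibers and an `sa_nodes` integer vector of sinoatrial exit nodes.
#' @export
build_atrial_mesh <- function(anatomy = default_anatomy(),
                              params = default_params()) {
  if (anatomy$la_volume_scale < 1) stop("la_volume_scale must be >= 1")
  an <- .apply_shape_coeffs(anatomy, params)
  res <- an$atrial_resolution
  w <- an$atrial_wall
  ra_c <- an$ra_center; ra_r <- an$ra_radius
  la_c <- an$la_center
  la_r <- an$la_radius * an$la_volume_scale^(1 / 3)
  lim_lo <- pmin(ra_c - ra_r - w, la_c - la_r - w) - res
  lim_hi <- pmax(ra_c + ra_r + w, la_c + la_r + w) + res
  origin <- floor(lim_lo / res) * res
  n_vox <- ceiling((lim_hi - origin) / res)
  g <- as.matrix(expand.grid(i = 0:(n_vox[1] - 1), j = 0:(n_vox[2] - 1),
                             k = 0:(n_vox[3] - 1)))
  ctr <- sweep((g + 0.5) * res, 2, origin, "+")
  d_ra <- sqrt(rowSums(sweep(ctr, 2, ra_c, "-")^2))
  d_la <- sqrt(rowSums(sweep(ctr, 2, la_c, "-")^2))
  in_ra <- d_ra >= ra_r & d_ra <= ra_r + w
  in_la <- d_la >= la_r & d_la <= la_r + w
  ## interatrial bridges spanning the gap between the shells
  bb_ax <- c(10, 14)    # (y, z) of the anterior-superior Bachmann tube
  po_ax <- c(-12, -6)   # posterior connection tube
  gap_lo <- ra_c[1] + ra_r - 2 * res   # RA inner-facing extent
  gap_hi <- la_c[1] - la_r + 2 * res   # LA inner-facing extent
  in_gap <- ctr[, 1] >= gap_lo & ctr[, 1] <= gap_hi
  in_bb <- in_gap &
    sqrt((ctr[, 2] - bb_ax[1])^2 + (ctr[, 3] - bb_ax[2])^2) <= 4.5 &
    d_ra > ra_r & d_la > la_r
  in_po <- in_gap &
    sqrt((ctr[, 2] - po_ax[1])^2 + (ctr[, 3] - po_ax[2])^2) <= 3.5 &
    d_ra > ra_r & d_la > la_r
  region <- rep(NA_character_, nrow(ctr))
  region[in_la] <- "bulk_tissue"
  region[in_ra] <- "bulk_tissue"
  ## RA bands in local spherical coordinates (psi: azimuth, 0 = lateral,
  ## i.e. pointing away from the left atrium)
  q <- sweep(ctr, 2, ra_c, "-")
  lat_sign <- if (ra_c[1] < la_c[1]) -1 else 1
  psi <- atan2(q[, 2], lat_sign * q[, 1])
  elev <- asin(pmin(pmax(q[, 3] / pmax(d_ra, 1e-9), -1), 1))
  ct_band <- in_ra & abs(psi) < 0.35 & elev > -0.9 & elev < 1.0
  pm_band <- in_ra & psi > 0.6 & psi < 1.6 & abs(elev) < 0.8
  ii_band <- in_ra & elev < -1.05
  region[pm_band] <- "pectinate_muscles"
  region[ii_band] <- "inferior_isthmus"
  region[ct_band] <- "crista_terminalis"
  region[in_bb & is.na(region)] <- "bachmanns_bundle"
  region[in_po & is.na(region)] <- "posterior_connection"
  keep <- !is.na(region)
  mesh <- .make_voxel_mesh(g[keep, , drop = FALSE], region[keep], res,
                           origin, "atrial")
  nd_ra <- sqrt(rowSums(sweep(mesh$nodes, 2, ra_c, "-")^2))
  nd_la <- sqrt(rowSums(sweep(mesh$nodes, 2, la_c, "-")^2))
  mesh$chamber <- ifelse(abs(nd_ra - (ra_r + w / 2)) <=
                           abs(nd_la - (la_r + w / 2)), "ra", "la")
  ## sinoatrial exit: crista terminalis / SVC junction surrogate
  sa_dir <- c(lat_sign * cos(0.95), 0, sin(0.95))
  p_sa <- ra_c + (ra_r + w / 2) * sa_dir
  mesh$sa_nodes <- which(sqrt(rowSums(sweep(mesh$nodes, 2, p_sa, "-")^2)) <= 4)
  if (length(mesh$sa_nodes) == 0) {
    mesh$sa_nodes <- which.min(rowSums(sweep(mesh$nodes, 2, p_sa, "-")^2))
  }
  ## tangential fibers: circumferential about each shell's vertical axis;
  ## along the meridian on the crista terminalis; along x in the bridges
  ctr_of <- ifelse(mesh$chamber == "ra", 1, -1)
  cc <- matrix(ra_c, nrow(mesh$nodes), 3, byrow = TRUE)
  cc[mesh$chamber == "la", ] <- matrix(la_c, sum(mesh$chamber == "la"), 3,
                                       byrow = TRUE)
  radial <- .renorm(mesh$nodes - cc)
  f <- cbind(-radial[, 2], radial[, 1], 0)
  bad <- sqrt(rowSums(f^2)) < 1e-6
  if (any(bad)) f[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
  f <- .renorm(f)
  ## meridian direction for CT nodes
  node_reg <- rep("bulk_tissue", nrow(mesh$nodes))
  for (rg in c("crista_terminalis", "pectinate_muscles", "inferior_isthmus",
               "bachmanns_bundle", "posterior_connection")) {
    el <- which(mesh$elem_region == rg)
    if (length(el)) node_reg[unique(as.vector(mesh$elems[el, ]))] <- rg
  }
  merid <- .renorm(.cross3(radial, f))
  is_ct <- node_reg == "crista_terminalis"
  f[is_ct, ] <- merid[is_ct, , drop = FALSE]
  is_br <- node_reg %in% c("bachmanns_bundle", "posterior_connection")
  if (any(is_br)) f[is_br, ] <- matrix(c(1, 0, 0), sum(is_br), 3, byrow = TRUE)
  s <- .renorm(.cross3(radial, f))
  deg <- sqrt(rowSums(s^2)) < 1e-6
  if (any(deg)) s[deg, ] <- matrix(c(0, 0, 1), sum(deg), 3, byrow = TRUE)
  s <- .renorm(s - rowSums(s * f) * f)
  n <- .cross3(f, s)
  mesh$fib_f <- f; mesh$fib_s <- s; mesh$fib_n <- n
  avg8 <- function(v) {
    out <- matrix(0, nrow(mesh$elems), 3)
    for (j in 1:8) out <- out + v[mesh$elems[, j], , drop = FALSE]
    out / 8
  }
  ef <- .renorm(avg8(f)); es <- avg8(s)
  es <- .renorm(es - rowSums(es * ef) * ef)
  mesh$elem_f <- ef; mesh$elem_s <- es; mesh$elem_n <- .cross3(ef, es)
  mesh$anatomy <- an
  mesh
}

#' Build a homogeneous rectangular slab mesh
#'
#' Test and benchmark fixture: a box voxelized at the requested resolution
#' with constant fibers, one region tag and trivial coordinates. Used for
#' closed-form verification of the Eikonal solver and forward operator.
#'
#' @param dims Length-3 box dimensions, mm.
#' @param res Voxel edge, mm.
#' @param fiber Fiber direction (unit-normalized internally).
#' @param region Region tag for every element.
#' @return A `cardiac_mesh` of kind `"slab"`.
#' @export
build_slab_mesh <- function(dims = c(40, 20, 20), res = 1,
                            fiber = c(1, 0, 0), region = "lv_myo") {
  n_vox <- pmax(round(dims / res), 1)
  g <- as.matrix(expand.grid(i = 0:(n_vox[1] - 1), j = 0:(n_vox[2] - 1),
                             k = 0:(n_vox[3] - 1)))
  mesh <- .make_voxel_mesh(g, rep(region, nrow(g)), res, c(0, 0, 0), "slab")
  f <- fiber / sqrt(sum(fiber^2))
  up <- if (abs(f[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  s <- c(f[2] * up[3] - f[3] * up[2], f[3] * up[1] - f[1] * up[3],
         f[1] * up[2] - f[2] * up[1])
  s <- s / sqrt(sum(s^2))
  n <- c(f[2] * s[3] - f[3] * s[2], f[3] * s[1] - f[1] * s[3],
         f[1] * s[2] - f[2] * s[1])
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  mesh$fib_f <- matrix(f, nn, 3, byrow = TRUE)
  mesh$fib_s <- matrix(s, nn, 3, byrow = TRUE)
  mesh$fib_n <- matrix(n, nn, 3, byrow = TRUE)
  mesh$elem_f <- matrix(f, ne, 3, byrow = TRUE)
  mesh$elem_s <- matrix(s, ne, 3, byrow = TRUE)
  mesh$elem_n <- matrix(n, ne, 3, byrow = TRUE)
  mesh$chamber <- rep("lv", nn)
  mesh$uvc <- data.frame(rho = rep(0.5, nn), phi = 0, z = 0.5, v = "lv")
  mesh
}

#' Rigid placement of the heart in the torso frame
#'
#' Applies the pose's rotations in x, y, z order followed by the
#' translation to all heart nodes, element centers and fiber vectors.
#' Electrode positions stay fixed in the torso frame.
#'
#' @param mesh A `cardiac_mesh`.
#' @param pose A `torso_pose` from [default_pose()].
#' @return The transformed mesh, with the pose stored in `$pose`.
#' @export
place_and_project <- function(mesh, pose) {
  R <- rotation_xyz(pose$alpha_x, pose$alpha_y, pose$alpha_z)
  tr <- c(pose$t_x, pose$t_y, pose$t_z)
  rot <- function(v) sweep(v %*% t(R), 2, c(0, 0, 0), "+")
  mesh$nodes <- sweep(mesh$nodes %*% t(R), 2, tr, "+")
  mesh$elem_center <- sweep(mesh$elem_center %*% t(R), 2, tr, "+")
  for (f in c("fib_f", "fib_s", "fib_n", "elem_f", "elem_s", "elem_n")) {
    if (!is.null(mesh[[f]])) mesh[[f]] <- mesh[[f]] %*% t(R)
  }
  mesh$pose <- pose
  mesh$rot <- if (is.null(mesh$rot)) R else R %*% mesh$rot
  mesh
}

#' Rotation matrix for rotations applied in x, y, z order
#'
#' @param ax,ay,az Rotation angles about the x, y and z axes, degrees.
#' @return A 3x3 rotation matrix `Rz %*% Ry %*% Rx`.
#' @export
rotation_xyz <- function(ax, ay, az) {
  a <- ax * pi / 180; b <- ay * pi / 180; c <- az * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Latin hypercube sample over named parameter ranges
#'
#' Draws `n` stratified samples per dimension: each of the `n` equal-width
#' strata of every range contains exactly one sample. Deterministic for a
#' fixed seed. Fixed (zero-width) ranges are returned as constants.
#'
#' @param ranges Named list of length-2 numeric ranges `c(lo, hi)` (or
#'   scalars for fixed values).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @return A data.frame with `n` rows and one column per range.
#' @export
lhs_sample <- function(ranges, n, seed) {
  stopifnot(n >= 1, length(ranges) >= 1)
  rg <- lapply(ranges, range_or_fixed)
  bad <- vapply(rg, function(r) r[1] > r[2], logical(1))
  if (any(bad)) {
    stop("inverted range for: ", paste(names(rg)[bad], collapse = ", "))
  }
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n, length(rg))
  out <- as.data.frame(mapply(function(r, col) r[1] + col * (r[2] - r[1]),
                              rg, as.data.frame(u), SIMPLIFY = FALSE))
  names(out) <- names(rg)
  out
}

#' Write a mesh (with optional per-node scalars) as legacy ASCII VTK
#'
#' @param mesh A `cardiac_mesh`.
#' @param path Output file path.
#' @param point_data Optional named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "cardiac_mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nn)), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(format(r, digits = 9),
                                                    collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9), con)
  writeLines(apply(mesh$elems - 1L, 1, function(r) paste(c(8L, r),
                                                         collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 9), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_mesh_vtk()]
#'
#' @param path File path.
#' @return List with `nodes` (N x 3), `elems` (E x 8, 1-based) and
#'   `point_data` (named list of numeric vectors).
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  nn <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  nodes <- matrix(scan(text = ln[(ip + 1):(ip + nn)], quiet = TRUE),
                  nn, 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  ne <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cl <- matrix(scan(text = ln[(ic + 1):(ic + ne)], quiet = TRUE),
               ne, 9, byrow = TRUE)
  elems <- cl[, -1, drop = FALSE] + 1L
  pd <- list()
  isc <- grep("^SCALARS", ln)
  for (i in isc) {
    nm <- strsplit(ln[i], " ")[[1]][2]
    pd[[nm]] <- scan(text = ln[(i + 2):(i + 1 + nn)], quiet = TRUE)
  }
  list(nodes = nodes, elems = elems, point_data = pd)
}

## 26-neighborhood lattice edges; cached on first use.
mesh_edges <- function(mesh) {
  if (!is.null(mesh$edges)) return(mesh[c("edges", "edge_vec", "edge_len")])
  key <- .lattice_key(mesh$lattice)
  ord <- order(key)
  skey <- key[ord]
  ## order-2 stencil: all coprime offsets with components in {-2..2};
  ## keeps plane-wave speed errors within a few percent in any direction
  offs <- as.matrix(expand.grid(di = -2:2, dj = -2:2, dk = -2:2))
  g2 <- apply(abs(offs), 1, function(r) {
    r <- r[r > 0]
    if (!length(r)) 0 else Reduce(function(a, b) {
      while (b) { t <- b; b <- a %% b; a <- t }; a
    }, r)
  })
  offs <- offs[g2 == 1, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  K <- 4096
  e_from <- integer(0); e_to <- integer(0); e_off <- NULL
  for (r in seq_len(nrow(offs))) {
    dk <- (offs[r, 1] * K + offs[r, 2]) * K + offs[r, 3]
    hit <- match(key + dk, skey)
    ok <- !is.na(hit)
    e_from <- c(e_from, which(ok))
    e_to <- c(e_to, ord[hit[ok]])
    e_off <- rbind(e_off, matrix(offs[r, ], sum(ok), 3, byrow = TRUE))
  }
  edge_vec <- e_off * mesh$res
  list(edges = cbind(e_from, e_to), edge_vec = edge_vec,
       edge_len = sqrt(rowSums(edge_vec^2)))
}

#' Cache lattice edges on a mesh
#'
#' Precomputes the 26-neighborhood edge list used by the Eikonal solver so
#' repeated solves on the same mesh skip the lattice matching step.
#'
#' @param mesh A `cardiac_mesh`.
#' @return The mesh with `$edges`, `$edge_vec`, `$edge_len` filled in.
#' @export
cache_edges <- function(mesh) {
  eg <- mesh_edges(mesh)
  mesh$edges <- eg$edges; mesh$edge_vec <- eg$edge_vec
  mesh$edge_len <- eg$edge_len
  mesh
}
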