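## Anisotropic Eikonal activation: regional conduction fields, fascicular
## His-Purkinje surrogate sources, a label-correcting shortest-path solver
## on the 26-neighborhood lattice graph, and geodesic region growing.

#' Ventricular conduction field
#'
#' Myocardium receives the fiber/sheet/normal velocities
#' `cv_myo * ratio / ratio[1]` (default 0.6, 0.3, 0.15 m/s from the 4:2:1
#' ratio); a fast-conducting endocardial layer (`rho <= rho_endo`, apico-
#' basal coordinate inside `endo_band_z`) is isotropic at `cv_endo`
#' (default 2.0 m/s) and is tagged `fast_endo`.
#'
#' @param mesh Ventricular `cardiac_mesh` with fibers.
#' @param cv_myo Fiber-direction myocardial velocity, m/s.
#' @param ratio Length-3 anisotropy ratio (fiber : sheet : normal).
#' @param cv_endo Isotropic fast-endocardium velocity, m/s.
#' @param endo_band_z Apico-basal band of the fast endocardium.
#' @param rho_endo Transmural extent of the fast endocardium.
#' @return A `conduction_field`: `elem_cv` (E x 3, m/s), `region`
#'   (per-element tag with `fast_endo` overlay), `inert` (logical E).
#' @export
build_conduction_field_ventricular <- function(mesh, cv_myo = 0.6,
                                               ratio = c(4, 2, 1),
                                               cv_endo = 2.0,
                                               endo_band_z = c(0.1, 0.9),
                                               rho_endo = 0.1) {
  if (is.null(mesh$elem_f)) stop("mesh has no fibers")
  ne <- nrow(mesh$elems)
  cvs <- cv_myo * ratio / ratio[1]
  elem_cv <- matrix(cvs, ne, 3, byrow = TRUE)
  region <- mesh$elem_region
  if (!is.null(mesh$uvc)) {
    erho <- .elem_mean(mesh, mesh$uvc$rho)
    ez <- .elem_mean(mesh, mesh$uvc$z)
    fast <- erho <= rho_endo & ez >= endo_band_z[1] & ez <= endo_band_z[2]
    elem_cv[fast, ] <- cv_endo
    region[fast] <- "fast_endo"
  }
  structure(list(elem_cv = elem_cv, region = region,
                 inert = rep(FALSE, ne)), class = "conduction_field")
}

.elem_mean <- function(mesh, node_val) {
  out <- numeric(nrow(mesh$elems))
  for (j in 1:8) out <- out + node_val[mesh$elems[, j]]
  out / 8
}

#' Atrial conduction field
#'
#' Per anatomical region, the transversal conduction velocity is taken
#' from `cv_regions` and the longitudinal (fiber) velocity is the
#' anisotropy ratio times the transversal one; the inferior isthmus is
#' isotropic. The posterior interatrial connection shares the interatrial-
#' connection values.
#'
#' @param mesh Atrial `cardiac_mesh`.
#' @param cv_regions Named numeric vector of transversal velocities (m/s)
#'   for `bulk_tissue`, `interatrial_connections`, `crista_terminalis`,
#'   `pectinate_muscles`, `inferior_isthmus`.
#' @param params Parameter registry (anisotropy ratios).
#' @return A `conduction_field`.
#' @export
build_conduction_field_atrial <- function(mesh, cv_regions,
                                          params = default_params()) {
  need <- c("bulk_tissue", "interatrial_connections", "crista_terminalis",
            "pectinate_muscles", "inferior_isthmus")
  missing_cv <- setdiff(need, names(cv_regions))
  if (length(missing_cv)) {
    stop("missing conduction velocities for: ",
         paste(missing_cv, collapse = ", "))
  }
  reg_of <- function(r) {
    ifelse(r %in% c("bachmanns_bundle", "posterior_connection"),
           "interatrial_connections", r)
  }
  present <- unique(reg_of(mesh$elem_region))
  missing_tag <- setdiff(setdiff(need, "interatrial_connections"), present)
  if (length(missing_tag)) {
    stop("mesh lacks region tags: ", paste(missing_tag, collapse = ", "))
  }
  ne <- nrow(mesh$elems)
  elem_cv <- matrix(0, ne, 3)
  rr <- reg_of(mesh$elem_region)
  cvt <- unname(cv_regions[rr])
  ar <- vapply(params$atrial_cv[rr], `[[`, numeric(1), "ar")
  elem_cv[, 1] <- ar * cvt
  elem_cv[, 2] <- cvt
  elem_cv[, 3] <- cvt
  structure(list(elem_cv = elem_cv, region = mesh$elem_region,
                 inert = rep(FALSE, ne)), class = "conduction_field")
}

## Approximate apico-basal arc length of a chamber (mid-wall meridian).
.chamber_arc <- function(mesh, chamber) {
  an <- mesh$anatomy
  if (is.null(an)) return(max(mesh$nodes[, 3]) - min(mesh$nodes[, 3]))
  ax <- if (chamber == "rv") an$rv_endo_axes + an$rv_wall / 2 else
    an$lv_endo_axes + an$lv_wall / 2
  th <- seq(-pi / 2, asin(min(2 * an$base_frac - 1, 1)), length.out = 100)
  pts <- cbind(ax[1] * cos(th), 0, ax[3] * sin(th))
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Fascicular breakthrough source sets
#'
#' Places the five disc-shaped fascicular node sets of the His-Purkinje
#' surrogate from their universal-coordinate specification: each disc
#' sits on the transmural shell `rho = rho_site`, spans a radius
#' `r * L_arc` (fraction of the chamber's apico-basal arc length) around
#' the site center, and is at least one node layer thick. Every site
#' carries its activation delay (10 ms fixed, except the sampled moderator
#' band delay).
#'
#' @param mesh Ventricular `cardiac_mesh` with UVCs.
#' @param omega_qrs Named list of sites (e.g. from
#'   [sample_fascicular_sites()]); each entry has `chamber`, `rho`,
#'   `phi`, `z`, `r`, `t`.
#' @return A `source_set`: list of `list(name, nodes, delay)`.
#' @export
fascicular_sources <- function(mesh, omega_qrs) {
  if (is.null(mesh$uvc)) stop("mesh has no universal coordinates")
  uvc <- mesh$uvc
  out <- lapply(names(omega_qrs), function(nm) {
    st <- omega_qrs[[nm]]
    if (st$rho < 0 || st$rho > 1 || st$z < 0 || st$z > 1 ||
        st$phi < -pi - 1e-9 || st$phi > pi + 1e-9) {
      stop("site ", nm, " UVC outside mesh range")
    }
    ch <- uvc$v == st$chamber
    dphi <- atan2(sin(uvc$phi - st$phi), cos(uvc$phi - st$phi))
    d2 <- (uvc$rho - st$rho)^2 + (0.5 * dphi)^2 + (uvc$z - st$z)^2
    d2[!ch] <- Inf
    center <- which.min(d2)
    wall <- if (st$chamber == "rv") mesh$anatomy$rv_wall else
      mesh$anatomy$lv_wall
    rho_band <- max(0.005, 0.75 * mesh$res / wall)
    rad <- st$r * .chamber_arc(mesh, st$chamber)
    dist <- sqrt(rowSums(sweep(mesh$nodes, 2, mesh$nodes[center, ], "-")^2))
    nodes <- which(ch & abs(uvc$rho - st$rho) <= rho_band & dist <= rad)
    if (!length(nodes)) nodes <- center
    list(name = nm, nodes = nodes, delay = st$t)
  })
  names(out) <- names(omega_qrs)
  structure(out, class = "source_set")
}

#' Sinoatrial source set
#'
#' @param mesh Atrial `cardiac_mesh` (with `sa_nodes`).
#' @param delay Activation delay, ms.
#' @return A `source_set` with the single sinoatrial exit site.
#' @export
sa_node_sources <- function(mesh, delay = 0) {
  structure(list(sa = list(name = "sa", nodes = mesh$sa_nodes,
                           delay = delay)),
            class = "source_set")
}

## Per-node conduction triple: each node takes the full (cv_f, cv_s, cv_n)
## of its fastest incident element, so thin fast layers stay connected; a
## node is inert only if all incident elements are inert.
.node_cv <- function(mesh, cond) {
  nn <- nrow(mesh$nodes)
  idx <- as.vector(mesh$elems)
  cvf <- rep(cond$elem_cv[, 1], 8)
  cvf[rep(cond$inert, 8)] <- -1
  o <- order(cvf)
  out <- matrix(0, nn, 3)
  oi <- idx[o]
  out[oi, 1] <- rep(cond$elem_cv[, 1], 8)[o]
  out[oi, 2] <- rep(cond$elem_cv[, 2], 8)[o]
  out[oi, 3] <- rep(cond$elem_cv[, 3], 8)[o]
  inert_contrib <- rep(cond$inert, 8)
  any_live <- rep(FALSE, nn)
  any_live[idx[!inert_contrib]] <- TRUE
  out[!any_live, ] <- 0
  out
}

#' Solve the anisotropic Eikonal problem
#'
#' Computes per-node local activation times as shortest arrival over the
#' 26-neighborhood lattice graph with the anisotropic edge metric
#' `||e||_M`, `M = R diag(cv_f^-2, cv_s^-2, cv_n^-2) R^T` (edge slowness
#' averaged between its endpoints), minimized over all sources plus their
#' delays. Nodes with no path through conducting tissue get `+Inf`.
#'
#' @param mesh A `cardiac_mesh`.
#' @param cond A `conduction_field`.
#' @param sources A `source_set`.
#' @return Numeric per-node LAT vector (ms), class `activation_map`.
#' @export
solve_eikonal <- function(mesh, cond, sources) {
  if (!length(sources)) stop("empty source set")
  eg <- mesh_edges(mesh)
  ncv <- .node_cv(mesh, cond)
  u <- eg$edge_vec / eg$edge_len
  slow_at <- function(i) {
    pf <- rowSums(u * mesh$fib_f[i, , drop = FALSE])
    ps <- rowSums(u * mesh$fib_s[i, , drop = FALSE])
    pn <- rowSums(u * mesh$fib_n[i, , drop = FALSE])
    s2 <- pf^2 / ncv[i, 1]^2 + ps^2 / ncv[i, 2]^2 + pn^2 / ncv[i, 3]^2
    sqrt(s2)
  }
  s1 <- slow_at(eg$edges[, 1])
  s2 <- slow_at(eg$edges[, 2])
  w <- eg$edge_len * (s1 + s2) / 2
  w[!is.finite(w)] <- 1e12
  nn <- nrow(mesh$nodes)
  aux <- nn + 1L
  src_nodes <- unlist(lapply(sources, `[[`, "nodes"))
  src_delay <- unlist(lapply(sources, function(s) {
    rep(s$delay, length(s$nodes))
  }))
  el <- rbind(eg$edges, cbind(rep(aux, length(src_nodes)), src_nodes))
  wt <- c(w, src_delay)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < aux) g <- igraph::add_vertices(g, aux - igraph::vcount(g))
  d <- igraph::distances(g, v = aux, weights = wt, algorithm = "dijkstra")
  lat <- as.numeric(d[1, seq_len(nn)])
  lat[lat >= 1e11] <- Inf
  structure(lat, class = "activation_map")
}

#' Grow a geodesic region around a universal-coordinate center
#'
#' Solves the Eikonal problem from the node nearest the center using the
#' supplied (healthy) conduction field and thresholds the activation map
#' at the time whose isochrone reaches geodesic radius `d_co * L`, where
#' `L` is the LV long-axis length. `d_co = 0` returns the single element
#' nearest the center.
#'
#' @param mesh Ventricular `cardiac_mesh`.
#' @param center List with `phi` and `z` (and optionally `rho`), UVC of
#'   the region center (left ventricle).
#' @param d_co Dimensionless radius fraction (>= 0).
#' @param cond `conduction_field` used for the growth metric.
#' @return Integer vector of element indices; the thresholded time is
#'   attached as attribute `t_star`, the node LAT map as `lat`.
#' @export
geodesic_region <- function(mesh, center, d_co, cond) {
  if (d_co < 0) stop("d_co must be >= 0")
  uvc <- mesh$uvc
  rho0 <- if (!is.null(center$rho)) center$rho else 0
  ch <- uvc$v == "lv"
  dphi <- atan2(sin(uvc$phi - center$phi), cos(uvc$phi - center$phi))
  d2 <- (uvc$rho - rho0)^2 + (0.5 * dphi)^2 + (uvc$z - center$z)^2
  d2[!ch] <- Inf
  cnode <- which.min(d2)
  ecn <- sqrt(rowSums(sweep(mesh$elem_center, 2, mesh$nodes[cnode, ], "-")^2))
  if (d_co == 0) {
    out <- which.min(ecn)
    attr(out, "t_star") <- 0
    return(out)
  }
  src <- structure(list(c0 = list(name = "c0", nodes = cnode, delay = 0)),
                   class = "source_set")
  lat <- solve_eikonal(mesh, cond, src)
  L <- mesh$lv_long_axis
  if (is.null(L)) L <- max(mesh$nodes[, 3]) - min(mesh$nodes[, 3])
  cv_max <- max(cond$elem_cv[, 1])
  t_star <- d_co * L / cv_max
  elat <- .elem_mean(mesh, ifelse(is.finite(lat), lat, 1e9))
  out <- which(elat <= t_star & mesh$elem_region %in% c("lv_myo", "fast_endo",
                                                        "rv_myo"))
  out <- out[mesh$uvc$v[.elem_nearest_node(mesh, out)] == "lv"]
  if (!length(out)) out <- which.min(ecn)
  attr(out, "t_star") <- t_star
  attr(out, "lat") <- lat
  out
}

.elem_nearest_node <- function(mesh, elems) mesh$elems[elems, 1]
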