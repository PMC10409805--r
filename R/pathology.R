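## Mechanistic disease modifiers: bundle branch block, myocardial
## infarction with border zone, atrial fibrosis, interatrial conduction
## block, left atrial enlargement, and the case-configuration dispatcher.

#' Complete bundle branch block
#'
#' Removes every fascicular breakthrough site in the blocked ventricle;
#' the contralateral sites and trans-septal myocardial spread then drive
#' activation of the blocked side.
#'
#' @param sources A `source_set` from [fascicular_sources()].
#' @param side `"lv"` (LBBB) or `"rv"` (RBBB).
#' @param omega_qrs The site specification used to build `sources`
#'   (carries each site's chamber).
#' @return The reduced `source_set`.
#' @export
apply_bbb <- function(sources, side = c("lv", "rv"), omega_qrs) {
  side <- match.arg(side)
  keep <- vapply(names(sources), function(nm) {
    omega_qrs[[nm]]$chamber != side
  }, logical(1))
  out <- sources[keep]
  if (!length(out)) stop("bundle branch block would leave no sources")
  structure(out, class = "source_set")
}

#' Insert a myocardial infarction
#'
#' Grows the infarct geometry as a geodesic region around the artery-
#' specific center (healthy conduction metric), intersects it with the
#' transmural extent `rho <= rho_n`, labels the outermost 5 percent of
#' the region's area (by the growth-time ranking) as border zone and the
#' remainder as core. The core becomes electrically inert (zero
#' conduction, excluded from the forward sum); the border zone conducts
#' isotropically at `cv_bz` with the border-zone cell parameters.
#'
#' @param mesh Ventricular `cardiac_mesh`.
#' @param cond Healthy `conduction_field`.
#' @param spec List with `artery` (`"LAD"`, `"RCA"`/`"RAD"`, `"LCX"`),
#'   `center` (list with `phi`, `z`), `rho_n` (0.3 or 1.0), `d_co`,
#'   and optionally `bz_fraction`, `cv_bz`.
#' @param params Parameter registry.
#' @return List: `cond` (modified field with `infarct_core` /
#'   `infarct_bz` region labels), `core` and `bz` element indices,
#'   `bz_cell` (border-zone cell parameters).
#' @export
apply_mi <- function(mesh, cond, spec, params = default_params()) {
  bz_fraction <- if (is.null(spec$bz_fraction)) params$infarct$bz_fraction else
    spec$bz_fraction
  cv_bz <- if (is.null(spec$cv_bz)) params$infarct$cv_bz else spec$cv_bz
  center <- spec$center
  center$rho <- 0     # growth starts at the endocardial origin
  region <- geodesic_region(mesh, center, spec$d_co, cond)
  if (!length(region)) stop("infarct region is empty")
  erho <- .elem_mean(mesh, mesh$uvc$rho)
  region <- region[erho[region] <= spec$rho_n + 1e-9]
  if (!length(region)) stop("infarct region is empty after transmural cut")
  lat <- attr(region, "lat")
  if (is.null(lat)) {
    elat <- rep(0, length(region))
  } else {
    elat <- .elem_mean(mesh, ifelse(is.finite(lat), lat, 1e9))[region]
  }
  n_bz <- max(round(bz_fraction * length(region)), 1L)
  if (length(region) == 1L) n_bz <- 0L
  ord <- order(elat, decreasing = TRUE)
  bz <- region[ord[seq_len(n_bz)]]
  core <- setdiff(region, bz)
  cond$elem_cv[core, ] <- 0
  cond$inert[core] <- TRUE
  cond$elem_cv[bz, ] <- cv_bz
  cond$region[core] <- "infarct_core"
  cond$region[bz] <- "infarct_bz"
  list(cond = cond, core = core, bz = bz, region = region,
       bz_cell = params$ms_bz)
}

#' Apply fibrotic atrial cardiomyopathy remodeling
#'
#' Grows seeded patches over the atrial myocardium up to the requested
#' volume fraction; inside the patches, `removal_fraction` of the
#' elements become passive conduction barriers (inert, excluded from the
#' forward sum) and the survivors keep fibrotic conduction: longitudinal
#' velocity scaled by 0.5 and transversal by 0.2, raising the anisotropy
#' ratio by exactly 2.5.
#'
#' @param mesh Atrial `cardiac_mesh`.
#' @param cond Atrial `conduction_field`.
#' @param spec List with `volume_fraction`, `seed`, and optionally
#'   `removal_fraction`, `cv_factor_long`, `cv_factor_trans`.
#' @param params Parameter registry.
#' @return List: `cond` (modified, `fibrotic` region labels), `patch`,
#'   `removed`, `surviving` element indices.
#' @export
apply_fibrosis <- function(mesh, cond, spec, params = default_params()) {
  fb <- params$fibrosis
  rem_f <- if (is.null(spec$removal_fraction)) fb$removal_fraction else
    spec$removal_fraction
  fl <- if (is.null(spec$cv_factor_long)) fb$cv_factor_long else
    spec$cv_factor_long
  ft <- if (is.null(spec$cv_factor_trans)) fb$cv_factor_trans else
    spec$cv_factor_trans
  frac <- spec$volume_fraction
  if (frac == 0) {
    return(list(cond = cond, patch = integer(0), removed = integer(0),
                surviving = integer(0)))
  }
  eligible <- which(!(mesh$elem_region %in%
                        c("bachmanns_bundle", "posterior_connection")))
  target <- round(frac * length(eligible))
  if (target > length(eligible)) stop("fibrosis fraction exceeds atrial volume")
  set.seed(as.integer(spec$seed))
  n_seed <- max(2L, round(target / 200))
  seeds <- sample(eligible, n_seed)
  patch <- .grow_patches(mesh, seeds, target, eligible)
  removed <- patch[stats::runif(length(patch)) < rem_f]
  surviving <- setdiff(patch, removed)
  cond$elem_cv[removed, ] <- 0
  cond$inert[removed] <- TRUE
  cond$elem_cv[surviving, 1] <- cond$elem_cv[surviving, 1] * fl
  cond$elem_cv[surviving, 2:3] <- cond$elem_cv[surviving, 2:3] * ft
  cond$region[patch] <- "fibrotic"
  list(cond = cond, patch = patch, removed = removed, surviving = surviving)
}

## Multi-source breadth-first patch growth over the voxel face adjacency.
.grow_patches <- function(mesh, seeds, target, eligible) {
  key <- .lattice_key(mesh$elem_lattice)
  elig_mask <- rep(FALSE, nrow(mesh$elems))
  elig_mask[eligible] <- TRUE
  ord <- order(key)
  skey <- key[ord]
  K <- 4096
  offs <- c(K * K, -K * K, K, -K, 1, -1)
  in_patch <- rep(FALSE, nrow(mesh$elems))
  in_patch[seeds] <- TRUE
  frontier <- seeds
  count <- length(seeds)
  while (count < target && length(frontier)) {
    nb <- integer(0)
    for (d in offs) {
      hit <- match(key[frontier] + d, skey)
      cand <- ord[hit[!is.na(hit)]]
      nb <- c(nb, cand)
    }
    nb <- unique(nb)
    nb <- nb[elig_mask[nb] & !in_patch[nb]]
    if (!length(nb)) break
    nb <- sample(nb)   # random order so patch boundaries are irregular
    take <- min(length(nb), target - count)
    nb <- nb[seq_len(take)]
    in_patch[nb] <- TRUE
    count <- count + take
    frontier <- nb
  }
  which(in_patch)
}

#' Complete interatrial conduction block
#'
#' Inhibits conduction through every Bachmann's-bundle element. The
#' posterior interatrial connection remains, so the left atrium is still
#' (retrogradely, more slowly) reachable; the function refuses to block
#' when that would disconnect the left atrium entirely.
#'
#' @param mesh Atrial `cardiac_mesh`.
#' @param cond Atrial `conduction_field`.
#' @return The modified `conduction_field`.
#' @export
apply_iab <- function(mesh, cond) {
  bb <- which(mesh$elem_region == "bachmanns_bundle")
  if (!length(bb)) stop("mesh has no Bachmann's bundle elements")
  alt <- which(mesh$elem_region == "posterior_connection" & !cond$inert)
  if (!length(alt)) {
    stop("blocking Bachmann's bundle would disconnect the left atrium")
  }
  cond$elem_cv[bb, ] <- 0
  cond$inert[bb] <- TRUE
  cond
}

#' Build a complete case configuration from a label and parameter sample
#'
#' Dispatches the pathology label to its mechanistic modifier settings:
#' `sinus` is the identity, `lbbb`/`rbbb` drop fascicular sites, the six
#' `mi_*` cases carry an artery-specific infarct specification, `fam`
#' carries a fibrosis specification, `iab` flags the Bachmann's-bundle
#' block, `lae` enlarges the left atrium, and `avblock` flags the
#' synthesis stage to sample PQ above 200 ms.
#'
#' @param label One of [case_labels()].
#' @param sample A one-row parameter sample (see [sample_case()]).
#' @param params Parameter registry.
#' @return A named list (`case_config`) consumed by
#'   [generate_record()].
#' @export
make_case_config <- function(label, sample, params = default_params()) {
  if (!label %in% case_labels()) {
    stop("unknown case label '", label, "'; valid labels: ",
         paste(case_labels(), collapse = ", "))
  }
  cfg <- list(label = label, class = sub("_.*", "", label), sample = sample,
              bbb = NULL, mi = NULL, fibrosis = NULL, iab = FALSE,
              avb = FALSE, la_volume_scale = 1)
  if (label == "lbbb") cfg$bbb <- "lv"
  if (label == "rbbb") cfg$bbb <- "rv"
  if (label == "avblock") cfg$avb <- TRUE
  if (label == "iab") cfg$iab <- TRUE
  if (label == "lae") cfg$la_volume_scale <- sample$lae_scale
  if (label == "fam") {
    lvl <- min(max(ceiling(sample$fam_u * 9), 1), 9)
    cfg$fibrosis <- list(volume_fraction = params$fibrosis$fractions[lvl],
                         seed = sample$seed)
  }
  if (grepl("^mi_", label)) {
    parts <- strsplit(label, "_")[[1]]
    artery <- parts[2]
    rho_n <- as.numeric(parts[3])
    cfg$mi <- list(artery = artery, rho_n = rho_n, d_co = sample$mi_d_co,
                   center = .mi_center(artery, sample$mi_u, sample$mi_z,
                                       params))
    cfg$mi_subclass <- paste(artery, format(rho_n, nsmall = 1), sep = "_")
  }
  cfg
}
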