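test_that("bundle branch block removes exactly the blocked side's sites", {
  m <- fx_small_vent()
  rows <- sample_case(1, 21)
  sites <- sample_fascicular_sites(rows[1, ])
  src <- fascicular_sources(m, sites)
  lbbb <- apply_bbb(src, "lv", sites)
  expect_setequal(names(lbbb), c("rv_mod", "rv_sept"))
  rbbb <- apply_bbb(src, "rv", sites)
  expect_setequal(names(rbbb), c("lv_ant", "lv_post", "lv_sept"))
  ## blocking a side with no sites present is a no-op
  expect_identical(names(apply_bbb(rbbb, "rv", sites)), names(rbbb))
  expect_error(apply_bbb(apply_bbb(src, "lv", sites), "rv", sites))
})

test_that("bundle branch block still activates the blocked ventricle, slower", {
  m <- cache_edges(fx_small_vent())
  rows <- sample_case(1, 22)
  sites <- sample_fascicular_sites(rows[1, ])
  src <- fascicular_sources(m, sites)
  cond <- build_conduction_field_ventricular(m)
  lat_h <- solve_eikonal(m, cond, src)
  lat_l <- solve_eikonal(m, cond, apply_bbb(src, "lv", sites))
  expect_true(all(is.finite(lat_l[m$uvc$v == "lv"])))
  expect_gt(max(lat_l[is.finite(lat_l)]), max(lat_h[is.finite(lat_h)]))
})

test_that("infarcts respect transmural extent and border-zone construction", {
  bundle <- fx_bundle()
  m <- bundle$vmesh
  cond <- build_conduction_field_ventricular(m)
  spec <- list(artery = "LAD", rho_n = 1.0, d_co = 0.5,
               center = list(phi = 1.0, z = 0.5))
  mi <- apply_mi(m, cond, spec)
  expect_gt(length(mi$region), 50)
  expect_length(intersect(mi$core, mi$bz), 0)
  expect_setequal(c(mi$core, mi$bz), mi$region)
  frac <- length(mi$bz) / length(mi$region)
  expect_lt(abs(frac - 0.05), 0.02)
  expect_true(all(mi$cond$elem_cv[mi$core, ] == 0))
  expect_true(all(mi$cond$elem_cv[mi$bz, ] == 0.15))
  ## subendocardial variant stays within rho <= 0.3
  spec3 <- list(artery = "LAD", rho_n = 0.3, d_co = 0.4,
                center = list(phi = 1.0, z = 0.5))
  mi3 <- apply_mi(m, cond, spec3)
  erho <- ecgsynth:::.elem_mean(m, m$uvc$rho)
  expect_true(all(erho[mi3$region] <= 0.3 + 1e-9))
  ## core is unreachable after the solve
  rows <- sample_case(1, 23)
  src <- fascicular_sources(m, sample_fascicular_sites(rows[1, ]))
  live <- lapply(src, function(s) {
    s$nodes <- setdiff(s$nodes, unique(as.vector(m$elems[mi$core, ]))); s
  })
  live <- structure(Filter(function(s) length(s$nodes) > 0, live),
                    class = "source_set")
  lat <- solve_eikonal(m, mi$cond, live)
  core_only <- setdiff(unique(as.vector(m$elems[mi$core, ])),
                       unique(as.vector(m$elems[-mi$core, ])))
  expect_true(all(!is.finite(lat[core_only])))
  ## removing the infarct recovers the healthy activation map exactly
  lat_h <- solve_eikonal(m, cond, src)
  lat_same <- solve_eikonal(m, cond, src)
  expect_identical(lat_h, lat_same)
})

test_that("fibrosis removes half the patch and raises anisotropy 2.5-fold", {
  a <- fx_atrial()
  cvs <- c(bulk_tissue = 0.7, interatrial_connections = 0.6,
           crista_terminalis = 0.7, pectinate_muscles = 0.8,
           inferior_isthmus = 0.7)
  cond <- build_conduction_field_atrial(a, cvs)
  fib <- apply_fibrosis(a, cond, list(volume_fraction = 0.3, seed = 5))
  expect_gt(length(fib$patch), 0.29 * sum(!(a$elem_region %in%
    c("bachmanns_bundle", "posterior_connection"))))
  rem_frac <- length(fib$removed) / length(fib$patch)
  expect_lt(abs(rem_frac - 0.5), 0.03)
  ## anisotropy ratio of survivors exactly 2.5x the healthy ratio
  sv <- fib$surviving[1]
  ar_h <- cond$elem_cv[sv, 1] / cond$elem_cv[sv, 3]
  ar_f <- fib$cond$elem_cv[sv, 1] / fib$cond$elem_cv[sv, 3]
  expect_equal(ar_f / ar_h, 2.5)
  ## zero fraction is the identity
  fib0 <- apply_fibrosis(a, cond, list(volume_fraction = 0, seed = 5))
  expect_identical(fib0$cond, cond)
  ## removed volume over seeds matches fraction x removal within 3 sigma
  for (sd in c(11, 12, 13)) {
    f <- apply_fibrosis(a, cond, list(volume_fraction = 0.25, seed = sd))
    n <- length(f$patch)
    expect_lt(abs(length(f$removed) / n - 0.5), 3 * sqrt(0.25 / n) + 1e-9)
  }
})

test_that("interatrial block leaves the left atrium reachable but delayed", {
  a <- fx_atrial()
  cvs <- c(bulk_tissue = 0.7, interatrial_connections = 0.6,
           crista_terminalis = 0.7, pectinate_muscles = 0.8,
           inferior_isthmus = 0.7)
  cond <- build_conduction_field_atrial(a, cvs)
  src <- sa_node_sources(a)
  lat_h <- solve_eikonal(a, cond, src)
  cond_iab <- apply_iab(a, cond)
  lat_i <- solve_eikonal(a, cond_iab, src)
  la <- a$chamber == "la"
  expect_true(any(is.finite(lat_i[la])))
  expect_gt(min(lat_i[la], na.rm = TRUE), min(lat_h[la], na.rm = TRUE))
  ## RA activation is unchanged (propagation is SA-node-outward);
  ## nodes of the blocked bridge itself are exempt
  bridge_nodes <- unique(as.vector(a$elems[a$elem_region %in%
    c("bachmanns_bundle", "posterior_connection"), ]))
  ra_far <- a$chamber == "ra" & is.finite(lat_h) &
    lat_h < min(lat_h[la]) - 5
  ra_far[bridge_nodes] <- FALSE
  expect_equal(lat_i[ra_far], lat_h[ra_far], tolerance = 1e-9)
  ## blocking with no remaining pathway is refused
  cond_dead <- cond
  cond_dead$inert[a$elem_region == "posterior_connection"] <- TRUE
  expect_error(apply_iab(a, cond_dead), "disconnect")
})

test_that("case configurations dispatch all thirteen labels", {
  rows <- sample_case(1, 31)
  expect_length(case_labels(), 13)
  cfgs <- lapply(case_labels(), make_case_config, sample = rows[1, ])
  expect_length(unique(vapply(cfgs, `[[`, "", "label")), 13)
  sin <- cfgs[[1]]
  expect_null(sin$bbb); expect_null(sin$mi); expect_false(sin$avb)
  lcx <- make_case_config("mi_LCX_1.0", rows[1, ])
  expect_true(abs(lcx$mi$center$phi) >= 2 & abs(lcx$mi$center$phi) <= pi)
  expect_equal(lcx$mi_subclass, "LCX_1.0")
  mi_classes <- grep("^mi_", case_labels(), value = TRUE)
  expect_length(mi_classes, 6)
  expect_error(make_case_config("flutter", rows[1, ]), "valid labels")
})
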