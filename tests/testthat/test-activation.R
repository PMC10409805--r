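pp <- default_params()

slab_sources <- function(mesh, at = c(0, 10, 10), delay = 0) {
  node <- which.min(rowSums(sweep(mesh$nodes, 2, at, "-")^2))
  structure(list(s = list(name = "s", nodes = node, delay = delay)),
            class = "source_set")
}

test_that("ventricular conduction field assigns myocardial and endo speeds", {
  m <- fx_small_vent()
  cond <- build_conduction_field_ventricular(m)
  fast <- cond$region == "fast_endo"
  expect_gt(sum(fast), 0)
  expect_true(all(cond$elem_cv[fast, ] == 2.0))
  myo <- which(!fast)[1:50]
  expect_true(all(cond$elem_cv[myo, 1] == 0.6))
  expect_true(all(cond$elem_cv[myo, 2] == 0.3))
  expect_true(all(cond$elem_cv[myo, 3] == 0.15))
  ## endo layer restricted to the apico-basal band
  ez <- ecgsynth:::.elem_mean(m, m$uvc$z)
  expect_true(all(!fast[ez > 0.92]))
})

test_that("atrial conduction field applies regional anisotropy ratios", {
  a <- fx_atrial()
  cvs <- c(bulk_tissue = 0.7, interatrial_connections = 0.5,
           crista_terminalis = 0.6, pectinate_muscles = 0.8,
           inferior_isthmus = 0.62)
  cond <- build_conduction_field_atrial(a, cvs)
  bulk <- a$elem_region == "bulk_tissue"
  expect_equal(unique(cond$elem_cv[bulk, 1]), 0.7 * 1.94)
  expect_equal(unique(cond$elem_cv[bulk, 2]), 0.7)
  ii <- a$elem_region == "inferior_isthmus"
  expect_true(all(cond$elem_cv[ii, 1] == cond$elem_cv[ii, 3]))
  bb <- a$elem_region == "bachmanns_bundle"
  expect_equal(unique(cond$elem_cv[bb, 1]), 0.5 * 3)
  expect_error(build_conduction_field_atrial(a, cvs[-1]), "missing")
})

test_that("fascicular sources form disjoint correctly-sided discs", {
  m <- fx_small_vent()
  rows <- sample_case(1, 9)
  sites <- sample_fascicular_sites(rows[1, ])
  src <- fascicular_sources(m, sites)
  expect_length(src, 5)
  for (nm in names(src)) {
    expect_gt(length(src[[nm]]$nodes), 0)
    expect_true(all(m$uvc$v[src[[nm]]$nodes] == sites[[nm]]$chamber))
  }
  lv_sets <- lapply(src[c("lv_sept", "lv_ant", "lv_post")], `[[`, "nodes")
  expect_length(Reduce(intersect, lv_sets), 0)
  ## delay bookkeeping and degenerate radius
  expect_equal(src$rv_mod$delay, sites$rv_mod$t)
  sites0 <- sites
  sites0$lv_ant$r <- 0
  src0 <- fascicular_sources(m, sites0)
  expect_length(src0$lv_ant$nodes, 1)
  sites_bad <- sites
  sites_bad$lv_ant$z <- 1.4
  expect_error(fascicular_sources(m, sites_bad), "outside")
})

test_that("the Eikonal solve matches closed forms on homogeneous slabs", {
  m <- cache_edges(build_slab_mesh(c(40, 20, 20), 1, c(1, 0, 0)))
  cond <- build_conduction_field_ventricular(m)
  cond$elem_cv[] <- 2.0
  src <- slab_sources(m)
  lat <- solve_eikonal(m, cond, src)
  i10 <- which(m$nodes[, 1] == 10 & m$nodes[, 2] == 10 & m$nodes[, 3] == 10)
  expect_equal(lat[i10], 5, tolerance = 1e-9)
  ## shift invariance of source delays
  lat5 <- solve_eikonal(m, cond, slab_sources(m, delay = 5))
  expect_equal(lat5, lat + 5, tolerance = 1e-9, ignore_attr = TRUE)
  ## anisotropic: fitted fiber-axis speed = 0.6 within 2 percent
  cond$elem_cv[] <- matrix(c(0.6, 0.3, 0.15), nrow(m$elems), 3, byrow = TRUE)
  lat_a <- solve_eikonal(m, cond, src)
  ax <- which(m$nodes[, 2] == 10 & m$nodes[, 3] == 10 & m$nodes[, 1] > 0)
  fit <- stats::coef(stats::lm(lat_a[ax] ~ m$nodes[ax, 1]))
  expect_lt(abs(1 / fit[2] - 0.6) / 0.6, 0.02)
  ## arbitrary off-lattice direction within 8 percent (isotropic field)
  cond$elem_cv[] <- 1.0
  lat_i <- solve_eikonal(m, cond, src)
  tgt <- which(m$nodes[, 1] == 20 & m$nodes[, 2] == 18 & m$nodes[, 3] == 14)
  d <- sqrt(sum((m$nodes[tgt, ] - c(0, 10, 10))^2))
  expect_lt(abs(lat_i[tgt] - d) / d, 0.08)
  expect_error(solve_eikonal(m, cond, structure(list(),
                                                class = "source_set")),
               "empty")
})

test_that("raising conduction velocities never raises activation times", {
  m <- cache_edges(build_slab_mesh(c(20, 12, 12), 2))
  cond1 <- build_conduction_field_ventricular(m)
  cond1$elem_cv[] <- 0.5
  cond2 <- cond1
  set.seed(1)
  faster <- sample(nrow(m$elems), 200)
  cond2$elem_cv[faster, ] <- 1.5
  src <- slab_sources(m, c(0, 6, 6))
  l1 <- solve_eikonal(m, cond1, src)
  l2 <- solve_eikonal(m, cond2, src)
  expect_true(all(l2 <= l1 + 1e-9))
  ## blocking elements cannot decrease any activation time
  cond3 <- cond1
  blocked <- which(abs(m$elem_center[, 1] - 10) < 2)
  cond3$elem_cv[blocked, ] <- 0
  cond3$inert[blocked] <- TRUE
  l3 <- solve_eikonal(m, cond3, src)
  expect_true(all(l3 >= l1 - 1e-9))
  expect_true(any(!is.finite(l3)) || max(l3) > max(l1))
})

test_that("geodesic regions are nested and match the isotropic ball", {
  m <- cache_edges(build_slab_mesh(c(30, 30, 10), 1))
  m$uvc$v <- "lv"
  m$lv_long_axis <- 30
  cond <- build_conduction_field_ventricular(m)
  cond$elem_cv[] <- 1.0
  ctr <- list(phi = 0, z = 0.5, rho = 0.5)
  m$uvc$phi <- 0; m$uvc$z <- 0.5; m$uvc$rho <- 0.5
  ## anchor the center at a known node
  cn <- which.min(rowSums(sweep(m$nodes, 2, c(15, 15, 5), "-")^2))
  m$uvc$phi[] <- 1; m$uvc$phi[cn] <- 0
  r0 <- geodesic_region(m, ctr, 0, cond)
  expect_length(r0, 1)
  r1 <- geodesic_region(m, ctr, 0.2, cond)
  r2 <- geodesic_region(m, ctr, 0.35, cond)
  expect_true(all(r1 %in% r2))
  ## isotropic field: region ~ Euclidean ball of radius d_co * L
  rad <- 0.2 * 30
  d <- sqrt(rowSums(sweep(m$elem_center, 2, m$nodes[cn, ], "-")^2))
  inside <- which(d <= rad - 1.8)
  outside_far <- which(d > rad + 1.8)
  expect_true(all(inside %in% r1))
  expect_length(intersect(outside_far, r1), 0)
  expect_error(geodesic_region(m, ctr, -1, cond))
})
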