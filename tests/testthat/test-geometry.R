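test_that("ventricular mesh carries valid universal coordinates", {
  m <- fx_small_vent()
  expect_gt(nrow(m$nodes), 0)
  expect_true(all(m$uvc$rho >= 0 & m$uvc$rho <= 1))
  expect_true(all(m$uvc$z >= 0 & m$uvc$z <= 1))
  expect_true(all(m$uvc$phi >= -pi & m$uvc$phi <= pi))
  expect_setequal(unique(m$uvc$v), c("lv", "rv"))
  expect_true(all(m$elem_vol > 0))
})

test_that("halving the resolution grows the element count ~8x", {
  an <- default_anatomy(resolution = 3)
  an$lv_endo_axes <- c(12, 12, 24); an$lv_wall <- 9
  an$rv_endo_axes <- c(19, 16, 25); an$rv_wall <- 4
  an$rv_offset <- c(-10, 6, 4)
  n3 <- nrow(build_ventricular_mesh(an)$elems)
  an$resolution <- 1.5
  n15 <- nrow(build_ventricular_mesh(an)$elems)
  expect_gt(n15 / n3, 8 * 0.8)
  expect_lt(n15 / n3, 8 * 1.2)
})

test_that("transmural coordinate matches the analytic ellipsoid offset", {
  ## points placed on the endocardial ellipsoid offset by 2.4 mm must get
  ## rho = 2.4 / 12 = 0.2 for a 12 mm wall
  a_endo <- c(20, 20, 44); wall <- 12
  th <- seq(-1.2, 0.4, length.out = 7)
  ph <- seq(0, 2 * pi, length.out = 9)
  g <- expand.grid(th = th, ph = ph)
  a <- a_endo + 2.4
  p <- cbind(a[1] * cos(g$th) * cos(g$ph), a[2] * cos(g$th) * sin(g$ph),
             a[3] * sin(g$th))
  rho <- ecgsynth:::.ell_rho(p, c(0, 0, 0), a_endo, wall)
  expect_equal(rho, rep(0.2, nrow(p)), tolerance = 1e-6)
})

test_that("resolution too coarse for the wall is rejected", {
  an <- default_anatomy(resolution = 5)
  expect_error(build_ventricular_mesh(an), "coarse")
})

test_that("fiber helix angle is linear in rho with exact endpoint values", {
  m <- fx_small_vent()
  expected <- 60 + m$uvc$rho * (-60 - 60)
  expect_equal(m$node_alpha, expected)
  at0 <- which(m$uvc$rho == 0)
  at1 <- which(m$uvc$rho == 1)
  expect_true(all(m$node_alpha[at0] == 60))
  expect_true(all(m$node_alpha[at1] == -60))
})

test_that("fiber triads are orthonormal to 1e-6", {
  m <- fx_small_vent()
  expect_lt(max(abs(rowSums(m$fib_f * m$fib_s))), 1e-6)
  expect_lt(max(abs(rowSums(m$fib_f * m$fib_n))), 1e-6)
  expect_lt(max(abs(rowSums(m$fib_s * m$fib_n))), 1e-6)
  expect_equal(rowSums(m$fib_f^2), rep(1, nrow(m$nodes)), tolerance = 1e-6)
  expect_error(assign_ventricular_fibers(build_slab_mesh()["nodes"]))
})

test_that("atrial mesh has all conduction regions, bridges and SA site", {
  a <- fx_atrial()
  regs <- unique(a$elem_region)
  for (r in c("bulk_tissue", "crista_terminalis", "pectinate_muscles",
              "inferior_isthmus", "bachmanns_bundle",
              "posterior_connection")) {
    expect_true(r %in% regs, label = paste("region", r))
  }
  expect_gt(length(a$sa_nodes), 0)
  expect_true(all(a$chamber[a$sa_nodes] == "ra"))
})

test_that("left-atrial volume scales monotonically and scale < 1 errors", {
  an <- default_anatomy()
  n_la_1 <- sum(build_atrial_mesh(an)$chamber == "la")
  an13 <- default_anatomy(la_volume_scale = 1.3)
  n_la_13 <- sum(build_atrial_mesh(an13)$chamber == "la")
  expect_gt(n_la_13, n_la_1)
  expect_error(build_atrial_mesh(
    default_anatomy() |> (\(x) { x$la_volume_scale <- 0.9; x })()
  ))
})

test_that("rigid placement matches the rotation-matrix oracle", {
  m <- build_slab_mesh(c(10, 10, 10), 2)
  pose0 <- default_pose()
  m0 <- place_and_project(m, pose0)
  expect_equal(m0$nodes, m$nodes)
  pose <- default_pose(alpha_z = 20)
  mz <- place_and_project(m, pose)
  th <- 20 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(mz$nodes, m$nodes %*% t(R), tolerance = 1e-9)
  ## inverse composition returns the identity
  pose_f <- default_pose(10, -15, 20, 3, -4, 5)
  mf <- place_and_project(m, pose_f)
  Rf <- rotation_xyz(10, -15, 20)
  back <- sweep(mf$nodes, 2, c(3, -4, 5), "-") %*% Rf
  expect_equal(back, m$nodes, tolerance = 1e-9)
  ## pairwise distances preserved
  i <- c(1, 5, 9); j <- c(20, 40, 60)
  d0 <- sqrt(rowSums((m$nodes[i, ] - m$nodes[j, ])^2))
  d1 <- sqrt(rowSums((mf$nodes[i, ] - mf$nodes[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("latin hypercube samples occupy every stratum exactly once", {
  rg <- list(z = c(0.1, 0.6), r = c(0.2, 0.8), t = c(0, 10))
  s <- lhs_sample(rg, 10, seed = 11)
  for (nm in names(rg)) {
    lo <- rg[[nm]][1]; hi <- rg[[nm]][2]
    strata <- floor((s[[nm]] - lo) / (hi - lo) * 10)
    expect_setequal(strata, 0:9)
  }
  ## property over several seeds and sizes
  for (seed in c(3, 17, 99)) {
    n <- 5 + seed %% 7
    s2 <- lhs_sample(rg, n, seed)
    for (nm in names(rg)) {
      lo <- rg[[nm]][1]; hi <- rg[[nm]][2]
      expect_setequal(floor((s2[[nm]] - lo) / (hi - lo) * n), 0:(n - 1))
    }
  }
  expect_identical(lhs_sample(rg, 7, 5), lhs_sample(rg, 7, 5))
  expect_equal(nrow(lhs_sample(rg, 1, 2)), 1)
  expect_error(lhs_sample(list(bad = c(2, 1)), 5, 1), "inverted")
})

test_that("the run configuration round-trips through YAML", {
  f <- tempfile(fileext = ".yml")
  an <- default_anatomy(resolution = 2.5, la_volume_scale = 1.2)
  write_config(f, anatomy = an)
  back <- read_config(f)
  expect_equal(back$anatomy$resolution, 2.5)
  expect_equal(back$anatomy$la_volume_scale, 1.2)
  expect_equal(back$params$conduction$cv_myo,
               default_params()$conduction$cv_myo)
  expect_equal(back$synth$mvn$A$cor, default_synth_config()$mvn$A$cor)
  expect_equal(unlist(back$params$fascicular_sites$rv_mod$z), c(0.1, 0.6))
})

test_that("VTK export round-trips nodes, elements and point data", {
  m <- build_slab_mesh(c(6, 6, 6), 2)
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f, point_data = list(lat = seq_len(nrow(m$nodes)) * 0.5))
  back <- read_mesh_vtk(f)
  expect_equal(back$nodes, unname(m$nodes), tolerance = 1e-6)
  expect_equal(back$elems, unname(m$elems))
  expect_equal(back$point_data$lat, seq_len(nrow(m$nodes)) * 0.5,
               tolerance = 1e-6)
})
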