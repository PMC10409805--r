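pp <- default_params()

test_that("transmembrane field evaluation shifts templates by activation time", {
  bk <- fx_sinus_bank()
  lat <- c(0, 5, Inf)
  V <- evaluate_tmv(structure(lat, class = "activation_map"),
                    rep(200, 3), bk, seq(0, 300, by = 1))
  ## before any activation every node rests
  expect_true(all(V[, 1] == -86.2))
  ## the delayed node replays the first node's trace shifted by 5 ms
  expect_equal(V[2, 6:301], V[1, 1:296])
  ## inert nodes stay at rest forever
  expect_true(all(V[3, ] == -86.2))
  ## uniform LAT and APD give a spatially uniform field
  Vu <- evaluate_tmv(structure(c(3, 3), class = "activation_map"),
                     c(210, 210), bk, seq(0, 100, 1))
  expect_equal(Vu[1, ], Vu[2, ])
  expect_error(evaluate_tmv(structure(0, class = "activation_map"),
                            500, bk, 0:10), "outside")
})

test_that("the forward operator matches the point-dipole closed form", {
  m <- build_slab_mesh(c(4, 4, 4), 2)
  sigma <- conductivity_set()
  ## single active element: nodal voltages rising along x across element 1
  nn <- nrow(m$nodes)
  V <- matrix(0, nn, 1)
  el <- 1
  nodes_el <- m$elems[el, ]
  V[nodes_el, 1] <- m$nodes[nodes_el, 1] * 10   # 10 mV/mm gradient
  ctr <- m$elem_center[el, ]
  electrode <- rbind(X = ctr + c(200, 0, 0))
  A <- forward_operator(m, electrode, sigma,
                        exclude_elems = setdiff(seq_len(nrow(m$elems)), el))
  phi <- (A %*% V)[1, 1]
  p_dip <- sigma$sigma_i_bulk * 10 * m$elem_vol[el]  # dipole moment
  expected <- p_dip / (4 * pi * sigma$sigma_medium * 200^2)
  expect_lt(abs(abs(phi) - expected) / expected, 0.01)
  ## uniform field produces zero potentials
  Vu <- matrix(-86.2, nn, 3)
  A_all <- forward_operator(m, electrode, sigma)
  expect_lt(max(abs(A_all %*% Vu)), 1e-9)
  ## doubling the medium conductivity halves potentials
  sigma2 <- conductivity_set(sigma_medium = 2 * sigma$sigma_medium)
  A2 <- forward_operator(m, electrode, sigma2,
                         exclude_elems = setdiff(seq_len(nrow(m$elems)), el))
  expect_equal(A2 %*% V, (A %*% V) / 2, tolerance = 1e-12)
  expect_error(forward_operator(m, rbind(X = ctr), sigma), "inside")
})

test_that("the forward operator is linear and decays as 1/r^2", {
  m <- build_slab_mesh(c(10, 10, 10), 2)
  sigma <- conductivity_set()
  set.seed(7)
  V1 <- matrix(rnorm(nrow(m$nodes) * 4), ncol = 4)
  V2 <- matrix(rnorm(nrow(m$nodes) * 4), ncol = 4)
  rs <- c(100, 200, 400, 800)
  el <- do.call(rbind, lapply(rs, function(r) c(5 + r, 5, 5)))
  rownames(el) <- paste0("E", rs)
  A <- forward_operator(m, el, sigma)
  expect_equal(A %*% (2 * V1 - 3 * V2), 2 * (A %*% V1) - 3 * (A %*% V2),
               tolerance = 1e-12)
  ## far-field decay exponent for a fixed random source
  mag <- abs(A %*% V1[, 1])
  slope <- stats::coef(stats::lm(log(mag) ~ log(rs)))[2]
  expect_lt(abs(slope - (-2)), 0.05)
})

test_that("potentials are invariant under rigid heart-electrode co-rotation", {
  m <- build_slab_mesh(c(10, 10, 6), 2)
  sigma <- conductivity_set()
  el <- rbind(E1 = c(150, 40, 30), E2 = c(-60, 120, -50))
  set.seed(11)
  V <- matrix(rnorm(nrow(m$nodes) * 3), ncol = 3)
  phi0 <- forward_operator(m, el, sigma) %*% V
  pose <- default_pose(12, -25, 33, 4, -6, 2)
  mr <- place_and_project(m, pose)
  R <- rotation_xyz(12, -25, 33)
  el_r <- sweep(el %*% t(R), 2, c(4, -6, 2), "+")
  rownames(el_r) <- rownames(el)
  phi1 <- forward_operator(mr, el_r, sigma) %*% V
  expect_equal(phi1, phi0, tolerance = 1e-9)
})

test_that("lead derivation obeys Einthoven and Goldberger identities", {
  set.seed(3)
  pot <- matrix(rnorm(9 * 40), 9, 40,
                dimnames = list(c("RA", "LA", "LL", paste0("V", 1:6)), NULL))
  b <- derive_leads(pot)
  s <- b$signal
  expect_lt(max(abs(s["I", ] - s["II", ] + s["III", ])), 1e-12)
  expect_lt(max(abs(s["aVR", ] + s["aVL", ] + s["aVF", ])), 1e-12)
  expect_identical(rownames(s)[1], "I")
  expect_identical(rownames(s)[7], "V1")
  expect_error(derive_leads(pot[-1, ]), "missing")
})

test_that("a simulated QRST beat has 225 samples and ordered fiducials", {
  bundle <- fx_bundle()
  rows <- sample_case(1, 55)
  cfg <- make_case_config("sinus", rows[1, ])
  bp <- simulate_beat_pair(cfg, bundle)
  expect_equal(ncol(bp$qrst$signal), 225)
  f <- bp$qrst$fiducials
  expect_lt(f$QRS_on, f$QRS_off)
  expect_lt(f$QRS_off, f$T_off)
  ## P wave window within the 150-200 ms band
  expect_gte(ncol(bp$pwave$signal) * 2, 150)
  expect_lte(ncol(bp$pwave$signal) * 2, 200)
  expect_lt(bp$pwave$fiducials$P_on, bp$pwave$fiducials$P_off)
})

test_that("without conducting tissue the P wave vanishes", {
  a <- fx_atrial()
  cvs <- c(bulk_tissue = 0.7, interatrial_connections = 0.6,
           crista_terminalis = 0.7, pectinate_muscles = 0.8,
           inferior_isthmus = 0.7)
  cond <- build_conduction_field_atrial(a, cvs)
  bank <- atrial_template_bank("healthy")
  el <- default_pose()$electrode_positions
  setup <- list(mesh = a, cond = cond, sources = sa_node_sources(a),
                apd = rep(250, nrow(a$nodes)), banks = bank,
                electrodes = el, sigma = conductivity_set(),
                exclude_elems = integer(0))
  healthy <- simulate_pwave(setup)
  cond0 <- cond; cond0$elem_cv[] <- 0
  setup$cond <- cond0
  ## only the point-like sinoatrial seed itself depolarizes
  dead <- simulate_pwave(setup)
  expect_lt(max(abs(dead$signal)), 0.05 * max(abs(healthy$signal)))
})
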