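random_stack <- function(n_slabs, rough = FALSE) {
  slab_stack(runif(1, -1e-6, 3e-6),
             thickness = runif(n_slabs, 5, 80),
             sld = runif(n_slabs, -1e-6, 8e-6),
             roughness = if (rough) runif(n_slabs, 0, 1.5) else 0,
             backing = runif(1, -1e-6, 8e-6),
             backing_roughness = if (rough) runif(1, 0, 1.5) else 0)
}

test_that("Fresnel amplitudes: total reflection, closed form, zero contrast", {
  qc <- critical_q(0, 4e-6)
  below <- fresnel_interface(seq(qc / 10, qc * 0.99, length.out = 20), 0, 4e-6)
  expect_true(all(abs(Mod(below$r) - 1) < 1e-12))
  # closed form at Q = 2 Qc: r = (2 - sqrt(3)) / (2 + sqrt(3))
  at2 <- fresnel_interface(2 * qc, 0, 4e-6)
  expect_equal(Mod(at2$r)^2, ((2 - sqrt(3)) / (2 + sqrt(3)))^2,
               tolerance = 1e-10)
  none <- fresnel_interface(0.1, 3e-6, 3e-6)
  expect_equal(Mod(none$r), 0)
  expect_equal(none$t, complex(real = 1))
})

test_that("Parratt and Abeles kernels agree to 1e-10 on random stacks", {
  set.seed(7)
  Q <- c(seq(1e-3, 0.02, length.out = 60), seq(0.021, 0.5, length.out = 120))
  for (k in 1:12) {
    st <- random_stack(sample(1:20, 1), rough = k %% 2 == 0)
    rp <- suppressWarnings(parratt_reflectivity(st, Q)$R)
    ra <- suppressWarnings(abeles_reflectivity(st, Q)$R)
    expect_lt(max(abs(rp - ra) / pmax(rp, 1e-300)), 1e-10)
    # unitarity for absorption-free stacks
    expect_true(all(rp >= 0 & rp <= 1 + 1e-12))
  }
})

test_that("Kiessig fringe spacing of a single slab is 2 pi over thickness", {
  st <- slab_stack(0, 50, 4e-6, backing = 2e-6)
  Q <- seq(0.15, 0.45, length.out = 6000)
  r <- parratt_reflectivity(st, Q)
  y <- log10(r$R)
  minima <- which(diff(sign(diff(y))) == 2) + 1L
  gaps <- diff(Q[minima])
  expect_equal(mean(gaps), 2 * pi / 50, tolerance = 0.01)
})

test_that("zero-contrast slabs and matched ends are invisible", {
  Q <- seq(0.005, 0.3, length.out = 200)
  base <- slab_stack(0, c(20, 30), c(3e-6, 1e-6), backing = 6e-6)
  padded <- slab_stack(0, c(40, 20, 30, 25), c(0, 3e-6, 1e-6, 6e-6),
                       backing = 6e-6)
  expect_lt(max(abs(parratt_reflectivity(base, Q)$R -
                      parratt_reflectivity(padded, Q)$R)), 1e-12)
})

test_that("reversing a symmetric stack leaves R unchanged", {
  Q <- seq(0.005, 0.4, length.out = 150)
  st <- slab_stack(1e-6, c(10, 25, 10), c(3e-6, -2e-7, 3e-6),
                   backing = 5e-6)
  rev_st <- slab_stack(1e-6, rev(st$thickness), Re(rev(st$sld)),
                       backing = 5e-6)
  expect_equal(parratt_reflectivity(st, Q)$R,
               parratt_reflectivity(rev_st, Q)$R, tolerance = 1e-12)
})

test_that("bare-interface reflectivity approaches the (Qc/2Q)^4 asymptote", {
  qc <- critical_q(SLD_SI, SLD_D2O)
  st <- slab_stack(SLD_SI, backing = SLD_D2O)
  r <- parratt_reflectivity(st, 50 * qc)
  expect_equal(r$R * (2 * 50 * qc / qc)^4, 1, tolerance = 0.01)
})

test_that("Nevot-Croce damping vanishes as sigma goes to zero", {
  Q <- seq(0.01, 0.4, length.out = 100)
  sharp <- slab_stack(0, 30, 3e-6, roughness = 0, backing = 6e-6)
  zero <- slab_stack(0, 30, 3e-6, roughness = 0, backing = 6e-6,
                     backing_roughness = 0)
  expect_identical(parratt_reflectivity(sharp, Q)$R,
                   parratt_reflectivity(zero, Q)$R)
  rough <- slab_stack(0, 30, 3e-6, roughness = 1e-9, backing = 6e-6,
                      backing_roughness = 1e-9)
  expect_equal(parratt_reflectivity(rough, Q)$R,
               parratt_reflectivity(sharp, Q)$R, tolerance = 1e-10)
  # and damps a bare interface once switched on
  r0 <- parratt_reflectivity(slab_stack(0, backing = 6e-6), 0.3)$R
  r3 <- parratt_reflectivity(
    slab_stack(0, backing = 6e-6, backing_roughness = 3), 0.3)$R
  expect_lt(r3, r0)
})

test_that("Nevot-Croce matches a finely binned erf interface profile", {
  sig <- 3
  edges <- seq(-25, 25, by = 0.1)
  zc <- (edges[-1] + edges[-length(edges)]) / 2
  prof <- sld_profile(edges, SLD_SI + (SLD_D2O - SLD_SI) * pnorm(zc, 0, sig),
                      fronting = SLD_SI, backing = SLD_D2O)
  Q <- seq(0.02, 0.3, length.out = 80)
  r_erf <- parratt_reflectivity(profile_to_slabs(prof), Q)$R
  r_nc <- parratt_reflectivity(
    slab_stack(SLD_SI, backing = SLD_D2O, backing_roughness = sig), Q)$R
  expect_lt(max(abs(r_erf - r_nc) / r_nc), 0.01)
})

test_that("Born master equation: exact at a sharp step, weak-contrast limit", {
  Q <- seq(0.02, 0.3, length.out = 120)
  step <- sld_profile(seq(0, 10, by = 0.5), rep(4e-6, 20),
                      fronting = 0, backing = 4e-6)
  rb <- born_reflectivity(step, Q)
  rf <- Mod(fresnel_interface(Q, 0, 4e-6)$r)^2
  expect_equal(rb$R, rf, tolerance = 1e-12)
  # weak slab, Q > 10 Qc: compare after light smearing, which removes the
  # measure-zero fringe nulls where relative error is undefined
  prof <- make_slab_profile(c(30, 50, 30), c(0, 0.5e-6, 1e-6), 0.5)
  qc <- critical_q(0, 1e-6)
  Qb <- seq(10.5 * qc, 0.3, length.out = 300)
  born_s <- smear_resolution(born_reflectivity(prof, Qb), 0.02)$R
  parr_s <- smear_resolution(
    parratt_reflectivity(profile_to_slabs(prof, 1e-10), Qb), 0.02)$R
  expect_lt(max(abs(born_s - parr_s) / parr_s), 0.05)
  # invalid below the critical edge: flagged, and exceeds unity for a
  # profile whose SLD steps interfere constructively beyond the net contrast
  dip <- make_slab_profile(c(10, 20, 10), c(3e-6, -0.4e-6, 3e-6), 0.5)
  dip <- sld_profile(dip$bin_edges, dip$rho, fronting = 0, backing = 1e-6)
  qc_dip <- critical_q(0, 1e-6)
  low <- born_reflectivity(dip, seq(qc_dip / 20, 0.3, length.out = 200))
  expect_false(all(attr(low, "valid")))
  expect_gt(max(low$R[!attr(low, "valid")]), 1)
  flat <- sld_profile(seq(0, 5, by = 0.5), rep(2e-6, 10),
                      fronting = 2e-6, backing = 2e-6)
  expect_error(born_reflectivity(flat, Q), "contrast")
})

test_that("resolution smearing: identity at zero, mass-conserving on peaks", {
  unit <- lamellar_unit()
  Q <- seq(0.01, 0.32, length.out = 1500)
  r <- refl_on_si(tile_unit_cell(unit, 12), Q)
  expect_identical(smear_resolution(r, 0), r)
  rs <- smear_resolution(r, 0.10)
  q1 <- 2 * pi / 66
  win <- Q > q1 * 0.75 & Q < q1 * 1.25 # +/- 5 FWHM around the first Bragg
  expect_lt(max(rs$R[win]), max(r$R[win]))
  expect_equal(pracma::trapz(Q[win], rs$R[win]),
               pracma::trapz(Q[win], r$R[win]), tolerance = 0.01)
})

test_that("scale and background act affinely with visible signatures", {
  st <- slab_stack(SLD_SI, backing = SLD_D2O)
  Q <- seq(0.005, 0.3, length.out = 200)
  r <- parratt_reflectivity(st, Q)
  expect_equal(apply_scale_background(r, 1, 0)$R, r$R)
  rb <- apply_scale_background(r, 1, 1e-6)
  expect_equal(rb$R[length(Q)], 1e-6, tolerance = 0.3)
  # a 0.9 scale error shows on the total-reflection plateau
  plateau <- apply_scale_background(r, 0.9, 0)$R[Q < critical_q(SLD_SI, SLD_D2O)]
  expect_true(all(abs(plateau - 0.9) < 1e-10))
})

test_that("incoherent mean is convex and damps higher Bragg orders more", {
  unit <- lamellar_unit()
  Q <- seq(0.01, 0.32, length.out = 900)
  curves <- lapply(jitter_ensemble(unit, 12,
                                   disorder_spec("uniform", 3, 24, seed = 9)),
                   refl_on_si, Q = Q)
  m <- incoherent_mean(curves)
  expect_equal(incoherent_mean(list(m, m))$R, m$R)
  lo <- do.call(pmin, lapply(curves, `[[`, "R"))
  hi <- do.call(pmax, lapply(curves, `[[`, "R"))
  expect_true(all(m$R >= lo - 1e-15 & m$R <= hi + 1e-15))
  ordered <- refl_on_si(tile_unit_cell(unit, 12), Q)
  peak_win <- function(order) {
    qn <- order * 2 * pi / 66
    Q > qn * 0.95 & Q < qn * 1.05
  }
  damp1 <- max(m$R[peak_win(1)]) / max(ordered$R[peak_win(1)])
  damp2 <- max(m$R[peak_win(2)]) / max(ordered$R[peak_win(2)])
  expect_lt(damp2, damp1) # Debye-Waller-like: higher order damped more
})

test_that("Bragg peak location recovers lamellar d-spacings", {
  unit <- lamellar_unit()
  Q <- seq(0.005, 0.32, length.out = 1500)
  r <- smear_resolution(refl_on_si(tile_unit_cell(unit, 36), Q), 0.03)
  pk <- locate_bragg_peaks(r, q_min = 0.02)
  expect_gte(nrow(pk), 2)
  expect_equal(pk$d[1], 66, tolerance = 1 / 66) # within 1 A
  # featureless Fresnel curve yields no peaks
  bare <- parratt_reflectivity(slab_stack(SLD_SI, backing = SLD_D2O), Q)
  expect_equal(nrow(locate_bragg_peaks(bare, q_min = 0.02)), 0)
})

test_that("a roughness-dominated slab triggers the validity warning", {
  expect_warning(slab_stack(0, 6, 3e-6, roughness = 5, backing = 6e-6),
                 "roughness")
})
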