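test_that("substrate splicing builds the supported geometry with guards", {
  prof <- bilayer_profile()
  sub <- substrate_spec(SLD_SI, oxide_thickness = 12, oxide_sld = 3.47e-6,
                        oxide_roughness = 2, surface_roughness = 2)
  sp <- splice_substrate(prof, sub, water_gap = 10, bulk_solvent_sld = SLD_D2O)
  expect_s3_class(sp, "sld_profile")
  expect_equal(sp$fronting, SLD_SI)
  expect_equal(sp$backing, SLD_D2O)
  expect_equal(sp$bin_width, prof$bin_width)
  # mismatched solvent is refused
  expect_error(splice_substrate(prof, sub, 10, SLD_H2O), "bulk solvent")
  # oxide roughness that cannot decay inside the gap is an artefact
  rough <- substrate_spec(SLD_SI, 12, 3.47e-6, 2, surface_roughness = 4)
  expect_error(splice_substrate(prof, rough, water_gap = 2,
                                bulk_solvent_sld = SLD_D2O), "artefact|decayed|roughness")
  # degenerate case: flat solvent profile, no oxide -> bare Fresnel interface
  flat <- make_slab_profile(30, SLD_D2O, 0.13)
  bare <- splice_substrate(flat, substrate_spec(SLD_SI, 0, 3.47e-6, 0, 0),
                           10, SLD_D2O)
  Q <- seq(0.005, 0.3, length.out = 150)
  rb <- parratt_reflectivity(profile_to_slabs(bare, 1e-9), Q)$R
  rf <- Mod(fresnel_interface(Q, SLD_SI, SLD_D2O)$r)^2
  expect_equal(rb, rf, tolerance = 1e-10)
})

test_that("5 vs 10 A water gaps produce clearly different reflectivity", {
  prof <- bilayer_profile()
  sub <- substrate_spec(SLD_SI, 12, 3.47e-6, 2, 2)
  Q <- seq(0.01, 0.3, length.out = 250)
  r <- lapply(c(10, 5), function(g)
    smear_resolution(parratt_reflectivity(profile_to_slabs(
      splice_substrate(prof, sub, g, SLD_D2O), 1e-8), Q), 0.035))
  fake <- r[[1]]; fake$dR <- 0.02 * fake$R
  expect_gt(chi_square(fake, r[[2]]), 10) # noise floor is chi2 ~ 0 here
})

test_that("water-gap adjustment is local and identity-safe", {
  prof <- bilayer_profile(lead = 15)
  run <- which(abs(prof$rho - SLD_D2O) < 1e-9)
  lead_run <- run[run < 50]
  shrunk <- adjust_water_gap(prof, lead_run, 5)
  expect_equal(length(prof$rho) - length(shrunk$rho),
               round((length(lead_run) * prof$bin_width - 5) / prof$bin_width))
  # membrane part untouched, bit-identical
  expect_identical(shrunk$rho[-seq_len(round(5 / prof$bin_width))],
                   prof$rho[-seq_len(length(lead_run))])
  same <- adjust_water_gap(prof, lead_run,
                           length(lead_run) * prof$bin_width)
  expect_equal(same$rho, prof$rho)
  expect_error(adjust_water_gap(prof, 1:500, 5), "not flat")
  expect_error(adjust_water_gap(prof, lead_run, -2), ">= 0")
})

test_that("enlarging the interlamellar water moves the Bragg peak as d", {
  # 66 A cell (42 A water) vs 74 A cell (50 A water)
  u66 <- lamellar_unit(gap = 42, tail = 11, head = 6.5)
  lead <- seq_len(round(21 / u66$bin_width))
  # widening the leading half-gap to 29 A makes every interlamellar gap
  # 50 A after tiling: a 74 A lattice
  u74 <- adjust_water_gap(u66, lead, 29)
  Q <- seq(0.04, 0.32, length.out = 3000)
  d_of <- function(u) {
    r <- smear_resolution(refl_on_si(tile_unit_cell(u, 36), Q), 0.03)
    locate_bragg_peaks(r, q_min = 0.06)$d[1]
  }
  d1 <- d_of(u66)
  d2 <- d_of(u74)
  expect_equal(d1, 66, tolerance = 0.02)
  expect_equal(d2, 74, tolerance = 0.02)
  expect_equal(d1 / d2, 66 / 74, tolerance = 0.02)
})

test_that("tiling repeats the unit cell and rejects unequal gaps", {
  unit <- lamellar_unit()
  expect_identical(tile_unit_cell(unit, 1), unit)
  t3 <- tile_unit_cell(unit, 3)
  expect_equal(length(t3$rho), 3 * length(unit$rho))
  expect_identical(t3$rho, rep(unit$rho, 3))
  # n-fold periodicity: interior autocorrelation peaks at lag d
  x <- tile_unit_cell(unit, 6)$rho
  x <- x - mean(x)
  lags <- round(length(unit$rho) * c(0.5, 1))
  ac <- sapply(lags, function(L)
    sum(x[seq_len(length(x) - L)] * x[-seq_len(L)]))
  expect_gt(ac[2], abs(ac[1]))
  # unequal alternating gaps are refused, unless overridden
  asym <- make_slab_profile(
    c(10, 6.5, 28, 6.5, 20, 6.5, 28, 6.5, 15),
    c(SLD_D2O, 1.8e-6, -0.4e-6, 1.8e-6, SLD_D2O, 1.8e-6, -0.4e-6, 1.8e-6,
      SLD_D2O), 0.13)
  expect_error(tile_unit_cell(asym, 4), "double the lattice")
  expect_s3_class(tile_unit_cell(asym, 4, allow_asymmetric = TRUE),
                  "sld_profile")
})

test_that("jitter ensembles are seeded, reproducible and degrade to tiling", {
  unit <- lamellar_unit()
  zero <- jitter_ensemble(unit, 6, disorder_spec("uniform", 0, 3, seed = 5))
  tiled <- tile_unit_cell(unit, 6)
  for (p in zero) expect_identical(p$rho, tiled$rho)
  e1 <- jitter_ensemble(unit, 6, disorder_spec("normal", 2, 4, seed = 11))
  e2 <- jitter_ensemble(unit, 6, disorder_spec("normal", 2, 4, seed = 11))
  expect_identical(lapply(e1, `[[`, "rho"), lapply(e2, `[[`, "rho"))
  e3 <- jitter_ensemble(unit, 6, disorder_spec("normal", 2, 4, seed = 12))
  expect_false(identical(lapply(e1, `[[`, "rho"), lapply(e3, `[[`, "rho")))
  expect_error(jitter_ensemble(unit, 6, disorder_spec("uniform", 30, 8, 1)),
               "non-positive")
})

test_that("disorder damps the second-order Bragg peak of the mean curve", {
  unit <- lamellar_unit()
  Q <- seq(0.05, 0.32, length.out = 900)
  ens <- jitter_ensemble(unit, 12, disorder_spec("uniform", 3, 32, seed = 21))
  m <- incoherent_mean(lapply(ens, refl_on_si, Q = Q))
  ordered <- refl_on_si(tile_unit_cell(unit, 12), Q)
  win <- Q > 2 * 2 * pi / 66 * 0.95 & Q < 2 * 2 * pi / 66 * 1.05
  expect_lt(max(m$R[win]), max(ordered$R[win]))
})

test_that("solvent-SLD scaling distinguishes bulk and lamellar contamination", {
  unit <- lamellar_unit()
  stacked <- tile_unit_cell(unit, 12)
  Q <- seq(0.005, 0.2, length.out = 800)
  r_ref <- refl_on_si(stacked, Q)
  expect_equal(scale_region_sld(stacked, "bulk_only", 1)$rho, stacked$rho)
  bulk <- scale_region_sld(stacked, "bulk_only", 0.8)
  expect_equal(bulk$backing, 0.8 * SLD_D2O)
  r_bulk <- refl_on_si(bulk, Q)
  # critical edge moves down, Bragg position does not
  edge_q <- function(r) max(r$Q[r$R > 0.999])
  expect_lt(edge_q(r_bulk), edge_q(r_ref))
  pk_ref <- locate_bragg_peaks(smear_resolution(r_ref, 0.03), 0.07)
  pk_blk <- locate_bragg_peaks(smear_resolution(r_bulk, 0.03), 0.07)
  expect_equal(pk_ref$Q_peak[1], pk_blk$Q_peak[1], tolerance = 0.005)
  # scaling all solvent additionally changes the Bragg-region intensity
  all_s <- scale_region_sld(stacked, "all_solvent", 0.8)
  r_all <- refl_on_si(all_s, Q)
  hiq <- Q > 0.08 & Q < 0.15
  expect_gt(max(abs(log10(r_all$R[hiq]) - log10(r_bulk$R[hiq]))), 0.1)
})

test_that("profile discretization honours the coarsening tolerance", {
  prof <- bilayer_profile()
  exact <- profile_to_slabs(prof, 0)
  expect_equal(length(exact$thickness), length(prof$rho))
  flat <- make_slab_profile(40, 3e-6, 0.13)
  expect_equal(length(profile_to_slabs(flat, 1e-12)$thickness), 1L)
  merged <- profile_to_slabs(prof, 1e-9)
  expect_equal(length(merged$thickness), 5L)
  expect_equal(sum(merged$thickness), sum(exact$thickness), tolerance = 1e-9)
  # reflectivity unchanged by lossless coarsening
  Q <- seq(0.01, 0.3, length.out = 100)
  expect_equal(parratt_reflectivity(merged, Q)$R,
               parratt_reflectivity(exact, Q)$R, tolerance = 1e-9)
})
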