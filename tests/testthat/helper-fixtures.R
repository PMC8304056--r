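# Shared fixtures, all built in code.

SLD_D2O <- 6.35e-6 # printed endpoint values, used as inputs
SLD_H2O <- -0.56e-6
SLD_SI <- 2.07e-6

# 66 A lamellar unit cell in D2O: half-gap | head | tail | head | half-gap
lamellar_unit <- function(gap = 25, tail = 28, head = 6.5, bin = 0.13) {
  make_slab_profile(c(gap / 2, head, tail, head, gap / 2),
                    c(SLD_D2O, 1.8e-6, -0.4e-6, 1.8e-6, SLD_D2O),
                    bin_width = bin)
}

# free-floating DMPC-like bilayer profile in a given solvent
bilayer_profile <- function(solvent = SLD_D2O, lead = 15) {
  make_slab_profile(c(lead, 9, 22, 9, lead),
                    c(solvent, 3.3e-6, -0.4e-6, 3.3e-6, solvent),
                    bin_width = 0.13)
}

refl_on_si <- function(profile, Q, coarsen = 1e-9) {
  stack <- profile_to_slabs(profile, coarsen)
  stack$fronting <- complex(real = SLD_SI)
  parratt_reflectivity(stack, Q)
}

# three-shell SoyPC-like vesicle
vesicle_fixture <- function(p = 0.25, scale = 1e-4, background = 1e-3) {
  vesicle_model(450, c(8, 17, 8), c(1.8e-6, -0.4e-6, 1.8e-6), SLD_D2O,
                polydispersity = p, scale = scale, background = background)
}

# independent oracle: spherically symmetric Fourier integral by per-shell
# trapezoid quadrature on a 0.1 A radial grid
brute_shell_amplitude <- function(model, Q, h = 0.1) {
  radii <- model$core_radius + cumsum(c(0, model$shell_thickness))
  drho <- model$shell_sld - model$solvent_sld
  vapply(Q, function(q) {
    tot <- 0
    for (i in seq_along(drho)) {
      r <- seq(radii[i], radii[i + 1],
               length.out = max(5, ceiling((radii[i + 1] - radii[i]) / h) + 1))
      f <- drho[i] * r^2 * sin(q * r) / (q * r)
      tot <- tot + 4 * pi * sum((f[-1] + f[-length(f)]) / 2 * diff(r))
    }
    tot
  }, numeric(1))
}
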