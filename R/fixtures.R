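#' Bilayer fixture specification
#'
#' Statistical stand-in for a free-floating phospholipid bilayer
#' trajectory: head-group atoms drawn from Gaussians centred at +/- z_head
#' around the membrane midplane, tail atoms from a Gaussian at the
#' midplane, and water atoms uniformly in the two solvent slabs outside the
#' membrane.  Defaults mirror common simulation scales: 128 lipids (64 per
#' leaflet), ~3000 waters, a box a few nm wide.
#'
#' @param n_lipids Number of lipids (split evenly between leaflets).
#' @param head_atoms Named counts of head-group atoms per lipid.
#' @param tail_atoms Named counts of tail atoms per lipid.
#' @param n_water Number of water molecules (each contributes 2 H + 1 O).
#' @param z_head Head-group Gaussian centre offset from the midplane, A.
#' @param head_width,tail_width Gaussian widths (sd), A.
#' @param water_margin Solvent starts at |z - mid| > z_head + water_margin.
#' @param box Box lengths (Lx, Ly, Lz), A.
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed; frames are reproducible given the spec.
#' @return An object of class `bilayer_fixture_spec`.
#' @export
bilayer_fixture_spec <- function(n_lipids = 128,
                                 head_atoms = c(C = 10, N = 1, O = 8,
                                                P = 1, H = 18),
                                 tail_atoms = c(C = 26, H = 54),
                                 n_water = 3000,
                                 z_head = 18, head_width = 3, tail_width = 6,
                                 water_margin = 4,
                                 box = c(62, 62, 68),
                                 n_frames = 5, seed = 1L) {
  stopifnot(n_lipids >= 2, n_water >= 0, z_head > 0, head_width > 0,
            tail_width > 0, water_margin >= 0,
            length(box) == 3L, all(box > 0), n_frames >= 1)
  if (any(head_atoms <= 0) || any(tail_atoms <= 0))
    stop("atom counts must be > 0")
  if (z_head + water_margin >= box[3] / 2)
    stop("box too short in z for the membrane plus solvent")
  structure(list(n_lipids = as.integer(n_lipids), head_atoms = head_atoms,
                 tail_atoms = tail_atoms, n_water = as.integer(n_water),
                 z_head = z_head, head_width = head_width,
                 tail_width = tail_width, water_margin = water_margin,
                 box = as.numeric(box), n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "bilayer_fixture_spec")
}

expand_counts <- function(counts, n_units) {
  rep(rep(names(counts), counts), n_units)
}

#' Generate synthetic bilayer trajectory frames
#'
#' Draws atom positions from the distributions stated in the spec:
#' head-group atoms N(mid +/- z_head, head_width) with one leaflet each,
#' tails N(mid, tail_width), water uniform outside the membrane slab.
#' Deterministic for a given spec (seeded).
#'
#' @param spec A [bilayer_fixture_spec()].
#' @return List of [md_frame()] objects.
#' @export
make_bilayer_frames <- function(spec) {
  stopifnot(inherits(spec, "bilayer_fixture_spec"))
  lx <- spec$box[1]; ly <- spec$box[2]; lz <- spec$box[3]
  mid <- lz / 2
  n_leaf <- spec$n_lipids %/% 2L
  head_lab <- expand_counts(spec$head_atoms, spec$n_lipids)
  tail_lab <- expand_counts(spec$tail_atoms, spec$n_lipids)
  n_head <- length(head_lab); n_tail <- length(tail_lab)
  n_head_leaf <- length(expand_counts(spec$head_atoms, n_leaf))
  leaflet <- rep(c(-1, 1), c(n_head_leaf, n_head - n_head_leaf))
  water_lab <- rep(c("H", "H", "O"), spec$n_water)
  n_wat <- length(water_lab)
  edge <- spec$z_head + spec$water_margin
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(f) {
      zh <- mid + leaflet * spec$z_head +
        stats::rnorm(n_head, 0, spec$head_width)
      zt <- mid + stats::rnorm(n_tail, 0, spec$tail_width)
      # water: uniform over the two slabs [0, mid-edge) and (mid+edge, lz]
      u <- stats::runif(n_wat, 0, lz - 2 * edge)
      zw <- ifelse(u < mid - edge, u, u + 2 * edge)
      n_tot <- n_head + n_tail + n_wat
      atoms <- data.frame(
        label = c(head_lab, tail_lab, water_lab),
        group = rep(c("head", "tail", "water"), c(n_head, n_tail, n_wat)),
        x = stats::runif(n_tot, 0, lx),
        y = stats::runif(n_tot, 0, ly),
        z = c(zh, zt, zw) %% lz,
        stringsAsFactors = FALSE)
      md_frame(atoms, spec$box)
    })
  })
}

#' Analytic piecewise-constant SLD profile
#'
#' Builds an [sld_profile()] from a list of slabs; every bin takes the SLD
#' of the slab containing its midpoint, so the total length is preserved to
#' within one bin when `bin_width` does not divide the slab thicknesses.
#'
#' @param thickness Slab thicknesses, A, in order.
#' @param sld Slab SLDs, 1/A^2.
#' @param bin_width Bin width, A.
#' @param fronting,backing Optional semi-infinite media (default: end-slab
#'   SLDs).
#' @return An [sld_profile()].
#' @export
make_slab_profile <- function(thickness, sld, bin_width = 0.13,
                              fronting = NULL, backing = NULL) {
  stopifnot(length(thickness) == length(sld), all(thickness > 0),
            bin_width > 0)
  total <- sum(thickness)
  n_bins <- max(1L, round(total / bin_width))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bounds <- cumsum(thickness)
  idx <- pmin(findInterval(mids, c(0, bounds), left.open = TRUE),
              length(sld))
  idx[idx < 1L] <- 1L
  sld_profile(edges, as.numeric(sld)[idx], fronting = fronting,
              backing = backing)
}

#' Add multiplicative Gaussian noise to a model curve
#'
#' Emulates counting noise on a reflectivity or SANS curve: each intensity
#' is multiplied by (1 + e), e ~ N(0, relative_noise), clipped at zero, and
#' the stated 1-sigma uncertainty is relative_noise times the noise-free
#' model.  Seeded and reproducible.
#'
#' @param curve A [refl_curve()] or [sans_curve()].
#' @param relative_noise Relative noise level, >= 0 (0 returns an exact
#'   copy that still carries the stated uncertainties).
#' @param seed Integer seed.
#' @return A curve of the same class with uncertainties filled in.
#' @export
make_noisy_curve <- function(curve, relative_noise, seed = 1L) {
  stopifnot(relative_noise >= 0)
  y_field <- if (inherits(curve, "sans_curve")) "I" else "R"
  y <- curve[[y_field]]
  noisy <- with_seed(seed, {
    pmax(y * (1 + stats::rnorm(length(y), 0, relative_noise)), 0)
  })
  out <- curve
  out[[y_field]] <- noisy
  out[[if (y_field == "I") "dI" else "dR"]] <- pmax(relative_noise * y, 1e-300)
  out
}
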