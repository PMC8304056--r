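#' Substrate specification
#'
#' Semi-infinite fronting (typically crystalline Si) with a native oxide
#' layer, for splicing a simulated membrane profile onto a supported-sample
#' geometry.
#'
#' @param fronting_sld SLD of the semi-infinite substrate.
#' @param oxide_thickness Native-oxide thickness, Angstrom, >= 0.
#' @param oxide_sld Oxide SLD.
#' @param oxide_roughness Sigma (A) of the substrate/oxide interface.
#' @param surface_roughness Sigma (A) of the oxide/solvent interface.
#' @return An object of class `substrate_spec`.
#' @export
substrate_spec <- function(fronting_sld = 2.07e-6, oxide_thickness = 12,
                           oxide_sld = 3.47e-6, oxide_roughness = 2,
                           surface_roughness = 3) {
  stopifnot(oxide_thickness >= 0, oxide_roughness >= 0, surface_roughness >= 0)
  structure(list(fronting_sld = as_sld(fronting_sld)$real,
                 oxide_thickness = oxide_thickness,
                 oxide_sld = as_sld(oxide_sld)$real,
                 oxide_roughness = oxide_roughness,
                 surface_roughness = surface_roughness),
            class = "substrate_spec")
}

#' Interlamellar disorder specification
#'
#' @param dist Jitter distribution of the water-gap thickness, `"uniform"`
#'   (on +/- width) or `"normal"` (sd = width); mean zero either way.
#' @param width Scale of the jitter in Angstrom.
#' @param n_realizations Number of stacked-profile realizations, >= 1.
#' @param seed Integer seed making the ensemble reproducible.
#' @return An object of class `disorder_spec`.
#' @export
disorder_spec <- function(dist = c("uniform", "normal"), width = 3,
                          n_realizations = 64, seed = 1L) {
  dist <- match.arg(dist)
  stopifnot(width >= 0, n_realizations >= 1)
  structure(list(dist = dist, width = width,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "disorder_spec")
}

# run-length view of which bins sit at the solvent SLD
solvent_mask <- function(rho, solvent, tol) abs(rho - solvent) <= tol

# erf-smoothed two-interface substrate block evaluated at bin centres zc,
# with interfaces at z0 (fronting/oxide) and z1 (oxide/solvent)
substrate_block <- function(zc, substrate, bulk, z0, z1) {
  step <- function(z, zi, sig) if (sig > 0) stats::pnorm(z, zi, sig) else as.numeric(z >= zi)
  substrate$fronting_sld +
    (substrate$oxide_sld - substrate$fronting_sld) *
      step(zc, z0, substrate$oxide_roughness) +
    (bulk - substrate$oxide_sld) * step(zc, z1, substrate$surface_roughness)
}

#' Splice a free-floating membrane profile onto a supported substrate
#'
#' Builds the measurable system from a simulated bilayer profile:
#' `[fronting | oxide (erf-smoothed interfaces) | water gap at the bulk
#' solvent SLD | membrane | semi-infinite bulk solvent]`.  The profile must
#' begin in bulk solvent (its leading solvent run is replaced by the
#' requested gap).  Each splice junction is checked for continuity — an SLD
#' jump above `tol` (e.g. a surface roughness too large for the gap, or a
#' solvent mismatch) is a modelling artefact and raises an error.
#'
#' @param profile An [sld_profile()] of the free-floating membrane, starting
#'   and ending in bulk solvent.
#' @param substrate A [substrate_spec()].
#' @param water_gap Substrate-to-headgroup water-layer thickness, A, >= 0.
#' @param bulk_solvent_sld Bulk solvent SLD (must match the profile ends).
#' @param tol Junction continuity tolerance, 1/A^2.
#' @param fronting_pad Thickness of explicit fronting bins ahead of the
#'   oxide, A.
#' @return An [sld_profile()] with `fronting` = substrate SLD and `backing`
#'   = bulk solvent SLD.
#' @export
splice_substrate <- function(profile, substrate, water_gap, bulk_solvent_sld,
                             tol = 1e-7, fronting_pad = 20) {
  stopifnot(inherits(profile, "sld_profile"),
            inherits(substrate, "substrate_spec"))
  if (water_gap < 0) stop("water_gap must be >= 0")
  bulk <- as_sld(bulk_solvent_sld)$real
  if (abs(profile$rho[1] - bulk) > tol)
    stop("profile does not start in the stated bulk solvent: |",
         format(profile$rho[1]), " - ", format(bulk), "| > tol")
  dz <- profile$bin_width
  mask <- solvent_mask(profile$rho, bulk, tol)
  n_lead <- which.min(c(mask, FALSE)) - 1L # length of leading solvent run
  body <- profile$rho[-seq_len(n_lead)]
  n_front <- round((fronting_pad + substrate$oxide_thickness + water_gap) / dz)
  zc <- (seq_len(n_front) - 0.5) * dz
  front <- substrate_block(zc, substrate, bulk, fronting_pad,
                           fronting_pad + substrate$oxide_thickness)
  # junction guards: front block must have relaxed to bulk, and the cut in
  # the profile was made in solvent
  if (length(front) && abs(front[length(front)] - bulk) > tol)
    stop("discontinuous splice at the water gap: oxide surface roughness ",
         "has not decayed to the bulk SLD within the gap (artefact guard)")
  if (n_lead > 0 && abs(profile$rho[n_lead] - bulk) > tol)
    stop("discontinuous splice: profile cut is not in bulk solvent")
  rho <- c(front, body)
  edges <- seq(0, by = dz, length.out = length(rho) + 1L)
  sld_profile(edges, rho, fronting = substrate$fronting_sld, backing = bulk,
              contrast = profile$contrast)
}

#' Adjust the thickness of a flat solvent region
#'
#' Inserts or removes whole bins of solvent inside a region that is flat at
#' the solvent SLD (e.g. the substrate-membrane water layer, or the
#' interlamellar water of a unit cell), leaving every other bin untouched.
#' The requested thickness is rounded to the bin width.
#'
#' @param profile An [sld_profile()].
#' @param region Integer vector of contiguous bin indices, all at a common
#'   SLD within `tol`.
#' @param new_thickness Target thickness in Angstrom, >= 0.
#' @param tol Flatness tolerance, 1/A^2.
#' @return An [sld_profile()].
#' @export
adjust_water_gap <- function(profile, region, new_thickness, tol = 1e-7) {
  stopifnot(inherits(profile, "sld_profile"))
  region <- sort(as.integer(region))
  if (length(region) == 0 || any(diff(region) != 1L) ||
      region[1] < 1 || region[length(region)] > length(profile$rho))
    stop("region must be a contiguous bin range inside the profile")
  if (new_thickness < 0) stop("new_thickness must be >= 0")
  vals <- profile$rho[region]
  if (max(vals) - min(vals) > 2 * tol)
    stop("region is not flat: cannot treat it as a solvent layer")
  dz <- profile$bin_width
  n_new <- round(new_thickness / dz)
  sol <- vals[1]
  rho <- c(profile$rho[seq_len(region[1] - 1L)], rep(sol, n_new),
           if (region[length(region)] < length(profile$rho))
             profile$rho[(region[length(region)] + 1L):length(profile$rho)])
  edges <- seq(0, by = dz, length.out = length(rho) + 1L)
  sld_profile(edges, rho, fronting = profile$fronting,
              backing = profile$backing, contrast = profile$contrast)
}

gap_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, end = ends, solvent = r$values)
}

#' Tile a lamellar unit cell into a multilayer
#'
#' Repeats a single-bilayer unit cell n times along z.  The unit must start
#' and end in solvent, and its two end half-gaps must merge into the same
#' interlamellar water thickness found anywhere else in the tiled stack;
#' unequal gaps would silently double the lattice constant and create a
#' spurious superlattice peak at half the first Bragg Q, so they are
#' rejected unless `allow_asymmetric = TRUE`.
#'
#' @param unit An [sld_profile()] unit cell (half water gap at both ends).
#' @param n Number of repetitions, >= 1.
#' @param tol Solvent-detection tolerance, 1/A^2.
#' @param allow_asymmetric Override the equal-gap validation (to study the
#'   period-doubling artefact deliberately).
#' @return An [sld_profile()] of length n times the unit-cell size.
#' @export
tile_unit_cell <- function(unit, n, tol = 1e-7, allow_asymmetric = FALSE) {
  stopifnot(inherits(unit, "sld_profile"), n >= 1)
  if (n == 1) return(unit)
  sol <- unit$backing
  mask <- solvent_mask(unit$rho, sol, tol)
  if (!mask[1] || !mask[length(mask)])
    stop("unit cell must start and end in bulk solvent")
  if (!allow_asymmetric) {
    tiled2 <- rep(unit$rho, 2L)
    runs <- gap_runs(solvent_mask(tiled2, sol, tol))
    interior <- runs[runs$solvent & runs$start > 1 &
                       runs$end < length(tiled2), , drop = FALSE]
    if (nrow(interior) > 0) {
      len <- interior$end - interior$start + 1L
      if (max(len) - min(len) > 1L)
        stop("unequal interlamellar water gaps (", min(len), " vs ", max(len),
             " bins): tiling would double the lattice constant and add a ",
             "superlattice peak at half the first Bragg Q; equalize the end ",
             "half-gaps or set allow_asymmetric = TRUE")
    }
  }
  rho <- rep(unit$rho, n)
  edges <- seq(0, by = unit$bin_width, length.out = length(rho) + 1L)
  sld_profile(edges, rho, fronting = unit$fronting, backing = unit$backing,
              contrast = unit$contrast)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Ensemble of multilayers with jittered water gaps
#'
#' Generates independent realizations of the tiled stack in which every
#' interior water gap is perturbed by a zero-mean random thickness (rounded
#' to whole bins).  Averaging the corresponding reflectivities incoherently
#' models uncorrelated interlamellar disorder, which damps higher-order
#' Bragg peaks like a Debye-Waller factor.
#'
#' @param unit An [sld_profile()] unit cell as for [tile_unit_cell()].
#' @param n Number of bilayer repetitions per realization.
#' @param disorder A [disorder_spec()].
#' @param tol Solvent-detection tolerance.
#' @return List of `n_realizations` [sld_profile()] objects.
#' @export
jitter_ensemble <- function(unit, n, disorder, tol = 1e-7) {
  stopifnot(inherits(unit, "sld_profile"), inherits(disorder, "disorder_spec"))
  sol <- unit$backing
  mask <- solvent_mask(unit$rho, sol, tol)
  if (!mask[1] || !mask[length(mask)])
    stop("unit cell must start and end in bulk solvent")
  runs <- gap_runs(mask)
  a <- runs$end[1]                     # leading half-gap, bins
  b <- runs$end[nrow(runs)] - runs$start[nrow(runs)] + 1L
  core <- unit$rho[(a + 1L):(length(unit$rho) - b)]
  g0 <- a + b                          # full interlamellar gap, bins
  dz <- unit$bin_width
  draw <- function(k) switch(disorder$dist,
    uniform = stats::runif(k, -disorder$width, disorder$width),
    normal = stats::rnorm(k, 0, disorder$width))
  with_seed(disorder$seed, {
    lapply(seq_len(disorder$n_realizations), function(i) {
      eps <- if (n > 1) round(draw(n - 1L) / dz) else integer(0)
      gaps <- g0 + eps
      if (any(gaps <= 0))
        stop("jitter produced a non-positive water gap; reduce the width")
      rho <- c(rep(sol, a),
               unlist(lapply(seq_len(n), function(j) {
                 if (j < n) c(core, rep(sol, gaps[j])) else core
               })),
               rep(sol, b))
      edges <- seq(0, by = dz, length.out = length(rho) + 1L)
      sld_profile(edges, rho, fronting = unit$fronting,
                  backing = unit$backing, contrast = unit$contrast)
    })
  })
}

#' Scale the SLD of a solvent region
#'
#' Multiplies selected bins (and, for `"bulk_only"`, the semi-infinite
#' backing) by a factor — the contamination scenarios of a lamellar stack in
#' D2O: `"bulk_only"` emulates hydrogenous material diffusing into the bulk
#' reservoir (moves the critical edge, leaves Bragg intensities alone) while
#' `"all_solvent"` emulates H2O contamination of all water (additionally
#' reduces the lamellar contrast and the Bragg intensities).
#'
#' @param profile An [sld_profile()].
#' @param region `"bulk_only"`, `"all_solvent"`, or an explicit integer
#'   vector of bin indices.
#' @param factor Positive scale factor.
#' @param tol Relative solvent-detection tolerance (fraction of the backing
#'   SLD).
#' @return An [sld_profile()].
#' @export
scale_region_sld <- function(profile, region = "bulk_only", factor,
                             tol = 0.01) {
  stopifnot(inherits(profile, "sld_profile"), factor > 0)
  rho <- profile$rho
  backing <- profile$backing
  if (is.numeric(region)) {
    idx <- as.integer(region)
    if (any(idx < 1) || any(idx > length(rho))) stop("region indices out of range")
    rho[idx] <- rho[idx] * factor
    new_backing <- backing
  } else {
    region <- match.arg(region, c("bulk_only", "all_solvent"))
    mask <- abs(rho - backing) <= tol * abs(backing)
    if (!any(mask)) stop("no bins resolve to the bulk solvent SLD")
    if (region == "bulk_only") {
      last_run <- rev(which(!mask))
      start <- if (length(last_run)) last_run[1] + 1L else 1L
      if (start > length(rho)) stop("no trailing bulk solvent run found")
      idx <- start:length(rho)
    } else {
      idx <- which(mask)
    }
    rho[idx] <- rho[idx] * factor
    new_backing <- backing * factor
  }
  sld_profile(profile$bin_edges, rho, fronting = profile$fronting,
              backing = new_backing, contrast = profile$contrast)
}

#' Discretize a binned profile into a slab stack
#'
#' Each bin becomes a zero-roughness slab; adjacent bins whose SLD stays
#' within `coarsen_tolerance` of the running thickness-weighted mean are
#' merged, which collapses piecewise-constant regions to single slabs and
#' keeps the exact-reflectivity kernels fast.  Fronting and backing are
#' taken from the profile's semi-infinite media.
#'
#' @param profile An [sld_profile()].
#' @param coarsen_tolerance Merge tolerance in 1/A^2; 0 keeps one slab per
#'   bin (exactly equal neighbours are still distinct slabs).
#' @return A [slab_stack()].
#' @export
profile_to_slabs <- function(profile, coarsen_tolerance = 0) {
  stopifnot(inherits(profile, "sld_profile"), coarsen_tolerance >= 0)
  rho <- profile$rho
  dz <- profile$bin_width
  if (coarsen_tolerance == 0) {
    return(slab_stack(profile$fronting, rep(dz, length(rho)), rho,
                      roughness = 0, backing = profile$backing))
  }
  th <- numeric(0); sl <- numeric(0)
  cur_n <- 1L; cur_mean <- rho[1]
  for (i in seq_along(rho)[-1]) {
    if (abs(rho[i] - cur_mean) <= coarsen_tolerance) {
      cur_mean <- (cur_mean * cur_n + rho[i]) / (cur_n + 1L)
      cur_n <- cur_n + 1L
    } else {
      th <- c(th, cur_n * dz); sl <- c(sl, cur_mean)
      cur_n <- 1L; cur_mean <- rho[i]
    }
  }
  th <- c(th, cur_n * dz); sl <- c(sl, cur_mean)
  slab_stack(profile$fronting, th, sl, roughness = 0,
             backing = profile$backing)
}
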