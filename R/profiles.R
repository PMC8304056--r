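#' Trajectory frame
#'
#' One snapshot of a membrane simulation: a table of atoms (isotope label,
#' structural group, Cartesian coordinates in Angstrom) plus the periodic
#' box.  The z axis is the membrane normal.
#'
#' @param atoms Data frame with columns `label` (isotope label resolvable by
#'   [isotope_table()]), `group` (one of "head", "tail", "water", "other"),
#'   `x`, `y`, `z` in Angstrom.
#' @param box Numeric length-3 box vector (Lx, Ly, Lz) in Angstrom.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(atoms, box) {
  stopifnot(is.data.frame(atoms),
            all(c("label", "group", "x", "y", "z") %in% names(atoms)))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (Lx, Ly, Lz) in Angstrom")
  structure(list(atoms = atoms, box = box), class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("MD frame: %d atoms | box %.2f x %.2f x %.2f A | groups: %s\n",
              nrow(x$atoms), x$box[1], x$box[2], x$box[3],
              paste(names(table(x$atoms$group)), collapse = ", ")))
  invisible(x)
}

species_key <- function(group, label) paste(group, label, sep = ":")

# Mass-weighted circular mean of z positions under PBC; returns the centre
# in [0, Lz).  Used to put the membrane at the grid centre independent of
# drift and of whether the bilayer straddles the periodic boundary.
circular_center <- function(z, lz, w = NULL) {
  th <- 2 * pi * z / lz
  if (is.null(w)) w <- rep(1, length(z))
  ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
  (ang %% (2 * pi)) / (2 * pi) * lz
}

#' Bin a trajectory into per-species number-density profiles
#'
#' Slices each frame into thin z bins, histograms every (group, isotope)
#' species, divides by the instantaneous slice volume Lx*Ly*dz and averages
#' over frames.  Before binning, each frame is shifted along z so that the
#' mass centre of the non-water atoms sits at the grid centre (suppresses
#' drift broadening of the time average); coordinates are wrapped back into
#' the box after the shift.  The grid is fixed by the first frame's Lz.
#'
#' @param frames List of [md_frame()] objects with a common species set.
#' @param bin_width Requested bin thickness dz in Angstrom (default 0.13);
#'   snapped to the nearest value for which an integer number of bins tiles
#'   the first frame's box, so no bin sticks out of the box with a partial
#'   slice volume.
#' @param center Logical; centre the membrane before binning.
#' @return An object of class `density_profile`: `bin_edges` (A), `density`
#'   (bins x species matrix, 1/A^3), `species` (data frame: species, group,
#'   label), `n_frames`, `axis_area` (mean Lx*Ly, A^2), `bin_width`.
#' @export
bin_number_density <- function(frames, bin_width = 0.13, center = TRUE) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  if (length(frames) == 0L) stop("no frames supplied")
  stopifnot(bin_width > 0)
  key0 <- sort(unique(species_key(frames[[1]]$atoms$group,
                                  frames[[1]]$atoms$label)))
  lz <- frames[[1]]$box[3]
  n_bins <- max(1L, round(lz / bin_width))
  bin_width <- lz / n_bins
  edges <- seq(0, lz, length.out = n_bins + 1L)
  acc <- matrix(0, n_bins, length(key0), dimnames = list(NULL, key0))
  area_sum <- 0
  masses <- isotope_row(sub("^[^:]*:", "", key0))$mass_amu
  names(masses) <- key0
  for (fr in frames) {
    at <- fr$atoms
    key <- species_key(at$group, at$label)
    if (!identical(sort(unique(key)), key0))
      stop("frames do not share a common species set")
    z <- at$z %% fr$box[3]
    if (center) {
      nw <- at$group != "water"
      if (any(nw)) {
        zc <- circular_center(z[nw], fr$box[3], masses[key[nw]])
        z <- (z + (fr$box[3] / 2 - zc)) %% fr$box[3]
      }
    }
    idx <- pmin(findInterval(z, edges, left.open = FALSE), n_bins)
    vol <- fr$box[1] * fr$box[2] * bin_width
    cnt <- table(factor(key, levels = key0), factor(idx, levels = seq_len(n_bins)))
    acc <- acc + t(unclass(cnt)) / vol
    area_sum <- area_sum + fr$box[1] * fr$box[2]
  }
  n <- length(frames)
  sp <- data.frame(species = key0,
                   group = sub(":.*$", "", key0),
                   label = sub("^[^:]*:", "", key0),
                   stringsAsFactors = FALSE)
  structure(list(bin_edges = edges, density = acc / n, species = sp,
                 n_frames = n, axis_area = area_sum / n,
                 bin_width = bin_width),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf(
    "Density profile: %d bins x %.3g A | %d species | %d frame(s)\n",
    nrow(x$density), x$bin_width, ncol(x$density), x$n_frames))
  invisible(x)
}

#' Frame-weighted average of density profiles
#'
#' Combines profiles binned on identical grids (e.g. trajectory chunks) into
#' one time average, weighting each by its frame count.
#'
#' @param profiles List of `density_profile` objects on identical grids with
#'   identical species sets.
#' @return A `density_profile`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  p1 <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!isTRUE(all.equal(p$bin_edges, p1$bin_edges)) ||
        !identical(p$species$species, p1$species$species))
      stop("profiles must share an identical grid and species set")
  }
  w <- vapply(profiles, function(p) p$n_frames, numeric(1))
  dens <- Reduce(`+`, Map(function(p, wi) p$density * wi, profiles, w)) / sum(w)
  area <- sum(w * vapply(profiles, function(p) p$axis_area, numeric(1))) / sum(w)
  out <- p1
  out$density <- dens
  out$n_frames <- sum(w)
  out$axis_area <- area
  out
}

match_species <- function(species, selection) {
  sel <- rep(TRUE, nrow(species))
  if (!is.null(selection$group))
    sel <- sel & species$group %in% selection$group
  if (!is.null(selection$label))
    sel <- sel & normalize_isotope(species$label) %in%
      normalize_isotope(selection$label)
  sel
}

#' Post-hoc isotopic substitution on a density profile
#'
#' Relabels selected species with a new isotope, leaving number densities
#' untouched — the histogram of e.g. lipid-tail hydrogens is simply
#' multiplied by b_D instead of b_H when converted to SLD.  Species that
#' collapse onto an existing (group, isotope) pair are merged by summing
#' densities.
#'
#' @param profile A `density_profile`.
#' @param selection List with optional elements `group` and `label`; a
#'   species is selected when it matches all given elements.  E.g.
#'   `list(group = "water", label = "H")` deuterates the water hydrogens.
#' @param new_isotope Replacement isotope label, e.g. `"D"`.
#' @return A `density_profile` with relabelled species.
#' @export
apply_isotope_substitution <- function(profile, selection, new_isotope) {
  stopifnot(inherits(profile, "density_profile"))
  isotope_row(new_isotope) # validates the label
  sel <- match_species(profile$species, selection)
  if (!any(sel)) stop("isotope substitution selected no species")
  sp <- profile$species
  sp$label[sel] <- new_isotope
  key <- species_key(sp$group, sp$label)
  uk <- sort(unique(key))
  dens <- matrix(0, nrow(profile$density), length(uk),
                 dimnames = list(NULL, uk))
  for (j in seq_along(key)) dens[, key[j]] <- dens[, key[j]] + profile$density[, j]
  out <- profile
  out$density <- dens
  out$species <- data.frame(species = uk, group = sub(":.*$", "", uk),
                            label = sub("^[^:]*:", "", uk),
                            stringsAsFactors = FALSE)
  out
}

#' SLD profile container
#'
#' Binned scattering-length density along z with the semi-infinite media at
#' either end.  `fronting` is the incidence side (substrate side once
#' assembled), `backing` the far side; both default to the end-bin values.
#'
#' @param bin_edges Uniform bin edges in Angstrom.
#' @param rho SLD per bin, 1/Angstrom^2 (may be negative).
#' @param breakdown Optional bins x groups matrix of per-group SLD
#'   contributions summing to `rho`.
#' @param fronting,backing Semi-infinite medium SLDs.
#' @param contrast Optional label, e.g. "D2O" or "SiMW".
#' @return An object of class `sld_profile`.
#' @export
sld_profile <- function(bin_edges, rho, breakdown = NULL, fronting = NULL,
                        backing = NULL, contrast = NULL) {
  bin_edges <- as.numeric(bin_edges)
  rho <- as.numeric(rho)
  stopifnot(length(bin_edges) == length(rho) + 1L, all(is.finite(rho)))
  w <- diff(bin_edges)
  if (max(abs(w - w[1])) > 1e-9 * w[1]) stop("bins must be uniform")
  if (!is.null(breakdown)) {
    stopifnot(nrow(breakdown) == length(rho))
    if (max(abs(rowSums(breakdown) - rho)) > 1e-12 * max(1, max(abs(rho))))
      stop("breakdown columns must sum to rho")
  }
  structure(list(bin_edges = bin_edges, rho = rho, breakdown = breakdown,
                 bin_width = w[1],
                 fronting = if (is.null(fronting)) rho[1] else as_sld(fronting)$real,
                 backing = if (is.null(backing)) rho[length(rho)] else as_sld(backing)$real,
                 contrast = contrast),
            class = "sld_profile")
}

#' @export
print.sld_profile <- function(x, ...) {
  cat(sprintf(
    "SLD profile: %d bins x %.3g A (%.1f A total) | fronting %.2f, backing %.2f x 1e-6/A^2%s\n",
    length(x$rho), x$bin_width, diff(range(x$bin_edges)),
    x$fronting * 1e6, x$backing * 1e6,
    if (is.null(x$contrast)) "" else paste0(" | ", x$contrast)))
  invisible(x)
}

bin_centers <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Convert a number-density profile to an SLD profile
#'
#' Multiplies each species' number density by its coherent scattering length
#' and sums: rho(z) = sum_s n_s(z) b_s.  Water hydrogens can be re-weighted
#' to an H2O/D2O mixture via `fraction_d2o` (b_eff = (1-f) b_H + f b_D),
#' implementing solvent contrast variation without touching the densities.
#'
#' @param profile A `density_profile`.
#' @param table Isotope table.
#' @param fraction_d2o Optional D2O volume fraction in \[0,1\] applied to
#'   hydrogen in the "water" group.
#' @param contrast Optional contrast label stored in the result.
#' @return An [sld_profile()] with a per-group `breakdown`.
#' @export
density_to_sld <- function(profile, table = isotope_table(),
                           fraction_d2o = NULL, contrast = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  sp <- profile$species
  b <- lookup_scattering_length(sp$label, table)
  if (!is.null(fraction_d2o)) {
    if (fraction_d2o < 0 || fraction_d2o > 1)
      stop("fraction_d2o must lie in [0, 1]")
    wh <- sp$group == "water" & normalize_isotope(sp$label) %in% c("1H", "H")
    if (any(wh)) {
      bH <- b[wh]
      bD <- lookup_scattering_length("2H", table)
      b[wh] <- (1 - fraction_d2o) * bH + fraction_d2o * bD
    }
  }
  contrib <- sweep(profile$density, 2, b * FM_TO_ANGSTROM, `*`)
  groups <- sort(unique(sp$group))
  breakdown <- vapply(groups, function(g)
    rowSums(contrib[, sp$group == g, drop = FALSE]), numeric(nrow(contrib)))
  rho <- rowSums(contrib)
  sld_profile(profile$bin_edges, rho, breakdown = breakdown,
              contrast = contrast)
}
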