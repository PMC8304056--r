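#' Slab stack
#'
#' An ordered stratified medium in beam-incidence order: semi-infinite
#' fronting, slabs (thickness, SLD, Gaussian roughness sigma of the slab's
#' top interface, i.e. towards the fronting), semi-infinite backing.
#'
#' @param fronting,backing Semi-infinite medium SLDs (`sld_value` or bare
#'   numbers, 1/A^2).
#' @param thickness Slab thicknesses in Angstrom (may be empty for a bare
#'   interface), all > 0.
#' @param sld Slab SLDs, same length as `thickness`.
#' @param roughness Sigma (A) of each slab's top interface; recycled.
#' @param backing_roughness Sigma of the final slab/backing interface.
#' @return An object of class `slab_stack`.
#' @export
#' @examples
#' slab_stack(0, thickness = 50, sld = 4e-6, backing = 6.35e-6)
slab_stack <- function(fronting, thickness = numeric(0), sld = numeric(0),
                       roughness = 0, backing, backing_roughness = 0) {
  thickness <- as.numeric(thickness)
  n <- length(thickness)
  stopifnot(length(sld) == n)
  if (n > 0 && any(thickness <= 0)) stop("slab thicknesses must be > 0")
  roughness <- rep_len(as.numeric(roughness), max(n, 1L))[seq_len(n)]
  if (any(roughness < 0) || backing_roughness < 0)
    stop("roughness must be >= 0")
  # Nevot-Croce is only trustworthy for roughness much below the layer
  # thickness; warn rather than refuse.
  if (n > 0 && (any(roughness > thickness / 3 + 1e-12) ||
                backing_roughness > thickness[n] / 3 + 1e-12))
    warning("interfacial roughness exceeds a third of an adjacent slab ",
            "thickness; the Nevot-Croce damping may be inaccurate")
  sldc <- vapply(if (n) as.list(sld) else list(), sld_complex, complex(1))
  structure(list(fronting = sld_complex(fronting),
                 thickness = thickness, sld = sldc, roughness = roughness,
                 backing = sld_complex(backing),
                 backing_roughness = backing_roughness),
            class = "slab_stack")
}

#' @export
print.slab_stack <- function(x, ...) {
  cat(sprintf(
    "Slab stack: %d slab(s), %.1f A total | fronting %.2f, backing %.2f x 1e-6/A^2\n",
    length(x$thickness), sum(x$thickness), Re(x$fronting) * 1e6,
    Re(x$backing) * 1e6))
  invisible(x)
}

#' Reflectivity curve container
#'
#' @param Q Momentum transfer grid, 1/A, strictly ascending and positive.
#' @param R Reflectivity (dimensionless intensities).
#' @param dR Optional 1-sigma uncertainties.
#' @param dQ_over_Q Optional relative resolution attached to the curve.
#' @param scale,background Metadata recording applied corrections.
#' @return An object of class `refl_curve`.
#' @export
refl_curve <- function(Q, R, dR = NULL, dQ_over_Q = NULL, scale = 1,
                       background = 0) {
  Q <- as.numeric(Q); R <- as.numeric(R)
  stopifnot(length(Q) == length(R))
  if (any(Q <= 0) || any(diff(Q) <= 0))
    stop("Q must be positive and strictly ascending")
  if (any(!is.finite(R)) || any(R < 0)) stop("R must be finite and >= 0")
  if (!is.null(dR)) {
    stopifnot(length(dR) == length(R))
    if (any(dR < 0)) stop("dR must be >= 0")
  }
  structure(list(Q = Q, R = R, dR = dR, dQ_over_Q = dQ_over_Q,
                 scale = scale, background = background),
            class = "refl_curve")
}

#' @export
print.refl_curve <- function(x, ...) {
  cat(sprintf("Reflectivity curve: %d points, Q in [%.4g, %.4g] 1/A%s\n",
              length(x$Q), min(x$Q), max(x$Q),
              if (is.null(x$dR)) "" else " (with uncertainties)"))
  invisible(x)
}

# z-component of the wavevector in medium with SLD rho, referenced to the
# fronting medium: kz = sqrt((Q/2)^2 - 4 pi (rho - rho_front)).  The complex
# square root's principal branch gives the +i kappa evanescent wave below
# the critical edge.
medium_kz <- function(Q, rho, rho_front) {
  sqrt(as.complex((Q / 2)^2 - 4 * pi * (rho - rho_front)))
}

#' Fresnel amplitudes of a single interface
#'
#' r = (q_f - q_b) / (q_f + q_b) and t = 2 q_f / (q_f + q_b) with q_i the
#' z wavevectors in the two media.  Below the critical edge q_b is purely
#' imaginary (evanescent transmitted wave) and |r| = 1.
#'
#' @param Q Momentum transfer, 1/A, vectorised.
#' @param sld_front,sld_back Medium SLDs.
#' @return List with complex vectors `r` and `t`.
#' @export
fresnel_interface <- function(Q, sld_front, sld_back) {
  stopifnot(all(Q > 0))
  f <- sld_complex(as_sld(sld_front)); b <- sld_complex(as_sld(sld_back))
  qf <- medium_kz(Q, f, f)
  qb <- medium_kz(Q, b, f)
  list(r = (qf - qb) / (qf + qb), t = 2 * qf / (qf + qb))
}

stack_media <- function(stack) {
  list(rho = c(stack$fronting, stack$sld, stack$backing),
       d = c(0, stack$thickness, 0),
       # sigma of interface j (between media j and j+1) is the roughness
       # attached to the lower medium j+1
       sigma = c(stack$roughness, stack$backing_roughness))
}

#' Specular reflectivity by Parratt recursion
#'
#' Exact recursive solution for a stratified medium: starting at the
#' semi-infinite backing, the amplitude reflectance is propagated interface
#' by interface to the surface.  Gaussian interfacial roughness enters as
#' the Nevot-Croce factor exp(-2 kz_j kz_j+1 sigma_j^2) on each interface
#' reflectance.
#'
#' @param stack A [slab_stack()].
#' @param Q Ascending positive Q grid, 1/A.
#' @return A [refl_curve()] with R = |r|^2.
#' @export
parratt_reflectivity <- function(stack, Q) {
  stopifnot(inherits(stack, "slab_stack"))
  m <- stack_media(stack)
  n_med <- length(m$rho)
  kz_lower <- medium_kz(Q, m$rho[n_med], m$rho[1])
  r_tot <- complex(length(Q)) # reflectance seen from just above the backing
  for (j in seq(n_med - 1L, 1L)) {
    kz_upper <- medium_kz(Q, m$rho[j], m$rho[1])
    r_j <- (kz_upper - kz_lower) / (kz_upper + kz_lower) *
      exp(-2 * kz_upper * kz_lower * m$sigma[j]^2)
    if (j == n_med - 1L) {
      r_tot <- r_j
    } else {
      phase <- exp(2i * kz_lower * m$d[j + 1L])
      r_tot <- (r_j + r_tot * phase) / (1 + r_j * r_tot * phase)
    }
    kz_lower <- kz_upper
  }
  refl_curve(Q, Mod(r_tot)^2)
}

#' Specular reflectivity by Abeles transfer matrices
#'
#' Optical transfer-matrix formulation: one characteristic 2x2 matrix per
#' interface (carrying the layer phase and the rough-interface Fresnel
#' coefficient) is accumulated from the fronting down; R = |M21 / M11|^2.
#' Exact, and an independent kernel from [parratt_reflectivity()] — the two
#' agree to floating-point accuracy and serve as mutual cross-checks.
#'
#' @inheritParams parratt_reflectivity
#' @return A [refl_curve()].
#' @export
abeles_reflectivity <- function(stack, Q) {
  stopifnot(inherits(stack, "slab_stack"))
  m <- stack_media(stack)
  n_med <- length(m$rho)
  one <- complex(real = rep(1, length(Q)))
  m11 <- one; m12 <- 0 * one; m21 <- 0 * one; m22 <- one
  kz_upper <- medium_kz(Q, m$rho[1], m$rho[1])
  for (j in seq_len(n_med - 1L)) {
    kz_lower <- medium_kz(Q, m$rho[j + 1L], m$rho[1])
    r_j <- (kz_upper - kz_lower) / (kz_upper + kz_lower) *
      exp(-2 * kz_upper * kz_lower * m$sigma[j]^2)
    beta <- kz_upper * m$d[j] # zero for the fronting medium
    ep <- exp(1i * beta); em <- exp(-1i * beta)
    c11 <- ep; c12 <- r_j * ep; c21 <- r_j * em; c22 <- em
    t11 <- m11 * c11 + m12 * c21
    t12 <- m11 * c12 + m12 * c22
    t21 <- m21 * c11 + m22 * c21
    t22 <- m21 * c12 + m22 * c22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
    kz_upper <- kz_lower
  }
  refl_curve(Q, Mod(m21 / m11)^2)
}

#' Born-approximation ("master equation") reflectivity of a binned profile
#'
#' R(Q) = R_Fresnel(Q) |integral drho/dz exp(iQz) dz|^2 / (delta rho)^2,
#' with the derivative evaluated as the SLD steps of the binned profile
#' (exact for a piecewise-constant profile) and R_Fresnel the bare
#' fronting/backing interface reflectivity.  Valid only well above the
#' critical edge; points with Q <= Qc are flagged in the `valid` attribute
#' and the weak-scattering assumption degrades as R approaches 1.
#'
#' @param profile An [sld_profile()] with distinct fronting and backing.
#' @param Q Ascending positive Q grid, 1/A.
#' @return A [refl_curve()] with attribute `valid` (logical per point,
#'   FALSE at and below the critical edge).
#' @export
born_reflectivity <- function(profile, Q) {
  stopifnot(inherits(profile, "sld_profile"))
  drho_tot <- profile$backing - profile$fronting
  if (abs(drho_tot) < 1e-15)
    stop("Born master equation needs a nonzero total fronting/backing contrast")
  steps <- diff(c(profile$fronting, profile$rho, profile$backing))
  z <- profile$bin_edges
  ft <- vapply(Q, function(q) sum(steps * exp(1i * q * z)), complex(1))
  rf <- Mod(fresnel_interface(Q, profile$fronting, profile$backing)$r)^2
  out <- refl_curve(Q, rf * Mod(ft)^2 / drho_tot^2)
  qc <- critical_q(profile$fronting, profile$backing)
  attr(out, "valid") <- Q > qc
  out
}

#' Gaussian resolution smearing
#'
#' Convolves a model curve pointwise with a Gaussian of width dQ = dQ/Q * Q,
#' interpreted as the kernel's full width at half maximum (the common
#' reflectometry convention; set `convention = "sigma"` for a sigma
#' fraction).  The integrand is evaluated with a fixed Gauss-Legendre rule
#' over +/- 4 sigma on a log10-interpolated copy of the curve, clamped at
#' the grid ends.
#'
#' @param curve A [refl_curve()] (or `sans_curve`) on a grid fine enough to
#'   resolve its features.
#' @param dQ_over_Q Relative resolution width (e.g. 0.035); 0 is identity.
#' @param convention `"fwhm"` or `"sigma"`.
#' @param n_nodes Quadrature nodes per point.
#' @return A curve of the same class on the same Q grid.
#' @export
smear_resolution <- function(curve, dQ_over_Q, convention = c("fwhm", "sigma"),
                             n_nodes = 51) {
  convention <- match.arg(convention)
  stopifnot(dQ_over_Q >= 0)
  if (dQ_over_Q == 0) return(curve)
  y_field <- if (inherits(curve, "sans_curve")) "I" else "R"
  Q <- curve$Q; y <- curve[[y_field]]
  fwhm_per_sigma <- 2 * sqrt(2 * log(2))
  sig <- dQ_over_Q * Q
  if (convention == "fwhm") sig <- sig / fwhm_per_sigma
  gl <- pracma::gaussLegendre(n_nodes, -4, 4)
  pos <- all(y > 0)
  f <- if (pos) stats::approxfun(Q, log10(y), rule = 2)
       else stats::approxfun(Q, y, rule = 2)
  w_gauss <- gl$w * stats::dnorm(gl$x)
  ys <- vapply(seq_along(Q), function(i) {
    qq <- Q[i] + gl$x * sig[i]
    vals <- f(qq)
    if (pos) vals <- 10^vals
    sum(w_gauss * vals) / sum(w_gauss)
  }, numeric(1))
  out <- curve
  out[[y_field]] <- ys
  out$dQ_over_Q <- dQ_over_Q
  out
}

#' Apply intensity scale and constant background
#'
#' R' = scale * R + background.  The scale absorbs normalization errors of
#' the incident-intensity measurement; the Q-independent background models
#' incoherent and instrumental scattering.
#'
#' @param curve A [refl_curve()] or `sans_curve`.
#' @param scale Positive multiplicative factor.
#' @param background Additive constant, >= 0.
#' @return A curve of the same class.
#' @export
apply_scale_background <- function(curve, scale = 1, background = 0) {
  stopifnot(scale > 0, background >= 0)
  y_field <- if (inherits(curve, "sans_curve")) "I" else "R"
  out <- curve
  out[[y_field]] <- scale * curve[[y_field]] + background
  if (!is.null(curve$dR)) out$dR <- scale * curve$dR
  if (!is.null(curve$dI)) out$dI <- scale * curve$dI
  out$scale <- scale * curve$scale
  out$background <- background + scale * curve$background
  out
}

#' Incoherent average of reflectivity curves
#'
#' Pointwise mean of intensities (never amplitudes) over structural
#' realizations, appropriate when the realizations are uncorrelated, e.g.
#' lamellar stacks with independently jittered water gaps.
#'
#' @param curves List of curves on identical Q grids.
#' @return A curve of the same class as the first element.
#' @export
incoherent_mean <- function(curves) {
  stopifnot(length(curves) >= 1L)
  y_field <- if (inherits(curves[[1]], "sans_curve")) "I" else "R"
  Q <- curves[[1]]$Q
  for (cv in curves[-1])
    if (!isTRUE(all.equal(cv$Q, Q))) stop("curves must share one Q grid")
  ys <- rowMeans(vapply(curves, function(cv) cv[[y_field]],
                        numeric(length(Q))))
  out <- curves[[1]]
  out[[y_field]] <- ys
  out
}

# scipy-style peak prominence on a numeric series
peak_prominence <- function(y, i) {
  side_base <- function(idx) {
    lo <- y[i]
    for (k in idx) {
      if (y[k] > y[i]) break
      lo <- min(lo, y[k])
    }
    lo
  }
  left <- if (i > 1) side_base(seq(i - 1, 1)) else y[i]
  right <- if (i < length(y)) side_base(seq(i + 1, length(y))) else y[i]
  y[i] - max(left, right)
}

#' Locate Bragg peaks on a reflectivity curve
#'
#' Finds local maxima of log10 R above a prominence threshold (in decades)
#' for Q >= q_min, refines each position by parabolic interpolation through
#' the three surrounding points and reports the lamellar spacing
#' d = 2 pi / Q_peak.
#'
#' @param curve A [refl_curve()], ideally after resolution smearing.
#' @param q_min Lower Q cutoff excluding the total-reflection/critical-edge
#'   region.
#' @param prominence Minimum peak prominence in decades of R (default 0.3).
#' @return Data frame with columns `Q_peak`, `d`, `prominence` (possibly
#'   zero rows).
#' @export
locate_bragg_peaks <- function(curve, q_min, prominence = 0.3) {
  keep <- curve$Q >= q_min & curve$R > 0
  Q <- curve$Q[keep]; y <- log10(curve$R[keep])
  n <- length(y)
  res <- data.frame(Q_peak = numeric(0), d = numeric(0),
                    prominence = numeric(0))
  if (n < 3) return(res)
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      p <- peak_prominence(y, i)
      if (p >= prominence) {
        denom <- y[i - 1] - 2 * y[i] + y[i + 1]
        delta <- if (abs(denom) > 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
        delta <- max(min(delta, 0.5), -0.5)
        qp <- Q[i] + delta * (Q[min(i + 1, n)] - Q[max(i - 1, 1)]) / 2
        res <- rbind(res, data.frame(Q_peak = qp, d = 2 * pi / qp,
                                     prominence = p))
      }
    }
  }
  res[order(res$Q_peak), , drop = FALSE]
}
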