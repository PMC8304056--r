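#' Unilamellar vesicle model
#'
#' A spherical vesicle with a solvent-filled core of radius `core_radius`
#' and `n` concentric shells of piecewise-constant SLD (inner to outer
#' leaflet), in a solvent of SLD `solvent_sld`.  The solvent core is
#' polydisperse with a Schulz-Zimm distribution of relative width `p`
#' (= sigma_R / mean R); shell thicknesses are monodisperse.
#'
#' @param core_radius Mean solvent-core radius R0, Angstrom, > 0.
#' @param shell_thickness Shell thicknesses, A, inner to outer, all > 0.
#' @param shell_sld Shell SLDs, 1/A^2, same length.
#' @param solvent_sld Solvent SLD.
#' @param polydispersity p = sigma_R / mean R of the core radius, in
#'   \[0, 1).
#' @param scale Multiplicative intensity prefactor (absorbs the vesicle
#'   number density and unit conversion to 1/cm).
#' @param background Constant incoherent background, same units as I(Q).
#' @return An object of class `vesicle_model`.
#' @export
vesicle_model <- function(core_radius, shell_thickness, shell_sld,
                          solvent_sld, polydispersity = 0, scale = 1,
                          background = 0) {
  stopifnot(core_radius > 0, length(shell_thickness) == length(shell_sld),
            length(shell_thickness) >= 1L)
  if (any(shell_thickness <= 0)) stop("shell thicknesses must be > 0")
  if (polydispersity < 0 || polydispersity >= 1)
    stop("polydispersity must lie in [0, 1)")
  stopifnot(scale > 0, background >= 0)
  structure(list(core_radius = core_radius,
                 shell_thickness = as.numeric(shell_thickness),
                 shell_sld = vapply(as.list(shell_sld),
                                    function(s) as_sld(s)$real, numeric(1)),
                 solvent_sld = as_sld(solvent_sld)$real,
                 polydispersity = polydispersity,
                 scale = scale, background = background),
            class = "vesicle_model")
}

#' @export
print.vesicle_model <- function(x, ...) {
  cat(sprintf(
    "Vesicle: core R0 = %.1f A, %d shell(s) (%.1f A total), p = %.3f\n",
    x$core_radius, length(x$shell_thickness), sum(x$shell_thickness),
    x$polydispersity))
  invisible(x)
}

#' SANS curve container
#'
#' @param Q Momentum transfer, 1/A, strictly ascending.
#' @param I Macroscopic cross section dSigma/dOmega, 1/cm.
#' @param dI Optional 1-sigma uncertainties.
#' @return An object of class `sans_curve`.
#' @export
sans_curve <- function(Q, I, dI = NULL) {
  Q <- as.numeric(Q); I <- as.numeric(I)
  stopifnot(length(Q) == length(I))
  if (any(Q <= 0) || any(diff(Q) <= 0))
    stop("Q must be positive and strictly ascending")
  if (!is.null(dI)) {
    stopifnot(length(dI) == length(I))
    if (any(dI < 0)) stop("dI must be >= 0")
  }
  structure(list(Q = Q, I = I, dI = dI), class = "sans_curve")
}

#' @export
print.sans_curve <- function(x, ...) {
  cat(sprintf("SANS curve: %d points, Q in [%.4g, %.4g] 1/A%s\n",
              length(x$Q), min(x$Q), max(x$Q),
              if (is.null(x$dI)) "" else " (with uncertainties)"))
  invisible(x)
}

# 3 V(R) [sin(QR) - QR cos(QR)] / (QR)^3, the hard-sphere kernel of the
# spherically symmetric Fourier integral; series expansion near QR = 0.
sphere_kernel <- function(Q, R) {
  x <- Q * R
  v <- 4 / 3 * pi * R^3
  small <- abs(x) < 1e-3
  out <- numeric(length(x))
  out[small] <- v * (1 - x[small]^2 / 10)
  xl <- x[!small]
  out[!small] <- v * 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

# radii of the shell boundaries, core first
shell_radii <- function(model, core_radius = model$core_radius) {
  core_radius + cumsum(c(0, model$shell_thickness))
}

#' Scattering amplitude of a concentric-shell vesicle
#'
#' Analytic evaluation of the spherically symmetric Fourier integral for a
#' piecewise-constant radial SLD profile: each shell contributes its
#' contrast against the solvent times the difference of hard-sphere kernels
#' at its outer and inner boundary.  The solvent core carries zero contrast
#' by construction, so F depends on SLDs only through shell-solvent
#' differences.
#'
#' @param model A [vesicle_model()].
#' @param Q Momentum transfer, 1/A, vectorised, >= 0.
#' @param core_radius Optional core radius overriding the model's (used by
#'   the polydispersity quadrature).
#' @return Amplitude F(Q) in Angstrom (F(0) = sum of shell volume *
#'   contrast).
#' @export
shell_amplitude <- function(model, Q, core_radius = model$core_radius) {
  stopifnot(inherits(model, "vesicle_model"), all(Q >= 0))
  radii <- shell_radii(model, core_radius)
  drho <- model$shell_sld - model$solvent_sld
  f <- numeric(length(Q))
  for (i in seq_along(drho)) {
    f <- f + drho[i] * (sphere_kernel(Q, radii[i + 1]) -
                          sphere_kernel(Q, radii[i]))
  }
  f
}

#' Wrap a planar membrane SLD profile onto a vesicle
#'
#' Maps each z-bin of a (solvent-trimmed) membrane profile onto one
#' concentric shell of the same thickness, inner leaflet first, starting at
#' `core_radius`.  Leading or trailing bins still at the bulk solvent SLD
#' indicate an untrimmed profile and are rejected, since they would inflate
#' the membrane thickness.
#'
#' @param profile An [sld_profile()] covering the membrane only.
#' @param core_radius Solvent-core radius, A.
#' @param solvent_sld Solvent SLD.
#' @param polydispersity,scale,background Passed to [vesicle_model()].
#' @param tol Solvent-detection tolerance, 1/A^2.
#' @return A [vesicle_model()] with one shell per bin.
#' @export
profile_to_shells <- function(profile, core_radius, solvent_sld,
                              polydispersity = 0, scale = 1, background = 0,
                              tol = 1e-7) {
  stopifnot(inherits(profile, "sld_profile"))
  sol <- as_sld(solvent_sld)$real
  rho <- profile$rho
  if (abs(rho[1] - sol) <= tol || abs(rho[length(rho)] - sol) <= tol)
    stop("profile has untrimmed bulk-solvent tails; trim to the membrane ",
         "before wrapping it onto a vesicle")
  vesicle_model(core_radius,
                shell_thickness = rep(profile$bin_width, length(rho)),
                shell_sld = rho, solvent_sld = sol,
                polydispersity = polydispersity, scale = scale,
                background = background)
}

#' Schulz-Zimm probability density
#'
#' Conventional vesicle-core size distribution, parameterised by the mean
#' radius and the relative width p = sigma/mean; the shape parameter is
#' z = 1/p^2 - 1.
#'
#' @param r Radii at which to evaluate, A.
#' @param mean_r Mean radius, A.
#' @param p Relative width, in (0, 1).
#' @return Density values (1/A).
#' @export
schulz_zimm_pdf <- function(r, mean_r, p) {
  stopifnot(mean_r > 0, p > 0, p < 1)
  z <- 1 / p^2 - 1
  out <- numeric(length(r))
  pos <- r > 0
  out[pos] <- exp((z + 1) * log((z + 1) / mean_r) + z * log(r[pos]) -
                    (z + 1) * r[pos] / mean_r - lgamma(z + 1))
  out
}

# Gauss-Legendre nodes/weights over the truncated Schulz-Zimm distribution
schulz_zimm_quadrature <- function(mean_r, p, n_points = 101) {
  sd <- p * mean_r
  lo <- max(mean_r - 5 * sd, 1e-6)
  hi <- mean_r + 5 * sd
  gl <- pracma::gaussLegendre(n_points, lo, hi)
  w <- gl$w * schulz_zimm_pdf(gl$x, mean_r, p)
  list(r = gl$x, w = w / sum(w))
}

#' Polydisperse vesicle SANS intensity
#'
#' I(Q) = scale * <|F(Q; R)|^2> + background, averaging the squared
#' concentric-shell amplitude over the Schulz-Zimm distribution of the core
#' radius by fixed Gauss-Legendre quadrature (mean +/- 5 sigma, truncated at
#' R > 0); shell thicknesses are held fixed.  p below 1e-8 short-circuits to
#' the monodisperse form factor.
#'
#' @param model A [vesicle_model()].
#' @param Q Ascending positive Q grid, 1/A.
#' @param n_quad Number of quadrature points (>= 15).
#' @return A [sans_curve()].
#' @export
polydisperse_intensity <- function(model, Q, n_quad = 101) {
  stopifnot(inherits(model, "vesicle_model"), n_quad >= 15)
  p <- model$polydispersity
  if (p < 1e-8) {
    i_q <- shell_amplitude(model, Q)^2
  } else {
    quad <- schulz_zimm_quadrature(model$core_radius, p, n_quad)
    fsq <- vapply(seq_along(quad$r), function(k)
      shell_amplitude(model, Q, core_radius = quad$r[k])^2,
      numeric(length(Q)))
    i_q <- as.numeric(fsq %*% quad$w)
  }
  sans_curve(Q, model$scale * i_q + model$background)
}

vesicle_update <- function(model, pars) {
  m <- model
  if (!is.null(pars[["R0"]])) m$core_radius <- pars[["R0"]]
  if (!is.null(pars[["p"]])) m$polydispersity <- pars[["p"]]
  if (!is.null(pars[["scale"]])) m$scale <- pars[["scale"]]
  if (!is.null(pars[["background"]])) m$background <- pars[["background"]]
  if (!is.null(pars[["thickness_factor"]]))
    m$shell_thickness <- model$shell_thickness * pars[["thickness_factor"]]
  m
}

#' Fit a vesicle model to SANS data
#'
#' Weighted least squares (Levenberg-Marquardt) of
#' [polydisperse_intensity()] against a measured curve.  Free parameters are
#' any subset of `R0` (core radius), `p` (polydispersity), `scale`,
#' `background` and `thickness_factor` (a common multiplier on all shell
#' thicknesses — the bilayer-thickness dial).  Start values come from the
#' supplied model.  Parameter uncertainties are the square roots of the
#' covariance diagonal, scaled by the reduced chi-square.
#'
#' @param data A [sans_curve()] with strictly positive `dI`.
#' @param model A [vesicle_model()] providing structure and start values.
#' @param free Character vector of free parameter names.
#' @param n_quad Quadrature points for the polydispersity average.
#' @return List with elements `model` (fitted), `par`, `se`, `chisq_red`,
#'   `converged`, `message`, `n_data`, `n_free`.
#' @export
fit_vesicle <- function(data, model,
                        free = c("R0", "p", "scale", "background"),
                        n_quad = 101) {
  stopifnot(inherits(data, "sans_curve"), inherits(model, "vesicle_model"))
  if (is.null(data$dI) || any(data$dI <= 0))
    stop("data must carry strictly positive uncertainties dI")
  allowed <- c("R0", "p", "scale", "background", "thickness_factor")
  if (!all(free %in% allowed))
    stop("free parameters must be a subset of: ", paste(allowed, collapse = ", "))
  start <- c(R0 = model$core_radius, p = model$polydispersity,
             scale = model$scale, background = model$background,
             thickness_factor = 1)[free]
  lower <- c(R0 = 1, p = 0, scale = 1e-30, background = 0,
             thickness_factor = 0.1)[free]
  upper <- c(R0 = Inf, p = 0.95, scale = Inf, background = Inf,
             thickness_factor = 10)[free]
  resid_fun <- function(par) {
    m <- vesicle_update(model, as.list(stats::setNames(par, free)))
    pred <- polydisperse_intensity(m, data$Q, n_quad)$I
    (data$I - pred) / data$dI
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  n_free <- length(free)
  dof <- max(length(data$Q) - n_free, 1L)
  chisq_red <- sum(fit$fvec^2) / dof
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("vesicle fit did not converge (info = ", fit$info, "): ",
            fit$message)
  covm <- tryCatch(chisq_red * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, n_free) else sqrt(pmax(diag(covm), 0))
  names(se) <- free
  fitted_model <- vesicle_update(model, as.list(fit$par))
  list(model = fitted_model, par = fit$par, se = se, chisq_red = chisq_red,
       converged = converged, message = fit$message,
       n_data = length(data$Q), n_free = n_free)
}
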