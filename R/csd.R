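#' Spherical-spline surface Laplacian parameters
#'
#' Constants for the current source density (CSD) transform: spline order
#' `m` (stiffness of the interpolating spline), Tikhonov regularization
#' `lambda` added to the diagonal of the spline matrix, and the number of
#' Legendre polynomial terms used to evaluate the spline kernels. Defaults
#' are the standard settings of the surface-Laplacian literature.
#'
#' @param m integer spline order >= 2 (default 4).
#' @param lambda regularization >= 0 (default 1e-5).
#' @param legendre_terms number of series terms >= 20 (default 50).
#' @return a `csd_params` list.
#' @export
csd_params <- function(m = 4, lambda = 1e-5, legendre_terms = 50) {
  assert_scalar_number(m, "m", lower = 2)
  assert_scalar_number(lambda, "lambda", lower = 0)
  assert_scalar_number(legendre_terms, "legendre_terms", lower = 20)
  structure(list(m = as.integer(m), lambda = lambda,
                 legendre_terms = as.integer(legendre_terms)),
            class = "csd_params")
}

# Legendre polynomials P_1..P_nmax evaluated at each element of x (matrix),
# returned as a list of matrices (three-term recurrence)
legendre_seq <- function(x, nmax) {
  out <- vector("list", nmax)
  pm1 <- array(1, dim = dim(x))   # P_0
  p <- x                          # P_1
  out[[1]] <- p
  for (n in 2:nmax) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[[n]] <- pn
    pm1 <- p
    p <- pn
  }
  out
}

# spline kernel matrices G (potential) and H (Laplacian numerator) for
# cos(angle) matrix x, per Perrin-style spherical splines of order m
csd_kernels <- function(x, m, nterms) {
  P <- legendre_seq(x, nterms)
  G <- array(0, dim = dim(x))
  H <- array(0, dim = dim(x))
  for (n in seq_len(nterms)) {
    gn <- (2 * n + 1) / (n * (n + 1))^m
    hn <- (2 * n + 1) / (n * (n + 1))^(m - 1)
    G <- G + gn * P[[n]]
    H <- H + hn * P[[n]]
  }
  list(G = G / (4 * pi), H = H / (4 * pi))
}

# linear operator mapping good-channel potentials to CSD (uV/mm^2);
# reference-free because the spline's constant component is projected out
csd_transform_matrix <- function(mont, labels, params) {
  idx <- match(labels, mont$label)
  if (anyNA(idx)) {
    stop_swatopo("montage does not cover all channels.",
                 "swatopo_parameter_error")
  }
  r <- head_radius(mont)
  p <- as.matrix(mont[idx, c("x", "y", "z")]) / r
  cosang <- tcrossprod(p)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-12)) {
    stop_swatopo("degenerate montage: coincident electrode positions.",
                 "swatopo_validation_error")
  }
  k <- csd_kernels(cosang, params$m, params$legendre_terms)
  n <- length(labels)
  A <- rbind(cbind(k$G + diag(params$lambda, n), rep(1, n)),
             c(rep(1, n), 0))
  Ainv <- solve(A)
  # coefficient solve: c = Ainv[1:n, 1:n] %*% v (constant row handled by
  # the bordered system; v enters only the first n rows)
  C <- Ainv[seq_len(n), seq_len(n)]
  (k$H %*% C) / r^2
}

#' Surface Laplacian (current source density) transform
#'
#' Spherical-spline surface Laplacian applied to every time sample over the
#' good channels, yielding reference-free current source density in
#' microvolts per square millimetre. Adding a constant to all input channels
#' leaves the output unchanged, and a spatially constant field maps to zero.
#' Bad channels are dropped from the output.
#'
#' @param epochs an [epoched_recording()] in microvolts.
#' @param mont a [montage()] covering the good channels.
#' @param params a [csd_params()].
#' @return an [epoched_recording()] of CSD signals over good channels, units
#'   `"uV/mm^2"`.
#' @export
laplacian_transform <- function(epochs, mont, params = csd_params()) {
  stopifnot(inherits(epochs, "epoched_recording"))
  good <- setdiff(epochs$channel_labels, epochs$bad_channels)
  if (length(good) < 8) {
    stop_swatopo("CSD needs at least 8 good channels.",
                 "swatopo_parameter_error")
  }
  L <- csd_transform_matrix(mont, good, params)
  gi <- match(good, epochs$channel_labels)
  d <- dim(epochs$epochs)
  out <- array(0, dim = c(d[1], length(good), d[3]))
  for (e in seq_len(d[1])) {
    out[e, , ] <- L %*% epochs$epochs[e, gi, , drop = TRUE]
  }
  epoched_recording(out, epochs$epoch_stage, good, epochs$sampling_rate,
                    character(), units = "uV/mm^2")
}

#' Whole-night CSD SWA map
#'
#' Chains [laplacian_transform()] into the identical spectral path used for
#' potentials: per-epoch spectra, band power in the SWA band, artifact-free
#' N2/N3 averaging, normalization to the electrode mean and log transform.
#' CSD power is strictly positive, so the relative/log steps are well defined.
#'
#' @param epochs an [epoched_recording()] in microvolts (good channels used).
#' @param mont a [montage()].
#' @param params a [csd_params()].
#' @param bd SWA [band()].
#' @param artifact_mask optional logical per-epoch artifact flags carried
#'   over from the potential-domain screening.
#' @param subepoch_s subepoch length for the spectra.
#' @return a log-relative CSD SWA [topomap()].
#' @export
csd_swa_pipeline <- function(epochs, mont, params = csd_params(),
                             bd = swa_band(), artifact_mask = NULL,
                             subepoch_s = 5) {
  csd <- laplacian_transform(epochs, mont, params)
  pw <- epoch_band_power(csd, bd, subepoch_s)
  if (!is.null(artifact_mask)) pw <- set_artifacts(pw, artifact_mask)
  m <- swa_map(pw)
  if (mean(m$value) <= 0) {
    stop_swatopo("zero CSD power; cannot normalize.",
                 "swatopo_validation_error")
  }
  log_map(relativize(m))
}
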