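# Morphometric sampling laws of the renal arterial tree.
#
# Four laws drive the tree generator: a Gaussian for daughter diameter given
# parent diameter (cubic mean, linear SD), a Gaussian for vessel length given
# diameter (linear mean and SD), an exponential for the spacing between
# neighboring afferent arteriole origins, and a Gaussian for afferent
# arteriole diameter.

#' Morphometric distribution profile
#'
#' Bundles the four statistical laws of renal vessel geometry used by the
#' tree generator: the daughter-diameter law (Gaussian whose mean is a cubic
#' polynomial of the parent diameter and whose SD is linear in it), the
#' vessel-length law (Gaussian, linear mean and SD in the vessel diameter),
#' the exponential inter-arteriole spacing law, and the Gaussian afferent
#' arteriole diameter law.
#'
#' Polynomial coefficients are given in increasing order, i.e.
#' `c(c0, c1, c2, c3)` means `c0 + c1*D + c2*D^2 + c3*D^3`.
#'
#' @param ddp_mean_coeffs numeric(4), cubic coefficients mapping parent
#'   diameter (um) to mean daughter diameter (um).
#' @param ddp_sd_coeffs numeric(2), linear coefficients mapping parent
#'   diameter to the SD of the daughter diameter (um).
#' @param vlvd_mean_coeffs numeric(2), linear coefficients mapping vessel
#'   diameter (um) to mean vessel length (um).
#' @param vlvd_sd_coeffs numeric(2), linear coefficients mapping vessel
#'   diameter to the SD of vessel length (um).
#' @param aa_spacing_rate exponential rate lambda (1/um) for the distance
#'   between neighboring afferent arteriole origins.
#' @param aa_diam_mean,aa_diam_sd Gaussian parameters (um) for the afferent
#'   arteriole diameter.
#' @param valid_diameter_range numeric(2), diameter interval (um) over which
#'   the fits hold; sampling outside it is allowed but flagged.
#' @param name profile label used in printing and tree metadata.
#' @return An object of class `morphometry_profile`.
#' @seealso [default_morphometry()], [degenerate_morphometry()],
#'   [read_morphometry()]
#' @export
morphometry_profile <- function(ddp_mean_coeffs, ddp_sd_coeffs,
                                vlvd_mean_coeffs, vlvd_sd_coeffs,
                                aa_spacing_rate, aa_diam_mean, aa_diam_sd,
                                valid_diameter_range = c(20, 530),
                                name = "custom") {
  ddp_mean_coeffs <- rep_len(as.numeric(ddp_mean_coeffs), 4)
  ddp_sd_coeffs <- rep_len(as.numeric(ddp_sd_coeffs), 2)
  vlvd_mean_coeffs <- rep_len(as.numeric(vlvd_mean_coeffs), 2)
  vlvd_sd_coeffs <- rep_len(as.numeric(vlvd_sd_coeffs), 2)
  stopifnot(length(valid_diameter_range) == 2,
            valid_diameter_range[1] < valid_diameter_range[2])
  if (!is.finite(aa_spacing_rate) || aa_spacing_rate < 0)
    stop("'aa_spacing_rate' must be a non-negative finite rate (1/um)")
  if (!is.finite(aa_diam_mean) || aa_diam_mean <= 0)
    stop("'aa_diam_mean' must be positive")
  if (aa_diam_sd < 0) stop("'aa_diam_sd' must be non-negative")
  prof <- structure(list(
    ddp_mean_coeffs = ddp_mean_coeffs,
    ddp_sd_coeffs = ddp_sd_coeffs,
    vlvd_mean_coeffs = vlvd_mean_coeffs,
    vlvd_sd_coeffs = vlvd_sd_coeffs,
    aa_spacing_rate = as.numeric(aa_spacing_rate),
    aa_diam_mean = as.numeric(aa_diam_mean),
    aa_diam_sd = as.numeric(aa_diam_sd),
    valid_diameter_range = as.numeric(valid_diameter_range),
    name = as.character(name)
  ), class = "morphometry_profile")
  # SD laws must stay positive over the declared validity range unless the
  # profile is deliberately degenerate (all-zero SD).
  dd <- seq(valid_diameter_range[1], valid_diameter_range[2], length.out = 64)
  if (any(polyval(prof$ddp_sd_coeffs, dd) < 0))
    stop("daughter-diameter SD law is negative inside 'valid_diameter_range'")
  if (any(polyval(prof$vlvd_sd_coeffs, dd) < 0))
    stop("vessel-length SD law is negative inside 'valid_diameter_range'")
  prof
}

#' @export
print.morphometry_profile <- function(x, ...) {
  cat("Renal morphometry profile:", x$name, "\n")
  cat("  daughter diameter mean (cubic in Dp): ",
      paste(signif(x$ddp_mean_coeffs, 4), collapse = ", "), "\n")
  cat("  daughter diameter SD (linear in Dp):  ",
      paste(signif(x$ddp_sd_coeffs, 4), collapse = ", "), "\n")
  cat("  length mean / SD (linear in D): ",
      paste(signif(x$vlvd_mean_coeffs, 4), collapse = ", "), " / ",
      paste(signif(x$vlvd_sd_coeffs, 4), collapse = ", "), "\n")
  cat("  AA spacing rate lambda: ", signif(x$aa_spacing_rate, 4),
      " 1/um (mean spacing ",
      ifelse(x$aa_spacing_rate > 0, signif(1 / x$aa_spacing_rate, 4), Inf),
      " um)\n", sep = "")
  cat("  AA diameter: ", x$aa_diam_mean, " +/- ", x$aa_diam_sd, " um\n",
      sep = "")
  cat("  valid diameter range: [", x$valid_diameter_range[1], ", ",
      x$valid_diameter_range[2], "] um\n", sep = "")
  invisible(x)
}

# Evaluate a polynomial with coefficients in increasing order.
polyval <- function(coeffs, x) {
  out <- 0
  for (k in rev(seq_along(coeffs))) out <- out * x + coeffs[k]
  out
}

#' Packaged default morphometry profile
#'
#' Smooth approximations to published micro-CT morphometry of the rat renal
#' arterial tree (daughter-vs-parent diameters and length-vs-diameter, with a
#' cubic mean / linear SD for diameters and linear mean / SD for lengths),
#' together with an exponential inter-arteriole spacing law measured in
#' optically cleared tissue and a Gaussian afferent-arteriole diameter law.
#' The coefficients are this package's own digitization of those curves,
#' adjusted so that whole-kidney trees generated at `D_initial = 530`,
#' `D_stop = 22` reproduce the published afferent-arteriole statistics as
#' closely as the algorithm permits.
#'
#' @return A `morphometry_profile`.
#' @export
default_morphometry <- function() {
  read_morphometry(system.file("extdata", "default_morphometry.yaml",
                               package = "nephronet", mustWork = TRUE))
}

#' Degenerate (zero-variance) test profile
#'
#' All SDs are zero and the daughter mean is `2^(-1/3)` times the parent
#' diameter, so every bifurcation is perfectly symmetric and every sampler is
#' deterministic. Used for exact structural tests.
#'
#' @param length_per_diameter mean vessel length as a multiple of diameter.
#' @param aa_spacing_rate exponential spacing rate; defaults to (near) zero so
#'   no side arterioles are generated.
#' @return A `morphometry_profile`.
#' @export
degenerate_morphometry <- function(length_per_diameter = 7.5,
                                   aa_spacing_rate = 1e-12) {
  morphometry_profile(
    ddp_mean_coeffs = c(0, 2^(-1 / 3), 0, 0),
    ddp_sd_coeffs = c(0, 0),
    vlvd_mean_coeffs = c(0, length_per_diameter),
    vlvd_sd_coeffs = c(0, 0),
    aa_spacing_rate = aa_spacing_rate,
    aa_diam_mean = 19.25, aa_diam_sd = 0,
    valid_diameter_range = c(1, 1000),
    name = "degenerate"
  )
}

#' Read / write a morphometry profile (YAML)
#'
#' @param path file path of a YAML profile with the fields of
#'   [morphometry_profile()].
#' @return `read_morphometry` returns a `morphometry_profile`;
#'   `write_morphometry` invisibly returns `path`.
#' @export
read_morphometry <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("ddp_mean_coeffs", "ddp_sd_coeffs", "vlvd_mean_coeffs",
            "vlvd_sd_coeffs", "aa_spacing_rate", "aa_diam_mean", "aa_diam_sd")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("morphometry file is missing fields: ", paste(miss, collapse = ", "))
  morphometry_profile(
    ddp_mean_coeffs = y$ddp_mean_coeffs,
    ddp_sd_coeffs = y$ddp_sd_coeffs,
    vlvd_mean_coeffs = y$vlvd_mean_coeffs,
    vlvd_sd_coeffs = y$vlvd_sd_coeffs,
    aa_spacing_rate = y$aa_spacing_rate,
    aa_diam_mean = y$aa_diam_mean,
    aa_diam_sd = y$aa_diam_sd,
    valid_diameter_range = if (!is.null(y$valid_diameter_range))
      y$valid_diameter_range else c(20, 530),
    name = if (!is.null(y$name)) y$name else basename(path)
  )
}

#' @rdname read_morphometry
#' @param profile a `morphometry_profile` to serialize.
#' @export
write_morphometry <- function(profile, path) {
  stopifnot(inherits(profile, "morphometry_profile"))
  yaml::write_yaml(unclass(profile), path)
  invisible(path)
}

# Truncated-normal draw on (lower, upper): rejection sampling with a retry
# cap, then clamping to the nearest admissible boundary value.
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf, retries = 100) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  tries <- 0
  while (length(bad) && tries < retries) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x <= lower | x >= upper)
    tries <- tries + 1
  }
  if (length(bad)) {
    # clamp 1% inside the violated boundary
    lo <- lower[bad]; up <- upper[bad]
    span <- ifelse(is.finite(up), up - lo, pmax(abs(mean[bad]), 1))
    x[bad] <- ifelse(x[bad] <= lo, lo + 0.01 * span, up - 0.01 * span)
  }
  x
}

check_diameter_range <- function(diam, profile, what, warn = TRUE) {
  out <- diam < profile$valid_diameter_range[1] |
    diam > profile$valid_diameter_range[2]
  if (warn && any(out))
    warning(sprintf(
      "%d %s value(s) outside the fitted diameter range [%g, %g] um; %s",
      sum(out), what, profile$valid_diameter_range[1],
      profile$valid_diameter_range[2], "extrapolating the fits"),
      call. = FALSE)
  invisible(sum(out))
}

#' Sample daughter vessel diameters
#'
#' Draws the first daughter diameter from a Gaussian whose mean is the cubic
#' fit and whose SD is the linear fit evaluated at the parent diameter,
#' truncated to `(0, parent_diam)` so that the Murray complement of the draw
#' stays real.
#'
#' @param parent_diam parent vessel diameter (um), scalar or vector.
#' @param profile a [morphometry_profile()].
#' @param n number of draws per parent value (only for scalar `parent_diam`).
#' @param warn warn when extrapolating outside the profile's validity range.
#' @return Sampled daughter diameters (um).
#' @export
sample_daughter_diameter <- function(parent_diam, profile, n = length(parent_diam),
                                     warn = TRUE) {
  if (any(!is.finite(parent_diam)) || any(parent_diam <= 0))
    stop("'parent_diam' must be positive")
  if (length(parent_diam) == 1) parent_diam <- rep(parent_diam, n)
  check_diameter_range(parent_diam, profile, "parent diameter", warn)
  m <- polyval(profile$ddp_mean_coeffs, parent_diam)
  s <- pmax(polyval(profile$ddp_sd_coeffs, parent_diam), 0)
  pmin(rnorm_trunc(n, m, s, lower = 0, upper = parent_diam),
       parent_diam * (1 - 1e-12))
}

#' Sample vessel lengths
#'
#' Gaussian draw with mean and SD linear in the vessel diameter, truncated to
#' be strictly positive.
#'
#' @inheritParams sample_daughter_diameter
#' @param diam vessel diameter (um), scalar or vector.
#' @return Sampled lengths (um).
#' @export
sample_vessel_length <- function(diam, profile, n = length(diam), warn = TRUE) {
  if (any(!is.finite(diam)) || any(diam <= 0)) stop("'diam' must be positive")
  if (length(diam) == 1) diam <- rep(diam, n)
  check_diameter_range(diam, profile, "vessel diameter", warn)
  m <- polyval(profile$vlvd_mean_coeffs, diam)
  s <- pmax(polyval(profile$vlvd_sd_coeffs, diam), 0)
  rnorm_trunc(n, m, s, lower = 0)
}

#' Sample inter-arteriole spacings
#'
#' Exponential draws with the profile's rate; support `[0, Inf)`, so zero or
#' near-zero distances (arteriole doublets/triplets) are legal outcomes.
#'
#' @inheritParams sample_daughter_diameter
#' @param n number of draws.
#' @return Sampled spacings (um).
#' @export
sample_aa_spacing <- function(n, profile) {
  if (profile$aa_spacing_rate <= 0)
    stop("profile has non-positive 'aa_spacing_rate'")
  stats::rexp(n, rate = profile$aa_spacing_rate)
}

#' Sample afferent arteriole diameters
#'
#' Truncated-Gaussian draw, strictly positive, and kept below the feeding
#' vessel diameter when one is supplied.
#'
#' @inheritParams sample_daughter_diameter
#' @param feeding_diam optional feeding vessel diameter (um) acting as an
#'   upper truncation bound; scalar or vector.
#' @param n number of draws.
#' @return Sampled arteriole diameters (um).
#' @export
sample_aa_diameter <- function(n, profile, feeding_diam = Inf) {
  if (profile$aa_diam_mean <= 0) stop("profile has non-positive 'aa_diam_mean'")
  up <- rep_len(feeding_diam, n)
  pmin(rnorm_trunc(n, profile$aa_diam_mean, profile$aa_diam_sd,
                   lower = 0, upper = up),
       ifelse(is.finite(up), up * (1 - 1e-12), Inf))
}

#' Fit the exponential inter-arteriole spacing rate
#'
#' Maximum-likelihood fit `lambda = 1 / mean(distance)` with a bootstrap
#' percentile confidence interval. Optionally rescales the input distances by
#' `1 / shrinkage` first, to undo isotropic tissue shrinkage from optical
#' clearing before fitting.
#'
#' @param distances non-negative spacings (um), length >= 2.
#' @param n_boot number of bootstrap resamples for the CI.
#' @param conf confidence level of the percentile interval.
#' @param shrinkage_correct logical; apply the shrinkage correction.
#' @param shrinkage linear shrinkage factor (cleared length / true length).
#' @return A list of class `aa_spacing_fit` with elements `rate` (1/um),
#'   `ci` (length-2), `mean_spacing` (um), `n`, `shrinkage_applied`.
#' @export
fit_exponential_spacing <- function(distances, n_boot = 1000, conf = 0.95,
                                    shrinkage_correct = FALSE, shrinkage = 0.8) {
  distances <- as.numeric(distances)
  if (length(distances) < 2) stop("need at least 2 distances")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and non-negative")
  if (all(distances == 0)) stop("all distances are zero; rate is undefined")
  if (shrinkage_correct) distances <- distances / shrinkage
  n <- length(distances)
  rate <- 1 / mean(distances)
  boot <- if (n_boot > 0) {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    1 / colMeans(matrix(distances[idx], nrow = n))
  } else rep(rate, 2)
  alpha <- (1 - conf) / 2
  structure(list(
    rate = rate,
    ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
    mean_spacing = 1 / rate,
    n = n,
    shrinkage_applied = if (shrinkage_correct) shrinkage else NA_real_
  ), class = "aa_spacing_fit")
}

#' @export
print.aa_spacing_fit <- function(x, ...) {
  cat("Exponential inter-arteriole spacing fit\n")
  cat(sprintf("  rate lambda = %.5g 1/um  (mean spacing %.4g um, n = %d)\n",
              x$rate, x$mean_spacing, x$n))
  cat(sprintf("  bootstrap CI: [%.5g, %.5g]\n", x$ci[1], x$ci[2]))
  if (!is.na(x$shrinkage_applied))
    cat(sprintf("  distances corrected for %.0f%% tissue shrinkage\n",
                100 * (1 - x$shrinkage_applied)))
  invisible(x)
}
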