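# Fluorescence-polarization conversion and one-site Kd fitting, linear
# rate fits, size-exclusion calibration, and Gaussian volume-histogram
# fits.

#' Polarization from channel intensities
#'
#' `P = (parallel - perpendicular) / (parallel + 2 * perpendicular)`,
#' dimensionless (multiply by 1000 for mP).
#'
#' @param parallel,perpendicular Non-negative channel intensities
#'   (vectorized).
#' @return Polarization values.
#' @export
#' @examples
#' polarization(2, 1)  # 0.25
polarization <- function(parallel, perpendicular) {
  denom <- parallel + 2 * perpendicular
  if (any(denom <= 0)) stop("parallel + 2*perpendicular must be > 0")
  (parallel - perpendicular) / denom
}

#' Anisotropy from polarization
#'
#' `A = 2P / (3 - P)`.
#'
#' @param P Polarization values (each < 3).
#' @return Anisotropy values.
#' @export
#' @examples
#' anisotropy(0.25)  # 0.18182
anisotropy <- function(P) {
  if (any(P >= 3)) stop("polarization must be < 3")
  2 * P / (3 - P)
}

#' One-site binding curve
#'
#' Ligand-excess hyperbola: `A(c) = A_free + (A_bound - A_free) * c /
#' (Kd + c)`. The quadratic tight-binding form (explicit tracer depletion
#' at tracer concentration `tracer`) is available for Kd near the tracer
#' concentration.
#'
#' @param conc Titrated protein concentrations, molar.
#' @param kd Dissociation constant, molar.
#' @param a_free,a_bound Anisotropy endpoints.
#' @param tracer Tracer concentration in molar; `0` (default) selects the
#'   hyperbola.
#' @return Anisotropy values.
#' @export
one_site_curve <- function(conc, kd, a_free, a_bound, tracer = 0) {
  if (tracer > 0) {
    b <- conc + tracer + kd
    frac <- (b - sqrt(b^2 - 4 * conc * tracer)) / (2 * tracer)
  } else {
    frac <- conc / (kd + conc)
  }
  a_free + (a_bound - a_free) * frac
}

#' Fit a one-site binding model to a titration
#'
#' Non-linear least squares of the one-site model on (concentration,
#' anisotropy) pairs. Initialization: `a_free = min(A)`,
#' `a_bound = max(A)`, `Kd` at the concentration nearest half-range;
#' bounds `Kd` in `[1e-12, 1e-2]` M. The convergence flag is `FALSE` when
#' the optimizer fails or `Kd` lands on a bound.
#'
#' @param conc Strictly increasing non-negative concentrations, molar
#'   (>= 4 distinct points).
#' @param aniso Anisotropy values, same length.
#' @param tracer Tracer concentration (molar) for the tight-binding
#'   variant; 0 for the default hyperbola.
#' @return Object of class `binding_fit`: list with `kd`, `a_free`,
#'   `a_bound`, `se` (named vector), `residuals`, `converged`.
#' @export
#' @examples
#' conc <- 10^seq(-8, -4, length.out = 12)
#' a <- one_site_curve(conc, 1e-6, 0.07, 0.20)
#' fit_one_site(conc, a)$kd  # ~1e-6
fit_one_site <- function(conc, aniso, tracer = 0) {
  conc <- as.numeric(conc); aniso <- as.numeric(aniso)
  if (length(conc) != length(aniso)) stop("length mismatch")
  if (length(conc) < 4) stop("need at least 4 titration points")
  if (anyDuplicated(conc)) stop("concentrations must be distinct")
  if (any(!is.finite(conc)) || any(!is.finite(aniso))) {
    stop("non-finite values in titration")
  }
  if (any(conc < 0)) stop("negative concentration")
  a_free0 <- min(aniso); a_bound0 <- max(aniso)
  half <- (a_free0 + a_bound0) / 2
  kd0 <- conc[which.min(abs(aniso - half))]
  if (kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
  lower <- c(kd = 1e-12, a_free = -1, a_bound = -1)
  upper <- c(kd = 1e-2, a_free = 1, a_bound = 1)
  df <- data.frame(conc = conc, aniso = aniso)
  fit <- tryCatch(
    stats::nls(aniso ~ one_site_curve(conc, kd, a_free, a_bound, tracer),
               data = df,
               start = list(kd = kd0, a_free = a_free0, a_bound = a_bound0),
               lower = lower, upper = upper, algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, a_free = a_free0,
                          a_bound = a_bound0,
                          se = c(kd = NA_real_, a_free = NA_real_,
                                 a_bound = NA_real_),
                          residuals = rep(NA_real_, length(conc)),
                          converged = FALSE),
                     class = "binding_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  on_bound <- est["kd"] <= lower["kd"] * (1 + 1e-6) ||
    est["kd"] >= upper["kd"] * (1 - 1e-6)
  structure(list(kd = unname(est["kd"]), a_free = unname(est["a_free"]),
                 a_bound = unname(est["a_bound"]),
                 se = stats::setNames(as.numeric(se),
                                      c("kd", "a_free", "a_bound")),
                 residuals = as.numeric(stats::residuals(fit)),
                 converged = !on_bound),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("one-site fit: Kd = %.4g M (A_free %.4g, A_bound %.4g, %s)\n",
              x$kd, x$a_free, x$a_bound,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fold preference between two dissociation constants
#'
#' Affinity fold of ligand A over ligand B: `kd_b / kd_a` (a smaller Kd is
#' a tighter binder).
#'
#' @param kd_a,kd_b Positive dissociation constants (same units).
#' @return The fold preference.
#' @export
#' @examples
#' fold_preference(2e-8, 1e-6)  # 50
fold_preference <- function(kd_a, kd_b) {
  if (any(c(kd_a, kd_b) <= 0)) stop("Kd values must be positive")
  kd_b / kd_a
}

#' Linear rate fit of a time course
#'
#' Ordinary least squares of intensity on time over an optional window.
#'
#' @param time Times, minutes.
#' @param intensity Band intensities (densitometry units).
#' @param window Optional `c(min, max)` window in minutes (inclusive).
#' @return List with `slope` (units/min), `intercept`, `r_squared`,
#'   `n` points used.
#' @export
#' @examples
#' fit_linear_rate(0:5, 3 * (0:5) + 1)$slope  # 3
fit_linear_rate <- function(time, intensity, window = NULL) {
  time <- as.numeric(time); intensity <- as.numeric(intensity)
  if (length(time) != length(intensity)) stop("length mismatch")
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; intensity <- intensity[keep]
  }
  if (length(time) < 2) stop("need at least 2 points in the fit window")
  if (stats::var(time) == 0) stop("zero variance in time")
  fit <- stats::lm(intensity ~ time)
  # direct R^2 (avoids summary.lm's perfect-fit warning on exact lines)
  ss_tot <- sum((intensity - mean(intensity))^2)
  r2 <- if (ss_tot == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)["time"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = r2, n = length(time))
}

#' Apparent molecular weight from size-exclusion standards
#'
#' Calibrates `log10(MW)` linearly against retention time (default) or MW
#' directly (`log = FALSE`), then evaluates the calibration at the query
#' retention. Queries outside the standards' retention range trigger an
#' extrapolation warning.
#'
#' @param retention_std,mw_std Standards: retention times (min) and
#'   molecular weights (kDa); >= 2 distinct retentions.
#' @param retention Query retention time(s), minutes.
#' @param log Calibrate on log10(MW) (default `TRUE`).
#' @return Apparent molecular weight(s), kDa.
#' @export
#' @examples
#' sec_apparent_mw(c(10, 14), c(100, 10), 12)  # 31.62 kDa
sec_apparent_mw <- function(retention_std, mw_std, retention, log = TRUE) {
  if (length(retention_std) < 2) stop("need at least 2 standards")
  if (length(retention_std) != length(mw_std)) stop("length mismatch")
  if (anyDuplicated(retention_std)) stop("standard retentions must be distinct")
  y <- if (log) log10(mw_std) else mw_std
  fit <- stats::lm(y ~ retention_std)
  if (any(retention < min(retention_std)) ||
      any(retention > max(retention_std))) {
    warning("query retention outside the standards' range: extrapolating")
  }
  pred <- stats::predict(fit,
                         newdata = data.frame(retention_std = retention))
  unname(if (log) 10^pred else pred)
}

#' Fit a single Gaussian to a value histogram
#'
#' Bins the values, then least-squares fits
#' `amplitude * exp(-(x - mean)^2 / (2 * sigma^2))` to the bin counts at
#' bin midpoints; seeds are the sample mean and SD.
#'
#' @param values Numeric values (>= 20, not all identical), e.g. AFM
#'   particle volumes in nm^3.
#' @param bins Number of histogram bins (default `"FD"` rule via
#'   [graphics::hist()] breaks specification, or an integer count).
#' @return List with `mean`, `sigma`, `amplitude`, `converged`, and the
#'   histogram `mids`/`counts` used.
#' @export
fit_gaussian_hist <- function(values, bins = "FD") {
  values <- as.numeric(values)
  if (length(values) < 20) stop("need at least 20 values")
  if (stats::sd(values) == 0) stop("degenerate input: all values identical")
  h <- graphics::hist(values, breaks = bins, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(amplitude = max(h$counts), mean = mean(values),
                sigma = stats::sd(values))
  fit <- tryCatch(
    stats::nls(y ~ amplitude * exp(-(x - mean)^2 / (2 * sigma^2)),
               data = df, start = start,
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mean = start$mean, sigma = start$sigma,
                amplitude = start$amplitude, converged = FALSE,
                mids = h$mids, counts = h$counts))
  }
  est <- stats::coef(fit)
  list(mean = unname(est["mean"]), sigma = abs(unname(est["sigma"])),
       amplitude = unname(est["amplitude"]), converged = TRUE,
       mids = h$mids, counts = h$counts)
}

#' Read a two-column titration CSV
#'
#' Accepts either `(conc_M, parallel, perpendicular)` — converted via
#' [polarization()] and [anisotropy()] — or `(conc_M, anisotropy)`.
#'
#' @param path CSV path.
#' @return Data frame with `conc_M` and `anisotropy`.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"conc_M" %in% names(df)) stop("titration CSV needs a conc_M column")
  if (all(c("parallel", "perpendicular") %in% names(df))) {
    df$anisotropy <- anisotropy(polarization(df$parallel, df$perpendicular))
  } else if (!"anisotropy" %in% names(df)) {
    stop("titration CSV needs (parallel, perpendicular) or anisotropy")
  }
  df[, c("conc_M", "anisotropy")]
}
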