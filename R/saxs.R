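#' Construct a validated SAXS profile
#'
#' @param q Momentum transfer grid (1/Angstrom), strictly increasing, > 0.
#' @param i Intensity (arbitrary units).
#' @param sigma Per-point uncertainty, > 0, same units as `i`.
#' @param label Free-text label.
#' @return A tibble of class `saxs_profile` with columns `q`, `i`, `sigma`.
#' @export
saxs_profile <- function(q, i, sigma, label = "") {
  if (!(length(q) == length(i) && length(i) == length(sigma))) {
    abort("q, i and sigma must have equal length.")
  }
  if (length(q) < 8) abort("a SAXS profile needs at least 8 points.")
  if (any(q <= 0)) abort("q must be strictly positive.")
  if (any(diff(q) <= 0)) abort("q must be strictly increasing.")
  if (any(sigma <= 0)) abort("sigma must be strictly positive.")
  out <- tibble(q = q, i = i, sigma = sigma)
  attr(out, "label") <- label
  class(out) <- c("saxs_profile", class(out))
  out
}

#' Merge a concentration pair of SAXS curves
#'
#' Scales the high-concentration curve onto the low-concentration one by
#' weighted least squares over a shared q-window, then splices: the
#' low-concentration data (free of inter-particle repulsion at low angle) is
#' kept below the window midpoint, the scaled high-concentration data (better
#' high-angle statistics) above it. Scaled uncertainties propagate with the
#' scale factor.
#'
#' @param low_c,high_c `saxs_profile`s measured at low/high concentration.
#' @param overlap Length-2 q-range used for scaling; default the intersection
#'   of the two q-ranges.
#' @return Merged `saxs_profile`; the fitted scale is in attribute `"scale"`.
#' @export
merge_profiles <- function(low_c, high_c, overlap = NULL) {
  overlap <- overlap %||% c(max(min(low_c$q), min(high_c$q)),
                            min(max(low_c$q), max(high_c$q)))
  if (overlap[1] >= overlap[2]) abort("profiles have no overlapping q-range.")
  in_lo <- low_c$q >= overlap[1] & low_c$q <= overlap[2]
  if (sum(in_lo) < 10) abort("overlap window holds fewer than 10 points.")
  hi_on_lo <- approx(high_c$q, high_c$i, xout = low_c$q[in_lo])$y
  w <- 1 / low_c$sigma[in_lo]^2
  scale <- sum(w * low_c$i[in_lo] * hi_on_lo) / sum(w * hi_on_lo^2)
  mid <- mean(overlap)
  lo_part <- low_c[low_c$q <= mid, ]
  hi_part <- high_c[high_c$q > mid, ]
  out <- saxs_profile(c(lo_part$q, hi_part$q),
                      c(lo_part$i, scale * hi_part$i),
                      c(lo_part$sigma, scale * hi_part$sigma),
                      label = paste0(attr(low_c, "label"), "+merged"))
  attr(out, "scale") <- scale
  lf_log("merge_profiles: scale=%.4g over q=[%.3g, %.3g]",
         scale, overlap[1], overlap[2])
  out
}

#' Guinier analysis
#'
#' Weighted linear fit of log I versus q^2 over the largest low-q window
#' satisfying `q_max * Rg <= q_rg_max`, iterated to self-consistency.
#' Leading points whose standardised residual exceeds 2.5 (beam-stop or
#' aggregation curvature) are dropped with a logged count. A residual
#' runs statistic (observed minus expected sign runs, standardised) reports
#' systematic curvature in the accepted window.
#'
#' @param profile A `saxs_profile`.
#' @param q_rg_max Upper limit on q*Rg for the fitted window (default 1.3).
#' @param min_points Minimum window size (default 8).
#' @return Object of class `guinier_result`: list with `rg`, `rg_err`, `i0`,
#'   `i0_err` , `q_window`, `q_rg_window`, `n_points`, `n_dropped_leading`,
#'   `runs_z`.
#' @export
guinier_fit <- function(profile, q_rg_max = 1.3, min_points = 8) {
  ok <- is.finite(profile$i) & profile$i > 0
  q <- profile$q[ok]; i <- profile$i[ok]; s <- profile$sigma[ok]
  if (length(q) < min_points) abort("too few positive-intensity points.")
  first <- 1
  # window fit: plain Guinier line for small windows; with a quartic
  # curvature correction for larger ones (compact particles deviate from the
  # Gaussian law towards q*Rg ~ 1.3 and bias the uncorrected slope)
  est <- function(idx) {
    df <- data.frame(q2 = q[idx]^2, y = log(i[idx]), w = (i[idx] / s[idx])^2)
    quad <- length(idx) >= 15
    fit <- if (quad) lm(y ~ q2 + I(q2^2), data = df, weights = w)
    else lm(y ~ q2, data = df, weights = w)
    slope <- coef(fit)[[2]]
    list(fit = fit, slope = slope, inter = coef(fit)[[1]],
         rg = if (slope < 0) sqrt(-3 * slope) else NA_real_,
         se = sqrt(diag(vcov(fit)))[1:2], quad = quad)
  }
  n_hi <- max(min_points, floor(length(q) / 3))
  for (iter in 1:60) {
    idx <- first:min(first + n_hi - 1, length(q))
    e <- est(idx)
    if (!is.finite(e$rg)) {
      abort("Guinier fit failed: non-negative slope (low-q upturn or aggregation).")
    }
    n_new <- max(min_points, sum(q >= q[first] & q <= q_rg_max / e$rg))
    n_new <- min(n_new, length(q) - first + 1)
    if (n_new == n_hi) break
    n_hi <- n_new
  }
  # enforce the q*Rg ceiling against the final estimate
  repeat {
    idx <- first:min(first + n_hi - 1, length(q))
    e <- est(idx)
    if (n_hi <= min_points || !is.finite(e$rg) ||
        max(q[idx]) * e$rg <= q_rg_max) break
    n_hi <- n_hi - 1
  }
  # drop leading outlier points (beam-stop artifacts at lowest q), judged on
  # sigma-weighted residuals so exact data never triggers rejection
  n_dropped <- 0
  repeat {
    idx <- first:min(first + n_hi - 1, length(q))
    if (length(idx) <= min_points) break
    wres <- stats::residuals(est(idx)$fit) * (i[idx] / s[idx])
    if (is.finite(wres[1]) && abs(wres[1]) > 2.5) {
      first <- first + 1; n_dropped <- n_dropped + 1
    } else break
  }
  # ceiling may need re-trimming after the window moved up
  repeat {
    idx <- first:min(first + n_hi - 1, length(q))
    e <- est(idx)
    if (n_hi <= min_points || !is.finite(e$rg) ||
        max(q[idx]) * e$rg <= q_rg_max) break
    n_hi <- n_hi - 1
  }
  idx <- first:min(first + n_hi - 1, length(q))
  e <- est(idx)
  if (!is.finite(e$rg)) abort("Guinier fit failed after leading-point rejection.")
  res_sign <- sign(stats::residuals(e$fit))
  runs <- sum(diff(res_sign) != 0) + 1
  n <- length(idx)
  exp_runs <- n / 2 + 1   # approximation for balanced signs
  runs_z <- (runs - exp_runs) / sqrt(max(n - 1, 1) / 4)
  out <- list(
    rg = e$rg, rg_err = 3 * e$se[[2]] / (2 * e$rg),
    i0 = exp(e$inter), i0_err = exp(e$inter) * e$se[[1]],
    q_window = range(q[idx]), q_rg_window = range(q[idx]) * e$rg,
    n_points = n, n_dropped_leading = n_dropped, runs_z = runs_z,
    curvature_corrected = e$quad
  )
  if (n_dropped > 0) lf_log("guinier_fit: dropped %d leading point(s)", n_dropped)
  class(out) <- "guinier_result"
  out
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("<guinier_result> Rg = %.2f +/- %.2f A, I0 = %.4g (qRg %.2f-%.2f, %d pts)\n",
              x$rg, x$rg_err, x$i0, x$q_rg_window[1], x$q_rg_window[2],
              x$n_points))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.guinier_result <- function(x, ...) {
  tibble(rg = x$rg, rg_err = x$rg_err, i0 = x$i0, i0_err = x$i0_err,
         q_rg_min = x$q_rg_window[1], q_rg_max = x$q_rg_window[2],
         n_points = x$n_points, n_dropped_leading = x$n_dropped_leading,
         runs_z = x$runs_z)
}

#' Dimensionless Kratky transform
#'
#' Rescales a profile to \eqn{(qR_g, (qR_g)^2 I(q)/I(0))}. In this
#' representation every compact globular particle peaks at
#' \eqn{qR_g = \sqrt{3} \approx 1.73} with height \eqn{3/e \approx 1.104},
#' while disordered chains rise monotonically towards a plateau, so the curve
#' shape is directly comparable across particle sizes.
#'
#' The interior maximum (if any) is located on the grid and refined by a
#' local parabolic fit through the three bracketing points.
#'
#' @param profile A `saxs_profile`.
#' @param guinier A `guinier_result` supplying Rg and I(0).
#' @return Tibble of class `kratky_curve` with columns `q_rg`, `kratky`;
#'   attributes `peak_q_rg`, `peak_height` (NA when no interior maximum,
#'   flagged by attribute `has_peak`).
#' @export
dimensionless_kratky <- function(profile, guinier) {
  stopifnot(inherits(guinier, "guinier_result"))
  x <- profile$q * guinier$rg
  y <- x^2 * profile$i / guinier$i0
  out <- tibble(q_rg = x, kratky = y)
  k <- which.max(y)
  has_peak <- k > 1 && k < length(y)
  peak_x <- NA_real_; peak_y <- NA_real_
  if (has_peak) {
    # parabola through the three points around the grid maximum
    xi <- x[(k - 1):(k + 1)]; yi <- y[(k - 1):(k + 1)]
    pf <- lm(yi ~ xi + I(xi^2))
    a <- coef(pf)[[3]]; b <- coef(pf)[[2]]
    if (is.finite(a) && a < 0) {
      peak_x <- -b / (2 * a)
      peak_y <- unname(predict(pf, newdata = data.frame(xi = peak_x)))
    } else {
      peak_x <- x[k]; peak_y <- y[k]
    }
  }
  attr(out, "has_peak") <- has_peak
  attr(out, "peak_q_rg") <- peak_x
  attr(out, "peak_height") <- peak_y
  class(out) <- c("kratky_curve", class(out))
  out
}

# Fourier kernel: I(q) = 4*pi * int P(r) sinc(q r) dr on the r grid,
# trapezoid weights folded into the columns
pofr_kernel <- function(q, r) {
  dr <- diff(r)
  w <- c(dr[1] / 2, (dr[-1] + dr[-length(dr)]) / 2, dr[length(dr)] / 2)
  x <- outer(q, r)
  sinc <- ifelse(x < 1e-12, 1, sin(x) / x)
  4 * pi * sweep(sinc, 2, w, "*")
}

# second-difference roughness penalty on the full r grid
second_diff_matrix <- function(n) {
  d <- matrix(0, n - 2, n)
  for (k in seq_len(n - 2)) d[k, k:(k + 2)] <- c(1, -2, 1)
  d
}

# solve the regularised inversion; interior coefficients only, endpoints
# pinned to zero. Returns full P on the grid.
pofr_solve <- function(a, b, dmat, lambda, nonneg) {
  astk <- rbind(a, sqrt(lambda) * dmat)
  bstk <- c(b, rep(0, nrow(dmat)))
  if (nonneg) {
    tryCatch(pracma::lsqnonneg(astk, bstk)$x, error = function(e) {
      # active-set stall: fall back to the clipped unconstrained solution
      pmax(pofr_solve(a, b, dmat, lambda, nonneg = FALSE), 0)
    })
  } else {
    # SVD pseudo-inverse: robust to the near-singularity of the Fourier
    # kernel at small regularisation weights
    sv <- svd(astk)
    keep <- sv$d > max(sv$d) * 1e-10
    as.numeric(sv$v[, keep, drop = FALSE] %*%
                 ((crossprod(sv$u[, keep, drop = FALSE], bstk)) / sv$d[keep]))
  }
}

#' Indirect Fourier transform to the pair-distance distribution
#'
#' Recovers P(r) on a fixed grid over `[0, Dmax]` by Tikhonov-regularised,
#' non-negative least squares:
#' \deqn{\min_P \; \|(I - T P)/\sigma\|^2 + \lambda \|\Delta^2 P\|^2,
#'   \quad P(0) = P(D_{max}) = 0,\; P \ge 0}
#' where T is the trapezoid-integrated kernel \eqn{4\pi \sin(qr)/(qr)}.
#' The regularisation weight is chosen by an L-curve corner search unless
#' given. Real-space invariants follow from the moments of P:
#' \eqn{I(0) = 4\pi\int P\,dr} and \eqn{R_g^2 = \int r^2 P\,dr / (2\int P\,dr)}.
#'
#' @param profile A `saxs_profile`.
#' @param dmax Maximum particle dimension (Angstrom), > 0.
#' @param lambda Regularisation weight (relative units); `NULL` (default)
#'   selects it on an L-curve.
#' @param n_r Number of r-grid points (default 101).
#' @param nonneg Enforce P >= 0 (default TRUE).
#' @return Tibble of class `pofr` with columns `r`, `p`; attributes `dmax`,
#'   `rg_real`, `i0_real`, `lambda`, `chi` (back-fit quality).
#' @export
pofr_invert <- function(profile, dmax, lambda = NULL, n_r = 101,
                        nonneg = TRUE) {
  if (dmax <= 0) abort("dmax must be positive.")
  if (min(profile$q) > pi / dmax) {
    warn(sprintf("q_min = %.4g exceeds pi/Dmax = %.4g; I(0) and Rg are extrapolated.",
                 min(profile$q), pi / dmax))
  }
  r <- seq(0, dmax, length.out = n_r)
  kern <- pofr_kernel(profile$q, r)
  interior <- 2:(n_r - 1)
  a <- kern[, interior] / profile$sigma
  b <- profile$i / profile$sigma
  dfull <- second_diff_matrix(n_r)
  dmat <- dfull[, interior]
  # scale so lambda ~ 1 balances misfit and roughness curvature
  lam_scale <- sum(a^2) / sum(dmat^2)
  if (is.null(lambda)) {
    # discrepancy-style choice: the smoothest solution whose misfit stays
    # within 5% of the best achievable over the grid
    grid <- 10^seq(-8, 1, length.out = 19)
    chi_at <- vapply(grid, function(lam) {
      x <- pofr_solve(a, b, dmat, lam * lam_scale, nonneg = FALSE)
      sqrt(mean((a %*% x - b)^2))
    }, numeric(1))
    lambda <- max(grid[chi_at <= 1.05 * min(chi_at)])
  }
  x <- pofr_solve(a, b, dmat, lambda * lam_scale, nonneg = nonneg)
  if (any(!is.finite(x))) {
    abort("P(r) system is ill-conditioned at this lambda; try lambda in [1e-4, 1].")
  }
  p <- numeric(n_r); p[interior] <- x
  dr <- r[2] - r[1]
  m0 <- sum(p) * dr
  if (m0 <= 0) abort("P(r) inversion produced a non-positive total; check inputs.")
  rg_real <- sqrt(sum(r^2 * p) * dr / (2 * m0))
  i0_real <- 4 * pi * m0
  chi <- sqrt(mean((a %*% x - b)^2))
  out <- tibble(r = r, p = p)
  attr(out, "dmax") <- dmax
  attr(out, "rg_real") <- rg_real
  attr(out, "i0_real") <- i0_real
  attr(out, "lambda") <- lambda
  attr(out, "chi") <- chi
  class(out) <- c("pofr", class(out))
  out
}

#' @exportS3Method generics::glance
glance.pofr <- function(x, ...) {
  tibble(dmax = attr(x, "dmax"), rg_real = attr(x, "rg_real"),
         i0_real = attr(x, "i0_real"), lambda = attr(x, "lambda"),
         chi = attr(x, "chi"))
}

#' Scan candidate Dmax values
#'
#' Fits P(r) at each candidate maximum dimension and selects the smallest
#' Dmax whose back-fit chi lies within 5 percent of the large-Dmax plateau
#' and whose unconstrained solution shows no forced negative lobe (a symptom
#' of a too-short distance range). When chi is still falling at the widest
#' candidate, that candidate is returned with a warning.
#'
#' @param profile A `saxs_profile`.
#' @param dmax_range Numeric vector of at least 5 candidate Dmax values (A).
#' @param lambda,n_r Passed to [pofr_invert()].
#' @return List with `dmax` (selected), `scan` (tibble: `dmax`, `chi`,
#'   `neg_frac`, `accepted`), and `plateau_found`.
#' @export
dmax_scan <- function(profile, dmax_range, lambda = NULL, n_r = 101) {
  dmax_range <- sort(unique(dmax_range))
  if (length(dmax_range) < 5) abort("supply at least 5 candidate Dmax values.")
  scan <- purrr::map_dfr(dmax_range, function(dm) {
    tryCatch({
      con <- suppressWarnings(
        pofr_invert(profile, dm, lambda = lambda, n_r = n_r, nonneg = TRUE))
      unc <- suppressWarnings(
        pofr_invert(profile, dm, lambda = lambda, n_r = n_r, nonneg = FALSE))
      neg <- -min(min(unc$p), 0) / max(abs(unc$p))
      tibble(dmax = dm, chi = attr(con, "chi"), neg_frac = neg)
    }, error = function(e) tibble(dmax = dm, chi = Inf, neg_frac = 1))
  })
  plateau <- min(scan$chi)
  scan$accepted <- scan$chi <= 1.05 * plateau & scan$neg_frac <= 0.05
  if (which.min(scan$chi) == nrow(scan)) {
    warn("dmax_scan: chi still improving at the widest candidate; widen the range.")
    return(list(dmax = max(dmax_range), scan = scan, plateau_found = FALSE))
  }
  list(dmax = min(scan$dmax[scan$accepted]), scan = scan,
       plateau_found = TRUE)
}
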