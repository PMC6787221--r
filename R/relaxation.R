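#' Physical constants for backbone amide 15N relaxation
#'
#' Bundles the dipolar and CSA interaction constants entering the 15N
#' relaxation expressions at a stated magnetic field. The squared dipolar
#' constant is \eqn{d^2 = [\mu_0 \hbar \gamma_H \gamma_N / (4\pi r_{NH}^3)]^2}
#' and the squared CSA constant \eqn{c^2 = (\omega_N \Delta\sigma_N)^2 / 3},
#' so `c2` scales with the square of the field.
#'
#' @param field_mhz Spectrometer 1H resonance frequency (MHz); default 600.
#' @param r_nh N-H bond length (Angstrom); default 1.02.
#' @param csa_n 15N chemical-shift anisotropy (ppm); default -160.
#' @return List with gyromagnetic ratios (`gamma_h`, `gamma_n`; rad/s/T),
#'   angular frequencies `omega_h`, `omega_n` (rad/s; `omega_n` < 0 because
#'   gamma_N < 0), `d2` and `c2` (rad^2/s^2), and the inputs.
#' @export
nh_constants <- function(field_mhz = 600, r_nh = 1.02, csa_n = -160) {
  stopifnot(field_mhz > 0, r_nh > 0)
  gamma_h <- 2.6752218744e8           # rad s^-1 T^-1
  gamma_n <- -2.7126180e7
  hbar <- 1.054571817e-34
  mu0_4pi <- 1e-7
  omega_h <- 2 * pi * field_mhz * 1e6
  b0 <- omega_h / gamma_h
  omega_n <- gamma_n * b0
  d <- mu0_4pi * hbar * gamma_h * gamma_n / (r_nh * 1e-10)^3
  c2 <- (omega_n * csa_n * 1e-6)^2 / 3
  list(field_mhz = field_mhz, r_nh = r_nh, csa_n = csa_n,
       gamma_h = gamma_h, gamma_n = gamma_n,
       omega_h = omega_h, omega_n = omega_n,
       d2 = d^2, c2 = c2)
}

#' Lipari-Szabo spectral density
#'
#' Two-timescale model-free spectral density
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right],\quad
#'   1/\tau' = 1/\tau_c + 1/\tau_e}
#' reducing to the rigid Lorentzian for `s2 = 1`.
#'
#' @param omega Angular frequency (rad/s); vectorised. Sign is ignored.
#' @param tau_c Overall rotational correlation time (s).
#' @param s2 Generalised order parameter in `[0, 1]`.
#' @param tau_e Effective internal correlation time (s).
#' @return J(omega) in s/rad.
#' @export
j_lipari_szabo <- function(omega, tau_c, s2 = 1, tau_e = 0) {
  stopifnot(tau_c > 0, s2 >= 0, s2 <= 1, tau_e >= 0)
  tp <- if (tau_e > 0) 1 / (1 / tau_c + 1 / tau_e) else 0
  0.4 * (s2 * tau_c / (1 + (omega * tau_c)^2) +
           (1 - s2) * tp / (1 + (omega * tp)^2))
}

#' Forward 15N relaxation rates from a spectral density
#'
#' Computes R1, R2 and the steady-state heteronuclear NOE from the full
#' dipolar + CSA expressions, evaluating J at 0, omega_N, omega_H and the
#' combination frequencies (no exchange contribution, Rex = 0).
#'
#' @param tau_c Correlation time (s); scalar.
#' @param s2,tau_e Model-free internal motion parameters (see
#'   [j_lipari_szabo()]).
#' @param constants Output of [nh_constants()].
#' @return One-row tibble with `r1`, `r2` (1/s), `noe`, and the
#'   cross-relaxation rate `sigma_nh` (1/s).
#' @export
nmr_rates <- function(tau_c, s2 = 1, tau_e = 0, constants = nh_constants()) {
  wh <- abs(constants$omega_h); wn <- abs(constants$omega_n)
  J <- function(w) j_lipari_szabo(w, tau_c, s2, tau_e)
  d2 <- constants$d2; c2 <- constants$c2
  r1 <- d2 / 4 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + c2 * J(wn)
  r2 <- d2 / 8 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                    6 * J(wh + wn)) +
    c2 / 6 * (4 * J(0) + 3 * J(wn))
  sigma <- d2 / 4 * (6 * J(wh + wn) - J(wh - wn))
  noe <- 1 + (constants$gamma_h / constants$gamma_n) * sigma / r1
  tibble(r1 = r1, r2 = r2, noe = noe, sigma_nh = sigma)
}

#' Mono-exponential decay rates from intensity ladders
#'
#' Fits \eqn{I(t) = I_0 e^{-Rt}} per residue by Levenberg-Marquardt least
#' squares, initialised from a log-linear regression. Non-decaying series
#' (non-positive fitted rate or increasing trend) are flagged
#' `not_determined` rather than reported as rates.
#'
#' @param decays Tibble with columns `residue`, `delay` (s), `intensity`;
#'   at least 5 distinct delays per residue.
#' @return Tibble with `residue`, `rate` (1/s), `rate_err` (covariance-based),
#'   `i0`, `status` (`"ok"` or `"not_determined"`).
#' @export
fit_exponential <- function(decays) {
  stopifnot(all(c("residue", "delay", "intensity") %in% names(decays)))
  if (any(decays$delay < 0)) abort("relaxation delays must be >= 0.")
  if (any(!is.finite(decays$intensity))) abort("intensities must be finite.")
  decays |>
    dplyr::group_by(.data$residue) |>
    dplyr::group_map(function(df, key) {
      out <- tibble(residue = key$residue, rate = NA_real_,
                    rate_err = NA_real_, i0 = NA_real_,
                    status = "not_determined")
      if (length(unique(df$delay)) < 5) {
        abort(sprintf("residue %s: fewer than 5 distinct relaxation delays.",
                      key$residue))
      }
      pos <- df$intensity > 0
      if (sum(pos) < 3) return(out)
      lin <- lm(log(intensity) ~ delay, data = df[pos, ])
      r0 <- -coef(lin)[[2]]
      if (!is.finite(r0) || r0 <= 0) return(out)
      fit <- tryCatch(
        minpack.lm::nlsLM(intensity ~ i0 * exp(-r * delay), data = df,
                          start = list(i0 = exp(coef(lin)[[1]]), r = r0),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL
      )
      if (is.null(fit) || coef(fit)[["r"]] <= 0) return(out)
      se <- sqrt(diag(vcov(fit)))
      out$rate <- coef(fit)[["r"]]; out$rate_err <- se[["r"]]
      out$i0 <- coef(fit)[["i0"]]; out$status <- "ok"
      out
    }) |>
    dplyr::bind_rows()
}

#' Steady-state heteronuclear NOE from saturated/reference intensities
#'
#' NOE = I_sat / I_ref, with the error propagated in quadrature from the two
#' intensity uncertainties.
#'
#' @param pairs Tibble with columns `residue`, `i_sat`, `i_ref` and optional
#'   `err_sat`, `err_ref`.
#' @return Tibble with `residue`, `noe`, `noe_err`.
#' @export
compute_noe <- function(pairs) {
  stopifnot(all(c("residue", "i_sat", "i_ref") %in% names(pairs)))
  if (any(pairs$i_ref == 0)) abort("reference intensity of zero.")
  es <- pairs$err_sat %||% rep(0, nrow(pairs))
  er <- pairs$err_ref %||% rep(0, nrow(pairs))
  noe <- pairs$i_sat / pairs$i_ref
  tibble(residue = pairs$residue, noe = noe,
         noe_err = abs(noe) * sqrt((es / pairs$i_sat)^2 +
                                     (er / pairs$i_ref)^2))
}

# 3x3 linear map (J0, JwN, JwH) -> (R1, R2, sigma_NH) for Rex = 0
sdm_matrix <- function(constants) {
  d2 <- constants$d2; c2 <- constants$c2
  rbind(
    c(0,                 3 * d2 / 4 + c2,      7 * d2 / 4),
    c(d2 / 2 + 2 * c2 / 3, 3 * d2 / 8 + c2 / 2, 13 * d2 / 8),
    c(0,                 0,                    5 * d2 / 4)
  )
}

#' Reduced spectral density mapping
#'
#' Inverts the linear combination that expresses R1, R2 and the
#' cross-relaxation rate \eqn{\sigma_{NH} = R_1(\mathrm{NOE}-1)\gamma_N/\gamma_H}
#' in terms of J(0), J(omega_N) and J(0.87 omega_H):
#' \deqn{R_1 = \tfrac{d^2}{4}[3J(\omega_N) + 7J(0.87\omega_H)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \tfrac{d^2}{8}[4J(0) + 3J(\omega_N) + 13J(0.87\omega_H)]
#'   + \tfrac{c^2}{6}[4J(0) + 3J(\omega_N)]}
#' \deqn{\sigma_{NH} = \tfrac{5 d^2}{4} J(0.87\omega_H)}
#' The 3x3 system is solved exactly per residue; no assumption is made about
#' the rotational diffusion. A negative J(0) (exchange contribution or noise)
#' is flagged, not suppressed.
#'
#' @param records Tibble with columns `residue`, `r1`, `r2`, `noe` (and
#'   optionally `domain`).
#' @param constants Output of [nh_constants()].
#' @return Tibble with `residue`, `j0`, `jwn`, `jwh` (s/rad), `flag`
#'   (`"ok"` or `"negative_j0"`).
#' @export
reduced_sdm <- function(records, constants = nh_constants()) {
  stopifnot(all(c("residue", "r1", "r2", "noe") %in% names(records)))
  a <- sdm_matrix(constants)
  sigma <- records$r1 * (records$noe - 1) *
    constants$gamma_n / constants$gamma_h
  sol <- t(solve(a, rbind(records$r1, records$r2, sigma)))
  out <- tibble(residue = records$residue,
                j0 = sol[, 1], jwn = sol[, 2], jwh = sol[, 3],
                flag = ifelse(sol[, 1] < 0, "negative_j0", "ok"))
  if ("domain" %in% names(records)) out$domain <- records$domain
  n_neg <- sum(out$flag != "ok")
  if (n_neg) lf_log("reduced_sdm: %d residue(s) with negative J(0)", n_neg)
  out
}

# forward rates at given (j0, jwn, jwh) through the same linear map;
# used by tests and by the exact round-trip property
sdm_forward <- function(j, constants = nh_constants()) {
  a <- sdm_matrix(constants)
  r <- a %*% as.numeric(j)
  noe <- 1 + (constants$gamma_h / constants$gamma_n) * r[3] / r[1]
  tibble(r1 = r[1], r2 = r[2], noe = noe)
}

#' Per-domain rotational correlation time from R2/R1
#'
#' Estimates an isotropic correlation time for each (rigid) domain. Flexible
#' residues are removed first (NOE below `noe_min`), then the 10 percent of
#' residues with the most extreme R2/R1 ratios (distance from the median) are
#' trimmed; each surviving residue's tau_c is obtained by bisection of the
#' rigid-Lorentzian R2/R1 ratio, and the domain estimate is the mean with the
#' across-residue SD as error.
#'
#' @param records Relaxation records: tibble with `residue`, `r1`, `r2`,
#'   `noe`, `domain`.
#' @param domains Which domain labels to estimate (default: all present).
#' @param constants Output of [nh_constants()].
#' @param noe_min Flexible-residue NOE cutoff (default 0.65).
#' @param trim Fraction of extreme R2/R1 ratios removed (default 0.10).
#' @param tau_range Bisection bracket in ns (default `c(0.5, 50)`).
#' @return Tibble with `domain`, `tau_c` (ns), `tau_c_sd`, `n_used`.
#' @export
estimate_tau_c <- function(records, domains = NULL,
                           constants = nh_constants(),
                           noe_min = 0.65, trim = 0.10,
                           tau_range = c(0.5, 50)) {
  stopifnot(all(c("residue", "r1", "r2", "noe", "domain") %in% names(records)))
  domains <- domains %||% unique(records$domain)
  ratio_at <- function(tc_ns) {
    r <- nmr_rates(tc_ns * 1e-9, constants = constants)
    r$r2 / r$r1
  }
  invert_ratio <- function(rho) {
    lo <- tau_range[1]; hi <- tau_range[2]
    if (rho <= ratio_at(lo) || rho >= ratio_at(hi)) return(NA_real_)
    stats::uniroot(function(t) ratio_at(t) - rho, c(lo, hi),
                   tol = 1e-6)$root
  }
  purrr::map_dfr(domains, function(dom) {
    df <- records |>
      dplyr::filter(.data$domain == dom, is.finite(.data$noe),
                    .data$noe >= noe_min, .data$r1 > 0, .data$r2 > 0)
    if (nrow(df) > 0) {
      rho <- df$r2 / df$r1
      keep <- rank(abs(rho - median(rho)), ties.method = "first") <=
        ceiling((1 - trim) * nrow(df))
      df <- df[keep, ]
    }
    if (nrow(df) < 5) {
      abort(sprintf(
        "domain %s: fewer than 5 rigid residues after trimming.", dom))
    }
    tc <- vapply(df$r2 / df$r1, invert_ratio, numeric(1))
    tc <- tc[is.finite(tc)]
    if (length(tc) < 5) {
      abort(sprintf("domain %s: R2/R1 ratios outside the tau_c bracket.", dom))
    }
    tibble(domain = dom, tau_c = mean(tc), tau_c_sd = sd(tc),
           n_used = length(tc))
  })
}

#' Mass-vs-R2 molecular ruler
#'
#' Fits a least-squares line through (molecular mass, mean R2) calibrant
#' points and predicts the R2 expected for a query mass tumbling as an
#' isolated particle; the deviation of an observed R2 from this line reports
#' on coupled or restricted tumbling.
#'
#' @param calibrants Tibble with columns `mass` (kDa) and `r2` (1/s);
#'   at least 3 rows.
#' @param query_mass Mass(es) at which to predict (kDa).
#' @return Tibble with `mass`, `r2_pred`, `se`, `extrapolated` (outside the
#'   calibrant mass range; reported with a warning).
#' @export
molecular_ruler <- function(calibrants, query_mass) {
  stopifnot(all(c("mass", "r2") %in% names(calibrants)))
  if (nrow(calibrants) < 3) abort("at least 3 calibrants required.")
  fit <- lm(r2 ~ mass, data = calibrants)
  new <- tibble(mass = query_mass)
  pr <- predict(fit, newdata = new, se.fit = TRUE)
  outside <- query_mass < min(calibrants$mass) |
    query_mass > max(calibrants$mass)
  if (any(outside)) {
    warn("molecular_ruler: query mass outside calibrant range (extrapolation).")
  }
  tibble(mass = query_mass, r2_pred = as.numeric(pr$fit),
         se = as.numeric(pr$se.fit),
         sigma_resid = summary(fit)$sigma,
         extrapolated = outside)
}
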