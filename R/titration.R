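#' Combined amide chemical-shift perturbation
#'
#' Collapses paired 1H and 15N amide shift changes into the standard combined
#' CSP, down-weighting the 15N dimension by its larger chemical-shift
#' dispersion:
#' \deqn{\Delta\delta = \sqrt{\left[(\Delta\delta_H)^2 +
#'   (\Delta\delta_N/5)^2\right] / 2}}
#'
#' @param d_h Change in amide 1H shift (ppm), relative to the ligand-free
#'   reference point. Vectorised.
#' @param d_n Change in amide 15N shift (ppm). Same length as `d_h`.
#' @return Numeric vector of combined CSPs (ppm), non-negative.
#' @examples
#' compute_csp(0.1, 0.5)   # 0.1
#' compute_csp(0, 0.5)     # ~0.0707
#' @export
compute_csp <- function(d_h, d_n) {
  if (length(d_h) != length(d_n)) {
    abort("`d_h` and `d_n` must have the same length.")
  }
  bad <- !is.na(d_h) & !is.na(d_n) & (!is.finite(d_h) | !is.finite(d_n))
  if (any(bad)) abort("non-finite shift differences supplied to compute_csp().")
  sqrt((d_h^2 + (d_n / 5)^2) / 2)
}

#' Fast-exchange binding isotherms
#'
#' Observed combined CSP as a population-weighted average between the free
#' (\eqn{\Delta\delta = 0}) and bound (\eqn{\Delta\delta_{bound}}) states.
#' The `"1to1"` model is the single-site quadratic isotherm; the `"2to1"`
#' model describes one bivalent ligand (e.g. Lys63-linked diubiquitin)
#' engaging two independent sites on the protein, so the ligand supplies two
#' binding units:
#' \deqn{\Delta\delta = \Delta\delta_b \frac{L_0 + P_0 + K_d -
#'   \sqrt{(L_0 + P_0 + K_d)^2 - 4 L_0 P_0}}{2 P_0}} (1:1)
#' \deqn{\Delta\delta = \Delta\delta_b \frac{2L_0 + P_0 + K_d -
#'   \sqrt{(2L_0 + P_0 + K_d)^2 - 8 L_0 P_0}}{2 P_0}} (2:1)
#'
#' @param l0 Total ligand concentration (uM). Vectorised.
#' @param p0 Total protein concentration (uM), > 0.
#' @param kd Dissociation constant (uM), >= 0.
#' @param dd_bound CSP of the fully bound state (ppm).
#' @param model `"1to1"` or `"2to1"`.
#' @return Combined CSP (ppm) at each `l0`; monotone non-decreasing in `l0`
#'   and bounded above by `dd_bound`.
#' @export
binding_curve <- function(l0, p0, kd, dd_bound, model = c("1to1", "2to1")) {
  model <- match.arg(model)
  if (any(l0 < 0) || any(p0 <= 0) || kd < 0) {
    abort("concentrations must be non-negative and `p0` > 0; `kd` >= 0.")
  }
  l <- if (model == "2to1") 2 * l0 else l0
  s <- l + p0 + kd
  disc <- pmax(s^2 - 4 * l * p0, 0)
  dd_bound * (s - sqrt(disc)) / (2 * p0)
}

#' @rdname binding_curve
#' @export
binding_curve_1to1 <- function(l0, p0, kd, dd_bound) {
  binding_curve(l0, p0, kd, dd_bound, model = "1to1")
}

#' @rdname binding_curve
#' @export
binding_curve_2to1 <- function(l0, p0, kd, dd_bound) {
  binding_curve(l0, p0, kd, dd_bound, model = "2to1")
}

#' Titration series from a shift table
#'
#' Converts absolute per-point amide shifts into combined CSPs relative to the
#' ligand-free reference point (`l0 == 0`). Broadened observations (missing
#' shifts) propagate as `NA` CSPs.
#'
#' @param shifts A shift table: tibble with columns `residue`, `point`, `p0`,
#'   `l0`, `d_h`, `d_n` and optionally `domain` (as returned by
#'   [read_titration_table()] or [simulate_titration()]).
#' @return Tibble with columns `residue`, `domain`, `point`, `p0`, `l0`, `dd`
#'   (combined CSP, ppm).
#' @export
csp_series <- function(shifts) {
  stopifnot(all(c("residue", "point", "p0", "l0", "d_h", "d_n") %in% names(shifts)))
  if (!"domain" %in% names(shifts)) shifts$domain <- "all"
  ref <- shifts |>
    dplyr::filter(.data$l0 == 0) |>
    dplyr::select("residue", ref_h = "d_h", ref_n = "d_n")
  if (nrow(ref) == 0) abort("no ligand-free (l0 = 0) reference point in table.")
  shifts |>
    dplyr::inner_join(ref, by = "residue") |>
    dplyr::mutate(dd = compute_csp(.data$d_h - .data$ref_h,
                                   .data$d_n - .data$ref_n)) |>
    dplyr::select("residue", "domain", "point", "p0", "l0", "dd") |>
    dplyr::arrange(.data$residue, .data$point)
}

# one-residue LM fit of (kd, dd_bound); returns a row or NULL on failure.
# The LM polish starts from kd = median(l0); if that start diverges or hits
# a bound (the isotherm's kd and dd_bound are strongly correlated when the
# start is far off), a profiled coarse grid over log kd supplies a new start.
fit_one_residue <- function(df, model, kd_init, kd_max = 1e5) {
  dd_init <- 1.2 * max(df$dd)
  profiled_start <- function() {
    kd_grid <- 10^seq(-1, log10(kd_max), length.out = 60)
    rss <- vapply(kd_grid, function(k) {
      f <- binding_curve(df$l0, df$p0, k, 1, model = model)
      b <- sum(f * df$dd) / sum(f^2)
      sum((df$dd - b * f)^2)
    }, numeric(1))
    k <- kd_grid[which.min(rss)]
    f <- binding_curve(df$l0, df$p0, k, 1, model = model)
    list(kd = k, ddb = sum(f * df$dd) / sum(f^2))
  }
  attempt <- function(start) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        dd ~ binding_curve(l0, p0, kd, ddb, model = model),
        data = df, start = start,
        lower = c(1e-9, 1e-9), upper = c(kd_max, 1e3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (coef(fit)[["kd"]] < 1e-8 || coef(fit)[["kd"]] > 0.99 * kd_max)) {
      fit <- NULL   # converged onto a bound: treat as failed
    }
    fit
  }
  fit <- attempt(list(kd = kd_init, ddb = dd_init))
  if (is.null(fit)) fit <- attempt(profiled_start())
  if (is.null(fit)) return(NULL)
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  tibble(
    kd = est[["kd"]], kd_err = se[[1]],
    dd_bound = est[["ddb"]], dd_bound_err = se[[2]],
    rss = sum(stats::residuals(fit)^2)
  )
}

# shared-Kd fit within one domain: dd_bound profiled out analytically
fit_global_kd <- function(df, model, kd_max = 1e5) {
  rss_at <- function(kd) {
    f <- binding_curve(df$l0, df$p0, kd, 1, model = model)
    sum(unlist(lapply(split(seq_len(nrow(df)), df$residue), function(i) {
      fi <- f[i]; yi <- df$dd[i]
      b <- sum(fi * yi) / sum(fi^2)
      sum((yi - b * fi)^2)
    })))
  }
  opt <- optimize(function(lk) rss_at(10^lk), c(-3, log10(kd_max)), tol = 1e-8)
  kd <- 10^opt$minimum
  # curvature-based standard error from a numeric second derivative of RSS
  n <- nrow(df); p <- length(unique(df$residue)) + 1
  s2 <- opt$objective / max(n - p, 1)
  h <- max(kd * 1e-3, 1e-6)
  d2 <- (rss_at(kd + h) - 2 * rss_at(kd) + rss_at(kd - h)) / h^2
  kd_err <- if (is.finite(d2) && d2 > 0) sqrt(2 * s2 / d2) else NA_real_
  list(kd = kd, kd_err = kd_err, rss = opt$objective)
}

#' Fit dissociation constants from titration CSPs
#'
#' Fits the chosen fast-exchange isotherm to per-residue CSP trajectories by
#' damped (Levenberg-Marquardt) nonlinear least squares. In `"per-residue"`
#' mode each residue yields its own `(Kd, dd_bound)` and the domain-level Kd
#' is the mean across usable residues with the standard deviation as its
#' error estimate. In `"global"` mode one Kd is shared by all residues of a
#' domain with residue-specific bound-state CSPs (profiled out analytically).
#'
#' Residues are excluded from the domain aggregate when their endpoint CSP
#' stays below `floor` (uninformative trajectories), when fewer than
#' `min_points` unbroadened points remain, or when the optimiser fails;
#' exclusions are counted, never silent.
#'
#' @param series Titration series as returned by [csp_series()].
#' @param model Binding model, `"1to1"` or `"2to1"`.
#' @param mode `"per-residue"` (default; mean +/- SD aggregation) or
#'   `"global"` (shared Kd per domain).
#' @param floor Endpoint-CSP exclusion floor (ppm); default 0.02.
#' @param min_points Minimum usable titration points per residue (default 4).
#' @return An object of class `binding_fit`: see [tidy()] for per-residue
#'   estimates and [kd_table()] for the per-domain summary.
#' @export
fit_kd <- function(series, model = c("1to1", "2to1"),
                   mode = c("per-residue", "global"),
                   floor = 0.02, min_points = 4) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  stopifnot(all(c("residue", "domain", "l0", "p0", "dd") %in% names(series)))

  per_res <- series |>
    dplyr::group_by(.data$residue, .data$domain) |>
    dplyr::group_map(function(df, key) {
      df <- df[is.finite(df$dd), ]
      n_broad <- sum(!is.finite(series$dd[series$residue == key$residue]))
      row <- tibble(residue = key$residue, domain = key$domain,
                    n_points = nrow(df), n_broadened = n_broad,
                    endpoint_dd = if (nrow(df)) max(df$dd) else NA_real_,
                    kd = NA_real_, kd_err = NA_real_,
                    dd_bound = NA_real_, dd_bound_err = NA_real_,
                    rss = NA_real_, status = "ok")
      if (nrow(df) < min_points) {
        row$status <- "too_few_points"
        return(row)
      }
      if (row$endpoint_dd < floor) {
        row$status <- "below_floor"
        return(row)
      }
      kd_init <- median(df$l0[df$l0 > 0])
      est <- fit_one_residue(df, model, kd_init)
      if (is.null(est)) {
        row$status <- "no_convergence"
        return(row)
      }
      row[names(est)] <- est
      row
    }) |>
    dplyr::bind_rows()

  usable <- per_res |> dplyr::filter(.data$status == "ok")
  domains <- usable |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(n_residues = dplyr::n(),
                     kd_sd = sd(.data$kd), kd = mean(.data$kd),
                     dd_bound_mean = mean(.data$dd_bound), .groups = "drop") |>
    dplyr::select("domain", "n_residues", "kd", "kd_sd", "dd_bound_mean")
  if (any(domains$n_residues < 2)) {
    abort(sprintf("fewer than 2 usable residues in domain(s): %s",
                  paste(domains$domain[domains$n_residues < 2], collapse = ", ")))
  }

  if (mode == "global") {
    glob <- series |>
      dplyr::filter(is.finite(.data$dd),
                    .data$residue %in% usable$residue) |>
      dplyr::group_by(.data$domain) |>
      dplyr::group_map(function(df, key) {
        g <- fit_global_kd(df, model)
        tibble(domain = key$domain, kd = g$kd, kd_sd = g$kd_err, rss = g$rss)
      }) |>
      dplyr::bind_rows()
    domains <- domains |>
      dplyr::select(-"kd", -"kd_sd") |>
      dplyr::left_join(glob, by = "domain")
  }

  lf_log("fit_kd: model=%s mode=%s residues=%d usable=%d excluded=%d",
         model, mode, nrow(per_res), nrow(usable), nrow(per_res) - nrow(usable))
  structure(
    list(residues = per_res, domains = domains, model = model, mode = mode,
         floor = floor),
    class = "binding_fit"
  )
}

#' Per-domain dissociation-constant summary
#'
#' @param fit A `binding_fit` object from [fit_kd()].
#' @return Tibble with one row per domain: `domain`, `n_residues`, `kd` (uM),
#'   `kd_sd` (uM; SD across residues, or the covariance-based error of the
#'   shared Kd in global mode).
#' @export
kd_table <- function(fit) {
  stopifnot(inherits(fit, "binding_fit"))
  fit$domains
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s model, %s mode\n", x$model, x$mode))
  print(x$domains)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) x$residues

#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble(model = x$model, mode = x$mode,
         n_residues = nrow(x$residues),
         n_usable = sum(x$residues$status == "ok"),
         n_broadened = sum(x$residues$n_broadened > 0),
         floor = x$floor)
}

#' Residues with significant endpoint CSPs
#'
#' Flags residues whose endpoint (largest-`l0`) combined CSP meets or exceeds
#' a threshold; the mapping convention used for interaction footprints.
#'
#' @param series Titration series from [csp_series()].
#' @param threshold Significance threshold in ppm (default 0.4).
#' @return Tibble of significant residues (`residue`, `domain`,
#'   `endpoint_dd`), possibly empty.
#' @export
csp_significance <- function(series, threshold = 0.4) {
  series |>
    dplyr::filter(is.finite(.data$dd)) |>
    dplyr::group_by(.data$residue, .data$domain) |>
    dplyr::summarise(endpoint_dd = .data$dd[which.max(.data$l0)],
                     .groups = "drop") |>
    dplyr::filter(.data$endpoint_dd >= threshold) |>
    dplyr::arrange(.data$domain, .data$residue)
}
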