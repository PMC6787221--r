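#' Ground truth attached to a synthetic dataset
#'
#' Every generator records the parameters and seed that produced its output,
#' sufficient to regenerate the dataset bit-exactly.
#'
#' @param x A synthetic dataset produced by one of the `simulate_*()` or
#'   `make_*()` generators.
#' @return A named list of ground-truth parameters.
#' @export
synthetic_truth <- function(x) attr(x, "truth")

with_truth <- function(x, truth) {
  attr(x, "truth") <- truth
  x
}

# ideal alpha-helix Calpha trace: rise 1.5 A, radius 2.3 A, 100 deg/residue
helix_beads <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  k <- seq_len(n) - 1
  cbind(2.3 * cos(k * 100 * pi / 180),
        2.3 * sin(k * 100 * pi / 180),
        1.5 * k)
}

# persistent self-avoiding walk continuing from `start` along `dir`
saw_linker <- function(n, start, dir, existing, step = 3.8, avoid = 3.4,
                       max_restart = 60) {
  for (rs in seq_len(max_restart)) {
    pts <- matrix(NA_real_, n, 3)
    cur <- start; d <- dir / sqrt(sum(dir^2))
    ok <- TRUE
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in 1:40) {
        nd <- d + rnorm(3, 0, 0.8)
        nd <- nd / sqrt(sum(nd^2))
        cand <- cur + step * nd
        prev <- rbind(existing, pts[seq_len(max(k - 2, 0)), , drop = FALSE])
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= avoid) {
          pts[k, ] <- cand; cur <- cand; d <- nd; placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  abort("self-avoiding linker placement failed after bounded retries.")
}

# compact globule: greedy self-avoiding walk on a jittered FCC lattice,
# growing toward a centre so the cluster fills a sphere of radius
# 0.6 * N^(1/3) * 3.8 A (chain-connected, near-close-packed)
fcc_globule <- function(n, start, dir, existing, avoid = 3.4,
                        max_restart = 60) {
  a2 <- 3.8 * sqrt(2) / 2
  nn <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  nn <- nn[rowSums(abs(nn)) == 2, , drop = FALSE]   # 12 FCC neighbours
  rs_ball <- 0.6 * n^(1 / 3) * 3.8
  dirn <- dir / sqrt(sum(dir^2))
  centre_lat <- round(rs_ball * 0.8 * dirn / a2)
  if (sum(abs(centre_lat)) %% 2 == 1) centre_lat[1] <- centre_lat[1] + 1
  for (rs in seq_len(max_restart)) {
    visited <- new.env(hash = TRUE)
    lat <- matrix(NA_real_, n, 3)
    cur <- c(0, 0, 0)
    lat[1, ] <- cur
    visited[[paste(cur, collapse = ",")]] <- TRUE
    ok <- TRUE
    for (k in 2:n) {
      cand <- sweep(nn, 2, cur, "+")
      keys <- apply(cand, 1, paste, collapse = ",")
      free <- vapply(keys, function(kk) is.null(visited[[kk]]), logical(1))
      inball <- sqrt(rowSums(sweep(cand, 2, centre_lat)^2)) * a2 <=
        rs_ball * 1.25
      cand <- cand[free & inball, , drop = FALSE]
      if (nrow(cand) == 0) { ok <- FALSE; break }
      score <- sqrt(rowSums(sweep(cand, 2, centre_lat)^2)) +
        runif(nrow(cand), 0, 0.3)
      cur <- cand[which.min(score), ]
      lat[k, ] <- cur
      visited[[paste(cur, collapse = ",")]] <- TRUE
    }
    if (!ok) next
    xyz <- lat * a2
    xyz <- sweep(xyz, 2, start - xyz[1, ], "+") +
      matrix(rnorm(3 * n, 0, 0.05), n, 3)
    # keep clear of the already-placed helix/linker
    if (nrow(existing) > 0) {
      dmin <- min(pracma::distmat(existing, xyz))
      if (dmin < avoid) next
    }
    return(xyz)
  }
  abort("compact globule placement failed after bounded retries.")
}

#' Synthetic two-domain bead model
#'
#' Builds a helix + disordered linker + compact globule chain emulating a
#' small helical recognition motif tethered to a folded domain: an ideal
#' alpha-helix Calpha trace (rise 1.5 A, radius 2.3 A), a persistent
#' self-avoiding linker (step 3.8 A), and a chain-connected globular cluster
#' packed on a jittered FCC lattice trimmed to a sphere of radius
#' `0.6 * N^(1/3) * 3.8` A. Linker residues form the flexible set.
#'
#' @param helix_len Helix length in residues (0 allowed, emulating a
#'   motif-deletion construct).
#' @param linker_len Linker length in residues (> 0).
#' @param globule_len Globular-domain length in residues (> 0).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param labels Domain labels for helix/linker/globule segments.
#' @return A validated [bead_model()] of `helix_len + linker_len +
#'   globule_len` beads, with ground truth via [synthetic_truth()].
#' @export
make_two_domain_model <- function(helix_len = 15, linker_len = 20,
                                  globule_len = 60, seed = 1,
                                  labels = c("helix", "linker", "globule")) {
  stopifnot(helix_len >= 0, linker_len > 0, globule_len > 0)
  set.seed(as.integer(seed))
  for (attempt in 1:30) {
    built <- tryCatch({
      hx <- helix_beads(helix_len)
      start <- if (helix_len > 0) hx[helix_len, ] else c(0, 0, 0)
      dir <- c(0, 0, 1)
      lk <- saw_linker(linker_len, start, dir,
                       existing = hx[seq_len(max(helix_len - 1, 0)), ,
                                     drop = FALSE])
      gdir <- lk[linker_len, ] - lk[max(linker_len - 3, 1), ]
      if (sqrt(sum(gdir^2)) < 1e-6) gdir <- dir
      gstart <- lk[linker_len, ] + 3.8 * gdir / sqrt(sum(gdir^2))
      gl <- fcc_globule(globule_len, gstart, gdir,
                        existing = rbind(hx, lk[seq_len(linker_len - 1), ,
                                                drop = FALSE]))
      xyz <- rbind(hx, lk, gl)
      model <- bead_model(
        xyz,
        domain = rep(labels, c(helix_len, linker_len, globule_len)),
        flexible = rep(c(FALSE, TRUE, FALSE),
                       c(helix_len, linker_len, globule_len))
      )
      model
    }, error = function(e) NULL)
    if (!is.null(built)) {
      return(with_truth(built, list(helix_len = helix_len,
                                    linker_len = linker_len,
                                    globule_len = globule_len, seed = seed,
                                    attempt = attempt)))
    }
  }
  abort("two-domain model generation failed after bounded retries.")
}

#' Simulate a chemical-shift titration
#'
#' Renders per-residue amide shift tables following the chosen fast-exchange
#' isotherm. A combined ground-truth CSP at each point is split into 1H and
#' 15N components with the fixed convention `dd_n = 2 * dd_h` (inverted
#' consistently by [compute_csp()]); Gaussian noise of `noise` ppm is added
#' to 1H shifts and `5 * noise` ppm to 15N shifts.
#'
#' @param truth Tibble with columns `residue`, `dd_bound` (ppm) and optional
#'   `domain`.
#' @param kd Ground-truth dissociation constant (uM).
#' @param model `"1to1"` or `"2to1"`.
#' @param p0 Protein concentration (uM; constant across points).
#' @param l0 Ligand ladder (uM), starting at 0; default 12 points to
#'   5x excess.
#' @param noise 1H shift noise SD (ppm), default 0.005.
#' @param seed Integer seed.
#' @return A shift-table tibble (`residue`, `domain`, `point`, `p0`, `l0`,
#'   `d_h`, `d_n`) with ground truth via [synthetic_truth()].
#' @export
simulate_titration <- function(truth, kd, model = c("1to1", "2to1"),
                               p0 = 100, l0 = seq(0, 5 * p0, length.out = 12),
                               noise = 0.005, seed = 1) {
  model <- match.arg(model)
  stopifnot(all(c("residue", "dd_bound") %in% names(truth)))
  if (noise < 0) abort("noise must be non-negative.")
  if (l0[1] != 0) abort("the ligand ladder must start at l0 = 0.")
  if (!"domain" %in% names(truth)) truth$domain <- "all"
  set.seed(as.integer(seed))
  split_h <- sqrt(2 / (1 + (2 / 5)^2))   # dd_h per unit combined CSP
  base <- truth |>
    dplyr::mutate(base_h = runif(dplyr::n(), 7.5, 9.5),
                  base_n = runif(dplyr::n(), 105, 130))
  out <- tidyr::crossing(base, tibble(point = seq_along(l0) - 1L,
                                      l0 = l0, p0 = p0)) |>
    dplyr::mutate(
      dd = binding_curve(.data$l0, .data$p0, kd, .data$dd_bound, model),
      d_h = .data$base_h + .data$dd * split_h +
        rnorm(dplyr::n(), 0, noise),
      d_n = .data$base_n + .data$dd * 2 * split_h +
        rnorm(dplyr::n(), 0, 5 * noise)
    ) |>
    dplyr::select("residue", "domain", "point", "p0", "l0", "d_h", "d_n") |>
    dplyr::arrange(.data$residue, .data$point)
  with_truth(out, list(kd = kd, model = model, p0 = p0, l0 = l0,
                       noise = noise, seed = seed,
                       dd_bound = setNames(truth$dd_bound, truth$residue)))
}

#' Simulate relaxation intensity ladders
#'
#' Computes ground-truth R1, R2 and NOE per residue from the Lipari-Szabo
#' spectral density (per-domain correlation time, per-residue order
#' parameter) via the full dipolar + CSA expressions, then renders them as
#' noisy mono-exponential intensity decays on the standard delay ladders and
#' as saturated/reference NOE intensity pairs.
#'
#' @param truth Tibble with columns `residue`, `domain`, `tau_c` (ns), `s2`,
#'   and optionally `tau_e` (ps, default 50).
#' @param field_mhz 1H frequency (MHz), default 600.
#' @param noise Fractional intensity noise (default 0.02).
#' @param seed Integer seed.
#' @param delays_r1 R1 delay ladder (s), default 8 points over 0.04-2.4 s.
#' @param delays_r2 R2 delay ladder (s), default 8 points over 0.008-0.224 s.
#' @param constants Optional [nh_constants()] override.
#' @return List of class `relaxation_sim` with elements `r1`, `r2` (decay
#'   tibbles), `noe` (intensity pairs), `rates` (ground-truth rates), and
#'   attached truth.
#' @export
simulate_relaxation <- function(truth, field_mhz = 600, noise = 0.02,
                                seed = 1,
                                delays_r1 = seq(0.04, 2.4, length.out = 8),
                                delays_r2 = seq(0.008, 0.224, length.out = 8),
                                constants = NULL) {
  stopifnot(all(c("residue", "domain", "tau_c", "s2") %in% names(truth)))
  if (any(truth$tau_c < 1 | truth$tau_c > 30)) {
    abort("tau_c outside the physical 1-30 ns range.")
  }
  if (any(truth$s2 < 0 | truth$s2 > 1)) abort("s2 must lie in [0, 1].")
  if (!"tau_e" %in% names(truth)) truth$tau_e <- 50
  constants <- constants %||% nh_constants(field_mhz)
  set.seed(as.integer(seed))
  rates <- truth |>
    dplyr::rowwise() |>
    dplyr::mutate(nmr_rates(.data$tau_c * 1e-9, .data$s2,
                            .data$tau_e * 1e-12, constants)) |>
    dplyr::ungroup()
  decay_table <- function(rate_col, delays) {
    tidyr::crossing(dplyr::select(rates, "residue", rate = {{ rate_col }}),
                    tibble(delay = delays)) |>
      dplyr::mutate(
        intensity = 100 * exp(-.data$rate * .data$delay) *
          (1 + rnorm(dplyr::n(), 0, noise))
      ) |>
      dplyr::select("residue", "delay", "intensity")
  }
  noe_pairs <- rates |>
    dplyr::mutate(i_ref = 100 * (1 + rnorm(dplyr::n(), 0, noise)),
                  i_sat = 100 * .data$noe * (1 + rnorm(dplyr::n(), 0, noise)),
                  err_sat = 100 * noise, err_ref = 100 * noise) |>
    dplyr::select("residue", "i_sat", "i_ref", "err_sat", "err_ref")
  out <- list(r1 = decay_table("r1", delays_r1),
              r2 = decay_table("r2", delays_r2),
              noe = noe_pairs,
              rates = dplyr::select(rates, "residue", "domain", "r1", "r2",
                                    "noe"),
              field_mhz = field_mhz)
  class(out) <- "relaxation_sim"
  with_truth(out, list(truth = truth, field_mhz = field_mhz, noise = noise,
                       seed = seed, delays_r1 = delays_r1,
                       delays_r2 = delays_r2))
}

#' Relaxation records from simulated (or measured) intensity ladders
#'
#' Convenience wrapper: fits R1 and R2 decays with [fit_exponential()],
#' forms NOEs with [compute_noe()], and joins everything into one record
#' table ready for [reduced_sdm()] and [estimate_tau_c()].
#'
#' @param sim A `relaxation_sim` (or any list with `r1`, `r2`, `noe`,
#'   `field_mhz` and optionally `rates$domain`).
#' @param domains Optional tibble `residue`, `domain` for labelling.
#' @return Tibble with `residue`, `domain`, `r1`, `r1_err`, `r2`, `r2_err`,
#'   `noe`, `noe_err`, `field_mhz`, `status`.
#' @export
extract_relaxation <- function(sim, domains = NULL) {
  f1 <- fit_exponential(sim$r1) |>
    dplyr::rename(r1 = "rate", r1_err = "rate_err") |>
    dplyr::select("residue", "r1", "r1_err", s1 = "status")
  f2 <- fit_exponential(sim$r2) |>
    dplyr::rename(r2 = "rate", r2_err = "rate_err") |>
    dplyr::select("residue", "r2", "r2_err", s2 = "status")
  nn <- compute_noe(sim$noe)
  out <- f1 |>
    dplyr::inner_join(f2, by = "residue") |>
    dplyr::inner_join(nn, by = "residue") |>
    dplyr::mutate(field_mhz = sim$field_mhz,
                  status = ifelse(.data$s1 == "ok" & .data$s2 == "ok",
                                  "ok", "not_determined")) |>
    dplyr::select(-"s1", -"s2")
  labels <- domains %||%
    (if (!is.null(sim$rates) && "domain" %in% names(sim$rates))
      dplyr::select(sim$rates, "residue", "domain") else NULL)
  if (!is.null(labels)) out <- dplyr::left_join(out, labels, by = "residue")
  out
}

#' Simulate a SAXS curve from a weighted conformer mixture
#'
#' The ideal curve is the weight-combination of member Debye profiles;
#' uncertainties follow \eqn{\sigma(q) = a\sqrt{I(q)} + b} and Gaussian
#' noise of that width is applied.
#'
#' @param pool A `conformer_pool` with profiles (see [pool_profiles()]).
#' @param members Indices of the mixed conformers.
#' @param weights Mixture weights (same length, sum to 1).
#' @param a,b Noise model coefficients; default `a = 0.01 * sqrt(max(I))`,
#'   `b = 0`.
#' @param seed Integer seed.
#' @return A `saxs_profile` with ground truth via [synthetic_truth()].
#' @export
simulate_saxs <- function(pool, members, weights, a = NULL, b = 0, seed = 1) {
  if (is.null(pool$profiles)) abort("call pool_profiles() first.")
  if (length(members) == 0) abort("empty member set.")
  if (length(weights) != length(members)) {
    abort("weights must match members.")
  }
  if (abs(sum(weights) - 1) > 1e-8) abort("weights must sum to 1.")
  set.seed(as.integer(seed))
  ideal <- as.numeric(pool$profiles[, members, drop = FALSE] %*% weights)
  a <- a %||% (0.01 * sqrt(max(ideal)))
  sigma <- a * sqrt(ideal) + b
  if (any(sigma <= 0)) abort("noise model produced non-positive sigma.")
  out <- saxs_profile(pool$q, ideal + rnorm(length(ideal), 0, sigma), sigma,
                      label = "synthetic mixture")
  with_truth(out, list(members = members, weights = weights, a = a, b = b,
                       seed = seed, pool_seed = pool$seed))
}
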