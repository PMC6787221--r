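#' Coarse-grained Debye scattering profile
#'
#' Computes the orientationally averaged scattering of a bead model with a
#' uniform per-residue form factor (f = 1):
#' \deqn{I(q) = \sum_i \sum_j \frac{\sin(q r_{ij})}{q r_{ij}}}
#' including the diagonal (sinc(0) = 1), so \eqn{I(0^+) = n^2}. Profiles of
#' rigid-body transformed copies of a model are identical by construction.
#'
#' @param model A `bead_model` (see [make_two_domain_model()],
#'   [read_coordinates()]) or a plain n x 3 coordinate matrix (Angstrom).
#' @param q Momentum-transfer grid (1/Angstrom), > 0.
#' @return Numeric vector I(q) (arbitrary units), strictly positive for
#'   compact models at the default q-range.
#' @export
debye_profile <- function(model, q) {
  xyz <- bead_coords(model)
  if (nrow(xyz) < 2) abort("at least 2 beads required.")
  if (any(q <= 0)) abort("q must be strictly positive.")
  d <- stats::dist(xyz)
  if (any(d < 1e-6)) abort("coincident beads in model.")
  .debye_sum(as.numeric(d), q, nrow(xyz))
}

# brute-force reference used in tests: O(n^2 nq) double loop in R
debye_profile_brute <- function(xyz, q) {
  n <- nrow(xyz)
  out <- numeric(length(q))
  for (k in seq_along(q)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        rij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        x <- q[k] * rij
        acc <- acc + if (x < 1e-12) 1 else sin(x) / x
      }
    }
    out[k] <- acc
  }
  out
}

#' Chi agreement between an experimental and a model profile
#'
#' The model is interpolated onto the experimental q-grid, scaled by the
#' closed-form optimal factor
#' \eqn{c = \sum I_e I_m/\sigma^2 \,/\, \sum I_m^2/\sigma^2}, and scored as
#' \deqn{\chi = \sqrt{\frac{1}{M}\sum_k \left(\frac{I_e(q_k) -
#'   c\,I_m(q_k)}{\sigma_k}\right)^2}.}
#'
#' @param experiment A `saxs_profile`.
#' @param model_i Model intensity: numeric vector on `model_q`, or already on
#'   the experimental grid when `model_q` is `NULL`.
#' @param model_q Optional model q-grid for interpolation.
#' @return List with `chi` and `scale`.
#' @export
chi_score <- function(experiment, model_i, model_q = NULL) {
  if (!is.null(model_q)) {
    if (min(model_q) > min(experiment$q) || max(model_q) < max(experiment$q)) {
      abort("experimental q-range extends beyond the model grid.")
    }
    model_i <- approx(model_q, model_i, xout = experiment$q)$y
  }
  if (length(model_i) != nrow(experiment)) {
    abort("model profile length does not match the experimental grid.")
  }
  w <- 1 / experiment$sigma^2
  scale <- sum(w * experiment$i * model_i) / sum(w * model_i^2)
  chi <- sqrt(mean(((experiment$i - scale * model_i) / experiment$sigma)^2))
  list(chi = chi, scale = scale)
}

# rigid segment ids: maximal runs of non-flexible residues get 1, 2, ...;
# flexible residues get 0 (always clash-checked)
rigid_segments <- function(flexible) {
  seg <- integer(length(flexible))
  id <- 0L; in_seg <- FALSE
  for (k in seq_along(flexible)) {
    if (flexible[k]) { in_seg <- FALSE; seg[k] <- 0L }
    else {
      if (!in_seg) { id <- id + 1L; in_seg <- TRUE }
      seg[k] <- id
    }
  }
  seg
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' Sample linker conformers by pivot moves
#'
#' Generates `n` conformations of a bead model by applying random pivot
#' rotations at each flexible bead (rotating everything downstream about a
#' random axis through the pivot), rejecting any conformation that brings
#' beads of different rigid segments, or any flexible bead, closer than
#' `clash` Angstrom while at least `minsep` apart in sequence. Rigid domains
#' move as solid bodies. The sampler is deterministic under a fixed seed.
#'
#' @param model A `bead_model` with a non-empty flexible set.
#' @param n Number of conformers.
#' @param seed Integer seed.
#' @param clash Clash cutoff between mobile bead pairs (default 4.0 A).
#' @param minsep Minimum sequence separation for clash checks (default 3).
#' @param max_angle Pivot angle scale in radians (draws from
#'   `Normal(0, max_angle)`); default 0.7.
#' @return Object of class `conformer_pool`: list with `coords` (list of
#'   n x 3 matrices), `rg` (per-conformer radius of gyration), `model`,
#'   `seed`, `acceptance` (accepted / attempted), `profiles = NULL` until
#'   [pool_profiles()] is called.
#' @export
generate_conformers <- function(model, n, seed = 1, clash = 4.0, minsep = 3,
                                max_angle = 0.7) {
  xyz0 <- bead_coords(model)
  flex <- bead_flexible(model)
  seg <- rigid_segments(flex)
  pivots <- which(flex)
  set.seed(as.integer(seed))
  coords <- vector("list", n)
  rg <- numeric(n)
  attempts <- 0L
  if (length(pivots) == 0) {
    coords <- replicate(n, xyz0, simplify = FALSE)
    rg[] <- radius_of_gyration(xyz0)
    attempts <- n
  } else {
    for (m in seq_len(n)) {
      repeat {
        attempts <- attempts + 1L
        xyz <- xyz0
        for (p in sample(pivots)) {
          if (p >= nrow(xyz)) next
          rot <- rotation_matrix(rnorm(3), rnorm(1, 0, max_angle))
          idx <- (p + 1):nrow(xyz)
          xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, xyz[p, ]) %*%
                                t(rot), 2, xyz[p, ], "+")
        }
        if (.min_cross_dist(xyz, seg, as.integer(minsep)) >= clash) break
        if (attempts > 100 * m && attempts / m > 100) {
          abort("conformer acceptance below 1%; loosen the topology or clash cutoff.")
        }
      }
      coords[[m]] <- xyz
      rg[m] <- radius_of_gyration(xyz)
    }
  }
  lf_log("generate_conformers: n=%d acceptance=%.1f%% seed=%d",
         n, 100 * n / attempts, as.integer(seed))
  structure(list(coords = coords, rg = rg, model = model,
                 seed = as.integer(seed), acceptance = n / attempts,
                 profiles = NULL, q = NULL),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("<conformer_pool> %d conformers, %d beads, Rg %.1f-%.1f A, acceptance %.0f%%\n",
              length(x$coords), nrow(x$coords[[1]]), min(x$rg), max(x$rg),
              100 * x$acceptance))
  invisible(x)
}

#' Compute member profiles for a conformer pool
#'
#' @param pool A `conformer_pool`.
#' @param q Common q-grid; default 171 points over 0.01-0.35 1/Angstrom.
#' @return The pool with `profiles` (matrix, length(q) x n) and `q` filled.
#' @export
pool_profiles <- function(pool, q = default_qgrid()) {
  pool$profiles <- vapply(pool$coords, debye_profile, numeric(length(q)),
                          q = q)
  pool$q <- q
  pool
}

#' @rdname pool_profiles
#' @export
default_qgrid <- function() seq(0.01, 0.35, length.out = 171)

# NNLS weight fit of one candidate subset; returns NULL for all-zero weights
fit_subset <- function(members, profiles, experiment) {
  a <- profiles[, members, drop = FALSE] / experiment$sigma
  w <- pracma::lsqnonneg(a, experiment$i / experiment$sigma)$x
  if (all(w <= 0)) return(NULL)
  fitv <- as.numeric(profiles[, members, drop = FALSE] %*% w)
  chi <- sqrt(mean(((experiment$i - fitv) / experiment$sigma)^2))
  list(members = members, weights = w / sum(w), scale = sum(w), chi = chi)
}

#' Select N-state ensembles against a SAXS curve
#'
#' For each candidate subset of `n_states` pool members, fits non-negative
#' weights to the sigma-weighted experimental intensities (overall scale
#' folded into the weight sum), scores the weighted mixture by chi, and
#' returns the `keep` best models. Subsets are enumerated exhaustively when
#' their count does not exceed `exhaustive_limit`; otherwise a seeded
#' stochastic search (random subsets refined by single-member swaps) is used.
#' Ties in chi are broken by smaller N, then lexicographic member indices.
#'
#' @param pool A `conformer_pool` with profiles (see [pool_profiles()]).
#' @param experiment A `saxs_profile` on a grid inside the pool's.
#' @param n_states Number of states N (1 to 5).
#' @param keep Number of top models to return (default 10).
#' @param exhaustive_limit Max subset count for exhaustive enumeration
#'   (default 2e4).
#' @param n_random Random restarts in stochastic mode (default 200).
#' @param seed Seed for the stochastic search.
#' @return Tibble of class `ensemble_models`, ranked by chi: columns
#'   `rank`, `n_states`, `chi`, `scale`, and list-columns `members`,
#'   `weights`, `rg`.
#' @export
multistate_fit <- function(pool, experiment, n_states, keep = 10,
                           exhaustive_limit = 2e4, n_random = 200, seed = 1) {
  if (is.null(pool$profiles)) abort("call pool_profiles() first.")
  if (n_states < 1 || n_states > 5) abort("n_states must be between 1 and 5.")
  npool <- length(pool$coords)
  if (n_states > npool) abort("n_states exceeds pool size.")
  profiles <- apply(pool$profiles, 2, function(p) {
    approx(pool$q, p, xout = experiment$q)$y
  })
  if (any(!is.finite(profiles))) {
    abort("experimental q-range extends beyond the pool grid.")
  }
  n_comb <- choose(npool, n_states)
  results <- list()
  if (n_comb <= exhaustive_limit) {
    subsets <- combn(npool, n_states, simplify = FALSE)
    results <- purrr::compact(purrr::map(subsets, fit_subset,
                                         profiles = profiles,
                                         experiment = experiment))
  } else {
    set.seed(as.integer(seed))
    seen <- new.env(hash = TRUE)
    try_subset <- function(members) {
      key <- paste(sort(members), collapse = ",")
      if (!is.null(seen[[key]])) return(NULL)
      r <- fit_subset(sort(members), profiles, experiment)
      seen[[key]] <- TRUE
      r
    }
    for (t in seq_len(n_random)) {
      cand <- try_subset(sample.int(npool, n_states))
      if (is.null(cand)) next
      # local swap refinement
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (pos in seq_len(n_states)) {
          for (repl in sample.int(npool, min(20, npool))) {
            if (repl %in% cand$members) next
            trial_m <- cand$members; trial_m[pos] <- repl
            trial <- try_subset(trial_m)
            if (!is.null(trial) && trial$chi < cand$chi) {
              cand <- trial; improved <- TRUE
            }
          }
        }
      }
      results[[length(results) + 1]] <- cand
    }
  }
  if (length(results) == 0) abort("no candidate subset yielded nonzero weights.")
  ord <- order(vapply(results, `[[`, numeric(1), "chi"),
               vapply(results, function(r) paste(sprintf("%06d", r$members),
                                                 collapse = ""), character(1)))
  results <- results[ord][seq_len(min(keep, length(results)))]
  out <- tibble(
    rank = seq_along(results),
    n_states = n_states,
    chi = vapply(results, `[[`, numeric(1), "chi"),
    scale = vapply(results, `[[`, numeric(1), "scale"),
    members = purrr::map(results, "members"),
    weights = purrr::map(results, "weights"),
    rg = purrr::map(results, function(r) pool$rg[r$members])
  )
  class(out) <- c("ensemble_models", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.ensemble_models <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(as_tibble(x), "rank", "n_states", "chi",
                  "members", "weights", "rg"),
    cols = c("members", "weights", "rg")
  )
}

#' @exportS3Method generics::glance
glance.ensemble_models <- function(x, ...) {
  tibble(n_states = x$n_states[1], n_models = nrow(x),
         best_chi = min(x$chi), worst_chi = max(x$chi))
}

#' Weighted Rg distribution of selected ensembles
#'
#' Histograms the member radii of gyration of a set of top-scoring ensemble
#' models: each model contributes equally (uniform rank weight) and each
#' member contributes its fitted weight within the model.
#'
#' @param models An `ensemble_models` tibble (or several row-bound together).
#' @param binwidth Histogram bin width in Angstrom (default 1).
#' @return Tibble with `rg_mid` (bin centre), `weight` (normalised to 1),
#'   and attribute `modes` (local maxima bin centres).
#' @export
rg_distribution <- function(models, binwidth = 1) {
  if (nrow(models) == 0) abort("empty model list.")
  long <- tidy.ensemble_models(models)
  long$w <- long$weights / nrow(models) * 1
  lo <- floor(min(long$rg) / binwidth) * binwidth
  bins <- lo + binwidth * (0:ceiling((max(long$rg) - lo) / binwidth + 1))
  idx <- findInterval(long$rg, bins, rightmost.closed = TRUE)
  wt <- tapply(long$w, factor(idx, levels = seq_len(length(bins) - 1)), sum)
  wt[is.na(wt)] <- 0
  wt <- as.numeric(wt) / sum(long$w)
  out <- tibble(rg_mid = bins[-length(bins)] + binwidth / 2, weight = wt)
  interior <- which(wt > 0 &
                      wt >= c(-Inf, head(wt, -1)) & wt >= c(tail(wt, -1), -Inf))
  attr(out, "modes") <- out$rg_mid[interior]
  out
}

#' Radius of gyration of a coordinate set
#'
#' @param xyz n x 3 coordinate matrix or `bead_model` (Angstrom).
#' @return Rg in Angstrom (uniform bead masses).
#' @export
radius_of_gyration <- function(xyz) {
  xyz <- bead_coords(xyz)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}
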