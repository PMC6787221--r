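test_that("Debye profile matches the two-bead closed form and brute force", {
  q <- seq(0.02, 0.5, length.out = 40)
  d <- 10
  two <- matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(debye_profile(two, q), 2 + 2 * sin(q * d) / (q * d),
               tolerance = 1e-12)
  expect_equal(debye_profile(two, 1e-8), 4, tolerance = 1e-6)

  xyz <- sphere_beads(50, 15, seed = 4)
  expect_equal(debye_profile(xyz, q), linkerflex:::debye_profile_brute(xyz, q),
               tolerance = 1e-10)
  expect_error(debye_profile(rbind(xyz, xyz[1, ]), q), "coincident")
})

test_that("a dense bead sphere reproduces the closed-form sphere intensity", {
  R <- 20
  beads <- sphere_beads(2000, R, seed = 8)
  q <- seq(0.01, 6 / R, length.out = 50)
  i <- debye_profile(beads, q)
  expect_lt(sqrt(mean((i / 2000^2 - sphere_intensity(q, R))^2)), 0.03)
})

test_that("Debye profiles are invariant under rigid rotation and translation", {
  xyz <- sphere_beads(60, 12, seed = 5)
  q <- seq(0.02, 0.4, length.out = 30)
  rot <- linkerflex:::rotation_matrix(c(1, 2, 3), 1.1)
  moved <- sweep(xyz %*% t(rot), 2, c(50, -20, 7), "+")
  expect_equal(debye_profile(xyz, q), debye_profile(moved, q),
               tolerance = 1e-9)
})

test_that("chi score is zero under scaling and ~1 under 1-sigma perturbation", {
  q <- seq(0.01, 0.3, length.out = 100)
  i <- 100 * exp(-q^2 * 18^2 / 3)
  p <- saxs_profile(q, i, 0.02 * i)
  expect_equal(chi_score(p, i)$chi, 0, tolerance = 1e-10)
  s <- chi_score(p, i * 3.7)
  expect_equal(s$chi, 0, tolerance = 1e-10)
  expect_equal(s$scale, 1 / 3.7, tolerance = 1e-10)
  chis <- vapply(1:30, function(s) {
    set.seed(s)
    pp <- saxs_profile(q, i + rnorm(100, 0, 0.02 * i), 0.02 * i)
    chi_score(pp, i)$chi
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 0.1)
})

test_that("conformer generation is seed-deterministic and spans compact to extended", {
  m <- make_two_domain_model(15, 20, 60, seed = 7)
  a <- generate_conformers(m, 25, seed = 3)
  b <- generate_conformers(m, 25, seed = 3)
  expect_identical(a$coords, b$coords)
  big <- generate_conformers(m, 120, seed = 3)
  expect_gt(max(big$rg) / min(big$rg), 1.5)
  # zero flexible residues: n identical copies
  rigid <- bead_model(bead_coords(make_two_domain_model(0, 5, 20, seed = 1)))
  pool0 <- generate_conformers(rigid, 4, seed = 1)
  expect_identical(pool0$coords[[1]], pool0$coords[[4]])
})

test_that("conformers preserve rigid-body internal geometry", {
  m <- make_two_domain_model(15, 20, 60, seed = 7)
  pool <- generate_conformers(m, 5, seed = 2)
  glob <- which(m$domain == "globule")
  d0 <- stats::dist(bead_coords(m)[glob, ])
  for (k in 1:5) {
    expect_equal(as.numeric(stats::dist(pool$coords[[k]][glob, ])),
                 as.numeric(d0), tolerance = 1e-9)
  }
})

test_that("a 1-state fit finds the generating conformer at the noise floor", {
  m <- make_two_domain_model(15, 20, 60, seed = 7)
  pool <- pool_profiles(generate_conformers(m, 40, seed = 3),
                        seq(0.01, 0.35, length.out = 81))
  ex <- simulate_saxs(pool, members = 12, weights = 1, seed = 5)
  fit <- multistate_fit(pool, ex, 1, keep = 3)
  expect_equal(fit$members[[1]], 12)
  expect_lt(fit$chi[1], 1.5)
})

test_that("two-state weights are recovered within 0.05 across seeds", {
  m <- make_two_domain_model(15, 20, 60, seed = 7)
  pool <- pool_profiles(generate_conformers(m, 60, seed = 3),
                        seq(0.01, 0.35, length.out = 81))
  ma <- which.min(pool$rg); mb <- which.max(pool$rg)
  hits <- vapply(1:20, function(s) {
    ex <- simulate_saxs(pool, members = c(ma, mb), weights = c(0.7, 0.3),
                        seed = s)
    f <- multistate_fit(pool, ex, 2, keep = 1)
    mm <- f$members[[1]]; ww <- f$weights[[1]]
    (ma %in% mm) && (mb %in% mm) &&
      abs(ww[match(ma, mm)] - 0.7) <= 0.05 &&
      abs(ww[match(mb, mm)] - 0.3) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("chi is weakly monotone in N and extra states do not reward a pure state", {
  m <- make_two_domain_model(15, 20, 60, seed = 7)
  pool <- pool_profiles(generate_conformers(m, 18, seed = 3),
                        seq(0.01, 0.35, length.out = 61))
  ma <- which.min(pool$rg); mb <- which.max(pool$rg)
  ex <- simulate_saxs(pool, members = c(ma, mb), weights = c(0.6, 0.4),
                      seed = 2)
  chis <- vapply(1:3, function(n) {
    multistate_fit(pool, ex, n, keep = 1)$chi[1]
  }, numeric(1))
  expect_true(all(diff(chis) <= 1e-9))

  pure <- simulate_saxs(pool, members = ma, weights = 1, seed = 4)
  c1 <- multistate_fit(pool, pure, 1, keep = 1)$chi[1]
  c5 <- multistate_fit(pool, pure, 5, keep = 1, exhaustive_limit = 2,
                       n_random = 60, seed = 9)$chi[1]
  expect_lt((c1 - c5) / c1, 0.05)
})

test_that("ensemble mixtures are linear in member profiles", {
  m <- make_two_domain_model(15, 20, 60, seed = 7)
  pool <- pool_profiles(generate_conformers(m, 10, seed = 3),
                        seq(0.01, 0.35, length.out = 41))
  w <- c(0.25, 0.75)
  mix <- pool$profiles[, c(2, 7)] %*% w
  byhand <- w[1] * pool$profiles[, 2] + w[2] * pool$profiles[, 7]
  expect_equal(as.numeric(mix), byhand, tolerance = 1e-12)
})

test_that("Rg distributions show modes at the true mixture components", {
  m <- make_two_domain_model(15, 20, 60, seed = 7)
  pool <- pool_profiles(generate_conformers(m, 60, seed = 3),
                        seq(0.01, 0.35, length.out = 81))
  ma <- which.min(pool$rg); mb <- which.max(pool$rg)
  ex <- simulate_saxs(pool, members = c(ma, mb), weights = c(0.7, 0.3),
                      seed = 3)
  f <- multistate_fit(pool, ex, 2, keep = 1)
  d <- rg_distribution(f)
  expect_equal(sum(d$weight), 1, tolerance = 1e-10)
  wa <- sum(d$weight[abs(d$rg_mid - pool$rg[ma]) <= 1.5])
  wb <- sum(d$weight[abs(d$rg_mid - pool$rg[mb]) <= 1.5])
  expect_equal(wa / wb, 7 / 3, tolerance = 0.35)
  # a single 1-state model concentrates all weight in one bin
  f1 <- multistate_fit(pool, simulate_saxs(pool, ma, 1, seed = 8), 1, keep = 1)
  d1 <- rg_distribution(f1)
  expect_equal(max(d1$weight), 1)
  # equal-weight pool prior is broad: many occupied bins
  prior <- tibble::tibble(rank = 1, n_states = length(pool$rg), chi = 0,
                          scale = 1, members = list(seq_along(pool$rg)),
                          weights = list(rep(1 / 60, 60)),
                          rg = list(pool$rg))
  class(prior) <- c("ensemble_models", class(prior))
  dp <- rg_distribution(prior)
  expect_gt(sum(dp$weight > 0), 8)
})
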