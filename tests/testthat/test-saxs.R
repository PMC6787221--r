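test_that("Guinier fit is exact on an ideal Gaussian profile", {
  q <- seq(0.001, 0.4, length.out = 500)
  p <- saxs_profile(q, 100 * exp(-q^2 * 20^2 / 3), rep(0.1, 500))
  g <- guinier_fit(p)
  expect_equal(g$rg, 20, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)
  expect_lte(g$q_rg_window[2], 1.3 + 1e-6)
})

test_that("Guinier Rg of a homogeneous sphere is sqrt(3/5) R within 1%", {
  R <- 20
  q <- seq(0.005, 0.3, length.out = 200)
  p <- saxs_profile(q, sphere_intensity(q, R, 100),
                    pmax(sphere_intensity(q, R, 100) * 0.01, 1e-10))
  g <- guinier_fit(p)
  expect_lt(abs(g$rg - sqrt(3 / 5) * R) / (sqrt(3 / 5) * R), 0.01)
})

test_that("mean Guinier Rg over noisy sphere curves stays within 2%", {
  R <- 20
  q <- seq(0.005, 0.3, length.out = 150)
  i0 <- sphere_intensity(q, R, 100)
  rgs <- vapply(1:30, function(s) {
    set.seed(s)
    sig <- 0.02 * i0
    guinier_fit(saxs_profile(q, i0 + rnorm(150, 0, sig), sig))$rg
  }, numeric(1))
  expect_lt(abs(mean(rgs) - sqrt(3 / 5) * R) / (sqrt(3 / 5) * R), 0.02)
})

test_that("aggregation-like upturn is rejected with a diagnostic", {
  q <- seq(0.005, 0.2, length.out = 100)
  p <- saxs_profile(q, 10 + 100 * q^2, rep(0.1, 100))
  expect_error(guinier_fit(p), "slope")
})

test_that("dimensionless Kratky of a Guinier-regime curve peaks at (sqrt(3), 3/e)", {
  q <- seq(0.002, 0.4, length.out = 2000)
  for (rg in c(15, 28)) {
    for (i0 in c(1, 250)) {
      p <- saxs_profile(q, i0 * exp(-q^2 * rg^2 / 3), rep(i0 * 1e-4, 2000))
      g <- guinier_fit(p)
      k <- dimensionless_kratky(p, g)
      expect_equal(attr(k, "peak_height"), 3 / exp(1), tolerance = 1e-3)
      expect_equal(attr(k, "peak_q_rg"), sqrt(3), tolerance = 1e-2)
    }
  }
})

test_that("the dimensionless Kratky transform is parameter-free", {
  q <- seq(0.002, 0.4, length.out = 400)
  curves <- purrr::map(list(c(15, 1), c(30, 500)), function(pp) {
    p <- saxs_profile(q, pp[2] * exp(-q^2 * pp[1]^2 / 3),
                      rep(pp[2] * 1e-4, 400))
    k <- dimensionless_kratky(p, guinier_fit(p))
    approx(k$q_rg, k$kratky, xout = seq(0.5, 3, by = 0.1))$y
  })
  expect_equal(curves[[1]], curves[[2]], tolerance = 1e-3)
})

test_that("a flat profile yields a monotone transform with no interior peak", {
  q <- seq(0.01, 0.3, length.out = 100)
  p <- saxs_profile(q, rep(50, 100), rep(0.5, 100))
  g <- list(rg = 20, i0 = 50)
  class(g) <- "guinier_result"
  k <- dimensionless_kratky(p, g)
  expect_false(attr(k, "has_peak"))
  expect_true(all(diff(k$kratky) > 0))
})

test_that("sphere Kratky peak matches the closed-form reference and falls symmetrically", {
  R <- 20
  q <- seq(0.004, 0.28, length.out = 600)
  p <- saxs_profile(q, sphere_intensity(q, R, 100),
                    pmax(sphere_intensity(q, R, 100) * 0.005, 1e-12))
  k <- dimensionless_kratky(p, guinier_fit(p))
  expect_true(attr(k, "has_peak"))
  # oracle: maximise (q Rg)^2 I(q)/I(0) of the exact sphere form factor
  ref <- optimize(function(u) u^2 * sphere_intensity(u / (sqrt(3 / 5) * R), R),
                  c(0.5, 3), maximum = TRUE)
  expect_equal(attr(k, "peak_height"), ref$objective, tolerance = 0.02)
  expect_equal(attr(k, "peak_q_rg"), ref$maximum, tolerance = 0.05)
  # symmetric rise/fall around the peak
  px <- attr(k, "peak_q_rg")
  up <- approx(k$q_rg, k$kratky, xout = px - 0.5)$y
  dn <- approx(k$q_rg, k$kratky, xout = px + 0.5)$y
  expect_equal(up, dn, tolerance = 0.15)
})

test_that("concentration merging recovers the scale and the low-q slope", {
  q <- seq(0.01, 0.3, length.out = 80)
  i <- 100 * exp(-q^2 * 18^2 / 3)
  lo <- saxs_profile(q, i, 0.02 * i)
  hi <- saxs_profile(q, 4 * i, 0.08 * i)
  mg <- merge_profiles(lo, hi)
  expect_equal(attr(mg, "scale"), 0.25, tolerance = 1e-10)
  expect_equal(approx(mg$q, mg$i, xout = q[5:70])$y, i[5:70],
               tolerance = 1e-8)
  # identical curves merge to themselves
  self <- merge_profiles(lo, lo)
  expect_equal(approx(self$q, self$i, xout = q[5:70])$y, i[5:70],
               tolerance = 1e-10)
  # low-q repulsion artifact on the high-c curve must not bias the Rg
  hi_rep <- saxs_profile(q, 4 * i * (1 - 0.3 * exp(-(q / 0.03)^2)), 0.08 * i)
  mg2 <- merge_profiles(lo, hi_rep)
  g_lo <- guinier_fit(lo); g_mg <- guinier_fit(mg2)
  expect_equal(g_mg$rg, g_lo$rg, tolerance = 0.01)
  expect_error(merge_profiles(
    saxs_profile(q[1:20], i[1:20], 0.02 * i[1:20]),
    saxs_profile(q[60:80], i[60:80], 0.02 * i[60:80])), "overlap")
})

test_that("P(r) of a sphere matches the closed-form distance distribution", {
  R <- 20
  q <- seq(0.005, 0.3, length.out = 200)
  i <- sphere_intensity(q, R, 100)
  p <- saxs_profile(q, i, pmax(0.01 * i, 1e-10))
  pr <- pofr_invert(p, dmax = 2 * R)
  pn <- pr$p / max(pr$p)
  pt <- sphere_pofr(pr$r, R) / max(sphere_pofr(pr$r, R))
  expect_lt(sqrt(mean((pn - pt)^2)), 0.03)
  expect_equal(attr(pr, "rg_real"), sqrt(3 / 5) * R, tolerance = 0.02)
  # endpoints pinned, non-negativity enforced
  expect_equal(pr$p[1], 0)
  expect_equal(pr$p[nrow(pr)], 0)
  expect_true(all(pr$p >= -1e-4 * max(pr$p)))
})

test_that("back-computed I(q) from P(r) reproduces the input within chi ~ 1", {
  R <- 18
  q <- seq(0.008, 0.28, length.out = 120)
  i0 <- sphere_intensity(q, R, 50)
  set.seed(17)
  sig <- 0.01 * i0
  p <- saxs_profile(q, i0 + rnorm(120, 0, sig), sig)
  pr <- pofr_invert(p, dmax = 2 * R)
  expect_lt(attr(pr, "chi"), 1.5)
})

test_that("Guinier and P(r)-moment Rg agree within 5% on rigid fixtures", {
  for (R in c(15, 24)) {
    q <- seq(0.005, 0.3, length.out = 150)
    i <- sphere_intensity(q, R, 100)
    p <- saxs_profile(q, i, pmax(0.01 * i, 1e-10))
    g <- guinier_fit(p)
    pr <- pofr_invert(p, dmax = 2 * R)
    expect_lt(abs(g$rg - attr(pr, "rg_real")) / g$rg, 0.05)
  }
})

test_that("a dumbbell of two spheres produces a shouldered P(r)", {
  beads <- rbind(sphere_beads(300, 10, seed = 2),
                 sweep(sphere_beads(300, 10, seed = 3), 2, c(35, 0, 0), "+"))
  q <- seq(0.01, 0.3, length.out = 120)
  i <- debye_profile(beads, q)
  p <- saxs_profile(q, i, pmax(0.005 * i, 1e-8))
  pr <- pofr_invert(p, dmax = 60)
  # interior local maxima: intradomain peak plus cross-domain hump
  y <- pr$p
  peaks <- sum(diff(sign(diff(y))) == -2)
  expect_gte(peaks, 2)
})

test_that("Dmax scan brackets the sphere diameter and warns outside range", {
  R <- 20
  q <- seq(0.005, 0.3, length.out = 150)
  i <- sphere_intensity(q, R, 100)
  p <- saxs_profile(q, i, pmax(0.01 * i, 1e-10))
  sc <- dmax_scan(p, seq(28, 56, by = 4))
  expect_true(sc$plateau_found)
  expect_lte(abs(sc$dmax - 2 * R), 4)
  expect_warning(dmax_scan(p, seq(16, 32, by = 4)), "widen")
  expect_error(dmax_scan(p, c(30, 40)), "at least 5")
})
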