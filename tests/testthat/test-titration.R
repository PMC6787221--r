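test_that("combined CSP follows the weighted quadrature formula", {
  expect_equal(compute_csp(0, 0), 0)
  expect_equal(compute_csp(0.1, 0.5), 0.1)
  expect_equal(compute_csp(0, 0.5), 0.070711, tolerance = 1e-5)
  expect_error(compute_csp(Inf, 0.1), "non-finite")
  expect_error(compute_csp(c(0.1, 0.2), 0.1), "same length")
})

test_that("isotherms match an independent equilibrium root-finding oracle", {
  # frozen value from the oracle: kd=86, p0=100, l0=100, 1:1
  expect_equal(binding_curve_1to1(100, 100, 86, 1), 0.40780, tolerance = 1e-5)
  for (kd in c(5, 60, 300)) {
    for (l0 in c(0, 25, 100, 400)) {
      expect_equal(binding_curve_1to1(l0, 100, kd, 1),
                   bound_fraction_1to1(kd, 100, l0), tolerance = 1e-6)
      expect_equal(binding_curve_2to1(l0, 100, kd, 1),
                   bound_fraction_2to1(kd, 100, l0), tolerance = 1e-6)
    }
  }
})

test_that("isotherm limits: free state, stoichiometric limit, bivalent limit", {
  expect_equal(binding_curve_1to1(0, 100, 86, 1), 0)
  # kd -> 0 with ligand excess saturates
  expect_equal(binding_curve_1to1(120, 100, 1e-9, 0.7), 0.7, tolerance = 1e-6)
  # bivalent kd -> 0: bound fraction = min(2 l0, p0) / p0
  expect_equal(binding_curve_2to1(30, 100, 1e-9, 1), 0.6, tolerance = 1e-6)
})

test_that("both isotherms are monotone in l0 and bounded by dd_bound", {
  set.seed(41)
  for (rep in 1:25) {
    kd <- 10^runif(1, 0, 3.5)
    p0 <- runif(1, 20, 400)
    ddb <- runif(1, 0.1, 2)
    l0 <- seq(0, 8 * p0, length.out = 60)
    for (mdl in c("1to1", "2to1")) {
      y <- binding_curve(l0, p0, kd, ddb, mdl)
      expect_true(all(diff(y) >= -1e-12))
      expect_true(all(y <= ddb + 1e-12))
    }
  }
})

test_that("bivalent curve at l0/2 equals the 1:1 curve at l0", {
  l0 <- seq(0, 500, length.out = 40)
  expect_equal(binding_curve_2to1(l0 / 2, 100, 86, 1),
               binding_curve_1to1(l0, 100, 86, 1), tolerance = 1e-12)
})

test_that("noiseless synthetic titrations invert exactly", {
  truth <- make_titration_truth(6)
  st <- simulate_titration(truth, kd = 100, model = "1to1", noise = 0, seed = 1)
  fit <- fit_kd(csp_series(st), "1to1")
  kds <- tidy(fit)$kd[tidy(fit)$status == "ok"]
  expect_true(all(abs(kds - 100) < 1e-3))
})

test_that("noisy recovery lands within the aggregate SD and both modes agree", {
  truth <- make_titration_truth(20)
  st <- simulate_titration(truth, kd = 86, model = "1to1", seed = 7)
  ser <- csp_series(st)
  per <- kd_table(fit_kd(ser, "1to1"))
  expect_true(abs(per$kd - 86) <= per$kd_sd)
  glob <- kd_table(fit_kd(ser, "1to1", mode = "global"))
  expect_equal(glob$kd, per$kd, tolerance = 0.1)
})

test_that("median relative Kd bias is below 5% at the study ground truths", {
  truth <- make_titration_truth(8)
  for (cfg in list(list(kd = 39, m = "1to1"), list(kd = 60, m = "2to1"),
                   list(kd = 86, m = "1to1"), list(kd = 483, m = "2to1"))) {
    bias <- vapply(1:50, function(s) {
      st <- simulate_titration(truth, kd = cfg$kd, model = cfg$m, seed = s)
      kd_table(fit_kd(csp_series(st), cfg$m))$kd / cfg$kd - 1
    }, numeric(1))
    expect_lt(abs(median(bias)), 0.05)
  }
})

test_that("residues below the endpoint floor are excluded without changing the aggregate", {
  truth <- make_titration_truth(10)
  st <- simulate_titration(truth, kd = 86, model = "1to1", seed = 3)
  base <- fit_kd(csp_series(st), "1to1")
  dead <- truth
  dead$residue <- 100 + dead$residue
  dead$dd_bound <- 1e-4   # never exceeds the floor
  st_dead <- simulate_titration(dead, kd = 86, model = "1to1", seed = 3)
  both <- dplyr::bind_rows(csp_series(st), csp_series(st_dead))
  aug <- fit_kd(both, "1to1")
  expect_equal(kd_table(aug)$kd, kd_table(base)$kd, tolerance = 1e-9)
  expect_true(all(tidy(aug)$status[tidy(aug)$residue > 100] == "below_floor"))
})

test_that("an unsaturated ladder widens the reported Kd error", {
  truth <- make_titration_truth(20)
  full <- simulate_titration(truth, kd = 86, model = "1to1", seed = 1)
  part <- simulate_titration(truth, kd = 86, model = "1to1",
                             l0 = seq(0, 30, length.out = 12), seed = 1)
  sd_full <- kd_table(fit_kd(csp_series(full), "1to1"))$kd_sd
  sd_part <- kd_table(fit_kd(csp_series(part), "1to1"))$kd_sd
  expect_gt(sd_part, sd_full)
  expect_gt(sd_part, 3 * sd_full)
})

test_that("significance threshold is inclusive and respects halved endpoints", {
  ser <- tibble::tibble(
    residue = rep(1:3, each = 2), domain = "UIM",
    point = rep(0:1, 3), p0 = 100,
    l0 = rep(c(0, 500), 3),
    dd = c(0, 0.39, 0, 0.40, 0, 0.41)
  )
  sig <- csp_significance(ser, threshold = 0.4)
  expect_equal(sort(sig$residue), c(2, 3))
  expect_equal(nrow(csp_significance(dplyr::mutate(ser, dd = 0))), 0)
  # halving bound-state shifts in one domain reduces its significant count
  truth <- make_titration_truth(12, seed = 5)
  truth$dd_bound <- runif(12, 0.45, 0.9)
  truth$domain <- rep(c("UIM", "SH3"), each = 6)
  truth$dd_bound[truth$domain == "SH3"] <-
    truth$dd_bound[truth$domain == "SH3"] / 2
  st <- simulate_titration(truth, kd = 50, model = "1to1", seed = 2)
  sig <- csp_significance(csp_series(st), 0.4)
  n_uim <- sum(sig$domain == "UIM"); n_sh3 <- sum(sig$domain == "SH3")
  expect_gt(n_uim, n_sh3)
})

test_that("broadened residues are excluded from fitting but counted", {
  truth <- make_titration_truth(6)
  st <- simulate_titration(truth, kd = 86, model = "1to1", seed = 2)
  st$d_h[st$residue == 3 & st$point >= 8] <- NA
  st$d_n[st$residue == 3 & st$point >= 8] <- NA
  fit <- fit_kd(csp_series(st), "1to1")
  row3 <- tidy(fit)[tidy(fit)$residue == 3, ]
  expect_equal(row3$n_broadened, 4)
  expect_equal(row3$n_points, 8)
})
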