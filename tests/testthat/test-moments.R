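test_that("profile moments match closed forms", {
  u <- profile_moments(rep(3, 12))
  expect_equal(u$mu1, 6.5)
  expect_equal(u$mu2, sqrt(143 / 12))
  d9 <- profile_moments(c(rep(0, 8), 5, 0, 0, 0))
  expect_equal(d9$mu1, 9)
  expect_equal(d9$mu2, 0)
  ramp <- profile_moments(1:12)
  expect_equal(ramp$mu1, 650 / 78)
})

test_that("moments are invariant to positive rescaling", {
  set.seed(1)
  p <- matrix(rexp(50 * 12), 50)
  m1 <- profile_moments(p)
  for (c0 in c(1e-6, 0.5, 3, 1e6)) {
    m2 <- profile_moments(p * c0)
    expect_equal(m2$mu1, m1$mu1, tolerance = 1e-12)
    expect_equal(m2$mu2, m1$mu2, tolerance = 1e-12)
  }
})

test_that("moving intensity mass deeper strictly increases mu1", {
  set.seed(2)
  for (rep in 1:200) {
    p <- rexp(12) + 0.05
    ab <- sort(sample.int(12, 2))
    q <- p
    shift <- runif(1, 0.01, 1) * p[ab[1]]
    q[ab[1]] <- q[ab[1]] - shift
    q[ab[2]] <- q[ab[2]] + shift
    expect_gt(profile_moments(q)$mu1, profile_moments(p)$mu1)
  }
})

test_that("mu2 indexes profile flatness: concentration lowers it, within its bound", {
  mu2_uniform <- sqrt(143 / 12)
  # global bound: mass split across the two extreme depths, sd = 5.5
  expect_lte(max(profile_moments(matrix(rexp(500 * 12), 500))$mu2), 5.5)
  expect_equal(profile_moments(c(1, rep(0, 10), 1))$mu2, 5.5)
  # concentrating the uniform profile toward any central depth strictly
  # lowers mu2; oracle is the closed-form mixture variance
  # (1-t) V_u + t (1-t) (6.5 - d0)^2
  u <- rep(1 / 12, 12)
  for (d0 in 4:9) {
    delta <- replace(rep(0, 12), d0, 1)
    for (t in c(0.1, 0.4, 0.7, 0.95)) {
      m <- profile_moments((1 - t) * u + t * delta)$mu2
      oracle <- sqrt((1 - t) * 143 / 12 + t * (1 - t) * (6.5 - d0)^2)
      expect_equal(m, oracle, tolerance = 1e-12)
      expect_lt(m, mu2_uniform)
    }
  }
  # across a realistic smooth-profile family, mu2 tracks flatness
  # (negatively correlates with the profile coefficient of variation)
  set.seed(3)
  fam <- t(replicate(400, {
    base <- seq(1, runif(1, 1, 3), length.out = 12)
    pmax(base + rnorm(12, sd = 0.2), 0.01)
  }))
  cv <- apply(fam, 1, function(x) sd(x) / mean(x))
  expect_lt(cor(profile_moments(fam)$mu2, cv), -0.5)
})

test_that("invalid profiles raise classed errors or NA as requested", {
  expect_error(profile_moments(c(rep(1, 11), -0.2)), class = "neolaminar_domain_error")
  expect_error(profile_moments(rep(0, 12)), class = "neolaminar_domain_error")
  clamped <- profile_moments(c(rep(1, 11), -0.2), negatives = "clamp")
  expect_equal(clamped$mu1, profile_moments(c(rep(1, 11), 0), degenerate = "na")$mu1)
  mixed <- profile_moments(rbind(rep(0, 12), rep(1, 12)), degenerate = "na")
  expect_true(is.na(mixed$mu1[1]) && mixed$mu1[2] == 6.5)
})

test_that("parcel profile averaging respects masks and exclusions", {
  p <- rbind(1:12, 13:24, rep(5, 12), rep(9, 12))
  labels <- c(1, 1, 2, 3)
  pm <- parcel_mean_profiles(p, labels)
  expect_equal(unname(as.matrix(pm[pm$parcel_id == "1", grep("^depth_", names(pm))])[1, ]),
               (c(1:12) + c(13:24)) / 2)
  # excluding 7 of 40 ids leaves 33 analyzed parcels
  set.seed(4)
  p40 <- matrix(rexp(400 * 12), 400)
  lab40 <- rep(1:40, each = 10)
  pm40 <- parcel_mean_profiles(p40, lab40, excluded_ids = 34:40)
  expect_equal(nrow(pm40), 33)
  # masked-out vertices are ignored
  pm_masked <- parcel_mean_profiles(
    structure(p, mask = c(TRUE, FALSE, TRUE, TRUE), class = c("laminar_profiles", "matrix", "array")),
    labels)
  expect_equal(unname(as.matrix(pm_masked[pm_masked$parcel_id == "1",
                                          grep("^depth_", names(pm_masked))])[1, ]),
               as.numeric(1:12))
  # moments of a parcel of identical vertices equal the member moments
  pmi <- parcel_mean_profiles(rbind(1:12, 1:12), c(7, 7))
  expect_equal(profile_moments(as.matrix(pmi[, grep("^depth_", names(pmi))]))$mu1,
               650 / 78)
  expect_error(parcel_mean_profiles(p, labels, excluded_ids = 1:3),
               class = "neolaminar_contract_error")
})

test_that("sliding windows step by width times one minus overlap", {
  p <- matrix(rep(1:12, each = 8), nrow = 8)
  ages <- c(38, 38.2, 38.5, 39, 39.4, 40, 40.3, 41)
  win <- sliding_window_profiles(p, ages, width = 1.5, overlap = 0.5)
  expect_equal(unique(round(diff(unique(win$window_start)), 10)), 0.75)
  expect_true(all(as.matrix(win[, grep("^depth_", names(win))]) ==
                    matrix(1:12, nrow(win), 12, byrow = TRUE)))
  # two close ages fall into one leading window
  win2 <- sliding_window_profiles(rbind(1:12, 2:13), c(38, 38.5), width = 1.5)
  expect_equal(nrow(win2), 1)
  expect_equal(win2$n_subjects, 2)
  expect_equal(unname(as.matrix(win2[, grep("^depth_", names(win2))])[1, ]),
               seq(1.5, 12.5))
})

test_that("moment-sorted bins preserve rank order and degenerate cases", {
  set.seed(5)
  p <- matrix(rexp(100 * 12), 100)
  b <- moment_sorted_bins(p, "mu1", n_bins = 100)
  expect_equal(nrow(b), 100)
  expect_true(all(b$n_profiles == 1))
  mom <- profile_moments(p)$mu1
  expect_equal(b$moment, sort(mom))
  # identical profiles give identical bins
  same <- moment_sorted_bins(matrix(rep(1:12, 30), 30, byrow = TRUE), "mu2", 10)
  depth_cols <- as.matrix(same[, grep("^depth_", names(same))])
  expect_true(all(apply(depth_cols, 2, function(x) all(x == x[1]))))
  # bin-mean mu1 is nondecreasing for mu1-sorted binning
  p2 <- matrix(rexp(500 * 12), 500)
  b2 <- moment_sorted_bins(p2, "mu1", n_bins = 50)
  binmu <- profile_moments(as.matrix(b2[, grep("^depth_", names(b2))]))$mu1
  expect_true(all(diff(binmu) > -1e-9))
  expect_error(moment_sorted_bins(matrix(numeric(0), 0, 12), "mu1"),
               class = "neolaminar_contract_error")
})
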