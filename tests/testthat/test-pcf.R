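test_that("Ripley's K matches a direct evaluation of the translation sum", {
  w <- transect_window(1000)
  pts <- data.frame(x = c(100, 110), y = c(20, 25))
  d <- sqrt(10^2 + 5^2)
  # |W|^2 / ((Lx - |dx|)(Ly - |dy|)) for the single pair, hand-evaluated
  expected <- (1000 * 50)^2 / ((1000 - 10) * (50 - 5))
  K <- ripley_K(pts, w, c(5, 11.18, 20), warn_guard = FALSE)
  expect_equal(K$K, c(0, 0, expected), tolerance = 1e-12)
  expect_true(all(diff(K$K) >= 0))
  expect_error(ripley_K(pts[1, , drop = FALSE], w, 10, warn_guard = FALSE),
               "2 points")
})

test_that("K agrees with an uncorrected pair count away from edge effects", {
  # all displacements tiny relative to the window: weights ~ 1, so
  # K ~ |W| * 2 * #{pairs with d <= r} / (n (n - 1))
  # displacements small against BOTH window dimensions: dy <= 2 of 50 m
  w <- transect_window(5000)
  set.seed(31)
  pts <- data.frame(x = runif(40, 2000, 2100), y = runif(40, 24, 26))
  r <- c(20, 50, 120)
  D <- as.matrix(dist(pts)); diag(D) <- Inf
  brute <- vapply(r, function(ri) sum(D <= ri), numeric(1)) *
    w$area_m2 / (40 * 39)
  K <- ripley_K(pts, w, r, warn_guard = FALSE)$K
  expect_equal(K, brute, tolerance = 0.06)
})

test_that("the pair correlation estimator equals a brute-force kernel sum", {
  w <- transect_window(200)
  pts <- data.frame(x = c(20, 35, 120), y = c(10, 30, 40))
  h <- 25
  r_grid <- c(15, 30, 60)
  # independent evaluation: explicit loops over ordered pairs
  n <- 3; area <- 200 * 50
  brute <- sapply(r_grid, function(r) {
    acc <- 0
    for (i in 1:n) for (j in 1:n) if (i != j) {
      dx <- abs(pts$x[i] - pts$x[j]); dy <- abs(pts$y[i] - pts$y[j])
      dd <- sqrt(dx^2 + dy^2)
      u <- (r - dd) / h
      if (abs(u) < 1)
        acc <- acc + (0.75 * (1 - u^2) / h) / ((200 - dx) * (50 - dy))
    }
    acc * area^2 / (2 * pi * r * n * (n - 1))
  })
  g <- pcf(pts, w, r_grid, bandwidth = h, warn_guard = FALSE)$g
  expect_equal(g, brute, tolerance = 1e-10)
})

test_that("g tracks the numerical derivative of K on smooth averages", {
  w <- transect_window(2000)
  r0 <- c(30, 60)
  acc_g <- 0; acc_dk <- 0
  for (s in 1:20) {
    p <- sim_poisson(w, 15, seed = 400 + s)
    acc_g <- acc_g + pcf(p, w, r0, bandwidth = 8, warn_guard = FALSE)$g
    K <- ripley_K(p, w, c(25, 35, 55, 65), warn_guard = FALSE)$K
    acc_dk <- acc_dk + (K[c(2, 4)] - K[c(1, 3)]) / 10 / (2 * pi * r0)
  }
  expect_equal(acc_g / 20, acc_dk / 20, tolerance = 0.1)
})

test_that("the CSR estimator tightens as intensity grows", {
  w <- transect_window(2000)
  err <- sapply(c(5, 40), function(lam) {
    g <- rowMeans(vapply(1:30, function(s) {
      pcf(sim_poisson(w, lam, seed = 1000 * lam + s), w, c(25, 40),
          bandwidth = 8, warn_guard = FALSE)$g
    }, numeric(2)))
    mean(abs(g - 1))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("CSR envelopes are ordered, seeded, and geometry-driven", {
  w <- transect_window(1500)
  p <- sim_poisson(w, 8, seed = 5)
  rg <- seq(10, 150, 10)
  e1 <- csr_envelope(p, w, rg, n_sim = 50, seed = 42)
  e2 <- csr_envelope(p, w, rg, n_sim = 50, seed = 42)
  expect_identical(e1$g_lo, e2$g_lo)
  expect_true(all(e1$g_lo <= e1$g_hi))
  # envelope depends only on geometry and count: shuffling rows changes nothing
  e3 <- csr_envelope(p[sample(nrow(p)), ], w, rg, n_sim = 50, seed = 42)
  expect_equal(e3$g_lo, e1$g_lo)
  expect_equal(e3$g_obs, e1$g_obs)
})

test_that("strong Thomas clustering is detected above the envelope", {
  w <- transect_window(2000)
  p <- sim_thomas(w, 2, 20, 15, seed = 8)
  e <- csr_envelope(p, w, seq(10, 100, 10), n_sim = 100, seed = 3)
  expect_equal(e$classification, "aggregated")
  expect_true(all(e$g_obs[e$r <= 15] > e$g_hi[e$r <= 15]))
  expect_gt(e$extent_m, 0)
})

test_that("pattern classification follows the initial-run rule", {
  rg <- seq(10, 1000, 10)
  base <- list(r = rg, g_lo = rep(0.8, 100), g_hi = rep(1.2, 100),
               g_obs = rep(1, 100))
  class(base) <- "envelope_result"
  # above the envelope up to 590 m, inside beyond: aggregated, extent 590
  agg <- base; agg$g_obs[rg <= 590] <- 1.5
  expect_equal(classify_pattern(agg),
               list(classification = "aggregated", extent_m = 590))
  expect_equal(classify_pattern(base),
               list(classification = "random", extent_m = 0))
  reg <- base; reg$g_obs[] <- 0.5
  expect_equal(classify_pattern(reg)$classification, "regular")
  mix <- base; mix$g_obs[30:40] <- 1.5
  expect_equal(classify_pattern(mix)$classification, "mixed")
  # an isolated single-point excursion is envelope noise, not "mixed"
  lone <- base; lone$g_obs[30] <- 1.5
  expect_equal(classify_pattern(lone)$classification, "random")
})

test_that("r beyond the half-width guard warns about quasi-1D behaviour", {
  w <- transect_window(500)
  p <- sim_poisson(w, 20, seed = 2)
  expect_warning(pcf(p, w, c(10, 100)), "one-dimensional")
  expect_silent(pcf(p, w, c(10, 20)))
})
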