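test_that("two points with distinct marks give I = -1 exactly", {
  p <- data.frame(x = c(0, 10), y = c(5, 5))
  cg <- moran_correlogram(p, c(20, 40), distance_bins(c(0, 100)),
                          low_support = 1)
  expect_identical(cg$I, -1)
  expect_equal(cg$n_pairs, 1L)
})

test_that("the correlogram matches a brute-force weight-matrix evaluation", {
  set.seed(11)
  p <- data.frame(x = runif(6, 0, 100), y = runif(6, 0, 50))
  mk <- rnorm(6, 30, 6)
  bins <- distance_bins(c(0, 40, 120))
  D <- as.matrix(dist(p)); z <- mk - mean(mk)
  brute <- sapply(1:2, function(k) {
    W <- (D > bins$lo[k] & D <= bins$hi[k]); diag(W) <- FALSE
    6 * sum(W * outer(z, z)) / (sum(W) * sum(z^2))
  })
  cg <- moran_correlogram(p, mk, bins, low_support = 1)
  expect_equal(cg$I, brute, tolerance = 1e-12)
  # marks equal to the x coordinate on a line: strong positive short-range I
  line <- data.frame(x = seq(0, 500, 100), y = 0)
  cgl <- moran_correlogram(line, line$x, distance_bins(c(0, 150)),
                           low_support = 1)
  expect_gt(cgl$I[1], 0)
})

test_that("the permutation null of I has mean -1/(N-1)", {
  set.seed(3)
  p <- data.frame(x = runif(30, 0, 500), y = runif(30, 0, 50))
  z0 <- rnorm(30)
  bins <- distance_bins(c(0, 100, 600))
  Is <- replicate(2000, moran_correlogram(p, sample(z0), bins,
                                          low_support = 1)$I)
  se <- apply(Is, 1, sd) / sqrt(2000)
  expect_true(all(abs(rowMeans(Is) + 1 / 29) < 4 * se + 1e-12))
  # and the envelope function reports the same permutation mean
  env <- mark_permutation_envelope(p, z0, bins, n_perm = 999, seed = 5)
  expect_true(all(abs(env$perm_mean + 1 / 29) < 0.02))
  expect_true(all(env$env_lo <= env$env_hi))
})

test_that("I is invariant to positive affine mark transforms", {
  bins <- distance_bins(seq(0, 400, 100))
  for (seed in 1:3) {
    set.seed(seed)
    p <- data.frame(x = runif(40, 0, 800), y = runif(40, 0, 50))
    m <- rlnorm(40, 3, 0.4)
    i0 <- moran_correlogram(p, m, bins)$I
    i1 <- moran_correlogram(p, 2.5 * m + 7, bins)$I
    expect_equal(i1, i0, tolerance = 1e-12)
    p2 <- data.frame(x = runif(30, 0, 800), y = runif(30, 0, 50))
    m2 <- rlnorm(30, 3, 0.4)
    expect_equal(intertype_moran(p, 3 * m + 1, p2, 0.5 * m2 + 2, bins)$I12,
                 intertype_moran(p, m, p2, m2, bins)$I12, tolerance = 1e-12)
  }
})

test_that("intertype I of a species against its own copy collapses to Eq-2 I", {
  # divisor-N sigmas make the identity exact for every bins configuration
  configs <- list(distance_bins(seq(0, 1000, 100)),
                  distance_bins(c(0, 50, 200, 800)),
                  distance_bins(seq(0, 400, 40)))
  for (seed in 1:3) {
    set.seed(seed)
    p <- data.frame(x = runif(150, 0, 3000), y = runif(150, 0, 50))
    m <- rlnorm(150, log(30), 0.4)
    for (b in configs) {
      expect_equal(intertype_moran(p, m, p, m, b)$I12,
                   moran_correlogram(p, m, b)$I,
                   tolerance = 1e-10)
    }
  }
})

test_that("negating the copied marks flips the intertype sign", {
  set.seed(5)
  p <- data.frame(x = runif(60, 0, 1000), y = runif(60, 0, 50))
  m <- rnorm(60, 30, 5)
  b <- distance_bins(seq(0, 600, 200))
  expect_equal(intertype_moran(p, m, p, -m, b)$I12,
               -moran_correlogram(p, m, b)$I, tolerance = 1e-10)
})

test_that("independent marks stay inside the intertype envelope almost always", {
  set.seed(17)
  p1 <- data.frame(x = runif(60, 0, 1500), y = runif(60, 0, 50))
  p2 <- data.frame(x = runif(60, 0, 1500), y = runif(60, 0, 50))
  b <- distance_bins(seq(0, 1000, 200))
  hits <- replicate(10, {
    m1 <- rnorm(60); m2 <- rnorm(60)
    it <- intertype_moran(p1, m1, p2, m2, b)
    env <- intertype_envelope(p1, m1, p2, m2, b, n_perm = 199,
                              seed = sample.int(1e6, 1))
    mean(it$I12 >= env$env_lo & it$I12 <= env$env_hi, na.rm = TRUE)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate correlogram inputs error or flag as specified", {
  p <- data.frame(x = 1:5, y = rep(0, 5))
  expect_error(moran_correlogram(p, rep(3, 5), distance_bins(c(0, 10))),
               "variance")
  expect_warning(
    cg <- moran_correlogram(p, rnorm(5), distance_bins(c(0, 0.5, 10))),
    "without pairs")
  expect_true(is.na(cg$I[1]))
  expect_true(all(cg$low_support))
  expect_error(intertype_moran(p, rep(1, 5), p, rnorm(5),
                               distance_bins(c(0, 10))), "variance")
})

test_that("the Mantel test matches exhaustive enumeration at n = 5", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  set.seed(23)
  p <- matrix(runif(10), 5, 2)
  A <- as.matrix(dist(p))
  B <- as.matrix(dist(matrix(runif(10), 5, 2)))
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  allp <- perms(1:5)
  exact <- mean(vapply(allp, function(idx)
    abs(cor(A[ut], B[idx, idx][ut])) >= abs(r_obs), logical(1)))
  mt <- mantel_test(A, B, n_perm = 999, seed = 7)
  expect_equal(mt$r, r_obs)
  expect_lt(abs(mt$p - exact), 0.1)
  # identical matrices: perfect correlation at the smallest achievable p
  mt1 <- mantel_test(A, A, n_perm = 999, seed = 1)
  expect_equal(mt1$r, 1)
  expect_lte(mt1$p, 5 / 120 + 0.05)   # ties of the 5-point orbit
  expect_error(mantel_test(matrix(1, 4, 4), A[1:4, 1:4]), "constant")
})

test_that("the diameter Mantel summary matches its direct formula", {
  p <- data.frame(x = c(0, 30, 70, 200), y = c(0, 10, 40, 20))
  m <- c(20, 22, 35, 60)
  z <- (m - mean(m)) / sd(m)
  D <- as.matrix(dist(p))
  ut <- upper.tri(D)
  r_direct <- cor(outer(z, z)[ut], log(D)[ut])
  mt <- dbh_mantel(p, m, n_perm = 199, seed = 3)
  expect_equal(mt$r, r_direct, tolerance = 1e-12)
  expect_true(mt$p > 0 && mt$p <= 1)
  # coincident points trigger the offset warning
  p2 <- rbind(p, p[1, ])
  expect_warning(dbh_mantel(p2, c(m, 21), n_perm = 99, seed = 1), "offset")
})

test_that("cohort-marked patterns give negative distance decay of similarity", {
  w <- desk_window()
  com <- gen_community(scenario_preset("h1", w, seed = 2))
  s1 <- com$stems[com$stems$species == "MUSCE", ]
  mt <- dbh_mantel(s1[, c("x", "y")], s1$dbh, n_perm = 199, seed = 5)
  expect_lt(mt$r, 0)
  expect_lt(mt$p, 0.05)
})

test_that("moran_analysis bundles correlogram, envelope and Mantel reproducibly", {
  set.seed(9)
  p <- data.frame(x = runif(50, 0, 1000), y = runif(50, 0, 50))
  m <- rlnorm(50, log(30), 0.3)
  b <- distance_bins(seq(0, 600, 200))
  r1 <- moran_analysis(p, m, b, n_perm = 199, seed = 77)
  r2 <- moran_analysis(p, m, b, n_perm = 199, seed = 77)
  expect_identical(r1$env_hi, r2$env_hi)
  expect_identical(attr(r1, "mantel_p"), attr(r2, "mantel_p"))
  expect_true(all(c("I", "env_lo", "env_hi", "significant") %in% names(r1)))
})
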