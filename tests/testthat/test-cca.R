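rand_community <- function(seed, n = 15, m = 6) {
  set.seed(seed)
  Y <- matrix(rpois(n * m, 4), n, m,
              dimnames = list(paste0("s", 1:n), paste0("sp", 1:m)))
  env <- data.frame(subplot_id = paste0("s", 1:n), a = rnorm(n), b = runif(n),
                    topo = sample(c("flat", "slope", "crest"), n, TRUE),
                    stringsAsFactors = FALSE)
  list(Y = Y, env = env)
}

test_that("constrained plus residual inertia equals total on random tables", {
  for (seed in 1:10) {
    d <- rand_community(seed)
    f <- fit_cca(d$Y, d$env, terms = c("a", "b", "topo"))
    expect_lt(abs(f$constrained_inertia + f$unconstrained_inertia -
                    f$total_inertia), 1e-8)
    expect_equal(f$proportion_constrained,
                 f$constrained_inertia / f$total_inertia)
    expect_true(all(f$eig_constrained >= 0))
    expect_true(all(diff(f$eig_constrained) <= 1e-12))
  }
})

test_that("a 4x3 toy fit matches a longhand brute-force eigensolution", {
  Y <- matrix(c(5, 0, 2, 1,
                1, 3, 0, 4,
                2, 2, 6, 1), 4, 3,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  x <- c(0.1, 0.9, 0.4, 0.7)
  env <- data.frame(subplot_id = paste0("s", 1:4), x = x)
  # brute force: explicit matrix construction and a dense eigensolver
  tot <- sum(Y); P <- Y / tot
  r <- rowSums(P); cc <- colSums(P)
  Q <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:3)
    Q[i, j] <- (P[i, j] - r[i] * cc[j]) / sqrt(r[i] * cc[j])
  xc <- x - sum(r * x)
  xw <- sqrt(r) * xc
  proj <- (xw %*% t(xw)) / sum(xw^2)
  Qhat <- proj %*% Q
  ev <- eigen(t(Qhat) %*% Qhat, symmetric = TRUE)$values
  f <- fit_cca(Y, env, terms = "x")
  expect_equal(f$eig_constrained, ev[1], tolerance = 1e-8)
  expect_equal(f$constrained_inertia, sum(Qhat^2), tolerance = 1e-10)
  expect_equal(f$total_inertia, sum(Q^2), tolerance = 1e-12)
})

test_that("the fit reproduces an independent CCA implementation", {
  d <- rand_community(9, n = 12)
  f <- fit_cca(d$Y, d$env, terms = c("a", "b", "topo"))
  v <- vegan::cca(d$Y ~ a + b + topo, data = d$env)
  expect_equal(f$eig_constrained, unname(v$CCA$eig), tolerance = 1e-10)
  expect_equal(f$total_inertia, unname(v$tot.chi), tolerance = 1e-10)
  expect_equal(f$proportion_constrained,
               unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-10)
  expect_equal(sort(f$eig_unconstrained, decreasing = TRUE),
               unname(v$CA$eig), tolerance = 1e-10)
})

test_that("degenerate designs give the algebraic limits", {
  d <- rand_community(4)
  # constant predictor: nothing constrained
  d$env$const <- 1
  expect_warning(f0 <- fit_cca(d$Y, d$env, terms = "const"), "collinear")
  expect_equal(f0$constrained_inertia, 0)
  expect_equal(f0$proportion_constrained, 0)
  # saturated design (site indicators): everything constrained, CCA = CA
  sat <- data.frame(subplot_id = d$env$subplot_id,
                    site = factor(d$env$subplot_id))
  fs <- fit_cca(d$Y, sat, terms = "site")
  expect_equal(fs$proportion_constrained, 1, tolerance = 1e-10)
  ca_eig <- unname(vegan::cca(d$Y)$CA$eig)
  expect_equal(fs$eig_constrained, ca_eig, tolerance = 1e-8)
})

test_that("scores reproduce the eigenvalues through weighted cross-products", {
  d <- rand_community(6)
  f <- fit_cca(d$Y, d$env, terms = c("a", "b"))
  lhs <- t(sqrt(f$r) * f$site_scores) %*% f$Q %*% (sqrt(f$c) * f$species_scores)
  expect_equal(diag(lhs), f$eig_constrained, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("empty rows and species columns are dropped with a record", {
  d <- rand_community(2)
  d$Y[3, ] <- 0; d$Y[, 2] <- 0
  f <- fit_cca(d$Y, d$env, terms = c("a", "b"))
  expect_equal(f$dropped_rows, 1)
  expect_equal(f$dropped_cols, 1)
  expect_equal(f$n, 14)
})

test_that("permutation tests calibrate under the null and keep joint-relabeling invariance", {
  set.seed(42)
  ps <- replicate(60, {
    Y <- matrix(rpois(30 * 5, 5), 30, 5)
    env <- data.frame(a = rnorm(30), b = rnorm(30))
    f <- fit_cca(Y, env, terms = c("a", "b"))
    c(anova_cca(f, n_perm = 99, seed = sample.int(1e6, 1), scope = "model")$p_perm,
      anova_cca(f, n_perm = 99, seed = sample.int(1e6, 1), scope = "margin")$p_perm[1])
  })
  expect_gt(mean(ps[1, ]), 0.35); expect_lt(mean(ps[1, ]), 0.65)
  expect_gt(mean(ps[2, ]), 0.35); expect_lt(mean(ps[2, ]), 0.65)
  # permuting rows of Y and X jointly leaves the pseudo-F unchanged
  d <- rand_community(8, n = 20)
  f1 <- fit_cca(d$Y, d$env, terms = c("a", "b"))
  idx <- sample(20)
  f2 <- fit_cca(d$Y[idx, ], d$env[idx, , drop = FALSE], terms = c("a", "b"))
  expect_equal(anova_cca(f1, n_perm = 49, seed = 1, "model")$pseudo_F,
               anova_cca(f2, n_perm = 49, seed = 1, "model")$pseudo_F,
               tolerance = 1e-10)
})

test_that("a strong gradient term is highly significant and axes are tested", {
  set.seed(13)
  grad <- seq(-1, 1, length.out = 40)
  Y <- sapply(1:8, function(k)
    rpois(40, exp(1.5 + (k %% 2 * 2 - 1) * 1.5 * grad)))
  env <- data.frame(driver = grad, noise = rnorm(40))
  f <- fit_cca(Y, env, terms = c("driver", "noise"))
  mg <- anova_cca(f, n_perm = 999, seed = 4, scope = "margin")
  expect_lte(mg$p_perm[mg$term == "driver"], 0.005)
  ax <- anova_cca(f, n_perm = 199, seed = 4, scope = "axes")
  expect_equal(nrow(ax), length(f$eig_constrained))
  expect_lte(ax$p_perm[1], 0.05)
})

test_that("backward elimination prunes noise and keeps true drivers", {
  # pure-noise designs collapse to the intercept-only model
  set.seed(42)
  gone <- mean(replicate(50, {
    Y <- matrix(rpois(50 * 16, 5), 50, 16)
    env <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
    length(backward_select(Y, env, terms = c("a", "b", "c"))$terms) == 0
  }))
  expect_gte(gone, 0.9)
  # a real gradient survives selection
  set.seed(7)
  kept <- mean(replicate(30, {
    grad <- seq(-1, 1, length.out = 50)
    Y <- sapply(1:10, function(k)
      rpois(50, exp(1 + (k %% 2 * 2 - 1) * 1.2 * grad)))
    env <- data.frame(driver = grad + rnorm(50, 0, 0.1), noise = rnorm(50))
    "driver" %in% backward_select(Y, env, terms = c("driver", "noise"))$terms
  }))
  expect_gte(kept, 0.9)
  # single-term design: trace has at most two rows
  d <- rand_community(3)
  tr <- backward_select(d$Y, d$env, terms = "a")$trace
  expect_lte(nrow(tr), 2)
})

test_that("variance shares behave in the orthogonal and single-term limits", {
  d <- rand_community(5, n = 20)
  f1 <- fit_cca(d$Y, d$env, terms = "a")
  vd1 <- variance_decomposition(f1)
  expect_equal(vd1$share_raw_pct, 100, tolerance = 1e-8)
  # predictors orthogonalized in the row-weight metric partition the
  # constrained inertia exactly
  r <- rowSums(d$Y / sum(d$Y))
  a <- d$env$a - sum(r * d$env$a) / sum(r)
  b0 <- d$env$b - sum(r * d$env$b) / sum(r)
  b <- b0 - a * sum(r * a * b0) / sum(r * a^2)
  env2 <- data.frame(subplot_id = d$env$subplot_id, a = a, b = b)
  f2 <- fit_cca(d$Y, env2, terms = c("a", "b"))
  vd2 <- variance_decomposition(f2)
  expect_equal(sum(vd2$share_raw_pct), 100, tolerance = 1e-6)
  expect_equal(sum(vd2$chi_square), f2$constrained_inertia, tolerance = 1e-10)
})

test_that("removing the water-affine reference species collapses the constrained share", {
  w <- desk_window()
  com <- gen_community(scenario_preset("h3", w, seed = 4))
  Y <- tabulate_abundance(com$stems, make_subplots(w), "species")
  cmp <- compare_with_without(Y, com$env, "GILBE")
  expect_gt(cmp$proportion_with, cmp$proportion_without)
  expect_gt(cmp$delta, 0.02)
  vd <- variance_decomposition(cmp$fit_with)
  expect_equal(vd$term[which.max(vd$chi_square)], "dist_water_m")
  expect_error(compare_with_without(Y, com$env, "NOPE"), "NOPE")
  # removing a species with no environmental ties barely moves the share
  cmp0 <- compare_with_without(Y, com$env, "PETER")
  expect_lt(abs(cmp0$delta), 0.05)
})
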