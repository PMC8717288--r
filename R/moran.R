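# Distance-class Moran's I correlograms of stem diameter, the intertype
# (cross-species) variant, mark-permutation envelopes and Mantel tests.

#' Distance classes for correlograms
#'
#' Non-overlapping half-open classes `(lo, hi]` defined by a strictly
#' increasing edge sequence starting at 0. The default emulates classes with
#' upper distances 100, 200, ..., 4000 m.
#'
#' @param edges increasing numeric vector of class edges (m), starting at 0.
#' @return object of class `distance_bins`: data frame with `lo`, `hi`.
#' @export
distance_bins <- function(edges = seq(0, 4000, by = 100)) {
  stopifnot(length(edges) >= 2, edges[1] == 0, all(diff(edges) > 0))
  structure(data.frame(lo = edges[-length(edges)], hi = edges[-1]),
            class = c("distance_bins", "data.frame"), edges = edges)
}

# class index of each unordered pair: k such that d in (edges[k], edges[k+1]],
# 0 when d is outside every class (including coincident points, d = 0).
# Pair enumeration follows dist() ordering (lower triangle, column-major).
pair_classes <- function(points, bins) {
  n <- nrow(points)
  d <- as.vector(stats::dist(cbind(points$x, points$y)))
  edges <- attr(bins, "edges")
  cls <- findInterval(d, edges, left.open = TRUE)
  cls[cls >= length(edges)] <- 0L   # beyond the last edge
  j <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  i <- sequence(rev(seq_len(n - 1L))) + j
  list(d = d, cls = cls, pairs = cbind(i = i, j = j))
}

# I(c) for all classes given centered marks z and a pair-class structure.
# Over ordered pairs, I(c) = N * sum_{pairs in c} z_i z_j / (n_c * sum z^2);
# unordered sums cancel the factor 2.
moran_from_pairs <- function(z, pc, n_classes) {
  s2 <- sum(z^2)
  I <- rep(NA_real_, n_classes); np <- integer(n_classes)
  prod_z <- z[pc$pairs[, 1]] * z[pc$pairs[, 2]]
  for (c in seq_len(n_classes)) {
    in_c <- pc$cls == c
    np[c] <- sum(in_c)
    if (np[c] > 0) I[c] <- length(z) * sum(prod_z[in_c]) / (np[c] * s2)
  }
  list(I = I, n_pairs = np)
}

#' Moran's I correlogram of a mark
#'
#' For each distance class `c`, computes
#' `I(c) = N / sum(w_ij) * sum_{i != j} w_ij (m_i - mbar)(m_j - mbar) / sum_i (m_i - mbar)^2`
#' with `w_ij = 1` when the pair distance falls in `(c_lo, c_hi]`. Positive
#' `I(c)` means stems separated by distances in class `c` carry more similar
#' marks (diameters) than random pairs — the cohort signature of a one-time
#' disturbance when seen at short distances. The randomization expectation of
#' `I` is `-1/(N-1)`.
#'
#' @param points data frame with `x`, `y` (metres).
#' @param marks numeric marks (dbh in cm, or standardized dbh), one per point.
#' @param bins a [distance_bins].
#' @param low_support minimum pair count per class below which the class is
#'   flagged (variance of I explodes with few pairs).
#' @return data frame of class `moran_correlogram`: `lo`, `hi`, `I`,
#'   `n_pairs`, `low_support`; classes without pairs get `NA` with a warning.
#' @export
moran_correlogram <- function(points, marks, bins = distance_bins(),
                              low_support = 30) {
  n <- nrow(points)
  stopifnot(length(marks) == n)
  if (n < 2) stop("need at least 2 points")
  z <- marks - mean(marks)
  if (sum(z^2) == 0) stop("zero mark variance: Moran's I undefined")
  pc <- pair_classes(points, bins)
  mi <- moran_from_pairs(z, pc, nrow(bins))
  if (anyNA(mi$I))
    warning(sum(is.na(mi$I)), " distance class(es) without pairs: I = NA")
  structure(
    data.frame(lo = bins$lo, hi = bins$hi, I = mi$I, n_pairs = mi$n_pairs,
               low_support = mi$n_pairs < low_support),
    class = c("moran_correlogram", "data.frame"), n = n)
}

#' Intertype Moran's I between two species
#'
#' Cross-species analog of the Moran correlogram: each species' diameters are
#' standardized by its own mean and standard deviation (divisor `N`, the
#' maximum-likelihood form), and
#' `I12(c) = sum_{i in 1} sum_{j in 2} w_ij z1_i z2_j / (sigma1 sigma2 sum w_ij)`
#' over cross pairs whose distance falls in class `c`. Positive values mean
#' that nearby stems of the two species deviate from their respective species
#' means in the same direction. With the divisor-`N` standard deviation, a
#' species compared against an exact copy of itself recovers the ordinary
#' Moran correlogram exactly (coincident self-pairs have distance 0 and fall
#' in no `(lo, hi]` class).
#'
#' @param points1,points2 data frames with `x`, `y` for each species.
#' @param marks1,marks2 numeric marks for each species.
#' @param bins a [distance_bins].
#' @return data frame `lo`, `hi`, `I12`, `n_pairs` (`NA` where a class holds
#'   no cross pair).
#' @export
intertype_moran <- function(points1, marks1, points2, marks2,
                            bins = distance_bins()) {
  n1 <- nrow(points1); n2 <- nrow(points2)
  stopifnot(length(marks1) == n1, length(marks2) == n2, n1 >= 2, n2 >= 2)
  z1 <- marks1 - mean(marks1); z2 <- marks2 - mean(marks2)
  s1 <- sqrt(mean(z1^2)); s2 <- sqrt(mean(z2^2))
  if (s1 == 0 || s2 == 0) stop("zero mark variance: intertype I undefined")
  d <- sqrt(outer(points1$x, points2$x, "-")^2 +
              outer(points1$y, points2$y, "-")^2)
  edges <- attr(bins, "edges")
  cls <- findInterval(d, edges, left.open = TRUE)
  cls[cls >= length(edges)] <- 0L
  zz <- outer(z1, z2)
  I12 <- rep(NA_real_, nrow(bins)); np <- integer(nrow(bins))
  for (c in seq_len(nrow(bins))) {
    in_c <- cls == c
    np[c] <- sum(in_c)
    if (np[c] > 0) I12[c] <- sum(zz[in_c]) / (s1 * s2 * np[c])
  }
  data.frame(lo = bins$lo, hi = bins$hi, I12 = I12, n_pairs = np)
}

#' Mark-permutation envelope for a Moran correlogram
#'
#' Permutes the marks over the fixed stem locations `n_perm` times and takes
#' pointwise quantiles of the permuted `I(c)` as the null envelope for "no
#' spatial structure in the marks".
#'
#' @inheritParams moran_correlogram
#' @param n_perm number of permutations (>= 99).
#' @param alpha two-sided envelope level.
#' @param seed integer seed.
#' @return data frame `lo`, `hi`, `env_lo`, `env_hi`, `perm_mean`.
#' @export
mark_permutation_envelope <- function(points, marks, bins = distance_bins(),
                                      n_perm = 999, alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 99)
  n <- nrow(points)
  z <- marks - mean(marks)
  if (sum(z^2) == 0) stop("zero mark variance")
  pc <- pair_classes(points, bins)
  n_classes <- nrow(bins)
  i1 <- pc$pairs[, 1]; i2 <- pc$pairs[, 2]
  by_class <- lapply(seq_len(n_classes), function(c) which(pc$cls == c))
  s2 <- sum(z^2)
  perm_I <- with_seed(seed, {
    out <- matrix(NA_real_, n_classes, n_perm)
    block <- 100L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      Z <- vapply(seq_len(b), function(k) z[sample.int(n)], numeric(n))
      P <- Z[i1, , drop = FALSE] * Z[i2, , drop = FALSE]
      for (c in seq_len(n_classes)) {
        idx <- by_class[[c]]
        if (length(idx))
          out[c, done + seq_len(b)] <-
            n * colSums(P[idx, , drop = FALSE]) / (length(idx) * s2)
      }
      done <- done + b
    }
    out
  })
  qs <- t(apply(perm_I, 1, function(v)
    if (all(is.na(v))) c(NA_real_, NA_real_)
    else stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                         type = 6)))
  data.frame(lo = bins$lo, hi = bins$hi, env_lo = qs[, 1], env_hi = qs[, 2],
             perm_mean = rowMeans(perm_I))
}

#' Permutation envelope for the intertype correlogram
#'
#' Each species' marks are permuted independently over its own locations.
#'
#' @inheritParams intertype_moran
#' @inheritParams mark_permutation_envelope
#' @return data frame `lo`, `hi`, `env_lo`, `env_hi`.
#' @export
intertype_envelope <- function(points1, marks1, points2, marks2,
                               bins = distance_bins(), n_perm = 999,
                               alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 99)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(k) {
      intertype_moran(points1, sample(marks1), points2, sample(marks2),
                      bins)$I12
    }, numeric(nrow(bins)))
    qs <- t(apply(perm, 1, function(v)
      if (all(is.na(v))) c(NA_real_, NA_real_)
      else stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                           na.rm = TRUE, type = 6)))
    data.frame(lo = bins$lo, hi = bins$hi, env_lo = qs[, 1], env_hi = qs[, 2])
  })
}

#' Mantel permutation test between two distance-like matrices
#'
#' Pearson correlation `r` of the upper-triangle entries (diagonals ignored),
#' with significance from joint row/column permutations of `B`. Two-sided on
#' `|r|`: `p = (1 + #{|r*| >= |r|}) / (1 + n_perm)`.
#'
#' @param A,B square symmetric numeric matrices of the same size.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = NULL) {
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)),
            nrow(A) == ncol(A))
  n <- nrow(A)
  ut <- upper.tri(A)
  a <- A[ut]
  if (stats::sd(a) == 0 || stats::sd(B[ut]) == 0)
    stop("constant matrix: Mantel correlation undefined")
  r_obs <- stats::cor(a, B[ut])
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      abs(stats::cor(a, B[idx, idx][ut])) >= abs(r_obs)
    }, logical(1)))
  })
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm))
}

#' Mantel test of diameter similarity against log distance
#'
#' Builds the pairwise mark-similarity matrix `I_ij = z_i z_j` (with
#' `z = (m - mbar)/sd`) and the `ln(d_ij)` matrix, and runs [mantel_test].
#' A negative correlation means diameter similarity decays with distance —
#' the correlogram-wide significance summary used alongside the Moran
#' correlograms. Coincident points get a 0.5 m offset before the log, with a
#' warning.
#'
#' @inheritParams moran_correlogram
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
dbh_mantel <- function(points, marks, n_perm = 999, seed = NULL) {
  n <- nrow(points)
  stopifnot(n >= 4, length(marks) == n)
  z <- (marks - mean(marks)) / stats::sd(marks)
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  if (any(D[upper.tri(D)] == 0)) {
    warning("coincident points: 0.5 m offset added before log")
    D <- D + 0.5
  }
  diag(D) <- 1  # ignored (diagonal excluded from the upper triangle)
  mantel_test(outer(z, z), log(D), n_perm = n_perm, seed = seed)
}

#' Full Moran correlogram analysis of a marked pattern
#'
#' Bundles the correlogram, its mark-permutation envelope and the Mantel
#' summary test into one result.
#'
#' @inheritParams mark_permutation_envelope
#' @return object of class `correlogram_result`: data frame `lo`, `hi`, `I`,
#'   `n_pairs`, `low_support`, `env_lo`, `env_hi`, `significant` (outside the
#'   envelope), with attributes `mantel_r`, `mantel_p`, `n`.
#' @export
moran_analysis <- function(points, marks, bins = distance_bins(),
                           n_perm = 999, alpha = 0.05, seed = NULL) {
  cg <- moran_correlogram(points, marks, bins)
  env <- mark_permutation_envelope(points, marks, bins, n_perm, alpha,
                                   seed = sub_seed(seed %||% 0, "envelope"))
  out <- cbind(cg, env[, c("env_lo", "env_hi")])
  out$significant <- !is.na(out$I) & (out$I > out$env_hi | out$I < out$env_lo)
  mt <- dbh_mantel(points, marks, n_perm = n_perm,
                   seed = sub_seed(seed %||% 0, "mantel"))
  structure(out, class = c("correlogram_result", class(cg)),
            mantel_r = mt$r, mantel_p = mt$p, n = attr(cg, "n"))
}

#' @export
print.correlogram_result <- function(x, ...) {
  cat(sprintf(
    "Moran correlogram: n = %d, %d classes, Mantel r = %.3f (p = %.4g)\n",
    attr(x, "n"), nrow(x), attr(x, "mantel_r"), attr(x, "mantel_p")))
  NextMethod()
}
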