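test_that("canonical_frame satisfies the defining identities", {
  # symmetric planar case
  R <- canonical_frame(c(-1, 1, 0), c(1, 1, 0))
  expect_equal(R, diag(3), tolerance = 1e-12)
  set.seed(10)
  for (r in 1:50) {
    v <- stats::rnorm(3); w <- stats::rnorm(3)
    if (sqrt(sum(rnaprecis:::cross3(v, w)^2)) < 1e-3) next
    R <- canonical_frame(v, w)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    vr <- crossprod(R, v); wr <- crossprod(R, w)
    expect_equal(vr[2], wr[2], tolerance = 1e-12)   # equal y-projection
    expect_gt(vr[2], 0)                             # positive
    expect_lt(abs(vr[3]), 1e-12)                    # in-plane
    expect_lt(abs(wr[3]), 1e-12)
    expect_gt(wr[1], vr[1])                         # later C1' has larger x
  }
  expect_error(canonical_frame(c(1, 0, 0), c(2, 0, 0)), "parallel|degenerate")
})

test_that("muccss_point reads off an identity configuration and matches direct formulas", {
  # landmarks pre-placed in the canonical frame with unit glycosidic bonds
  d2 <- 6; d3 <- 7; alpha <- 1.2
  v <- d2 * c(-sin(alpha / 2), cos(alpha / 2), 0)
  w <- d3 * c(sin(alpha / 2), cos(alpha / 2), 0)
  # symmetric v/w give frame = identity only when |v| = |w|; use direct checks
  L <- rbind(v + c(0, 0, 1), v, c(0, 0, 0), w, w + c(1, 0, 0))
  W <- muccss_point(L)
  expect_equal(W$d2, d2, tolerance = 1e-12)
  expect_equal(W$d3, d3, tolerance = 1e-12)
  expect_equal(W$alpha, acos(sum(v * w) / (d2 * d3)), tolerance = 1e-12)
  expect_equal(sqrt(sum(W$s1^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(W$s2^2)), 1, tolerance = 1e-12)

  # direct pairwise-distance/angle oracle on a built suite
  s <- suite_landmarks(build_cartesian(aform_torsions(), "P33"))
  L <- s$landmarks[[1]]
  W <- muccss_point(L)
  expect_equal(W$d2, sqrt(sum((L[2, ] - L[3, ])^2)), tolerance = 1e-12)
  expect_equal(W$d3, sqrt(sum((L[4, ] - L[3, ])^2)), tolerance = 1e-12)
  vv <- L[2, ] - L[3, ]; ww <- L[4, ] - L[3, ]
  expect_equal(W$alpha, acos(sum(vv * ww) / sqrt(sum(vv^2) * sum(ww^2))),
               tolerance = 1e-12)
})

test_that("muccss coordinates are invariant under rigid motions", {
  s <- suite_landmarks(build_cartesian(aform_torsions(), "P33"))
  W0 <- muccss_point(s$landmarks[[1]])
  set.seed(11)
  for (r in 1:100) {
    R <- rnaprecis:::random_rotation()
    tr <- stats::runif(3, -10, 10)
    L2 <- t(apply(s$landmarks[[1]], 1, function(p) as.numeric(R %*% p + tr)))
    W2 <- muccss_point(L2)
    expect_lt(muccss_distance(W0, W2), 1e-9)
  }
})

test_that("muccss_distance is a metric with the expected factor behaviour", {
  W <- random_muccss()
  expect_equal(muccss_distance(W, W), 0)
  W2 <- W; W2$d2 <- W$d2 + 0.3
  expect_equal(muccss_distance(W, W2), 0.3, tolerance = 1e-12)
  # orthogonal glycosidic directions differ by a quarter great circle
  W3 <- rnaprecis:::new_muccss(W$d2, W$d3, W$alpha,
                               c(1, 0, 0), W$s2)
  W4 <- rnaprecis:::new_muccss(W$d2, W$d3, W$alpha,
                               c(0, 1, 0), W$s2)
  expect_equal(muccss_distance(W3, W4), pi / 2, tolerance = 1e-12)
  # metric axioms on random triples
  set.seed(12)
  for (r in 1:1000) {
    a <- random_muccss(); b <- random_muccss(); c <- random_muccss()
    dab <- muccss_distance(a, b); dba <- muccss_distance(b, a)
    expect_lt(abs(dab - dba), 1e-9)
    expect_gte(dab, 0)
    expect_lte(dab, muccss_distance(a, c) + muccss_distance(c, b) + 1e-9)
  }
})

test_that("frechet_mean: identity, geodesic midpoint, local optimality", {
  W <- random_muccss()
  expect_equal(frechet_mean(list(W)), W)
  # two points differing only in s1 by a 20 degree arc -> midpoint
  th <- 10 * pi / 180
  Wa <- rnaprecis:::new_muccss(6, 6, 1.5, c(sin(-th), 0, cos(-th)), c(0, 0, 1))
  Wb <- rnaprecis:::new_muccss(6, 6, 1.5, c(sin(th), 0, cos(th)), c(0, 0, 1))
  m <- frechet_mean(list(Wa, Wb))
  expect_lt(sum(abs(m$s1 - c(0, 0, 1))), 1e-9)
  # local-optimality brute force on random clusters
  set.seed(13)
  for (r in 1:20) {
    cl <- muccss_cluster(30)
    m <- frechet_mean(cl)
    f0 <- frechet_value_at(m, cl)
    for (step in c(1e-3, 1e-2, 5e-2)) {
      for (coord in c("d2", "d3", "alpha")) {
        for (sgn in c(-1, 1)) {
          mp <- m; mp[[coord]] <- mp[[coord]] + sgn * step
          expect_gte(frechet_value_at(mp, cl), f0 - 1e-12)
        }
      }
      for (snm in c("s1", "s2")) {
        B <- rnaprecis:::tangent_basis(m[[snm]])
        for (k in 1:2) for (sgn in c(-1, 1)) {
          mp <- m
          mp[[snm]] <- rnaprecis:::sphere_exp(m[[snm]], sgn * step * B[, k])
          expect_gte(frechet_value_at(mp, cl), f0 - 1e-12)
        }
      }
    }
  }
  expect_error(frechet_mean(list()), "empty")
})

test_that("tangent coordinates: base maps to zero, flat factors pass through, projection norm", {
  base <- random_muccss()
  expect_equal(tangent_coords(base, base), rep(0, 7), tolerance = 1e-12)
  W <- base; W$alpha <- base$alpha + 0.1
  expect_equal(tangent_coords(W, base), c(0, 0, 0.1, 0, 0, 0, 0),
               tolerance = 1e-12)
  expect_length(tangent_coords(W, base), 7)
  # |s~| equals the norm of the orthogonal projection of s onto the plane
  # perpendicular to the base direction
  set.seed(14)
  for (r in 1:50) {
    base <- random_muccss()
    w <- base
    w$s1 <- base$s1 + stats::rnorm(3, 0, 0.2)
    w$s1 <- w$s1 / sqrt(sum(w$s1^2))
    t7 <- tangent_coords(w, base)
    proj <- w$s1 - base$s1 * sum(w$s1 * base$s1)
    expect_lt(abs(sqrt(sum(t7[4:5]^2)) - sqrt(sum(proj^2))), 1e-12)
  }
  # hemisphere violation
  far <- base; far$s1 <- -base$s1
  expect_error(tangent_coords(far, base), "hemisphere")
})

test_that("tangent_covariance matches the direct outer-product sum", {
  base <- random_muccss()
  expect_equal(tangent_covariance(list(base, base, base), base),
               matrix(0, 7, 7))
  # variation in d2 alone
  set.seed(15)
  d2s <- stats::rnorm(20, 6, 0.3)
  samples <- lapply(d2s, function(d) {
    w <- base; w$d2 <- d; w
  })
  S <- tangent_covariance(samples, base)
  direct <- sum((d2s - base$d2)^2) / 19
  expect_equal(S[1, 1], direct, tolerance = 1e-12)
  expect_equal(sum(abs(S)) - abs(S[1, 1]), 0, tolerance = 1e-12)
  # full random sample vs direct summation
  cl <- muccss_cluster(25)
  m <- frechet_mean(cl)
  S <- tangent_covariance(cl, m)
  TT <- sapply(cl, tangent_coords, base = m)
  expect_equal(S, tcrossprod(TT) / 24, tolerance = 1e-12)
  expect_true(isSymmetric(S))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  expect_error(tangent_covariance(list(base), base), "two")
})

test_that("frechet_mean recovers the generating mean on noisy clusters", {
  set.seed(16)
  for (r in 1:20) {
    spread <- 0.05
    base <- random_muccss()
    cl <- lapply(1:100, function(i) {
      jd <- function(s) {
        v <- s + stats::rnorm(3, 0, spread)
        v / sqrt(sum(v^2))
      }
      rnaprecis:::new_muccss(base$d2 + stats::rnorm(1, 0, spread),
                             base$d3 + stats::rnorm(1, 0, spread),
                             base$alpha + stats::rnorm(1, 0, spread / 2),
                             jd(base$s1), jd(base$s2))
    })
    m <- frechet_mean(cl)
    se <- spread / sqrt(100)
    expect_lt(abs(m$d2 - base$d2), 3 * se + 1e-9)
    expect_lt(abs(m$d3 - base$d3), 3 * se + 1e-9)
    # sphere part: the angular deviation pools two tangent dimensions, so its
    # standard error is spread * sqrt(2 / n)
    expect_lt(acos(min(1, sum(m$s1 * base$s1))),
              3 * spread * sqrt(2 / 100) + 1e-6)
  }
})
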