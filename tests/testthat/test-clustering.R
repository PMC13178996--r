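test_that("torus_distance wraps correctly and matches the unwrapping oracle", {
  expect_equal(torus_distance(rep(10, 7), rep(10, 7)), 0)
  t1 <- rep(0, 7); t2 <- rep(0, 7)
  t1[3] <- 350; t2[3] <- 10
  expect_equal(torus_distance(t1, t2), 20)
  # oracle: minimum flat Euclidean distance over all unwrapping shifts of b
  set.seed(20)
  shifts <- as.matrix(expand.grid(rep(list(c(-360, 0, 360)), 7)))
  for (r in 1:30) {
    a <- stats::runif(7, 0, 360); b <- stats::runif(7, 0, 360)
    want <- min(apply(shifts, 1, function(s) sqrt(sum((a - (b + s))^2))))
    expect_lt(abs(torus_distance(a, b) - want), 1e-9)
  }
  # metric axioms
  for (r in 1:200) {
    a <- stats::runif(7, 0, 360); b <- stats::runif(7, 0, 360)
    c <- stats::runif(7, 0, 360)
    expect_equal(torus_distance(a, b), torus_distance(b, a))
    expect_lte(torus_distance(a, b),
               torus_distance(a, c) + torus_distance(c, b) + 1e-9)
  }
})

test_that("average linkage matches a brute-force UPGMA oracle", {
  set.seed(21)
  ang <- matrix(stats::runif(20 * 7, 0, 360), 20)
  D <- torus_dist_matrix(ang)
  tree <- average_linkage_tree(ang)
  oracle <- brute_force_upgma(D)
  expect_equal(sort(tree$height), sort(oracle$heights), tolerance = 1e-9)
  coph <- as.matrix(stats::cophenetic(tree))
  dimnames(coph) <- NULL
  expect_equal(coph, oracle$cophenetic, tolerance = 1e-9)
  # near points merge first; duplicated points merge at height zero
  ang3 <- matrix(5, 3, 7); ang3[2, 1] <- 6; ang3[3, 1] <- 15
  t3 <- average_linkage_tree(ang3)
  expect_equal(sort(t3$merge[1, ]), c(-2, -1))
  dup <- rbind(ang[1, ], ang[1, ], ang[5, ])
  expect_equal(average_linkage_tree(dup)$height[1], 0)
})

test_that("age_cut separates blobs and flags isolated points", {
  set.seed(22)
  blob <- function(center, n, sigma = 5) {
    sapply(1:7, function(j) (stats::rnorm(n, center[j], sigma)) %% 360)
  }
  two <- rbind(blob(rep(50, 7), 30), blob(rep(50, 7) + c(90, 90, 0, 0, 0, 0, 0), 30))
  cut <- age_cut(average_linkage_tree(two), age_params(0.09, 3, 0.05))
  expect_length(cut$preclusters, 2)
  expect_length(cut$outliers, 0)
  expect_setequal(sort(unlist(cut$preclusters)), 1:60)

  one_plus_noise <- rbind(blob(rep(100, 7), 30),
                          matrix(c(rep(250, 7), rep(330, 7)), 2, 7, byrow = TRUE))
  cut2 <- suppressWarnings(
    age_cut(average_linkage_tree(one_plus_noise), age_params(0.09, 3, 0.05))
  )
  expect_length(cut2$preclusters, 1)
  expect_length(cut2$preclusters[[1]], 30)
  expect_equal(cut2$outliers, c(31L, 32L))
})

test_that("AGE defaults reproduce the per-pair tuning constants", {
  expect_equal(age_defaults("P33")$q, 0.09)
  expect_equal(age_defaults("P32")$q, 0.05)
  expect_equal(age_defaults("P23")$q, 0.07)
  expect_equal(age_defaults("P22")$q, 0.05)
  for (p in c("P33", "P32", "P23", "P22")) expect_equal(age_defaults(p)$kappa, 3)
})

test_that("principal circle scores capture a single varying coordinate", {
  set.seed(23)
  base <- rep(120, 7)
  ang <- matrix(base, 40, 7, byrow = TRUE)
  ang[, 4] <- (120 + stats::rnorm(40, 0, 15)) %% 360
  sc <- principal_circle_scores(ang)
  # scores reproduce the varying coordinate up to rotation/reflection
  u <- ((ang[, 4] - 120 + 180) %% 360) - 180
  su <- ((sc - rnaprecis:::circular_mean(sc) + 180) %% 360) - 180
  expect_gt(abs(stats::cor(u, su)), 1 - 1e-6)
  # global rotation of all angles leaves scores equal up to circle isometry
  ang2 <- (ang + 77) %% 360
  sc2 <- principal_circle_scores(ang2)
  su2 <- ((sc2 - rnaprecis:::circular_mean(sc2) + 180) %% 360) - 180
  expect_gt(abs(stats::cor(su, su2)), 1 - 1e-6)
  # a bimodal cluster produces clearly separated score groups
  angb <- matrix(base, 60, 7, byrow = TRUE)
  angb[, 2] <- c((80 + stats::rnorm(30, 0, 6)), (140 + stats::rnorm(30, 0, 6))) %% 360
  scb <- principal_circle_scores(angb)
  ub <- ((scb - rnaprecis:::circular_mean(scb) + 180) %% 360) - 180
  expect_gt(min(ub[31:60]) - max(ub[1:30]), 0) # groups do not interleave
})

test_that("mode_hunt_split keeps unimodal samples and splits bimodal ones", {
  # level: unimodal wrapped Gaussian retained in >= 90% of replicates
  keep <- 0
  for (r in 1:20) {
    set.seed(300 + r)
    x <- (stats::rnorm(50, 180, 10)) %% 360
    keep <- keep + (length(mode_hunt_split(x, 0.05, 200)) == 1)
  }
  expect_gte(keep, 18)
  # power: two wrapped Gaussians 90 degrees apart are split
  split <- 0
  for (r in 1:20) {
    set.seed(400 + r)
    x <- c(stats::rnorm(25, 120, 10), stats::rnorm(25, 210, 10)) %% 360
    split <- split + (length(mode_hunt_split(x, 0.05, 200)) >= 2)
  }
  expect_gte(split, 18)
  # very small samples: two tight pairs 120 degrees apart
  set.seed(42)
  x <- c(100, 100.5, 220, 220.5)
  parts <- mode_hunt_split(x, 0.05, 200)
  expect_length(parts, 2)
  expect_setequal(lengths(parts), c(2, 2))
})

test_that("mint_age recovers well-separated clusters including a small one", {
  set.seed(30)
  mix <- sample_torus_clusters(c(40, 40, 40, 4), sigma = 8)
  cl <- mint_age(mix$angles, age_params(0.09, 3, 0.011))
  expect_length(cl$clusters, 4)
  keep <- cl$assignment > 0
  expect_equal(adjusted_rand_index(mix$truth[keep], cl$assignment[keep]), 1)
  # every point is in exactly one cluster or the outlier set
  expect_setequal(c(unlist(cl$clusters), cl$outliers), seq_len(nrow(mix$angles)))
  # cluster labels are attached and numbering is by decreasing size
  sizes <- lengths(cl$clusters)
  expect_true(all(diff(sizes) <= 0))
})

test_that("clustering is invariant to point order and global torus rotation", {
  set.seed(31)
  mix <- sample_torus_clusters(c(20, 20), sigma = 5)
  cl1 <- mint_age(mix$angles, age_params(0.09, 3, 0.05))
  perm <- sample(nrow(mix$angles))
  cl2 <- mint_age(mix$angles[perm, ], age_params(0.09, 3, 0.05))
  expect_equal(adjusted_rand_index(cl1$assignment, cl2$assignment[order(perm)]), 1)
  cl3 <- mint_age((mix$angles + 123) %% 360, age_params(0.09, 3, 0.05))
  expect_equal(adjusted_rand_index(cl1$assignment, cl3$assignment), 1)
})
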