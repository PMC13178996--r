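# small trained model from synthetic clusters, one pucker pair
small_model <- function(lambda = 0.5, sizes = c(30, 30), seed = 50) {
  set.seed(seed)
  suites <- dplyr::bind_rows(lapply(seq_along(sizes), function(k) {
    pts <- muccss_cluster(sizes[k], spread = 0.05)
    tibble::tibble(
      structure_id = sprintf("m%d_%d", k, seq_len(sizes[k])),
      chain = "A", resnum = seq_len(sizes[k]), icode = "",
      pucker_pair = "P33", cluster = k, conformer = paste0(k, "a"),
      muccss = pts
    )
  }))
  precis_train(suites, lambda = lambda)
}

test_that("regularization endpoints behave as closed forms", {
  m1 <- small_model(lambda = 1)
  for (s in m1$clusters) {
    expect_equal(crossprod(s$RS_chol), s$cov, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  m0 <- small_model(lambda = 1e-12) # lambda -> 0 limit: RS = S1 throughout
  for (s in m0$clusters) {
    expect_equal(crossprod(s$RS_chol), m0$S1, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # default lambda is accepted and recorded
  md <- small_model()
  expect_equal(md$lambda, 0.5)
})

test_that("log posterior at the cluster mean reduces to prior and determinant terms", {
  m <- small_model()
  s <- m$clusters[[1]]
  lp <- rnaprecis:::log_unnorm_posterior(s$mean, s)
  expect_equal(lp$lp, log(s$n) - 0.5 * s$logdet_RS, tolerance = 1e-10)
  expect_equal(lp$maha, 0, tolerance = 1e-10)
})

test_that("identical clusters of sizes 30 and 3 give exact 10:1 posterior odds", {
  set.seed(51)
  pts <- muccss_cluster(30, spread = 0.05)
  suites <- tibble::tibble(
    structure_id = sprintf("s%d", 1:33), chain = "A", resnum = 1:33,
    icode = "", pucker_pair = "P33",
    cluster = rep(c(1L, 2L), c(30, 3)),
    conformer = rep(c("1a", "2a"), c(30, 3)),
    muccss = c(pts, pts[1:3])
  )
  # force identical means/covariances by training each cluster on the same
  # points, differing only in declared size
  model <- precis_train(suites, lambda = 0.5)
  model$clusters[[2]]$mean <- model$clusters[[1]]$mean
  model$clusters[[2]]$cov <- model$clusters[[1]]$cov
  model$clusters[[2]]$RS_chol <- model$clusters[[1]]$RS_chol
  model$clusters[[2]]$logdet_RS <- model$clusters[[1]]$logdet_RS
  for (r in 1:10) {
    w <- muccss_cluster(1, spread = 0.1)[[1]]
    w$s1 <- model$clusters[[1]]$mean$s1; w$s2 <- model$clusters[[1]]$mean$s2
    w$d2 <- model$clusters[[1]]$mean$d2 + stats::rnorm(1, 0, 0.1)
    lp1 <- rnaprecis:::log_unnorm_posterior(w, model$clusters[[1]])$lp
    lp2 <- rnaprecis:::log_unnorm_posterior(w, model$clusters[[2]])$lp
    expect_equal(exp(lp1 - lp2), 10, tolerance = 1e-9)
  }
})

test_that("log posterior matches a brute-force evaluation", {
  m <- small_model()
  set.seed(52)
  for (r in 1:50) {
    s <- m$clusters[[1 + r %% 2]]
    w <- s$mean
    w$d2 <- w$d2 + stats::rnorm(1, 0, 0.1)
    w$alpha <- w$alpha + stats::rnorm(1, 0, 0.05)
    got <- rnaprecis:::log_unnorm_posterior(w, s)$lp
    RS <- crossprod(s$RS_chol)
    t7 <- tangent_coords(w, s$mean)
    want <- log(s$n) - 0.5 * log(det(RS)) -
      0.5 * as.numeric(t7 %*% solve(RS) %*% t7)
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("shrinking a cluster's covariance increases the Mahalanobis term off-mean", {
  m <- small_model(lambda = 1)
  s <- m$clusters[[1]]
  w <- s$mean; w$d2 <- w$d2 + 0.2; w$d3 <- w$d3 - 0.1
  d_full <- rnaprecis:::log_unnorm_posterior(w, s)$maha
  s_shrunk <- s
  s_shrunk$RS_chol <- chol(0.5 * crossprod(s$RS_chol))
  s_shrunk$logdet_RS <- 2 * sum(log(diag(s_shrunk$RS_chol)))
  d_shrunk <- rnaprecis:::log_unnorm_posterior(w, s_shrunk)$maha
  expect_gt(d_shrunk, d_full)
})

test_that("posteriors are normalized and permutation-equivariant", {
  set.seed(53)
  cfg <- synthetic_config(pairs = "P33", n_clusters = 4, n_per_cluster = 25,
                          n_test_per_cluster = 4, sigma_noise = 8, seed = 60)
  gs <- sample_gold_standard(cfg)
  gs$train$cluster <- gs$train$true_cluster
  model <- precis_train(suite_muccss(suite_pucker_pair(gs$train, "HD") |>
                                       dplyr::mutate(pucker_pair = pucker_pair_HD)))
  preds <- predict(model, gs$test)
  for (rk in preds$ranking) {
    expect_lt(abs(sum(rk$posterior) - 1), 1e-12)
  }
  # permuting cluster order permutes posteriors identically
  model_perm <- model
  model_perm$clusters <- model$clusters[c(3, 1, 4, 2)]
  preds2 <- predict(model_perm, gs$test[1:5, ])
  for (i in 1:5) {
    a <- preds$ranking[[i]]; b <- preds2$ranking[[i]]
    expect_equal(a$posterior[order(a$cluster)], b$posterior[order(b$cluster)],
                 tolerance = 1e-12)
  }
})

test_that("held-out synthetic suites are assigned to their generating cluster", {
  cfg <- synthetic_config(pairs = "P33", n_clusters = 4, n_per_cluster = 40,
                          n_test_per_cluster = 50, sigma_noise = 8, seed = 61)
  gs <- sample_gold_standard(cfg)
  gs$train$cluster <- gs$train$true_cluster
  model <- precis_train(suite_muccss(suite_pucker_pair(gs$train, "HD") |>
                                       dplyr::mutate(pucker_pair = pucker_pair_HD)))
  preds <- predict(model, gs$test)
  label_of_truth <- paste0(gs$test$true_cluster, "a")
  hit <- mapply(function(pred, want) {
    !is.na(pred) && want %in% strsplit(pred, ";")[[1]]
  }, preds$predicted_conformers, label_of_truth)
  expect_gte(mean(hit), 0.95)
})

test_that("evaluation assigns the three categories as defined", {
  m <- small_model()
  # cluster 1 labelled "1a"; pretend it also contains "1b" (multi-label)
  m$clusters[[1]]$conformers <- c("1a", "1b")
  preds <- tibble::tibble(
    structure_id = c("x", "y", "z"), chain = "A", resnum = 1:3, icode = "",
    pucker_pair = c("P33", "P33", "P23"),
    best_cluster = c(1L, 1L, 1L),
    predicted_conformers = c("1a;1b", "1a;1b", "1a"),
    posterior = 1, mahalanobis = 0, ranking = list(NULL), note = NA_character_
  )
  manifest <- tibble::tibble(
    structure_id = c("x", "y", "z"), chain = "A", resnum = 1:3, icode = "",
    answer_conformer = c("1b", "2a", "6p"),
    answer_pucker_pair = c("P33", "P33", "P22")
  )
  ev <- precis_evaluate(preds, manifest, m)
  expect_equal(ev$records$category,
               c("prediction_match", "prediction_mismatch", "pucker_mismatch"))
  # an answer conformer absent from all clusters is flagged
  expect_true(ev$records$unclustered_answer[3])
  # multiple answers: any match counts
  manifest2 <- manifest[1, ]
  manifest2$answer_conformer <- "7z;1a"
  ev2 <- precis_evaluate(preds[1, ], manifest2, m)
  expect_equal(ev2$records$category, "prediction_match")
  # summary percentages add to 100
  sums <- ev$summary$match_pct + ev$summary$mismatch_pct +
    ev$summary$pucker_mismatch_pct
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("model JSON round-trips through write_model/read_model", {
  m <- small_model()
  tmp <- tempfile(fileext = ".json")
  write_model(m, tmp)
  m2 <- read_model(tmp)
  expect_equal(m2$lambda, m$lambda)
  expect_equal(length(m2$clusters), length(m$clusters))
  for (k in seq_along(m$clusters)) {
    expect_equal(m2$clusters[[k]]$cov, m$clusters[[k]]$cov, tolerance = 1e-12)
    expect_equal(m2$clusters[[k]]$mean$s1, m$clusters[[k]]$mean$s1,
                 tolerance = 1e-12)
    expect_equal(m2$clusters[[k]]$conformers, m$clusters[[k]]$conformers)
  }
  w <- m$clusters[[1]]$mean
  expect_equal(rnaprecis:::log_unnorm_posterior(w, m2$clusters[[1]])$lp,
               rnaprecis:::log_unnorm_posterior(w, m$clusters[[1]])$lp,
               tolerance = 1e-9)
})
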