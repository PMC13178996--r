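#' Train the low-detail conformer classifier
#'
#' Given training suites with cluster assignments (one clustering per pucker
#' pair, e.g. from [mint_age()]) and conformer labels, computes per cluster
#' the Frechet mean and tangent covariance of the low-detail MUCCSS
#' representation, regularizes every covariance towards the reference
#' covariance `S1` of the single largest P33 cluster,
#' `RS_i = lambda * S_i + (1 - lambda) * S1`, and checks positive
#' definiteness. Clusters with fewer than two members are trained with a zero
#' own covariance (pure regularizer) and a warning.
#'
#' @param suites Suite tibble with columns `pucker_pair`, `cluster`
#'   (integer, > 0) and `conformer`; MUCCSS coordinates are computed if
#'   absent.
#' @param lambda Regularization weight in (0, 1); 1 keeps each cluster's own
#'   covariance, 0 uses the reference alone.
#' @return Object of class `rnaprecis_model`.
#' @export
precis_train <- function(suites, lambda = 0.5) {
  stopifnot(lambda > 0 || lambda == 0, lambda <= 1)
  if (!"muccss" %in% names(suites)) suites <- suite_muccss(suites)
  stopifnot(all(c("pucker_pair", "cluster", "conformer") %in% names(suites)))
  suites <- suites[!is.na(suites$cluster) & suites$cluster > 0, ]
  groups <- split(seq_len(nrow(suites)),
                  paste(suites$pucker_pair, suites$cluster))
  summaries <- list()
  for (g in groups) {
    pair <- suites$pucker_pair[g[1]]
    idx <- suites$cluster[g[1]]
    pts <- suites$muccss[g]
    m <- frechet_mean(pts)
    S <- if (length(pts) >= 2) tangent_covariance(pts, m) else {
      warning(sprintf("cluster %s/%d has a single member; trained with zero covariance",
                      pair, idx), call. = FALSE)
      matrix(0, 7, 7)
    }
    summaries[[length(summaries) + 1]] <- list(
      pair = pair, cluster = idx, n = length(g), mean = m, cov = S,
      conformers = sort(unique(suites$conformer[g])),
      label_multiset = sort(suites$conformer[g])
    )
  }
  # reference covariance: the largest P33 cluster (the dominant helical class)
  p33 <- Filter(function(s) s$pair == "P33" && s$n >= 2, summaries)
  if (length(p33)) {
    S1 <- p33[[which.max(vapply(p33, `[[`, 0, "n"))]]$cov
  } else {
    warning("no P33 cluster with n >= 2; using the pooled covariance as reference",
            call. = FALSE)
    ok <- Filter(function(s) s$n >= 2, summaries)
    S1 <- Reduce(`+`, lapply(ok, function(s) s$cov * (s$n - 1))) /
      (sum(vapply(ok, `[[`, 0, "n")) - length(ok))
  }
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    RS <- lambda * s$cov + (1 - lambda) * S1
    ch <- tryCatch(chol(RS), error = function(e) NULL)
    if (is.null(ch)) {
      ev <- min(eigen(RS, symmetric = TRUE, only.values = TRUE)$values)
      stop(sprintf("regularized covariance of cluster %s/%d is not positive definite (min eigenvalue %.3e)",
                   s$pair, s$cluster, ev), call. = FALSE)
    }
    summaries[[i]]$RS_chol <- ch
    summaries[[i]]$logdet_RS <- 2 * sum(log(diag(ch)))
  }
  structure(list(clusters = summaries, lambda = lambda, S1 = S1),
            class = "rnaprecis_model")
}

#' @export
print.rnaprecis_model <- function(x, ...) {
  pairs <- table(vapply(x$clusters, `[[`, "", "pair"))
  cat(sprintf("rnaprecis model: %d clusters (%s), lambda = %.2f\n",
              length(x$clusters),
              paste(names(pairs), pairs, sep = ":", collapse = " "),
              x$lambda))
  invisible(x)
}

# log unnormalized posterior of one cluster summary at MUCCSS point w:
# log n_i - 1/2 log det RS_i - 1/2 * t' RS_i^{-1} t. Hemisphere failures
# return -Inf (the cluster is too far for this chart to apply).
log_unnorm_posterior <- function(w, summary) {
  t7 <- tryCatch(tangent_coords(w, summary$mean), error = function(e) NULL)
  if (is.null(t7)) return(list(lp = -Inf, maha = Inf))
  z <- backsolve(summary$RS_chol, t7, transpose = TRUE)
  maha2 <- sum(z^2)
  list(lp = log(summary$n) - 0.5 * summary$logdet_RS - 0.5 * maha2,
       maha = sqrt(maha2))
}

#' Predict conformer clusters for low-detail suites
#'
#' For each suite: gate by the Pperp pucker pair, evaluate the regularized
#' Gaussian log-posteriors of all clusters of that pair, normalize them on
#' the log scale (softmax with maximum subtraction) and return the ranked
#' result. Suites without the next-in-sequence phosphorus cannot be gated and
#' are returned with `NA` predictions.
#'
#' @param object A fitted `rnaprecis_model`.
#' @param suites Suite tibble (only the five landmarks plus the following
#'   phosphorus are needed).
#' @param ... Unused.
#' @return Tibble: suite identifiers, `pucker_pair`, `best_cluster`,
#'   `predicted_conformers` (semicolon-joined), `posterior` (of the best
#'   cluster), `mahalanobis` (of the best cluster), and a list-column
#'   `ranking` with the per-cluster table.
#' @export
predict.rnaprecis_model <- function(object, suites, ...) {
  if (!"muccss" %in% names(suites)) suites <- suite_muccss(suites)
  gate <- if ("pucker_pair_LD" %in% names(suites)) suites$pucker_pair_LD else
    suite_pucker_pair(suites, "LD")$pucker_pair_LD
  by_pair <- split(seq_along(object$clusters),
                   vapply(object$clusters, `[[`, "", "pair"))
  rows <- vector("list", nrow(suites))
  for (i in seq_len(nrow(suites))) {
    pair <- gate[i]
    base_row <- tibble::tibble(
      structure_id = suites$structure_id[i], chain = suites$chain[i],
      resnum = suites$resnum[i], icode = suites$icode[i],
      pucker_pair = pair, best_cluster = NA_integer_,
      predicted_conformers = NA_character_,
      posterior = NA_real_, mahalanobis = NA_real_,
      ranking = list(NULL), note = NA_character_
    )
    if (is.na(pair)) {
      base_row$note <- "no next phosphorus: pucker pair not gateable"
      rows[[i]] <- base_row
      next
    }
    ks <- by_pair[[pair]]
    if (is.null(ks) || !length(ks)) {
      base_row$note <- sprintf("no trained clusters for pucker pair %s", pair)
      rows[[i]] <- base_row
      next
    }
    evals <- lapply(object$clusters[ks], log_unnorm_posterior, w = suites$muccss[[i]])
    lp <- vapply(evals, `[[`, 0, "lp")
    if (all(!is.finite(lp))) {
      base_row$note <- "all clusters failed the tangent chart"
      rows[[i]] <- base_row
      next
    }
    post <- exp(lp - max(lp))
    post <- post / sum(post)
    rk <- tibble::tibble(
      cluster = vapply(object$clusters[ks], `[[`, 0L, "cluster"),
      n = vapply(object$clusters[ks], `[[`, 0, "n"),
      conformers = vapply(object$clusters[ks],
                          function(s) paste(s$conformers, collapse = ";"), ""),
      log_posterior = lp, posterior = post,
      mahalanobis = vapply(evals, `[[`, 0, "maha")
    )
    rk <- rk[order(-rk$posterior, rk$cluster), ] # ties go to the lowest index
    base_row$best_cluster <- rk$cluster[1]
    base_row$predicted_conformers <- rk$conformers[1]
    base_row$posterior <- rk$posterior[1]
    base_row$mahalanobis <- rk$mahalanobis[1]
    base_row$ranking <- list(rk)
    rows[[i]] <- base_row
  }
  dplyr::bind_rows(rows)
}

#' Evaluate predictions against an answer manifest
#'
#' Joins predictions with the manifest of probable-answer conformers and
#' assigns each suite one of three categories: `pucker_mismatch` when no
#' answer conformer belongs to the gated pucker-pair set, `prediction_match`
#' when the predicted cluster's conformer set intersects the answers, and
#' `prediction_mismatch` otherwise. Answers whose conformer appears in no
#' trained cluster are flagged `unclustered_answer` (necessarily a
#' mismatch).
#'
#' @param predictions Output of [predict.rnaprecis_model()].
#' @param manifest Tibble with suite identifier columns plus
#'   `answer_conformer` (may carry several, semicolon-separated) and
#'   optionally `answer_pucker_pair`; when the pair is absent it is looked up
#'   from the model's training labels.
#' @param model The fitted `rnaprecis_model` (for the conformer-to-pair map).
#' @return List with `records` (per-suite tibble incl. `category`) and
#'   `summary` (per pucker pair: count, matches, mismatches, pucker
#'   mismatches with percentages).
#' @export
precis_evaluate <- function(predictions, manifest, model) {
  pair_of <- conformer_pair_map(model)
  key <- c("structure_id", "chain", "resnum", "icode")
  df <- dplyr::inner_join(predictions, manifest, by = key)
  if (nrow(df) < nrow(predictions)) {
    warning(sprintf("%d prediction(s) had no manifest entry", nrow(predictions) - nrow(df)),
            call. = FALSE)
  }
  known <- unique(unlist(lapply(model$clusters, `[[`, "conformers")))
  rec <- lapply(seq_len(nrow(df)), function(i) {
    answers <- strsplit(df$answer_conformer[i], ";")[[1]]
    apairs <- if ("answer_pucker_pair" %in% names(df) && !is.na(df$answer_pucker_pair[i])) {
      rep(df$answer_pucker_pair[i], length(answers))
    } else {
      unname(pair_of[answers])
    }
    predicted <- if (is.na(df$predicted_conformers[i])) character() else
      strsplit(df$predicted_conformers[i], ";")[[1]]
    gate <- df$pucker_pair[i]
    category <- if (is.na(gate)) {
      NA_character_
    } else if (!any(apairs == gate, na.rm = TRUE)) {
      "pucker_mismatch"
    } else if (length(intersect(predicted, answers))) {
      "prediction_match"
    } else {
      "prediction_mismatch"
    }
    tibble::tibble(
      structure_id = df$structure_id[i], chain = df$chain[i],
      resnum = df$resnum[i], icode = df$icode[i],
      pucker_pair = gate, best_cluster = df$best_cluster[i],
      predicted_conformers = df$predicted_conformers[i],
      answer_conformer = df$answer_conformer[i],
      category = category,
      unclustered_answer = !any(answers %in% known)
    )
  })
  records <- dplyr::bind_rows(rec)
  summary <- records |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$pucker_pair) |>
    dplyr::summarise(
      count = dplyr::n(),
      prediction_matches = sum(.data$category == "prediction_match"),
      prediction_mismatches = sum(.data$category == "prediction_mismatch"),
      pucker_mismatches = sum(.data$category == "pucker_mismatch"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      match_pct = 100 * .data$prediction_matches / .data$count,
      mismatch_pct = 100 * .data$prediction_mismatches / .data$count,
      pucker_mismatch_pct = 100 * .data$pucker_mismatches / .data$count
    )
  list(records = records, summary = summary)
}

# map conformer class -> pucker pair, from the model's training labels
conformer_pair_map <- function(model) {
  out <- character()
  for (s in model$clusters) {
    for (cf in s$conformers) out[cf] <- s$pair
  }
  out
}

#' Tidy a fitted conformer classifier
#'
#' @param x A `rnaprecis_model`.
#' @param ... Unused.
#' @return One row per cluster: pucker pair, cluster index, size, conformer
#'   labels, the mean MUCCSS coordinates and the covariance trace.
#' @export
tidy.rnaprecis_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$clusters, function(s) tibble::tibble(
    pucker_pair = s$pair, cluster = s$cluster, n = s$n,
    conformers = paste(s$conformers, collapse = ";"),
    d2 = s$mean$d2, d3 = s$mean$d3, alpha = s$mean$alpha,
    cov_trace = sum(diag(s$cov))
  )))
}

#' @exportS3Method generics::glance
glance.rnaprecis_model <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$clusters),
    n_train = sum(vapply(x$clusters, `[[`, 0, "n")),
    n_pairs = length(unique(vapply(x$clusters, `[[`, "", "pair"))),
    lambda = x$lambda
  )
}

# ---- model serialisation ----------------------------------------------------

#' Write a fitted model to JSON
#'
#' @param model A `rnaprecis_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ser <- list(
    lambda = model$lambda,
    S1 = as.numeric(model$S1),
    clusters = lapply(model$clusters, function(s) list(
      pair = s$pair, cluster = s$cluster, n = s$n,
      mean = list(d2 = s$mean$d2, d3 = s$mean$d3, alpha = s$mean$alpha,
                  s1 = s$mean$s1, s2 = s$mean$s2),
      cov = as.numeric(s$cov),
      conformers = s$conformers,
      label_multiset = s$label_multiset
    ))
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `rnaprecis_model`.
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  S1 <- matrix(ser$S1, 7, 7)
  clusters <- lapply(seq_len(nrow(ser$clusters)), function(i) {
    row <- ser$clusters[i, ]
    s <- list(
      pair = row$pair, cluster = row$cluster, n = row$n,
      mean = new_muccss(row$mean$d2, row$mean$d3, row$mean$alpha,
                        unlist(row$mean$s1), unlist(row$mean$s2)),
      cov = matrix(unlist(row$cov), 7, 7),
      conformers = unlist(row$conformers),
      label_multiset = unlist(row$label_multiset)
    )
    RS <- ser$lambda * s$cov + (1 - ser$lambda) * S1
    s$RS_chol <- chol(RS)
    s$logdet_RS <- 2 * sum(log(diag(s$RS_chol)))
    s
  })
  structure(list(clusters = clusters, lambda = ser$lambda, S1 = S1),
            class = "rnaprecis_model")
}
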