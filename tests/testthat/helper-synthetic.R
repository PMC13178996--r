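# shared fixture builders; everything is generated in code at test time

# canonical A-form suite torsions (delta, epsilon, zeta, alpha, beta, gamma,
# delta)
aform_torsions <- function() c(84, 212, 289, 295, 174, 54, 84)

# the built-in separated cluster centers on the 7-torus for a pucker pair
test_centers <- function(pair = "P33") {
  geom <- ideal_geometry()
  pk <- rnaprecis:::pair_to_puckers(pair)
  mid <- rbind(
    c(212, 289, 295, 174, 54),
    c(212, 193, 146, 182, 190),
    c(242, 66, 68, 250, 300),
    c(150, 289, 212, 110, 54)
  )
  cbind(geom$delta[[pk[1]]], mid, geom$delta[[pk[2]]], deparse.level = 0)
}

# wrapped-Gaussian torus sample around the k-th center
sample_torus_clusters <- function(sizes, sigma = 8, pair = "P33") {
  ctr <- test_centers(pair)
  ang <- do.call(rbind, lapply(seq_along(sizes), function(k) {
    sapply(1:7, function(j) (stats::rnorm(sizes[k], ctr[k, j], sigma)) %% 360)
  }))
  list(angles = ang, truth = rep(seq_along(sizes), sizes))
}

# a random muccss point near realistic suite geometry
random_muccss <- function() {
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  rnaprecis:::new_muccss(
    stats::runif(1, 5, 7), stats::runif(1, 5, 7), stats::runif(1, 1, 2.5),
    rand_dir(), rand_dir()
  )
}

# a concentrated muccss cluster around a base point
muccss_cluster <- function(n, spread = 0.05) {
  base <- random_muccss()
  jitter_dir <- function(s) {
    v <- s + stats::rnorm(3, 0, spread)
    v / sqrt(sum(v^2))
  }
  lapply(seq_len(n), function(i) {
    rnaprecis:::new_muccss(
      base$d2 + stats::rnorm(1, 0, spread), base$d3 + stats::rnorm(1, 0, spread),
      base$alpha + stats::rnorm(1, 0, spread / 2),
      jitter_dir(base$s1), jitter_dir(base$s2)
    )
  })
}

# Frechet function of a sample at a point
frechet_value_at <- function(w, samples) {
  mean(vapply(samples, function(s) muccss_distance(w, s)^2, 0))
}

# hand-written one-residue PDB fixture (G nucleotide with P, sugar, N9)
one_residue_pdb <- function(path) {
  s <- build_cartesian(aform_torsions(), "P33", bases = c("G", "G"))
  at <- rnaprecis:::suites_to_atoms(s)
  at <- at[at$resnum == 2, ]
  at$structure_id <- "fix1"
  at$icode <- ""
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resnum, resid = at$base, chain = at$chain,
                   elety = at$atom, o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  path
}

# a bonded n-residue chain as an atom table in the read_rna_atoms format
chain_atoms <- function(n_res, drop_trailing_p = TRUE, structure_id = "chainfix") {
  set.seed(4)
  deltas <- rep(84, n_res)
  jn <- matrix(rep(aform_torsions()[2:6], n_res - 1), ncol = 5, byrow = TRUE)
  at <- build_chain(deltas, rep("C3_endo", n_res), jn)
  if (drop_trailing_p) at <- at[at$resnum <= n_res, ]
  tibble::tibble(
    structure_id = structure_id, chain = "A", resnum = as.integer(at$resnum),
    icode = "", base = at$base, atom = at$atom,
    x = at$x, y = at$y, z = at$z, altloc = "", occupancy = 1,
    has_altloc = FALSE
  )
}

# brute-force UPGMA (average linkage) agglomeration: returns merge heights
# and the cophenetic matrix, independently of hclust
brute_force_upgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 &&
           min(clusters[[i]], clusters[[j]]) < min(best))) {
        best_d <- d; best <- c(i, j)
      }
    }
    heights <- c(heights, best_d)
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}
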