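#' Ideal RNA backbone and ribose geometry
#'
#' Bond lengths (Angstrom), bond angles (degrees) and per-pucker ribose
#' template torsions used by the Cartesian suite builder. Values are standard
#' small-molecule nucleic-acid geometry; ring torsions come from the
#' pseudorotation description with amplitude 38 degrees at phase 18 (C3'-endo)
#' and 162 (C2'-endo). Bond lengths and angles in RNA are nearly constant
#' (spreads of order 0.01 Angstrom and ~2 degrees), so a single table serves
#' both pucker states except where noted.
#'
#' @return A nested list of constants; see the source for the entries.
#' @export
ideal_geometry <- function() {
  list(
    bonds = c(
      "O3'-P" = 1.607, "P-O5'" = 1.593, "O5'-C5'" = 1.440,
      "C5'-C4'" = 1.510, "C4'-C3'" = 1.524, "C3'-O3'" = 1.423,
      "C4'-O4'" = 1.453, "O4'-C1'" = 1.414, "C1'-C2'" = 1.528,
      "C2'-C3'" = 1.525, "C1'-N" = 1.470
    ),
    angles = c(
      "C3'-O3'-P" = 119.7, "O3'-P-O5'" = 104.0, "P-O5'-C5'" = 120.9,
      "O5'-C5'-C4'" = 111.5, "C5'-C4'-C3'" = 116.0, "C4'-C3'-O3'" = 110.6,
      "C3'-C4'-O4'" = 105.6, "C4'-O4'-C1'" = 109.7, "O4'-C1'-C2'" = 106.1,
      "O4'-C1'-N" = 108.2
    ),
    # ring torsions nu0..nu4 per pucker (pseudorotation, tau_m = 38 deg)
    ring = list(
      C3_endo = c(nu0 = 0.0, nu1 = -22.3, nu2 = 36.1, nu3 = -36.1, nu4 = 22.3),
      C2_endo = c(nu0 = -22.3, nu1 = 36.1, nu2 = -36.1, nu3 = 22.3, nu4 = 0.0)
    ),
    # torsion offsets around the C3'->C4' axis (O3' relative to C2') and the
    # O4'->C1' axis (N relative to C2'); signs fix the ribose chirality and
    # were set so that a built ring closes (C2'-C3' near its bond length) and
    # the base points to the correct side of the sugar
    offsets = c(o3_from_c2 = -121.0, n_from_c2 = -121.0),
    # canonical delta and epsilon-to-next-phosphorus per pucker state
    delta = c(C3_endo = 84, C2_endo = 147),
    eps_next = c(C3_endo = 212, C2_endo = 224)
  )
}

# NeRF placement: position of atom D bonded to C with bond length, angle
# B-C-D (deg) and torsion A-B-C-D (deg)
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- cross3(b - a, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# build the sugar + base nitrogen of one residue, given already-placed
# C5', C4', C3' and a delta torsion that has placed O3'; returns the ring
# atoms O4', C1', C2' and the glycosidic N
build_ribose <- function(c5, c4, c3, o3, pucker, geom = ideal_geometry()) {
  nu <- geom$ring[[pucker]]
  off <- geom$offsets
  b <- geom$bonds; an <- geom$angles
  # O4' off C4', torsion measured from O3' (offset from the ring torsion nu3)
  o4 <- place_atom(o3, c3, c4, b[["C4'-O4'"]], an[["C3'-C4'-O4'"]],
                   nu[["nu3"]] + off[["o3_from_c2"]])
  c1 <- place_atom(c3, c4, o4, b[["O4'-C1'"]], an[["C4'-O4'-C1'"]], nu[["nu4"]])
  c2 <- place_atom(c4, o4, c1, b[["C1'-C2'"]], an[["O4'-C1'-C2'"]], nu[["nu0"]])
  n  <- place_atom(c4, o4, c1, b[["C1'-N"]], an[["O4'-C1'-N"]],
                   nu[["nu0"]] + off[["n_from_c2"]])
  list(`O4'` = o4, `C1'` = c1, `C2'` = c2, N = n)
}

#' Build a Cartesian RNA chain from internal coordinates
#'
#' Places backbone and sugar atoms for `n` residues sequentially from bond
#' lengths, bond angles and torsions (the standard internal-coordinate chain
#' construction). Residue `j` has sugar pucker `puckers[j]` and delta torsion
#' `deltas[j]`; junction `j` (between residues `j` and `j+1`) has the five
#' torsions epsilon, zeta, alpha, beta, gamma in `junctions[j, ]`. A trailing
#' phosphorus after the last residue is placed with the pucker-appropriate
#' epsilon so that the last suite's second-sugar Pperp is measurable.
#'
#' @param deltas Numeric vector of delta torsions, one per residue.
#' @param puckers Character vector ("C3_endo"/"C2_endo"), one per residue.
#' @param junctions Matrix with one row per junction (`n - 1` rows) and
#'   columns epsilon, zeta, alpha, beta, gamma (degrees).
#' @param bases Character vector of base types per residue (A/U/C/G).
#' @param geom Geometry constants, see [ideal_geometry()].
#' @return A tibble of atoms: `resnum`, `base`, `atom`, `x`, `y`, `z`,
#'   including the trailing `P` as residue `n + 1`.
#' @export
build_chain <- function(deltas, puckers, junctions, bases = NULL,
                        geom = ideal_geometry()) {
  n <- length(deltas)
  stopifnot(length(puckers) == n)
  if (n > 1) {
    junctions <- rbind(junctions)
    stopifnot(nrow(junctions) == n - 1, ncol(junctions) == 5)
  }
  if (is.null(bases)) bases <- rep(c("G", "U"), length.out = n)
  b <- geom$bonds; an <- geom$angles
  rows <- list()
  add <- function(resnum, base, atom, pos) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      resnum = resnum, base = base, atom = atom,
      x = pos[1], y = pos[2], z = pos[3]
    )
  }
  for (j in seq_len(n)) {
    if (j == 1) {
      # seed the first sugar in a canonical pose
      c5 <- c(0, 0, 0)
      c4 <- c(b[["C5'-C4'"]], 0, 0)
      th <- an[["C5'-C4'-C3'"]] * pi / 180
      c3 <- c4 + b[["C4'-C3'"]] * c(-cos(th), sin(th), 0)
    } else {
      jn <- junctions[j - 1, ]
      p  <- place_atom(prev$`C4'`, prev$`C3'`, prev$`O3'`,
                       b[["O3'-P"]], an[["C3'-O3'-P"]], jn[[1]])       # epsilon
      o5 <- place_atom(prev$`C3'`, prev$`O3'`, p,
                       b[["P-O5'"]], an[["O3'-P-O5'"]], jn[[2]])       # zeta
      c5 <- place_atom(prev$`O3'`, p, o5,
                       b[["O5'-C5'"]], an[["P-O5'-C5'"]], jn[[3]])     # alpha
      c4 <- place_atom(p, o5, c5,
                       b[["C5'-C4'"]], an[["O5'-C5'-C4'"]], jn[[4]])   # beta
      c3 <- place_atom(o5, c5, c4,
                       b[["C4'-C3'"]], an[["C5'-C4'-C3'"]], jn[[5]])   # gamma
      add(j, bases[j], "P", p)
      add(j, bases[j], "O5'", o5)
    }
    o3 <- place_atom(c5, c4, c3, b[["C3'-O3'"]], an[["C4'-C3'-O3'"]], deltas[j])
    ring <- build_ribose(c5, c4, c3, o3, puckers[j], geom)
    n_name <- if (bases[j] %in% c("A", "G")) "N9" else "N1"
    add(j, bases[j], "C5'", c5)
    add(j, bases[j], "C4'", c4)
    add(j, bases[j], "C3'", c3)
    add(j, bases[j], "O3'", o3)
    add(j, bases[j], "O4'", ring$`O4'`)
    add(j, bases[j], "C1'", ring$`C1'`)
    add(j, bases[j], "C2'", ring$`C2'`)
    add(j, bases[j], n_name, ring$N)
    prev <- c(list(`C5'` = c5, `C4'` = c4, `C3'` = c3, `O3'` = o3), ring)
  }
  # trailing phosphorus so the last residue's 3' Pperp is defined
  eps_tail <- geom$eps_next[[puckers[n]]]
  p_next <- place_atom(prev$`C4'`, prev$`C3'`, prev$`O3'`,
                       b[["O3'-P"]], an[["C3'-O3'-P"]], eps_tail)
  add(n + 1, bases[n], "P", p_next)
  dplyr::bind_rows(rows)
}

#' Build one suite from its seven dihedrals
#'
#' Constructs Cartesian atoms for a single suite (two residues plus the
#' following phosphorus) whose measured backbone dihedrals reproduce the
#' requested values. The sugar puckers are realised through the per-pucker
#' ribose template and the delta torsions contained in `torus`.
#'
#' @param torus Numeric length-7 vector, the suite dihedrals in order
#'   (delta0, epsilon, zeta, alpha, beta, gamma, delta1), degrees.
#' @param pucker_pair One of "P33", "P32", "P23", "P22" (first digit = 5'
#'   sugar). Must be consistent with the delta values for realistic output.
#' @param bases Length-2 character vector of base types.
#' @inheritParams build_chain
#' @return A one-row suite tibble in the format of [build_suites()].
#' @export
build_cartesian <- function(torus, pucker_pair = "P33", bases = c("G", "U"),
                            geom = ideal_geometry()) {
  stopifnot(length(torus) == 7)
  puckers <- pair_to_puckers(pucker_pair)
  atoms <- build_chain(
    deltas = c(torus[1], torus[7]),
    puckers = puckers,
    junctions = matrix(torus[2:6], nrow = 1),
    bases = bases, geom = geom
  )
  chain_to_suites(atoms, structure_id = "SYN")
}

pair_to_puckers <- function(pair) {
  stopifnot(pair %in% c("P33", "P32", "P23", "P22"))
  code <- strsplit(sub("^P", "", pair), "")[[1]]
  ifelse(code == "3", "C3_endo", "C2_endo")
}

# convert a build_chain atom tibble into the suite-table format used by
# build_suites(): one row per adjacent residue pair, with prev/curr atom
# matrices and the next phosphorus when present
chain_to_suites <- function(atoms, structure_id = "SYN", chain = "A") {
  resnums <- sort(unique(atoms$resnum))
  res_mats <- lapply(resnums, function(r) {
    a <- atoms[atoms$resnum == r, ]
    m <- as.matrix(a[, c("x", "y", "z")])
    rownames(m) <- a$atom
    m
  })
  names(res_mats) <- as.character(resnums)
  bases <- vapply(resnums, function(r) atoms$base[atoms$resnum == r][1], "")
  # residues consisting only of a trailing P are not full residues
  full <- vapply(res_mats, function(m) "C1'" %in% rownames(m), TRUE)
  out <- list()
  for (k in seq_along(resnums)[-1]) {
    if (!full[k] || !full[k - 1]) next
    nxt <- if (k + 1 <= length(resnums) && "P" %in% rownames(res_mats[[k + 1]])) {
      res_mats[[k + 1]]["P", ]
    } else NULL
    out[[length(out) + 1]] <- tibble::tibble(
      structure_id = structure_id, chain = chain,
      resnum = resnums[k], icode = "",
      base_prev = bases[k - 1], base_curr = bases[k],
      atoms = list(list(prev = res_mats[[k - 1]], curr = res_mats[[k]],
                        next_P = nxt))
    )
  }
  dplyr::bind_rows(out)
}

#' Configuration for the synthetic gold standard
#'
#' Describes the simulated training/testing conditions: per pucker pair, a
#' set of cluster centers on the 7-torus, wrapped-Gaussian angular noise
#' around each center, cluster sizes, optional random rigid motion and
#' Cartesian coordinate noise, and a seed. Defaults give four well-separated
#' clusters of 40 suites in each of the four pucker pairs with 8 degrees of
#' angular spread, emulating concentrated rotameric conformer classes.
#'
#' @param pairs Pucker pairs to populate.
#' @param n_clusters Clusters per pucker pair (up to 4 with the built-in
#'   center table; use `centers = "random-separated"` for more).
#' @param n_per_cluster Training suites per cluster.
#' @param n_test_per_cluster Held-out test suites per cluster.
#' @param sigma_noise Angular standard deviation, degrees, applied to every
#'   dihedral before wrapping.
#' @param centers `"default"` (built-in center table), `"random-separated"`
#'   (uniform draws with minimum pairwise torus separation `4 * sigma_noise`),
#'   or a list mapping each pair to a matrix of 7-column centers.
#' @param rigid_motion Apply a random rotation + translation per suite.
#' @param coordinate_noise Isotropic Gaussian noise (Angstrom) added to every
#'   atom after building.
#' @param seed Integer seed governing all randomness.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(pairs = c("P33", "P32", "P23", "P22"),
                             n_clusters = 4, n_per_cluster = 40,
                             n_test_per_cluster = 5, sigma_noise = 8,
                             centers = "default", rigid_motion = TRUE,
                             coordinate_noise = 0, seed = 1L) {
  structure(list(
    pairs = pairs, n_clusters = n_clusters, n_per_cluster = n_per_cluster,
    n_test_per_cluster = n_test_per_cluster, sigma_noise = sigma_noise,
    centers = centers, rigid_motion = rigid_motion,
    coordinate_noise = coordinate_noise, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# five middle torsions (epsilon, zeta, alpha, beta, gamma) for the built-in
# cluster centers; deltas are filled in from the pucker pair. Centers are
# rotamer-like and mutually separated by >= 60 degrees in at least two
# coordinates so clusters are recoverable at the default noise level.
default_center_table <- function() {
  rbind(
    c(212, 289, 295, 174, 54),
    c(212, 193, 146, 182, 190),
    c(242, 66, 68, 250, 300),
    c(150, 289, 212, 110, 54)
  )
}

# conformer-class labels for synthetic clusters: digits index the cluster,
# the letter encodes the pucker pair
synthetic_labels <- function(pair, n_clusters) {
  letter <- c(P33 = "a", P32 = "b", P23 = "c", P22 = "d")[[pair]]
  paste0(seq_len(n_clusters), letter)
}

centers_for_pair <- function(cfg, pair) {
  geom <- ideal_geometry()
  puckers <- pair_to_puckers(pair)
  d5 <- geom$delta[[puckers[1]]]
  d3 <- geom$delta[[puckers[2]]]
  if (is.list(cfg$centers)) {
    ctr <- cfg$centers[[pair]]
    stopifnot(ncol(ctr) == 7)
    return(ctr)
  }
  if (identical(cfg$centers, "default")) {
    tab <- default_center_table()
    stopifnot(cfg$n_clusters <= nrow(tab))
    mid <- tab[seq_len(cfg$n_clusters), , drop = FALSE]
  } else if (identical(cfg$centers, "random-separated")) {
    mid <- random_separated_centers(cfg$n_clusters, 5, 4 * cfg$sigma_noise)
  } else {
    stop("unknown centers specification", call. = FALSE)
  }
  cbind(d5, mid, d3, deparse.level = 0)
}

random_separated_centers <- function(k, d, min_sep, max_tries = 2000) {
  ctr <- matrix(stats::runif(d, 0, 360), nrow = 1)
  tries <- 0
  while (nrow(ctr) < k && tries < max_tries) {
    cand <- stats::runif(d, 0, 360)
    seps <- apply(ctr, 1, function(r) {
      diff <- abs(r - cand)
      sqrt(sum(pmin(diff, 360 - diff)^2))
    })
    if (all(seps > min_sep)) ctr <- rbind(ctr, cand)
    tries <- tries + 1
  }
  if (nrow(ctr) < k) stop("could not place separated centers", call. = FALSE)
  ctr
}

wrap_gauss <- function(center, sigma, n) {
  # sample on the line, wrap into [0, 360)
  matrix(wrap360(rep(center, each = n) +
                   stats::rnorm(n * length(center), 0, sigma)),
         nrow = n)
}

#' Sample a synthetic gold standard
#'
#' Draws labeled suites from wrapped-Gaussian torus clusters, builds their
#' Cartesian atoms, and returns both the high-detail (dihedral) and low-detail
#' (landmark) material: a training suite table with true cluster labels, and a
#' held-out test suite table with an answer manifest. Deterministic under the
#' config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `train` (suite tibble with `conformer`,
#'   `true_cluster`, `pucker_pair` columns), `test` (suite tibble), and
#'   `manifest` (tibble: suite identifiers plus `answer_conformer`,
#'   `answer_pucker_pair`).
#' @export
sample_gold_standard <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  train <- list(); test <- list()
  for (pair in cfg$pairs) {
    ctr <- centers_for_pair(cfg, pair)
    labels <- synthetic_labels(pair, nrow(ctr))
    for (ci in seq_len(nrow(ctr))) {
      n_tot <- cfg$n_per_cluster + cfg$n_test_per_cluster
      angs <- wrap_gauss(ctr[ci, ], cfg$sigma_noise, n_tot)
      for (j in seq_len(n_tot)) {
        s <- build_cartesian(angs[j, ], pair)
        if (cfg$coordinate_noise > 0) s <- perturb_coords(s, cfg$coordinate_noise)
        if (cfg$rigid_motion) s <- perturb_rigid(s)
        role <- if (j <= cfg$n_per_cluster) "train" else "test"
        s$structure_id <- sprintf("SYN_%s_%s_%03d", pair, labels[ci], j)
        s$pucker_pair <- pair
        s$conformer <- labels[ci]
        s$true_cluster <- ci
        if (role == "train") train[[length(train) + 1]] <- s
        else test[[length(test) + 1]] <- s
      }
    }
  }
  train <- dplyr::bind_rows(train)
  test <- if (length(test)) dplyr::bind_rows(test) else {
    tr0 <- dplyr::bind_rows(train)[0, ]
    tr0
  }
  manifest <- test |>
    dplyr::transmute(
      .data$structure_id, .data$chain, .data$resnum, .data$icode,
      answer_conformer = .data$conformer,
      answer_pucker_pair = .data$pucker_pair
    )
  list(train = train, test = test, manifest = manifest)
}

# apply a function to every atom coordinate of a suite table
map_suite_coords <- function(suites, f) {
  suites$atoms <- lapply(suites$atoms, function(at) {
    at$prev <- t(apply(at$prev, 1, f))
    at$curr <- t(apply(at$curr, 1, f))
    if (!is.null(at$next_P)) at$next_P <- f(at$next_P)
    at
  })
  suites
}

perturb_coords <- function(suites, sd) {
  map_suite_coords(suites, function(p) p + stats::rnorm(3, 0, sd))
}

#' Apply a random rigid motion to every suite
#'
#' Rotates and translates all atoms of each suite by a uniformly random
#' rotation (Haar measure, via QR of a Gaussian matrix) and a translation
#' drawn uniformly from `[-20, 20]` Angstrom per axis. Internal geometry is
#' preserved exactly, so every rigid-motion-invariant quantity is unchanged.
#'
#' @param suites A suite tibble.
#' @param seed Optional integer; when given, randomness is local to the call.
#' @return The suite tibble with transformed coordinates.
#' @export
perturb_rigid <- function(suites, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed
    on.exit(.Random.seed <<- old)
    set.seed(seed)
  }
  suites$atoms <- lapply(suites$atoms, function(at) {
    R <- random_rotation()
    tr <- stats::runif(3, -20, 20)
    f <- function(p) as.numeric(R %*% p + tr)
    at$prev <- t(apply(at$prev, 1, f))
    at$curr <- t(apply(at$curr, 1, f))
    if (!is.null(at$next_P)) at$next_P <- f(at$next_P)
    at
  })
  suites
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Write suites to a PDB file
#'
#' Emits the atoms of a suite table as a (single-model) PDB file via
#' `bio3d::write.pdb`, one chain, residues numbered as in the table. Suites
#' sharing residues are merged; the trailing phosphorus of the final suite is
#' written as an extra residue.
#'
#' @param suites A suite tibble from [build_suites()] or the generator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_suites_pdb <- function(suites, path) {
  at <- suites_to_atoms(suites)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resnum, resid = at$base, chain = at$chain,
    elety = at$atom, o = rep(1, nrow(at)), b = rep(0, nrow(at))
  )
  invisible(path)
}

# flatten a suite table back to one atom row per (chain, resnum, atom)
suites_to_atoms <- function(suites) {
  rows <- list()
  for (i in seq_len(nrow(suites))) {
    at <- suites$atoms[[i]]
    rn <- suites$resnum[i]
    ch <- suites$chain[i]
    mk <- function(m, resnum, base) {
      tibble::tibble(chain = ch, resnum = resnum, base = base,
                     atom = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
    }
    rows[[length(rows) + 1]] <- mk(at$prev, rn - 1L, suites$base_prev[i])
    rows[[length(rows) + 1]] <- mk(at$curr, rn, suites$base_curr[i])
    if (!is.null(at$next_P)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain = ch, resnum = rn + 1L, base = suites$base_curr[i], atom = "P",
        x = at$next_P[1], y = at$next_P[2], z = at$next_P[3]
      )
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$chain, .data$resnum, .data$atom, .keep_all = TRUE) |>
    dplyr::arrange(.data$chain, .data$resnum)
}
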