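#' Torsion angle of four points
#'
#' Computes the standard signed torsion (dihedral) angle of the bonded
#' quadruple a-b-c-d: the rotation of the plane through (b, c, d) relative to
#' the plane through (a, b, c), viewed along the central bond b->c. The result
#' is wrapped into `[0, 360)` degrees, the convention used throughout the
#' suite-conformer literature. The angle is invariant under rigid motions and
#' negated (before wrapping) by a mirror reflection.
#'
#' @param a,b,c,d Numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in degrees in `[0, 360)`.
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # trans, 180
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("undefined dihedral: collinear atom triple", call. = FALSE)
  }
  # atan2 form: numerically stable for all geometries; sign follows the
  # standard convention (positive = clockwise rotation viewed along b -> c)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  wrap360(atan2(y, x) * 180 / pi)
}

#' Perpendicular distance from the next phosphorus to a glycosidic bond line
#'
#' Distance from `next_p` to the infinite line through `c1p` (C1') and
#' `n_glyc` (N1/N9), i.e. the extended glycosidic bond vector. This is the
#' "Pperp" measure used to call ribose pucker from low-detail coordinates.
#'
#' @param n_glyc Position of the glycosidic nitrogen (N1 or N9).
#' @param c1p Position of the C1' atom.
#' @param next_p Position of the next-in-sequence phosphorus.
#' @return Distance in Angstrom (non-negative).
#' @export
pperp_distance <- function(n_glyc, c1p, next_p) {
  u <- n_glyc - c1p
  nu <- vnorm(u)
  if (nu < 1e-10) stop("degenerate glycosidic bond: coincident endpoints", call. = FALSE)
  u <- u / nu
  r <- next_p - c1p
  vnorm(r - u * sum(r * u))
}

#' Ribose pucker from a Pperp distance
#'
#' The low-detail pucker call: C3'-endo iff the Pperp distance is at least
#' 2.9 Angstrom (the boundary itself belongs to C3'-endo), otherwise C2'-endo.
#'
#' @param d Pperp distance in Angstrom (non-negative).
#' @return A list with `state` ("C3_endo" or "C2_endo"), `source` = "pperp"
#'   and `pperp_value`.
#' @export
pucker_from_pperp <- function(d) {
  stopifnot(is.finite(d), d >= 0)
  state <- if (d >= PPERP_CUTOFF) "C3_endo" else "C2_endo"
  list(state = state, source = "pperp", pperp_value = d)
}

#' The Pperp classification boundary in Angstrom.
#' @keywords internal
PPERP_CUTOFF <- 2.9

#' Ribose pucker from ring geometry (high-detail route)
#'
#' Calls the pucker from the ribose ring atoms: the signed heights of C3' and
#' C2' over the oriented plane spanned by the C4'-O4' and C1'-O4' vectors.
#' C3'-endo means C3' lies on the positive side of that plane and farther from
#' it than C2'; otherwise C2'-endo. This geometric rule is cutoff-free.
#'
#' @param atoms Named list or matrix (rownames = atom names) with positions of
#'   `O4'`, `C1'`, `C2'`, `C3'`, `C4'`.
#' @return A list with `state`, `source` = "nu" and the two signed heights.
#' @export
pucker_from_nu <- function(atoms) {
  get <- atom_getter(atoms)
  o4 <- get("O4'"); c1 <- get("C1'"); c2 <- get("C2'")
  c3 <- get("C3'"); c4 <- get("C4'")
  n <- cross3(c4 - o4, c1 - o4)
  nn <- vnorm(n)
  if (nn < 1e-10) stop("degenerate ribose ring: C4'-O4' and C1'-O4' collinear", call. = FALSE)
  n <- n / nn
  h3 <- sum(n * (c3 - o4))
  h2 <- sum(n * (c2 - o4))
  if (abs(h3) < 1e-9 && abs(h2) < 1e-9) {
    stop("degenerate pucker: ring is planar", call. = FALSE)
  }
  state <- if (h3 > 0 && h3 > h2) "C3_endo" else "C2_endo"
  list(state = state, source = "nu", h3 = h3, h2 = h2)
}

# ---- per-suite measurements -------------------------------------------------

# atom quadruples for the 7 suite backbone torsions, in order
# (delta of residue i-1, epsilon, zeta, alpha, beta, gamma, delta of residue i)
suite_torsion_defs <- function() {
  list(
    delta0  = list(prev = c("C5'", "C4'", "C3'", "O3'"), curr = character()),
    epsilon = list(prev = c("C4'", "C3'", "O3'"), curr = "P"),
    zeta    = list(prev = c("C3'", "O3'"), curr = c("P", "O5'")),
    alpha   = list(prev = "O3'", curr = c("P", "O5'", "C5'")),
    beta    = list(prev = character(), curr = c("P", "O5'", "C5'", "C4'")),
    gamma   = list(prev = character(), curr = c("O5'", "C5'", "C4'", "C3'")),
    delta1  = list(prev = character(), curr = c("C5'", "C4'", "C3'", "O3'"))
  )
}

#' Names of the seven suite backbone dihedrals, in order.
#' @export
suite_dihedral_names <- function() {
  c("delta0", "epsilon", "zeta", "alpha", "beta", "gamma", "delta1")
}

# measure the 7 torsions for one suite (prev/curr atom matrices)
measure_suite_dihedrals <- function(prev, curr) {
  defs <- suite_torsion_defs()
  out <- numeric(7)
  names(out) <- names(defs)
  for (k in seq_along(defs)) {
    d <- defs[[k]]
    pts <- vector("list", 4)
    i <- 1
    for (nm in d$prev) {
      if (!nm %in% rownames(prev)) {
        stop(sprintf("cannot compute torsion '%s': missing atom %s in first residue",
                     names(defs)[k], nm), call. = FALSE)
      }
      pts[[i]] <- prev[nm, ]; i <- i + 1
    }
    for (nm in d$curr) {
      if (!nm %in% rownames(curr)) {
        stop(sprintf("cannot compute torsion '%s': missing atom %s in second residue",
                     names(defs)[k], nm), call. = FALSE)
      }
      pts[[i]] <- curr[nm, ]; i <- i + 1
    }
    out[k] <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }
  out
}

#' Seven backbone dihedrals per suite
#'
#' Adds the seven suite backbone dihedral angles (degrees in `[0, 360)`, in
#' the order delta of the first residue, epsilon, zeta, alpha, beta, gamma,
#' delta of the second residue) to a suite table built by [build_suites()].
#' Together the seven angles place each suite on the 7-torus, the high-detail
#' shape representation.
#'
#' @param suites A suite tibble from [build_suites()] or the synthetic
#'   generator.
#' @return The input with seven new numeric columns `delta0`, `epsilon`,
#'   `zeta`, `alpha`, `beta`, `gamma`, `delta1`.
#' @export
suite_dihedrals <- function(suites) {
  vals <- purrr::map(suites$atoms, function(at) {
    measure_suite_dihedrals(at$prev, at$curr)
  })
  m <- do.call(rbind, vals)
  dplyr::bind_cols(suites, tibble::as_tibble(m))
}

# pperp for one side of a suite; side "5" uses N/C1' of the first residue and
# P of the second; side "3" uses N/C1' of the second residue and the next P
suite_pperp_one <- function(atoms, side = c("5", "3")) {
  side <- match.arg(side)
  if (side == "5") {
    res <- atoms$prev
    p <- atoms$curr["P", ]
  } else {
    res <- atoms$curr
    if (is.null(atoms$next_P)) return(NA_real_)
    p <- atoms$next_P
  }
  n_name <- intersect(c("N9", "N1"), rownames(res))[1]
  pperp_distance(res[n_name, ], res["C1'", ], p)
}

#' Pperp distances for both sugars of each suite
#'
#' Adds `pperp5` (first sugar: its glycosidic bond against the suite's own P)
#' and `pperp3` (second sugar: against the phosphorus of the following
#' residue; `NA` when that phosphorus is absent) to a suite table.
#'
#' @inheritParams suite_dihedrals
#' @return The input with numeric columns `pperp5` and `pperp3`.
#' @export
suite_pperp <- function(suites) {
  suites$pperp5 <- purrr::map_dbl(suites$atoms, suite_pperp_one, side = "5")
  suites$pperp3 <- purrr::map_dbl(suites$atoms, suite_pperp_one, side = "3")
  suites
}

#' Pucker pair of each suite
#'
#' Determines the ordered sugar-pucker pair (P33, P32, P23 or P22; first
#' letter = 5' sugar, second = 3' sugar) for every suite. In low-detail mode
#' (`"LD"`) both sugars are called with the Pperp criterion, which needs the
#' next-in-sequence phosphorus for the 3' sugar; suites lacking it get `NA`.
#' In high-detail mode (`"HD"`) both riboses are called from their ring
#' geometry via [pucker_from_nu()].
#'
#' @inheritParams suite_dihedrals
#' @param mode `"LD"` (Pperp criterion) or `"HD"` (ring geometry).
#' @return The input with a character column `pucker_pair_LD` or
#'   `pucker_pair_HD`.
#' @export
suite_pucker_pair <- function(suites, mode = c("LD", "HD")) {
  mode <- match.arg(mode)
  code <- function(state) if (state == "C3_endo") "3" else "2"
  pair <- purrr::map_chr(suites$atoms, function(at) {
    if (mode == "LD") {
      d5 <- suite_pperp_one(at, "5")
      d3 <- suite_pperp_one(at, "3")
      if (is.na(d3)) return(NA_character_)
      paste0("P", code(pucker_from_pperp(d5)$state),
             code(pucker_from_pperp(d3)$state))
    } else {
      paste0("P", code(pucker_from_nu(at$prev)$state),
             code(pucker_from_nu(at$curr)$state))
    }
  })
  suites[[paste0("pucker_pair_", mode)]] <- pair
  suites
}

#' Per-suite geometry report
#'
#' Convenience wrapper returning the flat per-suite geometry table: suite
#' identifiers, the seven backbone dihedrals, both Pperp distances, and the
#' pucker pair under both the high-detail and the low-detail route.
#'
#' @inheritParams suite_dihedrals
#' @return A tibble without the raw atom list-column.
#' @export
suite_geometry_table <- function(suites) {
  suites |>
    suite_dihedrals() |>
    suite_pperp() |>
    suite_pucker_pair("HD") |>
    suite_pucker_pair("LD") |>
    dplyr::select(-"atoms")
}

# ---- small vector helpers ---------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x * x))

wrap360 <- function(x) {
  y <- x %% 360
  y[y < 0] <- y[y < 0] + 360
  # guard against 360 - eps rounding to exactly 360
  y[y >= 360] <- 0
  y
}

atom_getter <- function(atoms) {
  if (is.matrix(atoms)) {
    function(nm) {
      if (!nm %in% rownames(atoms)) stop(sprintf("missing ring atom %s", nm), call. = FALSE)
      atoms[nm, ]
    }
  } else {
    function(nm) {
      if (is.null(atoms[[nm]])) stop(sprintf("missing ring atom %s", nm), call. = FALSE)
      atoms[[nm]]
    }
  }
}
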