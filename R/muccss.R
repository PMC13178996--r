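#' Canonical frame of a low-detail suite
#'
#' Builds the right-handed orthogonal frame `R = (e1 | e2 | e3)` that maps the
#' pseudo-bond triangle (P at the origin, `v` = P to earlier C1', `w` = P to
#' later C1') into the (x, y)-plane: `e1` points along `w - v` so the later
#' C1' has the larger x-projection, `e2` is the in-plane unit vector giving
#' both C1' the same positive y-projection, and `e3 = e1 x e2` completes the
#' frame.
#'
#' @param v,w Numeric 3-vectors, the two pseudo-bonds from P (Angstrom).
#' @return A 3x3 orthogonal matrix with determinant +1, columns `e1,e2,e3`.
#' @export
canonical_frame <- function(v, w) {
  d <- w - v
  nd <- vnorm(d)
  if (nd < 1e-10) stop("degenerate frame: coincident pseudo-bond tips", call. = FALSE)
  e1 <- d / nd
  p <- v - e1 * sum(e1 * v)
  np <- vnorm(p)
  if (np < 1e-10) stop("degenerate frame: parallel pseudo-bonds", call. = FALSE)
  e2 <- p / np
  e3 <- cross3(e1, e2)
  cbind(e1, e2, e3, deparse.level = 0)
}

#' MUCCSS coordinates of a 5-landmark suite
#'
#' Maps the five low-detail landmarks (N1/N9 and C1' of the earlier residue,
#' P, then C1' and N1/N9 of the later residue, in that order) to the
#' multicentred constrained size-and-shape coordinates
#' `W = (d2, d3, alpha, s1, s2)`: the two pseudo-bond lengths P-C1'
#' (Angstrom), their opening angle at P (radians, in (0, pi)), and the two
#' glycosidic bond directions expressed as unit vectors in the canonical
#' frame. Each measured glycosidic vector is normalised to unit length, since
#' only its direction is informative. The map is invariant under rigid
#' motions of the landmarks.
#'
#' @param landmarks A 5x3 numeric matrix, rows in the order above.
#' @return An object of class `muccss`: list with `d2`, `d3`, `alpha`, `s1`,
#'   `s2`.
#' @export
muccss_point <- function(landmarks) {
  stopifnot(is.matrix(landmarks), nrow(landmarks) == 5, ncol(landmarks) == 3)
  x <- lapply(seq_len(5), function(i) as.numeric(landmarks[i, ]))
  y1 <- x[[1]] - x[[2]]
  v  <- x[[2]] - x[[3]]
  w  <- x[[4]] - x[[3]]
  y2 <- x[[5]] - x[[4]]
  d2 <- vnorm(v); d3 <- vnorm(w)
  if (d2 < 1e-10 || d3 < 1e-10) stop("degenerate pseudo-bond of zero length", call. = FALSE)
  n1 <- vnorm(y1); n2 <- vnorm(y2)
  if (n1 < 1e-10 || n2 < 1e-10) stop("degenerate glycosidic bond of zero length", call. = FALSE)
  alpha <- acos(clamp1(sum(v * w) / (d2 * d3)))
  R <- canonical_frame(v, w)
  new_muccss(d2, d3, alpha,
             as.numeric(crossprod(R, y1 / n1)),
             as.numeric(crossprod(R, y2 / n2)))
}

new_muccss <- function(d2, d3, alpha, s1, s2) {
  structure(list(d2 = d2, d3 = d3, alpha = alpha, s1 = s1, s2 = s2),
            class = "muccss")
}

#' @export
format.muccss <- function(x, ...) {
  sprintf("<muccss d2=%.3f d3=%.3f alpha=%.1f deg s1=(%.2f,%.2f,%.2f) s2=(%.2f,%.2f,%.2f)>",
          x$d2, x$d3, x$alpha * 180 / pi,
          x$s1[1], x$s1[2], x$s1[3], x$s2[1], x$s2[2], x$s2[3])
}

#' @export
print.muccss <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Product-manifold distance between two MUCCSS points
#'
#' The canonical direct-product metric: the square root of the sum of squared
#' differences in `d2`, `d3` and `alpha` plus the two squared great-circle
#' distances between the glycosidic directions. All factors enter unweighted.
#'
#' @param w1,w2 `muccss` objects.
#' @return Non-negative scalar; zero iff the points are equal.
#' @export
muccss_distance <- function(w1, w2) {
  sqrt((w1$d2 - w2$d2)^2 + (w1$d3 - w2$d3)^2 + (w1$alpha - w2$alpha)^2 +
         great_circle(w1$s1, w2$s1)^2 + great_circle(w1$s2, w2$s2)^2)
}

# arc length between unit vectors; the atan2 form stays accurate for nearly
# identical directions, where acos of the dot product loses half the digits
great_circle <- function(a, b) {
  atan2(vnorm(cross3(a, b)), sum(a * b))
}

#' Frechet mean of MUCCSS points
#'
#' Minimises the mean squared product-metric distance over the sample. On the
#' flat factors (`d2`, `d3`, `alpha`) the minimiser is the arithmetic mean,
#' exactly. On each sphere factor the intrinsic mean is found by the standard
#' log/exp fixed-point iteration, initialised at the normalised chordal mean,
#' run to gradient norm below `tol`. Samples are assumed concentrated (one
#' geodesically convex region), as holds for conformer clusters.
#'
#' @param samples List of `muccss` objects (length >= 1).
#' @param tol Convergence tolerance on the tangent-mean norm.
#' @param max_iter Iteration cap; exceeded means non-convergence (error).
#' @return A `muccss` object.
#' @export
frechet_mean <- function(samples, tol = 1e-10, max_iter = 1000) {
  n <- length(samples)
  if (n == 0) stop("cannot take the Frechet mean of an empty sample", call. = FALSE)
  if (n == 1) return(samples[[1]])
  new_muccss(
    mean(vapply(samples, `[[`, 0, "d2")),
    mean(vapply(samples, `[[`, 0, "d3")),
    mean(vapply(samples, `[[`, 0, "alpha")),
    sphere_mean(do.call(rbind, lapply(samples, `[[`, "s1")), tol, max_iter),
    sphere_mean(do.call(rbind, lapply(samples, `[[`, "s2")), tol, max_iter)
  )
}

# intrinsic mean on the unit 2-sphere; rows of S are unit vectors
sphere_mean <- function(S, tol = 1e-10, max_iter = 1000) {
  m <- colMeans(S)
  nm <- vnorm(m)
  if (nm < 1e-12) stop("sphere mean undefined: chordal mean at the origin", call. = FALSE)
  m <- m / nm
  for (it in seq_len(max_iter)) {
    tang <- t(apply(S, 1, sphere_log, base = m))
    g <- colMeans(tang)
    m <- sphere_exp(m, g)
    if (vnorm(g) < tol) return(m)
  }
  stop(sprintf("sphere mean did not converge in %d iterations (last step %.3e)",
               max_iter, vnorm(g)), call. = FALSE)
}

# log map on S^2: tangent vector at `base` pointing to s, length = arc length
sphere_log <- function(s, base) {
  ct <- clamp1(sum(s * base))
  r <- s - base * ct
  nr <- vnorm(r)
  if (nr < 1e-15) return(c(0, 0, 0))
  r / nr * acos(ct)
}

sphere_exp <- function(base, t) {
  nt <- vnorm(t)
  if (nt < 1e-15) return(base)
  base * cos(nt) + t / nt * sin(nt)
}

# orthonormal tangent basis Q = (b | c) at a unit vector s, built as in the
# residual-coordinate construction: a = standard basis vector with the
# smallest |component along s| (lowest index wins ties), b = normalised
# component of a orthogonal to s, c = b x s
tangent_basis <- function(s) {
  k <- which.min(abs(s))
  a <- c(0, 0, 0); a[k] <- 1
  b <- a - s * sum(a * s)
  b <- b / vnorm(b)
  cc <- cross3(b, s)
  cbind(b, cc, deparse.level = 0)
}

#' Tangent-space coordinates of a MUCCSS point at a base point
#'
#' Linearises the manifold at `base` (typically a cluster Frechet mean): the
#' flat coordinates enter as plain differences, and each glycosidic direction
#' is projected onto the tangent plane of the sphere at the base direction in
#' a two-vector orthonormal basis depending only on that base direction
#' (residual coordinates). The data direction must lie in the open hemisphere
#' around the base direction, otherwise the chart does not apply.
#'
#' @param w,base `muccss` objects.
#' @return Numeric length-7 vector `(dd2, dd3, dalpha, s1~ (2), s2~ (2))`;
#'   zero when `w == base`.
#' @export
tangent_coords <- function(w, base) {
  for (nm in c("s1", "s2")) {
    if (sum(w[[nm]] * base[[nm]]) <= 0) {
      stop(sprintf("hemisphere violation for %s: point too far from the base direction", nm),
           call. = FALSE)
    }
  }
  c(w$d2 - base$d2, w$d3 - base$d3, w$alpha - base$alpha,
    as.numeric(crossprod(tangent_basis(base$s1), w$s1)),
    as.numeric(crossprod(tangent_basis(base$s2), w$s2)))
}

#' Tangent-space covariance of MUCCSS samples at a base point
#'
#' The scatter of tangent-space coordinate vectors at `base`, divided by
#' `n - 1`. The estimator is deliberately uncentred in the tangent space:
#' when `base` is the Frechet mean the flat coordinates are exactly centred
#' and the sphere coordinates are centred to first order.
#'
#' @param samples List of `muccss` objects, length >= 2.
#' @param base `muccss` base point (typically `frechet_mean(samples)`).
#' @return Symmetric positive semidefinite 7x7 matrix.
#' @export
tangent_covariance <- function(samples, base) {
  n <- length(samples)
  if (n < 2) stop("tangent covariance needs at least two samples", call. = FALSE)
  TT <- vapply(samples, tangent_coords, numeric(7), base = base)
  tcrossprod(TT) / (n - 1)
}

#' Frechet summary of a MUCCSS sample
#'
#' Convenience bundle: Frechet mean, tangent covariance at the mean, the
#' attained Frechet function value and the sample size.
#'
#' @inheritParams tangent_covariance
#' @return A list with `mean`, `covariance`, `n`, `frechet_value`.
#' @export
frechet_summary <- function(samples) {
  m <- frechet_mean(samples)
  list(
    mean = m,
    covariance = if (length(samples) >= 2) tangent_covariance(samples, m) else
      matrix(0, 7, 7),
    n = length(samples),
    frechet_value = mean(vapply(samples, muccss_distance, 0, w2 = m)^2)
  )
}

#' Low-detail landmarks of each suite
#'
#' Extracts the 5 landmark positions (N1/N9 and C1' of the first residue, P,
#' C1' and N1/N9 of the second residue) from a suite table as 5x3 matrices.
#'
#' @inheritParams suite_dihedrals
#' @return The input with a list-column `landmarks`.
#' @export
suite_landmarks <- function(suites) {
  suites$landmarks <- purrr::map(suites$atoms, function(at) {
    n_prev <- intersect(c("N9", "N1"), rownames(at$prev))[1]
    n_curr <- intersect(c("N9", "N1"), rownames(at$curr))[1]
    rbind(at$prev[n_prev, ], at$prev["C1'", ], at$curr["P", ],
          at$curr["C1'", ], at$curr[n_curr, ])
  })
  suites
}

#' MUCCSS coordinates for each suite in a table
#'
#' Adds a list-column `muccss` of [muccss_point()] objects plus flat numeric
#' columns `d2`, `d3`, `alpha_mu` (radians) and the polar angles of the two
#' glycosidic directions in degrees (`theta1`, `phi1`, `theta2`, `phi2`).
#'
#' @inheritParams suite_dihedrals
#' @return The input tibble with the new columns.
#' @export
suite_muccss <- function(suites) {
  if (!"landmarks" %in% names(suites)) suites <- suite_landmarks(suites)
  suites$muccss <- purrr::map(suites$landmarks, muccss_point)
  polar <- function(s) {
    c(theta = acos(clamp1(s[3])) * 180 / pi,
      phi = wrap360(atan2(s[2], s[1]) * 180 / pi))
  }
  suites$d2 <- purrr::map_dbl(suites$muccss, "d2")
  suites$d3 <- purrr::map_dbl(suites$muccss, "d3")
  suites$alpha_mu <- purrr::map_dbl(suites$muccss, "alpha")
  p1 <- purrr::map(suites$muccss, ~ polar(.x$s1))
  p2 <- purrr::map(suites$muccss, ~ polar(.x$s2))
  suites$theta1 <- purrr::map_dbl(p1, "theta")
  suites$phi1 <- purrr::map_dbl(p1, "phi")
  suites$theta2 <- purrr::map_dbl(p2, "theta")
  suites$phi2 <- purrr::map_dbl(p2, "phi")
  suites
}

clamp1 <- function(x) pmin(1, pmax(-1, x))
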