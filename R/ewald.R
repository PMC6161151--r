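#' Ewald summation parameters
#'
#' Chooses the splitting width and reciprocal-space cap from a target
#' relative accuracy: with \code{s = sqrt(-log(accuracy))} the real
#' space part is truncated where \code{erfc(alpha r)} has decayed to
#' the target (\code{alpha = s / cutoff}) and the reciprocal sum where
#' \code{exp(-k^2 / 4 alpha^2)} has (\code{k_cut = 2 alpha s}).
#'
#' @param box orthorhombic box edges, nm.
#' @param cutoff real-space cutoff, nm (must not exceed half the
#'   smallest box edge).
#' @param accuracy target relative accuracy (default 1e-5).
#' @param alpha optional explicit splitting width, nm^-1.
#' @param kmax optional explicit per-axis integer reciprocal cap.
#' @return list with \code{alpha}, \code{cutoff}, \code{kmax} (length
#'   3), \code{accuracy}.
#' @export
ewald_params <- function(box, cutoff = 0.9, accuracy = 1e-5,
                         alpha = NULL, kmax = NULL) {
  if (cutoff > min(box) / 2 + 1e-12)
    stop("ewald cutoff exceeds half the smallest box edge")
  s <- sqrt(-log(accuracy))
  alpha <- alpha %||% (s / cutoff)
  if (is.null(kmax)) kmax <- pmax(1L, ceiling(alpha * s * box / pi))
  if (length(kmax) == 1L) kmax <- rep(kmax, 3L)
  list(alpha = alpha, cutoff = cutoff, kmax = as.integer(kmax),
       accuracy = accuracy)
}

#' Classic Ewald Coulomb energy
#'
#' Real-space, reciprocal-space and self contributions for a periodic
#' orthorhombic system; excluded bonded pairs (1-2/1-3/1-4) have their
#' full interaction removed by an explicit erf correction.  Non-neutral
#' systems trigger a warning and receive the uniform background-charge
#' correction \code{-k pi Q^2 / (2 alpha^2 V)}.
#'
#' Because every term is quadratic in the charge vector, the
#' charge-zeroing decomposition ([intermolecular_coulomb_by_zeroing()])
#' is exact for this method.
#'
#' @param coords n x 3 coordinates, nm.
#' @param charges length-n charge vector, e.
#' @param box orthorhombic box edges, nm.
#' @param exclusions data.frame of excluded pairs (\code{i}, \code{j},
#'   \code{sep}), as stored in a [system_topology()].
#' @param params parameter list from [ewald_params()].
#' @return energy in kJ/mol.
#' @export
ewald_energy <- function(coords, charges, box, exclusions, params) {
  ke <- md_constants$k_coulomb
  alpha <- params$alpha
  n <- nrow(coords)
  V <- prod(box)
  q <- charges

  Q <- sum(q)
  e_bg <- 0
  if (abs(Q) > 1e-8) {
    warning("non-neutral system (Q = ", signif(Q, 6),
            " e): applying uniform background-charge correction")
    e_bg <- -ke * pi * Q^2 / (2 * alpha^2 * V)
  }

  # real space
  d2 <- pair_dist2(coords, box)
  qq <- outer(q, q)
  ex <- matrix(FALSE, n, n)
  if (nrow(exclusions)) {
    ij <- cbind(exclusions$i, exclusions$j)
    ex[ij] <- TRUE
    ex[ij[, 2:1, drop = FALSE]] <- TRUE
  }
  live <- upper.tri(d2) & !ex & qq != 0 & d2 <= params$cutoff^2
  if (any(live & d2 < 1e-12))
    stop("overlapping charged atoms (r < 1e-6 nm)")
  e_real <- 0
  if (any(live)) {
    r <- sqrt(d2[live])
    e_real <- ke * sum(qq[live] * pracma::erfc(alpha * r) / r)
  }

  # reciprocal space
  km <- params$kmax
  grid <- as.matrix(expand.grid(-km[1]:km[1], -km[2]:km[2], -km[3]:km[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  kvec <- sweep(grid, 2L, 2 * pi / box, "*")
  k2 <- rowSums(kvec * kvec)
  kcut2 <- (2 * alpha * sqrt(-log(params$accuracy)))^2
  keep <- k2 <= kcut2 * 1.0000001
  kvec <- kvec[keep, , drop = FALSE]
  k2 <- k2[keep]
  e_recip <- 0
  if (length(k2)) {
    phases <- coords %*% t(kvec)               # n x nk
    s_re <- as.numeric(crossprod(q, cos(phases)))
    s_im <- as.numeric(crossprod(q, sin(phases)))
    e_recip <- ke * (2 * pi / V) *
      sum(exp(-k2 / (4 * alpha^2)) / k2 * (s_re^2 + s_im^2))
  }

  # self term
  e_self <- -ke * alpha / sqrt(pi) * sum(q * q)

  # excluded-pair correction: the reciprocal sum contains the full
  # interaction of every pair; remove erf part for excluded pairs.
  e_excl <- 0
  if (nrow(exclusions)) {
    i <- exclusions$i; j <- exclusions$j
    qq_ex <- q[i] * q[j]
    sel <- qq_ex != 0
    if (any(sel)) {
      d <- min_image(coords[j[sel], , drop = FALSE] -
                     coords[i[sel], , drop = FALSE], box)
      r <- sqrt(rowSums(d * d))
      if (any(r < 1e-6)) stop("overlapping charged atoms in excluded pair")
      e_excl <- -ke * sum(qq_ex[sel] * pracma::erf(alpha * r) / r)
    }
  }

  e_real + e_recip + e_self + e_excl + e_bg
}
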