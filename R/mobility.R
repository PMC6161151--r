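#' Unwrap a periodic trajectory
#'
#' Removes box jumps by accumulating minimum-image displacements
#' between successive frames, so every atom's path is continuous.
#' Valid mean-squared-displacement analysis requires unwrapped
#' coordinates.  Already-unwrapped input is returned unchanged.
#'
#' @param traj an [md_trajectory()] with a box.
#' @return the unwrapped trajectory (wrapped flag cleared).
#' @export
unwrap_trajectory <- function(traj) {
  if (!traj$wrapped) return(traj)
  if (is.null(traj$box)) {
    traj$wrapped <- FALSE
    return(traj)
  }
  coords <- traj$coords
  nf <- dim(coords)[1]
  if (nf > 1L) {
    for (k in 1:3) {
      xk <- matrix(coords[, , k], nrow = nf)
      d <- xk[-1L, , drop = FALSE] - xk[-nf, , drop = FALSE]
      bk <- traj$box[-1L, k]
      shift <- round(d / bk)
      d <- d - shift * bk
      if (any(abs(d) >= bk / 2 * 0.999))
        stop("inter-frame displacement reaches half the box edge: ",
             "sampling too sparse to unwrap")
      unw <- apply(d, 2L, cumsum)
      if (is.null(dim(unw))) unw <- matrix(unw, nrow = 1L)
      coords[, , k] <- rbind(xk[1L, ], sweep(unw, 2L, xk[1L, ], "+"))
    }
  }
  traj$coords <- coords
  traj$wrapped <- FALSE
  traj
}

#' Wrap a trajectory into the primary box
#'
#' @param traj an [md_trajectory()] with a box.
#' @return the wrapped trajectory (coordinates in [0, box)).
#' @export
wrap_trajectory <- function(traj) {
  if (is.null(traj$box)) stop("cannot wrap without a box")
  for (k in 1:3) {
    bk <- traj$box[, k]
    traj$coords[, , k] <- traj$coords[, , k] -
      floor(traj$coords[, , k] / bk) * bk
  }
  traj$wrapped <- TRUE
  traj
}

# Per-frame molecule centers of mass for the chosen species.
# Returns array (n_frames, n_molecules, 3).
com_trajectory <- function(traj, topology, species = "all") {
  ids <- molecule_ids_of(topology, species)
  at <- topology$atoms
  n <- topology$n_atoms
  W <- matrix(0, n, length(ids))
  for (j in seq_along(ids)) {
    sel <- at$mol_id == ids[j]
    W[sel, j] <- at$mass[sel] / sum(at$mass[sel])
  }
  nf <- dim(traj$coords)[1]
  com <- array(NA_real_, c(nf, length(ids), 3L))
  for (k in 1:3)
    com[, , k] <- matrix(traj$coords[, , k], nrow = nf) %*% W
  com
}

#' Mean squared displacement of molecule centers of mass
#'
#' Multiple-time-origin average of
#' \code{|r_com(t0 + tau) - r_com(t0)|^2} over the molecules of a
#' species and over origins spaced \code{origin_stride} frames apart.
#'
#' @param traj an unwrapped [md_trajectory()].
#' @param topology a [system_topology()].
#' @param species molecule selector (see
#'   [species_intermolecular_coulomb()]); default \code{"role:api"}.
#' @param origin_stride frame spacing between time origins.
#' @param n_lags number of lag times evaluated (evenly spaced up to the
#'   trajectory length; lag 0 is always included).
#' @return object of class \code{msd_curve}: data.frame with
#'   \code{lag} (ps), \code{msd} (nm^2) and \code{n_origins}; the
#'   number of molecules is stored in attribute \code{n_molecules}.
#' @export
msd <- function(traj, topology, species = "role:api",
                origin_stride = 10L, n_lags = 100L) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("MSD needs at least 2 frames")
  if (traj$wrapped)
    stop("MSD requires unwrapped coordinates; call unwrap_trajectory()")
  com <- com_trajectory(traj, topology, species)
  nm <- dim(com)[2]
  lags <- unique(round(seq(0L, nf - 1L, length.out = min(n_lags + 1L, nf))))
  vals <- numeric(length(lags))
  nor <- integer(length(lags))
  for (li in seq_along(lags)) {
    L <- lags[li]
    if (L == 0L) { vals[li] <- 0; nor[li] <- nf; next }
    o <- seq.int(1L, nf - L, by = max(1L, origin_stride))
    d <- com[o + L, , , drop = FALSE] - com[o, , , drop = FALSE]
    # mean over origins and molecules of the axis-summed square
    vals[li] <- mean(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
    nor[li] <- length(o)
  }
  out <- data.frame(lag = lags * traj$dt, msd = vals, n_origins = nor)
  attr(out, "n_molecules") <- nm
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Translational diffusion coefficient from an MSD curve
#'
#' Least-squares line through the MSD over a lag window (default 10-50
#' percent of the maximum lag, where the curve is expected to be
#' diffusive), slope divided by 6 (Einstein relation in 3D) and
#' converted from nm^2/ps to 1e-10 cm^2/s.  The fit r^2 is reported so
#' ballistic or plateau regimes are visible.
#'
#' @param curve an \code{msd_curve} from [msd()] spanning at least 10
#'   lags.
#' @param fit_window lag window as fractions of the maximum lag.
#' @return object of class \code{diffusion_result}: list with \code{D}
#'   (1e-10 cm^2/s), \code{fit_window} (ps), \code{r2} and
#'   \code{slope} (nm^2/ps).
#' @export
diffusion_coefficient <- function(curve, fit_window = c(0.1, 0.5)) {
  if (nrow(curve) < 10L) stop("MSD curve spans fewer than 10 lags")
  tmax <- max(curve$lag)
  lo <- fit_window[1] * tmax; hi <- fit_window[2] * tmax
  sel <- curve$lag >= lo & curve$lag <= hi & curve$lag > 0
  if (sum(sel) < 2L) stop("fit window contains fewer than 2 lags")
  fit <- stats::lm(msd ~ lag, data = curve[sel, ])
  slope <- unname(stats::coef(fit)[2L])
  # exact synthetic lines trigger the "perfect fit" note; harmless here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  D <- slope / 6
  if (D < 0) {
    warning("negative fitted MSD slope; clamping D to 0")
    D <- 0
  }
  structure(list(D = D * md_constants$nm2_ps_to_1e10_cm2_s,
                 fit_window = c(lo, hi), r2 = r2, slope = slope),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("D = %.4g x 1e-10 cm^2/s (fit %g-%g ps, r^2 = %.3f)\n",
              x$D, x$fit_window[1], x$fit_window[2], x$r2))
  invisible(x)
}

#' Roto-vibrational fluctuation (RMSF) after center-of-mass removal
#'
#' For every molecule of the species the mass-weighted center of mass
#' is moved to the origin in each frame, keeping conformation and
#' orientation intact (no rotational superposition).  Each atom's root
#' mean square fluctuation about its average position is computed over
#' frames, and the values of all non-hydrogen atoms of all molecules
#' are averaged.
#'
#' @param traj an [md_trajectory()] with at least 2 frames; periodic
#'   trajectories must be unwrapped first.
#' @param topology a [system_topology()].
#' @param species molecule selector; default \code{"role:api"}.
#' @return object of class \code{fluctuation_result}: list with
#'   \code{value} (nm, heavy-atom average), \code{per_atom} (nm, all
#'   atoms of all selected molecules) and \code{n_molecules}.
#' @export
rmsf <- function(traj, topology, species = "role:api") {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  if (traj$wrapped)
    stop("RMSF requires unwrapped coordinates; call unwrap_trajectory()")
  ids <- molecule_ids_of(topology, species)
  at <- topology$atoms
  per_atom <- list(); heavy <- list()
  kept <- 0L
  for (m in ids) {
    sel <- which(at$mol_id == m)
    w <- at$mass[sel] / sum(at$mass[sel])
    nf <- n_frames(traj)
    dev2 <- 0
    centered <- vector("list", 3L)
    for (k in 1:3) {
      xk <- matrix(traj$coords[, sel, k], nrow = nf)   # nf x n_atoms
      xk <- xk - as.numeric(xk %*% w)                  # COM to origin
      centered[[k]] <- xk
    }
    for (k in 1:3) {
      xk <- centered[[k]]
      dev2 <- dev2 + sweep(xk, 2L, colMeans(xk))^2
    }
    fl <- sqrt(colMeans(dev2))
    is_heavy <- at$element[sel] != "H"
    if (!any(is_heavy)) {
      warning("molecule ", m, " has no heavy atoms; excluded from RMSF")
      next
    }
    kept <- kept + 1L
    per_atom[[length(per_atom) + 1L]] <- fl
    heavy[[length(heavy) + 1L]] <- fl[is_heavy]
  }
  if (!kept) stop("no molecules with heavy atoms in species ", species)
  structure(list(value = mean(unlist(heavy)),
                 per_atom = unlist(per_atom),
                 n_molecules = kept),
            class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf("RMSF = %.4g nm (heavy-atom average over %d molecules)\n",
              x$value, x$n_molecules))
  invisible(x)
}

#' Replicate mean and spread
#'
#' Aggregates per-replicate descriptor values (typically four
#' independent simulations) into an arithmetic mean and a sample
#' standard deviation (n - 1 denominator, the usual error-bar
#' convention).
#'
#' @param values numeric vector of per-replicate values.
#' @return list with \code{mean}, \code{sd} and \code{n}; \code{sd} is
#'   NA (with a warning) for fewer than 2 replicates.
#' @export
replicate_stats <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stop("no replicate values")
  s <- if (n >= 2L) stats::sd(values) else {
    warning("standard deviation undefined for a single replicate")
    NA_real_
  }
  list(mean = mean(values), sd = s, n = n)
}
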