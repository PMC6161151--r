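#' Geometric hydrogen-bond detection in one frame
#'
#' A hydrogen bond is reported when the donor--acceptor distance is at
#' most \code{d_cut} (minimum image) and the hydrogen--donor--acceptor
#' angle (vertex at the donor heavy atom) is at most \code{a_cut}.
#' Donors are N/O atoms with a covalently bound hydrogen (flagged
#' \code{is_donor_h} on the H), acceptors are N/O atoms (fluorine is
#' not an acceptor unless flagged explicitly in the topology).
#' Intramolecular pairs are reported too, flagged \code{intra}.
#'
#' Note the angle convention: the cutoff applies to the H-D-A angle at
#' the donor, not to the D-H...A angle at the hydrogen; conventions
#' differ between analysis tools.
#'
#' @param frame an [md_frame()].
#' @param topology a [system_topology()].
#' @param d_cut donor-acceptor distance cutoff, nm (default 0.35).
#' @param a_cut H-donor-acceptor angle cutoff, degrees (default 30).
#' @return data.frame with one row per bond: \code{donor},
#'   \code{hydrogen}, \code{acceptor} (global atom indices),
#'   \code{distance} (nm), \code{angle} (degrees), \code{intra}
#'   (logical) and \code{pair} (species-pair label such as
#'   \code{"api-polymer"}).
#' @export
find_hbonds <- function(frame, topology, d_cut = 0.35, a_cut = 30) {
  at <- topology$atoms
  x <- frame$coords
  box <- frame$box
  hs <- which(at$is_donor_h)
  acc <- which(at$is_acceptor)
  empty <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric(), intra = logical(),
                      pair = character())
  if (!length(hs) || !length(acc)) return(empty)
  # donor heavy atom of each flagged H: its bonded N/O partner
  # (1-2 exclusion pairs are exactly the bonds)
  b <- topology$exclusions
  b <- b[b$sep == 1L, , drop = FALSE]
  partner <- function(h) {
    cand <- c(b$j[b$i == h], b$i[b$j == h])
    cand[at$element[cand] %in% c("N", "O")][1L]
  }
  out <- list()
  for (h in hs) {
    d <- partner(h)
    if (is.na(d) || !length(d)) next
    a_ok <- acc[acc != d]
    if (!length(a_ok)) next
    da <- min_image(x[a_ok, , drop = FALSE] -
                    matrix(x[d, ], length(a_ok), 3L, byrow = TRUE), box)
    dist <- sqrt(rowSums(da * da))
    near <- dist <= d_cut
    if (!any(near)) next
    dh <- min_image(matrix(x[h, ] - x[d, ], 1L), box)[1L, ]
    ang <- vapply(which(near), function(ii) {
      u <- da[ii, ]
      cosang <- sum(dh * u) / sqrt(sum(dh^2) * sum(u^2))
      acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }, 0)
    pass <- ang <= a_cut
    if (!any(pass)) next
    aa <- a_ok[near][pass]
    out[[length(out) + 1L]] <- data.frame(
      donor = d, hydrogen = h, acceptor = aa,
      distance = dist[near][pass], angle = ang[pass],
      intra = at$mol_id[aa] == at$mol_id[d],
      pair = vapply(aa, function(a2)
        paste(sort(c(at$role[d], at$role[a2])), collapse = "-"), ""))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-frame hydrogen-bond counts over a trajectory
#'
#' @param traj an [md_trajectory()].
#' @param topology a [system_topology()].
#' @param d_cut,a_cut see [find_hbonds()].
#' @param frames optional frame indices (default all).
#' @return data.frame with \code{frame}, \code{time}, \code{n} (total),
#'   \code{n_intra}, \code{n_inter} and per species-pair counts for
#'   inter-molecular bonds involving both roles
#'   (\code{n_api_polymer}).
#' @export
count_hbonds <- function(traj, topology, d_cut = 0.35, a_cut = 30,
                         frames = NULL) {
  idx <- frames %||% seq_len(n_frames(traj))
  rows <- lapply(idx, function(i) {
    hb <- find_hbonds(get_frame(traj, i), topology, d_cut, a_cut)
    data.frame(frame = i, time = traj$times[i], n = nrow(hb),
               n_intra = sum(hb$intra), n_inter = sum(!hb$intra),
               n_api_polymer = sum(!hb$intra & hb$pair == "api-polymer"))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Change in hydrogen-bond count upon mixing
#'
#' \code{dNHB = <N_blend> - (<N_pure_api> * napi_blend / napi_pure +
#' <N_pure_polymer> * npol_blend / npol_pure)}: the blend average minus
#' the pure-phase averages scaled to the same number of molecules.
#'
#' @param blend,pure_api,pure_polymer lists with elements \code{traj}
#'   (an [md_trajectory()]) and \code{topology} (a
#'   [system_topology()]).  The blend topology must contain molecules
#'   with role \code{"api"} and role \code{"polymer"}; each pure
#'   topology must contain the corresponding role.
#' @param d_cut,a_cut see [find_hbonds()].
#' @param window trailing fraction of frames averaged (see
#'   [window_frames()]); default uses every frame.
#' @return list with \code{delta_nhb}, the three phase averages
#'   (\code{n_blend}, \code{n_pure_api_scaled},
#'   \code{n_pure_polymer_scaled}) and the blend's average
#'   API-polymer cross-bond count (\code{n_cross_api_polymer}).
#' @export
delta_nhb <- function(blend, pure_api, pure_polymer,
                      d_cut = 0.35, a_cut = 30, window = 1) {
  n_role <- function(topology, role) {
    a <- topology$atoms
    length(unique(a$mol_id[a$role == role]))
  }
  napi_b <- n_role(blend$topology, "api")
  npol_b <- n_role(blend$topology, "polymer")
  napi_p <- n_role(pure_api$topology, "api")
  npol_p <- n_role(pure_polymer$topology, "polymer")
  if (napi_b == 0L || npol_b == 0L)
    stop("blend topology must contain api and polymer molecules")
  if (napi_p == 0L) stop("pure_api topology has no api molecules")
  if (npol_p == 0L) stop("pure_polymer topology has no polymer molecules")
  avg <- function(x) {
    cnt <- count_hbonds(x$traj, x$topology, d_cut, a_cut,
                        frames = window_frames(x$traj, window))
    cnt
  }
  cb <- avg(blend); ca <- avg(pure_api); cp <- avg(pure_polymer)
  n_b <- mean(cb$n)
  n_a <- mean(ca$n) * napi_b / napi_p
  n_p <- mean(cp$n) * npol_b / npol_p
  list(delta_nhb = n_b - n_a - n_p,
       n_blend = n_b, n_pure_api_scaled = n_a,
       n_pure_polymer_scaled = n_p,
       n_cross_api_polymer = mean(cb$n_api_polymer))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with
#'   nonzero variance (zero variance is flagged as undefined).
#' @return list of class \code{correlation_result} with \code{r} and
#'   \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  structure(list(r = stats::cor(x, y), n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d)\n", x$r, x$n))
  invisible(x)
}
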