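#' Join per-blend descriptors with experimental stability records
#'
#' @param descriptors data.frame keyed by \code{api}, \code{polymer}
#'   with descriptor columns (e.g. \code{dE_coul}, \code{dNHB},
#'   \code{D}, \code{RMSF}, optionally \code{*_sd} replicate spreads).
#' @param stability data.frame keyed by \code{api}, \code{polymer} with
#'   amorphicity-index columns (\code{AI25}, \code{AI40},
#'   \code{AI_mean}; dimensionless 0-100).
#' @return merged data.frame, one row per blend.
#' @export
descriptor_table <- function(descriptors, stability) {
  for (d in list(descriptors, stability))
    if (!all(c("api", "polymer") %in% names(d)))
      stop("tables must have api and polymer columns")
  ai <- intersect(c("AI25", "AI40", "AI_mean"), names(stability))
  for (cn in ai) {
    v <- stability[[cn]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("amorphicity indices must lie in [0, 100]")
  }
  out <- merge(descriptors, stability, by = c("api", "polymer"))
  if (anyDuplicated(out[c("api", "polymer")]))
    stop("more than one row per blend")
  out
}

#' Range of a descriptor across the polymers of one API
#'
#' @param table a descriptor table (see [descriptor_table()] or
#'   [asd_descriptors()]).
#' @param api API name.
#' @param descriptor descriptor column name.
#' @return \code{max - min} over that API's polymers, in the
#'   descriptor's own units.
#' @export
descriptor_range <- function(table, api, descriptor) {
  rows <- table[table$api == api, , drop = FALSE]
  if (nrow(rows) < 2L) stop("need at least 2 blends for API ", api)
  v <- rows[[descriptor]]
  if (is.null(v)) stop("no descriptor column '", descriptor, "'")
  if (anyNA(v)) stop("missing values in descriptor '", descriptor, "'")
  max(v) - min(v)
}

#' Association between a descriptor and amorphous stability
#'
#' Rank (Spearman) correlation between a descriptor and the
#' amorphicity index across the polymers of one API; Pearson is
#' reported alongside for transparency.  Ties (common at the AI
#' ceiling of 100) receive mid-ranks.  The stability-favourable
#' direction is negative for both descriptor families used here: lower
#' mixing energy and lower mobility are both expected to accompany a
#' higher AI.
#'
#' @param table a descriptor table.
#' @param api API name.
#' @param descriptor descriptor column name.
#' @param ai stability column (default \code{"AI40"}).
#' @return list with \code{spearman}, \code{pearson}, \code{n} and
#'   \code{flag} (\code{"ok"}, \code{"low_power"} for n < 3, or
#'   \code{"undefined"} when either variable has zero variance, in
#'   which case the correlations are NA).
#' @export
descriptor_stability_association <- function(table, api, descriptor,
                                             ai = "AI40") {
  rows <- table[table$api == api, , drop = FALSE]
  x <- rows[[descriptor]]; y <- rows[[ai]]
  if (is.null(x) || is.null(y))
    stop("missing descriptor or stability column")
  n <- length(x)
  if (n < 2L) stop("need at least 2 blends for API ", api)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(spearman = NA_real_, pearson = NA_real_, n = n,
                flag = "undefined"))
  list(spearman = stats::cor(x, y, method = "spearman"),
       pearson = stats::cor(x, y),
       n = n,
       flag = if (n < 3L) "low_power" else "ok")
}

# TRUE when every pair of per-polymer values lies within the sum of
# their error bars: the descriptor does not discriminate the blends.
.all_overlap <- function(v, s) {
  n <- length(v)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (abs(v[i] - v[j]) > s[i] + s[j]) return(FALSE)
  TRUE
}

#' Classify the stability-limiting factor for one API
#'
#' Compares how strongly the thermodynamic descriptor (mixing energy)
#' and the kinetic descriptor (diffusion coefficient) associate with
#' the amorphicity index across polymers.  Each descriptor's strength
#' is its Spearman correlation with AI taken in the
#' stability-favourable direction (negative; see
#' [descriptor_stability_association()]) and floored at zero, so a
#' descriptor correlating the "wrong" way contributes nothing.  If
#' replicate standard deviations are available
#' (columns \code{<descriptor>_sd}) a descriptor whose per-polymer
#' values all mutually overlap within one standard deviation is
#' treated as non-discriminating; without them the screening is
#' skipped with a warning.
#'
#' @param table a descriptor table.
#' @param api API name.
#' @param energy,mobility descriptor column names (defaults
#'   \code{"dE_coul"}, \code{"D"}).
#' @param ai stability column (default \code{"AI40"}).
#' @param threshold required strength difference (default 0.3).
#' @return list with \code{classification} (\code{"thermodynamic"},
#'   \code{"kinetic"} or \code{"indeterminate"}), the signed rank
#'   correlations \code{rho_energy}, \code{rho_mobility}, the floored
#'   \code{strength_energy}, \code{strength_mobility}, and
#'   \code{threshold}.
#' @export
classify_limiting_factor <- function(table, api, energy = "dE_coul",
                                     mobility = "D", ai = "AI40",
                                     threshold = 0.3) {
  strength <- function(descriptor) {
    assoc <- descriptor_stability_association(table, api, descriptor, ai)
    rho <- assoc$spearman
    s <- if (is.na(rho)) 0 else max(0, -rho)
    sd_col <- paste0(descriptor, "_sd")
    rows <- table[table$api == api, , drop = FALSE]
    if (!is.null(rows[[sd_col]]) && !anyNA(rows[[sd_col]])) {
      if (.all_overlap(rows[[descriptor]], rows[[sd_col]])) s <- 0
    } else {
      warning("no replicate spread column '", sd_col,
              "'; overlap screening skipped")
    }
    list(rho = rho, s = s)
  }
  e <- strength(energy)
  m <- strength(mobility)
  cls <- if (e$s - m$s > threshold) "thermodynamic"
         else if (m$s - e$s > threshold) "kinetic"
         else "indeterminate"
  list(classification = cls,
       rho_energy = e$rho, rho_mobility = m$rho,
       strength_energy = e$s, strength_mobility = m$s,
       threshold = threshold)
}
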