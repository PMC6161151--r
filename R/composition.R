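#' Molecular mass from a chemical formula
#'
#' @param formula either a formula string such as \code{"C14H10F3NO2"}
#'   or a named numeric vector of element counts.
#' @return mass in amu (sum of standard atomic weights times counts).
#' @examples
#' molecular_mass("C14H10F3NO2")  # flufenamic acid, 281.23
#' molecular_mass("C10H13NO2")    # phenacetin, 179.22
#' @export
molecular_mass <- function(formula) {
  if (is.character(formula)) {
    stopifnot(length(formula) == 1L)
    toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (!length(toks) || sum(nchar(toks)) != nchar(formula))
      stop("cannot parse formula '", formula, "'")
    el <- sub("[0-9]*$", "", toks)
    ct <- as.numeric(sub("^[A-Za-z]+", "", toks))
    ct[is.na(ct)] <- 1
    counts <- tapply(ct, el, sum)
  } else {
    counts <- formula
    if (is.null(names(counts))) stop("element counts must be named")
  }
  sum(atomic_weight(names(counts)) * as.numeric(counts))
}

#' API weight percent of a blend
#'
#' @param napi number of API molecules.
#' @param api_mass molecular mass of the API, amu.
#' @param total_mass total blend mass, amu.
#' @return weight percent, \code{100 * napi * api_mass / total_mass}.
#' @export
api_weight_percent <- function(napi, api_mass, total_mass) {
  if (any(napi * api_mass <= 0)) stop("napi * api_mass must be > 0")
  if (any(total_mass < napi * api_mass))
    stop("total_mass smaller than the API mass it should contain")
  100 * napi * api_mass / total_mass
}

#' Blend composition record
#'
#' Bookkeeping for one drug-polymer blend: molecule counts, total mass,
#' API weight percent and (optionally) the average simulation volume.
#'
#' @param polymer_name,api_name species names.
#' @param npol number of polymer chains.
#' @param nmon monomers per chain.
#' @param napi number of API molecules.
#' @param api_mass API molecular mass, amu.
#' @param total_mass total system mass, amu.
#' @param volume average box volume in nm^3, or NA.
#' @return an object of class \code{blend_composition} (a one-row
#'   data.frame with a derived \code{w_api} column).
#' @export
blend_composition <- function(polymer_name, npol, nmon, api_name, napi,
                              api_mass, total_mass, volume = NA_real_) {
  if (total_mass <= 0) stop("total_mass must be > 0")
  w <- if (napi > 0) api_weight_percent(napi, api_mass, total_mass) else 0
  if (w < 0 || w > 100) stop("derived w_api outside [0, 100]")
  structure(data.frame(polymer = polymer_name, npol = npol, nmon = nmon,
                       api = api_name, napi = napi, api_mass = api_mass,
                       total_mass = total_mass, w_api = w,
                       volume = volume),
            class = c("blend_composition", "data.frame"))
}

#' Enumerate blend compositions over APIs, polymers and target loads
#'
#' Builds the Cartesian product of APIs, polymers and target API weight
#' fractions.  For each combination the integer API count minimizing
#' \code{|w_api - target|} is chosen, where \code{w_api} is computed
#' against \code{napi * api_mass + polymer_mass}.
#'
#' @param apis data.frame with columns \code{name}, \code{mass} (amu per
#'   molecule).
#' @param polymers data.frame with columns \code{name}, \code{npol},
#'   \code{nmon} and \code{mass} (total polymer mass of the system, amu).
#' @param target_wt_percent numeric vector of target API loads (weight
#'   percent, 0-100 exclusive).
#' @return data.frame of blend compositions, one row per combination.
#' @export
enumerate_blends <- function(apis, polymers, target_wt_percent) {
  if (!nrow(apis) || !nrow(polymers) || !length(target_wt_percent))
    stop("apis, polymers and target_wt_percent must be non-empty")
  if (any(polymers$mass <= 0)) stop("polymer mass must be > 0")
  if (any(target_wt_percent <= 0 | target_wt_percent >= 100))
    stop("target weight percents must lie in (0, 100)")
  out <- list()
  for (a in seq_len(nrow(apis))) for (p in seq_len(nrow(polymers)))
    for (w in target_wt_percent) {
      ma <- apis$mass[a]; mp <- polymers$mass[p]
      # w = 100 n ma / (n ma + mp)  =>  n* = w mp / (ma (100 - w))
      n_star <- w * mp / (ma * (100 - w))
      cand <- unique(pmax(1L, c(floor(n_star), ceiling(n_star))))
      wc <- 100 * cand * ma / (cand * ma + mp)
      n_best <- cand[which.min(abs(wc - w))]
      out[[length(out) + 1L]] <- blend_composition(
        polymers$name[p], polymers$npol[p] %||% NA, polymers$nmon[p] %||% NA,
        apis$name[a], n_best, ma, n_best * ma + mp)
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recompute API weight percents for a composition table
#'
#' Checks the internal consistency of a printed composition table by
#' recomputing \code{w_api} from the API count, the API molecular mass
#' and the printed total mass.  Where a pure-polymer mass is available
#' an alternative value \code{w_alt = 100 n M / (n M + m_pure)} is also
#' reported; tables whose printed total mass is inconsistent with the
#' stated molecule content (as happens for the PSA rows of the bundled
#' table) match \code{w_alt} instead of \code{w_recomputed}.
#'
#' @param comp data.frame with columns \code{polymer}, \code{api},
#'   \code{napi}, \code{total_mass}, \code{w_api}; rows with
#'   \code{napi = 0} or 100 percent API are passed through.
#' @param api_masses named numeric vector of API molecular masses, amu.
#' @param pure_polymer_mass optional named numeric vector of pure
#'   polymer system masses, amu (names = polymer names).
#' @return the input with added columns \code{w_recomputed},
#'   \code{w_alt} and \code{w_diff} (= recomputed - printed).
#' @export
weight_percent_check <- function(comp, api_masses,
                                 pure_polymer_mass = NULL) {
  comp <- as.data.frame(comp)
  w_re <- rep(NA_real_, nrow(comp))
  w_alt <- rep(NA_real_, nrow(comp))
  for (r in seq_len(nrow(comp))) {
    napi <- comp$napi[r]
    if (is.na(napi) || napi == 0) next
    ma <- api_masses[[comp$api[r]]]
    if (is.null(ma)) stop("no molecular mass for API ", comp$api[r])
    w_re[r] <- api_weight_percent(napi, ma, comp$total_mass[r])
    if (!is.null(pure_polymer_mass) &&
        comp$polymer[r] %in% names(pure_polymer_mass)) {
      mp <- pure_polymer_mass[[comp$polymer[r]]]
      w_alt[r] <- 100 * napi * ma / (napi * ma + mp)
    }
  }
  comp$w_recomputed <- w_re
  comp$w_alt <- w_alt
  comp$w_diff <- w_re - comp$w_api
  comp
}
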