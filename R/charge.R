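# pH-dependent dominant-state net charge and counterion bookkeeping.
#
# The pentapeptide carries five titratable groups; with the standard
# pKa set (Glu side 4.2, Arg side 12.5, Lys side 10.5, N-terminus ~8,
# C-terminus ~3) the dominant-state net charge ladder is +2 / +1 / 0 at
# pH 4 / 7 / 10. The cysteine thiol (pKa ~8.3) is treated as
# non-titrating by default, consistent with that ladder, and can be
# enabled explicitly.

#' Default ionizable sites of CREKA / CRENKA
#'
#' @param include_cys Also titrate the cysteine thiol (pKa 8.3, acid).
#'   Off by default: the +2/+1/0 charge ladder across pH 4-10 treats
#'   the thiol as non-titrating.
#' @return Data frame with columns `name`, `pKa`, `kind` (`"ACID"`:
#'   neutral/-1, `"BASE"`: +1/neutral).
#' @export
default_sites <- function(include_cys = FALSE) {
  out <- data.frame(
    name = c("Glu-side", "Arg-side", "Lys-side", "N-term", "C-term"),
    pKa = c(4.2, 12.5, 10.5, 8.0, 3.0),
    kind = c("ACID", "BASE", "BASE", "BASE", "ACID"),
    stringsAsFactors = FALSE)
  if (include_cys) {
    out <- rbind(out, data.frame(name = "Cys-side", pKa = 8.3,
                                 kind = "ACID", stringsAsFactors = FALSE))
  }
  out
}

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1L,
            all(c("name", "pKa", "kind") %in% names(sites)))
  if (!all(is.finite(sites$pKa))) stop("non-finite pKa")
  if (!all(sites$kind %in% c("ACID", "BASE"))) {
    stop("site kind must be ACID or BASE")
  }
  invisible(sites)
}

#' Dominant-protonation-state net charge at a given pH
#'
#' Each site is protonated iff `pH < pKa` (strictly; the tie at
#' `pH == pKa` resolves as deprotonated). A protonated acid contributes
#' 0 and a deprotonated acid -1; a protonated base +1 and a
#' deprotonated base 0. The net charge is the sum over sites.
#'
#' @param pH pH value; values outside `[0, 14]` produce a warning.
#' @param sites Site table as in [default_sites()].
#' @return List of class `"charge_profile"`: `pH`, `per_site_charge`
#'   (named integer vector) and `net` (integer).
#' @export
dominant_charge <- function(pH, sites = default_sites()) {
  validate_sites(sites)
  if (pH < 0 || pH > 14) {
    warning("pH ", pH, " outside the [0, 14] range")
  }
  protonated <- pH < sites$pKa
  q <- ifelse(sites$kind == "ACID",
              ifelse(protonated, 0L, -1L),
              ifelse(protonated, 1L, 0L))
  per_site <- setNames(as.integer(q), sites$name)
  structure(list(pH = pH, per_site_charge = per_site,
                 net = sum(per_site)),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("<charge_profile> pH %.2f, net %+d\n", x$pH, x$net))
  sgn <- sprintf("%+d", x$per_site_charge)
  cat(paste0("  ", format(names(x$per_site_charge)), " ", sgn,
             collapse = "\n"), "\n")
  invisible(x)
}

#' Henderson-Hasselbalch fractional net charge
#'
#' Smooth version of [dominant_charge()]: an acid site contributes
#' `-1 / (1 + 10^(pKa - pH))` and a base `+1 / (1 + 10^(pH - pKa))`.
#' Continuous and non-increasing in pH; converges to the dominant-state
#' charge as `|pH - pKa|` grows.
#'
#' @inheritParams dominant_charge
#' @return Net fractional charge (numeric scalar).
#' @export
fractional_charge <- function(pH, sites = default_sites()) {
  validate_sites(sites)
  acid <- sites$kind == "ACID"
  sum(ifelse(acid,
             -1 / (1 + 10^(sites$pKa - pH)),
             1 / (1 + 10^(pH - sites$pKa))))
}

#' Counterions needed to neutralise a multi-chain system
#'
#' One counterion charge per unit of dominant-state net charge per
#' chain: chloride for positively charged peptides (one per strand at
#' pH 7, where the net charge is +1), sodium for negative, none at zero
#' net charge.
#'
#' @param n_chains Number of peptide chains (>= 0).
#' @param pH pH value.
#' @param sites Site table as in [default_sites()].
#' @return List with `species` (`"chloride"`, `"sodium"` or `"none"`)
#'   and integer `count`.
#' @export
counterions_needed <- function(n_chains, pH, sites = default_sites()) {
  stopifnot(n_chains >= 0)
  net <- dominant_charge(pH, sites)$net
  species <- if (net > 0L) "chloride" else if (net < 0L) "sodium" else
    "none"
  list(species = species, count = as.integer(n_chains * abs(net)))
}
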