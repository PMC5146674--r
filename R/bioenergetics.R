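# Anode-potential bioenergetics: energy gain of anode respiration as a
# function of set potential, full-reaction Gibbs free energies at pH 7,
# and thermodynamic ranking of anode respiration vs methanogenesis.

#' Donor redox couples
#'
#' Standard biological redox potentials (V vs SHE, pH 7, 25 degC) of the
#' donor half-couples used for anode-respiration energetics. Two
#' profiles are shipped: `"paper"` (back-derived from the printed
#' free-energy grid they reproduce exactly) and `"literature"`
#' (textbook values). The two differ by a few mV to tens of mV; the
#' formate potential differs most.
#'
#' @param profile `"paper"` (default) or `"literature"`.
#' @return data.frame with columns `donor`, `n` (electrons per mol
#'   donor) and `E0prime_V`.
#' @export
donor_couples <- function(profile = c("paper", "literature")) {
  profile <- match.arg(profile)
  e0 <- switch(profile,
    paper      = c(acetate = -0.278, H2 = -0.413, formate = -0.489),
    literature = c(acetate = -0.290, H2 = -0.414, formate = -0.432)
  )
  data.frame(donor = names(e0), n = c(8L, 2L, 2L), E0prime_V = unname(e0))
}

#' Redox couple constructor
#'
#' @param name identifier.
#' @param n electrons transferred per mol donor (> 0).
#' @param E0prime_V standard biological redox potential (V vs SHE),
#'   within (-1, 1).
#' @return Object of class `redox_couple`.
#' @export
redox_couple <- function(name, n, E0prime_V) {
  stopifnot(n > 0, E0prime_V > -1, E0prime_V < 1)
  structure(list(name = name, n = n, E0prime_V = E0prime_V),
            class = "redox_couple")
}

# accept a redox_couple, a donor name (looked up in a profile), or a row
resolve_couple <- function(couple, profile = "paper") {
  if (inherits(couple, "redox_couple")) return(couple)
  if (is.character(couple) && length(couple) == 1L) {
    dc <- donor_couples(profile)
    i <- match(couple, dc$donor)
    if (is.na(i)) stop("unknown donor couple: ", couple)
    return(redox_couple(couple, dc$n[i], dc$E0prime_V[i]))
  }
  stop("expected a redox_couple or a donor name")
}

#' Energy gain of anode respiration at a set potential
#'
#' Maximum energy available to a microbe oxidizing a donor with the
#' anode as terminal electron acceptor:
#' dG0' = -n F (E_anode - E0'), in kJ per mol donor (one decimal).
#' Negative values are exergonic; the gain grows linearly with the set
#' potential at slope -nF.
#'
#' @param e_anode_V set anode potential(s), V vs SHE.
#' @param couple a `redox_couple`, or a donor name (`"acetate"`,
#'   `"H2"`, `"formate"`).
#' @param profile constants profile for named donors; see
#'   [donor_couples()].
#' @return kJ/mol donor, rounded to one decimal; vectorized over
#'   `e_anode_V`.
#' @examples
#' anode_energy_gain(0, "acetate") # -214.6
#' @export
anode_energy_gain <- function(e_anode_V, couple, profile = "paper") {
  cp <- resolve_couple(couple, profile)
  round(-cp$n * FARADAY * (e_anode_V - cp$E0prime_V) / 1000, 1)
}

#' Gibbs free energy of a balanced reaction at pH 7
#'
#' dG0' = sum(nu_i dGf'0_i) over signed stoichiometric coefficients
#' (products positive, reactants negative), using the registry's
#' formation free energies (Thauer convention, H+ at -39.87 kJ/mol).
#' The reaction must balance in C, H, O, N and charge.
#'
#' @param stoichiometry named numeric vector of signed coefficients over
#'   registry compound names, e.g.
#'   `c(H2 = -4, HCO3 = -1, "H+" = -1, CH4 = 1, H2O = 3)`.
#' @param registry compound registry with `dGf` values.
#' @return kJ per mole of reaction as written, rounded to one decimal.
#' @examples
#' reaction_deltaG(c(H2 = -4, HCO3 = -1, `H+` = -1, CH4 = 1, H2O = 3))
#' @export
reaction_deltaG <- function(stoichiometry, registry = compound_registry()) {
  stopifnot(is.numeric(stoichiometry))
  if (length(stoichiometry) == 0L) return(0)
  stopifnot(!is.null(names(stoichiometry)))
  cps <- lapply(names(stoichiometry), resolve_compound, registry = registry)
  # element and charge balance
  bal <- c(C = 0, H = 0, O = 0, N = 0, charge = 0)
  for (i in seq_along(cps)) {
    bal[1:4] <- bal[1:4] + stoichiometry[i] * cps[[i]]$composition
    bal["charge"] <- bal["charge"] + stoichiometry[i] * cps[[i]]$charge
  }
  if (any(abs(bal) > 1e-9)) {
    stop("reaction is not balanced (residual: ",
         paste(names(bal), round(bal, 6), sep = "=", collapse = ", "), ")")
  }
  dgf <- vapply(cps, function(cp) {
    if (is.na(cp$dGf)) stop("missing dGf for compound '", cp$name, "'")
    cp$dGf
  }, numeric(1))
  round(sum(stoichiometry * dgf), 1)
}

#' Methanogenic reference reactions
#'
#' Hydrogenotrophic (from H2), acetoclastic (from acetate) and
#' formate-based methanogenesis, written with HCO3- as the carbonate
#' species.
#'
#' @return Named list; each entry has `stoichiometry` (signed
#'   coefficients), `donor` and `nu_donor` (mol donor consumed per mole
#'   of reaction as written).
#' @export
methanogenic_reactions <- function() {
  list(
    hydrogenotrophic = list(
      stoichiometry = c(H2 = -4, HCO3 = -1, `H+` = -1, CH4 = 1, H2O = 3),
      donor = "H2", nu_donor = 4),
    acetoclastic = list(
      stoichiometry = c(acetate = -1, H2O = -1, CH4 = 1, HCO3 = 1),
      donor = "acetate", nu_donor = 1),
    formate = list(
      stoichiometry = c(formate = -4, H2O = -1, `H+` = -1, CH4 = 1,
                        HCO3 = 3),
      donor = "formate", nu_donor = 4)
  )
}

#' Reaction-quotient correction
#'
#' dG = dG0' + RT ln Q, for conditions away from 1 M / 1 atm. Not used
#' by the standard-condition ranking; provided as a helper.
#'
#' @param deltaG0_kJ standard free energy (kJ/mol).
#' @param Q reaction quotient (> 0).
#' @param temp_K temperature (K).
#' @return kJ/mol.
#' @export
deltaG_with_quotient <- function(deltaG0_kJ, Q, temp_K = 298.15) {
  stopifnot(Q > 0)
  deltaG0_kJ + 8.314462618e-3 * temp_K * log(Q)
}

#' Thermodynamic favorability of current vs methane per donor
#'
#' For every (set potential, donor) pair, reports the standard-condition
#' free energy of oxidizing the donor to electrical current (via the
#' anode-potential model) and to methane (via the packaged methanogenic
#' reactions), and which sink is preferred. To rank routes with
#' different stoichiometries on a common basis, the comparison uses
#' kJ per mol donor (the reaction value divided by its donor
#' coefficient); the per-reaction value as written is also reported.
#'
#' @param e_anode_V vector of set potentials (V vs SHE).
#' @param donors donor names among `"acetate"`, `"H2"`, `"formate"`.
#' @param profile constants profile; see [donor_couples()].
#' @param registry compound registry.
#' @return data.frame with one row per (potential, donor):
#'   `dG_current_kJ_mol` (per mol donor), `dG_ch4_kJ_rxn` (per reaction
#'   as written), `dG_ch4_kJ_mol` (per mol donor), `preferred`
#'   (`"current"`, `"methane"` or `"tie"`).
#' @examples
#' favorability_matrix(c(-0.25, 0, 0.25), "acetate")
#' @export
favorability_matrix <- function(e_anode_V,
                                donors = c("acetate", "H2", "formate"),
                                profile = "paper",
                                registry = compound_registry()) {
  stopifnot(length(e_anode_V) >= 1, length(donors) >= 1)
  rxns <- methanogenic_reactions()
  rx_by_donor <- stats::setNames(rxns, vapply(rxns, `[[`, "", "donor"))
  rows <- expand.grid(e_anode_V = e_anode_V, donor = donors,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    ea <- rows$e_anode_V[i]
    d <- rows$donor[i]
    rx <- rx_by_donor[[d]]
    if (is.null(rx)) stop("no methanogenic reaction for donor: ", d)
    g_cur <- anode_energy_gain(ea, d, profile)
    g_rxn <- reaction_deltaG(rx$stoichiometry, registry)
    g_ch4 <- g_rxn / rx$nu_donor
    pref <- if (isTRUE(all.equal(g_cur, g_ch4))) "tie"
            else if (g_cur < g_ch4) "current" else "methane"
    data.frame(e_anode_V = ea, donor = d, dG_current_kJ_mol = g_cur,
               dG_ch4_kJ_rxn = g_rxn, dG_ch4_kJ_mol = g_ch4,
               preferred = pref, stringsAsFactors = FALSE)
  }))
  out[order(out$donor, out$e_anode_V), , drop = FALSE]
}
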