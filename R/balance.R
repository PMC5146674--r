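# Electron ledger: distribute donor electron equivalents over measured
# sinks (current, methane, hydrogen, residual acids) and close the
# balance with an "undefined" remainder (biomass, soluble microbial
# products, unmeasured losses).

#' Electron equivalents of an amount of a compound
#'
#' @param amount_mol moles (>= 0).
#' @param compound a [compound] or registry name.
#' @param registry compound registry.
#' @return Electron equivalents (mol e- eq).
#' @seealso [charge_equivalents()] for converting coulombs.
#' @export
sink_equivalents <- function(amount_mol, compound,
                             registry = compound_registry()) {
  if (any(amount_mol < 0)) stop("amount must be >= 0")
  amount_mol * electron_equivalents(resolve_compound(compound, registry))
}

#' Electron equivalents of a charge
#'
#' @param charge_C coulombs.
#' @return mol e- eq (charge / F).
#' @export
charge_equivalents <- function(charge_C) charge_C / FARADAY

#' Close a percentage ledger with an undefined remainder
#'
#' Given measured sink percentages of donor electrons, the undefined
#' remainder is 100 minus their sum, so the closed ledger always sums to
#' exactly 100. A negative remainder (over-closure) is allowed but
#' flagged with a warning.
#'
#' @param measured_pct named numeric vector of measured sink percentages.
#' @return Named vector with an added `undefined` entry; sums to 100.
#' @examples
#' close_percentages(c(current = 56, methane = 28.7, hydrogen = 0.05))
#' @export
close_percentages <- function(measured_pct) {
  stopifnot(is.numeric(measured_pct), !is.null(names(measured_pct)))
  if (any(measured_pct < 0)) stop("measured sink percentages must be >= 0")
  undef <- 100 - sum(measured_pct)
  if (undef < 0) warning("over-closure: undefined sink is negative")
  c(measured_pct, undefined = undef)
}

#' Electron balance over the sinks of a batch cycle
#'
#' Builds the end-of-cycle ledger: the electron equivalents of the fed
#' donor are distributed over electrical current (charge / F), methane,
#' escaped hydrogen, unused (residual) donor, acetate and formate; the
#' remainder closes the balance as "undefined sinks". Methane is counted
#' from anode and cathode headspace combined by default; the hydrogen
#' sink counts anode headspace only, because cathodic H2 is the product
#' of the current already on the ledger. When the donor is fully
#' consumed (residual below detection), the fed and consumed electron
#' bases coincide.
#'
#' @param record a [batch_cycle_record] with gas data.
#' @param charge_C charge to use; defaults to the record's.
#' @param ch4_phases phases whose CH4 counts toward the methane sink.
#' @param h2_phases phases whose H2 counts toward the hydrogen sink.
#' @param registry compound registry.
#' @return Object of class `sink_balance`: data.frame with columns
#'   `sink`, `m_eeq` (milli electron equivalents) and `percent`, plus
#'   attributes `donor_meq` and `over_closure`. Percentages sum to 100
#'   exactly (undefined is the closure term).
#' @export
electron_balance <- function(record, charge_C = record$charge_C,
                             ch4_phases = c("anode", "cathode"),
                             h2_phases = "anode",
                             registry = compound_registry()) {
  stopifnot(inherits(record, "batch_cycle_record"))
  donor <- resolve_compound(record$donor, registry)
  gamma_d <- electron_equivalents(donor)
  V <- record$anode_volume_m3
  ci <- record$conc_initial_mM[[record$donor]]
  cf <- record$conc_final_mM[[record$donor]]
  consumed_mol <- (ci - cf) * V
  if (consumed_mol <= 0) stop("donor consumed must be > 0")
  donor_eq <- gamma_d * ci * V  # electrons fed; unused donor is a sink

  conc_or_0 <- function(nm) {
    if (nm %in% names(record$conc_final_mM)) record$conc_final_mM[[nm]] else 0
  }
  eq <- c(
    current    = charge_equivalents(charge_C),
    methane    = sink_equivalents(
      phase_gas_moles(record$gas, "CH4", ch4_phases), "CH4", registry),
    hydrogen   = sink_equivalents(
      phase_gas_moles(record$gas, "H2", h2_phases), "H2", registry),
    propionate = sink_equivalents(cf * V, donor, registry),
    acetate    = sink_equivalents(conc_or_0("acetate") * V, "acetate",
                                  registry),
    formate    = sink_equivalents(conc_or_0("formate") * V, "formate",
                                  registry)
  )
  names(eq)[names(eq) == "propionate"] <- paste0("residual_", record$donor)
  pct <- 100 * eq / donor_eq
  undef_pct <- 100 - sum(pct)
  over <- undef_pct < 0
  if (over) warning("over-closure: undefined sink is negative")
  if (any(pct > 100)) warning("a measured sink exceeds 100% of donor electrons")
  out <- data.frame(
    sink = c(names(eq), "undefined"),
    m_eeq = c(eq, donor_eq - sum(eq)) * 1000,
    percent = c(pct, undef_pct),
    row.names = NULL
  )
  structure(out, class = c("sink_balance", "data.frame"),
            donor_meq = donor_eq * 1000, over_closure = over)
}

#' @export
print.sink_balance <- function(x, digits = 2, ...) {
  cat(sprintf("<sink_balance> donor = %.2f m e-eq\n",
              attr(x, "donor_meq")))
  df <- data.frame(sink = x$sink,
                   m_eeq = round(x$m_eeq, digits),
                   percent = round(x$percent, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Time course of electron fractions in intermediates
#'
#' Expresses intermediate concentrations over a batch cycle as the
#' percentage of the donor's initial electron pool:
#' percent_i(t) = 100 gamma_i C_i(t) / (gamma_donor C_donor,0).
#'
#' @param hplc data.frame with a `time_h` column and one `<name>_mM`
#'   column per compound (e.g. `acetate_mM`).
#' @param donor_initial_mM initial donor concentration (mM, > 0); the
#'   100% electron reference.
#' @param donor donor registry name.
#' @param registry compound registry.
#' @return data.frame: `time_h` plus `<name>_pct` electron-percentage
#'   series for every intermediate column.
#' @examples
#' tc <- time_course_fractions(
#'   data.frame(time_h = 70, acetate_mM = 9.9), 36)
#' tc$acetate_pct # ~15.7
#' @export
time_course_fractions <- function(hplc, donor_initial_mM,
                                  donor = "propionate",
                                  registry = compound_registry()) {
  if (is.null(donor_initial_mM) || donor_initial_mM <= 0) {
    stop("donor_initial_mM must be a positive electron basis")
  }
  if (!"time_h" %in% names(hplc)) stop("hplc table needs a 'time_h' column")
  gamma_d <- electron_equivalents(resolve_compound(donor, registry))
  basis <- gamma_d * donor_initial_mM
  out <- data.frame(time_h = hplc$time_h)
  conc_cols <- grep("_mM$", names(hplc), value = TRUE)
  for (col in conc_cols) {
    nm <- sub("_mM$", "", col)
    if (nm == donor) next
    gamma_i <- electron_equivalents(resolve_compound(nm, registry))
    out[[paste0(nm, "_pct")]] <- 100 * gamma_i * hplc[[col]] / basis
  }
  out
}

#' Electron fractions of a degradation pathway
#'
#' For a pathway producing nu_i mol of intermediate i per mol donor, the
#' fraction of donor electrons carried by i is 100 nu_i gamma_i /
#' gamma_donor. A complete pathway's fractions sum to 100; an incomplete
#' one is flagged.
#'
#' @param pathway named numeric vector: mol of each intermediate per mol
#'   donor, e.g. `c(acetate = 1, H2 = 3)` for propionate fermentation.
#' @param donor donor registry name or [compound].
#' @param registry compound registry.
#' @return Named numeric vector of electron percentages with attribute
#'   `complete` (`TRUE` if they sum to 100 within 1e-9).
#' @examples
#' pathway_fraction(c(acetate = 1, H2 = 3), "propionate")
#' @export
pathway_fraction <- function(pathway, donor = "propionate",
                             registry = compound_registry()) {
  stopifnot(is.numeric(pathway), !is.null(names(pathway)))
  gamma_d <- electron_equivalents(resolve_compound(donor, registry))
  gam <- vapply(names(pathway), function(nm)
    electron_equivalents(resolve_compound(nm, registry)), numeric(1))
  frac <- 100 * pathway * gam / gamma_d
  if (sum(frac) > 100 + 1e-9) {
    stop("over-stoichiometric pathway: fractions sum to ",
         format(sum(frac)), "% > 100%")
  }
  complete <- abs(sum(frac) - 100) <= 1e-9
  if (!complete) {
    warning("incomplete pathway: fractions sum to ",
            format(round(sum(frac), 2)), "% of donor electrons")
  }
  structure(frac, complete = complete)
}
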