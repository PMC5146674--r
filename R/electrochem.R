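# Performance metrics of a fed-batch MEC cycle: charge integration,
# coulombic efficiency, volumetric current density, H2 production rate
# and yield, substrate removal, gas-amount conversion.

#' Current-versus-time trace
#'
#' @param time_s numeric vector of sampling times (seconds), strictly
#'   increasing; potentiostat telemetry is typically at 600 s intervals.
#' @param current_A currents (amperes). Individual samples may dip below
#'   zero (sensor noise) but a trace with negative mean current is
#'   rejected.
#' @return Object of class `current_trace` (data.frame with columns
#'   `time_s`, `current_A`).
#' @export
current_trace <- function(time_s, current_A) {
  stopifnot(is.numeric(time_s), is.numeric(current_A),
            length(time_s) == length(current_A))
  if (length(time_s) < 2L) stop("a trace needs at least 2 samples")
  if (any(diff(time_s) <= 0)) stop("trace times must be strictly increasing")
  if (mean(current_A) < 0) stop("trace has negative mean current")
  structure(data.frame(time_s = time_s, current_A = current_A),
            class = c("current_trace", "data.frame"))
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples over %.2f h, peak %.3g A\n",
              nrow(x), diff(range(x$time_s)) / 3600, max(x$current_A)))
  invisible(x)
}

#' Integrate a current trace to charge
#'
#' Trapezoidal integration of current over time. Telemetry is
#' piecewise-linear between samples, so the trapezoid rule is exact for
#' the recorded signal.
#'
#' @param trace a [current_trace] (or data.frame with `time_s`,
#'   `current_A`).
#' @return Charge in coulombs.
#' @examples
#' tr <- current_trace(c(0, 1000), c(0.001, 0.001))
#' integrate_charge(tr) # 1 C
#' @export
integrate_charge <- function(trace) {
  if (!inherits(trace, "current_trace")) {
    trace <- current_trace(trace$time_s, trace$current_A)
  }
  t <- trace$time_s
  i <- trace$current_A
  if (length(t) < 2L) stop("a trace needs at least 2 samples")
  sum(diff(t) * (head(i, -1) + tail(i, -1)) / 2)
}

#' Peak current of a smoothed trace
#'
#' Maximum of the moving-median (default window 3) smoothed current, so
#' single-sample telemetry spikes do not set the peak.
#'
#' @param trace a [current_trace].
#' @param window odd integer moving-median window; 1 disables smoothing.
#' @return Peak current (A).
#' @export
peak_current <- function(trace, window = 3L) {
  i <- trace$current_A
  if (window > 1L && length(i) >= window) i <- stats::runmed(i, window)
  max(i)
}

#' Coulombic efficiency
#'
#' Percentage of the substrate's electrons recovered as integrated
#' electrical charge: CE = 100 Q / (F gamma n_donor), with F = 96485
#' C/mol e-. Values above 100% are possible when more charge is
#' recovered than the consumed donor accounts for (e.g. storage
#' carry-over) and are flagged with a warning, not an error.
#'
#' @param charge_C integrated charge (coulombs).
#' @param donor_mol moles of donor consumed (> 0).
#' @param gamma electron equivalents per mole donor (14 for propionate).
#' @return CE in percent.
#' @examples
#' coulombic_efficiency(1381.1, 1.44e-3, 14) # ~71
#' @export
coulombic_efficiency <- function(charge_C, donor_mol, gamma) {
  if (donor_mol <= 0) stop("donor_mol must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  ce <- 100 * charge_C / (FARADAY * gamma * donor_mol)
  if (ce > 100) warning("coulombic efficiency exceeds 100%")
  ce
}

#' Volumetric current density
#'
#' @param peak_A peak (or other representative) current, amperes.
#' @param anode_volume_m3 anode liquid volume (m^3); 4e-5 for a 40 mL
#'   chamber.
#' @return Current density in A/m^3.
#' @examples
#' volumetric_current_density(4.12e-3, 4e-5) # 103 A/m^3
#' @export
volumetric_current_density <- function(peak_A, anode_volume_m3) {
  if (anode_volume_m3 <= 0) stop("anode volume must be > 0")
  peak_A / anode_volume_m3
}

#' Cathodic hydrogen production rate
#'
#' Q = V_H2 / (V_reactor * t), in m^3 H2 per m^3 reactor per day. The
#' reactor volume defaults to the anode liquid volume, the basis used
#' for all volumetric quantities here.
#'
#' @param v_h2_m3 H2 volume produced (m^3, at the reporting reference
#'   conditions).
#' @param duration_days cycle duration (days, > 0).
#' @param anode_volume_m3 anode liquid volume (m^3).
#' @return Rate in m^3 H2 / m^3 / day.
#' @examples
#' h2_production_rate(8.8e-5, 4, 4e-5) # 0.55
#' @export
h2_production_rate <- function(v_h2_m3, duration_days, anode_volume_m3) {
  if (duration_days <= 0) stop("duration must be > 0")
  if (anode_volume_m3 <= 0) stop("anode volume must be > 0")
  v_h2_m3 / (anode_volume_m3 * duration_days)
}

#' Hydrogen yield
#'
#' Moles of H2 recovered per mole of donor consumed.
#'
#' @param h2_mol moles H2.
#' @param donor_mol moles donor consumed (> 0).
#' @return mol H2 / mol donor.
#' @seealso [h2_yield_ceiling()] for the stoichiometric maximum.
#' @export
h2_yield <- function(h2_mol, donor_mol) {
  if (donor_mol <= 0) stop("donor_mol must be > 0")
  h2_mol / donor_mol
}

#' Stoichiometric hydrogen-yield ceiling
#'
#' gamma_donor / gamma_H2: all donor electrons recovered as H2
#' (7 mol/mol for propionate).
#'
#' @param donor a [compound] or registry name.
#' @param registry compound registry.
#' @return mol H2 / mol donor.
#' @export
h2_yield_ceiling <- function(donor, registry = compound_registry()) {
  donor <- resolve_compound(donor, registry)
  electron_equivalents(donor) / electron_equivalents(registry$H2)
}

#' Substrate removal extent and rate
#'
#' @param initial_mM initial donor concentration (mM, > 0).
#' @param final_mM final donor concentration (mM, >= 0). A final value
#'   above the initial produces a warning and a negative removal.
#' @param duration_days cycle duration (days, > 0).
#' @return List with `removal_pct` (percent removed) and `rate_mM_day`.
#' @examples
#' substrate_removal(36, 0, 3.43) # ~10.5 mM/day
#' @export
substrate_removal <- function(initial_mM, final_mM, duration_days) {
  if (initial_mM <= 0) stop("initial concentration must be > 0")
  if (final_mM < 0) stop("final concentration must be >= 0")
  if (duration_days <= 0) stop("duration must be > 0")
  if (final_mM > initial_mM) {
    warning("final concentration exceeds initial; negative removal reported")
  }
  list(removal_pct = 100 * (initial_mM - final_mM) / initial_mM,
       rate_mM_day = (initial_mM - final_mM) / duration_days)
}

#' Moles of gas from volume (ideal gas)
#'
#' n = PV/RT, with the gas-chromatograph sampling conditions defaulting
#' to the 30 degC room (303.15 K) at 1 atm.
#'
#' @param volume_mL gas volume (mL, >= 0).
#' @param temp_K temperature (K, > 0).
#' @param pressure_atm pressure (atm, > 0).
#' @return Moles of gas.
#' @examples
#' gas_moles(24.87, 303.15, 1) # ~1e-3 mol
#' @export
gas_moles <- function(volume_mL, temp_K = 303.15, pressure_atm = 1) {
  stopifnot(all(volume_mL >= 0), all(temp_K > 0), all(pressure_atm > 0))
  pressure_atm * (volume_mL * 1e-6) / (R_M3_ATM * temp_K)
}

#' Volume of a gas amount at reference conditions
#'
#' Inverse of [gas_moles()]; used to re-express measured gas at a common
#' reporting reference before computing rates.
#'
#' @param n_mol moles of gas.
#' @param temp_K,pressure_atm reference conditions.
#' @return Volume in m^3.
#' @export
gas_volume_m3 <- function(n_mol, temp_K = 303.15, pressure_atm = 1) {
  n_mol * R_M3_ATM * temp_K / pressure_atm
}

#' Batch-cycle measurement record
#'
#' Bundles one fed-batch cycle's measurements: geometry, set potential,
#' start/end concentrations, accumulated charge and/or current trace,
#' and headspace gas per phase.
#'
#' @param anode_volume_m3 anode liquid volume (m^3, > 0).
#' @param cycle_days cycle duration (days, > 0).
#' @param set_potential_V set anode potential (V vs SHE).
#' @param conc_initial_mM,conc_final_mM named numeric vectors of liquid
#'   concentrations (mM), e.g. `c(propionate = 36, acetate = 0,
#'   formate = 0)`.
#' @param charge_C accumulated charge (coulombs), or `NULL` to integrate
#'   `trace`.
#' @param trace optional [current_trace].
#' @param gas data.frame with columns `phase` (`"anode"`/`"cathode"`),
#'   `volume_mL`, `temp_K`, `pressure_atm`, `x_H2`, `x_CH4`, `x_CO2`
#'   (mole fractions in [0, 1], per-phase sum <= 1), or `NULL`.
#' @param donor name of the fed electron donor (registry name).
#' @return Object of class `batch_cycle_record`.
#' @export
batch_cycle_record <- function(anode_volume_m3, cycle_days, set_potential_V,
                               conc_initial_mM, conc_final_mM,
                               charge_C = NULL, trace = NULL, gas = NULL,
                               donor = "propionate") {
  stopifnot(anode_volume_m3 > 0, cycle_days > 0)
  stopifnot(!is.null(names(conc_initial_mM)), !is.null(names(conc_final_mM)))
  if (!donor %in% names(conc_initial_mM)) {
    stop("initial concentrations must include the donor '", donor, "'")
  }
  if (is.null(charge_C) && is.null(trace)) {
    stop("provide charge_C and/or a current trace")
  }
  if (is.null(charge_C)) charge_C <- integrate_charge(trace)
  if (!is.null(gas)) {
    need <- c("phase", "volume_mL", "temp_K", "pressure_atm",
              "x_H2", "x_CH4", "x_CO2")
    miss <- setdiff(need, names(gas))
    if (length(miss)) stop("gas table misses column(s): ",
                           paste(miss, collapse = ", "))
    x <- as.matrix(gas[, c("x_H2", "x_CH4", "x_CO2")])
    if (any(x < 0) || any(x > 1) || any(rowSums(x) > 1 + 1e-9)) {
      stop("gas mole fractions must lie in [0, 1] with per-phase sum <= 1")
    }
    if (any(gas$volume_mL < 0)) stop("gas volumes must be >= 0")
  }
  structure(
    list(anode_volume_m3 = anode_volume_m3, cycle_days = cycle_days,
         set_potential_V = set_potential_V,
         conc_initial_mM = conc_initial_mM, conc_final_mM = conc_final_mM,
         charge_C = charge_C, trace = trace, gas = gas, donor = donor),
    class = "batch_cycle_record"
  )
}

#' @export
print.batch_cycle_record <- function(x, ...) {
  cat(sprintf(
    "<batch_cycle_record> %s-fed, %.3g mL anode, %.2f d at %+.2f V vs SHE\n",
    x$donor, x$anode_volume_m3 * 1e6, x$cycle_days, x$set_potential_V))
  cat(sprintf("  charge %.1f C; donor %.1f -> %.2f mM\n", x$charge_C,
              x$conc_initial_mM[[x$donor]], x$conc_final_mM[[x$donor]]))
  invisible(x)
}

# moles of one gas species summed over the selected phases
phase_gas_moles <- function(gas, species, phases = c("anode", "cathode")) {
  if (is.null(gas)) return(0)
  sel <- gas$phase %in% phases
  if (!any(sel)) return(0)
  sum(gas_moles(gas$volume_mL[sel], gas$temp_K[sel], gas$pressure_atm[sel]) *
        gas[[paste0("x_", species)]][sel])
}

#' Performance metrics for one batch cycle
#'
#' Computes volumetric current density, coulombic efficiency, cathodic
#' H2 rate and yield, and substrate removal from a
#' [batch_cycle_record].
#'
#' @param record a [batch_cycle_record].
#' @param registry compound registry (for the donor's electron
#'   equivalents).
#' @param reference_temp_K,reference_pressure_atm reporting reference for
#'   gas volumes entering the H2 rate.
#' @return Object of class `performance_metrics`: list with `I_V_A_m3`
#'   (NA without a trace), `CE_pct`, `Q_H2_m3_m3_day`, `Y_H2_mol_mol`,
#'   `removal_pct`, `removal_rate_mM_day`.
#' @export
performance_metrics <- function(record, registry = compound_registry(),
                                reference_temp_K = 303.15,
                                reference_pressure_atm = 1) {
  stopifnot(inherits(record, "batch_cycle_record"))
  donor <- resolve_compound(record$donor, registry)
  gamma <- electron_equivalents(donor)
  ci <- record$conc_initial_mM[[record$donor]]
  cf <- record$conc_final_mM[[record$donor]]
  donor_mol <- (ci - cf) * record$anode_volume_m3  # mM * m^3 = mol
  rem <- substrate_removal(ci, cf, record$cycle_days)
  h2_cath_mol <- phase_gas_moles(record$gas, "H2", "cathode")
  v_h2 <- gas_volume_m3(h2_cath_mol, reference_temp_K,
                        reference_pressure_atm)
  structure(list(
    I_V_A_m3 = if (is.null(record$trace)) NA_real_ else
      volumetric_current_density(peak_current(record$trace),
                                 record$anode_volume_m3),
    CE_pct = coulombic_efficiency(record$charge_C, donor_mol, gamma),
    Q_H2_m3_m3_day = h2_production_rate(v_h2, record$cycle_days,
                                        record$anode_volume_m3),
    Y_H2_mol_mol = h2_yield(h2_cath_mol, donor_mol),
    removal_pct = rem$removal_pct,
    removal_rate_mM_day = rem$rate_mM_day
  ), class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat("<performance_metrics>\n")
  cat(sprintf("  I_V      %8.1f A/m^3\n", x$I_V_A_m3))
  cat(sprintf("  CE       %8.1f %%\n", x$CE_pct))
  cat(sprintf("  Q_H2     %8.2f m^3 H2/m^3/day\n", x$Q_H2_m3_m3_day))
  cat(sprintf("  Y_H2     %8.2f mol H2/mol donor\n", x$Y_H2_mol_mol))
  cat(sprintf("  removal  %8.1f %% (%.1f mM/day)\n",
              x$removal_pct, x$removal_rate_mM_day))
  invisible(x)
}
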