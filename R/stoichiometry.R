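# Electron-equivalent (degree of reduction) stoichiometry for C/H/O/N
# compounds, referenced to the anaerobic end products HCO3-, H2O and NH4+.

#' Faraday constant (C per mol electrons)
#' @export
FARADAY <- 96485

# gas constant in m^3 atm / (mol K), for ideal-gas conversions
R_M3_ATM <- 8.314462618 / 101325

#' Parse an element-count formula string
#'
#' Accepts strings such as `"C3H5O2"` or `"CH4"` containing only the
#' elements C, H, O and N with optional integer counts.
#'
#' @param formula character scalar, e.g. `"C2H3O2"`.
#' @return Named integer vector with entries `C`, `H`, `O`, `N`.
#' @examples
#' parse_formula("C3H5O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula string: ", formula)
  }
  counts <- c(C = 0L, H = 0L, O = 0L, N = 0L)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    if (!el %in% names(counts)) {
      stop("unsupported element '", el, "' in formula ", formula,
           " (only C, H, O, N are handled)")
    }
    n <- gsub("[A-Za-z]", "", tok)
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  counts
}

#' Define a compound
#'
#' A compound carries its elemental composition, formal charge, phase and
#' (optionally) its standard formation free energy at pH 7
#' (Thauer convention), and is the currency of all electron accounting.
#'
#' @param name identifier, e.g. `"propionate"`.
#' @param formula element-count string (anion formula for charged species,
#'   e.g. `"C3H5O2"` for propionate).
#' @param charge integer formal charge.
#' @param dGf standard formation free energy at pH 7 (kJ/mol), or `NA`.
#' @param phase `"aqueous"` or `"gas"`.
#' @return An object of class `compound`.
#' @examples
#' propionate <- compound("propionate", "C3H5O2", charge = -1)
#' electron_equivalents(propionate)
#' @export
compound <- function(name, formula, charge = 0L, dGf = NA_real_,
                     phase = c("aqueous", "gas")) {
  phase <- match.arg(phase)
  comp <- parse_formula(formula)
  if (any(comp < 0L)) stop("composition counts must be non-negative")
  stopifnot(length(charge) == 1L, charge == round(charge))
  structure(
    list(name = name, composition = comp, charge = as.integer(charge),
         dGf = dGf, phase = phase),
    class = "compound"
  )
}

#' @export
print.compound <- function(x, ...) {
  f <- paste0(names(x$composition)[x$composition > 0],
              ifelse(x$composition[x$composition > 0] > 1,
                     x$composition[x$composition > 0], ""),
              collapse = "")
  cat(sprintf("<compound> %s (%s, charge %+d, %s), gamma = %d e-/mol",
              x$name, f, x$charge, x$phase, electron_equivalents(x)))
  if (!is.na(x$dGf)) cat(sprintf(", dGf'0 = %.2f kJ/mol", x$dGf))
  cat("\n")
  invisible(x)
}

#' Electron equivalents per mole of a compound
#'
#' Degree of reduction gamma = 4C + H - 2O - 3N - z, the moles of
#' electrons released by complete oxidation to HCO3- (carbon), H2O
#' (oxygen/hydrogen) and NH4+ (nitrogen). Independent of phase; the
#' `-z` term makes the anion and free-acid conventions agree.
#'
#' @param x a [compound].
#' @return Integer electron equivalents per mole.
#' @examples
#' electron_equivalents(compound("acetate", "C2H3O2", -1)) # 8
#' @export
electron_equivalents <- function(x) {
  stopifnot(inherits(x, "compound"))
  cc <- x$composition
  g <- 4L * cc[["C"]] + cc[["H"]] - 2L * cc[["O"]] - 3L * cc[["N"]] -
    x$charge
  if (g < 0L) {
    stop("negative electron equivalents for '", x$name,
         "': check the composition/charge")
  }
  as.integer(g)
}

#' Balanced oxidation half-reaction of a compound
#'
#' Balances the oxidation of a CxHyOzNw compound (charge z) to HCO3-,
#' NH4+, H+ and electrons, consuming water:
#' donor + a H2O -> x HCO3- + w NH4+ + h H+ + gamma e-.
#' The electron count always equals [electron_equivalents()], computed
#' here independently from charge balance.
#'
#' @param x a [compound].
#' @return An object of class `half_reaction` with fields `donor`,
#'   `electrons` and `coefficients` (named: negative = consumed).
#' @examples
#' oxidation_half_reaction(compound("acetate", "C2H3O2", -1))
#' @export
oxidation_half_reaction <- function(x) {
  stopifnot(inherits(x, "compound"))
  cc <- x$composition
  a <- 3L * cc[["C"]] - cc[["O"]]              # water consumed
  h <- cc[["H"]] + 2L * a - cc[["C"]] - 4L * cc[["N"]]  # protons released
  # electrons from charge balance (independent of the gamma formula)
  e <- -cc[["C"]] + cc[["N"]] + h - x$charge
  if (e < 0L || h < 0L) {
    stop("composition of '", x$name, "' cannot be balanced as an oxidation")
  }
  coef <- c(donor = -1L, H2O = -a, HCO3 = cc[["C"]], NH4 = cc[["N"]],
            `H+` = h)
  hr <- structure(
    list(donor = x, electrons = as.integer(e), coefficients = coef),
    class = "half_reaction"
  )
  stopifnot(hr$electrons == electron_equivalents(x))
  hr
}

#' @export
print.half_reaction <- function(x, ...) {
  lhs <- c(x$donor$name,
           if (x$coefficients[["H2O"]] < 0)
             paste0(-x$coefficients[["H2O"]], " H2O"))
  rhs <- character(0)
  for (sp in c("HCO3", "NH4", "H+")) {
    n <- x$coefficients[[sp]]
    if (n > 0) rhs <- c(rhs, paste0(if (n > 1) paste0(n, " "), sp))
  }
  rhs <- c(rhs, paste0(x$electrons, " e-"))
  cat("<half_reaction>", paste(lhs, collapse = " + "), "->",
      paste(rhs, collapse = " + "), "\n")
  invisible(x)
}

#' Built-in compound registry
#'
#' The compounds used in propionate-fed MEC electron accounting, with
#' anion formulas, formal charges and standard formation free energies at
#' pH 7 (kJ/mol, Thauer convention, H+ at -39.87).
#'
#' @return Named list of [compound] objects: propionate, acetate, formate,
#'   H2, CH4, CO2, HCO3, H2O, `H+`.
#' @examples
#' sapply(compound_registry(), electron_equivalents)
#' @export
compound_registry <- function() {
  list(
    propionate = compound("propionate", "C3H5O2", -1L, dGf = -361.08),
    acetate    = compound("acetate",    "C2H3O2", -1L, dGf = -369.41),
    formate    = compound("formate",    "CHO2",   -1L, dGf = -351.04),
    H2         = compound("H2",  "H2",  0L, dGf = 0,       phase = "gas"),
    CH4        = compound("CH4", "CH4", 0L, dGf = -50.75,  phase = "gas"),
    CO2        = compound("CO2", "CO2", 0L, dGf = -394.36, phase = "gas"),
    HCO3       = compound("HCO3", "CHO3", -1L, dGf = -586.85),
    H2O        = compound("H2O", "H2O", 0L, dGf = -237.18),
    `H+`       = compound("H+",  "H",   1L, dGf = -39.87)
  )
}

#' Read a compound registry from a YAML file
#'
#' Each entry must have `formula` and `charge`, and may carry `dGf`
#' (kJ/mol at pH 7) and `phase`.
#'
#' @param path YAML file; see
#'   `system.file("extdata", "compounds.yml", package = "mecflux")`.
#' @return Named list of [compound] objects.
#' @export
read_compound_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    if (is.null(e$formula) || is.null(e$charge)) {
      stop("registry entry '", nm, "' needs 'formula' and 'charge'")
    }
    compound(nm, e$formula, as.integer(e$charge),
             dGf = if (is.null(e$dGf)) NA_real_ else e$dGf,
             phase = if (is.null(e$phase)) "aqueous" else e$phase)
  })
  names(out) <- names(raw)
  out
}

# resolve a compound argument: object, or name in registry
resolve_compound <- function(x, registry = compound_registry()) {
  if (inherits(x, "compound")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% names(registry)) stop("unknown compound: ", x)
    return(registry[[x]])
  }
  stop("expected a compound object or a registry name")
}
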