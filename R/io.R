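# Readers and writers for the delimited measurement formats, and the
# pipeline entry point tying the stages together.

# read a delimited file, checking required columns and numeric cells,
# reporting offending lines (1-based, counting the header as line 1)
read_checked <- function(path, required, sep = ",", numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in ", basename(path), ", column '", col,
             "', line ", bad[1] + 1L, ": '", v[bad[1]], "'")
      }
      df[[col]] <- num
    }
  }
  df
}

#' Read a current trace CSV
#'
#' Expected header: `time_s,current_A`.
#'
#' @param path CSV file.
#' @return A [current_trace].
#' @export
read_trace <- function(path) {
  df <- read_checked(path, c("time_s", "current_A"))
  current_trace(df$time_s, df$current_A)
}

#' Read an HPLC concentration series CSV
#'
#' Expected header: `time_h,propionate_mM,acetate_mM,formate_mM`.
#'
#' @param path CSV file.
#' @return data.frame of times (h) and concentrations (mM).
#' @export
read_hplc <- function(path) {
  read_checked(path, c("time_h", "propionate_mM", "acetate_mM",
                       "formate_mM"))
}

#' Read a headspace gas CSV
#'
#' Expected header:
#' `phase,volume_mL,temp_K,pressure_atm,x_H2,x_CH4,x_CO2`, with phase in
#' {anode, cathode}.
#'
#' @param path CSV file.
#' @return data.frame of per-phase gas measurements.
#' @export
read_gas <- function(path) {
  need <- c("phase", "volume_mL", "temp_K", "pressure_atm", "x_H2",
            "x_CH4", "x_CO2")
  df <- read_checked(path, need, numeric_cols = setdiff(need, "phase"))
  bad <- !df$phase %in% c("anode", "cathode")
  if (any(bad)) {
    stop("unknown phase in ", basename(path), ", line ",
         which(bad)[1] + 1L, ": '", df$phase[which(bad)[1]], "'")
  }
  df
}

#' Read an OTU table TSV
#'
#' Tab-separated, first header cell `#OTU ID`, one column per sample,
#' optional final `taxonomy` column with semicolon-separated lineages.
#' A separate two-column (OTU, lineage) taxonomy TSV may be supplied
#' instead.
#'
#' @param path OTU table TSV.
#' @param taxonomy_path optional two-column taxonomy TSV.
#' @return An [otu_counts] table.
#' @export
read_otu_table <- function(path, taxonomy_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) == 0L || header[1] != "#OTU ID") {
    stop("OTU table must start with a '#OTU ID' header cell")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  names(df)[1] <- "otu"
  tax <- NULL
  if ("taxonomy" %in% names(df)) {
    tax <- stats::setNames(df$taxonomy, df$otu)
    df$taxonomy <- NULL
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$otu
  if (!is.numeric(counts)) {
    stop("non-numeric counts in ", basename(path))
  }
  if (!is.null(taxonomy_path)) {
    td <- utils::read.table(taxonomy_path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    tax <- stats::setNames(td[[2]], td[[1]])
  }
  otu_counts(counts, tax)
}

#' Write a simulated dataset to CSV/TSV files
#'
#' Writes `trace.csv`, `hplc.csv`, `gas.csv` (the dialects the readers
#' accept) and `ground_truth.json` (routing fractions, totals, seed)
#' into a directory.
#'
#' @param sim a `mec_simulation` from [simulate_batch_cycle()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mec_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trace.csv", "hplc.csv", "gas.csv",
                            "ground_truth.json"))
  utils::write.csv(as.data.frame(sim$trace), paths[1], row.names = FALSE)
  utils::write.csv(sim$hplc, paths[2], row.names = FALSE)
  utils::write.csv(sim$gas, paths[3], row.names = FALSE)
  gt <- sim$ground_truth
  gt$fractions <- as.list(gt$fractions)
  jsonlite::write_json(gt, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write an OTU table TSV
#'
#' @param x an [otu_counts] table.
#' @param path output TSV (`#OTU ID` dialect, taxonomy column appended
#'   when present).
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_counts"))
  df <- data.frame(`#OTU ID` = rownames(x$counts), x$counts,
                   check.names = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- x$taxonomy
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert a potential from Ag/AgCl to SHE
#'
#' @param e_ag_agcl_V potential vs Ag/AgCl (V).
#' @param offset_V reference offset (the RE-5B electrode sits at
#'   +0.210 V vs SHE).
#' @return Potential vs SHE (V).
#' @export
ag_agcl_to_she <- function(e_ag_agcl_V, offset_V = 0.210) {
  e_ag_agcl_V + offset_V
}

#' Run the analysis pipeline over a set of measurement files
#'
#' Reads whatever inputs the configuration provides and computes
#' performance metrics, the electron ledger (skipped with a warning if
#' gas data are missing), the thermodynamic favorability matrix, and --
#' when an OTU table is given -- alpha diversity, three-way OTU sharing
#' and Archaea:Bacteria ratios. Optionally writes `metrics.tsv`,
#' `balance.tsv`, `thermo.tsv`, `diversity.tsv` and a `report.json`
#' with sorted keys.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `trace`, `hplc`, `gas`, `otu_table`, `taxonomy` (file paths,
#'   all optional except that metrics need `trace` and `hplc`);
#'   `anode_volume_m3`, `cycle_days`, `set_potential_V`,
#'   `initial_propionate_mM`; `potentials_V` (for the favorability
#'   matrix), `constants_profile` (`"paper"`/`"literature"`);
#'   `rarefaction_depth`, `seed`; `out_dir` (omit to skip writing).
#' @return List with elements `metrics`, `balance`, `thermo`,
#'   `diversity`, `domain_ratio` (those that could be computed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  get_or <- function(nm, default) {
    if (!is.null(config[[nm]])) config[[nm]] else default
  }
  out <- list()
  trace <- if (!is.null(config$trace)) read_trace(config$trace)
  hplc <- if (!is.null(config$hplc)) read_hplc(config$hplc)
  gas <- if (!is.null(config$gas)) read_gas(config$gas)

  if (!is.null(trace) && !is.null(hplc)) {
    ci <- get_or("initial_propionate_mM", hplc$propionate_mM[1])
    record <- batch_cycle_record(
      anode_volume_m3 = get_or("anode_volume_m3", 4e-5),
      cycle_days = get_or("cycle_days",
                          max(trace$time_s) / 86400),
      set_potential_V = get_or("set_potential_V", 0),
      conc_initial_mM = c(propionate = ci, acetate = hplc$acetate_mM[1],
                          formate = hplc$formate_mM[1]),
      conc_final_mM = c(
        propionate = utils::tail(hplc$propionate_mM, 1),
        acetate = utils::tail(hplc$acetate_mM, 1),
        formate = utils::tail(hplc$formate_mM, 1)),
      trace = trace, gas = gas
    )
    out$metrics <- performance_metrics(record)
    if (is.null(gas)) {
      warning("no gas data: electron ledger skipped")
    } else {
      out$balance <- electron_balance(record)
    }
    out$time_course <- time_course_fractions(hplc, ci)
  }

  out$thermo <- favorability_matrix(
    get_or("potentials_V", c(-0.25, 0, 0.25)),
    profile = get_or("constants_profile", "paper"))

  if (!is.null(config$otu_table)) {
    tab <- read_otu_table(config$otu_table, config$taxonomy)
    depth <- get_or("rarefaction_depth", NULL)
    if (!is.null(depth)) {
      tab <- rarefy_counts(tab, depth, seed = get_or("seed", 1L))
    }
    out$diversity <- alpha_diversity(tab)
    if (!is.null(tab$taxonomy)) {
      out$domain_ratio <- domain_ratio(tab)
    }
    if (ncol(tab$counts) >= 3L) {
      sets <- lapply(1:3, function(j)
        rownames(tab$counts)[tab$counts[, j] > 0])
      out$venn <- venn3(sets[[1]], sets[[2]], sets[[3]],
                        labels = colnames(tab$counts)[1:3])
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, nm) utils::write.table(
      df, file.path(config$out_dir, nm), sep = "\t", row.names = FALSE,
      quote = FALSE)
    if (!is.null(out$metrics)) {
      wtsv(data.frame(metric = names(unclass(out$metrics)),
                      value = unlist(unclass(out$metrics))), "metrics.tsv")
    }
    if (!is.null(out$balance)) wtsv(out$balance, "balance.tsv")
    wtsv(out$thermo, "thermo.tsv")
    if (!is.null(out$diversity)) wtsv(out$diversity, "diversity.tsv")
    rep <- lapply(out, function(x) {
      if (inherits(x, "performance_metrics")) unclass(x) else x
    })
    rep <- rep[order(names(rep))]
    jsonlite::write_json(rep, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
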