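# Readers and writers: measurement-table TSV, bottle config YAML, JSON
# summaries, FASTA. TSV dialect: tab-separated, "." decimal point, UTF-8,
# Unix newlines, literal "NA" for missing OD.

#' Read a measurement table
#'
#' Tab-separated, one header row, columns exactly `time_h`, `p_before_bar`,
#' `p_after_bar`, `x_h2`, `x_o2`, `x_n2`, `x_co`, `x_co2`, `od600`,
#' `v_gas_ml`, `v_liq_ml`; `od600` may be `NA`. Validation errors name the
#' offending row/column.
#'
#' @param path file path.
#' @param bottle a [bottle_spec()] describing the run.
#' @return A [measurement_series()].
#' @export
read_measurements <- function(path, bottle = bottle_spec()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                   check.names = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  measurement_series(df, bottle)
}

#' Write a measurement table
#'
#' @param series a [measurement_series()] (or a [simulate_wgs()] result,
#'   whose observed series is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series, path) {
  if (inherits(series, "wgs_simulation")) series <- series$series
  stopifnot(inherits(series, "measurement_series"))
  write.table(series$points, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read a bottle configuration
#'
#' Flat YAML key-value file mirroring the [bottle_spec()] fields, e.g.
#' `total_volume: 250`. Unknown keys are rejected; missing keys take the
#' `bottle_spec` defaults.
#'
#' @param path YAML file path.
#' @return A [bottle_spec()].
#' @export
read_bottle_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(bottle_spec)), "...")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(bottle_spec, cfg)
}

#' Write a bottle configuration
#'
#' @param bottle a [bottle_spec()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_bottle_config <- function(bottle, path) {
  stopifnot(inherits(bottle, "bottle_spec"))
  yaml::write_yaml(bottle[setdiff(names(bottle), "gas_constant")], path)
  invisible(path)
}

#' Write a JSON balance summary
#'
#' Fixed-schema JSON with the derived statistics of a [gas_balance()]:
#' yield (2 d.p., the reporting convention for summaries), onset/depletion
#' times, growth, per-species totals (2 d.p.), and tool metadata. Absent
#' quantities are `null`.
#'
#' @param balance a [gas_balance()].
#' @param path output path.
#' @return The summary list, invisibly.
#' @export
write_summary <- function(balance, path) {
  stopifnot(inherits(balance, "gas_balance"))
  s <- balance$summary
  r2 <- function(x) if (is.null(x) || all(is.na(x))) NULL else round(x, 2)
  out <- list(
    tool = "cowgas",
    version = as.character(packageVersion("cowgas")),
    schema = "gas-balance-summary/1",
    yield_h2_per_co = r2(s$yield_h2_per_co),
    h2_onset_time_h = r2(s$h2_onset_time),
    o2_depletion_time_h = r2(s$o2_depletion_time),
    max_od = r2(s$max_od), max_od_time_h = r2(s$max_od_time),
    final_od = r2(s$final_od),
    onset_threshold_mmol = s$onset_threshold,
    o2_threshold_mmol = s$o2_threshold,
    net_production_mmol = as.list(round(s$final_net_production, 2)),
    withdrawn_mmol = as.list(round(s$total_withdrawn, 2)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return List of [protein_record()]s.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  mapply(protein_record, ids, as.character(ss), SIMPLIFY = FALSE,
         USE.NAMES = FALSE)
}

#' Read nucleotide sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_nucleotide_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a list of [protein_record()]s.
#' @param path output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1]], "protein_record"))
    seqs <- setNames(vapply(seqs, `[[`, "", "sequence"),
                     vapply(seqs, `[[`, "", "id"))
  ss <- if (type == "AA") Biostrings::AAStringSet(seqs)
        else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write the simulator's ground truth as JSON
#'
#' @param sim a [simulate_wgs()] result.
#' @param path output path.
#' @return The truth list, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "wgs_simulation"))
  gt <- ground_truth_balance(sim)
  out <- list(
    tool = "cowgas", scenario = sim$scenario$name,
    net_production_mmol = as.list(gt$q),
    withdrawn_mmol = as.list(gt$withdrawn),
    pathways_mmol = as.list(gt$pathways))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
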