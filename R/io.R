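# File interchange and reproducibility plumbing. Per-cell tables and
# division records travel as plain CSV (the upstream instrument exports
# tabular per-cell features); configs as JSON. All randomness flows from a
# single top-level seed via derive_seed().

.cells_cols <- c("cell_id", "size", "septated", "fluor", "condition")
.records_cols <- c("birth_time", "division_time", "birth_size",
                   "division_size", "extension", "duration")

.check_header <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
}

.check_numeric_col <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "NA")
  if (length(bad))
    stop(sprintf("%s: non-numeric '%s' on line %d", path, col, bad[1] + 1L))
  v
}

#' Read / write a per-cell cytometry table
#'
#' CSV with exact header \code{cell_id,size,septated,fluor,condition};
#' \code{septated} is stored as 0/1 and read back as logical. Schema
#' violations report the offending column and file line (header = line 1).
#'
#' @param path file path.
#' @return \code{read_cells}: a validated per-cell data.frame (possibly with
#'   zero rows).
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  .check_header(df, .cells_cols, path)
  if (nrow(df) == 0) {
    return(data.frame(cell_id = integer(0), size = numeric(0),
                      septated = logical(0), fluor = numeric(0),
                      condition = character(0)))
  }
  size <- .check_numeric_col(df$size, "size", path)
  bad <- which(!is.finite(size) | size <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive 'size' on line %d", path, bad[1] + 1L))
  sept_raw <- df$septated
  bad <- which(!sept_raw %in% c("0", "1", "TRUE", "FALSE"))
  if (length(bad))
    stop(sprintf("%s: 'septated' not in {0,1} on line %d", path, bad[1] + 1L))
  fluor <- .check_numeric_col(df$fluor, "fluor", path)
  data.frame(cell_id = .check_numeric_col(df$cell_id, "cell_id", path),
             size = size, septated = sept_raw %in% c("1", "TRUE"),
             fluor = fluor, condition = df$condition)
}

#' @param table a per-cell data.frame as produced by [synth_snapshot()],
#'   [synth_cyclin_table()] or [read_cells()].
#' @rdname read_cells
#' @export
write_cells <- function(table, path) {
  .check_header(table, .cells_cols, "table")
  out <- table[, .cells_cols]
  out$septated <- as.integer(.septated_flag(table))
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write division records
#'
#' CSV with exact header \code{birth_time,division_time,birth_size,
#' division_size,extension,duration}. A header-only file reads back as an
#' empty record set, not an error; round trips are lossless to at least 12
#' significant digits.
#'
#' @param path file path.
#' @return \code{read_records}: a validated division-record data.frame.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  .check_header(df, .records_cols, path)
  if (nrow(df) == 0)
    return(as.data.frame(sapply(.records_cols, function(x) numeric(0),
                                simplify = FALSE)))
  out <- as.data.frame(lapply(stats::setNames(.records_cols, .records_cols),
                              function(col)
                                .check_numeric_col(df[[col]], col, path)))
  bad <- which(out$division_time <= out$birth_time)
  if (length(bad))
    stop(sprintf("%s: division_time <= birth_time on line %d",
                 path, bad[1] + 1L))
  out
}

#' @param records a division-record data.frame or [run_simulation()] result.
#' @rdname read_records
#' @export
write_records <- function(records, path) {
  records <- .as_records(records)
  if (nrow(records) == 0) {
    writeLines(paste(.records_cols, collapse = ","), path)
    return(invisible(path))
  }
  .check_header(records, .records_cols, "records")
  utils::write.csv(format(records[, .records_cols], digits = 15,
                          trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a simulation config as JSON
#'
#' The JSON document mirrors the [sim_config()] field names, with
#' \code{rule_params} an object whose fields match the rule's parameter
#' class. Unknown keys are rejected.
#'
#' @param path file path.
#' @return \code{read_sim_config}: a [sim_config()].
#' @export
read_sim_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("rule", "growth_rate", "dt", "n_init", "t_max", "init_mean",
             "init_sd", "daughter_factor", "asymmetry_sd",
             "septation_duration", "min_cycle_duration", "rule_params",
             "seed")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(unknown, collapse = ", ")))
  rp <- doc$rule_params
  if (!is.null(rp)) {
    rp <- as.list(rp)
    rule <- doc$rule
    doc$rule_params <- switch(rule,
      pdiv = do.call(hill_curve, rp),
      cdc13 = do.call(cdc13_params, rp),
      do.call(gaussian_rule, rp))
  }
  do.call(sim_config, doc)
}

#' @param config a [sim_config()].
#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  doc <- unclass(config)
  doc$rule_params <- unclass(doc$rule_params)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Stable 31-based string hash, kept below 2^31 - 1 (representable exactly in
# doubles throughout: intermediate values stay < 2^53).
.stable_hash <- function(label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Derive a stage seed from the top-level seed
#'
#' Deterministic, platform-independent derivation: the top-level seed plus a
#' stable hash of the stage label, modulo 2^31 - 1. Every randomized stage of
#' a run (sweep cells, sampling, noise) uses a seed derived this way, so
#' stages are mutually independent but the whole run reproduces from one
#' integer.
#'
#' @param seed integer top-level seed.
#' @param label character stage label (e.g. \code{"sweep/14/10/2"}).
#' @return integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  as.integer((abs(seed) + .stable_hash(label)) %% 2147483647)
}

#' Write a run manifest
#'
#' Records what produced a set of output files: a stage name, a digest of the
#' configuration (stable under key reordering), the seed, the file paths, the
#' package version and a timestamp. JSON, one file per run.
#'
#' @param stage character stage name.
#' @param config a list or \code{sim_config} (digested after sorting keys).
#' @param seed integer seed of the run (or NULL).
#' @param outputs character vector of output file paths.
#' @param path manifest destination (JSON).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(stage, config, seed, outputs, path) {
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  digest <- .stable_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                          digits = NA, force = TRUE))
  manifest <- list(stage = stage, config_digest = digest,
                   seed = if (is.null(seed)) NA else seed,
                   outputs = as.list(outputs),
                   package_version =
                     as.character(utils::packageVersion("pdivsim")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a Hill fit as JSON
#'
#' @param fit a [fit_hill()] result.
#' @param path destination path.
#' @export
write_hill_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hill_fit"))
  jsonlite::write_json(
    list(pmax = fit$curve$pmax, ec50 = fit$curve$ec50, n = fit$curve$n,
         rss = fit$rss, se_pmax = fit$se[["pmax"]],
         se_ec50 = fit$se[["ec50"]], se_n = fit$se[["n"]],
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
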