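#' @importFrom utils read.table write.table head tail packageVersion
NULL

# sniff the delimiter of a delimited-text file: tab wins if the first
# non-empty line contains tabs, else comma, else whitespace
sniff_sep <- function(path) {
  l1 <- readLines(path, n = 25L, warn = FALSE)
  l1 <- l1[nzchar(l1)][1L]
  if (is.na(l1)) stop("'", path, "': empty file")
  if (grepl("\t", l1)) "\t" else if (grepl(",", l1)) "," else ""
}

time_to_hours <- function(x, unit = c("h", "min", "s")) {
  unit <- match.arg(unit)
  switch(unit, h = x, min = x / 60, s = x / 3600)
}

#' Read a two-column trace file
#'
#' Delimited text (tab or comma, auto-sniffed) with a time column followed
#' by one value column; a header row is accepted. Non-monotone time is a
#' parse error naming the offending row.
#'
#' @param path File path.
#' @param sep Field separator; default auto-sniffed.
#' @param time_unit Unit of the time column (`"h"`, `"min"`, `"s"`);
#'   times are returned unchanged plus an `hours` attribute-free column
#'   conversion left to the caller.
#' @return Data frame with columns `time`, `value`.
#' @export
read_trace <- function(path, sep = NULL, time_unit = "s") {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE)
  if (ncol(df) < 2L) stop("'", path, "': expected two columns (time, value)")
  tm <- as.numeric(df[[1L]])
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop("'", path, "', data row ", bad[1L] + 1L,
         ": time not strictly increasing")
  data.frame(time = tm, value = as.numeric(df[[2L]]))
}

#' Write a two-column trace file
#'
#' @param times,values Trace data.
#' @param path Output path; `.tsv` extension selects tab, otherwise comma.
#' @param col_names Header names, default `c("time", "value")`.
#' @export
write_trace <- function(times, values, path,
                        col_names = c("time", "value")) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(times, values)
  names(df) <- col_names
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a ThT plate with its layout sidecar
#'
#' The plate file is delimited text with the time column first and one
#' column per well; the layout sidecar maps wells to roles and conditions
#' (columns `well`, `role`, `condition`, optionally `compound`,
#' `concentration`).
#'
#' @param path Plate trace file.
#' @param layout_path Layout sidecar file.
#' @param sep Separator (auto-sniffed by default).
#' @param time_unit Unit of the time column; converted to hours.
#' @return A [tht_plate()].
#' @export
read_plate <- function(path, layout_path, sep = NULL, time_unit = "h") {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  tm <- time_to_hours(as.numeric(df[[1L]]), time_unit)
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop("'", path, "', data row ", bad[1L] + 1L,
         ": time not strictly increasing")
  wells <- as.matrix(df[-1L])
  layout <- read.table(layout_path, sep = sniff_sep(layout_path),
                       header = TRUE, stringsAsFactors = FALSE)
  tht_plate(tm, wells, layout)
}

#' Write a ThT plate and its layout sidecar
#'
#' @param plate A [tht_plate()].
#' @param path Plate trace output path.
#' @param layout_path Layout sidecar output path.
#' @export
write_plate <- function(plate, path, layout_path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(time = plate$times, plate$wells, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  write.table(plate$layout, layout_path,
              sep = if (grepl("\\.tsv$", layout_path)) "\t" else ",",
              row.names = FALSE, quote = FALSE)
}

#' Read an NMR peak table
#'
#' Delimited text with columns `residue`, `dH`, `dN`, `intensity`.
#'
#' @param path File path.
#' @param sep Separator (auto-sniffed by default).
#' @return Data frame suitable for [csp()].
#' @export
read_peak_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE)
  req <- c("residue", "dH", "dN", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("'", path, "': missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a dose series from per-condition trace files
#'
#' Each condition file holds the time column first and one column per
#' replicate well, all sharing a grid.
#'
#' @param paths Character vector of per-condition file paths.
#' @param conc Concentrations (uM) parallel to `paths`.
#' @param m0 Monomer concentration(s) (uM).
#' @param time_unit Unit of the time columns; converted to hours.
#' @return A [dose_series()].
#' @export
read_dose_series <- function(paths, conc, m0, time_unit = "h") {
  stopifnot(length(paths) == length(conc))
  parsed <- lapply(paths, function(p) {
    sep <- sniff_sep(p)
    df <- read.table(p, sep = sep, header = TRUE, check.names = FALSE)
    list(time = time_to_hours(as.numeric(df[[1L]]), time_unit),
         y = as.matrix(df[-1L]))
  })
  tt <- parsed[[1L]]$time
  for (i in seq_along(parsed))
    if (!isTRUE(all.equal(parsed[[i]]$time, tt)))
      stop("'", paths[i], "': time grid differs from '", paths[1L], "'")
  traces <- lapply(parsed, `[[`, "y")
  names(traces) <- sprintf("dose_%g", conc)
  dose_series(tt, traces, conc = conc, m0 = m0)
}

#' Write / read kinetic parameters as flat YAML
#'
#' Ground truth and fitted parameter sets are exchanged as a flat
#' key-value YAML mapping with the mechanism selected by name.
#'
#' @param p A [kinetic_params()] object (or plain named list).
#' @param path Output path.
#' @export
write_params <- function(p, path) {
  x <- unclass(p)
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
}

#' @rdname write_params
#' @return `read_params()` returns a [kinetic_params()] when the mapping
#'   carries a `mechanism` key, otherwise the plain list.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$mechanism)) return(x)
  do.call(kinetic_params, x)
}

# md5 of a serialized object, used to stamp result tables
config_hash <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

#' Run the screening-to-mechanism analysis workflow
#'
#' Orchestrates the analysis sequence on a manifest: (1) plate screening
#' (blank subtraction, normalization, activity calls), (2) dose-series
#' scenario comparison, (3) per-condition extraction of the macroscopic
#' rates. Stage failures are isolated: the failure is recorded and
#' downstream stages that need the failed output are skipped with a
#' reason. Result tables are written to `out_dir` together with a
#' provenance record (seed, package version, manifest hash).
#'
#' @param manifest Named list (or path to a YAML file) with optional
#'   entries `screen` (fields `plate`, `layout`, `compound`, `control`,
#'   `time_unit`), `dose_fit` (fields `paths`, `conc`, `m0`,
#'   `scenarios`, `time_unit`) and `extract` (logical; reuses the dose
#'   series); plus `seed` and `out_dir`.
#' @return List of class `"workflow_result"` with per-stage results,
#'   `failures`, and the provenance record. Written tables are delimited
#'   text under `out_dir`.
#' @export
run_workflow <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  seed <- if (is.null(manifest$seed)) 1L else as.integer(manifest$seed)
  out_dir <- if (is.null(manifest$out_dir)) "." else manifest$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = seed,
               package_version = as.character(packageVersion("amylokin")),
               manifest_hash = config_hash(manifest))
  results <- list(); failures <- list()

  stamp <- function(df) {
    df$config_hash <- prov$manifest_hash
    df$seed <- seed
    df
  }
  if (!is.null(manifest$screen)) {
    sc <- manifest$screen
    res <- try({
      plate <- read_plate(sc$plate, sc$layout,
                          time_unit = if (is.null(sc$time_unit)) "h"
                                      else sc$time_unit)
      plate <- normalize_plate(blank_subtract(plate))
      calls <- lapply(sc$compound, function(cmp)
        call_activity(plate, cmp, sc$control))
      tab <- do.call(rbind, lapply(calls, function(cl)
        data.frame(compound = cl$compound, fold_change = cl$fold_change,
                   fold_change_se = cl$fold_change_se, p_value = cl$p_value,
                   active = cl$active, direction = cl$direction)))
      write.table(stamp(tab), file.path(out_dir, "activity_calls.csv"),
                  sep = ",", row.names = FALSE, quote = FALSE)
      list(plate = plate, calls = calls, table = tab)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      failures$screen <- conditionMessage(attr(res, "condition"))
    else results$screen <- res
  }

  series <- NULL
  if (!is.null(manifest$dose_fit)) {
    dfm <- manifest$dose_fit
    res <- try({
      series <- read_dose_series(unlist(dfm$paths), unlist(dfm$conc),
                                  if (is.null(dfm$m0)) 20 else dfm$m0,
                                  time_unit = if (is.null(dfm$time_unit)) "h"
                                              else dfm$time_unit)
      scen <- if (is.null(dfm$scenarios)) perturbation_scenarios()
              else unlist(dfm$scenarios)
      bad <- setdiff(scen, c(perturbation_scenarios(), "none_vary"))
      if (length(bad))
        stop("unknown scenario name(s): ", paste(bad, collapse = ", "))
      cmp <- compare_scenarios(series, scen, seed = seed)
      write.table(stamp(cmp$table), file.path(out_dir, "scenario_fits.csv"),
                  sep = ",", row.names = FALSE, quote = FALSE)
      cmp
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      failures$dose_fit <- conditionMessage(attr(res, "condition"))
    else results$dose_fit <- res
  }

  if (isTRUE(manifest$extract)) {
    if (is.null(series)) {
      failures$extract <- "skipped: no dose series available (dose_fit missing or failed)"
    } else {
      res <- try({
        mac <- extract_macroscopic(series, seed = seed)
        write.table(stamp(as.data.frame(mac)),
                    file.path(out_dir, "macroscopic_rates.csv"),
                    sep = ",", row.names = FALSE, quote = FALSE)
        mac
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        failures$extract <- conditionMessage(attr(res, "condition"))
      else results$extract <- res
    }
  }

  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  structure(list(results = results, failures = failures,
                 provenance = prov, out_dir = out_dir,
                 ok = length(failures) == 0L),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("Workflow:", if (x$ok) "all stages completed" else "with failures", "\n")
  cat("  stages run:", paste(names(x$results), collapse = ", "), "\n")
  if (length(x$failures))
    for (nm in names(x$failures))
      cat("  FAILED ", nm, ": ", x$failures[[nm]], "\n", sep = "")
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}
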