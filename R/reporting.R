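# Structured output writers (CSV + JSON) and the run manifest.

#' Write a cost breakdown to CSV and JSON
#'
#' The CSV holds one row per cost category and one per unit operation; the
#' JSON mirrors the full object.
#'
#' @param costs A `biocogs_costs` object (see [annual_costs()]).
#' @param csv,json Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_cost_breakdown <- function(costs, csv = NULL, json = NULL) {
  written <- character()
  if (!is.null(csv)) {
    df <- rbind(
      data.frame(scope = "category", name = names(costs$by_category),
                 annual_cost = unname(costs$by_category)),
      data.frame(scope = "unit_operation",
                 name = names(costs$by_unit_operation),
                 annual_cost = unname(costs$by_unit_operation)))
    utils::write.csv(df, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      by_category = as.list(costs$by_category),
      by_unit_operation = as.list(costs$by_unit_operation),
      total = costs$total, batches = costs$batches,
      annual_mass = costs$annual_mass, cog_basis = costs$cog_basis,
      cog_per_gram = costs$cog_per_gram,
      capacity_expanded = costs$capacity_expanded),
      json, auto_unbox = TRUE, digits = NA)
    written <- c(written, json)
  }
  invisible(written)
}

#' Write Monte Carlo samples and summary
#'
#' @param mc A `biocogs_mc` object.
#' @param csv Path for the per-run sample table (one row per run).
#' @param json Path for the summary (mean, median, range, sd,
#'   runs-to-convergence, seed).
#' @return Invisibly, the paths written.
#' @export
write_mc <- function(mc, csv = NULL, json = NULL) {
  written <- character()
  if (!is.null(csv)) {
    utils::write.csv(mc$samples, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      summary = as.list(mc$summary),
      runs = nrow(mc$samples),
      runs_to_convergence = if (is.na(mc$runs_to_convergence)) NULL else
        mc$runs_to_convergence,
      seed = mc$seed),
      json, auto_unbox = TRUE, digits = NA)
    written <- c(written, json)
  }
  invisible(written)
}

#' Write a linear fit as JSON and a coefficient-table CSV
#'
#' @param fit A `biocogs_fit` object.
#' @param csv,json Output paths; either may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, csv = NULL, json = NULL) {
  written <- character()
  if (!is.null(csv)) {
    utils::write.csv(fit$coefficients, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(coefficients = fit$coefficients,
                              sigma2 = fit$sigma2, n = fit$n,
                              df_residual = fit$df_residual),
                         json, auto_unbox = TRUE, digits = NA)
    written <- c(written, json)
  }
  invisible(written)
}

#' Run manifest for a set of outputs
#'
#' Records the package version, seed, timestamp, configuration files and
#' every output file with its MD5 content hash, so a deterministic
#' subcommand rerun with the same config and seed reproduces identical
#' hashes.
#'
#' @param outputs Character vector of output file paths (must exist).
#' @param seed Integer seed used for the run.
#' @param configs Character vector of configuration files consumed.
#' @return A list of class `biocogs_manifest`.
#' @export
run_manifest <- function(outputs, seed, configs = character()) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("Manifest lists nonexistent output(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  hash <- function(paths) {
    if (!length(paths)) return(list())
    h <- tools::md5sum(paths)
    stats::setNames(as.list(unname(h)), basename(paths))
  }
  structure(list(
    package = "biocogs",
    version = as.character(utils::packageVersion("biocogs")),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    configs = hash(configs[file.exists(configs)]),
    outputs = hash(outputs)),
    class = "biocogs_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE)
  invisible(path)
}
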