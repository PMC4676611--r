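## Results serialization: counts and snapshots as CSV, run manifest as
## JSON; regimen and sensitivity tables as delimited text.

#' Write simulation results to a directory
#'
#' Writes \code{counts.csv} (step, N_MM, N_OB, N_OC), \code{snapshots.csv}
#' (step, type, i, j, k) and \code{manifest.json} (config echo, seed,
#' package version, file list) - enough to reproduce the run bit-exactly.
#'
#' @param result a [SimulationResult-class].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
writeResults <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- cellCounts(result)
  counts <- data.frame(step = seq_len(nrow(cm)) - 1L,
                       N_MM = cm[, "MM"], N_OB = cm[, "OB"],
                       N_OC = cm[, "OC"])
  utils::write.csv(counts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(snapshots(result), file.path(dir, "snapshots.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "myelomaABM",
    version = as.character(utils::packageVersion("myelomaABM")),
    seed = result@seed,
    config = result@config,
    files = c("counts.csv", "snapshots.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a counts time series written by [writeResults()]
#' @param dir directory holding \code{counts.csv}.
#' @return data.frame (step, N_MM, N_OB, N_OC).
#' @export
readCounts <- function(dir) {
  utils::read.csv(file.path(dir, "counts.csv"))
}

#' Summarize a regimen suite into the regimen-response table
#'
#' Median endpoint counts and median R_drug per regimen (the layout of
#' the drug-combination response table).
#'
#' @param suite data.frame from [runRegimenSuite()].
#' @return data.frame with one row per regimen.
#' @export
summarizeRegimens <- function(suite) {
  sp <- split(suite, factor(suite$regimen, levels = unique(suite$regimen)))
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(regimen = d$regimen[1L],
               N_MM120 = stats::median(d$N_MM120),
               N_OB120 = stats::median(d$N_OB120),
               N_OC120 = stats::median(d$N_OC120),
               R_drug = stats::median(d$R_drug))))
  rownames(out) <- NULL
  out
}

#' Write regimen / sensitivity tables as delimited text
#'
#' @param table data.frame ([summarizeRegimens()] or
#'   [sensitivitySpearman()] output).
#' @param path output file (CSV).
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
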