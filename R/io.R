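# Readers and writers for the pipeline's on-disk formats. Text tables are
# TSV with '#'-prefixed metadata header lines; the only binary format is
# the raw trace (little-endian float32 + JSON sidecar).

# TSV reader that drops whole lines starting with '#' but keeps '#'
# inside fields (device tags like "Device #4" contain one). Columns are
# read as character and converted to numeric only when every entry is
# numeric, so amino-acid labels like "T" or "F" are never coerced to
# logicals.
read_tsv_commented <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no data rows in ", path)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           colClasses = "character")
  for (nm in names(tab)) {
    num <- suppressWarnings(as.numeric(tab[[nm]]))
    if (!anyNA(num)) tab[[nm]] <- num
  }
  tab
}

#' Write a trace recording
#'
#' Two formats: `"tsv"` writes two columns (`time_s`, `current_nA`) with
#' metadata in `#` header lines; `"raw"` writes little-endian 4-byte floats
#' of current in nA plus a JSON sidecar (`<path>.json`) holding the
#' sampling rate, units, and provenance metadata.
#'
#' @param trace A [trace_recording].
#' @param path Output path.
#' @param format `"tsv"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("tsv", "raw")) {
  stopifnot(inherits(trace, "trace_recording"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# sampling_rate_Hz\t%.10g", trace$sampling_rate),
                 "# units\tnA",
                 "time_s\tcurrent_nA"), con)
    utils::write.table(
      data.frame(time_s = (seq_along(trace$samples) - 1L) / trace$sampling_rate,
                 current_nA = trace$samples),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    writeBin(as.numeric(trace$samples), path, size = 4L, endian = "little")
    jsonlite::write_json(
      c(list(sampling_rate_Hz = trace$sampling_rate, units = "nA",
             dtype = "float32le", n_samples = length(trace$samples)),
        trace$meta[vapply(trace$meta, function(x) !is.function(x), logical(1))]),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trace recording written by [write_trace()]
#'
#' @param path Trace path; format is inferred (a JSON sidecar marks the
#'   raw binary format).
#' @return A [trace_recording].
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$sampling_rate_Hz)) stop("sidecar lacks sampling_rate_Hz")
    x <- readBin(path, "numeric", n = meta$n_samples, size = 4L, endian = "little")
    return(trace_recording(x, meta$sampling_rate_Hz,
                           meta[setdiff(names(meta), c("sampling_rate_Hz", "dtype", "n_samples"))]))
  }
  hdr <- readLines(path, n = 20L)
  fs_line <- grep("^# sampling_rate_Hz\t", hdr, value = TRUE)
  if (length(fs_line) == 0L) stop("trace file lacks a sampling-rate header")
  fs <- as.numeric(sub("^# sampling_rate_Hz\t", "", fs_line[1]))
  tab <- read_tsv_commented(path)
  if (nrow(tab) == 0L) stop("trace file contains no samples")
  trace_recording(tab$current_nA, fs, list(units = "nA"))
}

#' Write an event table
#'
#' TSV with `#` metadata lines; columns as produced by the detector plus
#' any annotation columns present (e.g. `label`, `device`).
#'
#' @param events Event data frame.
#' @param path Output path.
#' @param meta Named list written as `# key\tvalue` header lines.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) writeLines(sprintf("# %s\t%s", nm, meta[[nm]]), con)
  utils::write.table(events, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path Event TSV path.
#' @return Event data frame.
#' @export
read_events <- function(path) {
  read_tsv_commented(path)
}

#' Serialize a density fit
#'
#' Writes the density curve as TSV (`grid`, `density`) and a JSON summary
#' (`<path>.json`) with the method, bandwidth, modes, and any mixture
#' components.
#'
#' @param fit A `density_fit`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_density_fit <- function(fit, path) {
  stopifnot(inherits(fit, "density_fit"))
  utils::write.table(data.frame(grid = fit$grid, density = fit$density),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(method = fit$method, bandwidth = fit$bandwidth,
                            n = fit$n, modes = fit$modes,
                            components = fit$components,
                            loglik = fit$loglik, bic = fit$bic),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a dwell-blockade heatmap
#'
#' Counts matrix as TSV; axis breaks and scale flags in `#` header lines.
#'
#' @param hm A `dwell_heatmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(hm, path) {
  stopifnot(inherits(hm, "dwell_heatmap"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dwell_breaks\t%s", paste(hm$dwell_breaks, collapse = ",")),
               sprintf("# blockade_breaks\t%s", paste(hm$blockade_breaks, collapse = ",")),
               sprintf("# log_dwell\t%s", hm$log_dwell),
               sprintf("# blockade_col\t%s", hm$blockade_col)), con)
  utils::write.table(hm$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a classifier report
#'
#' JSON with the confusion matrix, per-class metrics, and accuracy.
#'
#' @param report A `classifier_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_classifier_report <- function(report, path) {
  stopifnot(inherits(report, "classifier_report"))
  jsonlite::write_json(list(classes = rownames(report$confusion),
                            confusion = unclass(unname(as.matrix(report$confusion))),
                            per_class = report$per_class,
                            average_accuracy = report$average_accuracy,
                            n = report$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
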