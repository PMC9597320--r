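# Fluorescence transients: construction, validation, CSV input.
#
# A transient is one dark-adapted fast induction curve recorded from the
# onset of a saturating light pulse: a strictly increasing time grid in
# microseconds plus raw fluorescence values, labelled with genotype,
# treatment arm and replicate.

.treatments <- c("control", "stress")

#' Construct a single fluorescence transient
#'
#' @param sample_id unique sample label.
#' @param genotype genotype label.
#' @param treatment "control" or "stress" (case-insensitive).
#' @param replicate positive integer replicate number (need not be
#'   consecutive; identity is the (genotype, treatment, replicate, sample_id)
#'   tuple).
#' @param times time grid in microseconds, strictly increasing, spanning at
#'   least 60 us to 300 ms, length >= 10.
#' @param values fluorescence in instrument units, same length as `times`,
#'   all positive.
#' @return an object of class `transient`.
#' @export
transient <- function(sample_id, genotype, treatment, replicate, times, values) {
  treatment <- tolower(as.character(treatment))
  if (!treatment %in% .treatments)
    stop("unknown treatment label '", treatment, "' for sample ", sample_id,
         " (expected one of: ", paste(.treatments, collapse = ", "), ")")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1)
    stop("replicate must be a positive integer for sample ", sample_id)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values differ in length for sample ", sample_id)
  if (length(times) < 10)
    stop("transient for sample ", sample_id, " has fewer than 10 points")
  if (any(diff(times) <= 0))
    stop("times are not strictly increasing (duplicate or non-monotone time) for sample ",
         sample_id)
  if (times[1] > 60)
    stop("first sample time ", times[1], " us is later than 60 us for sample ", sample_id)
  if (times[length(times)] < 3e5)
    stop("last sample time ", times[length(times)], " us is before 300000 us for sample ",
         sample_id)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("fluorescence values must be positive and finite for sample ", sample_id)
  structure(list(sample_id = as.character(sample_id),
                 genotype = as.character(genotype),
                 treatment = treatment,
                 replicate = replicate,
                 times = times, values = values),
            class = "transient")
}

#' @export
print.transient <- function(x, ...) {
  cat(sprintf("<transient> %s | %s/%s rep %d | %d points, %.0f-%.0f us, F in [%.1f, %.1f]\n",
              x$sample_id, x$genotype, x$treatment, x$replicate, length(x$times),
              x$times[1], x$times[length(x$times)], min(x$values), max(x$values)))
  invisible(x)
}

#' Bundle transients into a set
#'
#' @param transients list of [transient()] objects.
#' @param metadata named list of free-form run annotations.
#' @return an object of class `transient_set`.
#' @export
transient_set <- function(transients, metadata = list()) {
  keys <- vapply(transients, function(tr)
    paste(tr$genotype, tr$treatment, tr$replicate, tr$sample_id, sep = "\r"), "")
  if (anyDuplicated(keys))
    stop("duplicate (genotype, treatment, replicate, sample_id) tuple: ",
         gsub("\r", "/", keys[duplicated(keys)][1]))
  grids <- lapply(transients, `[[`, "times")
  shared <- length(transients) <= 1 ||
    all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])), TRUE))
  structure(list(transients = transients, metadata = metadata,
                 shared_grid = shared),
            class = "transient_set")
}

#' @export
print.transient_set <- function(x, ...) {
  cat(sprintf("<transient_set> %d transients (%d genotypes), %s time grid\n",
              length(x$transients),
              length(unique(vapply(x$transients, `[[`, "", "genotype"))),
              if (x$shared_grid) "shared" else "mixed"))
  invisible(x)
}

#' @export
length.transient_set <- function(x) length(x$transients)

#' Read fluorescence transients from a long-format CSV
#'
#' The file must carry columns `sample_id`, `genotype`, `treatment`,
#' `replicate`, `time_us`, `fluorescence` (comma separated, header required).
#' Rows are grouped by sample and sorted by time, so row order in the file is
#' immaterial.  Treatment labels are matched case-insensitively against
#' control/stress; anything else is rejected.
#'
#' @param path CSV file path.
#' @param dialect only `"long_csv"` is defined.
#' @param time_unit unit of the time column: `"us"` (native), `"ms"` or
#'   `"s"`; times are converted to microseconds internally.
#' @return a [transient_set()].
#' @export
read_transients <- function(path, dialect = "long_csv", time_unit = c("us", "ms", "s")) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("format error reading ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("format error: ", path, " contains no data rows")
  required <- c("sample_id", "genotype", "treatment", "replicate", "time_us", "fluorescence")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("format error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  scale <- c(us = 1, ms = 1e3, s = 1e6)[[time_unit]]
  df$time_us <- as.numeric(df$time_us) * scale
  trs <- lapply(split(df, df$sample_id), function(g) {
    g <- g[order(g$time_us), , drop = FALSE]
    if (anyDuplicated(g$time_us))
      stop("validation error: duplicate time point within sample ", g$sample_id[1])
    if (length(unique(g$genotype)) > 1 || length(unique(g$treatment)) > 1 ||
        length(unique(g$replicate)) > 1)
      stop("validation error: inconsistent labels within sample ", g$sample_id[1])
    transient(g$sample_id[1], g$genotype[1], g$treatment[1], g$replicate[1],
              g$time_us, g$fluorescence)
  })
  trs <- trs[order(names(trs))]
  transient_set(unname(trs), metadata = list(source = path, time_unit = time_unit))
}

#' Write a transient set to the long CSV dialect
#'
#' Inverse of [read_transients()]: emits one row per recorded point with the
#' native microsecond time column.
#'
#' @param ts a [transient_set()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_transients <- function(ts, path) {
  stopifnot(inherits(ts, "transient_set"))
  rows <- lapply(ts$transients, function(tr)
    data.frame(sample_id = tr$sample_id, genotype = tr$genotype,
               treatment = tr$treatment, replicate = tr$replicate,
               time_us = sprintf("%.17g", tr$times),
               fluorescence = sprintf("%.17g", tr$values),
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, useBytes = TRUE)
  writeLines(do.call(paste, c(df, sep = ",")), con, useBytes = TRUE)
  invisible(path)
}

# iterate helpers used across modules
set_labels <- function(ts) {
  data.frame(
    sample_id = vapply(ts$transients, `[[`, "", "sample_id"),
    genotype  = vapply(ts$transients, `[[`, "", "genotype"),
    treatment = vapply(ts$transients, `[[`, "", "treatment"),
    replicate = vapply(ts$transients, `[[`, 1L, "replicate"),
    stringsAsFactors = FALSE)
}
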