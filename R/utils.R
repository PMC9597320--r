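#' @keywords internal
"_PACKAGE"

# Named random substreams derived from one master seed.  Offsets are fixed
# constants so every stage sees a reproducible, stage-specific stream no
# matter in which order stages run.  Kept below 2^31 - 1.
.substream_offsets <- c(
  transients = 104729L,
  biochem    = 224737L,
  noise      = 350377L,
  stats      = 479909L,
  cluster    = 611953L,
  cmi        = 733331L
)

substream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.substream_offsets))
  as.integer((as.numeric(seed) + .substream_offsets[[stream]]) %% 2147483647)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' 1 means identical partitions, values near 0 are expected for unrelated
#' partitions.
#'
#' @param a,b vectors of cluster labels (any type coercible to factor), same
#'   length.
#' @return a single number, the Hubert-Arabie adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must label the same items")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Write a table of flat records as TSV
#'
#' Writes records to a UTF-8 tab-separated file with header, '.' decimal
#' separator and NA for missing values.  Numbers are written with enough
#' digits that reading the file back reproduces them to at least 12
#' significant digits.
#'
#' @param records a data.frame, or a list of named lists sharing one key set.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records) == 0) stop("cannot infer a schema from an empty list; pass a data.frame")
    keys <- names(records[[1]])
    for (i in seq_along(records)) {
      if (!identical(sort(names(records[[i]])), sort(keys)))
        stop("record ", i, " has keys {", paste(names(records[[i]]), collapse = ","),
             "} differing from record 1 {", paste(keys, collapse = ","), "}")
    }
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r[keys], check.names = FALSE)))
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  if (nrow(out) > 0) {
    body <- do.call(paste, c(lapply(out, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "NA"
      x
    }), sep = "\t"))
    writeLines(body, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path file path.
#' @return a data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

# significance stars as used throughout the report tables
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

# linear interpolation of y at x0 on the log10(x) axis; x strictly increasing
interp_logtime <- function(x, y, x0) {
  stats::approx(log10(x), y, xout = log10(x0), rule = 1)$y
}
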