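.trial_schema <- c("subject", "trial_index", "numeral_type", "num_a",
                   "num_b", "log_distance", "is_dummy", "correct", "rt")

#' Write a trial table to CSV
#'
#' @param trials Trial table (any columns; the documented schema plus
#'   whatever extras are present).
#' @param path Output file.
#' @param seed,config_hash Optional provenance values embedded as comment
#'   header lines (`# seed: ...`, `# config: ...`).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(config_hash)) writeLines(paste0("# config: ", config_hash), con)
  write.csv(trials, con, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the documented trial schema: mandatory columns must be present
#' (a missing one raises a schema error naming it), `numeral_type` values
#' must be known (rows failing this are reported by row number), and
#' response times must look like seconds - values beyond the task deadline
#' trigger a unit-sanity warning, since millisecond-scale numbers like 710
#' would exceed the 3-second deadline.
#'
#' @param path CSV file (comment lines starting with `#` are skipped).
#' @param required Mandatory columns.
#' @param deadline_s Deadline used for the RT unit check.
#' @return Trial data frame; malformed-row details, if any, are attached as
#'   attribute `"problems"`.
#' @export
read_trials <- function(path, required = c("subject", "numeral_type",
                                           "log_distance", "correct", "rt"),
                        deadline_s = 3.0) {
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  problems <- NULL
  if (!is.null(tab$numeral_type)) {
    bad <- which(!tab$numeral_type %in% .numeral_types)
    if (length(bad))
      stop("schema error: unknown numeral_type in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.character(tab$correct))
    tab$correct <- as.logical(tab$correct)
  if (!is.null(tab$rt)) {
    too_big <- !is.na(tab$rt) & tab$rt > deadline_s
    if (any(too_big)) {
      warning("rt values exceed the ", deadline_s,
              " s deadline; are they in milliseconds?")
      problems <- data.frame(row = which(too_big),
                             issue = "rt beyond deadline")
    }
  }
  attr(tab, "problems") <- problems
  tab
}

# small deterministic string hash (djb2-style polynomial mod 2^31 - 1) for
# config provenance lines in output files
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
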