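# Serialization of analysis results and access to the published reference
# tables shipped with the package.

#' Flatten CEA results into the standard results table
#'
#' One row per arm and country with discounted cost, QALYs, incremental
#' cost/QALY (experimental row only) and the ICER. A result whose
#' incremental QALY sign makes the ratio meaningless carries its dominance
#' status (`"dominant"`, `"dominated"`, `"undefined"`) in the `icer`
#' column instead of a number.
#'
#' @param results A `cea_result` or (possibly empty) list of them.
#' @return data.frame with columns `country`, `arm`, `cost`, `qaly`,
#'   `incremental_cost`, `incremental_qaly`, `icer` (character).
#' @export
cea_table <- function(results) {
  if (inherits(results, "cea_result")) results <- list(results)
  cols <- c("country", "arm", "cost", "qaly", "incremental_cost",
            "incremental_qaly", "icer")
  if (!length(results)) {
    out <- data.frame(country = character(), arm = character(),
                      cost = numeric(), qaly = numeric(),
                      incremental_cost = numeric(),
                      incremental_qaly = numeric(), icer = character())
    return(out)
  }
  rows <- lapply(results, function(res) {
    icer_chr <- if (res$status %in% c("dominated", "undefined")) res$status
      else if (res$status == "dominant") "dominant"
      else as.character(res$icer)
    data.frame(
      country = res$country,
      arm = c("experimental", "control"),
      cost = c(res$experimental$total_cost, res$control$total_cost),
      qaly = c(res$experimental$total_qaly, res$control$total_qaly),
      incremental_cost = c(res$delta_cost, NA_real_),
      incremental_qaly = c(res$delta_qaly, NA_real_),
      icer = c(icer_chr, NA_character_)
    )
  })
  stats::setNames(do.call(rbind, rows), cols)
}

#' Write / read the results table
#'
#' `write_results()` serializes a results table (or `cea_result`(s)) to CSV
#' with full double precision, so `read_results(write_results(x, f))`
#' reproduces every numeric value; `write_results_json()` writes the same
#' rows as a JSON mirror.
#'
#' @param results A `cea_result`, list of them, or a [cea_table()]
#'   data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  tab <- if (is.data.frame(results)) results else cea_table(results)
  out <- tab
  for (cc in c("cost", "qaly", "incremental_cost", "incremental_qaly"))
    out[[cc]] <- vapply(tab[[cc]], function(v)
      if (is.na(v)) NA_character_ else format(v, digits = 17), "")
  handler <- function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e), call. = FALSE)
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = handler, warning = handler)
  invisible(path)
}

#' @rdname write_results
#' @export
write_results_json <- function(results, path) {
  tab <- if (is.data.frame(results)) results else cea_table(results)
  jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, colClasses = c(country = "character",
                                       arm = "character",
                                       icer = "character"))
}

#' Published reference tables
#'
#' Checked-in copies of the published model-input table
#' (`table1_reference()`: one row per parameter, one column per country)
#' and base-case results table (`table2_reference()`: per-country arm
#' costs, QALYs, incremental values and ICERs) used by the golden tests
#' and the worked examples.
#'
#' @return A data.frame.
#' @export
table1_reference <- function() {
  utils::read.csv(system.file("extdata", "table1_reference.csv",
                              package = "partsaCEA", mustWork = TRUE))
}

#' @rdname table1_reference
#' @export
table2_reference <- function() {
  utils::read.csv(system.file("extdata", "table2_reference.csv",
                              package = "partsaCEA", mustWork = TRUE))
}
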