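# Exposure-stratified mortality table and crude association measures.
#
# A cohort table records, per exposure stratum, the cause-of-interest deaths
# ("cases"), the subjects classified alive at study end, and the subjects
# known dead of other causes; the latter two together are the non-cases.
# The count of subjects lost to follow-up is carried at the table level,
# because in the motivating study losses could not be attributed to strata.

abort_degenerate <- function(msg) {
  abort(msg, class = "ltfbias_degenerate_table")
}

check_count <- function(x, what, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", what),
          class = "ltfbias_input_error")
  }
  if (any(x != trunc(x))) {
    abort(sprintf("`%s` must contain whole numbers; fractional counts are rejected, not rounded.", what),
          class = "ltfbias_input_error")
  }
  lo <- if (allow_zero) 0L else 1L
  if (any(x < lo)) {
    abort(sprintf("`%s` must be >= %d.", what, lo), class = "ltfbias_input_error")
  }
  as.integer(x)
}

#' Build an exposure-stratified cohort mortality table
#'
#' Constructs the central data object of the bias analysis: one row per
#' exposure stratum with counts of cases (deaths from the cause of
#' interest), non-cases classified alive at study end, and non-cases known
#' dead of other causes, plus the total number of subjects lost to
#' follow-up. Strata are ordered; by convention the last stratum is the
#' highest-exposure (target) stratum, and the reference stratum is named
#' explicitly.
#'
#' @param strata Data frame with columns `label`, `cases`,
#'   `alive_noncases`, `deceased_other`. Counts must be whole and
#'   non-negative; fractional values are rejected rather than rounded.
#' @param n_lost Total number of subjects lost to follow-up (whole,
#'   non-negative).
#' @param reference Label of the reference (unexposed) stratum. Defaults to
#'   the first stratum.
#'
#' @return A `cohort_table`: a tibble of strata with attributes `n_lost`
#'   and `reference`.
#' @examples
#' tab <- cohort_table(
#'   data.frame(
#'     label = c("never", "high"),
#'     cases = c(14, 14),
#'     alive_noncases = c(414, 112),
#'     deceased_other = c(37, 36)
#'   ),
#'   n_lost = 338, reference = "never"
#' )
#' crude_odds_ratio(tab, "high")
#' @export
cohort_table <- function(strata, n_lost, reference = strata$label[[1]]) {
  if (!is.data.frame(strata)) {
    abort("`strata` must be a data frame.", class = "ltfbias_input_error")
  }
  needed <- c("label", "cases", "alive_noncases", "deceased_other")
  missing_cols <- setdiff(needed, names(strata))
  if (length(missing_cols)) {
    abort(paste0("`strata` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ltfbias_input_error")
  }
  if (nrow(strata) < 2) {
    abort("A cohort table needs at least two exposure strata.",
          class = "ltfbias_input_error")
  }
  out <- tibble(
    label = as.character(strata$label),
    cases = check_count(strata$cases, "cases"),
    alive_noncases = check_count(strata$alive_noncases, "alive_noncases"),
    deceased_other = check_count(strata$deceased_other, "deceased_other")
  )
  if (anyDuplicated(out$label)) {
    abort("Stratum labels must be unique.", class = "ltfbias_input_error")
  }
  if (length(reference) != 1L || !reference %in% out$label) {
    abort("`reference` must name exactly one existing stratum.",
          class = "ltfbias_input_error")
  }
  n_lost <- check_count(n_lost, "n_lost")
  structure(out,
            n_lost = n_lost,
            reference = as.character(reference),
            class = c("cohort_table", class(out)))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort mortality table: %d strata, reference \"%s\", %d lost to follow-up\n",
              nrow(x), reference_label(x), n_lost(x)))
  NextMethod()
  invisible(x)
}

#' Number of subjects lost to follow-up
#' @param table A [cohort_table()].
#' @return Integer count of subjects whose vital status is unknown.
#' @export
n_lost <- function(table) attr(table, "n_lost", exact = TRUE)

#' Reference-stratum label of a cohort table
#' @inheritParams n_lost
#' @return Character label of the reference stratum.
#' @export
reference_label <- function(table) attr(table, "reference", exact = TRUE)

#' Default target stratum: the last (highest-exposure) stratum
#' @inheritParams n_lost
#' @return Character label of the highest-exposure stratum.
#' @export
highest_label <- function(table) {
  last <- table$label[[nrow(table)]]
  if (identical(last, reference_label(table))) {
    setdiff(table$label, reference_label(table)) |> utils::tail(1)
  } else {
    last
  }
}

stratum_row <- function(table, label) {
  i <- match(label, table$label)
  if (is.na(i)) {
    abort(sprintf("No stratum labelled \"%s\".", label),
          class = "ltfbias_input_error")
  }
  table[i, , drop = FALSE]
}

#' Non-case counts by stratum
#'
#' Non-cases are subjects classified alive at study end plus subjects known
#' dead of causes other than the cause of interest.
#'
#' @inheritParams n_lost
#' @param label Optional stratum label; when `NULL`, returns the vector for
#'   all strata in table order.
#' @return Integer vector of non-case counts.
#' @export
noncases <- function(table, label = NULL) {
  if (!is.null(label)) table <- stratum_row(table, label)
  table$alive_noncases + table$deceased_other
}

#' Crude odds of cause-specific death in one stratum
#'
#' @inheritParams n_lost
#' @param label Stratum label.
#' @return cases / non-cases for the stratum.
#' @export
crude_odds <- function(table, label) {
  s <- stratum_row(table, label)
  nc <- noncases(table, label)
  if (nc == 0) {
    abort_degenerate(sprintf("Stratum \"%s\" has zero non-cases; odds are undefined.", label))
  }
  s$cases / nc
}

four_cells <- function(table, exposed_label) {
  ref <- reference_label(table)
  if (identical(exposed_label, ref)) {
    abort("The exposed stratum cannot be the reference stratum.",
          class = "ltfbias_input_error")
  }
  e <- stratum_row(table, exposed_label)
  r <- stratum_row(table, ref)
  c(a = e$cases, b = noncases(table, exposed_label),
    c = r$cases, d = noncases(table, ref))
}

#' Crude (observed) odds ratio
#'
#' Odds of cause-specific death in the named exposed stratum divided by
#' the odds in the reference stratum.
#'
#' @inheritParams n_lost
#' @param exposed_label Label of the exposed stratum; defaults to the
#'   highest-exposure (last) stratum.
#' @return The observed odds ratio.
#' @export
crude_odds_ratio <- function(table, exposed_label = highest_label(table)) {
  cells <- four_cells(table, exposed_label)
  if (any(cells == 0)) {
    abort_degenerate("A zero cell makes the odds ratio undefined.")
  }
  (cells[["a"]] / cells[["b"]]) / (cells[["c"]] / cells[["d"]])
}

#' Wald confidence interval for the crude odds ratio
#'
#' Standard large-sample interval on the log-odds-ratio scale,
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, with no continuity
#' correction.
#'
#' @inheritParams crude_odds_ratio
#' @param level Two-sided coverage in `[0, 1)`; `level = 0` collapses both
#'   bounds onto the point estimate.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
wald_ci <- function(table, exposed_label = highest_label(table), level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level >= 1) {
    abort("`level` must be a single number in [0, 1).", class = "ltfbias_input_error")
  }
  cells <- four_cells(table, exposed_label)
  if (any(cells == 0)) {
    abort_degenerate("A zero cell makes the Wald interval undefined.")
  }
  or <- (cells[["a"]] / cells[["b"]]) / (cells[["c"]] / cells[["d"]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
}

#' Crude association summary as a one-row tibble
#'
#' Convenience wrapper bundling [crude_odds()], [crude_odds_ratio()] and
#' [wald_ci()] for piping into reports.
#'
#' @inheritParams wald_ci
#' @return One-row tibble with the stratum odds, the odds ratio and its
#'   Wald interval.
#' @export
crude_association <- function(table, exposed_label = highest_label(table),
                              level = 0.95) {
  ci <- wald_ci(table, exposed_label, level)
  tibble(
    exposed = exposed_label,
    reference = reference_label(table),
    odds_exposed = crude_odds(table, exposed_label),
    odds_reference = crude_odds(table, reference_label(table)),
    or = crude_odds_ratio(table, exposed_label),
    lower = ci[["lower"]],
    upper = ci[["upper"]],
    level = level
  )
}

#' Read / write a cohort table as delimited text
#'
#' The on-disk format is tab-separated with one row per stratum
#' (`label`, `cases`, `alive_noncases`, `deceased_other`) preceded by
#' comment header lines `# n_lost: <int>` and `# reference: <label>`.
#'
#' @param path File path.
#' @return `read_cohort_table()` returns a [cohort_table()];
#'   `write_cohort_table()` returns `path` invisibly.
#' @export
read_cohort_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (!length(m)) {
      abort(sprintf("Cohort table file is missing the \"# %s:\" header.", key),
            class = "ltfbias_input_error")
    }
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", m[[1]]))
  }
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE)
  cohort_table(body,
               n_lost = as.numeric(get_field("n_lost")),
               reference = get_field("reference"))
}

#' @rdname read_cohort_table
#' @param table A [cohort_table()].
#' @export
write_cohort_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_lost: %d", n_lost(table)),
               sprintf("# reference: %s", reference_label(table))), con)
  write.table(as.data.frame(table), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled trichlorophenol-worker cohort table
#'
#' Three TCDD exposure strata (never-exposed reference, 0-2085.7 ppt-mo,
#' >=2085.8 ppt-mo) with ischemic-heart-disease deaths as cases and 338
#' subjects lost to follow-up, as published for the New Zealand
#' trichlorophenol production cohort.
#'
#' @return A [cohort_table()].
#' @export
mcbride_cohort <- function() {
  read_cohort_table(system.file("extdata", "mcbride_cohort.tsv",
                                package = "ltfbias", mustWork = TRUE))
}
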