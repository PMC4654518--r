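#' Read a bioluminescence table
#'
#' Reads one of the three CSV layouts the package's analysis functions
#' consume:
#' * `"single"` — columns `time` (or `time_hours`) and `value`: one
#'   population-level trace;
#' * `"cells_long"` — columns `cell_id`, `time` (or `time_hours`), `value`:
#'   a single-cell trace collection;
#' * `"plate_wide"` — metadata columns `plate_id`, `well_pos`, optionally
#'   `gene_id` and `category`, followed by time-point columns: a plate
#'   screen. Wells without a `gene_id` are classed as controls (no siRNA).
#'
#' Uniform sampling is validated (relative tolerance 1e-6); ragged or
#' non-numeric rows produce an error naming the offending row.
#'
#' @param path CSV file path.
#' @param layout One of `"single"`, `"cells_long"`, `"plate_wide"`.
#' @return A tibble in the layout's canonical form.
#' @export
read_timeseries_table <- function(path,
                                  layout = c("single", "cells_long",
                                             "plate_wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(sprintf("malformed CSV: problem in data row %d (%s).",
                  pr$row[1] - 1, pr$expected[1]))
  }
  names(df)[names(df) == "time_hours"] <- "time"
  if (layout == "single") {
    if (!all(c("time", "value") %in% names(df))) {
      abort("single layout needs `time` (or `time_hours`) and `value` columns.")
    }
    out <- tibble::tibble(time = as.numeric(df$time),
                          value = as.numeric(df$value))
    series_interval(out)
    check_series_values(out$value)
    return(out)
  }
  if (layout == "cells_long") {
    if (!all(c("cell_id", "time", "value") %in% names(df))) {
      abort("cells_long layout needs `cell_id`, `time`, `value` columns.")
    }
    out <- tibble::tibble(cell_id = as.character(df$cell_id),
                          time = as.numeric(df$time),
                          value = as.numeric(df$value))
    for (id in unique(out$cell_id)) {
      sub <- out[out$cell_id == id, ]
      series_interval(sub)
      if (!all(is.finite(sub$value))) {
        abort(sprintf("non-finite values in trace of cell %s.", id))
      }
    }
    return(out)
  }
  # plate_wide
  if (!all(c("plate_id", "well_pos") %in% names(df))) {
    abort("plate_wide layout needs `plate_id` and `well_pos` columns.")
  }
  meta <- intersect(c("plate_id", "well_pos", "gene_id", "category"),
                    names(df))
  tcols <- setdiff(names(df), meta)
  if (length(tcols) < 4) abort("plate_wide layout needs >= 4 time-point columns.")
  mat <- suppressWarnings(vapply(df[tcols], as.numeric, numeric(nrow(df))))
  bad <- which(!stats::complete.cases(mat))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or missing time points in row %d.", bad[1]))
  }
  key <- paste(df$plate_id, df$well_pos)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicated well id: %s.", key[anyDuplicated(key)[1]]))
  }
  out <- dplyr::bind_cols(df[meta], tibble::as_tibble(mat))
  if (!"gene_id" %in% names(out)) out$gene_id <- NA_character_
  if (!"category" %in% names(out)) {
    out$category <- ifelse(is.na(out$gene_id) | out$gene_id == "",
                           "control", "perturbed")
  }
  dplyr::relocate(out, "plate_id", "well_pos", "gene_id", "category")
}

#' Write analysis results to CSV or JSON
#'
#' CSV output keeps the column order of the input and renders numeric
#' columns at 6 significant digits, so repeated write/read/write round
#' trips are byte-identical. JSON output embeds the configuration and seed
#' used for the run alongside the results.
#'
#' @param x A data frame (CSV) or any list/data frame (JSON).
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @param config,seed Optional run configuration and seed recorded in JSON
#'   output.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, format = NULL, config = NULL,
                          seed = NULL) {
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  if (format == "csv") {
    df <- as.data.frame(x)
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
    }
    readr::write_csv(df, path, progress = FALSE)
  } else {
    payload <- list(config = config, seed = seed, results = x)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}
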