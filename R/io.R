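# Delimited-text readers/writers for the assay table schemas and the keyed
# parameter report.

#' Assay table schemas
#'
#' Column contracts for the delimited tables the fitting stages consume.
#' Required columns must be present (any order); `numeric` columns are
#' validated cell by cell with line-numbered errors.
#'
#' @return Named list of schemas, each with `required`, `numeric`, and
#'   `optional` character vectors.
#' @export
assay_schemas <- function() {
  list(
    melt = list(required = c("curve_id", "denaturant_M", "signal"),
                numeric = c("denaturant_M", "signal", "temperature_K",
                            "zn_free_M"),
                optional = c("temperature_K", "zn_free_M",
                             "denaturant_kind")),
    binding = list(required = c("assay", "curve_id", "x_M", "y"),
                   numeric = c("x_M", "y", "fz3_total_M", "zn_total_M"),
                   optional = c("fz3_total_M", "zn_total_M", "oligo",
                                "mutant")),
    stability = list(required = c("temperature_K", "dg"),
                     numeric = c("temperature_K", "dg", "se"),
                     optional = "se"),
    linkage = list(required = c("zn_free_M", "dg"),
                   numeric = c("zn_free_M", "dg", "se"),
                   optional = "se"),
    mutants = list(required = c("name", "dg_apo", "k_zn"),
                   numeric = c("dg_apo", "se_dg_apo", "k_zn", "se_k_zn",
                               "k_zn_direct"),
                   optional = c("se_dg_apo", "se_k_zn", "k_zn_direct",
                                "class_label")),
    landscape = list(required = c("temperature_K", "log10_zn_free_M",
                                  "f_holo"),
                     numeric = c("temperature_K", "log10_zn_free_M",
                                 "f_holo"),
                     optional = character(0))
  )
}

#' Read and validate a delimited assay table
#'
#' Reads a comma-delimited UTF-8 table, checks the schema's required columns
#' (order-insensitive), and converts numeric columns with cell-level error
#' reporting (file line numbers, counting the header as line 1).
#' Concentration columns accept unit suffixes via [parse_conc()].
#'
#' @param path File path.
#' @param schema One of `names(assay_schemas())`.
#' @return Validated tibble.
#' @export
read_assay_table <- function(path, schema) {
  schemas <- assay_schemas()
  if (!schema %in% names(schemas)) {
    abort(sprintf("unknown schema '%s' (use one of %s).", schema,
                  paste(names(schemas), collapse = ", ")))
  }
  sc <- schemas[[schema]]
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(sc$required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  conc_cols <- grep("_M$", names(raw), value = TRUE)
  for (col in intersect(sc$numeric, names(raw))) {
    vals <- raw[[col]]
    parsed <- if (col %in% conc_cols) {
      vapply(vals, function(v) {
        if (is.na(v)) return(NA_real_)
        tryCatch(parse_conc(v), error = function(e) NaN)
      }, numeric(1), USE.NAMES = FALSE)
    } else {
      suppressWarnings(as.numeric(vals))
    }
    bad <- which((is.na(parsed) & !is.na(vals)) | is.nan(parsed))
    if (length(bad) > 0) {
      abort(sprintf("%s: column '%s', line %d: cannot parse '%s' as a number.",
                    path, col, bad[1] + 1, vals[bad[1]]))
    }
    raw[[col]] <- parsed
  }
  raw
}

#' Write a delimited assay or result table
#'
#' @param data Data frame.
#' @param path Output path (comma-delimited UTF-8).
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a landscape grid to delimited text
#'
#' Long-format export with columns `temperature_K`, `log10_zn_free_M`,
#' `f_holo`.
#'
#' @param grid A [landscape_grid()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(grid, path) {
  need <- c("temperature_K", "log10_zn_free_M", "f_holo")
  if (!all(need %in% names(grid))) abort("not a landscape grid.")
  readr::write_csv(grid[need], path, progress = FALSE)
  invisible(path)
}

#' Write an analysis report as keyed text
#'
#' Serialises a named list of sections -- each a named list of scalar values
#' or small data frames -- to a human-readable keyed text file with
#' deterministic field order. Scalars are written as `key: value` (full
#' double precision); data frames as embedded CSV blocks. The report always
#' carries the package version and the sign-convention statement.
#'
#' @param report Named list of sections.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  if (is.null(names(report)) || any(names(report) == "")) {
    abort("`report` must be a fully named list of sections.")
  }
  lines <- c("# zincfold analysis report",
             sprintf("version: %s",
                     as.character(utils::packageVersion("zincfold"))),
             "sign_convention: stability free energy, positive = folded state favoured; K_apo = exp(+dG/RT)",
             "")
  for (sec in names(report)) {
    lines <- c(lines, sprintf("[%s]", sec))
    entry <- report[[sec]]
    if (is.data.frame(entry)) {
      lines <- c(lines, "table:",
                 readr::format_csv(entry) |>
                   strsplit("\n") |> unlist() |> (\(x) paste0("  ", x))(),
                 "")
      next
    }
    if (is.null(names(entry)) || any(names(entry) == "")) {
      abort(sprintf("section '%s' must be named.", sec))
    }
    for (k in names(entry)) {
      v <- entry[[k]]
      lines <- c(lines, sprintf("%s: %s", k,
                                if (is.numeric(v))
                                  paste(format(v, digits = 17),
                                        collapse = ", ")
                                else paste(v, collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a keyed-text analysis report
#'
#' Parses a file written by [write_report()] back into a named list of
#' sections; scalar values round-trip at full double precision, embedded
#' tables return as tibbles.
#'
#' @param path File path.
#' @return Named list with attributes `version` and `sign_convention`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  out <- list()
  sec <- NULL
  version <- sign_conv <- NA_character_
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^version: ", ln) && is.null(sec)) {
      version <- sub("^version: ", "", ln)
    } else if (grepl("^sign_convention: ", ln) && is.null(sec)) {
      sign_conv <- sub("^sign_convention: ", "", ln)
    } else if (grepl("^\\[.+\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (!is.null(sec) && ln == "table:") {
      j <- i + 1
      while (j <= length(lines) && grepl("^  ", lines[j])) j <- j + 1
      csv <- paste(sub("^  ", "", lines[(i + 1):(j - 1)]), collapse = "\n")
      out[[sec]] <- readr::read_csv(I(csv), col_types = readr::cols(),
                                    progress = FALSE)
      i <- j
      next
    } else if (!is.null(sec) && grepl("^[^:]+: ", ln)) {
      k <- sub(":.*$", "", ln)
      v <- sub("^[^:]+: ", "", ln)
      parts <- strsplit(v, ", ", fixed = TRUE)[[1]]
      num <- suppressWarnings(as.numeric(parts))
      out[[sec]][[k]] <- if (!anyNA(num)) num else parts
    }
    i <- i + 1
  }
  attr(out, "version") <- version
  attr(out, "sign_convention") <- sign_conv
  out
}
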