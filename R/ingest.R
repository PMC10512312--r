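# Canonical TSV dialect: UTF-8, Unix newlines, mandatory header, no quoting;
# tabs and newlines are therefore forbidden inside fields.

read_tsv_checked <- function(path, columns, col_classes) {
  if (!file.exists(path)) {
    stop_io(sprintf("file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                      colClasses = col_classes, check.names = FALSE,
                      stringsAsFactors = FALSE, encoding = "UTF-8",
                      blank.lines.skip = TRUE),
    error = function(e) stop_format(sprintf("cannot parse %s: %s",
                                            path, conditionMessage(e)))
  )
  miss <- setdiff(columns, names(df))
  if (length(miss) > 0L) {
    stop_format(sprintf("%s is missing required column(s): %s",
                        basename(path), paste(miss, collapse = ", ")))
  }
  df[, columns, drop = FALSE]
}

check_species_known <- function(ids, species, what, strict) {
  unknown <- setdiff(unique(ids), species$species_id)
  if (length(unknown) == 0L) return(invisible(character(0)))
  msg <- sprintf("%s refers to species absent from the taxonomy: %s",
                 what, paste(unknown, collapse = ", "))
  if (strict) stop_validation(msg, unknown = unknown)
  warning(msg, call. = FALSE)
  invisible(unknown)
}

#' Read a species-to-section taxonomy table
#'
#' Reads the canonical `taxonomy.tsv` dialect (tab-separated, UTF-8, header
#' row `species_id`, `section`, `strain`) and validates it: unique non-empty
#' species, non-empty section labels, row order preserved.
#'
#' @param path Path to a taxonomy TSV file.
#' @return A [species_table()].
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path, c("species_id", "section", "strain"),
                         col_classes = "character")
  validate_species_table(df)
}

#' Read a per-species count table
#'
#' Reads the canonical `counts.tsv` dialect (columns `species_id`,
#' `category`, `count`). Counts must be non-negative integers; in strict
#' mode every species must appear in the taxonomy, in lenient mode unknown
#' species are kept with a warning.
#'
#' @param path Path to a counts TSV file.
#' @param species Optional [species_table()] to cross-check species against.
#' @param strict If `TRUE` (default) unknown species raise an error.
#' @return A [count_table()].
#' @export
read_counts <- function(path, species = NULL, strict = TRUE) {
  df <- read_tsv_checked(path, c("species_id", "category", "count"),
                         col_classes = c("character", "character",
                                         "character"))
  if (nrow(df) > 0L) {
    parsed <- suppressWarnings(as.numeric(df$count))
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) {
      stop_format(sprintf("%s: unparseable count in data row(s): %s",
                          basename(path), paste(bad, collapse = ", ")))
    }
    df$count <- parsed
  } else {
    df$count <- integer(0)
  }
  out <- validate_count_table(df)
  if (!is.null(species)) {
    check_species_known(out$species_id, species, basename(path), strict)
  }
  out
}

#' Read a feature hit table
#'
#' Reads the canonical `hits.tsv` dialect (columns `species_id`,
#' `feature_name`, `match_percent`, `annotation`). `match_percent` is parsed
#' as a real number and must lie in `[0, 100]`.
#'
#' @inheritParams read_counts
#' @param path Path to a hits TSV file.
#' @return A [hit_table()].
#' @export
read_hits <- function(path, species = NULL, strict = TRUE) {
  df <- read_tsv_checked(
    path, c("species_id", "feature_name", "match_percent", "annotation"),
    col_classes = "character")
  out <- validate_hit_table(df)
  if (!is.null(species)) {
    check_species_known(out$species_id, species, basename(path), strict)
  }
  out
}

format_num <- function(x) {
  # shortest decimal round-tripping representation
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.15g", v)
  }, character(1))
}

write_tsv_canonical <- function(df, path) {
  chr <- vapply(df, is.character, logical(1))
  for (j in which(chr)) {
    bad <- grepl("[\t\n\r]", df[[j]])
    if (any(bad)) {
      stop_validation(sprintf(
        "field values may not contain tabs or newlines (column %s)",
        names(df)[j]))
    }
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_io(sprintf(
                    "cannot open %s for writing: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  lines <- paste(names(df), collapse = "\t")
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(x) {
      if (is.numeric(x) && !is.integer(x)) format_num(x) else as.character(x)
    })
    lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
  }
  writeLines(lines, con, sep = "\n", useBytes = FALSE)
  invisible(path)
}

#' Write tables in the canonical TSV dialects
#'
#' @param x A [species_table()], [count_table()] or [hit_table()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_taxonomy <- function(x, path) {
  write_tsv_canonical(validate_species_table(x), path)
}

#' @rdname write_taxonomy
#' @export
write_counts <- function(x, path) {
  write_tsv_canonical(validate_count_table(x), path)
}

#' @rdname write_taxonomy
#' @export
write_hits <- function(x, path) {
  write_tsv_canonical(validate_hit_table(x), path)
}
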