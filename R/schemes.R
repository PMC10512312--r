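#' Define a percent-match binning scheme
#'
#' A bin scheme is an ordered set of pairwise-disjoint intervals over the
#' percent-match axis together with an exclusion threshold: values strictly
#' below the threshold are dropped, and every retained value must fall in
#' exactly one bin.
#'
#' @param bins Data frame with columns `label`, `lower`, `upper`,
#'   `lower_inclusive`, `upper_inclusive`, ordered by decreasing lower
#'   bound.
#' @param exclusion_threshold Values strictly below this are excluded.
#' @return An object of class `bin_scheme`.
#' @seealso [amp_bin_scheme()] for the shipped antimicrobial-peptide bins.
#' @export
bin_scheme <- function(bins, exclusion_threshold = 0) {
  need <- c("label", "lower", "upper", "lower_inclusive", "upper_inclusive")
  if (!is.data.frame(bins) || !all(need %in% names(bins)) ||
      nrow(bins) < 1L) {
    stop_config("bins must be a non-empty data frame with columns label, lower, upper, lower_inclusive, upper_inclusive")
  }
  bins <- bins[, need]
  bins$label <- as.character(bins$label)
  if (anyDuplicated(bins$label)) stop_config("bin labels must be unique")
  if (is.unsorted(rev(bins$lower), strictly = TRUE)) {
    stop_config("bins must be ordered by strictly decreasing lower bound")
  }
  if (any(bins$upper < bins$lower)) {
    stop_config("each bin needs lower <= upper")
  }
  scheme <- structure(list(bins = bins,
                           exclusion_threshold = exclusion_threshold),
                      class = "bin_scheme")
  check_bin_cover(scheme)
  scheme
}

# Disjointness and coverage of [exclusion_threshold, 100] are checked on a
# 0.01 grid (finer than the one-decimal resolution of the data) plus all
# interval endpoints.
check_bin_cover <- function(scheme) {
  lo <- scheme$exclusion_threshold
  grid <- unique(c(round(seq(lo * 100, 100 * 100) / 100, 2),
                   scheme$bins$lower, scheme$bins$upper))
  grid <- grid[grid >= lo & grid <= 100]
  hits <- bin_membership_matrix(grid, scheme)
  n_in <- rowSums(hits)
  if (any(n_in > 1L)) {
    stop_config(sprintf("bins overlap at value(s) near %s",
                        paste(utils::head(grid[n_in > 1L], 3),
                              collapse = ", ")))
  }
  if (any(n_in < 1L)) {
    stop_config(sprintf("bins leave value(s) near %s uncovered",
                        paste(utils::head(grid[n_in < 1L], 3),
                              collapse = ", ")))
  }
  invisible(TRUE)
}

bin_membership_matrix <- function(values, scheme) {
  b <- scheme$bins
  out <- matrix(FALSE, length(values), nrow(b))
  for (i in seq_len(nrow(b))) {
    lo_ok <- if (b$lower_inclusive[i]) values >= b$lower[i]
             else values > b$lower[i]
    hi_ok <- if (b$upper_inclusive[i]) values <= b$upper[i]
             else values < b$upper[i]
    out[, i] <- lo_ok & hi_ok
  }
  out
}

# Assign each value to its bin label; NA for excluded values.
assign_bins <- function(values, scheme) {
  lab <- rep(NA_character_, length(values))
  keep <- values >= scheme$exclusion_threshold
  if (any(keep)) {
    m <- bin_membership_matrix(values[keep], scheme)
    idx <- max.col(m, ties.method = "first")
    idx[rowSums(m) == 0L] <- NA_integer_
    lab[keep] <- scheme$bins$label[idx]
  }
  lab
}

#' The shipped antimicrobial-peptide percent-match bins
#'
#' Six bins over the percent match of a predicted peptide to known
#' sequences: exactly 100, then 99.9--95.0, 94.9--90.0, 89.9--80.0,
#' 79.9--70 and 69.9--51.0, implemented as half-open intervals
#' `[lower, upper)` with an exact top bin so every retained value is
#' decidable. Anything below 51.0 (i.e. 50.9 and lower) is excluded.
#'
#' @return A [bin_scheme()].
#' @export
amp_bin_scheme <- function() {
  dash <- "\u2013"
  bin_scheme(
    data.frame(
      label = c("100",
                paste0("99.9", dash, "95.0"),
                paste0("94.9", dash, "90.0"),
                paste0("89.9", dash, "80.0"),
                paste0("79.9", dash, "70"),
                paste0("69.9", dash, "51.0")),
      lower = c(100, 95, 90, 80, 70, 51),
      upper = c(100, 100, 95, 90, 80, 70),
      lower_inclusive = TRUE,
      upper_inclusive = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE
    ),
    exclusion_threshold = 51.0
  )
}

#' Define a keyword annotation scheme
#'
#' Ordered categories of case-insensitive substring patterns applied to
#' free-text annotations; the first matching category wins, unmatched
#' annotations fall back to `fallback_label`.
#'
#' @param categories Named list: category label -> character vector of
#'   substring patterns (non-empty).
#' @param fallback_label Label for unmatched annotations.
#' @return An object of class `keyword_scheme`.
#' @export
keyword_scheme <- function(categories, fallback_label = "other") {
  if (!is.list(categories) || length(categories) < 1L ||
      is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop_config("categories must be a named list of pattern vectors")
  }
  if (anyDuplicated(names(categories))) {
    stop_config("category labels must be unique")
  }
  if (any(vapply(categories, length, integer(1)) < 1L)) {
    stop_config("every category needs at least one pattern")
  }
  structure(list(categories = lapply(categories, as.character),
                 fallback_label = as.character(fallback_label)),
            class = "keyword_scheme")
}

#' The shipped annotation keyword categories
#'
#' Functional-annotation categories commonly dominating NCBI descriptions
#' of predicted antimicrobial peptides in filamentous fungi: hypothetical
#' proteins, glycoside hydrolases, cytochrome P450s, non-ribosomal peptide
#' synthetases, ABC transporters, glycosyltransferases and peptidases.
#'
#' @return A [keyword_scheme()].
#' @export
default_keyword_scheme <- function() {
  keyword_scheme(
    list(
      "hypothetical protein" = "hypothetical protein",
      "glycoside hydrolase family" = "glycoside hydrolase",
      "cytochrome P450 family" = c("cytochrome p450", "p450"),
      "non-ribosomal peptide synthetase" =
        c("non-ribosomal peptide synthetase", "nonribosomal peptide",
          "nrps"),
      "ABC transporter" = "abc transporter",
      "glycosyltransferase" = "glycosyltransferase",
      "peptidase" = "peptidase"
    ),
    fallback_label = "other"
  )
}

#' Read bin and keyword schemes from a YAML config file
#'
#' The YAML layout mirrors the shipped default at
#' `system.file("extdata", "default_config.yaml", package = "bgcrank")`:
#' a `bins` block (list of label/lower/upper/lower_inclusive/
#' upper_inclusive plus `exclusion_threshold`), a `keywords` block
#' (`categories` mapping label -> patterns and `fallback_label`), and an
#' optional `pagerank` block (`damping`, `tolerance`, `max_iterations`).
#'
#' @param path Path to a YAML file.
#' @return List with elements `bin_scheme`, `keyword_scheme`,
#'   `pagerank_params`.
#' @export
read_scheme_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  out <- list(bin_scheme = amp_bin_scheme(),
              keyword_scheme = default_keyword_scheme(),
              pagerank_params = pagerank_params())
  if (!is.null(cfg$bins)) {
    b <- do.call(rbind, lapply(cfg$bins$intervals, function(x) {
      data.frame(label = as.character(x$label), lower = x$lower,
                 upper = x$upper,
                 lower_inclusive = isTRUE(x$lower_inclusive),
                 upper_inclusive = isTRUE(x$upper_inclusive),
                 stringsAsFactors = FALSE)
    }))
    out$bin_scheme <- bin_scheme(b, cfg$bins$exclusion_threshold %||% 0)
  }
  if (!is.null(cfg$keywords)) {
    out$keyword_scheme <- keyword_scheme(
      cfg$keywords$categories,
      cfg$keywords$fallback_label %||% "other")
  }
  if (!is.null(cfg$pagerank)) {
    p <- cfg$pagerank
    out$pagerank_params <- pagerank_params(
      damping = p$damping %||% 0.85,
      tolerance = p$tolerance %||% 1e-10,
      max_iterations = p$max_iterations %||% 1000L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
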