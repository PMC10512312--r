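#' Construct a species table
#'
#' The species table anchors every aggregation step: it assigns each genome
#' (one row per species/strain) to a taxonomic section, the unit over which
#' per-category counts are averaged before any graph is built.
#'
#' @param species_id Character vector of unique, non-empty species labels.
#' @param section Character vector of non-empty section labels (surrounding
#'   whitespace is trimmed; comparisons are case-sensitive).
#' @param strain Optional character vector of free-text strain labels.
#' @return A `data.frame` of class `species_table` with columns
#'   `species_id`, `section`, `strain`.
#' @examples
#' species_table(c("T_sp1", "T_sp2"), c("Harzianum", "Harzianum"))
#' @export
species_table <- function(species_id, section, strain = "") {
  df <- data.frame(
    species_id = trimws(as.character(species_id)),
    section = trimws(as.character(section)),
    strain = rep_len(as.character(strain), length(species_id)),
    stringsAsFactors = FALSE
  )
  validate_species_table(df)
}

validate_species_table <- function(df) {
  need <- c("species_id", "section")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_format(sprintf("species table is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  if (!"strain" %in% names(df)) df$strain <- ""
  df$species_id <- trimws(as.character(df$species_id))
  df$section <- trimws(as.character(df$section))
  df$strain <- as.character(df$strain)
  if (nrow(df) > 0L) {
    if (any(!nzchar(df$species_id))) {
      stop_validation("species table has empty species_id value(s)")
    }
    dup <- unique(df$species_id[duplicated(df$species_id)])
    if (length(dup) > 0L) {
      stop_validation(sprintf("duplicated species_id: %s",
                              paste(dup, collapse = ", ")),
                      duplicates = dup)
    }
    if (any(!nzchar(df$section))) {
      bad <- df$species_id[!nzchar(df$section)]
      stop_validation(sprintf("empty section label for species: %s",
                              paste(bad, collapse = ", ")))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("species_table", "data.frame")
  df[, c("species_id", "section", "strain")]
}

#' Construct a count table
#'
#' Long-format per-species counts over named feature categories, e.g. the
#' number of predicted backbone enzymes of each class in each genome.
#'
#' @param species_id Character vector of species labels.
#' @param category Character vector of feature-category labels.
#' @param count Non-negative integer counts; `(species_id, category)` pairs
#'   must be unique.
#' @return A `data.frame` of class `count_table` with columns `species_id`,
#'   `category`, `count`.
#' @examples
#' count_table(c("sp1", "sp1"), c("T1PKS", "NRPS"), c(7L, 12L))
#' @export
count_table <- function(species_id, category, count) {
  df <- data.frame(
    species_id = trimws(as.character(species_id)),
    category = trimws(as.character(category)),
    count = count,
    stringsAsFactors = FALSE
  )
  validate_count_table(df)
}

validate_count_table <- function(df) {
  need <- c("species_id", "category", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_format(sprintf("count table is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  df$species_id <- trimws(as.character(df$species_id))
  df$category <- trimws(as.character(df$category))
  if (nrow(df) > 0L) {
    cnt <- suppressWarnings(as.numeric(df$count))
    bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
    if (length(bad) > 0L) {
      stop_validation(sprintf(
        "count must be a non-negative integer; offending row(s): %s",
        paste(bad, collapse = ", ")), rows = bad)
    }
    df$count <- as.integer(cnt)
    key <- paste(df$species_id, df$category, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop_validation(sprintf("duplicated (species_id, category) pair(s): %s",
                              paste(gsub("\r", " / ", dup), collapse = "; ")))
    }
    if (any(!nzchar(df$species_id))) {
      stop_validation("count table has empty species_id value(s)")
    }
  } else {
    df$count <- integer(0)
  }
  rownames(df) <- NULL
  class(df) <- c("count_table", "data.frame")
  df[, need]
}

#' Construct a hit table
#'
#' One row per predicted feature hit (a putative metabolite matched against
#' known clusters, or a predicted antimicrobial peptide), carrying the
#' percent sequence match on which all binning rules operate and an optional
#' free-text annotation.
#'
#' @param species_id Character vector of species labels (non-empty).
#' @param feature_name Character vector of feature labels (metabolite name,
#'   peptide accession, ...).
#' @param match_percent Numeric in `[0, 100]`.
#' @param annotation Optional character vector; may be empty strings.
#' @return A `data.frame` of class `hit_table`.
#' @examples
#' hit_table("sp1", "clavaric acid", 82.4, "triterpenoid synthase")
#' @export
hit_table <- function(species_id, feature_name, match_percent,
                      annotation = "") {
  df <- data.frame(
    species_id = trimws(as.character(species_id)),
    feature_name = as.character(feature_name),
    match_percent = match_percent,
    annotation = rep_len(as.character(annotation), length(species_id)),
    stringsAsFactors = FALSE
  )
  validate_hit_table(df)
}

validate_hit_table <- function(df) {
  need <- c("species_id", "feature_name", "match_percent", "annotation")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_format(sprintf("hit table is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  df$species_id <- trimws(as.character(df$species_id))
  df$feature_name <- as.character(df$feature_name)
  df$annotation <- as.character(df$annotation)
  if (nrow(df) > 0L) {
    mp <- df$match_percent
    if (is.character(mp)) {
      parsed <- suppressWarnings(as.numeric(mp))
      if (anyNA(parsed) && !all(is.na(mp[is.na(parsed)]))) {
        bad <- which(is.na(parsed) & !is.na(mp))
        stop_format(sprintf("unparseable match_percent in row(s): %s",
                            paste(bad, collapse = ", ")), rows = bad)
      }
      mp <- parsed
    }
    mp <- as.numeric(mp)
    bad <- which(is.na(mp) | mp < 0 | mp > 100)
    if (length(bad) > 0L) {
      stop_validation(sprintf(
        "match_percent must lie in [0, 100]; offending row(s): %s",
        paste(bad, collapse = ", ")), rows = bad)
    }
    df$match_percent <- mp
    if (any(!nzchar(df$species_id))) {
      stop_validation("hit table has empty species_id value(s)")
    }
  } else {
    df$match_percent <- numeric(0)
  }
  df$annotation[is.na(df$annotation)] <- ""
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df[, need]
}

empty_count_table <- function() {
  count_table(character(0), character(0), integer(0))
}

empty_hit_table <- function() {
  hit_table(character(0), character(0), numeric(0), character(0))
}
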