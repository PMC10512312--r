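# Aggregation rules: similarity-class splitting, percent-match binning with
# exclusion, keyword categorization, per-genome totals and per-section
# average matrices.

tally_counts <- function(species_id, category) {
  if (length(species_id) == 0L) return(empty_count_table())
  tab <- table(species_id = species_id, category = category)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, , drop = FALSE]
  df <- df[order(df$species_id, df$category), , drop = FALSE]
  count_table(df$species_id, df$category, as.integer(df$Freq))
}

#' Split metabolite hits at a percent-match threshold
#'
#' Putative metabolite hits are divided into a high-similarity class
#' (`match_percent >= threshold`, default 75, inclusive) and the low class
#' (`< threshold`), and each class is tallied per species and feature name.
#' Total counts are conserved.
#'
#' @param hits A [hit_table()].
#' @param threshold Percent-match split point; hits at exactly the
#'   threshold fall in the high class.
#' @return List with [count_table()] elements `high` and `low`.
#' @examples
#' h <- hit_table(c("sp1", "sp1"), c("enniatin", "depudecin"), c(75, 74.9))
#' split_by_threshold(h)$high
#' @export
split_by_threshold <- function(hits, threshold = 75) {
  hits <- validate_hit_table(hits)
  hi <- hits$match_percent >= threshold
  list(
    high = tally_counts(hits$species_id[hi], hits$feature_name[hi]),
    low = tally_counts(hits$species_id[!hi], hits$feature_name[!hi])
  )
}

#' Bin peptide hits by percent match
#'
#' Assigns each hit to exactly one bin of `scheme` (or excludes it when its
#' match percent falls strictly below the scheme's exclusion threshold) and
#' tallies hits per species both per bin label and per (bin, feature).
#'
#' @param hits A [hit_table()].
#' @param scheme A [bin_scheme()]; defaults to the shipped peptide bins
#'   ([amp_bin_scheme()]).
#' @return List with elements `counts` (a [count_table()] of hits per
#'   species and bin label), `per_bin` (named list of per-(species,
#'   feature) count tables, one per bin), `dropped` (number of excluded
#'   hits) and `dropped_by_species` (named integer vector).
#' @export
bin_amp_matches <- function(hits, scheme = amp_bin_scheme()) {
  hits <- validate_hit_table(hits)
  if (!inherits(scheme, "bin_scheme")) {
    stop_config("scheme must be a bin_scheme object")
  }
  lab <- assign_bins(hits$match_percent, scheme)
  keep <- !is.na(lab)
  dropped_tab <- table(hits$species_id[!keep])
  per_bin <- lapply(stats::setNames(nm = scheme$bins$label), function(bl) {
    sel <- keep & lab == bl
    tally_counts(hits$species_id[sel], hits$feature_name[sel])
  })
  list(
    counts = tally_counts(hits$species_id[keep], lab[keep]),
    per_bin = per_bin,
    dropped = sum(!keep),
    dropped_by_species = stats::setNames(as.integer(dropped_tab),
                                         names(dropped_tab))
  )
}

#' Categorize hits by annotation keywords
#'
#' Each hit's free-text annotation is matched case-insensitively against
#' the ordered substring patterns of `scheme`; the first matching category
#' wins and unmatched (or empty) annotations fall back to the scheme's
#' fallback label. Counts are conserved: the output grand total equals the
#' number of hits.
#'
#' @param hits A [hit_table()].
#' @param scheme A [keyword_scheme()].
#' @return A [count_table()] over annotation categories.
#' @export
bin_keywords <- function(hits, scheme = default_keyword_scheme()) {
  hits <- validate_hit_table(hits)
  if (!inherits(scheme, "keyword_scheme")) {
    stop_config("scheme must be a keyword_scheme object")
  }
  ann <- tolower(hits$annotation)
  cat <- rep(scheme$fallback_label, nrow(hits))
  unassigned <- rep(TRUE, nrow(hits))
  for (lbl in names(scheme$categories)) {
    pats <- tolower(scheme$categories[[lbl]])
    m <- rep(FALSE, nrow(hits))
    for (p in pats) m <- m | grepl(p, ann, fixed = TRUE)
    sel <- unassigned & m
    cat[sel] <- lbl
    unassigned <- unassigned & !sel
  }
  tally_counts(hits$species_id, cat)
}

#' Per-species fraction of hypothetical proteins
#'
#' For each species, the share of keyword-categorized hits labelled as
#' hypothetical proteins. Species with no hits at all are reported as
#' absent, not as zero.
#'
#' @param keyword_counts A [count_table()] over annotation categories,
#'   typically built from hits restricted to the high-match classes.
#' @param hypothetical_label The category label counted in the numerator.
#' @return Named numeric vector in `[0, 1]`, one entry per species with a
#'   positive total.
#' @export
hypothetical_fraction <- function(keyword_counts,
                                  hypothetical_label = "hypothetical protein") {
  kc <- validate_count_table(keyword_counts)
  if (nrow(kc) == 0L) return(stats::setNames(numeric(0), character(0)))
  tot <- tapply(kc$count, kc$species_id, sum)
  hyp <- tapply(kc$count * (kc$category == hypothetical_label),
                kc$species_id, sum)
  keep <- tot > 0
  stats::setNames(as.numeric(hyp[keep] / tot[keep]), names(tot)[keep])
}

#' Top-k annotation categories per species
#'
#' Ranks categories by descending count within each species, breaking ties
#' lexicographically by label, and returns the top `k`. The fallback
#' ("other") category is excluded by default; named categories (including
#' hypothetical proteins) can additionally be excluded via
#' `exclude_labels`.
#'
#' @param keyword_counts A [count_table()] over annotation categories.
#' @param k Number of categories to keep per species.
#' @param exclude_fallback Drop the fallback category before ranking.
#' @param fallback_label The fallback category's label.
#' @param exclude_labels Additional category labels to drop.
#' @return Named list of character vectors (length at most `k`).
#' @export
top_k_annotations <- function(keyword_counts, k = 5,
                              exclude_fallback = TRUE,
                              fallback_label = "other",
                              exclude_labels = character(0)) {
  if (k < 1) stop_config("k must be >= 1")
  kc <- validate_count_table(keyword_counts)
  drop <- exclude_labels
  if (exclude_fallback) drop <- c(drop, fallback_label)
  kc <- kc[!kc$category %in% drop, , drop = FALSE]
  sp <- unique(kc$species_id)
  out <- lapply(stats::setNames(nm = sp), function(s) {
    sub <- kc[kc$species_id == s, , drop = FALSE]
    sub <- sub[order(-sub$count, sub$category), , drop = FALSE]
    utils::head(sub$category, k)
  })
  out
}

#' Per-genome total counts
#'
#' Sums counts over all categories for each species. When a species table
#' is supplied, species with no rows in the count table are reported with
#' total 0.
#'
#' @param counts A [count_table()].
#' @param species Optional [species_table()] fixing the species set and
#'   order.
#' @return Named numeric vector of totals.
#' @export
genome_totals <- function(counts, species = NULL) {
  counts <- validate_count_table(counts)
  tot <- tapply(counts$count, counts$species_id, sum)
  tot <- stats::setNames(as.numeric(tot), names(tot))
  if (is.null(species)) return(tot)
  species <- validate_species_table(species)
  out <- stats::setNames(numeric(nrow(species)), species$species_id)
  out[names(tot)] <- tot
  out
}

#' Average counts per species within each taxonomic section
#'
#' Builds the section-by-category matrix of mean counts that supplies the
#' edge weights of the section graph: cell (s, c) is the summed count over
#' all species assigned to section s, divided by the number of species in
#' that section. Species without a recorded count for a category
#' contribute zero to the numerator but still count in the denominator.
#'
#' @param counts A [count_table()].
#' @param species A [species_table()] assigning every counted species to a
#'   section; sections keep their order of first appearance.
#' @return A numeric matrix of class `section_matrix` (rows = sections,
#'   columns = categories, sorted) with a `species_counts` attribute
#'   giving each section's denominator.
#' @export
section_average <- function(counts, species) {
  counts <- validate_count_table(counts)
  species <- validate_species_table(species)
  if (nrow(species) == 0L) {
    stop_config("species table is empty: every section needs at least one species")
  }
  check_species_known(counts$species_id, species, "count table", TRUE)
  sections <- unique(species$section)
  n_per <- table(factor(species$section, levels = sections))
  if (any(n_per == 0L)) {
    stop_config("section with zero species")  # unreachable by construction
  }
  categories <- sort(unique(counts$category))
  m <- matrix(0, nrow = length(sections), ncol = length(categories),
              dimnames = list(sections, categories))
  if (nrow(counts) > 0L) {
    sec_of <- stats::setNames(species$section, species$species_id)
    sums <- tapply(counts$count,
                   list(factor(sec_of[counts$species_id], levels = sections),
                        factor(counts$category, levels = categories)),
                   sum)
    sums[is.na(sums)] <- 0
    m <- sums / as.numeric(n_per)
    dimnames(m) <- list(sections, categories)
  }
  structure(m, species_counts = stats::setNames(as.integer(n_per), sections),
            class = c("section_matrix", class(m)))
}

#' Write a section-average matrix as TSV
#'
#' @param matrix A `section_matrix` from [section_average()].
#' @param path Output path; rows are sections, columns categories.
#' @return The path, invisibly.
#' @export
write_section_matrix <- function(matrix, path) {
  df <- data.frame(section = rownames(matrix),
                   as.data.frame(unclass(matrix), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_canonical(df, path)
}
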