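default_categories <- function() {
  c("T1PKS", "NRPS", "NRPS-like", "terpene", "T3PKS",
    "indole", "betalactone", "siderophore", "RiPP", "PKS-NRPS hybrid")
}

default_sections <- function(n) {
  base <- c("Harzianum", "Trichoderma", "Longibrachiatum",
            "Brevicompactum", "Pachybasium")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("Section%02d", seq_len(n - length(base)) +
                         length(base)))
}

default_keyword_pool <- function() {
  data.frame(
    annotation = c("hypothetical protein",
                   "glycoside hydrolase family protein",
                   "cytochrome P450 family protein",
                   "non-ribosomal peptide synthetase",
                   "ABC transporter",
                   "glycosyltransferase",
                   "peptidase"),
    weight = c(0.50, 0.10, 0.10, 0.08, 0.08, 0.07, 0.07),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic predictor output
#'
#' Defines the generative model used in place of genome-scale predictor
#' runs: per-(species, category) counts are independent Poisson draws with
#' rate `base_rate`, multiplied by `effect_multiplier` for species in the
#' planted section; each counted event becomes a hit with a percent match
#' drawn from `match_percent_distribution` (rounded to one decimal place)
#' and an annotation drawn from `keyword_pool`.
#'
#' Defaults emulate the shape of a genus-wide fungal genome screen: five
#' taxonomic sections of five genomes each, ten backbone-enzyme categories,
#' and around four predictions per genome per category.
#'
#' @param n_sections Positive integer number of sections.
#' @param species_per_section Positive integer genomes per section.
#' @param categories Character vector of feature-category labels.
#' @param base_rate Non-negative expected count per species per category.
#' @param planted_section Section label receiving the enriched rate, or
#'   `NULL` for no planted signal.
#' @param effect_multiplier Multiplier (>= 1) on the planted section's rate.
#' @param match_percent_distribution List naming the percent-match law:
#'   `list(kind = "uniform", min = 0, max = 100)` (default) or
#'   `list(kind = "beta", shape1, shape2)` rescaled to `[0, 100]`.
#' @param keyword_pool Data frame with columns `annotation` and `weight`
#'   (non-negative, positive total) giving the annotation mixture.
#' @param sections Optional explicit section labels (length `n_sections`).
#' @param seed Integer master seed; each generated table uses its own
#'   stream derived from it by a fixed offset.
#' @return A list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_sections = 2, species_per_section = 3,
#'                          seed = 42)
#' @export
simulation_config <- function(n_sections = 5,
                              species_per_section = 5,
                              categories = default_categories(),
                              base_rate = 4,
                              planted_section = NULL,
                              effect_multiplier = 1,
                              match_percent_distribution =
                                list(kind = "uniform", min = 0, max = 100),
                              keyword_pool = default_keyword_pool(),
                              sections = NULL,
                              seed = 1L) {
  chk_int <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
      stop_config(sprintf("%s must be a positive integer (got %s)",
                          nm, deparse(x)), field = nm)
    }
    as.integer(x)
  }
  n_sections <- chk_int(n_sections, "n_sections")
  species_per_section <- chk_int(species_per_section, "species_per_section")
  if (length(categories) < 1L || anyDuplicated(categories)) {
    stop_config("categories must be a non-empty vector of unique labels",
                field = "categories")
  }
  if (length(base_rate) != 1L || is.na(base_rate) || base_rate < 0) {
    stop_config("base_rate must be a non-negative number",
                field = "base_rate")
  }
  if (length(effect_multiplier) != 1L || is.na(effect_multiplier) ||
      effect_multiplier < 1) {
    stop_config("effect_multiplier must be >= 1",
                field = "effect_multiplier")
  }
  if (!is.list(match_percent_distribution) ||
      is.null(match_percent_distribution$kind) ||
      !match_percent_distribution$kind %in% c("uniform", "beta")) {
    stop_config("match_percent_distribution must name kind 'uniform' or 'beta'",
                field = "match_percent_distribution")
  }
  if (!is.data.frame(keyword_pool) ||
      !all(c("annotation", "weight") %in% names(keyword_pool))) {
    stop_config("keyword_pool must be a data frame with columns annotation, weight",
                field = "keyword_pool")
  }
  if (nrow(keyword_pool) > 0L) {
    w <- keyword_pool$weight
    if (any(is.na(w)) || any(w < 0) || sum(w) <= 0) {
      stop_config("keyword_pool weights must be non-negative with a positive sum",
                  field = "keyword_pool")
    }
  }
  if (is.null(sections)) {
    sections <- default_sections(n_sections)
  } else if (length(sections) != n_sections || anyDuplicated(sections)) {
    stop_config("sections must be n_sections unique labels",
                field = "sections")
  }
  if (length(seed) != 1L || is.na(seed) || seed != floor(seed)) {
    stop_config("seed must be a single integer", field = "seed")
  }
  structure(list(
    n_sections = n_sections,
    species_per_section = species_per_section,
    categories = as.character(categories),
    base_rate = as.numeric(base_rate),
    planted_section = planted_section,
    effect_multiplier = as.numeric(effect_multiplier),
    match_percent_distribution = match_percent_distribution,
    keyword_pool = keyword_pool,
    sections = as.character(sections),
    seed = as.numeric(seed)
  ), class = "simulation_config")
}

# One pseudorandom stream per table: fixed offsets from the master seed so
# adding a table never perturbs another table's draws.
stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' Generate a synthetic species-to-section table
#'
#' @param config A [simulation_config()].
#' @return A [species_table()] with
#'   `n_sections * species_per_section` rows, each species assigned to
#'   exactly one section.
#' @export
generate_species_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sec <- rep(config$sections, each = config$species_per_section)
  idx <- rep(seq_len(config$species_per_section), config$n_sections)
  species_table(
    species_id = sprintf("%s_sp%02d", gsub("[^A-Za-z0-9]+", "", sec), idx),
    section = sec,
    strain = sprintf("SYN%04d", seq_along(sec))
  )
}

#' Generate synthetic per-species category counts
#'
#' Each `(species, category)` count is an independent Poisson draw with
#' rate `base_rate`, multiplied by `effect_multiplier` for species in
#' `planted_section`.
#'
#' @param species A [species_table()].
#' @param config A [simulation_config()].
#' @return A [count_table()] with one row per species and category.
#' @export
generate_count_table <- function(species, config) {
  stopifnot(inherits(config, "simulation_config"))
  species <- validate_species_table(species)
  planted <- config$planted_section
  if (!is.null(planted) && !planted %in% species$section) {
    stop_config(sprintf("planted_section '%s' is not a section of the species table",
                        planted), field = "planted_section")
  }
  n_cat <- length(config$categories)
  lambda <- rep(config$base_rate, nrow(species))
  if (!is.null(planted)) {
    lambda[species$section == planted] <-
      config$base_rate * config$effect_multiplier
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, 1L))
  counts <- stats::rpois(nrow(species) * n_cat,
                         lambda = rep(lambda, each = n_cat))
  count_table(
    species_id = rep(species$species_id, each = n_cat),
    category = rep(config$categories, nrow(species)),
    count = counts
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

draw_match_percent <- function(n, dist) {
  x <- switch(dist$kind,
    uniform = stats::runif(n,
                           min = if (is.null(dist$min)) 0 else dist$min,
                           max = if (is.null(dist$max)) 100 else dist$max),
    beta = 100 * stats::rbeta(n, dist$shape1, dist$shape2)
  )
  # one decimal place, matching the resolution of the binning rules
  round(pmin(pmax(x, 0), 100), 1)
}

#' Generate synthetic feature hits from a count table
#'
#' Emits one hit row per counted event: for each `(species, category)` row
#' of `counts` with count `k`, `k` hit rows are produced with
#' `feature_name` equal to the category, a percent match drawn from the
#' configured distribution (one decimal place), and an annotation drawn
#' from the keyword pool.
#'
#' @param species A [species_table()].
#' @param counts A [count_table()] generated for the same species.
#' @param config A [simulation_config()].
#' @return A [hit_table()] with `sum(counts$count)` rows.
#' @export
generate_hit_table <- function(species, counts, config) {
  stopifnot(inherits(config, "simulation_config"))
  species <- validate_species_table(species)
  counts <- validate_count_table(counts)
  check_species_known(counts$species_id, species, "count table", TRUE)
  total <- sum(counts$count)
  if (total == 0L) return(empty_hit_table())
  pool <- config$keyword_pool
  if (nrow(pool) == 0L) {
    stop_config("keyword_pool is empty but annotations are requested",
                field = "keyword_pool")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(config$seed, 2L))
  idx <- rep(seq_len(nrow(counts)), counts$count)
  hit_table(
    species_id = counts$species_id[idx],
    feature_name = counts$category[idx],
    match_percent = draw_match_percent(total,
                                       config$match_percent_distribution),
    annotation = sample(pool$annotation, total, replace = TRUE,
                        prob = pool$weight)
  )
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes `taxonomy.tsv`, `counts.tsv` and `hits.tsv` in the canonical TSV
#' dialects; re-reading them with [read_taxonomy()], [read_counts()] and
#' [read_hits()] reproduces the in-memory tables exactly.
#'
#' @param dir_path Output directory (created if missing).
#' @param species A [species_table()].
#' @param counts A [count_table()].
#' @param hits A [hit_table()].
#' @return Character vector of the three written paths (the manifest).
#' @export
write_fixture_bundle <- function(dir_path, species, counts, hits) {
  if (!dir.exists(dir_path)) {
    ok <- dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create directory: %s", dir_path))
  }
  paths <- file.path(dir_path, c("taxonomy.tsv", "counts.tsv", "hits.tsv"))
  write_taxonomy(species, paths[1L])
  write_counts(counts, paths[2L])
  write_hits(hits, paths[3L])
  paths
}

#' Generate a full synthetic fixture bundle in memory
#'
#' Convenience wrapper chaining [generate_species_table()],
#' [generate_count_table()] and [generate_hit_table()].
#'
#' @param config A [simulation_config()].
#' @return A list with elements `species`, `counts`, `hits`.
#' @export
simulate_bundle <- function(config) {
  species <- generate_species_table(config)
  counts <- generate_count_table(species, config)
  hits <- generate_hit_table(species, counts, config)
  list(species = species, counts = counts, hits = hits)
}
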