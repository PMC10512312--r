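RANK_MEASURES <- c("strength_out", "strength_in", "broadcast", "receive")

#' Rank nodes by a centrality measure
#'
#' Within each node class, nodes are ranked by descending raw score, ties
#' broken by ascending label, yielding ranks 1..k with no gaps. Normalized
#' scores are carried through (for the strength measures they are min-max
#' normalized within the class here).
#'
#' @param result A `centrality_result` from [broadcast_receive()].
#' @param measure One of `"strength_out"`, `"strength_in"`, `"broadcast"`,
#'   `"receive"`.
#' @return Data frame of class `rank_table` with columns `node`, `class`,
#'   `measure`, `raw`, `normalized`, `rank`.
#' @export
rank_nodes <- function(result, measure = "broadcast") {
  if (!measure %in% RANK_MEASURES) {
    stop_config(sprintf("unknown measure '%s'; valid measures: %s",
                        measure, paste(RANK_MEASURES, collapse = ", ")))
  }
  raw <- switch(measure,
                strength_out = result$out_strength,
                strength_in = result$in_strength,
                broadcast = result$broadcast_raw,
                receive = result$receive_raw)
  norm <- switch(measure,
                 broadcast = result$broadcast_norm,
                 receive = result$receive_norm,
                 NULL)
  df <- data.frame(node = result$node, class = result$class,
                   measure = measure, raw = raw,
                   normalized = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(norm)) df$normalized <- norm
  out <- list()
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, , drop = FALSE]
    if (is.null(norm)) {
      sub$normalized <- suppressWarnings(minmax_normalize(
        stats::setNames(sub$raw, sub$node)))
    }
    ord <- order(-sub$raw, sub$node)
    sub <- sub[ord, , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    out[[cl]] <- sub
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("rank_table", "data.frame")
  df
}

ANALYSES <- c("backbone", "metabolites_high", "metabolites_low",
              "amp_bins", "amp_keywords")

#' Pipeline configuration
#'
#' Bundles the input paths, the analysis recipe and all tunables of a full
#' run. Five shipped recipes cover the study design: `backbone` ranks
#' sections against backbone-enzyme categories from the count table;
#' `metabolites_high` / `metabolites_low` rank against putative-metabolite
#' hits at or above / below the similarity threshold; `amp_bins` ranks
#' against peptide percent-match bins; `amp_keywords` against annotation
#' keyword categories.
#'
#' @param taxonomy,counts,hits Paths to the canonical TSV inputs (`hits`
#'   may be `NULL` for the `backbone` recipe, `counts` may be `NULL` for
#'   hit-based recipes).
#' @param analysis One of the five recipe names.
#' @param out_dir Output directory for the written tables.
#' @param bin_scheme A [bin_scheme()] for `amp_bins`.
#' @param keyword_scheme A [keyword_scheme()] for `amp_keywords`.
#' @param pagerank A [pagerank_params()].
#' @param threshold Similarity split point for the metabolite recipes.
#' @param restrict_keywords_high_match For `amp_keywords`: restrict hits
#'   to those with `match_percent >=` `high_match_cutoff` before keyword
#'   categorization (default `TRUE`).
#' @param high_match_cutoff Cutoff used by the restriction (default 95).
#' @param binarize Ignore weights in the PageRank step.
#' @param strict Unknown species in counts/hits are an error (default) or
#'   a warning.
#' @param log_level `"info"` to report stage progress and dropped-record
#'   counts, `"quiet"` to suppress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(taxonomy, counts = NULL, hits = NULL,
                            analysis = "backbone",
                            out_dir = tempfile("bgcrank_run_"),
                            bin_scheme = amp_bin_scheme(),
                            keyword_scheme = default_keyword_scheme(),
                            pagerank = pagerank_params(),
                            threshold = 75,
                            restrict_keywords_high_match = TRUE,
                            high_match_cutoff = 95,
                            binarize = FALSE,
                            strict = TRUE,
                            log_level = c("info", "quiet")) {
  if (!analysis %in% ANALYSES) {
    stop_config(sprintf("unknown analysis '%s'; valid recipes: %s",
                        analysis, paste(ANALYSES, collapse = ", ")))
  }
  needs_hits <- analysis != "backbone"
  if (needs_hits && is.null(hits)) {
    stop_config(sprintf("analysis '%s' requires a hits file", analysis))
  }
  if (!needs_hits && is.null(counts)) {
    stop_config("analysis 'backbone' requires a counts file")
  }
  structure(list(
    taxonomy = taxonomy, counts = counts, hits = hits,
    analysis = analysis, out_dir = out_dir,
    bin_scheme = bin_scheme, keyword_scheme = keyword_scheme,
    pagerank = pagerank, threshold = threshold,
    restrict_keywords_high_match = isTRUE(restrict_keywords_high_match),
    high_match_cutoff = high_match_cutoff,
    binarize = isTRUE(binarize), strict = isTRUE(strict),
    log_level = match.arg(log_level)
  ), class = "pipeline_config")
}

pipeline_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf(paste0("[bgcrank] ", fmt), ...))
  }
}

# Derive the analysis-specific count table (and dropped-record bookkeeping)
# from the inputs.
analysis_counts <- function(config, species) {
  dropped <- 0L
  counts <- switch(config$analysis,
    backbone = with_stage("read_counts",
      read_counts(config$counts, species, strict = config$strict)),
    metabolites_high = ,
    metabolites_low = {
      hits <- with_stage("read_hits",
        read_hits(config$hits, species, strict = config$strict))
      split <- with_stage("split_by_threshold",
        split_by_threshold(hits, config$threshold))
      if (config$analysis == "metabolites_high") split$high else split$low
    },
    amp_bins = {
      hits <- with_stage("read_hits",
        read_hits(config$hits, species, strict = config$strict))
      binned <- with_stage("bin_amp_matches",
        bin_amp_matches(hits, config$bin_scheme))
      dropped <- binned$dropped
      binned$counts
    },
    amp_keywords = {
      hits <- with_stage("read_hits",
        read_hits(config$hits, species, strict = config$strict))
      if (config$restrict_keywords_high_match) {
        n0 <- nrow(hits)
        hits <- hits[hits$match_percent >= config$high_match_cutoff, ,
                     drop = FALSE]
        dropped <- n0 - nrow(hits)
      }
      with_stage("bin_keywords", bin_keywords(hits, config$keyword_scheme))
    })
  list(counts = counts, dropped = dropped)
}

#' Run a full ranking pipeline
#'
#' Executes the selected recipe end to end: read and validate the inputs,
#' derive the analysis count table, average it per section, build the
#' weighted directed section graph, compute strengths and
#' broadcasting/receiving PageRank, rank the nodes on all four measures,
#' and write the section matrix, edge list, centrality table, rank table
#' and a JSON run manifest to the output directory. Runs are deterministic:
#' identical inputs and configuration produce byte-identical outputs. On
#' error, partially written outputs are removed and the failing stage is
#' named in the condition.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `bgcrank_run`: list with elements
#'   `analysis`, `matrix`, `graph`, `centrality`, `ranks`, `dropped`,
#'   `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    ok <- dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create out_dir: %s", config$out_dir))
  }
  files <- file.path(config$out_dir,
                     c("section_matrix.tsv", "edges.tsv", "centrality.tsv",
                       "ranks.tsv", "manifest.json"))
  names(files) <- c("section_matrix", "edges", "centrality", "ranks",
                    "manifest")
  on_error_cleanup <- function(e) {
    unlink(files[file.exists(files)])
    stop(e)
  }
  tryCatch({
    species <- with_stage("read_taxonomy", read_taxonomy(config$taxonomy))
    pipeline_log(config, "analysis '%s': %d species in %d section(s)",
                 config$analysis, nrow(species),
                 length(unique(species$section)))
    derived <- analysis_counts(config, species)
    if (derived$dropped > 0L) {
      pipeline_log(config, "dropped %d record(s) during filtering",
                   derived$dropped)
    }
    mat <- with_stage("section_average",
                      section_average(derived$counts, species))
    graph <- with_stage("build_graph", build_graph(mat))
    centrality <- with_stage("broadcast_receive",
                             broadcast_receive(graph, config$pagerank,
                                               binarize = config$binarize))
    ranks <- do.call(rbind, lapply(RANK_MEASURES, function(m)
      rank_nodes(centrality, m)))
    class(ranks) <- c("rank_table", "data.frame")
    with_stage("write_outputs", {
      write_section_matrix(mat, files[["section_matrix"]])
      write_edge_list(graph, files[["edges"]])
      write_centrality(centrality, files[["centrality"]])
      write_tsv_canonical(as.data.frame(ranks), files[["ranks"]])
      write_manifest(config, derived$dropped, files)
    })
    pipeline_log(config, "wrote %d file(s) to %s", length(files),
                 config$out_dir)
    structure(list(analysis = config$analysis, matrix = mat, graph = graph,
                   centrality = centrality, ranks = ranks,
                   dropped = derived$dropped, files = files),
              class = "bgcrank_run")
  }, error = on_error_cleanup)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, dropped, files) {
  manifest <- list(
    tool = "bgcrank",
    version = as.character(utils::packageVersion("bgcrank")),
    analysis = config$analysis,
    inputs = list(taxonomy = config$taxonomy,
                  counts = config$counts, hits = config$hits),
    config_hash = config_hash(config),
    pagerank = unclass(config$pagerank),
    binarize = config$binarize,
    dropped_records = dropped,
    outputs = as.list(basename(files[names(files) != "manifest"]))
  )
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(files[["manifest"]])
}

#' @export
print.bgcrank_run <- function(x, ...) {
  cat(sprintf("bgcrank run: analysis '%s'\n", x$analysis))
  cat(sprintf("  sections: %d, feature categories: %d, edges: %d\n",
              nrow(x$matrix), sum(x$graph$nodes$class == "feature"),
              nrow(x$graph$edges)))
  if (x$dropped > 0L) cat(sprintf("  dropped records: %d\n", x$dropped))
  sec <- x$ranks[x$ranks$measure == "broadcast" &
                   x$ranks$class == "section", , drop = FALSE]
  cat("  sections by broadcasting PageRank:\n")
  print.data.frame(sec[, c("rank", "node", "raw", "normalized")],
                   digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.bgcrank_run <- function(object, ...) {
  summary(object$centrality)
}
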