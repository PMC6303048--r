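#' Run the full barcode delimitation pipeline
#'
#' Orchestrates the end-to-end analysis: QC, K2P distances, base composition
#' and rank summaries, per-species barcode-gap reports, OTU clustering with
#' concordance classes, the NJ tree with bootstrap support, and the
#' delimitation rules. All outputs are written under `outdir` and returned;
#' `report.json` aggregates the summaries together with an echo of every
#' threshold and seed used, and is byte-identical across reruns with the
#' same inputs and configuration.
#'
#' Thresholds exposed here are in percent (matching field convention);
#' internal computation is in substitutions/site.
#'
#' @param fasta_path,metadata_path Input files (see [load_dataset()]).
#' @param outdir Output directory, created if needed.
#' @param qc A [qc_config()].
#' @param dist A [dist_config()].
#' @param cluster_threshold_pct Single-linkage OTU threshold in percent K2P
#'   distance (default 2.2).
#' @param bootstrap A [bootstrap_config()] (set `replicates = 0` via
#'   `run_tree = FALSE` is not supported; lower `replicates` to speed runs).
#' @param delim A [delim_config()].
#' @param use_external_clusters If `TRUE`, OTUs are taken from the metadata's
#'   `external_cluster_id` column (e.g. BOLD BINs) instead of internal
#'   single-linkage clustering.
#' @return Invisibly, a list of class `barcode_run` with elements
#'   `alignment`, `taxonomy`, `qc_report`, `dm`, `composition`, `ranks`,
#'   `species` (barcode-gap reports), `otus`, `otu_classes`, `profiles`,
#'   `tree`, `delimitation`, `counts`, `report` (the report.json payload)
#'   and `files`.
#' @export
run_pipeline <- function(fasta_path, metadata_path, outdir,
                         qc = qc_config(),
                         dist = dist_config(),
                         cluster_threshold_pct = 2.2,
                         bootstrap = bootstrap_config(),
                         delim = delim_config(),
                         use_external_clusters = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- load_dataset(fasta_path, metadata_path, qc)
  message("QC: ", nrow(ds$alignment), "/", nrow(ds$qc_report),
          " sequences passed")
  readr::write_tsv(ds$qc_report, file.path(outdir, "qc_report.tsv"))

  dm <- k2p_matrix(ds$alignment, dist)
  write_distance_matrix(dm, file.path(outdir, "distance_matrix.tsv"),
                        long_path = file.path(outdir, "distances_long.tsv"))

  composition <- base_composition(ds$alignment)
  readr::write_tsv(composition, file.path(outdir, "composition.tsv"))
  ranks <- rank_summaries(dm, ds$taxonomy)
  readr::write_tsv(ranks, file.path(outdir, "ranks.tsv"))
  species <- species_reports(dm, ds$taxonomy)
  readr::write_tsv(species, file.path(outdir, "summary.tsv"))

  otus <- if (use_external_clusters) {
    external_clusters(ds$taxonomy)
  } else {
    cluster_single_linkage(dm, threshold = cluster_threshold_pct / 100)
  }
  otu_classes <- classify_otus(otus, ds$taxonomy)
  profiles <- species_cluster_profile(otus, ds$taxonomy)
  write_otus(otus, ds$taxonomy, file.path(outdir, "otus.tsv"),
             profile_path = file.path(outdir, "species_profile.tsv"))

  tree <- bootstrap_support(ds$alignment, bootstrap, dist)
  write_newick(tree, file.path(outdir, "tree.nwk"))

  delimitation <- delimit_species(species, profiles, delim)
  readr::write_tsv(tidy(delimitation), file.path(outdir, "delimitation.tsv"))
  counts <- count_delimited(delimitation)

  report <- list(
    schema_version = "1.0",
    config = list(
      qc = unclass(qc),
      dist = unclass(dist),
      cluster_threshold_pct = cluster_threshold_pct,
      cluster_source = attr(otus, "source"),
      bootstrap_replicates = bootstrap$replicates,
      bootstrap_seed = bootstrap$seed,
      bootstrap_replicates_used = attr(tree, "n_replicates_used"),
      nnd_threshold_pct = delim$nnd_threshold_pct,
      intra_threshold_pct = delim$intra_threshold_pct
    ),
    n_input = nrow(ds$qc_report),
    n_passed_qc = nrow(ds$alignment),
    base_composition = as.list(composition),
    rank_summaries = ranks,
    otu_census = as.list(table(otu_classes$status)),
    n_otus = nrow(otu_classes),
    delimitation = list(
      n_species = counts$n_species,
      n_candidate = counts$n_candidate,
      n_cryptic = counts$n_cryptic,
      candidates = counts$candidates[[1]]
    )
  )
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  files <- file.path(outdir, c(
    "qc_report.tsv", "distance_matrix.tsv", "distances_long.tsv",
    "composition.tsv", "ranks.tsv", "summary.tsv", "otus.tsv",
    "species_profile.tsv", "tree.nwk", "delimitation.tsv", "report.json"
  ))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("Pipeline finished without producing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }

  invisible(structure(
    list(alignment = ds$alignment, taxonomy = ds$taxonomy,
         qc_report = ds$qc_report, dm = dm, composition = composition,
         ranks = ranks, species = species, otus = otus,
         otu_classes = otu_classes, profiles = profiles, tree = tree,
         delimitation = delimitation, counts = counts, report = report,
         files = files),
    class = "barcode_run"
  ))
}

#' @export
print.barcode_run <- function(x, ...) {
  cat("Barcode delimitation run\n")
  cat("  sequences: ", nrow(x$alignment), " (of ", nrow(x$qc_report),
      " input)\n", sep = "")
  cat("  OTUs: ", nrow(x$otu_classes), " (",
      paste(names(table(x$otu_classes$status)),
            table(x$otu_classes$status), sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  species: ", x$counts$n_species, "; candidates: ",
      x$counts$n_candidate, "; cryptic complexes: ", x$counts$n_cryptic,
      "\n", sep = "")
  invisible(x)
}

#' Tidy a pipeline run into the per-species table
#'
#' @param x A `barcode_run` object.
#' @param ... Unused.
#' @return The per-species delimitation tibble.
#' @method tidy barcode_run
#' @export
tidy.barcode_run <- function(x, ...) {
  tidy(x$delimitation)
}

#' One-row summary of a pipeline run
#'
#' @param x A `barcode_run` object.
#' @param ... Unused.
#' @return A one-row tibble with sequence, OTU and delimitation counts.
#' @method glance barcode_run
#' @export
glance.barcode_run <- function(x, ...) {
  census <- table(x$otu_classes$status)
  get0 <- function(s) if (s %in% names(census)) as.integer(census[[s]]) else 0L
  tibble::tibble(
    n_sequences = nrow(x$alignment),
    n_otus = nrow(x$otu_classes),
    n_concordant = get0("concordant"),
    n_discordant = get0("discordant"),
    n_singleton = get0("singleton"),
    n_species = x$counts$n_species,
    n_candidate = x$counts$n_candidate,
    n_cryptic = x$counts$n_cryptic
  )
}
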