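#' Single-linkage OTU clustering at a distance threshold
#'
#' Groups specimens into molecular OTUs as the connected components of the
#' graph joining every pair at K2P distance <= `threshold` (single-linkage
#' chaining). This is a documented, reproducible proxy for BOLD's BIN
#' clusters: 0.022 substitutions/site is the published RESL seed threshold,
#' but RESL's Markov re-assignment step is not reproduced, so BIN counts from
#' BOLD are not promised to match exactly. Undefined distances never merge
#' specimens. OTU IDs are the lexicographically smallest member ID, prefixed
#' `OTU_`, so output is deterministic for identical input.
#'
#' @param dm A `k2p_dist` object from [k2p_matrix()].
#' @param threshold Merge threshold in substitutions/site (default 0.022).
#' @return An object of class `otu_assignment`: a tibble with `specimen_id`
#'   and `otu_id`, carrying `threshold` and `source = "internal_single_linkage"`
#'   as attributes.
#' @export
cluster_single_linkage <- function(dm, threshold = 0.022) {
  if (length(dm$ids) == 0) stop("Empty distance matrix.", call. = FALSE)
  d <- dm$d
  n <- length(dm$ids)
  # union-find over specimens; NA distances are treated as above threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(upper.tri(d) & !is.na(d) & d <= threshold, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ri <- find(idx[k, 1])
    rj <- find(idx[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  comp <- vapply(seq_len(n), find, integer(1))
  otu_id <- vapply(split(seq_len(n), comp), function(members) {
    paste0("OTU_", min(dm$ids[members]))
  }, character(1))[as.character(comp)]
  out <- tibble::tibble(specimen_id = dm$ids, otu_id = unname(otu_id))
  structure(out, threshold = threshold, source = "internal_single_linkage",
            class = c("otu_assignment", class(out)))
}

#' Use externally assigned cluster IDs (e.g. BOLD BINs) as OTUs
#'
#' Pass-through mode: takes the `external_cluster_id` column of the taxonomy
#' table as the OTU partition, so concordance classification and delimitation
#' can run on true BOLD BINs downloaded with the data instead of the internal
#' single-linkage proxy.
#'
#' @param tax Taxonomy tibble with `specimen_id` and a non-missing
#'   `external_cluster_id` for every specimen.
#' @return An `otu_assignment` tibble with `source = "external"`.
#' @export
external_clusters <- function(tax) {
  if (!"external_cluster_id" %in% names(tax) ||
      any(is.na(tax$external_cluster_id) | !nzchar(tax$external_cluster_id))) {
    missing <- if ("external_cluster_id" %in% names(tax)) {
      tax$specimen_id[is.na(tax$external_cluster_id) |
                        !nzchar(tax$external_cluster_id)]
    } else tax$specimen_id
    stop("Missing external_cluster_id for: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...", call. = FALSE)
  }
  out <- tibble::tibble(specimen_id = tax$specimen_id,
                        otu_id = tax$external_cluster_id)
  structure(out, threshold = NA_real_, source = "external",
            class = c("otu_assignment", class(out)))
}

#' Classify OTUs against morphospecies labels
#'
#' Each OTU is labeled `singleton` (one specimen — takes precedence over
#' concordant), `discordant` (more than one species label among its members)
#' or `concordant` (several specimens, one species). Output is sorted by
#' `otu_id`.
#'
#' @param assignment An `otu_assignment` from [cluster_single_linkage()] or
#'   [external_clusters()].
#' @param tax Taxonomy tibble with `specimen_id` and `species`.
#' @return A tibble with `otu_id`, `n_specimens`, `n_species`, `species_set`
#'   (list column of labels) and `status`.
#' @export
classify_otus <- function(assignment, tax) {
  missing <- setdiff(assignment$specimen_id, tax$specimen_id)
  if (length(missing) > 0) {
    stop("Clustered specimens missing a species label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::mutate(
    assignment,
    species = tax$species[match(.data$specimen_id, tax$specimen_id)]
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$otu_id),
    n_specimens = dplyr::n(),
    n_species = dplyr::n_distinct(.data$species),
    species_set = list(sort(unique(.data$species))),
    .groups = "drop"
  )
  out <- dplyr::mutate(out, status = dplyr::case_when(
    n_specimens == 1 ~ "singleton",
    n_species > 1 ~ "discordant",
    TRUE ~ "concordant"
  ))
  dplyr::arrange(out, .data$otu_id)
}

#' Per-species OTU occupancy profile
#'
#' For each species, lists the OTUs its specimens occupy with their
#' concordance statuses, and whether none of those OTUs is discordant —
#' the species-level condition used by the delimitation rules.
#'
#' @inheritParams classify_otus
#' @return A tibble with `species`, `n_otus`, `otu_ids` (list), `statuses`
#'   (list, parallel to `otu_ids`), `all_non_discordant`.
#' @export
species_cluster_profile <- function(assignment, tax) {
  classes <- classify_otus(assignment, tax)
  df <- dplyr::mutate(
    assignment,
    species = tax$species[match(.data$specimen_id, tax$specimen_id)],
    status = classes$status[match(.data$otu_id, classes$otu_id)]
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$species),
    n_otus = dplyr::n_distinct(.data$otu_id),
    otu_ids = list(sort(unique(.data$otu_id))),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    statuses = purrr::map(.data$otu_ids, function(ids) {
      classes$status[match(ids, classes$otu_id)]
    }),
    all_non_discordant = purrr::map_lgl(.data$statuses,
                                        ~ !any(.x == "discordant"))
  )
  dplyr::arrange(out, .data$species)
}

#' Write OTU tables as TSV
#'
#' @param assignment An `otu_assignment`.
#' @param tax Taxonomy tibble.
#' @param otus_path Output path for the per-specimen table
#'   (otu_id, specimen_id, species, status).
#' @param profile_path Optional output path for the per-species profile.
#' @return `otus_path`, invisibly.
#' @export
write_otus <- function(assignment, tax, otus_path, profile_path = NULL) {
  classes <- classify_otus(assignment, tax)
  per_specimen <- dplyr::mutate(
    tibble::as_tibble(assignment),
    species = tax$species[match(.data$specimen_id, tax$specimen_id)],
    status = classes$status[match(.data$otu_id, classes$otu_id)]
  )
  per_specimen <- dplyr::arrange(
    dplyr::select(per_specimen, "otu_id", "specimen_id", "species", "status"),
    .data$otu_id, .data$specimen_id
  )
  readr::write_tsv(per_specimen, otus_path)
  if (!is.null(profile_path)) {
    prof <- species_cluster_profile(assignment, tax)
    flat <- dplyr::mutate(
      prof,
      otu_ids = purrr::map_chr(.data$otu_ids, paste, collapse = ","),
      statuses = purrr::map_chr(.data$statuses, paste, collapse = ",")
    )
    readr::write_tsv(flat, profile_path)
  }
  invisible(otus_path)
}
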