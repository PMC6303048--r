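#' Mean base composition of an alignment
#'
#' Per-sequence base percentages are computed over that sequence's
#' unambiguous (A/C/G/T) sites and then averaged across sequences without
#' weighting by length. Sequences with no unambiguous sites are excluded
#' with a warning.
#'
#' @param alignment Tibble with `specimen_id` and `sequence` columns.
#' @return A one-row tibble with `pct_A`, `pct_C`, `pct_G`, `pct_T`.
#' @export
base_composition <- function(alignment) {
  stopifnot(nrow(alignment) >= 1)
  counts <- vapply(alignment$sequence, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    c(A = sum(ch == "A"), C = sum(ch == "C"),
      G = sum(ch == "G"), T = sum(ch == "T"))
  }, numeric(4))
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " sequence(s) with no unambiguous sites excluded ",
            "from base composition.", call. = FALSE)
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
    if (length(tot) == 0) stop("No sequences with unambiguous sites.",
                               call. = FALSE)
  }
  pct <- rowMeans(sweep(counts, 2, tot, "/")) * 100
  tibble::tibble(pct_A = pct[["A"]], pct_C = pct[["C"]],
                 pct_G = pct[["G"]], pct_T = pct[["T"]])
}

# Long tibble of defined unordered pairs annotated with both specimens'
# taxonomy and the taxonomic rank of the comparison.
pair_table <- function(dm, tax) {
  missing <- setdiff(dm$ids, tax$specimen_id)
  if (length(missing) > 0) {
    stop("Specimens missing from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs <- tidy(dm)
  ta <- tax[match(pairs$id_a, tax$specimen_id), ]
  tb <- tax[match(pairs$id_b, tax$specimen_id), ]
  dplyr::mutate(
    pairs,
    species_a = ta$species, species_b = tb$species,
    genus_a = ta$genus, genus_b = tb$genus,
    family_a = ta$family, family_b = tb$family,
    rank = dplyr::case_when(
      species_a == species_b ~ "intraspecific",
      genus_a == genus_b ~ "intrageneric",
      family_a == family_b ~ "intrafamilial",
      TRUE ~ "interfamilial"
    )
  )
}

#' Distance summaries by taxonomic rank
#'
#' Summarises defined pairwise K2P distances at three nested ranks:
#' intraspecific (same species), intrageneric (same genus, different
#' species) and intrafamilial (same family, different genus). Classes are
#' mutually exclusive; means are unweighted over pairs. Distances are
#' reported as percent.
#'
#' @param dm A `k2p_dist` object from [k2p_matrix()].
#' @param tax Taxonomy tibble with `specimen_id`, `species`, `genus`,
#'   `family`.
#' @return A tibble with `rank`, `n_comparisons`, `mean_pct`, `min_pct`,
#'   `max_pct` (one row per rank; `NA` statistics when a rank has no pairs).
#' @export
rank_summaries <- function(dm, tax) {
  pairs <- dplyr::filter(pair_table(dm, tax), !is.na(.data$k2p))
  ranks <- c("intraspecific", "intrageneric", "intrafamilial")
  purrr::map_dfr(ranks, function(r) {
    d <- pairs$k2p_pct[pairs$rank == r]
    tibble::tibble(
      rank = r,
      n_comparisons = length(d),
      mean_pct = if (length(d)) mean(d) else NA_real_,
      min_pct = if (length(d)) min(d) else NA_real_,
      max_pct = if (length(d)) max(d) else NA_real_
    )
  })
}

#' Per-species barcode-gap report
#'
#' For each species: specimen count, mean and maximum intraspecific K2P
#' distance (absent when n < 2), nearest-neighbor distance (NND — the minimum
#' defined distance from any member to any specimen of another species), the
#' nearest species, and whether the species shows a barcode gap
#' (`nnd_pct > max_intra_pct`; `TRUE` by convention for species without an
#' intraspecific distance, flagged `insufficient_sampling`).
#' Ties in the nearest species are broken lexicographically by species label.
#'
#' @inheritParams rank_summaries
#' @return A tibble with one row per species: `species`, `n`,
#'   `mean_intra_pct`, `max_intra_pct`, `nnd_pct`, `nearest_species`,
#'   `has_barcode_gap`, `note`.
#' @export
species_reports <- function(dm, tax) {
  pairs <- dplyr::filter(pair_table(dm, tax), !is.na(.data$k2p))
  tax_used <- tax[tax$specimen_id %in% dm$ids, ]
  species <- sort(unique(tax_used$species))
  one_species <- length(species) < 2
  if (one_species) {
    warning("Fewer than 2 species: nearest-neighbor distances are undefined.",
            call. = FALSE)
  }

  intra <- pairs[pairs$rank == "intraspecific", ]
  inter <- pairs[pairs$rank != "intraspecific", ]
  # each interspecific pair seen from both sides
  inter_both <- dplyr::bind_rows(
    tibble::tibble(species = inter$species_a, other = inter$species_b,
                   k2p_pct = inter$k2p_pct),
    tibble::tibble(species = inter$species_b, other = inter$species_a,
                   k2p_pct = inter$k2p_pct)
  )

  purrr::map_dfr(species, function(sp) {
    n <- sum(tax_used$species == sp)
    di <- intra$k2p_pct[intra$species_a == sp]
    dn <- inter_both[inter_both$species == sp, ]
    if (nrow(dn) > 0) {
      dn <- dn[order(dn$k2p_pct, dn$other), ]
      nnd <- dn$k2p_pct[1]
      nearest <- dn$other[1]
    } else {
      nnd <- NA_real_
      nearest <- NA_character_
    }
    has_intra <- length(di) > 0
    tibble::tibble(
      species = sp,
      n = n,
      mean_intra_pct = if (has_intra) mean(di) else NA_real_,
      max_intra_pct = if (has_intra) max(di) else NA_real_,
      nnd_pct = nnd,
      nearest_species = nearest,
      has_barcode_gap = if (!has_intra) TRUE else
        if (is.na(nnd)) NA else nnd > max(di),
      note = if (!has_intra) "insufficient_sampling" else NA_character_
    )
  })
}

#' Species exceeding an intraspecific divergence threshold
#'
#' Returns the species whose maximum intraspecific distance exceeds
#' `threshold_pct`, sorted by descending maximum — the usual screen for deep
#' conspecific lineages worth inspecting as possible cryptic complexes.
#'
#' @param reports Output of [species_reports()].
#' @param threshold_pct Threshold in percent K2P distance (default 2).
#' @return The qualifying rows of `reports`, sorted by `max_intra_pct`
#'   descending.
#' @export
flag_divergent <- function(reports, threshold_pct = 2.0) {
  out <- dplyr::filter(reports, !is.na(.data$max_intra_pct),
                       .data$max_intra_pct > threshold_pct)
  dplyr::arrange(out, dplyr::desc(.data$max_intra_pct))
}

#' Barcode-gap scatter plot
#'
#' Maximum intraspecific distance against nearest-neighbor distance, one
#' point per species; points below the identity line lack a barcode gap.
#'
#' @param reports Output of [species_reports()].
#' @return A ggplot object.
#' @export
plot_barcode_gap <- function(reports) {
  df <- dplyr::mutate(reports,
                      max_intra_pct = dplyr::coalesce(.data$max_intra_pct, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_intra_pct,
                                   y = .data$nnd_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$has_barcode_gap)) +
    ggplot2::labs(x = "Max intraspecific K2P distance (%)",
                  y = "Nearest-neighbor distance (%)",
                  colour = "Barcode gap") +
    ggplot2::theme_minimal()
}

#' Distance distributions by taxonomic rank
#'
#' Overlaid histograms of pairwise distances at each rank — the visual form
#' of the barcode gap.
#'
#' @inheritParams rank_summaries
#' @param binwidth Histogram bin width in percent (default 0.5).
#' @return A ggplot object.
#' @export
plot_distance_ranks <- function(dm, tax, binwidth = 0.5) {
  pairs <- dplyr::filter(pair_table(dm, tax), !is.na(.data$k2p))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$k2p_pct, fill = .data$rank)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "K2P distance (%)", y = "Pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
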