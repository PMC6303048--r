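#' Delimitation configuration
#'
#' Thresholds for the two decision rules: a species is a candidate when none
#' of its OTUs is discordant and its nearest-neighbor distance exceeds
#' `nnd_threshold_pct`; it is flagged as a cryptic complex when its maximum
#' intraspecific distance exceeds `intra_threshold_pct` and no morphological
#' distinctiveness between its specimens was reported.
#'
#' @param nnd_threshold_pct NND threshold in percent (default 2).
#' @param intra_threshold_pct Intraspecific-distance threshold in percent
#'   (default 2).
#' @param morphology_distinct Optional named logical vector (species ->
#'   whether its deep lineages are morphologically distinct). Species absent
#'   from it default to `FALSE` (no distinctiveness reported), so every
#'   deeply divergent species is a cryptic candidate unless overridden.
#' @return A list of class `delim_config`.
#' @export
delim_config <- function(nnd_threshold_pct = 2.0, intra_threshold_pct = 2.0,
                         morphology_distinct = NULL) {
  stopifnot(nnd_threshold_pct > 0, intra_threshold_pct > 0)
  structure(list(nnd_threshold_pct = nnd_threshold_pct,
                 intra_threshold_pct = intra_threshold_pct,
                 morphology_distinct = morphology_distinct),
            class = "delim_config")
}

#' Apply the species-delimitation decision rules
#'
#' Combines the per-species barcode-gap report with the OTU occupancy
#' profile. Two independent flags per species:
#' `candidate` — no discordant OTU (singletons allowed) and NND above the
#' threshold; `cryptic_complex` — maximum intraspecific distance above the
#' threshold and no morphological distinctiveness reported. A
#' multi-OTU species counts as concordant so long as no occupied OTU is
#' discordant. The rationale string names the rules that fired or failed.
#'
#' @param reports Output of [species_reports()].
#' @param profiles Output of [species_cluster_profile()] over the same
#'   species set.
#' @param config A [delim_config()].
#' @return An object of class `delimitation`: a tibble with `species`,
#'   `candidate`, `cryptic_complex`, `n_otus`, `otu_statuses`,
#'   `max_intra_pct`, `nnd_pct`, `rationale`, carrying `config` as an
#'   attribute.
#' @export
delimit_species <- function(reports, profiles, config = delim_config()) {
  stopifnot(inherits(config, "delim_config"))
  only_r <- setdiff(reports$species, profiles$species)
  only_p <- setdiff(profiles$species, reports$species)
  if (length(only_r) > 0 || length(only_p) > 0) {
    stop("Species sets differ between distance reports and cluster profiles.",
         if (length(only_r)) paste0(" Only in reports: ",
                                    paste(only_r, collapse = ", "), "."),
         if (length(only_p)) paste0(" Only in profiles: ",
                                    paste(only_p, collapse = ", "), "."),
         call. = FALSE)
  }
  prof <- profiles[match(reports$species, profiles$species), ]
  morpho <- rep(FALSE, nrow(reports))
  if (!is.null(config$morphology_distinct)) {
    m <- config$morphology_distinct[reports$species]
    morpho <- ifelse(is.na(m), FALSE, m)
  }

  out <- purrr::pmap_dfr(
    list(reports$species, reports$max_intra_pct, reports$nnd_pct,
         prof$n_otus, prof$statuses, prof$all_non_discordant, morpho),
    function(sp, max_intra, nnd, n_otus, statuses, non_disc, morph) {
      nnd_ok <- !is.na(nnd) && nnd > config$nnd_threshold_pct
      candidate <- non_disc && nnd_ok
      deep <- !is.na(max_intra) && max_intra > config$intra_threshold_pct
      cryptic <- deep && !morph
      rationale <- paste(c(
        if (!non_disc) "discordant OTU present (candidate rule 1 failed)"
        else "no discordant OTU (candidate rule 1 passed)",
        if (is.na(nnd)) "NND undefined (candidate rule 2 failed)"
        else sprintf("NND %.2f%% %s threshold %.2f%% (candidate rule 2 %s)",
                     nnd, if (nnd_ok) ">" else "<=",
                     config$nnd_threshold_pct,
                     if (nnd_ok) "passed" else "failed"),
        if (is.na(max_intra))
          "no intraspecific comparison (cryptic rule not applicable)"
        else sprintf("max intraspecific %.2f%% %s threshold %.2f%%",
                     max_intra, if (deep) ">" else "<=",
                     config$intra_threshold_pct),
        if (deep && morph)
          "morphological distinctiveness reported (not cryptic)"
      ), collapse = "; ")
      tibble::tibble(
        species = sp, candidate = candidate, cryptic_complex = cryptic,
        n_otus = n_otus, otu_statuses = list(statuses),
        max_intra_pct = max_intra, nnd_pct = nnd, rationale = rationale
      )
    }
  )
  structure(out, config = config,
            class = c("delimitation", class(out)))
}

#' Summary counts of a delimitation result
#'
#' @param results A `delimitation` tibble from [delimit_species()].
#' @return A one-row tibble with `n_species`, `n_candidate`, `n_cryptic`,
#'   `n_neither` and a `candidates` list column of candidate species labels.
#' @export
count_delimited <- function(results) {
  tibble::tibble(
    n_species = nrow(results),
    n_candidate = sum(results$candidate),
    n_cryptic = sum(results$cryptic_complex),
    n_neither = sum(!results$candidate & !results$cryptic_complex),
    candidates = list(results$species[results$candidate])
  )
}

#' @export
print.delimitation <- function(x, ...) {
  cnt <- count_delimited(x)
  cat("Species delimitation: ", cnt$n_species, " species — ",
      cnt$n_candidate, " candidate, ", cnt$n_cryptic,
      " cryptic complex(es)\n", sep = "")
  NextMethod()
}

#' Tidy a delimitation result
#'
#' @param x A `delimitation` object.
#' @param ... Unused.
#' @return The underlying tibble with `otu_statuses` flattened to a
#'   comma-separated string.
#' @method tidy delimitation
#' @export
tidy.delimitation <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                otu_statuses = purrr::map_chr(.data$otu_statuses, paste,
                                              collapse = ","))
}

#' One-row summary of a delimitation result
#'
#' @param x A `delimitation` object.
#' @param ... Unused.
#' @return Output of [count_delimited()] without the list column.
#' @method glance delimitation
#' @export
glance.delimitation <- function(x, ...) {
  dplyr::select(count_delimited(x), -"candidates")
}
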