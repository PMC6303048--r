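#' Read barcode sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of specimen records. The header token
#' before the first whitespace is taken as the specimen ID and sequences are
#' uppercased. Gaps (`-`) and IUPAC ambiguity codes are kept as-is; their
#' treatment is deferred to QC and to the pairwise-deletion distance code.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `specimen_id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("Not FASTA-formatted (first non-blank line is not a header): ",
         path, call. = FALSE)
  }
  grp <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  seqs <- vapply(
    split(lines[!is_header], grp[!is_header]),
    function(x) toupper(paste(gsub("\\s", "", x), collapse = "")),
    character(1)
  )
  # headers with no sequence lines would be dropped by split(); catch them
  n_seq_per_header <- tabulate(grp[!is_header], nbins = length(ids))
  if (any(n_seq_per_header == 0L)) {
    stop("FASTA entries with no sequence: ",
         paste(ids[n_seq_per_header == 0L], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("Duplicate specimen IDs in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(specimen_id = ids, sequence = unname(seqs))
}

#' Write specimen records to a FASTA file
#'
#' @param records A tibble with columns `specimen_id` and `sequence`
#'   (as returned by [read_fasta()] or [simulate_barcodes()]).
#' @param path Output file path.
#' @param width Line width for wrapping sequences (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(all(c("specimen_id", "sequence") %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$specimen_id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Tab-separated, UTF-8, `#`-prefixed comment lines ignored (loosely matching
#' BOLD specimen exports). Must contain at least `specimen_id`, `species`,
#' `genus` and `family`; `site` and `external_cluster_id` are optional and
#' filled with `NA` when absent.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `specimen_id`, `species`, `genus`, `family`,
#'   `site`, `external_cluster_id`.
#' @export
read_metadata <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()
  ))
  required <- c("specimen_id", "species", "genus", "family")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("Metadata is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (opt in c("site", "external_cluster_id")) {
    if (!opt %in% names(tab)) tab[[opt]] <- NA_character_
  }
  if (anyDuplicated(tab$specimen_id)) {
    dup <- unique(tab$specimen_id[duplicated(tab$specimen_id)])
    stop("Duplicate specimen IDs in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tab$species) | !nzchar(tab$species))) {
    stop("Metadata rows with empty species label: ",
         paste(tab$specimen_id[is.na(tab$species) | !nzchar(tab$species)],
               collapse = ", "), call. = FALSE)
  }
  dplyr::select(tab, "specimen_id", "species", "genus", "family", "site",
                "external_cluster_id", dplyr::everything())
}

#' QC configuration for barcode sequences
#'
#' Captures the standard barcode quality filters: a minimum ungapped length,
#' a cap on the fraction of ambiguous bases, an optional no-indel requirement,
#' and a reading-frame check for premature stop codons under a mitochondrial
#' genetic code.
#'
#' @param min_length Minimum ungapped sequence length in sites (default 500,
#'   the conventional cutoff for a full-length barcode record).
#' @param max_ambiguous_fraction Maximum fraction of ambiguous (non-ACGT,
#'   non-gap) characters over ungapped length, in `[0, 1]` (default 0.01).
#' @param genetic_code `"vertebrate_mito"` (default) or `"standard"`; controls
#'   the stop-codon set used by the open-reading-frame check.
#' @param require_no_indels If `TRUE` (default), any `-` character fails QC.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_length = 500, max_ambiguous_fraction = 0.01,
                      genetic_code = c("vertebrate_mito", "standard"),
                      require_no_indels = TRUE) {
  genetic_code <- match.arg(genetic_code)
  stopifnot(min_length >= 1, max_ambiguous_fraction >= 0,
            max_ambiguous_fraction <= 1)
  structure(
    list(min_length = as.integer(min_length),
         max_ambiguous_fraction = max_ambiguous_fraction,
         genetic_code = genetic_code,
         require_no_indels = isTRUE(require_no_indels)),
    class = "qc_config"
  )
}

stop_codons <- function(genetic_code) {
  switch(genetic_code,
         vertebrate_mito = c("TAA", "TAG", "AGA", "AGG"),
         standard = c("TAA", "TAG", "TGA"),
         stop("Unknown genetic code: ", genetic_code, call. = FALSE))
}

# TRUE iff at least one of the three forward frames contains no stop codon
# among its complete codons. Codons containing ambiguity codes cannot be
# called as stops and never fail a frame.
has_open_frame <- function(seq, genetic_code = "vertebrate_mito") {
  stops <- stop_codons(genetic_code)
  s <- gsub("-", "", seq, fixed = TRUE)
  n <- nchar(s)
  for (offset in 0:2) {
    n_codons <- (n - offset) %/% 3L
    if (n_codons < 1L) next
    starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, starts, starts + 2L)
    if (!any(codons %in% stops)) return(TRUE)
  }
  FALSE
}

#' Filter barcode sequences on quality criteria
#'
#' A record passes when its ungapped length reaches `min_length`, its
#' ambiguous-base fraction does not exceed `max_ambiguous_fraction`, it has no
#' alignment gaps (when `require_no_indels`), and at least one forward reading
#' frame is free of stop codons under the configured genetic code. The report
#' names the first criterion each failing record violated, checked in the
#' order length, indel, ambiguity, stop codon.
#'
#' @param records Tibble with `specimen_id` and `sequence` columns.
#' @param config A [qc_config()].
#' @return A list with `passed` (tibble of surviving records) and `report`
#'   (tibble with `specimen_id`, `status` of `"pass"`/`"fail"`, and `reason`
#'   of `"length"`, `"indel"`, `"ambiguity"`, `"stop_codon"` or `NA`).
#' @export
qc_filter <- function(records, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"), nrow(records) > 0)
  seqs <- records$sequence
  ungapped <- gsub("-", "", seqs, fixed = TRUE)
  len <- nchar(ungapped)
  n_ambig <- len - vapply(gregexpr("[ACGT]", ungapped), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  has_gap <- grepl("-", seqs, fixed = TRUE)

  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & len < config$min_length] <- "length"
  if (config$require_no_indels) {
    reason[is.na(reason) & has_gap] <- "indel"
  }
  ambig_frac <- ifelse(len > 0, n_ambig / len, 1)
  reason[is.na(reason) & ambig_frac > config$max_ambiguous_fraction] <- "ambiguity"
  need_orf <- which(is.na(reason))
  orf_ok <- vapply(seqs[need_orf], has_open_frame, logical(1),
                   genetic_code = config$genetic_code, USE.NAMES = FALSE)
  reason[need_orf[!orf_ok]] <- "stop_codon"

  report <- tibble::tibble(
    specimen_id = records$specimen_id,
    status = ifelse(is.na(reason), "pass", "fail"),
    reason = reason
  )
  list(passed = records[is.na(reason), , drop = FALSE], report = report)
}

#' Load and validate a barcode dataset
#'
#' Reads a FASTA and a metadata TSV, applies QC, cross-checks specimen IDs
#' between the two inputs, and enforces the equal-length (pre-aligned) input
#' contract. This package does not align sequences: supply aligned or
#' uniformly trimmed input.
#'
#' @param fasta_path Path to the FASTA file.
#' @param metadata_path Path to the metadata TSV.
#' @param config A [qc_config()].
#' @return A list with `alignment` (tibble of QC-passing records, all the
#'   same length), `taxonomy` (metadata rows for those records, in matching
#'   order) and `qc_report`.
#' @export
load_dataset <- function(fasta_path, metadata_path, config = qc_config()) {
  records <- read_fasta(fasta_path)
  tax <- read_metadata(metadata_path)

  only_fasta <- setdiff(records$specimen_id, tax$specimen_id)
  only_meta <- setdiff(tax$specimen_id, records$specimen_id)
  if (length(only_fasta) > 0 || length(only_meta) > 0) {
    stop("Specimen IDs do not match between FASTA and metadata.",
         if (length(only_fasta)) paste0(" Only in FASTA: ",
                                        paste(only_fasta, collapse = ", "), "."),
         if (length(only_meta)) paste0(" Only in metadata: ",
                                       paste(only_meta, collapse = ", "), "."),
         call. = FALSE)
  }

  qc <- qc_filter(records, config)
  if (nrow(qc$passed) == 0) {
    stop("No sequences passed QC.", call. = FALSE)
  }
  lens <- nchar(qc$passed$sequence)
  if (length(unique(lens)) > 1) {
    stop("Surviving sequences differ in length (",
         paste(range(lens), collapse = "-"),
         " sites); supply aligned or equal-length-trimmed input — ",
         "this package does not align sequences.", call. = FALSE)
  }
  tax_kept <- tax[match(qc$passed$specimen_id, tax$specimen_id), , drop = FALSE]
  list(alignment = qc$passed, taxonomy = tax_kept, qc_report = qc$report)
}

#' Write a specimen metadata table
#'
#' @param taxonomy Tibble with at least `specimen_id`, `species`, `genus`,
#'   `family` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path)
  invisible(path)
}
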