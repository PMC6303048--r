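# Shared fixtures and independent oracles used across the test files.

random_seq <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

random_alignment <- function(n, L, ambiguous = FALSE) {
  alphabet <- c("A", "C", "G", "T")
  if (ambiguous) alphabet <- c(alphabet, "N", "-", "R", "Y")
  tibble::tibble(
    specimen_id = sprintf("s%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) random_seq(L, alphabet),
                      character(1))
  )
}

# Alignment of sequences derived from one ancestor by point mutations, so
# pairwise divergences stay realistic (far from K2P saturation).
related_alignment <- function(n, L, mut = 0.08, ambiguous = FALSE) {
  base <- strsplit(random_seq(L), "")[[1]]
  alphabet <- c("A", "C", "G", "T")
  if (ambiguous) alphabet <- c(alphabet, "N", "R")
  tibble::tibble(
    specimen_id = sprintf("s%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      s <- base
      idx <- sample(L, ceiling(mut * L))
      s[idx] <- sample(alphabet, length(idx), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
  )
}

# Independent site-by-site K2P oracle: explicit loop over columns, direct
# closed form. Deliberately naive; shares no code with the implementation.
brute_k2p <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (x != y) {
        if ((x == "A" && y == "G") || (x == "G" && y == "A") ||
            (x == "C" && y == "T") || (x == "T" && y == "C")) {
          ts <- ts + 1L
        } else {
          tv <- tv + 1L
        }
      }
    }
  }
  P <- ts / n; Q <- tv / n
  # same domain guard as the implementation: the exact boundary leaves
  # floating-point residue in 1 - 2P - Q
  if ((1 - 2 * P - Q) <= 1e-12 || (1 - 2 * Q) <= 1e-12) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Raw proportion of differing comparable sites (p-distance oracle).
brute_p_dist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  mean(ca[ok] != cb[ok])
}

# Metadata tibble for a set of specimen IDs, round-robin over species.
toy_taxonomy <- function(ids, n_species = 2, n_genera = 1, n_families = 1) {
  sp <- rep_len(sprintf("Sp%02d", seq_len(n_species)), length(ids))
  sp_idx <- as.integer(factor(sp))
  tibble::tibble(
    specimen_id = ids,
    species = sp,
    genus = sprintf("Gen%02d", ((sp_idx - 1) %% n_genera) + 1),
    family = sprintf("Fam%02d", ((sp_idx - 1) %% n_families) + 1),
    site = "UDV",
    external_cluster_id = NA_character_
  )
}

write_toy_dataset <- function(alignment, taxonomy, dir = withr::local_tempdir(
  .local_envir = parent.frame())) {
  fa <- file.path(dir, "seqs.fasta")
  md <- file.path(dir, "meta.tsv")
  barcodegap::write_fasta(alignment, fa)
  readr::write_tsv(taxonomy, md)
  list(fasta = fa, metadata = md, dir = dir)
}

# Build a k2p_dist-shaped object directly from a distance matrix, for tests
# that want full control over the pairwise values.
dist_from_matrix <- function(d, ids = rownames(d)) {
  if (is.null(ids)) ids <- sprintf("t%02d", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 n_comparable = matrix(1000L, nrow(d), ncol(d),
                                       dimnames = list(ids, ids)),
                 config = barcodegap::dist_config()),
            class = "k2p_dist")
}
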