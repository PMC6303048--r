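#' Count transitions and transversions between two aligned sequences
#'
#' Only columns where both characters are unambiguous bases (A, C, G, T) are
#' comparable; gaps, Ns and IUPAC partial ambiguities are excluded pairwise.
#' Differences are split into transitions (A<->G, C<->T) and transversions
#' (all other differing pairs).
#'
#' @param seq_a,seq_b Equal-length sequence strings.
#' @return A one-row tibble with `n_sites`, `n_transitions`, `n_transversions`.
#' @examples
#' count_differences("ACGT", "ACGA")
#' @export
count_differences <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("Sequences have unequal lengths (", nchar(seq_a), " vs ",
         nchar(seq_b), ")", call. = FALSE)
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  bases <- c("A", "C", "G", "T")
  comparable <- a %in% bases & b %in% bases
  a <- a[comparable]
  b <- b[comparable]
  diff <- a != b
  purine_a <- a %in% c("A", "G")
  purine_b <- b %in% c("A", "G")
  ts <- diff & (purine_a == purine_b)
  tibble::tibble(
    n_sites = sum(comparable),
    n_transitions = sum(ts),
    n_transversions = sum(diff) - sum(ts)
  )
}

#' Kimura 2-parameter distance from substitution counts
#'
#' Evaluates `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with
#' `P = n_transitions / n_sites` and `Q = n_transversions / n_sites`.
#' When the log argument leaves its domain (saturation), the result is
#' `NA` under the default `mark_undefined` policy or an error under `error`.
#' Vectorised over counts.
#'
#' @param n_sites,n_transitions,n_transversions Integer count vectors.
#' @param on_saturation `"mark_undefined"` (default) or `"error"`.
#' @return Numeric vector of distances in substitutions/site (`NA` where
#'   saturated under the default policy).
#' @examples
#' k2p_distance(100, 10, 5) # 0.17018
#' @export
k2p_distance <- function(n_sites, n_transitions, n_transversions,
                         on_saturation = c("mark_undefined", "error")) {
  on_saturation <- match.arg(on_saturation)
  if (any(n_sites == 0)) {
    stop("No comparable sites between sequences; cannot compute a distance.",
         call. = FALSE)
  }
  P <- n_transitions / n_sites
  Q <- n_transversions / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  # epsilon guards the exact domain boundary against floating-point residue
  sat <- w1 <= 1e-12 | w2 <= 1e-12
  if (any(sat) && on_saturation == "error") {
    stop("Saturated distance (log argument outside its domain) for ",
         sum(sat), " pair(s).", call. = FALSE)
  }
  d <- rep(NA_real_, length(P))
  d[!sat] <- -0.5 * log(w1[!sat] * sqrt(w2[!sat]))
  # guard tiny negative zero from floating point
  d[!sat & d < 0 & d > -1e-12] <- 0
  d
}

#' Configuration for pairwise distance estimation
#'
#' @param min_overlap Minimum number of comparable sites required to report a
#'   distance for a pair (default 100); pairs below it are marked undefined.
#' @param on_saturation Policy for pairs where the K2P log argument leaves its
#'   domain: `"mark_undefined"` (default) or `"error"`.
#' @return A list of class `dist_config`.
#' @export
dist_config <- function(min_overlap = 100,
                        on_saturation = c("mark_undefined", "error")) {
  on_saturation <- match.arg(on_saturation)
  stopifnot(min_overlap >= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 on_saturation = on_saturation),
            class = "dist_config")
}

# Encode an equal-length alignment as four 0/1 indicator matrices (n x L),
# one per unambiguous base. Everything else (gap, N, IUPAC codes) is
# non-comparable.
encode_alignment <- function(alignment) {
  stopifnot(all(c("specimen_id", "sequence") %in% names(alignment)))
  lens <- nchar(alignment$sequence)
  if (length(unique(lens)) > 1) {
    stop("Alignment sequences are not all the same length.", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(toupper(alignment$sequence), ""),
                         use.names = FALSE),
                  nrow = nrow(alignment), byrow = TRUE)
  lapply(stats::setNames(nm = c("A", "C", "G", "T")),
         function(b) (chars == b) * 1)
}

#' Pairwise Kimura 2-parameter distance matrix
#'
#' Computes all pairwise K2P distances over an equal-length alignment with
#' pairwise deletion: a column is dropped only for the pairs in which either
#' member carries a gap, N or IUPAC ambiguity there. Pairs with fewer than
#' `min_overlap` comparable sites, and saturated pairs, are marked undefined
#' (`NA`) with a warning.
#'
#' @param alignment Tibble with `specimen_id` and equal-length `sequence`
#'   columns (at least 2 rows).
#' @param config A [dist_config()].
#' @return An object of class `k2p_dist`: a list with `ids`, `d` (symmetric
#'   distance matrix, substitutions/site, zero diagonal, `NA` where
#'   undefined), `n_comparable` (symmetric matrix of comparable-site counts)
#'   and `config`.
#' @export
k2p_matrix <- function(alignment, config = dist_config()) {
  stopifnot(inherits(config, "dist_config"))
  if (nrow(alignment) < 2) {
    stop("Need at least 2 sequences for a distance matrix.", call. = FALSE)
  }
  ind <- encode_alignment(alignment)
  V <- ind$A + ind$C + ind$G + ind$T
  n_comp <- V %*% t(V)
  matches <- ind$A %*% t(ind$A) + ind$C %*% t(ind$C) +
    ind$G %*% t(ind$G) + ind$T %*% t(ind$T)
  n_ts <- ind$A %*% t(ind$G) + ind$G %*% t(ind$A) +
    ind$C %*% t(ind$T) + ind$T %*% t(ind$C)
  n_tv <- n_comp - matches - n_ts

  n <- nrow(alignment)
  P <- ifelse(n_comp > 0, n_ts / n_comp, NA_real_)
  Q <- ifelse(n_comp > 0, n_tv / n_comp, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  defined <- !is.na(w1) & w1 > 1e-12 & w2 > 1e-12
  d <- matrix(NA_real_, n, n)
  d[defined] <- -0.5 * log(w1[defined] * sqrt(w2[defined]))
  d[defined & d < 0 & d > -1e-12] <- 0
  diag(d) <- 0

  low_overlap <- n_comp < config$min_overlap
  d[low_overlap] <- NA_real_
  diag(low_overlap) <- FALSE

  off <- upper.tri(d)
  n_sat <- sum(!defined[off] & !low_overlap[off] & n_comp[off] > 0)
  n_low <- sum(low_overlap[off])
  if (config$on_saturation == "error" && n_sat > 0) {
    stop(n_sat, " saturated pair(s) in distance matrix.", call. = FALSE)
  }
  if (n_sat > 0) {
    warning(n_sat, " saturated pair(s) marked undefined.", call. = FALSE)
  }
  if (n_low > 0) {
    warning(n_low, " pair(s) below min_overlap (", config$min_overlap,
            " sites) marked undefined.", call. = FALSE)
  }

  ids <- alignment$specimen_id
  dimnames(d) <- dimnames(n_comp) <- list(ids, ids)
  structure(list(ids = ids, d = d, n_comparable = n_comp, config = config),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat("K2P distance matrix: ", length(x$ids), " specimens, ",
      sum(!is.na(off)), " defined pairs (", sum(is.na(off)), " undefined)\n",
      sep = "")
  if (any(!is.na(off))) {
    cat(sprintf("  range %.4f-%.4f substitutions/site\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' Tidy a K2P distance matrix into long format
#'
#' One row per unordered specimen pair, with the distance (substitutions/site
#' and percent) and the number of comparable sites.
#'
#' @param x A `k2p_dist` object.
#' @param ... Unused.
#' @return A tibble with `id_a`, `id_b`, `k2p`, `k2p_pct`, `n_sites`.
#' @method tidy k2p_dist
#' @export
tidy.k2p_dist <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    id_a = x$ids[idx[, 1]],
    id_b = x$ids[idx[, 2]],
    k2p = x$d[idx],
    k2p_pct = x$d[idx] * 100,
    n_sites = as.integer(x$n_comparable[idx])
  )
}

#' One-row summary of a K2P distance matrix
#'
#' @param x A `k2p_dist` object.
#' @param ... Unused.
#' @return A tibble with specimen/pair counts and distance range.
#' @method glance k2p_dist
#' @export
glance.k2p_dist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  tibble::tibble(
    n_specimens = length(x$ids),
    n_pairs = length(off),
    n_undefined = sum(is.na(off)),
    mean_pct = mean(off, na.rm = TRUE) * 100,
    min_pct = if (all(is.na(off))) NA_real_ else min(off, na.rm = TRUE) * 100,
    max_pct = if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE) * 100
  )
}

#' Write a distance matrix as TSV
#'
#' Writes both a square matrix (IDs as header row and first column) and, when
#' `long_path` is given, a long-format table `id_a, id_b, k2p, n_sites`.
#'
#' @param dm A `k2p_dist` object.
#' @param path Output path for the square matrix TSV.
#' @param long_path Optional output path for the long format.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, long_path = NULL) {
  square <- tibble::as_tibble(dm$d, rownames = "specimen_id")
  readr::write_tsv(square, path)
  if (!is.null(long_path)) {
    readr::write_tsv(tidy(dm), long_path)
  }
  invisible(path)
}
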