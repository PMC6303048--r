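#' Neighbor-joining tree from a K2P distance matrix
#'
#' Standard neighbor joining: at each step the pair minimising
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' branch lengths `L_i = d(i,j)/2 + (R_i - R_j) / (2 (r - 2))` and the new
#' node's distances `(d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken
#' deterministically by the lowest (i, j) index pair in the current node
#' ordering (tips in input order, joined nodes appended), so runs are
#' reproducible across platforms. Negative branch-length estimates are
#' clamped to zero (MEGA-like display convention); the raw estimates are
#' reported in a message and kept in the `clamped_raw` attribute. The result
#' is unrooted (basal trifurcation).
#'
#' @param dm A `k2p_dist` object with all pairwise distances defined.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  D <- dm$d
  n <- length(dm$ids)
  if (n < 3) stop("Neighbor joining needs at least 3 taxa.", call. = FALSE)
  if (anyNA(D[upper.tri(D)])) {
    idx <- which(upper.tri(D) & is.na(D), arr.ind = TRUE)
    bad <- unique(c(dm$ids[idx[, 1]], dm$ids[idx[, 2]]))
    stop("Distance matrix has undefined entries; exclude the affected ",
         "specimens first: ", paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ...", call. = FALSE)
  }
  fmt <- function(x) sprintf("%.15g", x)
  clamped <- numeric(0)
  clamp <- function(x) {
    if (x < 0) {
      clamped[length(clamped) + 1L] <<- x
      0
    } else x
  }
  lab <- dm$ids
  while (nrow(D) > 3) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    dij <- D[i, j]
    Li <- clamp(dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2)))
    Lj <- clamp(dij - (dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))))
    newlab <- paste0("(", lab[i], ":", fmt(Li), ",", lab[j], ":", fmt(Lj), ")")
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    lab <- c(lab[keep], newlab)
  }
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  xa <- clamp((dab + dac - dbc) / 2)
  xb <- clamp((dab + dbc - dac) / 2)
  xc <- clamp((dac + dbc - dab) / 2)
  nwk <- paste0("(", lab[1], ":", fmt(xa), ",", lab[2], ":", fmt(xb), ",",
                lab[3], ":", fmt(xc), ");")
  tree <- ape::read.tree(text = nwk)
  if (length(clamped) > 0) {
    shown <- head(clamped, 5)
    message(length(clamped), " negative branch-length estimate(s) clamped ",
            "to 0 (raw: ", paste(sprintf("%.3g", shown), collapse = ", "),
            if (length(clamped) > 5) ", ..." else "", ")")
  }
  attr(tree, "clamped_raw") <- clamped
  tree
}

#' Bootstrap configuration
#'
#' @param replicates Number of bootstrap pseudo-replicates (default 1000).
#' @param seed Master seed; per-replicate column-resampling streams are
#'   derived from it, so a fixed seed gives bit-identical supports.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(replicates = 1000, seed = NULL) {
  stopifnot(replicates >= 1)
  structure(list(replicates = as.integer(replicates), seed = seed),
            class = "bootstrap_config")
}

alignment_char_matrix <- function(alignment) {
  matrix(unlist(strsplit(toupper(alignment$sequence), ""), use.names = FALSE),
         nrow = nrow(alignment), byrow = TRUE,
         dimnames = list(alignment$specimen_id, NULL))
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement (same length), recomputes the K2P matrix and NJ
#' tree per replicate, and maps bipartition frequencies onto the original
#' tree as integer percentage node labels (standard bootstrap, not a
#' consensus). Replicates whose resampled distance matrix contains undefined
#' entries are dropped with a warning and the support denominator adjusted.
#'
#' @param alignment Tibble with `specimen_id` and equal-length `sequence`.
#' @param config A [bootstrap_config()].
#' @param dist_cfg A [dist_config()] used for every distance computation.
#' @return A `phylo` object whose `node.label` holds integer bootstrap
#'   percentages; attributes `n_replicates_used` and `n_replicates_dropped`
#'   record the denominator.
#' @export
bootstrap_support <- function(alignment, config = bootstrap_config(),
                              dist_cfg = dist_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  dm <- k2p_matrix(alignment, dist_cfg)
  tree <- neighbor_joining(dm)
  chars <- alignment_char_matrix(alignment)
  L <- ncol(chars)

  if (!is.null(config$seed)) set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$replicates)

  rep_trees <- vector("list", config$replicates)
  dropped <- 0L
  for (b in seq_len(config$replicates)) {
    set.seed(rep_seeds[b])
    cols <- sample.int(L, L, replace = TRUE)
    res <- alignment
    res$sequence <- apply(chars[, cols, drop = FALSE], 1, paste,
                          collapse = "")
    dm_b <- suppressWarnings(k2p_matrix(res, dist_cfg))
    if (anyNA(dm_b$d[upper.tri(dm_b$d)])) {
      dropped <- dropped + 1L
      next
    }
    rep_trees[[b]] <- suppressMessages(neighbor_joining(dm_b))
  }
  rep_trees <- rep_trees[!vapply(rep_trees, is.null, logical(1))]
  n_used <- length(rep_trees)
  if (dropped > 0) {
    warning(dropped, " bootstrap replicate(s) dropped (undefined distances); ",
            "support based on ", n_used, " replicates.", call. = FALSE)
  }
  if (n_used == 0) stop("All bootstrap replicates were dropped.",
                        call. = FALSE)
  class(rep_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_used)
  tree$node.label <- as.character(support)
  attr(tree, "n_replicates_used") <- n_used
  attr(tree, "n_replicates_dropped") <- dropped
  tree
}

#' Write a tree to a Newick file
#'
#' Branch lengths and integer bootstrap supports (as internal node labels)
#' are preserved; the output is parseable by any standard Newick reader.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Plot an NJ tree with bootstrap supports
#'
#' Thin wrapper around [ape::plot.phylo()] showing node support labels.
#'
#' @param tree A `phylo` object (e.g. from [bootstrap_support()]).
#' @param ... Passed to [ape::plot.phylo()].
#' @return `tree`, invisibly.
#' @export
plot_nj_tree <- function(tree, ...) {
  ape::plot.phylo(tree, ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(tree$node.label, frame = "none", adj = c(1.2, -0.3),
                    cex = 0.7)
  }
  invisible(tree)
}
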