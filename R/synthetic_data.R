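# Per-species specimen counts used as the default sampling multiset: the
# empirical distribution of barcoded specimens per species in a published
# stream-fish survey (29 species, 2-24 specimens each, mean ~8.6).
default_specimen_counts <- c(16L, 6L, 19L, 5L, 2L, 24L, 9L, 17L, 24L, 14L,
                             11L, 4L, 9L, 2L, 18L, 5L, 7L, 3L, 2L, 2L, 2L,
                             3L, 8L, 5L, 2L, 11L, 13L, 5L, 2L)

#' Simulation configuration for synthetic barcode datasets
#'
#' Defaults emulate the statistical structure of a typical single-basin COI
#' fish survey: 29 morphospecies sampled with 2-24 specimens each (mean ~8.6,
#' drawn from an empirical per-species count multiset), 600 bp sequences,
#' base composition A 23.5 / C 27.8 / G 18.1 / T 30.7 %, shallow
#' within-species divergence (0.5% expected) against deep between-species
#' divergence (10% expected), and a transition/transversion rate ratio of 3.
#'
#' @param n_species Number of species.
#' @param specimens_per_species `NULL` (default: draw from the empirical
#'   count multiset; with 29 species the multiset is used verbatim), a single
#'   integer, or an integer vector of length `n_species`.
#' @param seq_length Sites per sequence (default 600).
#' @param kappa Transition/transversion rate ratio (default 3).
#' @param base_freqs Named numeric vector of root base frequencies (A, C, G,
#'   T), summing to 1.
#' @param intra_depth Expected within-species pairwise divergence in
#'   substitutions/site (default 0.005); specimen branches are exponential
#'   with mean `intra_depth / 2`.
#' @param inter_depth Expected between-species pairwise divergence (default
#'   0.10); the species tree is scaled so the mean pairwise path equals it.
#' @param min_separation Floor on the pairwise divergence between species
#'   ancestors (default 0.04, matching the smallest nearest-neighbor
#'   distances typically seen in single-basin barcode surveys). After
#'   scaling, terminal species-tree branches are extended equally until the
#'   closest ancestor pair reaches this floor, so species boundaries are
#'   unambiguous except where `discordant_pairs` deliberately erases them.
#' @param cryptic_species List of `list(species =` index`, divergence =`
#'   lineage split in substitutions/site`, proportion =` fraction of
#'   specimens in the second lineage`)` entries injecting deep conspecific
#'   lineages.
#' @param discordant_pairs List of length-2 integer vectors: species pairs
#'   whose ancestors are forced to `discordant_separation` apart so they
#'   merge into one OTU at the usual cluster threshold.
#' @param discordant_separation Total divergence between forced-close species
#'   ancestors (default 0.005).
#' @param enforce_orf If `TRUE`, the root is drawn without stop codons in the
#'   first reading frame (vertebrate mitochondrial code) and every branch's
#'   evolution is redrawn until the child sequence keeps that frame open —
#'   emulating purifying selection against nonsense mutations, so output
#'   passes the standard barcode QC. Default `FALSE`: neutral simulation
#'   makes no open-reading-frame guarantee.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 29,
                       specimens_per_species = NULL,
                       seq_length = 600,
                       kappa = 3.0,
                       base_freqs = c(A = 0.2349, C = 0.2776,
                                      G = 0.1806, T = 0.307),
                       intra_depth = 0.005,
                       inter_depth = 0.10,
                       min_separation = 0.04,
                       cryptic_species = list(),
                       discordant_pairs = list(),
                       discordant_separation = 0.005,
                       enforce_orf = FALSE,
                       seed = NULL) {
  stopifnot(n_species >= 1, seq_length >= 1, kappa > 0,
            intra_depth >= 0, inter_depth > intra_depth,
            min_separation >= 0)
  base_freqs <- base_freqs[c("A", "C", "G", "T")]
  # published compositions are rounded percentages; allow that slack and
  # renormalise
  if (anyNA(base_freqs) || abs(sum(base_freqs) - 1) > 1e-3) {
    stop("base_freqs must be named A/C/G/T and sum to 1.", call. = FALSE)
  }
  base_freqs <- base_freqs / sum(base_freqs)
  for (cs in cryptic_species) {
    stopifnot(cs$species >= 1, cs$species <= n_species,
              cs$proportion > 0, cs$proportion < 1)
    # at finite sequence length, estimated distances saturate long before
    # the expectation does: require clear headroom in the log domain
    pr <- k80_probs(cs$divergence, kappa)
    if (1 - 2 * pr[["ts"]] - pr[["tv"]] < 0.05) {
      stop("Cryptic lineage divergence ", cs$divergence,
           " saturates the K2P distance at realistic sequence lengths; ",
           "choose a smaller value.", call. = FALSE)
    }
  }
  structure(
    list(n_species = as.integer(n_species),
         specimens_per_species = specimens_per_species,
         seq_length = as.integer(seq_length),
         kappa = kappa, base_freqs = base_freqs,
         intra_depth = intra_depth, inter_depth = inter_depth,
         min_separation = min_separation,
         cryptic_species = cryptic_species,
         discordant_pairs = discordant_pairs,
         discordant_separation = discordant_separation,
         enforce_orf = isTRUE(enforce_orf),
         seed = seed),
    class = "sim_config"
  )
}

# K80 substitution probabilities after branch length d (expected subs/site)
# at transition/transversion rate ratio kappa. Returns the probability of a
# transition and the total probability of a transversion.
k80_probs <- function(d, kappa) {
  e_tv <- exp(-4 * d / (kappa + 2))
  e_ts <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  p_ts <- 0.25 + 0.25 * e_tv - 0.5 * e_ts
  p_tv <- 0.5 - 0.5 * e_tv
  c(ts = p_ts, tv = p_tv)
}

#' Expected K2P quantities for a simulated divergence
#'
#' Closed-form expectation for two sequences whose lineages each evolved for
#' `depth` substitutions/site from their common ancestor under the Kimura
#' two-parameter process (total path `2 * depth`): the expected transition
#' proportion P, transversion proportion Q, and the K2P distance they imply
#' (which equals `2 * depth` — the estimator is consistent for the
#' generating process). Used to validate that estimated distances recover
#' simulated depths.
#'
#' @param depth Per-lineage divergence in substitutions/site.
#' @param kappa Transition/transversion rate ratio.
#' @return A one-row tibble with `P_expected`, `Q_expected`, `d_expected`
#'   (`NA` when the distance saturates).
#' @export
expected_k2p <- function(depth, kappa = 3.0) {
  stopifnot(depth >= 0, kappa > 0)
  pr <- k80_probs(2 * depth, kappa)
  P <- unname(pr["ts"]); Q <- unname(pr["tv"])
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 > 0 && w2 > 0) -0.5 * log(w1 * sqrt(w2)) else NA_real_
  if (!is.na(d) && d < 0) d <- 0
  tibble::tibble(P_expected = P, Q_expected = Q, d_expected = d)
}

# TRUE iff the integer-coded sequence has no vertebrate-mito stop codon
# (TAA, TAG, AGA, AGG) among the complete codons of frame 1.
frame1_open <- function(seq_int) {
  n_cod <- length(seq_int) %/% 3L
  if (n_cod == 0L) return(TRUE)
  m <- matrix(seq_int[seq_len(3L * n_cod)], nrow = 3L)
  code <- (m[1, ] - 1L) * 16L + (m[2, ] - 1L) * 4L + m[3, ]
  stops <- c((4L - 1L) * 16L + (1L - 1L) * 4L + 1L,   # TAA
             (4L - 1L) * 16L + (1L - 1L) * 4L + 3L,   # TAG
             (1L - 1L) * 16L + (3L - 1L) * 4L + 1L,   # AGA
             (1L - 1L) * 16L + (3L - 1L) * 4L + 3L)   # AGG
  !any(code %in% stops)
}

# Evolve an integer-coded sequence (1=A, 2=C, 3=G, 4=T) along a branch of
# length d under the K80 process, vectorised over sites.
evolve_sequence <- function(seq_int, d, kappa) {
  if (d <= 0) return(seq_int)
  pr <- k80_probs(d, kappa)
  L <- length(seq_int)
  u <- stats::runif(L)
  ts_partner <- c(3L, 4L, 1L, 2L)
  is_ts <- u < pr["ts"]
  is_tv <- !is_ts & u < pr["ts"] + pr["tv"]
  out <- seq_int
  out[is_ts] <- ts_partner[seq_int[is_ts]]
  if (any(is_tv)) {
    # transversion targets: the two bases of the opposite purine/pyrimidine
    # class, each equally likely
    purine <- seq_int[is_tv] %in% c(1L, 3L)
    pick_second <- stats::runif(sum(is_tv)) < 0.5
    out[is_tv] <- ifelse(purine,
                         ifelse(pick_second, 4L, 2L),
                         ifelse(pick_second, 3L, 1L))
  }
  out
}

#' Simulate a barcode dataset with known ground truth
#'
#' Draws a root sequence from the configured base frequencies, places
#' species ancestors on a random coalescent-shaped species tree rescaled so
#' the mean pairwise species divergence equals `inter_depth`, hangs each
#' specimen off its species ancestor at an exponential depth with mean
#' `intra_depth / 2` (a star genealogy within species), and evolves sequences
#' site-by-site under the Kimura two-parameter process at rate ratio
#' `kappa` — the same model family the distance estimator assumes, so
#' recovery checks are exact in expectation. Cryptic entries split a species
#' into two lineages whose ancestors sit `divergence` apart; discordant
#' pairs force two species' ancestors to `discordant_separation` apart so
#' they merge under threshold clustering. Genus and family labels are
#' obtained by cutting the species tree at `inter_depth` and
#' `2 * inter_depth`.
#'
#' @param config A [sim_config()].
#' @return A list with `alignment` (tibble: `specimen_id`, `sequence`),
#'   `taxonomy` (tibble: `specimen_id`, `species`, `genus`, `family`, `site`,
#'   `external_cluster_id`), and `truth` (tibble: `specimen_id`,
#'   `true_species`, `true_lineage`).
#' @export
simulate_barcodes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- config$n_species
  L <- config$seq_length
  kappa <- config$kappa

  counts <- config$specimens_per_species
  if (is.null(counts)) {
    counts <- if (ns == length(default_specimen_counts)) {
      default_specimen_counts
    } else {
      sample(default_specimen_counts, ns, replace = TRUE)
    }
  } else if (length(counts) == 1L) {
    counts <- rep(as.integer(counts), ns)
  } else if (length(counts) != ns) {
    stop("specimens_per_species must be NULL, length 1 or length n_species.",
         call. = FALSE)
  }
  counts <- as.integer(counts)
  stopifnot(all(counts >= 1))

  # root with the configured composition held exactly (rounded counts,
  # random site order): a multinomial draw would leave ~1-2% composition
  # noise at 600 bp that every descendant would inherit
  base_counts <- diff(c(0L, round(cumsum(config$base_freqs) * L)))
  root <- sample(rep.int(1:4, base_counts))
  if (config$enforce_orf) {
    # resample stop codons in frame 1 until the frame is open
    for (tries in 1:1000) {
      if (frame1_open(root)) break
      n_cod <- L %/% 3L
      m <- matrix(root[seq_len(3L * n_cod)], nrow = 3L)
      bad <- which(!vapply(seq_len(n_cod),
                           function(i) frame1_open(m[, i]), logical(1)))
      for (i in bad) {
        root[(3L * (i - 1L) + 1L):(3L * i)] <-
          sample.int(4L, 3L, replace = TRUE, prob = config$base_freqs)
      }
    }
    if (!frame1_open(root)) stop("Could not draw a stop-free root sequence.",
                                 call. = FALSE)
  }
  # branch evolution, optionally conditioned on keeping frame 1 open
  evolve_branch <- function(seq_int, d) {
    if (!config$enforce_orf) return(evolve_sequence(seq_int, d, kappa))
    for (tries in 1:1000) {
      out <- evolve_sequence(seq_int, d, kappa)
      if (frame1_open(out)) return(out)
    }
    stop("Could not evolve a stop-free sequence along a branch of length ",
         d, "; divergence too high for ORF-preserving simulation.",
         call. = FALSE)
  }

  # species ancestors along a rescaled coalescent species tree
  sp_label <- sprintf("Species%02d", seq_len(ns))
  if (ns == 1L) {
    ancestors <- list(root)
    genus <- "Genus01"
    family <- "Family01"
  } else {
    sp_tree <- ape::rcoal(ns, tip.label = sp_label)
    coph <- ape::cophenetic.phylo(sp_tree)
    scale <- config$inter_depth / mean(coph[upper.tri(coph)])
    sp_tree$edge.length <- sp_tree$edge.length * scale
    coph <- coph * scale
    # enforce the separation floor by lengthening every terminal branch
    min_sep <- min(coph[upper.tri(coph)])
    if (min_sep < config$min_separation) {
      bump <- (config$min_separation - min_sep) / 2
      tip_edges <- sp_tree$edge[, 2] <= ape::Ntip(sp_tree)
      sp_tree$edge.length[tip_edges] <- sp_tree$edge.length[tip_edges] + bump
      coph <- ape::cophenetic.phylo(sp_tree)
    }

    # evolve root-to-tip down the species tree, preorder over edges
    n_nodes <- ape::Ntip(sp_tree) + sp_tree$Nnode
    node_seq <- vector("list", n_nodes)
    node_seq[[ape::Ntip(sp_tree) + 1L]] <- root
    edges <- ape::reorder.phylo(sp_tree, "cladewise")
    for (e in seq_len(nrow(edges$edge))) {
      par <- edges$edge[e, 1]
      chd <- edges$edge[e, 2]
      node_seq[[chd]] <- evolve_branch(node_seq[[par]],
                                       edges$edge.length[e])
    }
    ancestors <- node_seq[match(sp_label, sp_tree$tip.label)]

    # nested genus/family labels by cutting the species tree
    hc <- stats::hclust(stats::as.dist(coph), method = "average")
    g_cut <- stats::cutree(hc, h = config$inter_depth)
    f_cut <- stats::cutree(hc, h = 2 * config$inter_depth)
    genus <- sprintf("Genus%02d", g_cut[sp_label])
    family <- sprintf("Family%02d", f_cut[sp_label])
  }

  # force discordant pairs: second species ancestor re-derived from the
  # first at sub-threshold separation
  for (dp in config$discordant_pairs) {
    stopifnot(length(dp) == 2, all(dp >= 1), all(dp <= ns))
    ancestors[[dp[2]]] <- evolve_branch(ancestors[[dp[1]]],
                                        config$discordant_separation)
  }

  cryptic_idx <- vapply(config$cryptic_species, function(cs) cs$species,
                        numeric(1))
  sites <- c("UDV", "ISB", "SRS", "IRU", "SJ1", "SJ2", "BRC", "CUP16",
             "CUP19", "CUP22")

  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    n_i <- counts[s]
    cs <- if (s %in% cryptic_idx) {
      config$cryptic_species[[match(s, cryptic_idx)]]
    } else NULL
    if (is.null(cs)) {
      lin_anc <- list(ancestors[[s]])
      lineage <- rep(1L, n_i)
    } else {
      half <- cs$divergence / 2
      lin_anc <- list(evolve_branch(ancestors[[s]], half),
                      evolve_branch(ancestors[[s]], half))
      n2 <- max(1L, min(n_i - 1L, round(cs$proportion * n_i)))
      lineage <- c(rep(1L, n_i - n2), rep(2L, n2))
    }
    depths <- if (config$intra_depth > 0) {
      stats::rexp(n_i, rate = 2 / config$intra_depth)
    } else rep(0, n_i)
    seqs <- vapply(seq_len(n_i), function(k) {
      paste(c("A", "C", "G", "T")[
        evolve_branch(lin_anc[[lineage[k]]], depths[k])],
        collapse = "")
    }, character(1))
    rows[[s]] <- tibble::tibble(
      specimen_id = sprintf("%s-%02d", sp_label[s], seq_len(n_i)),
      sequence = seqs,
      species = sp_label[s],
      genus = genus[s],
      family = family[s],
      site = sample(sites, n_i, replace = TRUE),
      true_lineage = sprintf("%s_L%d", sp_label[s], lineage)
    )
  }
  all_rows <- dplyr::bind_rows(rows)
  list(
    alignment = dplyr::select(all_rows, "specimen_id", "sequence"),
    taxonomy = dplyr::mutate(
      dplyr::select(all_rows, "specimen_id", "species", "genus", "family",
                    "site"),
      external_cluster_id = NA_character_
    ),
    truth = tibble::tibble(specimen_id = all_rows$specimen_id,
                           true_species = all_rows$species,
                           true_lineage = all_rows$true_lineage)
  )
}

#' Write a simulated dataset to disk
#'
#' Writes the FASTA and metadata TSV in the dialect [load_dataset()] reads,
#' plus a `truth.tsv` with the generating labels.
#'
#' @param sim Output of [simulate_barcodes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$alignment, file.path(dir, "sim.fasta"))
  write_metadata(sim$taxonomy, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
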