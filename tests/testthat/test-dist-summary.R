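test_that("base composition averages per-sequence percentages, excluding
           ambiguous sites", {
  one <- tibble::tibble(specimen_id = "s1", sequence = "ACGT")
  expect_equal(base_composition(one),
               tibble::tibble(pct_A = 25, pct_C = 25, pct_G = 25, pct_T = 25))
  two <- tibble::tibble(specimen_id = c("s1", "s2"),
                        sequence = c("AAAA", "CCCC"))
  expect_equal(base_composition(two)$pct_A, 50)
  expect_equal(base_composition(two)$pct_C, 50)
  expect_equal(base_composition(two)$pct_G, 0)
  ambig <- tibble::tibble(specimen_id = "s1", sequence = "AANN")
  expect_equal(base_composition(ambig)$pct_A, 100)
  # unweighted across sequences even when lengths differ
  uneq <- tibble::tibble(specimen_id = c("s1", "s2"),
                         sequence = c("A", "CCCCCCCC"))
  expect_equal(base_composition(uneq)$pct_A, 50)
})

test_that("rank summaries partition pairs into exclusive nested classes", {
  # 2 species x 2 specimens, same genus: 2 intraspecific + 4 intrageneric
  aln <- tibble::tibble(
    specimen_id = c("a1", "a2", "b1", "b2"),
    sequence = c(strrep("A", 200), strrep("A", 200),
                 paste0(strrep("A", 180), strrep("G", 20)),
                 paste0(strrep("A", 180), strrep("G", 20)))
  )
  tax <- tibble::tibble(specimen_id = aln$specimen_id,
                        species = c("X", "X", "Y", "Y"),
                        genus = "G", family = "F",
                        site = "UDV", external_cluster_id = NA)
  dm <- k2p_matrix(aln)
  rs <- rank_summaries(dm, tax)
  expect_equal(rs$n_comparisons[rs$rank == "intraspecific"], 2L)
  expect_equal(rs$n_comparisons[rs$rank == "intrageneric"], 4L)
  expect_equal(rs$n_comparisons[rs$rank == "intrafamilial"], 0L)
  expect_equal(rs$mean_pct[rs$rank == "intraspecific"], 0)
  expect_gt(rs$mean_pct[rs$rank == "intrageneric"], 0)
})

test_that("intraspecific comparison counts follow the combinatorial oracle
           and summaries match a double-loop reference", {
  withr::local_seed(41)
  n_per_species <- c(2L, 5L, 3L, 7L, 1L, 2L)
  ids <- sprintf("s%02d", seq_len(sum(n_per_species)))
  tax <- tibble::tibble(
    specimen_id = ids,
    species = rep(sprintf("Sp%d", seq_along(n_per_species)), n_per_species),
    genus = rep(c("G1", "G1", "G2", "G2", "G3", "G3"), n_per_species),
    family = rep(c("F1", "F1", "F1", "F2", "F2", "F2"), n_per_species),
    site = "UDV", external_cluster_id = NA
  )
  aln <- related_alignment(length(ids), 300)
  aln$specimen_id <- ids
  dm <- k2p_matrix(aln, dist_config(min_overlap = 10))
  rs <- rank_summaries(dm, tax)
  expect_equal(rs$n_comparisons[rs$rank == "intraspecific"],
               sum(choose(n_per_species, 2)))

  # independent double loop over the matrix
  ref <- list(intraspecific = c(), intrageneric = c(), intrafamilial = c())
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      d <- dm$d[i, j] * 100
      if (tax$species[i] == tax$species[j]) {
        ref$intraspecific <- c(ref$intraspecific, d)
      } else if (tax$genus[i] == tax$genus[j]) {
        ref$intrageneric <- c(ref$intrageneric, d)
      } else if (tax$family[i] == tax$family[j]) {
        ref$intrafamilial <- c(ref$intrafamilial, d)
      }
    }
  }
  for (r in names(ref)) {
    row <- rs[rs$rank == r, ]
    expect_equal(row$n_comparisons, length(ref[[r]]))
    expect_equal(row$mean_pct, mean(ref[[r]]))
    expect_equal(row$min_pct, min(ref[[r]]))
    expect_equal(row$max_pct, max(ref[[r]]))
  }
})

test_that("species reports: NND, nearest species, gap flag and singletons", {
  # X = {s1, s2} at 0.5%; Y at 4%; singleton Z far away
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.005
  d[1, 3] <- d[3, 1] <- 0.040
  d[2, 3] <- d[3, 2] <- 0.045
  d[1, 4] <- d[4, 1] <- d[2, 4] <- d[4, 2] <- 0.20
  d[3, 4] <- d[4, 3] <- 0.21
  dm <- dist_from_matrix(d, c("s1", "s2", "s3", "s4"))
  tax <- tibble::tibble(specimen_id = dm$ids,
                        species = c("X", "X", "Y", "Z"),
                        genus = "G", family = "F",
                        site = "UDV", external_cluster_id = NA)
  rep <- species_reports(dm, tax)
  x <- rep[rep$species == "X", ]
  expect_equal(x$mean_intra_pct, 0.5)
  expect_equal(x$nnd_pct, 4.0)
  expect_equal(x$nearest_species, "Y")
  expect_true(x$has_barcode_gap)
  z <- rep[rep$species == "Z", ]
  expect_true(is.na(z$mean_intra_pct))
  expect_equal(z$nnd_pct, 20)
  expect_true(z$has_barcode_gap)
  expect_equal(z$note, "insufficient_sampling")
})

test_that("a species whose max intraspecific distance exceeds its NND has no
           barcode gap", {
  # deep split inside W (20.48%) but a neighbor at 18.07%
  d <- matrix(0.25, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.2048
  d[1, 3] <- d[3, 1] <- 0.1807
  dm <- dist_from_matrix(d, c("w1", "w2", "v1"))
  tax <- tibble::tibble(specimen_id = dm$ids,
                        species = c("W", "W", "V"),
                        genus = c("Gw", "Gw", "Gv"),
                        family = "F", site = "UDV",
                        external_cluster_id = NA)
  rep <- species_reports(dm, tax)
  w <- rep[rep$species == "W", ]
  expect_equal(w$max_intra_pct, 20.48)
  expect_equal(w$nnd_pct, 18.07)
  expect_false(w$has_barcode_gap)
})

test_that("NND properties: species minimum equals global minimum and bounds
           all member distances", {
  withr::local_seed(42)
  aln <- related_alignment(20, 300)
  tax <- toy_taxonomy(aln$specimen_id, n_species = 5, n_genera = 3,
                      n_families = 2)
  dm <- k2p_matrix(aln, dist_config(min_overlap = 10))
  rep <- species_reports(dm, tax)
  pairs <- tidy(dm)
  sp_of <- stats::setNames(tax$species, tax$specimen_id)
  inter <- pairs[sp_of[pairs$id_a] != sp_of[pairs$id_b], ]
  expect_equal(min(rep$nnd_pct), min(inter$k2p_pct))
  for (s in rep$species) {
    member <- sp_of[pairs$id_a] == s | sp_of[pairs$id_b] == s
    cross <- member & (sp_of[pairs$id_a] != sp_of[pairs$id_b])
    expect_equal(rep$nnd_pct[rep$species == s], min(pairs$k2p_pct[cross]))
  }
})

test_that("flag_divergent returns species above threshold, sorted", {
  rep <- tibble::tibble(
    species = c("Knodus sp.1", "Aequidens epae", "Copella callolepis",
                "Hoplias malabaricus", "Quiet species"),
    n = c(14, 8, 18, 7, 5),
    mean_intra_pct = c(5.71, 2.97, 0.99, 0.7, 0.1),
    max_intra_pct = c(20.48, 7.99, 3.77, 2.48, 0.3),
    nnd_pct = c(18.07, 10.84, 21.54, 18.32, 9),
    nearest_species = "x", has_barcode_gap = TRUE, note = NA_character_
  )
  out <- flag_divergent(rep, 2.0)
  expect_equal(out$species, c("Knodus sp.1", "Aequidens epae",
                              "Copella callolepis", "Hoplias malabaricus"))
  expect_equal(out$max_intra_pct, c(20.48, 7.99, 3.77, 2.48))
  expect_equal(nrow(flag_divergent(rep, 25)), 0)
  expect_equal(nrow(flag_divergent(rep, 0)), 5)
})

test_that("barcode gap and rank distribution plots build", {
  withr::local_seed(43)
  aln <- related_alignment(12, 200)
  tax <- toy_taxonomy(aln$specimen_id, n_species = 4, n_genera = 2,
                      n_families = 2)
  dm <- k2p_matrix(aln, dist_config(min_overlap = 10))
  rep <- species_reports(dm, tax)
  expect_s3_class(plot_barcode_gap(rep), "ggplot")
  expect_s3_class(plot_distance_ranks(dm, tax), "ggplot")
})
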