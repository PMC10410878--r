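# Planted-motif simulator: class counts, plant fidelity, determinism, and
# the label-signal consistency invariant.

test_that("class counts are exact for the requested positive fraction", {
  sim <- simulate_pairs(200, seq_len = 60, positive_fraction = 0.5, seed = 7)
  expect_equal(sum(sim$label == 1), 100L)
  expect_equal(sum(sim$label == 0), 100L)
  sim2 <- simulate_pairs(50, seq_len = 60, positive_fraction = 0.3, seed = 7)
  expect_equal(sum(sim2$label == 1), 15L)
  s <- pairs_summary(sim)
  expect_equal(s$seq_len, 60L)
})

test_that("zero noise plants the motifs verbatim at the recorded offsets", {
  sim <- simulate_pairs(60, seq_len = 80, noise_rate = 0, seed = 9)
  motifs <- attr(sim, "sim")
  pos <- sim[sim$label == 1, ]
  expect_true(all(substr(pos$seq_a, pos$pos_a,
                         pos$pos_a + nchar(motifs$motif_a) - 1) ==
                    motifs$motif_a))
  expect_true(all(substr(pos$seq_b, pos$pos_b,
                         pos$pos_b + nchar(motifs$motif_b) - 1) ==
                    motifs$motif_b))
  # centered planting: one offset shared by all positives
  expect_equal(length(unique(pos$pos_a)), 1L)
  expect_equal(unique(pos$pos_a), floor((80 - 12) / 2) + 1L)
  # negatives carry exactly one decoy motif, never the compatible pair
  neg <- sim[sim$label == 0, ]
  expect_true(all(xor(is.na(neg$planted_a), is.na(neg$planted_b))))
  # without decoys, negatives are pure background
  sim_nd <- simulate_pairs(30, seq_len = 80, noise_rate = 0,
                           decoy_in_negatives = FALSE, seed = 9)
  neg_nd <- sim_nd[sim_nd$label == 0, ]
  expect_true(all(is.na(neg_nd$planted_a) & is.na(neg_nd$planted_b)))
})

test_that("generation is byte-identical for a seed and valid over ACGT", {
  d <- withr::local_tempdir()
  s1 <- simulate_pairs(40, seq_len = 50, seed = 123)
  s2 <- simulate_pairs(40, seq_len = 50, seed = 123)
  write_pairs(s1, file.path(d, "a.tsv"))
  write_pairs(s2, file.path(d, "b.tsv"))
  expect_identical(readLines(file.path(d, "a.tsv")),
                   readLines(file.path(d, "b.tsv")))
  s3 <- simulate_pairs(40, seq_len = 50, seed = 124)
  expect_false(identical(s1$seq_a, s3$seq_a))
  expect_false(any(grepl("[^ACGT]", c(s1$seq_a, s1$seq_b))))
})

test_that("generator rejects invalid settings", {
  expect_error(simulate_pairs(10, seq_len = 50, noise_rate = 1.5),
               "noise_rate")
  expect_error(simulate_pairs(10, seq_len = 10), "shorter than seq_len")
  expect_error(simulate_pairs(1, seq_len = 50), "n_pairs")
  expect_error(simulate_pairs(10, seq_len = 50, background_gc = -0.1),
               "background_gc")
})

test_that("signal strength reports exact-match fraction and Hamming distance", {
  clean <- simulate_pairs(100, seq_len = 60, noise_rate = 0, seed = 11)
  ss <- signal_strength(clean)
  pos_rows <- ss[ss$label == 1, ]
  expect_equal(pos_rows$exact_match_fraction, rep(1, nrow(pos_rows)))
  expect_equal(pos_rows$mean_hamming, rep(0, nrow(pos_rows)))

  # mean Hamming ~ Binomial(motif length, noise) within 3 standard errors
  noisy <- simulate_pairs(600, seq_len = 60, noise_rate = 0.1, seed = 12)
  ssn <- signal_strength(noisy)
  row <- ssn[ssn$label == 1 & ssn$branch == "a", ]
  expected <- 0.1 * 12
  se <- sqrt(12 * 0.1 * 0.9 / row$n_planted)
  expect_lt(abs(row$mean_hamming - expected), 3 * se)
  # substitution excludes the original base: full noise keeps nothing
  allnoise <- simulate_pairs(60, seq_len = 60, noise_rate = 1, seed = 13)
  ssa <- signal_strength(allnoise)
  expect_equal(max(ssa$exact_match_fraction), 0)
  expect_equal(ssa$mean_hamming[ssa$label == 1 & ssa$branch == "a"], 12)
})

test_that("condition pairs share or separate motifs as requested", {
  shared <- simulate_condition_pair(20, shared_motifs = TRUE, seq_len = 50,
                                    seed = 3)
  expect_named(shared, c("cellA", "cellB"))
  ma <- attr(shared$cellA, "sim"); mb <- attr(shared$cellB, "sim")
  expect_identical(ma$motif_a, mb$motif_a)
  expect_identical(ma$motif_b, mb$motif_b)
  expect_equal(unique(shared$cellA$cell_type), "cellA")

  disjoint <- simulate_condition_pair(20, shared_motifs = FALSE, seq_len = 50,
                                      seed = 3)
  da <- attr(disjoint$cellA, "sim"); db <- attr(disjoint$cellB, "sim")
  expect_false(da$motif_a == db$motif_a)
  expect_false(da$motif_b == db$motif_b)
  # construction forbids transfer: no shared 4-mer between condition motifs
  kmers <- function(s) {
    vapply(1:(nchar(s) - 3), function(i) substr(s, i, i + 3), character(1))
  }
  expect_length(intersect(c(kmers(da$motif_a), kmers(da$motif_b)),
                          c(kmers(db$motif_a), kmers(db$motif_b))), 0)
  expect_equal(nrow(disjoint$cellA), 20L)
  expect_equal(nrow(disjoint$cellB), 20L)
})

test_that("a trivial Hamming matcher separates the simulated classes", {
  # label-signal consistency independent of the neural model
  sim <- simulate_pairs(300, seq_len = 100, noise_rate = 0.1, seed = 21)
  motifs <- attr(sim, "sim")
  score <- -(motif_min_hamming(sim$seq_a, motifs$motif_a) +
               motif_min_hamming(sim$seq_b, motifs$motif_b))
  expect_gt(roc_auc(sim$label, score), 0.9)
})

test_that("plant-record sidecar JSON round-trips the generator settings", {
  sim <- simulate_pairs(20, seq_len = 50, seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_sidecar(sim, path)
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(side$config$motif_a, attr(sim, "sim")$motif_a)
  expect_equal(nrow(side$records), 20L)
  expect_error(write_sim_sidecar(random_pairs_tbl(4, 20), path),
               "not a simulated dataset")
})
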