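test_that("clusters on a small synthetic survey match generator truth", {
  cfg <- small_config(seed = 21)
  panel <- generate_reference_sequences(cfg)
  ss <- generate_specimen_set(cfg, panel)
  refs <- panel$panels$COI
  q <- ss$queries$COI
  combined <- seq_panel(c(refs$id, q$id), c(refs$residues, q$residues),
                        c(refs$species, q$species), "COI")
  tr <- bootstrap_support(combined, replicates = 200, seed = 2)
  cl <- extract_clusters(tr, refs, min_support = 99)

  expect_equal(length(setdiff(unique(cl$cluster_id), NA)), 5)
  truth <- setNames(ss$truth$true_species, ss$truth$id)
  queries <- cl[!cl$is_reference, ]
  expect_true(all(queries$species_call == truth[queries$id]))

  # unreachable threshold leaves queries unresolved
  cl101 <- extract_clusters(tr, refs, min_support = 101)
  expect_true(all(cl101$species_call[!cl101$is_reference] == "UNRESOLVED"))

  expect_error(extract_clusters(tr, refs[0, ], 99), "no reference")
})

test_that("a single-species tree collapses to one cluster of all leaves", {
  set.seed(4)
  base <- random_seq(150)
  panel <- seq_panel(paste0("r", 1:6),
                     vapply(1:6, function(i) mutate_seq(base, 2),
                            character(1)),
                     "Mobula_kuhlii", "COI")
  tr <- neighbor_joining(distance_matrix(panel))
  cl <- extract_clusters(tr, panel, min_support = 99)
  expect_equal(unique(cl$cluster_id), "C1")
  expect_true(all(cl$species_call == "Mobula_kuhlii"))
})

test_that("identity assignment follows the 99% threshold contract", {
  set.seed(6)
  ref_seq <- random_seq(100)
  refs <- seq_panel(c("ref_jap", "ref_kuh"),
                    c(ref_seq, mutate_seq(ref_seq, 10)),
                    c("Mobula_japanica", "Mobula_kuhlii"), "COI")

  hit <- assign_by_identity(seq_panel("q1", ref_seq), refs)
  expect_equal(hit$species, "Mobula_japanica")
  expect_equal(hit$identity, 1.0)
  expect_false(hit$tie)

  near <- assign_by_identity(seq_panel("q2", mutate_seq(ref_seq, 2)), refs)
  expect_equal(near$identity, 0.98)
  expect_equal(near$species, "UNASSIGNED") # 0.98 < default 0.99

  expect_equal(assign_by_identity(seq_panel("q2", mutate_seq(ref_seq, 2)),
                                  refs, min_identity = 0.95)$species,
               "Mobula_japanica")

  # exact tie: two identical references, first in panel order wins, flagged
  refs2 <- seq_panel(c("a", "b"), c(ref_seq, ref_seq),
                     c("SpA", "SpB"), "COI")
  tie <- assign_by_identity(seq_panel("q", ref_seq), refs2)
  expect_equal(tie$species, "SpA")
  expect_equal(tie$best_ref, "a")
  expect_true(tie$tie)

  expect_error(assign_by_identity(seq_panel("q", ref_seq), NULL), "empty")
})

test_that("generated queries are assigned to their true species", {
  cfg <- small_config(seed = 31)
  panel <- generate_reference_sequences(cfg)
  ss <- generate_specimen_set(cfg, panel)
  truth <- setNames(ss$truth$true_species, ss$truth$id)
  for (mk in c("COI", "NADH2")) {
    calls <- assign_by_identity(ss$queries[[mk]], panel$panels[[mk]])
    expect_true(all(calls$identity >= 0.99))
    expect_true(all(calls$species == truth[calls$id]))
  }
})

test_that("barcoding gap summarizes intra/inter ranges in percent", {
  # two species: two identical A sequences, one B at a hand-counted distance
  base <- paste(rep("ACGT", 25), collapse = "") # 100 sites
  bvar <- paste0(paste(rep("ACGT", 24), collapse = ""), "GTGT") # 2 transitions
  o <- oracle_counts(base, bvar)
  dexp <- 100 * oracle_k2p(o$P, o$Q)
  panel <- seq_panel(c("a1", "a2", "b1"), c(base, base, bvar),
                     c("SpA", "SpA", "SpB"), "COI")
  gap <- barcoding_gap(distance_matrix(panel),
                       setNames(panel$species, panel$id))
  expect_equal(gap$intra_min, 0)
  expect_equal(gap$intra_max, 0)
  expect_equal(gap$inter_min, dexp, tolerance = 1e-9)
  expect_equal(gap$inter_max, dexp, tolerance = 1e-9)
  expect_true(gap$gap)

  expect_error(barcoding_gap(distance_matrix(panel),
                             rep("UNKNOWN", 3)), "UNKNOWN")
  expect_error(barcoding_gap(distance_matrix(panel),
                             c("SpA", "SpA", "SpA")), "2 labelled species")
})

test_that("label permutation destroys the synthetic barcoding gap", {
  cfg <- small_config(seed = 13)
  panel <- generate_reference_sequences(cfg)
  refs <- panel$panels$COI
  dm <- distance_matrix(refs)
  labels <- setNames(refs$species, refs$id)
  expect_true(barcoding_gap(dm, labels)$gap)

  set.seed(99)
  broken <- 0
  for (i in 1:20) {
    shuffled <- setNames(sample(refs$species), refs$id)
    g <- barcoding_gap(dm, shuffled)
    if (!g$gap) broken <- broken + 1
  }
  expect_gte(broken, 18) # permutation collapses the gap w.h.p.
})
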