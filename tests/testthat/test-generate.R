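test_that("the generator is deterministic and hits the configured counts", {
  cfg <- generator_config(seed = 12)
  p1 <- generate_reference_sequences(cfg)
  p2 <- generate_reference_sequences(cfg)
  expect_identical(p1, p2)
  s1 <- generate_specimen_set(cfg, p1)
  s2 <- generate_specimen_set(cfg, p2)
  expect_identical(s1, s2)

  counts <- table(s1$specimens$true_species)
  expect_equal(as.integer(counts[names(cfg$species_counts)]),
               unname(as.integer(cfg$species_counts)))
  expect_equal(nrow(s1$specimens), 188)
  expect_equal(sum(!s1$specimens$has_sequence), round(0.16 * 188))
  # queries exist for exactly the sequenced specimens, ids match
  expect_setequal(s1$queries$COI$id, s1$specimens$id[s1$specimens$has_sequence])
  expect_equal(nchar(s1$queries$COI$residues[1]), 761)
  expect_equal(nchar(s1$queries$NADH2$residues[1]), 1033)
})

test_that("degenerate divergence settings behave as promised", {
  cfg0 <- small_config(seed = 2, intra_divergence = 0)
  p <- generate_reference_sequences(cfg0)
  for (mk in c("COI", "NADH2")) {
    refs <- p$panels[[mk]]
    for (sp in unique(refs$species))
      expect_length(unique(refs$residues[refs$species == sp]), 1)
  }

  cfgI <- small_config(seed = 2, ts_tv_ratio = Inf)
  pI <- generate_reference_sequences(cfgI)
  dm <- distance_matrix(pI$panels$COI)
  expect_true(all(dm$Q == 0)) # transversion-free by construction

  # unattainable targets must error, not silently saturate
  expect_error(generate_reference_sequences(
    small_config(seed = 2, marker_lengths = c(COI = 30, NADH2 = 30))),
    "unattainable|off target")
})

test_that("reference panels show a clean barcoding gap", {
  cfg <- generator_config(seed = 3)
  p <- generate_reference_sequences(cfg)
  for (mk in c("COI", "NADH2")) {
    refs <- p$panels[[mk]]
    gap <- barcoding_gap(distance_matrix(refs),
                         setNames(refs$species, refs$id))
    expect_true(gap$gap)
    expect_lte(gap$intra_max, 100 * cfg$intra_divergence + 0.2)
    expect_gte(gap$inter_min, 100 * cfg$inter_divergence[1] * 0.75)
    expect_lte(gap$inter_max, 100 * cfg$inter_divergence[2] * 1.25)
  }
})

test_that("empirical trait frequencies recover the configured marginals", {
  cfg <- generator_config(seed = 8,
                          species_counts = c(Mobula_japanica = 1030,
                                             Mobula_kuhlii = 250,
                                             Mobula_tarapacana = 270,
                                             Mobula_thurstoni = 120,
                                             Manta_birostris = 210))
  ss <- generate_specimen_set(cfg)
  prof <- cfg$trait_freqs
  for (tr in names(prof$freqs)) {
    m <- prof$freqs[[tr]]
    for (sp in prof$species) {
      n_sp <- sum(ss$specimens$true_species == sp)
      emp <- table(factor(ss$specimens[[tr]][ss$specimens$true_species == sp],
                          levels = colnames(m))) / n_sp
      tol <- pmax(0.03, 4 * sqrt(m[sp, ] * (1 - m[sp, ]) / n_sp))
      expect_true(all(abs(as.numeric(emp) - m[sp, ]) <= tol),
                  info = paste(tr, sp))
    }
  }
})

test_that("lengths and prices respect truncation; empty sets are empty", {
  ss <- generate_specimen_set(generator_config(seed = 14))
  fl <- as.matrix(ss$specimens[paste0("fl", 1:5)])
  expect_true(all(fl > 0))
  expect_true(all(ss$specimens$price_usd_kg >= 10))

  cfg0 <- generator_config(seed = 1, species_counts = c(Mobula_japanica = 0,
                                                        Mobula_kuhlii = 0))
  e <- generate_specimen_set(cfg0)
  expect_equal(nrow(e$specimens), 0)
  expect_null(e$queries)
})

test_that("unknown species in the mix raise a trait-table error", {
  prof <- mobulid_trait_profile()
  lt <- rbind(mobulid_length_table(),
              data.frame(species = "Mobula_mobular", length_mean = 40,
                         length_sd = 8))
  pp <- rbind(mobulid_market_table()[c("species", "price_mean", "price_sd")],
              data.frame(species = "Mobula_mobular", price_mean = 100,
                         price_sd = 20))
  pp$price_sd[is.na(pp$price_sd)] <- 10
  cfg <- generator_config(seed = 4,
                          species_counts = c(Mobula_mobular = 5,
                                             Mobula_kuhlii = 5),
                          length_params = lt, price_params = pp)
  expect_error(generate_specimen_set(cfg), "missing from trait tables")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(), "seed is mandatory")
  expect_error(generator_config(seed = 1, n_specimens = 10), "must equal")
  expect_error(generator_config(seed = 1, inter_divergence = c(0.004, 0.01)),
               "above the intra")
  expect_error(generator_config(seed = 1, dropout_rate = 2), "dropout")
})
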