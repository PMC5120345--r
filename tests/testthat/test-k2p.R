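test_that("substitution counting matches hand counts and contracts", {
  s <- count_substitutions("AAAA", "AAAA")
  expect_equal(unclass(s), list(n_sites = 4L, P = 0, Q = 0))

  s <- count_substitutions("AAAA", "AGAA") # A->G is a transition
  expect_equal(s$n_sites, 4L)
  expect_equal(s$P, 0.25)
  expect_equal(s$Q, 0)

  s <- count_substitutions("AAAA", "A-CA") # gap site dropped, A->C transversion
  expect_equal(s$n_sites, 3L)
  expect_equal(s$P, 0)
  expect_equal(s$Q, 1 / 3)

  expect_error(count_substitutions("AAA", "AAAA"), "unequal lengths")
  expect_error(count_substitutions("NNNN", "AAAA"), "no comparable sites")
  expect_error(count_substitutions(seq_panel("a", "ACGT", marker = "COI"),
                                   seq_panel("b", "ACGT", marker = "NADH2")),
               "different markers")
})

test_that("k2p_distance matches the closed form and rejects saturation", {
  expect_equal(k2p_distance(list(P = 0, Q = 0)), 0)
  expect_equal(k2p_distance(list(P = 0.25, Q = 0)), -0.5 * log(0.5),
               tolerance = 1e-12)
  expect_equal(k2p_distance(list(P = 0, Q = 0.25)),
               -0.5 * log(0.75) - 0.25 * log(0.5), tolerance = 1e-12)
  # frozen spec values
  expect_equal(round(k2p_distance(list(P = 0.25, Q = 0)), 5), 0.34657)
  expect_equal(round(k2p_distance(list(P = 0, Q = 0.25)), 5), 0.31713)

  expect_error(k2p_distance(list(P = 0.5, Q = 0.1)), "saturation")
  expect_error(k2p_distance(list(P = 0.1, Q = 0.5)), "saturation")
  expect_error(k2p_distance(list(P = -0.1, Q = 0)), "invalid")
})

test_that("k2p_distance is monotone in P and Q and linear near zero", {
  ps <- seq(0, 0.3, by = 0.03)
  qs <- seq(0, 0.2, by = 0.02)
  grid <- expand.grid(P = ps, Q = qs)
  grid <- grid[1 - 2 * grid$P - grid$Q > 0.05, ]
  d <- mapply(function(p, q) k2p_distance(list(P = p, Q = q)),
              grid$P, grid$Q)
  expect_equal(d, oracle_k2p(grid$P, grid$Q), tolerance = 1e-12)
  # monotone in P at fixed Q and in Q at fixed P
  for (q in qs) {
    dq <- d[grid$Q == q][order(grid$P[grid$Q == q])]
    expect_true(all(diff(dq) > 0))
  }
  for (p in ps) {
    dp <- d[grid$P == p][order(grid$Q[grid$P == p])]
    expect_true(all(diff(dp) > 0))
  }
  # first-order agreement: d ~ P + Q for small divergence
  small <- expand.grid(P = seq(0, 0.03, by = 0.005),
                       Q = seq(0, 0.02, by = 0.005))
  small <- small[small$P + small$Q <= 0.05, ]
  d <- mapply(function(p, q) k2p_distance(list(P = p, Q = q)),
              small$P, small$Q)
  expect_true(all(abs(d - (small$P + small$Q)) <=
                    2 * (small$P + small$Q)^2 + 1e-12))
})

test_that("distance_matrix agrees with the per-pair recount oracle", {
  set.seed(42)
  for (rep in 1:3) {
    panel <- random_panel(n = 20, L = 100)
    dm <- distance_matrix(panel)
    expect_equal(dm$d, t(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 20))
    for (pair in list(c(1, 2), c(3, 17), c(9, 20), c(5, 6))) {
      o <- oracle_counts(panel$residues[pair[1]], panel$residues[pair[2]])
      expect_equal(dm$n_sites[pair[1], pair[2]], o$n_sites)
      expect_equal(dm$P[pair[1], pair[2]], o$P)
      expect_equal(dm$Q[pair[1], pair[2]], o$Q)
      expect_equal(dm$d[pair[1], pair[2]], oracle_k2p(o$P, o$Q),
                   tolerance = 1e-12)
    }
    # independent library route (ape, K80, pairwise deletion)
    bin <- ape::as.DNAbin(lapply(setNames(panel$residues, panel$id),
                                 function(s) strsplit(tolower(s), "")[[1]]))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
    expect_equal(unname(dm$d), unname(ref[panel$id, panel$id]),
                 tolerance = 1e-8)
  }
})

test_that("pairwise deletion: shared all-gap columns never change distances", {
  set.seed(7)
  panel <- random_panel(n = 8, L = 80)
  d0 <- distance_matrix(panel)$d
  gapped <- seq_panel(panel$id,
                      paste0(substr(panel$residues, 1, 40), "-",
                             substr(panel$residues, 41, 80), "-"),
                      panel$species, "COI")
  expect_equal(distance_matrix(gapped)$d, d0)
})

test_that("distance exports carry the full pair information", {
  set.seed(3)
  panel <- random_panel(n = 5, L = 60)
  dm <- distance_matrix(panel)
  long <- distance_long(dm)
  expect_equal(nrow(long), choose(5, 2))
  expect_named(long, c("id1", "id2", "n_sites", "P", "Q", "d"))
  i <- which(long$id1 == "s2" & long$id2 == "s4")
  expect_equal(long$d[i], dm$d["s2", "s4"])

  f <- withr::local_tempfile(fileext = ".phy")
  write_distance_phylip(dm, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 5)
  expect_length(lines, 6)
})
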