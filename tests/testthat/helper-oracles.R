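# Independent oracles and fixture builders. Everything here is deliberately
# naive (per-site loops, closed forms) and shares no code with the package
# internals it checks.

# per-site recount of transition/transversion proportions, pairwise deletion
oracle_counts <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  acgt <- c("A", "C", "G", "T")
  ok <- ca %in% acgt & cb %in% acgt
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  purine <- function(x) x %in% c("A", "G")
  diff <- ca != cb
  ts <- sum(diff & (purine(ca) == purine(cb)))
  tv <- sum(diff) - ts
  list(n_sites = n, P = ts / n, Q = tv / n)
}

oracle_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                collapse = "")

# substitute k random sites with any different base (oracle-side mutator)
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a random panel with some N/gap noise for recount-oracle comparisons
random_panel <- function(n = 20, L = 100, miss_rate = 0.02) {
  base <- random_seq(L)
  seqs <- vapply(seq_len(n), function(i) {
    s <- mutate_seq(base, sample(0:8, 1))
    ch <- strsplit(s, "")[[1]]
    m <- runif(L) < miss_rate
    ch[m] <- sample(c("N", "-"), sum(m), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  seq_panel(paste0("s", seq_len(n)), seqs, "UNKNOWN", "COI")
}

# scaled-down five-species generator config for fast unit tests
small_config <- function(seed, ...) {
  generator_config(
    seed,
    species_counts = c(Mobula_japanica = 20, Mobula_kuhlii = 8,
                       Mobula_tarapacana = 8, Mobula_thurstoni = 6,
                       Manta_birostris = 8),
    ...
  )
}

# random unrooted tree with positive branch lengths; its path-length
# (cophenetic) matrix is additive by construction
random_additive_tree <- function(n_taxa) {
  tr <- ape::unroot(ape::rtree(n_taxa))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  tr
}
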