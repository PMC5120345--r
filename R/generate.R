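#' Configuration for the synthetic market-survey generator
#'
#' The generator emulates a dried gill-raker market survey with the
#' published statistical structure: the five-species mix (103/25/27/12/21
#' specimens), per-species filament-length and price Normals, published
#' categorical trait frequencies, and two-marker sequence sets whose
#' within-species K2P divergence stays below ~1% while between-species
#' divergence sits in the 4-13% band.
#'
#' @param seed integer RNG seed (mandatory; all outputs are reproducible
#'   per seed).
#' @param species_counts named integer vector of specimens per species.
#' @param n_specimens total specimens; must equal `sum(species_counts)`.
#' @param marker_lengths named lengths of the aligned markers (bp).
#' @param intra_divergence target within-species K2P divergence (fraction).
#' @param inter_divergence length-2 range of between-species K2P targets.
#' @param ts_tv_ratio transitions per transversion among introduced
#'   substitutions (`Inf` = transitions only).
#' @param length_params data.frame `species`, `length_mean`, `length_sd`
#'   (mm).
#' @param trait_freqs a `trait_profile` supplying categorical frequencies.
#' @param price_params data.frame `species`, `price_mean`, `price_sd`
#'   (US$/kg); the default substitutes sd = 10 for *Mobula kuhlii*, whose
#'   published price rests on a single observation.
#' @param dropout_rate fraction of specimens without sequences (default
#'   0.16, the published unidentified/collected ratio).
#' @param n_ref_haplotypes reference haplotypes per species and marker
#'   (>= 2).
#' @param city_probs named sampling probabilities for the survey cities.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             species_counts = NULL,
                             n_specimens = NULL,
                             marker_lengths = c(COI = 761L, NADH2 = 1033L),
                             intra_divergence = 0.006,
                             inter_divergence = c(0.04, 0.13),
                             ts_tv_ratio = 2,
                             length_params = mobulid_length_table(),
                             trait_freqs = mobulid_trait_profile(),
                             price_params = NULL,
                             dropout_rate = 0.16,
                             n_ref_haplotypes = 3,
                             city_probs = c(Guangzhou = 0.60,
                                            Zhanjiang = 0.15, Beihai = 0.10,
                                            Zhapo = 0.05, Shanwei = 0.10)) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.null(species_counts)) {
    mt <- mobulid_market_table()
    species_counts <- setNames(mt$n, mt$species)
  }
  if (is.null(n_specimens)) n_specimens <- sum(species_counts)
  if (n_specimens != sum(species_counts))
    stop("n_specimens must equal sum(species_counts)")
  if (any(species_counts < 0)) stop("species counts must be >= 0")
  if (is.null(price_params)) {
    mt <- mobulid_market_table()
    mt$price_sd[is.na(mt$price_sd)] <- 10
    price_params <- mt[c("species", "price_mean", "price_sd")]
  }
  stopifnot(intra_divergence >= 0, intra_divergence < 1,
            length(inter_divergence) == 2,
            all(inter_divergence > 0), all(inter_divergence < 1),
            inter_divergence[1] <= inter_divergence[2],
            ts_tv_ratio >= 0, dropout_rate >= 0, dropout_rate <= 1,
            n_ref_haplotypes >= 2)
  if (inter_divergence[1] <= intra_divergence)
    stop("inter-divergence range must lie above the intra-divergence target")
  structure(list(seed = seed, n_specimens = as.integer(n_specimens),
                 species_counts = species_counts,
                 marker_lengths = marker_lengths,
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 ts_tv_ratio = ts_tv_ratio, length_params = length_params,
                 trait_freqs = trait_freqs, price_params = price_params,
                 dropout_rate = dropout_rate,
                 n_ref_haplotypes = as.integer(n_ref_haplotypes),
                 city_probs = city_probs),
            class = "generator_config")
}

# mutate `codes` at `sites` (1-based), transition with probability
# R/(R+1); transversion target picked uniformly between the two candidates
.mutate_sites <- function(codes, sites, ts_tv_ratio) {
  if (length(sites) == 0) return(codes)
  p_ts <- if (is.infinite(ts_tv_ratio)) 1 else ts_tv_ratio / (ts_tv_ratio + 1)
  is_ts <- runif(length(sites)) < p_ts
  shift <- ifelse(is_ts, 2L, sample(c(1L, 3L), length(sites), replace = TRUE))
  codes[sites] <- bitwXor(codes[sites], shift)
  codes
}

#' Generate a reference sequence panel
#'
#' Builds, per marker, a random ancestral sequence and five species
#' consensus sequences by placing substitutions at disjoint random sites so
#' that pairwise between-species K2P distances land in the configured
#' range; each species then receives `n_ref_haplotypes` reference
#' haplotypes within the intra-species divergence target of its consensus.
#' Realized consensus-to-consensus K2P distances are verified within 25% of
#' their targets before returning.
#'
#' @param cfg a [generator_config()].
#' @return Object of class `reference_panel`: list with `panels` (one
#'   [seq_panel()] per marker), `consensus` (named residue strings per
#'   marker) and `config`.
#' @export
generate_reference_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  species <- names(cfg$species_counts)
  S <- length(species)

  # per-species root-to-consensus K2P targets: arithmetic ladder whose
  # pairwise sums stay inside the configured range. The ladder starts well
  # above the range floor so every species keeps a long consensus stem
  # (many diagnostic sites); short stems erode bootstrap support for the
  # smallest-divergence species.
  lo <- cfg$inter_divergence[1] + 0.3 * diff(cfg$inter_divergence)
  hi <- cfg$inter_divergence[2] - 0.1 * diff(cfg$inter_divergence)
  if (S >= 3) {
    s <- (hi - lo) / (2 * S - 4)
    a <- (lo - s) / 2
    e <- a + (seq_len(S) - 1) * s
  } else if (S == 2) {
    e <- rep((lo + hi) / 4, 2)
  } else {
    e <- lo / 2
  }

  panels <- list()
  consensus <- list()
  for (mk in names(cfg$marker_lengths)) {
    L <- cfg$marker_lengths[[mk]]
    anc <- sample(0:3, L, replace = TRUE)
    p_exp <- 0.75 * (1 - exp(-4 * e / 3)) # expected site-difference fraction
    k <- pmax(1L, round(L * p_exp))
    if (sum(k) > L)
      stop("divergence targets unattainable for sequence length ", L)
    all_sites <- sample.int(L, sum(k))
    split_at <- rep(seq_len(S), k)
    cons <- lapply(seq_len(S), function(i)
      .mutate_sites(anc, all_sites[split_at == i], cfg$ts_tv_ratio))
    names(cons) <- species

    kmax <- floor(L * cfg$intra_divergence / 2)
    ids <- character(0); seqs <- character(0); labs <- character(0)
    for (i in seq_len(S)) {
      for (h in seq_len(cfg$n_ref_haplotypes)) {
        u <- if (kmax > 0) sample.int(kmax + 1, 1) - 1L else 0L
        hap <- .mutate_sites(cons[[i]], sample.int(L, u), cfg$ts_tv_ratio)
        ids <- c(ids, sprintf("REF_%s_%s_h%d", species[i], mk, h))
        labs <- c(labs, species[i])
        seqs <- c(seqs, .decode_seq(hap))
      }
    }
    panel <- seq_panel(ids, seqs, labs, mk)

    cons_str <- vapply(cons, .decode_seq, character(1))
    if (S >= 2) {
      cdm <- distance_matrix(seq_panel(species, cons_str, species, mk))
      for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) {
        target <- e[i] + e[j]
        if (abs(cdm$d[i, j] - target) > 0.25 * target)
          stop("realized inter-species divergence off target for ",
               species[i], " / ", species[j], " (", mk, ")")
      }
    }
    panels[[mk]] <- panel
    consensus[[mk]] <- cons_str
  }
  structure(list(panels = panels, consensus = consensus, config = cfg),
            class = "reference_panel")
}

#' Generate a synthetic specimen set (morphology, prices, sequences)
#'
#' Draws `n_specimens` gill-raker plates with the configured species mix:
#' per specimen, a plate-level mean length from the species Normal
#' (truncated at 2 mm) with 5 measured points jittered at 5% of the plate
#' mean; categorical traits sampled independently from the species
#' frequency rows; price from the species Normal truncated at 10 US$/kg; a
#' survey city; and - unless the specimen is one of the `dropout_rate`
#' fraction without amplifiable DNA, and a panel is supplied - one query
#' sequence per marker mutated from a random conspecific reference
#' haplotype within the intra-species divergence target. Query sequence ids
#' equal specimen ids. Byte-identical outputs for identical config + seed.
#'
#' @param cfg a [generator_config()].
#' @param panel a `reference_panel` from [generate_reference_sequences()],
#'   or `NULL` to generate morphology only.
#' @return Object of class `specimen_set`: list with `specimens` (specimen
#'   data.frame incl. `true_species`, `has_sequence`), `queries` (one
#'   unlabelled [seq_panel()] per marker, or `NULL`), `truth` and `config`.
#' @export
generate_specimen_set <- function(cfg, panel = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(panel) && !inherits(panel, "reference_panel"))
    stop("panel must be a reference_panel (or NULL)")
  species <- names(cfg$species_counts)
  prof <- cfg$trait_freqs
  missing_sp <- setdiff(species[cfg$species_counts > 0], prof$species)
  if (length(missing_sp))
    stop("species in counts missing from trait tables: ",
         paste(missing_sp, collapse = ", "))
  set.seed(cfg$seed + 1L)

  n <- cfg$n_specimens
  if (n == 0) {
    df <- data.frame(id = character(0), fl1 = numeric(0), fl2 = numeric(0),
                     fl3 = numeric(0), fl4 = numeric(0), fl5 = numeric(0),
                     arrangement = character(0), color = character(0),
                     middle_lobe = character(0), terminal_lobe = character(0),
                     price_usd_kg = numeric(0), city = character(0),
                     true_species = character(0), has_sequence = logical(0),
                     stringsAsFactors = FALSE)
    return(structure(list(specimens = df, queries = NULL,
                          truth = df[c("id", "true_species")], config = cfg),
                     class = "specimen_set"))
  }

  sp <- rep(species, cfg$species_counts)
  id <- sprintf("GR%04d", seq_len(n))
  li <- match(sp, cfg$length_params$species)
  if (anyNA(li)) stop("species missing from length_params")
  plate <- truncnorm::rtruncnorm(n, a = 2,
                                 mean = cfg$length_params$length_mean[li],
                                 sd = cfg$length_params$length_sd[li])
  pts <- matrix(plate, n, 5) +
    matrix(rnorm(5 * n, 0, 0.05 * plate), n, 5)
  pts <- pmax(pts, 0.1)

  spi <- match(sp, prof$species)
  traits <- lapply(names(prof$freqs), function(tr) {
    m <- prof$freqs[[tr]]
    vapply(spi, function(i)
      sample(colnames(m), 1, prob = m[i, ]), character(1))
  })
  names(traits) <- names(prof$freqs)

  pi <- match(sp, cfg$price_params$species)
  if (anyNA(pi)) stop("species missing from price_params")
  price <- truncnorm::rtruncnorm(n, a = 10,
                                 mean = cfg$price_params$price_mean[pi],
                                 sd = cfg$price_params$price_sd[pi])
  city <- sample(names(cfg$city_probs), n, replace = TRUE,
                 prob = cfg$city_probs)

  nd <- round(cfg$dropout_rate * n)
  no_seq <- if (nd > 0) sample.int(n, nd) else integer(0)
  has_seq <- !(seq_len(n) %in% no_seq)

  queries <- NULL
  if (!is.null(panel)) {
    queries <- list()
    for (mk in names(cfg$marker_lengths)) {
      refs <- panel$panels[[mk]]
      if (is.null(refs)) next
      L <- cfg$marker_lengths[[mk]]
      kmax <- floor(L * cfg$intra_divergence / 2)
      ref_codes <- .seq_codes(refs$residues)
      qseqs <- character(0); qids <- character(0)
      for (i in which(has_seq)) {
        cand <- which(refs$species == sp[i])
        if (length(cand) == 0)
          stop("no reference haplotypes for species ", sp[i])
        src <- cand[sample.int(length(cand), 1)]
        u <- if (kmax > 0) sample.int(kmax + 1, 1) - 1L else 0L
        q <- .mutate_sites(ref_codes[, src], sample.int(L, u),
                           cfg$ts_tv_ratio)
        qids <- c(qids, id[i])
        qseqs <- c(qseqs, .decode_seq(q))
      }
      queries[[mk]] <- if (length(qids))
        seq_panel(qids, qseqs, "UNKNOWN", mk) else NULL
    }
  }

  df <- data.frame(id = id, fl1 = pts[, 1], fl2 = pts[, 2], fl3 = pts[, 3],
                   fl4 = pts[, 4], fl5 = pts[, 5],
                   arrangement = traits$arrangement, color = traits$color,
                   middle_lobe = traits$middle_lobe,
                   terminal_lobe = traits$terminal_lobe,
                   price_usd_kg = price, city = city, true_species = sp,
                   has_sequence = has_seq, stringsAsFactors = FALSE)
  structure(list(specimens = validate_specimens(df), queries = queries,
                 truth = df[c("id", "true_species")], config = cfg),
            class = "specimen_set")
}
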