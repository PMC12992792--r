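# Seeded ground-truth generators for all three data modalities. Every
# generator is a pure function of (configuration, seed): identical inputs
# give identical outputs.

#' Simulate a matrix-format yeast two-hybrid screen
#'
#' Generates plate-style colony observations for the full ordered bait x
#' prey construct grid of a screen design, together with complete ground
#' truth. True interacting pairs are detectable in a random subset of their
#' configurations (tag fusions may mask a binding surface, so a true pair
#' can be orientation-specifically undetectable); detectable configurations
#' have a per-position detection probability. Colony sizes are drawn from
#' two beta modes on \[0, 1\] (background mean ~0.1, full growth mean ~0.8).
#' Auto-active baits grow without prey (and on no-prey control plates);
#' sticky preys grow with most baits. Each bait strain is screened in 2-3
#' biological replicates; each prey is stamped in 3-4 technical positions.
#'
#' @param design a [screen_design()]; default the 11-gene, five-species
#'   piRNA-pathway design.
#' @param true_pairs character vector of true-interaction `pair_id`s, or
#'   NULL to sample `n_true` pairs uniformly.
#' @param n_true number of true pairs when `true_pairs` is NULL.
#' @param p_config_detectable probability that a configuration of a true
#'   pair is detectable at all.
#' @param detect_prob_range per-position detection probability of a
#'   detectable configuration, drawn uniformly from this range.
#' @param fp_rate probability that a background position grows to full size.
#' @param n_auto_baits,n_auto_preys number of planted auto-active bait /
#'   sticky prey constructs.
#' @param auto_signal per-position growth probability of auto-active
#'   constructs.
#' @param bio_reps,tech_reps candidate biological-replicate counts per bait
#'   and technical positions per prey (sampled per construct).
#' @param control_positions no-prey control positions per bait and
#'   biological replicate.
#' @param size_shapes list with `neg` and `pos` beta shape pairs for the
#'   background and full-growth colony-size modes.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with `observations` (bait_id, prey_id, bio_rep, position,
#'   colony_size), `controls` (bait_id, bio_rep, position, colony_size),
#'   and `truth`: `true_pairs` (pair_id, n_detectable,
#'   n_detectable_clean = detectable configurations not involving an
#'   auto-active construct, min/mean detection probability),
#'   `auto_baits`, `auto_preys`, and the per-configuration `config_detect`
#'   table.
#' @export
simulate_y2h <- function(design = default_screen_design(),
                         true_pairs = NULL, n_true = 199L,
                         p_config_detectable = 0.8,
                         detect_prob_range = c(0.6, 0.95),
                         fp_rate = 0.005,
                         n_auto_baits = 10L, n_auto_preys = 2L,
                         auto_signal = 0.9,
                         bio_reps = 2:3, tech_reps = 3:4,
                         control_positions = 4L,
                         size_shapes = list(neg = c(1.5, 13), pos = c(8, 2)),
                         seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  set.seed(seed)
  cs <- design$constructs
  baits <- cs$construct_id[cs$role == "bait"]
  preys <- cs$construct_id[cs$role == "prey"]
  pairs <- enumerate_pairs(design)

  if (is.null(true_pairs)) {
    true_pairs <- sample(pairs$pair_id, min(n_true, nrow(pairs)))
  } else if (!all(true_pairs %in% pairs$pair_id)) {
    abort("true pair outside the design: %s",
          true_pairs[!true_pairs %in% pairs$pair_id][1L])
  }
  auto_baits <- sort(sample(baits, n_auto_baits))
  auto_preys <- sort(sample(preys, n_auto_preys))
  nbio <- stats::setNames(sample(bio_reps, length(baits), replace = TRUE),
                          baits)
  ntech <- stats::setNames(sample(tech_reps, length(preys), replace = TRUE),
                           preys)

  cfg <- expand.grid(prey_id = preys, bait_id = baits,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cfg <- cfg[, c("bait_id", "prey_id")]
  b <- match(cfg$bait_id, cs$construct_id)
  p <- match(cfg$prey_id, cs$construct_id)
  cfg$pair_id <- canonical_pairs(cs$gene[b], cs$species[b],
                                 cs$gene[p], cs$species[p])$pair_id
  cfg$is_true <- cfg$pair_id %in% true_pairs
  cfg$detectable <- cfg$is_true &
    stats::runif(nrow(cfg)) < p_config_detectable
  cfg$detect_prob <- ifelse(
    cfg$detectable,
    stats::runif(nrow(cfg), detect_prob_range[1L], detect_prob_range[2L]),
    0)

  # expand configurations to stamped positions
  nb <- nbio[cfg$bait_id]
  nt <- ntech[cfg$prey_id]
  per_cfg <- nb * nt
  idx <- rep(seq_len(nrow(cfg)), per_cfg)
  j <- sequence(per_cfg) - 1L
  obs <- data.frame(
    bait_id = cfg$bait_id[idx],
    prey_id = cfg$prey_id[idx],
    bio_rep = as.integer(j %/% nt[idx] + 1L),
    position = as.integer(j %% nt[idx] + 1L),
    stringsAsFactors = FALSE)
  p_signal <- cfg$detect_prob[idx]
  p_signal[obs$bait_id %in% auto_baits] <- auto_signal
  is_auto_prey <- obs$prey_id %in% auto_preys
  p_signal[is_auto_prey] <- pmax(p_signal[is_auto_prey], auto_signal)
  grows <- stats::runif(nrow(obs)) < p_signal |
    stats::runif(nrow(obs)) < fp_rate
  obs$colony_size <- ifelse(
    grows,
    stats::rbeta(nrow(obs), size_shapes$pos[1L], size_shapes$pos[2L]),
    stats::rbeta(nrow(obs), size_shapes$neg[1L], size_shapes$neg[2L]))

  # no-prey control plates per bait strain
  nb_ctl <- nbio[baits]
  ctl_idx <- rep(seq_along(baits), nb_ctl * control_positions)
  jc <- sequence(nb_ctl * control_positions) - 1L
  controls <- data.frame(
    bait_id = baits[ctl_idx],
    bio_rep = as.integer(jc %/% control_positions + 1L),
    position = as.integer(jc %% control_positions + 1L),
    stringsAsFactors = FALSE)
  ctl_signal <- ifelse(controls$bait_id %in% auto_baits, auto_signal, 0)
  ctl_grows <- stats::runif(nrow(controls)) < ctl_signal
  controls$colony_size <- ifelse(
    ctl_grows,
    stats::rbeta(nrow(controls), size_shapes$pos[1L], size_shapes$pos[2L]),
    stats::rbeta(nrow(controls), size_shapes$neg[1L], size_shapes$neg[2L]))

  clean <- !(cfg$bait_id %in% auto_baits | cfg$prey_id %in% auto_preys)
  tp <- cfg[cfg$is_true, , drop = FALSE]
  truth_pairs <- data.frame(
    pair_id = sort(unique(tp$pair_id)),  # tapply below sorts by key
    stringsAsFactors = FALSE)
  truth_pairs$n_configs <- as.integer(tapply(rep(1L, nrow(tp)),
                                             tp$pair_id, sum))
  truth_pairs$n_detectable <- as.integer(tapply(tp$detectable,
                                                tp$pair_id, sum))
  truth_pairs$n_detectable_clean <- as.integer(
    tapply(tp$detectable & clean[cfg$is_true], tp$pair_id, sum))
  truth_pairs$min_detect_prob <- as.numeric(tapply(
    ifelse(tp$detectable, tp$detect_prob, NA_real_), tp$pair_id,
    function(z) if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE)))

  list(observations = obs, controls = controls,
       truth = list(true_pairs = truth_pairs, auto_baits = auto_baits,
                    auto_preys = auto_preys, config_detect = cfg),
       seed = seed)
}

#' Simulate cross-species call matrices with planted trajectory labels
#'
#' Generates species x species interaction call matrices for synthetic gene
#' pairs under the four generative trajectory models: `conserved` (signal in
#' every cell), `coevolving` (signal probability decaying logistically with
#' divergence time; with the default sharp scale this is signal for close
#' relatives only), `species_restricted` (signal confined to the cells where
#' one randomly chosen gene's ortholog comes from at most `k_species`
#' species), and `not_detected` (no signal). Noise is signal dropout: each
#' signal cell is observed positive with probability `1 - noise`. A separate
#' false-positive rate (default 0) can flip background cells.
#'
#' @param n_pairs number of simulated gene pairs.
#' @param mix named label probabilities (names from the four labels above).
#' @param noise signal-cell dropout probability.
#' @param design a [screen_design()] supplying the species universe and
#'   divergence matrix; default: the five-species roster with a generic
#'   two-gene roster and no absences.
#' @param fp_rate background false-positive probability per cell.
#' @param midpoint,scale logistic decay parameters (My) of the coevolving
#'   model.
#' @param k_species species support of the species-restricted model (1 or 2,
#'   sampled per pair).
#' @param seed integer seed.
#' @return list with `matrices` (list of 0/1 matrices), `labels`
#'   (planted labels), and `design`.
#' @export
simulate_trajectory_matrices <- function(n_pairs = 200L,
                                         mix = c(conserved = 0.25,
                                                 coevolving = 0.25,
                                                 species_restricted = 0.25,
                                                 not_detected = 0.25),
                                         noise = 0.1,
                                         design = NULL,
                                         fp_rate = 0,
                                         midpoint = 9, scale = 1,
                                         k_species = 1:2,
                                         seed = 1L) {
  allowed <- c("conserved", "coevolving", "species_restricted",
               "not_detected")
  if (!all(names(mix) %in% allowed) || any(mix < 0) || sum(mix) <= 0)
    abort("mix must be non-negative weights over: %s",
          paste(allowed, collapse = ", "))
  if (is.null(design)) {
    base <- default_screen_design()
    design <- screen_design(species = stats::setNames(base$species$name,
                                                      base$species$species_id),
                            genes = c("GeneA", "GeneB"),
                            divergence = base$divergence)
  }
  set.seed(seed)
  sp <- design$species$species_id
  dv <- design$divergence
  ns <- length(sp)
  labels <- sample(names(mix), n_pairs, replace = TRUE,
                   prob = mix / sum(mix))
  d <- dv[sp, sp]
  matrices <- lapply(labels, function(lab) {
    q <- switch(lab,
      conserved = matrix(1, ns, ns),
      coevolving = stats::plogis((midpoint - d) / scale),
      species_restricted = {
        q0 <- matrix(0, ns, ns)
        k <- sample(k_species, 1L)
        who <- sample(sp, k)
        if (stats::runif(1) < 0.5) q0[sp %in% who, ] <- 1
        else q0[, sp %in% who] <- 1
        q0
      },
      not_detected = matrix(0, ns, ns))
    p <- 1 - (1 - q * (1 - noise)) * (1 - fp_rate)
    m <- matrix(stats::rbinom(ns * ns, 1L, p), ns, ns,
                dimnames = list(sp, sp))
    m
  })
  list(matrices = matrices, labels = labels, design = design, seed = seed)
}

#' Simulate a diverged in-frame codon sequence pair
#'
#' Draws an ancestor of sense codons and evolves two independent descendant
#' lineages. Substitution attempts arrive as a Poisson process with expected
#' `divergence / 2` attempts per codon per lineage; each attempt mutates one
#' random position of one random codon to another base (transitions weighted
#' by `kappa`). Attempts creating stop codons are rejected. Selection is
#' encoded by relative acceptance: synonymous attempts are accepted with
#' probability `1 / max(1, omega)`, nonsynonymous with `omega / max(1,
#' omega)`, so `omega = 1` treats both classes identically and `omega = 0`
#' forbids amino-acid change. This is a deliberately simple
#' mutation-acceptance scheme (not a full codon substitution model); its
#' adequacy is established by the omega-recovery calibration tests.
#'
#' @param n_codons number of codons.
#' @param omega true dN/dS (> 0).
#' @param divergence expected attempted substitutions per codon, pair total.
#' @param kappa transition/transversion weight (1 = unweighted).
#' @param seed integer seed.
#' @inheritParams codon_sites
#' @return list with `alignment` (a `codon_alignment`: `seq1`, `seq2`,
#'   `names`) and `truth` (accepted synonymous/nonsynonymous substitution
#'   counts per lineage and the generating parameters).
#' @export
simulate_codon_pair <- function(n_codons = 500L, omega = 1,
                                divergence = 0.2, kappa = 1,
                                seed = 1L, code = NULL) {
  if (omega < 0) abort("omega must be >= 0")
  if (divergence < 0) abort("divergence must be >= 0")
  set.seed(seed)
  cd <- .code(code)
  sense <- .sense_codons(code)
  ancestor <- sample(sense, n_codons, replace = TRUE)
  p_syn <- 1 / max(1, omega)
  p_non <- omega / max(1, omega)
  transition <- c(A = "G", G = "A", C = "T", T = "C")

  evolve <- function(seqs) {
    n_attempts <- stats::rpois(1L, divergence / 2 * n_codons)
    n_s <- 0L; n_n <- 0L
    for (a in seq_len(n_attempts)) {
      i <- sample.int(n_codons, 1L)
      pos <- sample.int(3L, 1L)
      old <- seqs[i]
      nt <- strsplit(old, "")[[1L]]
      alt <- .bases[.bases != nt[pos]]
      w <- ifelse(alt == transition[[nt[pos]]], kappa, 1)
      nt[pos] <- sample(alt, 1L, prob = w)
      new <- paste(nt, collapse = "")
      if (cd[new] == "*") next
      syn <- cd[new] == cd[old]
      if (stats::runif(1) < (if (syn) p_syn else p_non)) {
        seqs[i] <- new
        if (syn) n_s <- n_s + 1L else n_n <- n_n + 1L
      }
    }
    list(seqs = seqs, n_syn = n_s, n_nonsyn = n_n)
  }
  l1 <- evolve(ancestor)
  l2 <- evolve(ancestor)
  aln <- structure(list(seq1 = paste(l1$seqs, collapse = ""),
                        seq2 = paste(l2$seqs, collapse = ""),
                        names = c("lineage1", "lineage2")),
                   class = "codon_alignment")
  list(alignment = aln,
       truth = list(n_syn_1 = l1$n_syn, n_nonsyn_1 = l1$n_nonsyn,
                    n_syn_2 = l2$n_syn, n_nonsyn_2 = l2$n_nonsyn,
                    omega = omega, divergence = divergence, seed = seed))
}

#' Simulate a co-IP/MS protein-group intensity table
#'
#' Emulates the structure of a label-free co-IP proteomics experiment: one
#' or more bait IP groups and a GFP control group, each with `n_bio`
#' biological x `n_tech` technical replicates; protein-group baseline
#' abundances on the log2 scale; bait-specific planted linear fold
#' enrichment; a GFP reference protein group present (never missing) in all
#' samples; and intensity-dependent missingness (low-abundance protein
#' groups drop out more often).
#'
#' @param n_proteins number of protein groups (including the reference).
#' @param baits character vector of bait group names.
#' @param control control group name.
#' @param n_enriched planted enriched protein groups per bait.
#' @param fold linear fold enrichment of planted proteins.
#' @param cv coefficient of variation of biological replicates (linear
#'   scale).
#' @param base_mean,base_sd log2 baseline abundance distribution.
#' @param missing_rate overall target missingness rate in \[0, 1\];
#'   1 means everything (except the reference) is missing.
#' @param n_bio,n_tech replicate structure.
#' @param reference reference protein-group id.
#' @param seed integer seed.
#' @return list with `intensities` (linear-scale matrix, NA = not
#'   detected), `meta` (sample, group, bio_rep, tech_rep) and `truth`
#'   (`enriched`: data.frame of bait, protein, fold).
#' @export
simulate_coip <- function(n_proteins = 300L, baits = "baitA",
                          control = "GFP", n_enriched = 12L, fold = 8,
                          cv = 0.1, base_mean = 25, base_sd = 2,
                          missing_rate = 0.1, n_bio = 4L, n_tech = 2L,
                          reference = "eGFP", seed = 1L) {
  if (fold <= 0) abort("fold effects must be > 0")
  if (missing_rate < 0 || missing_rate > 1)
    abort("missing_rate must be in [0, 1]")
  if (n_enriched > n_proteins - 1L)
    abort("enriched set larger than the number of protein groups")
  set.seed(seed)
  proteins <- c(reference,
                sprintf("PG%04d", seq_len(n_proteins - 1L)))
  mu <- stats::rnorm(n_proteins, base_mean, base_sd)
  names(mu) <- proteins
  mu[reference] <- base_mean + 3 * base_sd  # tagged bait: always abundant

  groups <- c(baits, control)
  meta <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      group = groups, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  meta$sample <- paste(meta$group, meta$bio_rep, meta$tech_rep, sep = "_")
  meta <- meta[, c("sample", "group", "bio_rep", "tech_rep")]

  enriched <- do.call(rbind, lapply(baits, function(bt) {
    data.frame(bait = rep(bt, n_enriched),
               protein = sample(setdiff(proteins, reference), n_enriched),
               fold = rep(fold, n_enriched), stringsAsFactors = FALSE)
  }))

  sd_bio <- cv / log(2)
  sd_tech <- cv / (2 * log(2))
  x <- matrix(NA_real_, n_proteins, nrow(meta),
              dimnames = list(proteins, meta$sample))
  for (g in groups) {
    eff <- rep(0, n_proteins)
    if (g %in% baits) {
      hit <- enriched$protein[enriched$bait == g]
      eff[match(hit, proteins)] <- log2(fold)
    }
    for (b in seq_len(n_bio)) {
      bio_val <- mu + eff + stats::rnorm(n_proteins, 0, sd_bio)
      for (t in seq_len(n_tech)) {
        smp <- paste(g, b, t, sep = "_")
        x[, smp] <- bio_val + stats::rnorm(n_proteins, 0, sd_tech)
      }
    }
  }

  # intensity-dependent missingness, normalized to the target overall rate
  if (missing_rate >= 1) {
    pm <- rep(1, n_proteins)
  } else if (missing_rate > 0) {
    w <- stats::plogis((stats::quantile(mu, 0.2) - mu) / 2)
    pm <- pmin(1, missing_rate * w / mean(w))
  } else {
    pm <- rep(0, n_proteins)
  }
  pm[proteins == reference] <- 0
  drop <- matrix(stats::runif(length(x)) < pm, n_proteins, ncol(x))
  intens <- 2^x
  intens[drop] <- NA_real_

  list(intensities = intens, meta = meta,
       truth = list(enriched = enriched, reference = reference,
                    missing_prob = pm, seed = seed))
}
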