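#' Discretize colony sizes into growth scores
#'
#' Colony readouts are scored 0 (no growth), 1 (background: a single small
#' colony) or 3 (fully grown spot). Sizes below `t_low` score 0, sizes in
#' `[t_low, t_high)` score 1, and sizes at or above `t_high` score 3 (the
#' upper boundary is inclusive).
#'
#' @param size numeric vector of colony sizes (>= 0; the synthetic generator
#'   uses a normalized 0-1 scale, real-data thresholds are user-supplied).
#' @param thresholds numeric `c(t_low, t_high)` with `t_low < t_high`.
#' @return integer vector of growth scores in `{0, 1, 3}`.
#' @export
discretize_colony <- function(size, thresholds = c(0.25, 0.6)) {
  if (length(thresholds) != 2L || !(thresholds[1L] < thresholds[2L]))
    abort("thresholds must be increasing (t_low < t_high)")
  if (any(size < 0, na.rm = TRUE)) abort("colony sizes must be non-negative")
  ifelse(size >= thresholds[2L], 3L, ifelse(size >= thresholds[1L], 1L, 0L))
}

# Extract a validated growth_score column, discretizing colony_size if needed.
.growth_scores <- function(df, thresholds) {
  sc <- if (!is.null(df$growth_score)) {
    as.integer(df$growth_score)
  } else if (!is.null(df$colony_size)) {
    discretize_colony(df$colony_size, thresholds)
  } else {
    abort("observations need a 'growth_score' or 'colony_size' column")
  }
  bad <- which(!sc %in% c(0L, 1L, 3L))
  if (length(bad))
    abort("invalid growth score %s (allowed: 0, 1, 3) at row %d",
          sc[bad[1L]], bad[1L])
  sc
}

#' Per-configuration, per-replicate replication ratio
#'
#' The fraction of technical-replicate positions of one bait x prey
#' configuration in one biological replicate that reached full growth
#' (score 3). Maximum 1 per configuration per biological replicate.
#'
#' @param scores growth scores (`{0,1,3}`) of all stamped positions of one
#'   configuration in one biological replicate.
#' @return ratio in `[0, 1]`.
#' @export
score_configuration <- function(scores) {
  if (length(scores) == 0L) abort("no observations for configuration")
  mean(scores == 3L)
}

#' Combine biological replicates of one configuration
#'
#' A configuration contributes to its pair's replication score only if it
#' showed the interaction (ratio > 0) in the required set of biological
#' replicates; the contribution is then the highest ratio observed in any
#' biological replicate, otherwise 0. The default gate requires positivity
#' in every biological replicate in which the configuration was tested
#' (a single tested replicate passes vacuously); `"majority"` requires more
#' than half.
#'
#' @param ratios per-biological-replicate replication ratios.
#' @param gate `"all"` (default) or `"majority"`.
#' @return contribution in `[0, 1]`.
#' @export
combine_bio_replicates <- function(ratios, gate = c("all", "majority")) {
  gate <- match.arg(gate)
  if (length(ratios) == 0L) abort("no replicate ratios supplied")
  ok <- switch(gate,
               all = all(ratios > 0),
               majority = mean(ratios > 0) > 0.5)
  if (ok) max(ratios) else 0
}

#' Sum configuration contributions into a pair replication score
#'
#' @param contributions named numeric vector, one entry per distinct
#'   configuration of the pair (names are configuration keys).
#' @return replication score in `[0, 8]`.
#' @export
pair_replication_score <- function(contributions) {
  if (!is.null(names(contributions)) && anyDuplicated(names(contributions)))
    abort("duplicate configuration keys in contributions")
  if (length(contributions) == 0L) return(0)
  sum(contributions)
}

#' Flag auto-active bait constructs from no-prey control plates
#'
#' Bait strains stamped onto selective medium without prior mating must not
#' grow; a bait whose control positions reach full growth activates the
#' reporter on its own and is excluded from the screen.
#'
#' @param controls data.frame of control observations with columns `bait_id`
#'   and `growth_score` (or `colony_size`).
#' @param min_fraction if NULL (default) a single score-3 control position
#'   flags the bait; otherwise the fraction of score-3 positions must reach
#'   `min_fraction`.
#' @param thresholds passed to [discretize_colony()] when sizes are given.
#' @return sorted character vector of flagged bait construct ids.
#' @export
flag_auto_active_baits <- function(controls, min_fraction = NULL,
                                   thresholds = c(0.25, 0.6)) {
  if (is.null(controls) || nrow(controls) == 0L) {
    warning("empty control set: no auto-active baits flagged")
    return(character())
  }
  sc <- .growth_scores(controls, thresholds)
  frac3 <- tapply(sc == 3L, controls$bait_id, mean)
  flagged <- if (is.null(min_fraction)) frac3 > 0 else frac3 >= min_fraction
  sort(names(frac3)[flagged])
}

#' Flag auto-active (sticky) prey constructs
#'
#' A prey that scores positive with many independently mated baits is
#' auto-active. Positivity with a bait uses the same replicate gate as
#' scoring: every tested biological replicate of the bait x prey
#' configuration has at least one score-3 position.
#'
#' @param obs screen observations (see [score_y2h()] for the schema).
#' @param min_fraction flag a prey positive with more than this fraction of
#'   tested baits (default 0.5); must be in (0, 1].
#' @param exclude_baits bait construct ids (e.g. auto-active baits) to drop
#'   before counting.
#' @param thresholds passed to [discretize_colony()] when sizes are given.
#' @return sorted character vector of flagged prey construct ids.
#' @export
flag_auto_active_preys <- function(obs, min_fraction = 0.5,
                                   exclude_baits = character(),
                                   thresholds = c(0.25, 0.6)) {
  if (!(min_fraction > 0 && min_fraction <= 1))
    abort("min_fraction must be in (0, 1]")
  obs <- obs[!obs$bait_id %in% exclude_baits, , drop = FALSE]
  if (nrow(obs) == 0L) return(character())
  sc <- .growth_scores(obs, thresholds)
  key_rep <- paste(obs$prey_id, obs$bait_id, obs$bio_rep, sep = "\r")
  rep_pos <- tapply(sc == 3L, key_rep, any)
  cfg_of_rep <- sub("\r[^\r]*$", "", names(rep_pos))
  cfg_pos <- tapply(rep_pos, cfg_of_rep, all)
  prey_of_cfg <- sub("\r.*$", "", names(cfg_pos))
  frac <- tapply(cfg_pos, prey_of_cfg, mean)
  sort(names(frac)[frac > min_fraction])
}

#' Score a yeast two-hybrid matrix screen
#'
#' Full replication-scoring pipeline: discretize colony sizes (if needed),
#' drop observations involving auto-active constructs, compute the
#' per-configuration per-biological-replicate ratio of fully grown positions,
#' gate and collapse biological replicates ([combine_bio_replicates()]),
#' collapse the up to eight configurations of each unordered protein pair
#' into a summed replication score in `[0, 8]`, and call interactions at the
#' threshold.
#'
#' @param obs data.frame of colony observations with columns `bait_id`,
#'   `prey_id`, `bio_rep`, `position`, and `growth_score` or `colony_size`.
#' @param design a [screen_design()] whose construct table maps construct ids
#'   to proteins.
#' @param threshold replication-score call cutoff (default 0.75, inclusive:
#'   a pair scoring exactly the threshold is positive).
#' @param gate biological-replicate gate, see [combine_bio_replicates()].
#' @param auto_active_baits,auto_active_preys construct ids excluded from
#'   scoring (see [flag_auto_active_baits()], [flag_auto_active_preys()]).
#' @param size_thresholds passed to [discretize_colony()].
#' @return data.frame of class `y2h_calls`, one row per tested protein pair:
#'   `pair_id`, `gene_a`, `species_a`, `gene_b`, `species_b`, `scope`,
#'   `homotypic`, `score`, `n_configs`, `positive`. The per-configuration
#'   audit table is attached as `attr(, "audit")`.
#' @export
score_y2h <- function(obs, design, threshold = 0.75,
                      gate = c("all", "majority"),
                      auto_active_baits = character(),
                      auto_active_preys = character(),
                      size_thresholds = c(0.25, 0.6)) {
  gate <- match.arg(gate)
  if (!(threshold > 0 && threshold <= 8))
    abort("threshold must be in (0, 8]")
  stopifnot(inherits(design, "screen_design"))
  obs <- obs[!(obs$bait_id %in% auto_active_baits |
                 obs$prey_id %in% auto_active_preys), , drop = FALSE]
  if (nrow(obs) == 0L) abort("no observations left to score")
  sc <- .growth_scores(obs, size_thresholds)

  cs <- design$constructs
  bi <- match(obs$bait_id, cs$construct_id)
  pi <- match(obs$prey_id, cs$construct_id)
  if (anyNA(bi)) abort("unknown bait construct id: %s",
                       obs$bait_id[which(is.na(bi))[1L]])
  if (anyNA(pi)) abort("unknown prey construct id: %s",
                       obs$prey_id[which(is.na(pi))[1L]])
  if (any(cs$role[bi] != "bait")) abort("non-bait construct used as bait")
  if (any(cs$role[pi] != "prey")) abort("non-prey construct used as prey")

  # per (configuration, bio_rep): ratio of score-3 positions
  key_cfg <- paste(obs$bait_id, obs$prey_id, sep = "\r")
  key_rep <- paste(key_cfg, obs$bio_rep, sep = "\r")
  n3 <- rowsum(as.numeric(sc == 3L), key_rep)
  nn <- rowsum(rep(1, length(sc)), key_rep)
  ratio <- n3[, 1L] / nn[, 1L]
  cfg_of_rep <- sub("\r[^\r]*$", "", rownames(n3))

  # per configuration: replicate gate + max ratio
  gate_ok <- if (gate == "all") {
    tapply(ratio > 0, cfg_of_rep, all)
  } else {
    tapply(ratio > 0, cfg_of_rep, function(z) mean(z) > 0.5)
  }
  max_ratio <- tapply(ratio, cfg_of_rep, max)
  n_reps <- tapply(ratio, cfg_of_rep, length)
  cfg_keys <- names(max_ratio)
  contribution <- ifelse(gate_ok[cfg_keys], max_ratio, 0)

  cfg_bait <- sub("\r.*$", "", cfg_keys)
  cfg_prey <- sub("^.*\r", "", cfg_keys)
  b <- match(cfg_bait, cs$construct_id)
  p <- match(cfg_prey, cs$construct_id)
  pairs <- canonical_pairs(cs$gene[b], cs$species[b], cs$gene[p], cs$species[p])

  audit <- data.frame(bait_id = cfg_bait, prey_id = cfg_prey,
                      pair_id = pairs$pair_id,
                      n_bio_reps = as.integer(n_reps[cfg_keys]),
                      max_ratio = as.numeric(max_ratio),
                      gate_passed = as.logical(gate_ok[cfg_keys]),
                      contribution = as.numeric(contribution),
                      stringsAsFactors = FALSE)
  rownames(audit) <- NULL

  score <- rowsum(audit$contribution, audit$pair_id)
  n_configs <- rowsum(rep(1L, nrow(audit)), audit$pair_id)
  out <- unique(pairs)
  out <- out[match(rownames(score), out$pair_id), , drop = FALSE]
  out$scope <- ifelse(out$species_a == out$species_b, "intra", "inter")
  out$score <- score[, 1L]
  out$n_configs <- as.integer(n_configs[, 1L])
  out$positive <- out$score >= threshold
  out <- out[order(out$pair_id),
             c("pair_id", "gene_a", "species_a", "gene_b", "species_b",
               "scope", "homotypic", "score", "n_configs", "positive")]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  attr(out, "threshold") <- threshold
  attr(out, "gate") <- gate
  class(out) <- c("y2h_calls", "data.frame")
  out
}

#' Call interactions from pair replication scores
#'
#' @param pair_scores data.frame with at least `pair_id` and `score`
#'   (e.g. the output of [score_y2h()]).
#' @param threshold call cutoff in (0, 8]; comparison is inclusive (>=).
#' @return the input with an updated logical `positive` column and
#'   `attr(, "threshold")`.
#' @export
call_interactions <- function(pair_scores, threshold = 0.75) {
  if (!(threshold > 0 && threshold <= 8))
    abort("threshold must be in (0, 8]")
  pair_scores$positive <- pair_scores$score >= threshold
  attr(pair_scores, "threshold") <- threshold
  pair_scores
}

#' @export
print.y2h_calls <- function(x, ...) {
  cat(sprintf(
    "Y2H interaction calls: %d pairs tested, %d positive (threshold %.2f)\n",
    nrow(x), sum(x$positive), attr(x, "threshold")))
  tab <- table(x$scope[x$positive])
  if (sum(x$positive))
    cat(sprintf("  positive: %d intra, %d inter\n",
                if ("intra" %in% names(tab)) tab[["intra"]] else 0L,
                if ("inter" %in% names(tab)) tab[["inter"]] else 0L))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
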