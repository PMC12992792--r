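# Independent brute-force oracles and tiny fixtures. These deliberately do
# not call package internals: they re-derive expected values from first
# principles so the implementation is checked against an independent path.

ORACLE_CODE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})
ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_SENSE <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

# NG86 site counts by explicit neighbor enumeration, renormalizing each
# position over its non-stop neighbors (same convention as the package,
# independently derived).
oracle_codon_sites <- function(codon) {
  aa0 <- ORACLE_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    aa_neighbors <- character()
    for (b in ORACLE_BASES) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (ORACLE_CODE[[mut]] != "*") aa_neighbors <- c(aa_neighbors,
                                                       ORACLE_CODE[[mut]])
    }
    if (length(aa_neighbors))
      s <- s + mean(aa_neighbors == aa0)
  }
  c(s = s, n = 3 - s)
}

# NG86 pathway averaging by recursive enumeration of substitution orders.
oracle_codon_differences <- function(c1, c2) {
  walk <- function(cur, skip_stop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (skip_stop && ORACLE_CODE[[nxt]] == "*") next
      step <- if (ORACLE_CODE[[nxt]] == ORACLE_CODE[[cur]])
        c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      for (tail in walk(nxt, skip_stop))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  paths <- walk(c1, TRUE)
  if (!length(paths)) paths <- walk(c1, FALSE)
  Reduce(`+`, paths) / length(paths)
}

# Benjamini-Hochberg step-up, written out directly.
oracle_bh <- function(p) {
  n <- length(p)
  s <- sort(p)
  adj <- numeric(n)
  run <- 1
  for (i in n:1) {
    run <- min(run, s[i] * n / i)
    adj[i] <- run
  }
  adj[rank(p, ties.method = "first")]
}

# per-cell tally of a call matrix by species-pair distance
oracle_distance_tally <- function(mat, divergence) {
  acc <- list()
  for (i in rownames(mat)) for (j in colnames(mat)) {
    v <- mat[i, j]
    if (is.na(v)) next
    d <- as.character(divergence[i, j])
    if (is.null(acc[[d]])) acc[[d]] <- c(0, 0)
    acc[[d]] <- acc[[d]] + c(1, v)
  }
  d <- sort(as.numeric(names(acc)))
  data.frame(distance = d,
             n_tested = vapply(as.character(d), function(k)
               as.integer(acc[[k]][1]), integer(1)),
             n_positive = vapply(as.character(d), function(k)
               as.integer(acc[[k]][2]), integer(1)),
             row.names = NULL)
}

# small three-species, two-gene design with the default-style distances
small_design <- function(absences = NULL) {
  dv <- matrix(c(0, 5, 13,
                 5, 0, 13,
                 13, 13, 0), 3, 3,
               dimnames = list(c("S1", "S2", "S3"), c("S1", "S2", "S3")))
  screen_design(species = c(S1 = "sp one", S2 = "sp two", S3 = "sp three"),
                genes = c("g1", "g2"), absences = absences, divergence = dv)
}

# observation rows for one configuration
obs_block <- function(bait, prey, bio_rep, scores) {
  data.frame(bait_id = bait, prey_id = prey, bio_rep = as.integer(bio_rep),
             position = seq_along(scores), growth_score = as.integer(scores),
             stringsAsFactors = FALSE)
}
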