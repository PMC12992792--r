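#' Cross-species call matrix for one ortholog gene pair
#'
#' Arranges interaction calls for one gene pair into a species x species
#' matrix: rows are the species providing gene A's ortholog, columns the
#' species providing gene B's ortholog. Entries are 1 (positive), 0
#' (negative) or NA (untested, or ortholog absent in that species). For a
#' homotypic gene pair (A = B) the matrix is read as unordered and
#' symmetrized by OR.
#'
#' @param calls a `y2h_calls` data.frame (see [score_y2h()]).
#' @param gene_a,gene_b gene symbols (must be in the design's roster).
#' @param design a [screen_design()] object.
#' @return numeric matrix with species ids as dimnames, of class
#'   `cross_species_matrix` with attributes `gene_a`, `gene_b`.
#' @export
build_call_matrix <- function(calls, gene_a, gene_b, design) {
  stopifnot(inherits(design, "screen_design"))
  if (!gene_a %in% design$genes) abort("gene %s not in roster", gene_a)
  if (!gene_b %in% design$genes) abort("gene %s not in roster", gene_b)
  sp <- design$species$species_id
  m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  has_a <- sp %in% design$proteins$species[design$proteins$gene == gene_a]
  has_b <- sp %in% design$proteins$species[design$proteins$gene == gene_b]

  rel <- calls[(calls$gene_a == gene_a & calls$gene_b == gene_b) |
                 (calls$gene_a == gene_b & calls$gene_b == gene_a), ,
               drop = FALSE]
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    # orient so that the row species carries gene_a
    if (r$gene_a == gene_a) {
      sa <- r$species_a; sb <- r$species_b
    } else {
      sa <- r$species_b; sb <- r$species_a
    }
    v <- as.numeric(r$positive)
    m[sa, sb] <- max(m[sa, sb], v, na.rm = TRUE)
    if (gene_a == gene_b) m[sb, sa] <- max(m[sb, sa], v, na.rm = TRUE)
  }
  m[!has_a, ] <- NA_real_
  m[, !has_b] <- NA_real_
  structure(m, gene_a = gene_a, gene_b = gene_b,
            class = c("cross_species_matrix", class(m)))
}

#' Fraction of positive interactions by evolutionary distance
#'
#' Assigns every tested cell of a cross-species call matrix to the
#' divergence-time group of its species pair (intra-species cells have
#' distance 0) and computes the fraction of positive interactions among
#' tested interactions per group. Untested/absent cells never enter a
#' denominator.
#'
#' @param mat a matrix from [build_call_matrix()].
#' @param divergence symmetric divergence-time matrix over the species
#'   universe of `mat` (e.g. `design$divergence`).
#' @param breaks optional numeric breaks for custom distance bins; the
#'   default groups by exact unique divergence values.
#' @return data.frame with columns `distance` (group key: the divergence
#'   time, or bin midpoint label for custom bins), `n_tested`, `n_positive`,
#'   `fraction`.
#' @export
fraction_by_distance <- function(mat, divergence, breaks = NULL) {
  sp_r <- rownames(mat); sp_c <- colnames(mat)
  miss <- setdiff(union(sp_r, sp_c), rownames(divergence))
  if (length(miss))
    abort("species missing from divergence matrix: %s",
          paste(miss, collapse = ", "))
  idx <- which(!is.na(mat), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(distance = numeric(), n_tested = integer(),
                      n_positive = integer(), fraction = numeric()))
  d <- divergence[cbind(sp_r[idx[, 1L]], sp_c[idx[, 2L]])]
  v <- mat[idx]
  grp <- if (is.null(breaks)) d else
    breaks[pmax(1L, findInterval(d, breaks))]
  agg_n <- tapply(v, grp, length)
  agg_p <- tapply(v, grp, sum)
  out <- data.frame(distance = as.numeric(names(agg_n)),
                    n_tested = as.integer(agg_n),
                    n_positive = as.integer(agg_p),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_positive / out$n_tested
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best non-increasing (antitonic) least-squares fit via PAVA on the
# distance-ordered fractions; used for the monotone-decay check.
.antitonic_fit <- function(y) {
  if (length(y) <= 1L) return(y)
  -stats::isoreg(seq_along(y), -y)$yf
}

#' Classify the evolutionary trajectory of a gene pair's interaction
#'
#' Applies an explicit rule set to the distance profile of a cross-species
#' call matrix, with precedence:
#' \enumerate{
#'   \item `not_detected`: no positive cell.
#'   \item `conserved`: fraction >= `theta_c` in every tested distance group
#'     (including the largest).
#'   \item `coevolving`: intra-species fraction >= `theta_c`, fractions
#'     compatible with a non-increasing trend in distance (maximum deviation
#'     from the best non-increasing fit <= `mono_tol`), and fraction <=
#'     `theta_f` in the largest tested distance group.
#'   \item `species_restricted`: positives exist and, for at least one of the
#'     two genes, the orthologs appearing in positive cells come from at most
#'     `k_restrict` species.
#'   \item `sporadic` otherwise.
#' }
#'
#' @param mat matrix from [build_call_matrix()].
#' @param divergence divergence-time matrix (see [fraction_by_distance()]).
#' @param theta_c conserved/coevolving high-fraction threshold (default 0.5).
#' @param theta_f far-distance low-fraction threshold (default 0.25).
#' @param k_restrict maximum species support for `species_restricted`
#'   (default 2).
#' @param mono_tol tolerance of the non-increasing-trend check (default 0.1).
#' @param profile optional precomputed [fraction_by_distance()] profile.
#' @return list of class `trajectory` with elements `label`, `profile`,
#'   `species_support` (named count for each gene), and the parameters used.
#' @export
classify_trajectory <- function(mat, divergence, theta_c = 0.5,
                                theta_f = 0.25, k_restrict = 2L,
                                mono_tol = 0.1, profile = NULL) {
  if (theta_c < 0 || theta_c > 1 || theta_f < 0 || theta_f > 1)
    abort("theta_c and theta_f must be in [0, 1]")
  if (k_restrict < 1L) abort("k_restrict must be >= 1")
  if (is.null(profile)) profile <- fraction_by_distance(mat, divergence)
  if (nrow(profile) == 0L) abort("no tested cells in matrix")

  pos <- which(mat == 1, arr.ind = TRUE)
  support_a <- length(unique(rownames(mat)[pos[, 1L]]))
  support_b <- length(unique(colnames(mat)[pos[, 2L]]))

  f <- profile$fraction
  label <- if (nrow(pos) == 0L) {
    "not_detected"
  } else if (all(f >= theta_c)) {
    "conserved"
  } else {
    intra <- profile$fraction[profile$distance == 0]
    far <- f[length(f)]
    mono_ok <- max(abs(f - .antitonic_fit(f))) <= mono_tol + 1e-12
    if (length(intra) == 1L && intra >= theta_c && mono_ok && far <= theta_f) {
      "coevolving"
    } else if (min(support_a, support_b) <= k_restrict) {
      "species_restricted"
    } else {
      "sporadic"
    }
  }
  structure(list(label = label, profile = profile,
                 species_support = c(a = support_a, b = support_b),
                 params = list(theta_c = theta_c, theta_f = theta_f,
                               k_restrict = k_restrict, mono_tol = mono_tol)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %s (species support %d/%d)\n", x$label,
              x$species_support[["a"]], x$species_support[["b"]]))
  print(x$profile)
  invisible(x)
}

#' Per-gene-pair trajectory summary of a screen
#'
#' Classifies every gene-level pair of the design (including homotypic gene
#' pairs) and extracts the per-species intra-species interaction edge list.
#'
#' @param calls `y2h_calls` data.frame.
#' @param design a [screen_design()] with a divergence matrix.
#' @param ... trajectory rule parameters passed to [classify_trajectory()].
#' @return data.frame with one row per gene pair: `gene_a`, `gene_b`,
#'   `label`, `n_tested`, `n_positive`, and `profile_json` (the distance
#'   profile serialized as JSON). The intra-species positive edge list
#'   (`species`, `gene_a`, `gene_b`, `score`) is attached as
#'   `attr(, "intra_edges")`.
#' @export
network_summary <- function(calls, design, ...) {
  stopifnot(inherits(design, "screen_design"))
  if (is.null(design$divergence))
    abort("design has no divergence matrix")
  g <- design$genes
  gp <- expand.grid(j = seq_along(g), i = seq_along(g),
                    KEEP.OUT.ATTRS = FALSE)
  gp <- gp[gp$i <= gp$j, , drop = FALSE]
  rows <- lapply(seq_len(nrow(gp)), function(k) {
    ga <- g[gp$i[k]]; gb <- g[gp$j[k]]
    m <- build_call_matrix(calls, ga, gb, design)
    if (!any(!is.na(m))) {
      return(data.frame(gene_a = ga, gene_b = gb, label = "not_detected",
                        n_tested = 0L, n_positive = 0L,
                        profile_json = "[]", stringsAsFactors = FALSE))
    }
    tr <- classify_trajectory(m, design$divergence, ...)
    data.frame(gene_a = ga, gene_b = gb, label = tr$label,
               n_tested = sum(tr$profile$n_tested),
               n_positive = sum(tr$profile$n_positive),
               profile_json = as.character(
                 jsonlite::toJSON(tr$profile, digits = NA)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  intra <- calls[calls$scope == "intra" & calls$positive, , drop = FALSE]
  attr(out, "intra_edges") <- data.frame(
    species = intra$species_a, gene_a = intra$gene_a, gene_b = intra$gene_b,
    score = intra$score, stringsAsFactors = FALSE)
  out
}
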