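# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction,
# implemented from first principles on the standard genetic code.

.dnds_cache <- new.env(parent = emptyenv())

.bases <- c("A", "C", "G", "T")

# standard genetic code as a named vector codon -> amino acid ('*' = stop)
.code <- function(code = NULL) {
  if (!is.null(code)) return(code)
  if (is.null(.dnds_cache$code)) {
    gc <- Biostrings::GENETIC_CODE
    .dnds_cache$code <- stats::setNames(as.character(gc), names(gc))
  }
  .dnds_cache$code
}

.sense_codons <- function(code = NULL) {
  cd <- .code(code)
  names(cd)[cd != "*"]
}

.is_stop <- function(codon, code = NULL) .code(code)[codon] == "*"

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts, per Nei & Gojobori (1986), the fraction of the three possible
#' single-nucleotide changes at each codon position that are synonymous.
#' Changes creating stop codons are excluded and the position renormalized so
#' that the synonymous and nonsynonymous site counts of a codon always sum
#' to 3 (one of the two standard conventions; stated here and covered by the
#' exhaustive test oracle).
#'
#' @param codon 3-letter uppercase codon string (A/C/G/T only; not a stop).
#' @param code optional named codon -> amino-acid vector (default: standard
#'   genetic code).
#' @return named numeric `c(s = , n = )` with `s + n == 3`.
#' @export
codon_sites <- function(codon, code = NULL) {
  cd <- .code(code)
  if (is.na(cd[codon])) abort("invalid or ambiguous codon: %s", codon)
  if (cd[codon] == "*") abort("stop codon has no site counts: %s", codon)
  nt <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    alt <- .bases[.bases != nt[pos]]
    neigh <- vapply(alt, function(b) {
      x <- nt; x[pos] <- b; paste(x, collapse = "")
    }, character(1L))
    aa <- cd[neigh]
    keep <- aa != "*"
    if (any(keep)) s <- s + sum(aa[keep] == cd[codon]) / sum(keep)
  }
  c(s = s, n = 3 - s)
}

# site-count lookup table over all sense codons (built once)
.site_table <- function(code = NULL) {
  if (!is.null(code)) {
    sc <- .sense_codons(code)
    return(t(vapply(sc, codon_sites, c(s = 0, n = 0), code = code)))
  }
  if (is.null(.dnds_cache$sites)) {
    sc <- .sense_codons()
    .dnds_cache$sites <- t(vapply(sc, codon_sites, c(s = 0, n = 0)))
  }
  .dnds_cache$sites
}

# all permutations of 1..k (k <= 3)
.perms <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' For k mismatched positions, averages the synonymous/nonsynonymous step
#' counts over all k! substitution pathways between the codons. Pathways
#' passing through a stop codon are skipped; when no stop-free pathway
#' exists, all pathways are used as a documented fallback. When at least one
#' stop-free pathway exists, `sd + nd` equals the number of mismatches.
#'
#' @param codon1,codon2 sense codons (uppercase, A/C/G/T).
#' @inheritParams codon_sites
#' @return named numeric `c(sd = , nd = )`.
#' @export
codon_differences <- function(codon1, codon2, code = NULL) {
  cd <- .code(code)
  for (cc in c(codon1, codon2)) {
    if (is.na(cd[cc])) abort("invalid or ambiguous codon: %s", cc)
    if (cd[cc] == "*") abort("stop codon in comparison: %s", cc)
  }
  if (codon1 == codon2) return(c(sd = 0, nd = 0))
  a <- strsplit(codon1, "")[[1L]]
  b <- strsplit(codon2, "")[[1L]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  paths <- .perms(k)
  tally <- function(skip_stop) {
    tot_s <- 0; tot_n <- 0; used <- 0L
    for (ord in paths) {
      cur <- a; s <- 0; n <- 0; ok <- TRUE
      for (pos in diff_pos[ord]) {
        nxt <- cur; nxt[pos] <- b[pos]
        c_cur <- paste(cur, collapse = ""); c_nxt <- paste(nxt, collapse = "")
        if (skip_stop && cd[c_nxt] == "*") { ok <- FALSE; break }
        if (cd[c_nxt] == cd[c_cur]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; used <- used + 1L }
    }
    if (used == 0L) return(NULL)
    c(sd = tot_s / used, nd = tot_n / used)
  }
  tally(TRUE) %||% tally(FALSE)
}

# split an in-frame sequence into codon strings
.codon_split <- function(x) {
  x <- toupper(as.character(x))
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Pairwise dN/dS by Nei-Gojobori codon counting
#'
#' Estimates synonymous (dS) and nonsynonymous (dN) distances and their
#' ratio omega for an aligned in-frame pair of coding sequences. Site counts
#' are averaged over both sequences; proportions of differences are
#' Jukes-Cantor corrected, `d = -3/4 log(1 - 4p/3)`. Codon columns with a
#' gap, ambiguity code, or stop codon in either sequence are dropped
#' entirely (complete deletion). Omega is NA (flagged in `status`) when
#' dS = 0 or a proportion is saturated (p >= 3/4).
#'
#' @param seq1,seq2 aligned nucleotide sequences of equal length divisible
#'   by 3 (character strings, or a `codon_alignment` from
#'   [read_fasta_pair()] as `seq1` with `seq2` missing).
#' @inheritParams codon_sites
#' @return object of class `dnds`: list with `n_codons`, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `status`.
#' @examples
#' sim <- simulate_codon_pair(n_codons = 500, omega = 0.5,
#'                            divergence = 0.2, seed = 1)
#' dnds(sim$alignment)
#' @export
dnds <- function(seq1, seq2, code = NULL) {
  if (missing(seq2) && inherits(seq1, "codon_alignment")) {
    seq2 <- seq1$seq2; seq1 <- seq1$seq1
  }
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (nchar(s1) != nchar(s2)) abort("aligned sequences differ in length")
  if (nchar(s1) == 0L || nchar(s1) %% 3L != 0L)
    abort("alignment length must be a positive multiple of 3")
  c1 <- .codon_split(s1); c2 <- .codon_split(s2)
  cd <- .code(code)
  ok <- !is.na(cd[c1]) & !is.na(cd[c2]) & cd[c1] != "*" & cd[c2] != "*"
  c1 <- c1[ok]; c2 <- c2[ok]
  if (length(c1) == 0L) abort("no comparable codon columns after filtering")

  st <- .site_table(code)
  S <- (sum(st[c1, "s"]) + sum(st[c2, "s"])) / 2
  N <- (sum(st[c1, "n"]) + sum(st[c2, "n"])) / 2

  mism <- c1 != c2
  Sd <- 0; Nd <- 0
  if (any(mism)) {
    key <- paste(c1[mism], c2[mism])
    cnt <- table(key)
    for (k in names(cnt)) {
      cp <- strsplit(k, " ")[[1L]]
      d <- codon_differences(cp[1L], cp[2L], code)
      Sd <- Sd + d[["sd"]] * cnt[[k]]
      Nd <- Nd + d[["nd"]] * cnt[[k]]
    }
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (!is.finite(p) || p >= 0.75) NA_real_
                    else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  status <- if (!is.finite(pS) || !is.finite(pN)) "no_sites"
            else if (is.na(dS) || is.na(dN)) "saturated"
            else if (dS == 0) "undefined_omega" else "ok"
  omega <- if (identical(status, "ok")) dN / dS else NA_real_
  structure(list(n_codons = length(c1), S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                 status = status),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("Pairwise dN/dS (NG86, %d codons)\n", x$n_codons))
  cat(sprintf("  S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS = %.4f, pN = %.4f, dS = %.4f, dN = %.4f\n",
              x$pS, x$pN, x$dS, x$dN))
  cat(sprintf("  omega = %s [%s]\n",
              if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega),
              x$status))
  invisible(x)
}

#' Batch pairwise dN/dS over a manifest of alignment files
#'
#' @param manifest data.frame with columns `gene`, `file`, `species_a`,
#'   `species_b`; each file a 2-record aligned in-frame FASTA.
#' @inheritParams codon_sites
#' @return data.frame with one row per manifest row: the [dnds()] fields
#'   plus `gene`, `species_a`, `species_b`, `status` ("failed: <reason>"
#'   for unreadable or frame-violating inputs; failures are per-row, never
#'   fatal).
#' @export
dnds_batch <- function(manifest, code = NULL) {
  need <- c("gene", "file", "species_a", "species_b")
  if (!all(need %in% names(manifest)))
    abort("manifest needs columns: %s", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    base <- data.frame(gene = m$gene, species_a = m$species_a,
                       species_b = m$species_b, n_codons = NA_integer_,
                       S = NA_real_, N = NA_real_, Sd = NA_real_,
                       Nd = NA_real_, pS = NA_real_, pN = NA_real_,
                       dS = NA_real_, dN = NA_real_, omega = NA_real_,
                       status = NA_character_, stringsAsFactors = FALSE)
    est <- tryCatch({
      aln <- read_fasta_pair(m$file)
      dnds(aln, code = code)
    }, error = function(e) e)
    if (inherits(est, "error")) {
      base$status <- paste("failed:", conditionMessage(est))
    } else {
      base[names(est)[names(est) != "status"]] <-
        est[names(est) != "status"]
      base$status <- est$status
    }
    base
  })
  do.call(rbind, rows)
}

#' Write a pairwise alignment in sequential PHYLIP format
#'
#' Convenience export for downstream codon-model tools that take PHYLIP
#' input (site-class likelihood tests are outside this package's scope).
#'
#' @param aln a `codon_alignment` (see [read_fasta_pair()]) or list with
#'   `seq1`, `seq2` and optionally `names`.
#' @param path output file.
#' @export
write_phylip_pair <- function(aln, path) {
  nm <- aln$names %||% c("seq1", "seq2")
  nm <- sprintf("%-10s", substr(nm, 1L, 10L))
  writeLines(c(sprintf(" 2 %d", nchar(aln$seq1)),
               paste0(nm[1L], aln$seq1),
               paste0(nm[2L], aln$seq2)), path)
  invisible(path)
}
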