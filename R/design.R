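#' Build a cross-species matrix-screen design
#'
#' Models the combinatorial universe of an all-versus-all yeast two-hybrid
#' matrix screen across several species: a gene roster expanded over a
#' species roster (minus declared gene absences), four constructs per protein
#' (bait/prey x N/C tag), and a pairwise species divergence-time matrix.
#'
#' @param species named character vector (`id = full name`) or character
#'   vector of species ids, or a data.frame with columns `species_id`, `name`.
#' @param genes character vector of gene symbols (ordered; order is kept and
#'   determines the deterministic roster ordering).
#' @param absences data.frame with columns `gene`, `species` listing
#'   (gene, species) combinations that do not exist (no ortholog), or NULL.
#' @param divergence symmetric numeric matrix of pairwise divergence times
#'   (million years) with species ids as dimnames and a zero diagonal, or
#'   NULL if distance-based analyses are not needed.
#' @return An object of class `screen_design`: a list with elements
#'   `species`, `genes`, `absences`, `proteins` (one row per existing
#'   (gene, species) protein), `constructs` (4 rows per protein) and
#'   `divergence`.
#' @examples
#' d <- screen_design(species = c(sp1 = "Species one", sp2 = "Species two"),
#'                    genes = c("geneA", "geneB"))
#' nrow(d$proteins)    # 4
#' nrow(d$constructs)  # 16
#' @export
screen_design <- function(species, genes, absences = NULL, divergence = NULL) {
  if (is.data.frame(species)) {
    sp_id <- as.character(species$species_id)
    sp_nm <- as.character(species$name %||% species$species_id)
  } else {
    sp_id <- if (!is.null(names(species))) names(species) else as.character(species)
    sp_nm <- as.character(species)
  }
  genes <- as.character(genes)
  if (anyDuplicated(sp_id)) abort("duplicate species ids: %s",
                                  paste(unique(sp_id[duplicated(sp_id)]), collapse = ", "))
  if (anyDuplicated(genes)) abort("duplicate gene symbols: %s",
                                  paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(sp_id) < 1L || length(genes) < 1L)
    abort("need at least one species and one gene")

  if (is.null(absences)) {
    absences <- data.frame(gene = character(), species = character(),
                           stringsAsFactors = FALSE)
  } else {
    absences <- data.frame(gene = as.character(absences$gene),
                           species = as.character(absences$species),
                           stringsAsFactors = FALSE)
    bad_g <- setdiff(absences$gene, genes)
    bad_s <- setdiff(absences$species, sp_id)
    if (length(bad_g)) abort("absence references unknown gene(s): %s",
                             paste(bad_g, collapse = ", "))
    if (length(bad_s)) abort("absence references unknown species: %s",
                             paste(bad_s, collapse = ", "))
    if (anyDuplicated(paste(absences$gene, absences$species)))
      abort("duplicate absence entries")
  }

  if (!is.null(divergence)) {
    divergence <- as.matrix(divergence)
    if (is.null(dimnames(divergence)))
      dimnames(divergence) <- list(sp_id, sp_id)
    if (!setequal(rownames(divergence), sp_id) ||
        !setequal(colnames(divergence), sp_id))
      abort("divergence matrix dimnames must match the species roster")
    divergence <- divergence[sp_id, sp_id, drop = FALSE]
    if (any(divergence < 0)) abort("divergence times must be non-negative")
    if (any(diag(divergence) != 0)) abort("divergence diagonal must be zero")
    if (!isTRUE(all.equal(divergence, t(divergence))))
      abort("divergence matrix must be symmetric")
  }

  # Deterministic roster expansion: genes outer, species inner, input order.
  proteins <- expand.grid(species = sp_id, gene = genes,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  proteins <- proteins[, c("gene", "species")]
  absent <- paste(proteins$gene, proteins$species) %in%
    paste(absences$gene, absences$species)
  proteins <- proteins[!absent, , drop = FALSE]
  proteins$protein_id <- paste(proteins$gene, proteins$species, sep = "_")
  rownames(proteins) <- NULL

  roles <- c("bait", "prey")
  tags <- c("N", "C")
  constructs <- expand.grid(tag = tags, role = roles,
                            protein_id = proteins$protein_id,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  constructs <- constructs[, c("protein_id", "role", "tag")]
  idx <- match(constructs$protein_id, proteins$protein_id)
  constructs$gene <- proteins$gene[idx]
  constructs$species <- proteins$species[idx]
  constructs$construct_id <- paste(constructs$protein_id, constructs$role,
                                   constructs$tag, sep = "|")
  rownames(constructs) <- NULL

  structure(list(
    species = data.frame(species_id = sp_id, name = sp_nm,
                         stringsAsFactors = FALSE),
    genes = genes,
    absences = absences,
    proteins = proteins,
    constructs = constructs,
    divergence = divergence
  ), class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Cross-species Y2H screen design\n")
  cat(sprintf("  species:    %d (%s)\n", nrow(x$species),
              paste(x$species$species_id, collapse = ", ")))
  cat(sprintf("  genes:      %d\n", length(x$genes)))
  cat(sprintf("  absences:   %d\n", nrow(x$absences)))
  cat(sprintf("  proteins:   %d\n", nrow(x$proteins)))
  cat(sprintf("  constructs: %d (2 bait + 2 prey per protein)\n",
              nrow(x$constructs)))
  if (!is.null(x$divergence))
    cat(sprintf("  divergence: %g-%g My\n", min(x$divergence),
                max(x$divergence)))
  invisible(x)
}

#' Default five-species piRNA-pathway screen design
#'
#' The germline piRNA precursor biogenesis screen design: 11 pathway genes
#' across five Drosophila species (D. melanogaster, D. simulans, D. erecta,
#' D. persimilis, D. virilis), with Kipferl absent in D. persimilis and
#' D. virilis, giving 53 proteins and 212 constructs. Divergence times are
#' approximate defaults (Dmel-Dsim 5, melanogaster subgroup-Dere 13,
#' melanogaster group-Dper 30, anything-Dvir 40 My) and can be overridden by
#' supplying a config file to [read_design_config()].
#'
#' @return A [screen_design()] object.
#' @export
default_screen_design <- function() {
  sp <- c(Dmel = "D. melanogaster", Dsim = "D. simulans",
          Dere = "D. erecta", Dper = "D. persimilis", Dvir = "D. virilis")
  genes <- c("Rhi", "Kipf", "Del", "Cuff", "Moon", "TfIIA-S", "Trf2",
             "CtBP", "Boot", "Nxf3", "UAP56")
  absences <- data.frame(gene = c("Kipf", "Kipf"),
                         species = c("Dper", "Dvir"),
                         stringsAsFactors = FALSE)
  ids <- names(sp)
  dv <- matrix(0, 5, 5, dimnames = list(ids, ids))
  dv["Dmel", "Dsim"] <- dv["Dsim", "Dmel"] <- 5
  dv[c("Dmel", "Dsim"), "Dere"] <- dv["Dere", c("Dmel", "Dsim")] <- 13
  dv[c("Dmel", "Dsim", "Dere"), "Dper"] <- dv["Dper", c("Dmel", "Dsim", "Dere")] <- 30
  dv[, "Dvir"] <- dv["Dvir", ] <- 40
  dv["Dvir", "Dvir"] <- 0
  screen_design(species = sp, genes = genes, absences = absences,
                divergence = dv)
}

#' Enumerate all unique protein pairs of a screen design
#'
#' All unordered pairs over the roster's proteins, including homotypic
#' self-pairs, partitioned into intra-species (both members from the same
#' species) and inter-species pairs. For P proteins this yields
#' P(P+1)/2 pairs.
#'
#' @param design a [screen_design()] object.
#' @return data.frame with one row per unique pair: canonical `gene_a`,
#'   `species_a`, `gene_b`, `species_b`, `pair_id`, `homotypic`, and
#'   `scope` in `c("intra", "inter")`.
#' @examples
#' d <- default_screen_design()
#' p <- enumerate_pairs(d)
#' table(p$scope)  # 308 intra, 1123 inter
#' @export
enumerate_pairs <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  pr <- design$proteins
  n <- nrow(pr)
  idx <- which(upper.tri(matrix(0L, n, n), diag = TRUE), arr.ind = TRUE)
  out <- canonical_pairs(pr$gene[idx[, 1L]], pr$species[idx[, 1L]],
                         pr$gene[idx[, 2L]], pr$species[idx[, 2L]])
  out$scope <- ifelse(out$species_a == out$species_b, "intra", "inter")
  out <- out[order(out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate bait x prey configurations for one protein pair
#'
#' Every protein is represented by two bait and two prey constructs (N- and
#' C-terminal fusions). A heterotypic pair is therefore testable in up to 8
#' configurations (2 bait tags x 2 prey tags x 2 orientations); a homotypic
#' pair in 4 (the orientation swap is an identity). Constructs flagged
#' auto-active can be excluded.
#'
#' @param design a [screen_design()] object.
#' @param gene_a,species_a,gene_b,species_b the two proteins.
#' @param auto_active character vector of auto-active construct ids to drop.
#' @return data.frame with columns `bait_id`, `prey_id`.
#' @export
enumerate_configurations <- function(design, gene_a, species_a,
                                     gene_b, species_b,
                                     auto_active = character()) {
  stopifnot(inherits(design, "screen_design"))
  pa <- paste(gene_a, species_a, sep = "_")
  pb <- paste(gene_b, species_b, sep = "_")
  if (!pa %in% design$proteins$protein_id)
    abort("protein %s not in roster", pa)
  if (!pb %in% design$proteins$protein_id)
    abort("protein %s not in roster", pb)
  cs <- design$constructs
  cfg <- function(bait_protein, prey_protein) {
    b <- cs$construct_id[cs$protein_id == bait_protein & cs$role == "bait"]
    p <- cs$construct_id[cs$protein_id == prey_protein & cs$role == "prey"]
    expand.grid(bait_id = b, prey_id = p,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  out <- cfg(pa, pb)
  if (pa != pb) out <- rbind(out, cfg(pb, pa))
  out <- unique(out)
  out <- out[!(out$bait_id %in% auto_active | out$prey_id %in% auto_active), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
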