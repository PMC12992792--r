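#' Read colony observations from TSV
#'
#' Schema-validated reader for the canonical observation table: required
#' columns `bait_id`, `prey_id`, `bio_rep`, `position` plus `growth_score`
#' (values 0/1/3) or `colony_size` (non-negative). '#' comment lines are
#' skipped; CSV and CRLF line endings are accepted. Malformed rows are
#' reported with their line numbers.
#'
#' @param path input file.
#' @return data.frame of observations.
#' @export
read_observations <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("\r$", "", raw)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  lineno <- which(keep)
  if (!length(lineno)) abort("%s: empty observation file", path)
  sep <- if (grepl("\t", raw[lineno[1L]])) "\t" else ","
  df <- utils::read.table(text = raw[keep], sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", fill = FALSE)
  data_lines <- lineno[-1L]
  need <- c("bait_id", "prey_id", "bio_rep", "position")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (!"growth_score" %in% names(df) && !"colony_size" %in% names(df))
    abort("%s: need a 'growth_score' or 'colony_size' column", path)
  if ("growth_score" %in% names(df)) {
    bad <- which(!df$growth_score %in% c(0L, 1L, 3L))
    if (length(bad))
      abort("%s line %d: invalid growth_score %s (allowed: 0, 1, 3)",
            path, data_lines[bad[1L]], df$growth_score[bad[1L]])
  }
  if ("colony_size" %in% names(df)) {
    bad <- which(is.na(df$colony_size) | df$colony_size < 0)
    if (length(bad))
      abort("%s line %d: invalid colony_size", path, data_lines[bad[1L]])
  }
  key <- paste(df$bait_id, df$prey_id, df$bio_rep, df$position)
  dup <- which(duplicated(key))
  if (length(dup))
    abort("%s line %d: duplicate (configuration, bio_rep, position)",
          path, data_lines[dup[1L]])
  df
}

#' Write colony observations as TSV
#'
#' Inverse of [read_observations()]; round-trips losslessly.
#'
#' @param obs observation data.frame.
#' @param path output file.
#' @export
write_observations <- function(obs, path) {
  write_tsv(obs, path, comments = "table colony_observations")
}

#' Read an aligned in-frame sequence pair from FASTA
#'
#' Expects exactly two aligned records of equal length divisible by 3.
#' Codon columns containing a gap or ambiguity character in either sequence
#' are dropped (complete deletion) and recorded.
#'
#' @param path FASTA file with 2 records.
#' @return object of class `codon_alignment`: `seq1`, `seq2` (filtered,
#'   concatenated codons), `names`, `n_codons`, `dropped_columns` (1-based
#'   codon-column indices removed).
#' @export
read_fasta_pair <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2L)
    abort("%s: expected exactly 2 records, found %d", path, length(seqs))
  s1 <- toupper(as.character(seqs[[1L]]))
  s2 <- toupper(as.character(seqs[[2L]]))
  if (nchar(s1) != nchar(s2))
    abort("%s: records have unequal lengths (%d vs %d)", path,
          nchar(s1), nchar(s2))
  if (nchar(s1) %% 3L != 0L)
    abort("%s: alignment length %d is not divisible by 3", path, nchar(s1))
  c1 <- .codon_split(s1)
  c2 <- .codon_split(s2)
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  structure(list(seq1 = paste(c1[clean], collapse = ""),
                 seq2 = paste(c2[clean], collapse = ""),
                 names = names(seqs),
                 n_codons = sum(clean),
                 dropped_columns = which(!clean)),
            class = "codon_alignment")
}

#' Read a screen-design configuration file
#'
#' YAML (default) or JSON configuration with keys `species` (map id ->
#' name, or list of ids), `genes`, optional `absences` (list of
#' `{gene, species}`) and `divergence_my` (map `"idA-idB" -> My` or a full
#' nested matrix).
#'
#' @param path config file (.yaml/.yml/.json; YAML parsed first, JSON as
#'   fallback).
#' @return a [screen_design()] object.
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) jsonlite::read_json(path,
                                                     simplifyVector = TRUE))
  }
  if (is.null(cfg$species) || is.null(cfg$genes))
    abort("%s: config needs 'species' and 'genes'", path)
  species <- unlist(cfg$species)
  genes <- unlist(cfg$genes)
  absences <- NULL
  if (length(cfg$absences)) {
    absences <- if (is.data.frame(cfg$absences)) {
      cfg$absences  # jsonlite simplifies a record list to a data.frame
    } else {
      do.call(rbind, lapply(cfg$absences, function(a)
        data.frame(gene = a$gene, species = a$species,
                   stringsAsFactors = FALSE)))
    }
  }
  divergence <- NULL
  if (length(cfg$divergence_my)) {
    ids <- if (!is.null(names(species))) names(species)
           else as.character(species)
    divergence <- matrix(0, length(ids), length(ids),
                         dimnames = list(ids, ids))
    for (k in names(cfg$divergence_my)) {
      ab <- strsplit(k, "-", fixed = TRUE)[[1L]]
      if (length(ab) != 2L || !all(ab %in% ids))
        abort("%s: bad divergence key '%s'", path, k)
      divergence[ab[1L], ab[2L]] <- divergence[ab[2L], ab[1L]] <-
        as.numeric(cfg$divergence_my[[k]])
    }
  }
  screen_design(species = species, genes = genes, absences = absences,
                divergence = divergence)
}

#' Consolidated pipeline report
#'
#' Writes a single markdown report combining whichever stage outputs are
#' supplied: design combinatorics, QC (auto-active constructs), interaction
#' call summary with intra/inter split, trajectory table, dN/dS table and
#' enrichment summary. Missing stages are marked skipped, never fatal. A run
#' manifest (package version, seed, input hashes) is embedded; with
#' `timestamp = FALSE` (default) regeneration from identical inputs is
#' byte-identical.
#'
#' @param path output markdown file.
#' @param design optional [screen_design()].
#' @param qc optional list with `auto_baits`, `auto_preys`.
#' @param calls optional `y2h_calls`.
#' @param trajectories optional [network_summary()] table.
#' @param dnds_table optional [dnds_batch()] table.
#' @param enrichment optional [differential_enrichment()] table.
#' @param seed optional integer recorded in the manifest.
#' @param timestamp include the generation time (breaks byte-identical
#'   regeneration; default FALSE).
#' @return the output path, invisibly.
#' @export
run_report <- function(path, design = NULL, qc = NULL, calls = NULL,
                       trajectories = NULL, dnds_table = NULL,
                       enrichment = NULL, seed = NULL, timestamp = FALSE) {
  L <- c("# Cross-species interaction screen report", "")
  skip <- function(what) c(sprintf("## %s", what), "", "_skipped_", "")
  if (!is.null(design)) {
    pr <- enumerate_pairs(design)
    L <- c(L, "## Screen design", "",
           sprintf("- species: %d; genes: %d; absences: %d",
                   nrow(design$species), length(design$genes),
                   nrow(design$absences)),
           sprintf("- proteins: %d; constructs: %d", nrow(design$proteins),
                   nrow(design$constructs)),
           sprintf("- unique protein pairs: %d (%d intra-species, %d inter-species)",
                   nrow(pr), sum(pr$scope == "intra"),
                   sum(pr$scope == "inter")), "")
  } else L <- c(L, skip("Screen design"))
  if (!is.null(qc)) {
    L <- c(L, "## Auto-activity QC", "",
           sprintf("- auto-active bait constructs: %d (%s)",
                   length(qc$auto_baits),
                   paste(qc$auto_baits, collapse = ", ")),
           sprintf("- auto-active prey constructs: %d (%s)",
                   length(qc$auto_preys),
                   paste(qc$auto_preys, collapse = ", ")), "")
  } else L <- c(L, skip("Auto-activity QC"))
  if (!is.null(calls)) {
    L <- c(L, "## Interaction calls", "",
           sprintf("- pairs tested: %d; positive at threshold %.2f: %d",
                   nrow(calls), attr(calls, "threshold"),
                   sum(calls$positive)),
           sprintf("- positive intra-species: %d; inter-species: %d",
                   sum(calls$positive & calls$scope == "intra"),
                   sum(calls$positive & calls$scope == "inter")), "")
  } else L <- c(L, skip("Interaction calls"))
  if (!is.null(trajectories)) {
    tab <- table(trajectories$label)
    L <- c(L, "## Evolutionary trajectories", "",
           sprintf("- %s: %d", names(tab), as.integer(tab)), "")
  } else L <- c(L, skip("Evolutionary trajectories"))
  if (!is.null(dnds_table)) {
    ok <- dnds_table[dnds_table$status == "ok", , drop = FALSE]
    L <- c(L, "## Pairwise dN/dS", "",
           sprintf("- alignments: %d; with finite omega: %d",
                   nrow(dnds_table), nrow(ok)),
           if (nrow(ok)) sprintf("- omega range: %.3f - %.3f",
                                 min(ok$omega), max(ok$omega)), "")
  } else L <- c(L, skip("Pairwise dN/dS"))
  if (!is.null(enrichment)) {
    th <- attr(enrichment, "thresholds")
    L <- c(L, "## co-IP enrichment", "",
           sprintf("- protein groups: %d; testable: %d; hits (>%.1f-fold, -log10 adj p > %g): %d",
                   nrow(enrichment), sum(enrichment$testable),
                   th[["fc"]], th[["logp"]], sum(enrichment$hit)), "")
  } else L <- c(L, skip("co-IP enrichment"))

  inputs <- list(design = design, qc = qc, calls = calls,
                 trajectories = trajectories, dnds_table = dnds_table,
                 enrichment = enrichment)
  L <- c(L, "## Run manifest", "",
         sprintf("- ppievo version: %s",
                 as.character(utils::packageVersion("ppievo"))),
         sprintf("- seed: %s", if (is.null(seed)) "none" else seed),
         sprintf("- input hash: %s", hash_object(inputs)),
         if (timestamp) sprintf("- generated: %s",
                                format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
         "")
  writeLines(L, path)
  invisible(path)
}
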