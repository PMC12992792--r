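# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered protein-pair keys
#'
#' A protein is identified by its (gene, species) tuple. Unordered pairs are
#' canonicalised lexicographically on the `gene_species` label so that the
#' same pair always yields the same key regardless of bait/prey orientation.
#'
#' @param gene_a,species_a,gene_b,species_b character vectors (recycled).
#' @return data.frame with canonically ordered `gene_a`, `species_a`,
#'   `gene_b`, `species_b`, a `pair_id` key, and a `homotypic` flag.
#' @keywords internal
canonical_pairs <- function(gene_a, species_a, gene_b, species_b) {
  a <- paste(gene_a, species_a, sep = "_")
  b <- paste(gene_b, species_b, sep = "_")
  swap <- a > b
  out <- data.frame(
    gene_a    = ifelse(swap, gene_b, gene_a),
    species_a = ifelse(swap, species_b, species_a),
    gene_b    = ifelse(swap, gene_a, gene_b),
    species_b = ifelse(swap, species_a, species_b),
    stringsAsFactors = FALSE
  )
  out$pair_id <- paste(paste(out$gene_a, out$species_a, sep = "_"),
                       paste(out$gene_b, out$species_b, sep = "_"),
                       sep = "--")
  out$homotypic <- out$gene_a == out$gene_b & out$species_a == out$species_b
  out
}

#' Write a data frame as TSV with '#' header comments
#'
#' The canonical tabular dialect of the package: tab-separated, UTF-8, header
#' row, '#'-prefixed comment lines carrying tool version and a content hash.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param comments extra comment lines (without the leading '#').
#' @export
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(
    sprintf("ppievo %s", as.character(utils::packageVersion("ppievo"))),
    sprintf("content_hash %s", hash_object(df)),
    comments
  )
  writeLines(paste("#", hdr), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV/CSV table, skipping '#' comment lines
#'
#' @param path input path; tab-separated by default, comma accepted.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!startsWith(first, "#")]
  sep <- if (length(first) && !grepl("\t", first[[1L]]) &&
             grepl(",", first[[1L]])) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", fill = FALSE)
}

# MD5 of a serialized object (used for config hashes in run manifests).
hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2L)
  unname(tools::md5sum(tf))
}

# stop() with a consistent prefix, no call
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
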