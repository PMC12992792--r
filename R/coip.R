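#' Preprocess a co-IP/MS protein-group intensity table
#'
#' Log2-transforms raw intensities, normalizes across samples (per-sample
#' median centering by default, making sample medians equal; quantile
#' normalization available via the limma package), keeps a protein group in
#' a biological-replicate sample only when it was detected in every
#' technical replicate of that sample, and averages technical replicates.
#' Protein groups missing everywhere after filtering are dropped and
#' recorded.
#'
#' @param intensities numeric matrix (protein groups x samples; 0 or NA =
#'   not detected) or data.frame whose first column is the protein-group id.
#' @param meta data.frame with columns `sample`, `group`, `bio_rep`,
#'   `tech_rep` covering every intensity column.
#' @param normalize `"median"` (default), `"quantile"` or `"none"`.
#' @return list of class `coip_processed`: `mat` (protein x biological
#'   sample, log2 scale, technical replicates averaged), `meta`
#'   (`biosample`, `group`, `bio_rep`), `dropped` (ids removed as
#'   all-missing).
#' @export
coip_preprocess <- function(intensities, meta,
                            normalize = c("median", "quantile", "none")) {
  normalize <- match.arg(normalize)
  if (is.data.frame(intensities)) {
    ids <- as.character(intensities[[1L]])
    intensities <- as.matrix(intensities[, -1L, drop = FALSE])
    rownames(intensities) <- ids
  }
  mode(intensities) <- "numeric"
  if (ncol(intensities) < 1L) abort("need at least one sample column")
  miss <- setdiff(colnames(intensities), meta$sample)
  if (length(miss))
    abort("sample metadata missing for: %s", paste(miss, collapse = ", "))
  meta <- meta[match(colnames(intensities), meta$sample), , drop = FALSE]
  if (any(intensities < 0, na.rm = TRUE))
    abort("intensities must be non-negative")

  x <- intensities
  x[!is.na(x) & x == 0] <- NA          # zero reads as not detected
  x <- log2(x)

  x <- switch(normalize,
    none = x,
    median = {
      med <- apply(x, 2L, stats::median, na.rm = TRUE)
      sweep(x, 2L, med - stats::median(med), "-")
    },
    quantile = {
      if (!requireNamespace("limma", quietly = TRUE))
        abort("quantile normalization requires the limma package")
      limma::normalizeBetweenArrays(x, method = "quantile")
    })

  # both-technical-replicate detection filter, then average tech reps
  biosample <- paste(meta$group, meta$bio_rep, sep = ".")
  ub <- unique(biosample)
  out <- matrix(NA_real_, nrow(x), length(ub),
                dimnames = list(rownames(x), ub))
  for (b in ub) {
    cols <- which(biosample == b)
    sub <- x[, cols, drop = FALSE]
    full <- rowSums(!is.na(sub)) == length(cols)
    out[full, b] <- rowMeans(sub[full, , drop = FALSE])
  }
  dropped <- rownames(out)[rowSums(!is.na(out)) == 0L]
  if (length(dropped))
    message(sprintf("dropping %d protein group(s) with no retained values",
                    length(dropped)))
  out <- out[!rownames(out) %in% dropped, , drop = FALSE]
  bmeta <- unique(data.frame(biosample = biosample, group = meta$group,
                             bio_rep = meta$bio_rep,
                             stringsAsFactors = FALSE))
  structure(list(mat = out, meta = bmeta, dropped = dropped),
            class = "coip_processed")
}

#' Enrichment relative to the tagged-GFP reference
#'
#' Expresses each protein group's log2 abundance relative to the average
#' abundance of the GFP reference protein group within the same sample
#' group, making enrichment comparable across bait IPs. The reference's own
#' ratio is 0 on the log2 scale (1 on the linear scale) in every group, up
#' to replicate noise.
#'
#' @param processed a `coip_processed` object (see [coip_preprocess()]).
#' @param reference protein-group id of the GFP/eGFP reference.
#' @param groups sample groups to process (default: all). Groups where the
#'   reference was not retained are skipped with a warning.
#' @return data.frame with columns `protein`, `group`, `bio_rep`,
#'   `log2_ratio` (per biological replicate), plus the per-group mean as
#'   attribute-free rows are aggregated with [stats::aggregate()] by callers
#'   if needed.
#' @export
gfp_relative <- function(processed, reference, groups = NULL) {
  stopifnot(inherits(processed, "coip_processed"))
  if (!reference %in% rownames(processed$mat))
    abort("reference protein group '%s' not present", reference)
  groups <- groups %||% unique(processed$meta$group)
  rows <- list()
  for (g in groups) {
    cols <- processed$meta$biosample[processed$meta$group == g]
    ref <- processed$mat[reference, cols]
    if (all(is.na(ref))) {
      warning(sprintf("reference missing in group '%s'; group skipped", g))
      next
    }
    ref_mean <- mean(ref, na.rm = TRUE)
    sub <- processed$mat[, cols, drop = FALSE] - ref_mean
    idx <- which(!is.na(sub), arr.ind = TRUE)
    rows[[g]] <- data.frame(
      protein = rownames(sub)[idx[, 1L]],
      group = g,
      bio_rep = processed$meta$bio_rep[match(cols[idx[, 2L]],
                                             processed$meta$biosample)],
      log2_ratio = sub[idx],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential enrichment between bait and control IPs
#'
#' Per protein group: mean log2 fold change between bait and control
#' biological replicates, Welch two-sample t test (two-sided, unpaired),
#' Benjamini-Hochberg adjustment across all tested protein groups, and
#' volcano hit classification: more than `fc_threshold`-fold change (strict,
#' on the linear scale, either direction) with -log10(adjusted p) above
#' `logp_threshold`. Protein groups with fewer than two retained biological
#' replicates on either side are flagged untestable (p undefined), never
#' silently dropped.
#'
#' @param processed a `coip_processed` object.
#' @param bait,control sample-group names.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param logp_threshold -log10 adjusted-p threshold (default 2).
#' @return data.frame of class `coip_enrichment`: `protein`, `log2_fc`,
#'   `p`, `p_adj`, `hit`, `direction`, `n_bait`, `n_control`, `testable`.
#' @export
differential_enrichment <- function(processed, bait, control,
                                    fc_threshold = 1.5,
                                    logp_threshold = 2) {
  stopifnot(inherits(processed, "coip_processed"))
  for (g in c(bait, control))
    if (!g %in% processed$meta$group) abort("unknown sample group '%s'", g)
  bcols <- processed$meta$biosample[processed$meta$group == bait]
  ccols <- processed$meta$biosample[processed$meta$group == control]
  m <- processed$mat
  out <- data.frame(protein = rownames(m),
                    log2_fc = NA_real_, p = NA_real_, p_adj = NA_real_,
                    hit = FALSE, direction = NA_character_,
                    n_bait = 0L, n_control = 0L, testable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    x <- m[i, bcols]; x <- x[!is.na(x)]
    y <- m[i, ccols]; y <- y[!is.na(y)]
    out$n_bait[i] <- length(x); out$n_control[i] <- length(y)
    if (length(x) >= 1L && length(y) >= 1L)
      out$log2_fc[i] <- mean(x) - mean(y)
    if (length(x) >= 2L && length(y) >= 2L) {
      out$testable[i] <- TRUE
      out$p[i] <- tryCatch(
        stats::t.test(x, y, var.equal = FALSE)$p.value,
        error = function(e) NA_real_)  # zero-variance degenerate inputs
    }
  }
  tested <- out$testable & !is.na(out$p)
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$direction <- ifelse(is.na(out$log2_fc), NA_character_,
                          ifelse(out$log2_fc >= 0, "enriched", "depleted"))
  out$hit <- tested & !is.na(out$p_adj) &
    abs(out$log2_fc) > log2(fc_threshold) &
    -log10(out$p_adj) > logp_threshold
  attr(out, "bait") <- bait
  attr(out, "control") <- control
  attr(out, "thresholds") <- c(fc = fc_threshold, logp = logp_threshold)
  class(out) <- c("coip_enrichment", "data.frame")
  out
}

#' @export
print.coip_enrichment <- function(x, ...) {
  cat(sprintf("co-IP enrichment: %s vs %s; %d protein groups, %d testable, %d hits\n",
              attr(x, "bait"), attr(x, "control"), nrow(x),
              sum(x$testable), sum(x$hit)))
  print.data.frame(utils::head(as.data.frame(x[order(x$p_adj), ]), 10L))
  invisible(x)
}

#' Tukey's fences and outliers
#'
#' Boxplot-whisker bounds: `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`, quartiles by
#' linear interpolation (R quantile type 7); values beyond the fences are
#' outliers.
#'
#' @param values numeric vector with at least 4 non-missing values.
#' @param k fence multiplier (default 1.5).
#' @return list with `lower`, `upper`, `q1`, `q3`, `outliers`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) abort("need at least 4 values for Tukey fences")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  lower <- q[1L] - k * iqr
  upper <- q[2L] + k * iqr
  list(lower = lower, upper = upper, q1 = q[1L], q3 = q[2L],
       outliers = values[values < lower | values > upper])
}
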