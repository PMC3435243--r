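## Affected-versus-unaffected CNV burden with family-aware permutation
## inference.  Phenotype labels are permuted only within families, so every
## family keeps its observed number of affected members under the null.

#' Compare CNV burden between affected and unaffected individuals
#'
#' Per-sample burden metrics (segment count, mean segment size, number of
#' distinct genes intersected, deletion and duplication counts) are compared
#' between affected and unaffected individuals.  Two-sided p-values come
#' from within-family phenotype-label permutations of the difference in
#' group means.  Individuals of unknown phenotype are excluded.
#'
#' @param cnvs merged autosomal CNV data frame.
#' @param pedigree a `cnv_pedigree`; defines the sample universe (samples
#'   with no calls count as zero burden).
#' @param gene_track optional gene track (`chrom`, `start`, `end`, `name`);
#'   when supplied, a gene is counted once per sample regardless of how many
#'   of the sample's CNVs hit it.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed.
#' @param samples optional character vector restricting the sample universe
#'   (e.g. post-QC samples).
#' @return a `cnv_burden`: list with `per_sample` metrics, `summary` (group
#'   means and permutation p per metric), `n_perm` and `seed`.
#' @export
burden_summary <- function(cnvs, pedigree, gene_track = NULL,
                           n_perm = 10000, seed = 1, samples = NULL) {
  ped <- pedigree[pedigree$phenotype != "unknown", , drop = FALSE]
  if (!is.null(samples)) {
    ped <- ped[ped$individual_id %in% samples, , drop = FALSE]
  }
  y <- ped$phenotype == "affected"
  if (!any(y) || all(y)) {
    stop("both an affected and an unaffected group are required",
         call. = FALSE)
  }
  cnvs <- cnvs[is_autosome(cnvs$chrom) &
                 cnvs$sample_id %in% ped$individual_id, , drop = FALSE]

  idx <- match(cnvs$sample_id, ped$individual_id)
  sizes <- interval_length(cnvs$start, cnvs$end)
  n <- nrow(ped)
  per <- data.frame(
    individual_id = ped$individual_id, family_id = ped$family_id,
    phenotype = ped$phenotype,
    n_segments = tabulate(idx, n),
    total_size = as.numeric(tapply2(sizes, idx, n, sum)),
    n_del = tabulate(idx[cnvs$state == "loss"], n),
    n_dup = tabulate(idx[cnvs$state == "gain"], n),
    stringsAsFactors = FALSE
  )
  per$mean_size <- ifelse(per$n_segments > 0,
                          per$total_size / per$n_segments, NA_real_)
  metrics <- c("n_segments", "mean_size", "n_del", "n_dup")
  if (!is.null(gene_track)) {
    pairs <- intersect_genes(ensure_cnv_ids(cnvs), gene_track)
    gene_per_sample <- if (nrow(pairs)) {
      tapply(pairs$gene, pairs$sample_id, function(g) length(unique(g)))
    } else integer(0)
    per$n_genes <- 0L
    hit <- match(names(gene_per_sample), per$individual_id)
    per$n_genes[hit[!is.na(hit)]] <-
      as.integer(gene_per_sample[!is.na(hit)])
    metrics <- c(metrics, "n_genes")
  }

  mm <- as.matrix(per[, metrics, drop = FALSE])
  stat <- function(lab) {
    colMeans(mm[lab, , drop = FALSE], na.rm = TRUE) -
      colMeans(mm[!lab, , drop = FALSE], na.rm = TRUE)
  }
  obs <- stat(y)

  fam <- split(seq_len(n), per$family_id)
  set.seed(seed)
  exceed <- numeric(length(metrics))
  for (b in seq_len(n_perm)) {
    lab <- y
    for (ii in fam) {
      if (length(ii) > 1L) lab[ii] <- lab[ii][sample.int(length(ii))]
    }
    exceed <- exceed + (abs(stat(lab)) >= abs(obs) - 1e-12)
  }
  pval <- (1 + exceed) / (n_perm + 1)

  summ <- data.frame(
    metric = metrics,
    mean_affected = colMeans(mm[y, , drop = FALSE], na.rm = TRUE),
    mean_unaffected = colMeans(mm[!y, , drop = FALSE], na.rm = TRUE),
    diff = obs, p_perm = pval, stringsAsFactors = FALSE, row.names = NULL
  )
  res <- list(per_sample = per, summary = summ,
              n_affected = sum(y), n_unaffected = sum(!y),
              n_perm = n_perm, seed = seed)
  class(res) <- "cnv_burden"
  res
}

## tabulate-like sum aggregation with explicit length.
tapply2 <- function(x, idx, n, fun) {
  out <- numeric(n)
  if (length(idx)) {
    agg <- tapply(x, idx, fun)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' @export
print.cnv_burden <- function(x, ...) {
  cat(sprintf(
    "CNV burden: %d affected vs %d unaffected, %d within-family permutations\n",
    x$n_affected, x$n_unaffected, x$n_perm))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
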