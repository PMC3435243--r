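## Sample-level quality control and the phenotype summary table.

#' Exclude samples with excessive CNV call counts
#'
#' A sample is excluded when its call count lies strictly above
#' `mean + k * sd` of the per-sample counts, with the sample standard
#' deviation (n - 1 denominator).
#'
#' @param counts named numeric vector of per-sample call counts.
#' @param k number of standard deviations (default 3).
#' @return a `cnv_qc_report`: list with `counts`, `mean`, `sd`, `k`,
#'   `threshold` and `excluded_samples`.
#' @export
#' @examples
#' cnt <- c(s1 = 45, s2 = 52, s3 = 49, s4 = 120)
#' exclude_outlier_samples(cnt)
exclude_outlier_samples <- function(counts, k = 3) {
  if (length(counts) < 2L) {
    stop("need at least two samples for the outlier rule", call. = FALSE)
  }
  m <- mean(counts)
  s <- sd(counts)
  thr <- m + k * s
  res <- list(counts = counts, mean = m, sd = s, k = k, threshold = thr,
              excluded_samples = names(counts)[counts > thr])
  class(res) <- "cnv_qc_report"
  res
}

#' @export
print.cnv_qc_report <- function(x, ...) {
  cat(sprintf("CNV call-count QC: %d samples, mean %.2f, sd %.2f (n-1)\n",
              length(x$counts), x$mean, x$sd))
  cat(sprintf("threshold mean + %g sd = %.2f (strictly above excludes)\n",
              x$k, x$threshold))
  cat(sprintf("excluded: %d sample(s)%s\n", length(x$excluded_samples),
              if (length(x$excluded_samples))
                paste0(" [", paste(x$excluded_samples, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Ancestry oval filter specification
#'
#' @param center length-2 numeric, oval center in the projected PC space.
#' @param axis_sd length-2 positive numeric, reference-cluster standard
#'   deviation along each projected axis.
#' @param factor oval half-axis length in units of `axis_sd` (default 10).
#' @return an `oval_filter_spec` list.
#' @export
oval_filter_spec <- function(center, axis_sd, factor = 10) {
  stopifnot(length(center) == 2L, length(axis_sd) == 2L)
  if (any(axis_sd <= 0)) stop("axis_sd must be positive", call. = FALSE)
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), axis_sd = as.numeric(axis_sd),
                 factor = factor), class = "oval_filter_spec")
}

#' Remove ancestry outliers falling outside the projected-space oval
#'
#' A sample at coordinates `x` is removed iff
#' `sum(((x - center) / (factor * axis_sd))^2) > 1`, i.e. it falls outside
#' the axis-aligned oval whose half-axes are `factor` reference-cluster
#' standard deviations.
#'
#' @param points matrix or data frame of per-sample 2-D coordinates,
#'   rownames (or an `individual_id` column) holding sample ids.
#' @param spec an [oval_filter_spec()].
#' @return list with `retained` and `removed` id vectors and the squared
#'   normalized distance `d2` per sample.
#' @export
oval_outlier_filter <- function(points, spec) {
  stopifnot(inherits(spec, "oval_filter_spec"))
  if (is.data.frame(points)) {
    ids <- points$individual_id %||% rownames(points)
    xy <- as.matrix(points[, setdiff(names(points), "individual_id")])
  } else {
    ids <- rownames(points)
    xy <- as.matrix(points)
  }
  stopifnot(ncol(xy) == 2L)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(xy)))
  d2 <- ((xy[, 1] - spec$center[1]) / (spec$factor * spec$axis_sd[1]))^2 +
    ((xy[, 2] - spec$center[2]) / (spec$factor * spec$axis_sd[2]))^2
  names(d2) <- ids
  list(retained = ids[d2 <= 1], removed = ids[d2 > 1], d2 = d2)
}

#' Phenotype summary by lesion category
#'
#' Counts affected individuals per lesion category with percentages relative
#' to the number of affected individuals (rounded half away from zero to one
#' decimal), and reports the overall affected fraction among phenotyped
#' individuals.
#'
#' @param pedigree a `cnv_pedigree`.
#' @param lesion_table data frame with columns `individual_id` and
#'   `category`, covering the affected individuals.
#' @return a `cnv_phenotype_summary`: list with the per-category `table`
#'   (`category`, `count`, `pct`), `n_affected`, `n_phenotyped` and
#'   `affected_pct`.
#' @export
summarize_phenotypes <- function(pedigree, lesion_table) {
  aff <- pedigree$individual_id[pedigree$phenotype == "affected"]
  n_aff <- length(aff)
  n_phen <- sum(pedigree$phenotype != "unknown")
  cat_of <- lesion_table$category[match(aff, lesion_table$individual_id)]
  if (anyNA(cat_of)) {
    warning(sum(is.na(cat_of)),
            " affected individual(s) without a lesion category;",
            " counted as uncategorized")
    cat_of[is.na(cat_of)] <- "uncategorized"
  }
  cats <- unique(lesion_table$category)
  if ("uncategorized" %in% cat_of && !("uncategorized" %in% cats)) {
    cats <- c(cats, "uncategorized")
  }
  cnt <- vapply(cats, function(cc) sum(cat_of == cc), integer(1))
  tab <- data.frame(category = cats, count = cnt,
                    pct = round_half_away(100 * cnt / n_aff, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- list(table = tab, n_affected = n_aff, n_phenotyped = n_phen,
              affected_pct = round_half_away(100 * n_aff / n_phen, 1))
  class(res) <- "cnv_phenotype_summary"
  res
}

#' @export
print.cnv_phenotype_summary <- function(x, ...) {
  cat(sprintf("Affected: %d of %d phenotyped (%.1f%%)\n",
              x$n_affected, x$n_phenotyped, x$affected_pct))
  print(x$table, row.names = FALSE)
  invisible(x)
}
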