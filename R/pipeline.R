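## End-to-end orchestration: two-caller merge, sample QC, rarity filter
## chain, transmission classification, cosegregation and de novo rates —
## plus the planted-truth evaluation used to validate the pipeline on
## synthetic cohorts.

#' Run the rare-CNV discovery pipeline on a cohort
#'
#' Steps: (1) per-sample two-caller consensus merge for the family cohort
#' and the control cohort; (2) excess-call sample QC (strictly above
#' mean + 3 sd excludes) and, when PC coordinates are supplied, the
#' ancestry oval filter; (3) the rarity filter chain on the affected
#' individuals' CNVs; (4) transmission classification of the kept CNVs,
#' familial cosegregation scan and per-trio de novo rates.
#'
#' @param calls_a,calls_b cohort call tables from callers A and B.
#' @param controls_a,controls_b control-cohort call tables.
#' @param pedigree a `cnv_pedigree` (phenotypes known).
#' @param segdup_track,known_track annotation tracks.
#' @param pcs optional per-sample PC coordinates (`individual_id`, 2
#'   columns).
#' @param oval_spec an [oval_filter_spec()]; required when `pcs` given.
#' @param min_overlap,min_size,min_probes,merge_mode consensus-merge
#'   parameters (see [merge_two_callers()]).
#' @param thr overlap threshold of the filter/segregation stages
#'   (default 0.5).
#' @param qc_k QC standard-deviation multiplier (default 3).
#' @return a `rare_cnv_result`: list with `merged`, `merged_controls`,
#'   `qc`, `excluded_samples`, `samples` (post-QC), `filter`
#'   (`cnv_filter_result`), `kept`, `transmissions`, `events`
#'   (cosegregation table), `trios`, `de_novo_rates`.
#' @export
run_rare_cnv_pipeline <- function(calls_a, calls_b, controls_a, controls_b,
                                  pedigree, segdup_track, known_track,
                                  pcs = NULL, oval_spec = NULL,
                                  min_overlap = 0.5, min_size = 20000,
                                  min_probes = 5,
                                  merge_mode = c("of_a", "reciprocal"),
                                  thr = 0.5, qc_k = 3) {
  merge_mode <- match.arg(merge_mode)
  merged <- merge_cohort(calls_a, calls_b, min_overlap, min_size,
                         min_probes, merge_mode)
  merged_controls <- merge_cohort(controls_a, controls_b, min_overlap,
                                  min_size, min_probes, merge_mode)

  counts <- table(factor(merged$sample_id,
                         levels = pedigree$individual_id))
  qc <- exclude_outlier_samples(setNames(as.numeric(counts),
                                         names(counts)), k = qc_k)
  samples <- setdiff(pedigree$individual_id, qc$excluded_samples)
  if (!is.null(pcs)) {
    if (is.null(oval_spec)) {
      stop("oval_spec required when pcs are supplied", call. = FALSE)
    }
    ov <- oval_outlier_filter(pcs, oval_spec)
    samples <- setdiff(samples, ov$removed)
  }
  merged_kept <- merged[merged$sample_id %in% samples, , drop = FALSE]

  pheno <- setNames(pedigree$phenotype, pedigree$individual_id)
  aff <- merged_kept[pheno[merged_kept$sample_id] == "affected", ,
                     drop = FALSE]
  unaff <- merged_kept[pheno[merged_kept$sample_id] == "unaffected", ,
                       drop = FALSE]
  filt <- run_filter_chain(aff, unaff, merged_controls, segdup_track,
                           known_track, pedigree, thr)

  transmissions <- classify_transmissions(filt$kept, pedigree, merged_kept,
                                          thr, genotyped = samples)
  events <- cosegregation_scan(filt$kept, pedigree)
  trios <- build_trios(pedigree, genotyped = samples)
  rates <- if (nrow(trios)) {
    de_novo_rate(trios, filt$kept, pedigree, thr, genotyped = samples)
  } else NULL

  res <- list(merged = merged, merged_controls = merged_controls,
              qc = qc, excluded_samples = qc$excluded_samples,
              samples = samples, filter = filt, kept = filt$kept,
              transmissions = transmissions, events = events,
              trios = trios, de_novo_rates = rates)
  class(res) <- "rare_cnv_result"
  res
}

#' @export
print.rare_cnv_result <- function(x, ...) {
  cat(sprintf("Rare-CNV pipeline: %d consensus CNV(s), %d sample(s) post-QC\n",
              nrow(x$merged), length(x$samples)))
  print(x$filter)
  st <- table(x$transmissions$status)
  if (length(st)) {
    cat("transmission:",
        paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a pipeline run against the planted ground truth
#'
#' A planted causal event counts as recovered when some kept CNV of a true
#' carrier matches it (same state, overlap at least `thr` of the truth
#' interval).  Kept CNVs are attributed to their truth source by sample and
#' reciprocal overlap; surviving common-CNP and artifact calls are counted.
#' Transmission labels are scored over kept truth-derived CNVs whose true
#' status is known (de novo or inherited) and whose carrier has both
#' parents genotyped.
#'
#' @param result a `rare_cnv_result`.
#' @param truth a `cnv_truth`.
#' @param pedigree the phenotyped `cnv_pedigree`.
#' @param thr overlap threshold for truth matching (default 0.5).
#' @return list with `causal_recovery` (fraction), `n_causal`,
#'   `cnp_survivors`, `artifact_survivors`, `transmission_accuracy`,
#'   `n_transmission_evaluated`.
#' @export
evaluate_recovery <- function(result, truth, pedigree, thr = 0.5) {
  kept <- result$kept
  ind <- truth$individual_cnvs

  ## attribute kept CNVs to truth rows (same sample, reciprocal overlap)
  origin <- rep(NA_character_, nrow(kept))
  truth_tx <- rep(NA_character_, nrow(kept))
  for (j in seq_len(nrow(kept))) {
    cand <- ind[ind$sample_id == kept$sample_id[j] &
                  ind$state == kept$state[j], , drop = FALSE]
    if (!nrow(cand)) next
    ov <- intersect_length(kept$start[j], kept$end[j],
                           cand$start, cand$end)
    ov[cand$chrom != kept$chrom[j]] <- 0
    rec <- pmin(ov / interval_length(kept$start[j], kept$end[j]),
                ov / interval_length(cand$start, cand$end))
    best <- which.max(rec)
    if (rec[best] >= thr) {
      origin[j] <- cand$origin[best]
      truth_tx[j] <- cand$truth_transmission[best]
    }
  }

  causal_events <- truth$events[truth$events$type == "causal", ,
                                drop = FALSE]
  recovered <- vapply(seq_len(nrow(causal_events)), function(e) {
    ev <- causal_events[e, ]
    carriers <- ind$sample_id[ind$event_id == ev$event_id]
    hit <- kept$sample_id %in% carriers & kept$chrom == ev$chrom &
      kept$state == ev$state &
      intersect_length(kept$start, kept$end, ev$start, ev$end) /
        interval_length(ev$start, ev$end) >= thr
    any(hit)
  }, logical(1))

  ## transmission label accuracy on kept truth-derived CNVs
  fa <- setNames(pedigree$father_id, pedigree$individual_id)
  mo <- setNames(pedigree$mother_id, pedigree$individual_id)
  evaluable <- !is.na(truth_tx) & truth_tx %in% c("de_novo", "inherited") &
    !is.na(fa[kept$sample_id]) & !is.na(mo[kept$sample_id]) &
    fa[kept$sample_id] %in% result$samples &
    mo[kept$sample_id] %in% result$samples
  pred <- result$transmissions$status[match(kept$cnv_id,
                                            result$transmissions$cnv_id)]
  correct <- (truth_tx == "de_novo" & pred == "de_novo") |
    (truth_tx == "inherited" & startsWith(pred, "inherited"))
  acc <- if (any(evaluable)) mean(correct[evaluable]) else NA_real_

  list(causal_recovery = mean(recovered), n_causal = nrow(causal_events),
       cnp_survivors = sum(origin == "cnp", na.rm = TRUE),
       artifact_survivors = sum(origin == "artifact", na.rm = TRUE),
       transmission_accuracy = acc,
       n_transmission_evaluated = sum(evaluable))
}
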