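## The rarity filter chain.  Fixed stage order:
##   unaffected_cohort -> control_cohort -> segdup -> common -> family.
## Uniqueness keeps a CNV overlapped 50% *or less* by any same-state
## comparison CNV (strictly-greater overlap removes); the segmental-
## duplication and known-variant stages remove at 50% *or more*.  The 50%
## point therefore behaves differently across stages — both boundaries are
## implemented exactly as stated and are deliberately asymmetric.
## Comparisons are state-stratified (loss vs loss, gain vs gain), and the
## overlap denominator is the query CNV ("of_a") unless reciprocal mode is
## requested.

new_trace <- function(cnvs, stage, kept, reason, frac) {
  data.frame(cnv_id = cnvs$cnv_id, stage = stage, kept = kept,
             reason = reason, overlap = frac, stringsAsFactors = FALSE)
}

#' Select CNVs unique to affected individuals
#'
#' An affected individual's CNV is kept iff every same-state CNV among the
#' unaffected cohort members and among the controls overlaps it by at most
#' `thr` (fraction of the affected's CNV); strictly greater overlap removes
#' it.  The two comparisons are recorded as separate stages.
#'
#' @param affected_cnvs,unaffected_cnvs,control_cnvs merged CNV data frames
#'   with harmonized states.
#' @param thr overlap threshold (default 0.5).
#' @param mode overlap denominator (`"of_a"` default, or `"reciprocal"`).
#' @return list with `kept` (data frame) and `traces`.
#' @export
unique_to_affected <- function(affected_cnvs, unaffected_cnvs, control_cnvs,
                               thr = 0.5, mode = c("of_a", "reciprocal")) {
  mode <- match.arg(mode)
  cur <- ensure_cnv_ids(affected_cnvs)
  traces <- list()
  for (stage in c("unaffected_cohort", "control_cohort")) {
    cmp <- if (stage == "unaffected_cohort") unaffected_cnvs else
      control_cnvs
    frac <- max_overlap_fraction(cur, cmp, mode, match_state = TRUE)
    keep <- frac <= thr
    traces[[stage]] <- new_trace(
      cur, stage, keep,
      ifelse(keep, "unique", sprintf("overlap > %g with %s", thr, stage)),
      frac)
    cur <- cur[keep, , drop = FALSE]
  }
  list(kept = cur, traces = do.call(rbind, traces))
}

#' Select sex-chromosomal CNVs unique to affected individuals
#'
#' Sex-chromosomal uniqueness is stricter than the autosomal rule: any
#' same-state overlap (>= 1 bp) with a comparison CNV removes the call.
#'
#' @param affected_cnvs X/Y CNVs of affected individuals.
#' @param comparison_cnvs X/Y CNVs of unaffecteds and controls.
#' @return kept data frame.
#' @export
unique_sex_chromosomal <- function(affected_cnvs, comparison_cnvs) {
  for (df in list(affected_cnvs, comparison_cnvs)) {
    if (nrow(df) && any(is_autosome(df$chrom))) {
      stop("unique_sex_chromosomal expects X/Y CNVs only", call. = FALSE)
    }
  }
  frac <- max_overlap_fraction(affected_cnvs, comparison_cnvs,
                               match_state = TRUE)
  affected_cnvs[frac == 0, , drop = FALSE]
}

#' Remove CNVs covered >= 50% by segmental duplications
#'
#' Coverage is computed against the union of the segmental-duplication
#' records (overlapping records are not double-counted).
#'
#' @param cnvs merged CNV data frame.
#' @param segdup_track track data frame.
#' @param thr coverage threshold removing at `>= thr` (default 0.5).
#' @return list with `kept` and `traces`.
#' @export
filter_segdup <- function(cnvs, segdup_track, thr = 0.5) {
  cnvs <- ensure_cnv_ids(cnvs)
  cov <- union_coverage_fraction(cnvs, segdup_track)
  keep <- cov < thr
  list(kept = cnvs[keep, , drop = FALSE],
       traces = new_trace(cnvs, "segdup", keep,
                          ifelse(keep, "kept",
                                 sprintf("segdup coverage >= %g", thr)),
                          cov))
}

#' Remove CNVs matching known/common variants
#'
#' A CNV is removed iff at least one known-variant record overlaps it by
#' `thr` or more (fraction of the CNV) — the operational surrogate for the
#' population-frequency criterion.
#'
#' @param cnvs merged CNV data frame.
#' @param known_track known/common variant track.
#' @param overlap_thr removal threshold, inclusive (default 0.5).
#' @return list with `kept` and `traces`.
#' @export
filter_common <- function(cnvs, known_track, overlap_thr = 0.5) {
  cnvs <- ensure_cnv_ids(cnvs)
  frac <- max_overlap_fraction(cnvs, known_track)
  keep <- frac < overlap_thr
  list(kept = cnvs[keep, , drop = FALSE],
       traces = new_trace(cnvs, "common", keep,
                          ifelse(keep, "kept",
                                 sprintf("known-variant overlap >= %g",
                                         overlap_thr)),
                          frac))
}

#' Family-consistency filter and familial event grouping
#'
#' A CNV is removed when a same-state CNV of an unaffected member of the
#' same family overlaps it by `thr` or more (fraction of the query CNV).
#' Kept CNVs that overlap reciprocally by `thr` or more among affected
#' relatives of one family are grouped into a single familial event and
#' share an `event_id`.
#'
#' @param cnvs CNVs of affected individuals (post earlier stages).
#' @param pedigree a `cnv_pedigree`.
#' @param all_cohort_cnvs merged CNVs of the whole cohort (used to find
#'   unaffected relatives' calls).
#' @param thr overlap threshold (default 0.5).
#' @return list with `kept` (with `event_id` column) and `traces`.
#' @export
family_consistency_filter <- function(cnvs, pedigree, all_cohort_cnvs,
                                      thr = 0.5) {
  cnvs <- ensure_cnv_ids(cnvs)
  unaff <- pedigree$individual_id[pedigree$phenotype == "unaffected"]
  removed <- logical(nrow(cnvs))
  frac_out <- numeric(nrow(cnvs))
  for (fam in unique(cnvs$family_id)) {
    qi <- which(cnvs$family_id == fam)
    cmp <- all_cohort_cnvs[all_cohort_cnvs$family_id == fam &
                             all_cohort_cnvs$sample_id %in% unaff, ,
                           drop = FALSE]
    if (!nrow(cmp)) next
    frac <- max_overlap_fraction(cnvs[qi, , drop = FALSE], cmp,
                                 match_state = TRUE)
    removed[qi] <- frac >= thr
    frac_out[qi] <- frac
  }
  traces <- new_trace(cnvs, "family", !removed,
                      ifelse(removed,
                             sprintf("present in unaffected relative (>= %g)",
                                     thr), "kept"),
                      frac_out)
  kept <- cnvs[!removed, , drop = FALSE]
  kept$event_id <- rep(NA_character_, nrow(kept))
  if (nrow(kept)) {
    for (fam in unique(kept$family_id)) {
      ki <- which(kept$family_id == fam)
      sub <- kept[ki, , drop = FALSE]
      edges <- list()
      if (nrow(sub) > 1L) {
        hits <- GenomicRanges::findOverlaps(as_granges(sub), as_granges(sub))
        a <- S4Vectors::queryHits(hits); b <- S4Vectors::subjectHits(hits)
        sel <- a < b & sub$state[a] == sub$state[b]
        a <- a[sel]; b <- b[sel]
        if (length(a)) {
          ov <- intersect_length(sub$start[a], sub$end[a],
                                 sub$start[b], sub$end[b])
          rec <- pmin(ov / interval_length(sub$start[a], sub$end[a]),
                      ov / interval_length(sub$start[b], sub$end[b]))
          pair <- which(rec >= thr)
          edges <- lapply(pair, function(j) c(a[j], b[j]))
        }
      }
      comp <- union_find_components(nrow(sub), edges)
      kept$event_id[ki] <- sprintf("%s_E%02d", fam, comp)
    }
  }
  list(kept = kept, traces = traces)
}

#' Run the full rarity filter chain
#'
#' Applies, in fixed order: uniqueness against the unaffected cohort,
#' uniqueness against the controls, segmental-duplication exclusion,
#' known-variant exclusion, and the family-consistency filter.  Every
#' removal is attributed to exactly one stage.
#'
#' @param affected_cnvs merged CNVs of affected individuals.
#' @param unaffected_cnvs merged CNVs of unaffected cohort members.
#' @param control_cnvs merged CNVs of the control cohort.
#' @param segdup_track,known_track annotation tracks.
#' @param pedigree a `cnv_pedigree`.
#' @param thr overlap threshold shared by all stages (default 0.5).
#' @param mode overlap denominator for the uniqueness stages.
#' @return a `cnv_filter_result`: list with `kept` (with `event_id`),
#'   `traces` (one row per CNV per stage reached) and `stage_counts`.
#' @export
run_filter_chain <- function(affected_cnvs, unaffected_cnvs, control_cnvs,
                             segdup_track, known_track, pedigree,
                             thr = 0.5, mode = c("of_a", "reciprocal")) {
  mode <- match.arg(mode)
  affected_cnvs <- ensure_cnv_ids(affected_cnvs)
  n_in <- nrow(affected_cnvs)

  u <- unique_to_affected(affected_cnvs, unaffected_cnvs, control_cnvs,
                          thr, mode)
  s <- filter_segdup(u$kept, segdup_track, thr)
  cm <- filter_common(s$kept, known_track, thr)
  cols <- intersect(names(affected_cnvs), names(unaffected_cnvs))
  all_cohort <- rbind(affected_cnvs[, cols, drop = FALSE],
                      unaffected_cnvs[, cols, drop = FALSE])
  fam <- family_consistency_filter(cm$kept, pedigree, all_cohort, thr)

  traces <- rbind(u$traces, s$traces, cm$traces, fam$traces)
  removed_at <- traces[!traces$kept, c("cnv_id", "stage")]
  stage_names <- c("unaffected_cohort", "control_cohort", "segdup",
                   "common", "family")
  stage_counts <- data.frame(
    stage = stage_names,
    removed = vapply(stage_names,
                     function(s) sum(removed_at$stage == s), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- list(kept = fam$kept, traces = traces, stage_counts = stage_counts,
              n_input = n_in)
  class(res) <- "cnv_filter_result"
  res
}

#' @export
print.cnv_filter_result <- function(x, ...) {
  cat(sprintf("Rarity filter chain: %d affected CNV(s) in, %d kept\n",
              x$n_input, nrow(x$kept)))
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}
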