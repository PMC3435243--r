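## Pedigree transmission classification and de novo rate estimation.
## A parent "carries" an offspring's CNV when one of the parent's same-state
## calls overlaps it by at least `thr` — as a fraction of the *offspring's*
## CNV, since boundary jitter tends to inflate parental envelopes.

#' Classify the transmission status of one CNV
#'
#' With both parents genotyped and neither carrying, the CNV is `de_novo`;
#' with exactly one carrier parent it is `inherited_paternal` /
#' `inherited_maternal`; with both carrying, `inherited_either`.  If a
#' parent is ungenotyped (or absent from the pedigree) and no genotyped
#' parent carries, the status is `unknown` — de novo status is never imputed.
#'
#' @param cnv one-row CNV data frame (fields `sample_id`, `family_id`,
#'   `chrom`, `start`, `end`, `state`).
#' @param pedigree a `cnv_pedigree`.
#' @param all_calls merged CNV calls of the cohort (searched for parental
#'   carrier calls).
#' @param thr overlap threshold, fraction of the offspring CNV (default 0.5).
#' @param genotyped character vector of genotyped individual ids (default:
#'   every pedigree member).
#' @return one-row data frame: `cnv_id`, `individual_id`, `status`,
#'   `supporting_parent` (id or `NA`).
#' @export
classify_transmission <- function(cnv, pedigree, all_calls, thr = 0.5,
                                  genotyped = NULL) {
  if (is.null(genotyped)) genotyped <- pedigree$individual_id
  i <- which(pedigree$individual_id == cnv$sample_id &
               pedigree$family_id == cnv$family_id)
  if (!length(i)) {
    stop("individual ", cnv$sample_id, " absent from pedigree",
         call. = FALSE)
  }
  parent_carries <- function(pid) {
    if (is.na(pid) || !(pid %in% genotyped)) return(NA)
    calls <- all_calls[all_calls$sample_id == pid, , drop = FALSE]
    frac <- max_overlap_fraction(cnv, calls, match_state = TRUE)
    frac >= thr
  }
  fa <- parent_carries(pedigree$father_id[i])
  mo <- parent_carries(pedigree$mother_id[i])

  status <- if (isTRUE(fa) && isTRUE(mo)) "inherited_either"
  else if (isTRUE(fa)) "inherited_paternal"
  else if (isTRUE(mo)) "inherited_maternal"
  else if (identical(fa, FALSE) && identical(mo, FALSE)) "de_novo"
  else "unknown"
  support <- switch(status,
                    inherited_paternal = pedigree$father_id[i],
                    inherited_maternal = pedigree$mother_id[i],
                    inherited_either = pedigree$father_id[i],
                    NA_character_)
  data.frame(cnv_id = cnv$cnv_id %||% NA_character_,
             individual_id = cnv$sample_id, status = status,
             supporting_parent = support, stringsAsFactors = FALSE)
}

#' Classify transmission for a table of CNVs
#'
#' @param cnvs CNV data frame (one row per call).
#' @inheritParams classify_transmission
#' @return data frame with one classification row per input CNV.
#' @export
classify_transmissions <- function(cnvs, pedigree, all_calls, thr = 0.5,
                                   genotyped = NULL) {
  cnvs <- ensure_cnv_ids(cnvs)
  out <- lapply(seq_len(nrow(cnvs)), function(j) {
    classify_transmission(cnvs[j, , drop = FALSE], pedigree, all_calls,
                          thr, genotyped)
  })
  do.call(rbind, c(list(data.frame(cnv_id = character(),
                                   individual_id = character(),
                                   status = character(),
                                   supporting_parent = character(),
                                   stringsAsFactors = FALSE)), out))
}

#' Enumerate genotyped offspring-father-mother trios
#'
#' @param pedigree a `cnv_pedigree`.
#' @param genotyped genotyped individual ids (default: all members).
#' @return data frame `family_id`, `offspring`, `father`, `mother`,
#'   `phenotype` (of the offspring).
#' @export
build_trios <- function(pedigree, genotyped = NULL) {
  if (is.null(genotyped)) genotyped <- pedigree$individual_id
  sel <- !is.na(pedigree$father_id) & !is.na(pedigree$mother_id) &
    pedigree$individual_id %in% genotyped &
    pedigree$father_id %in% genotyped &
    pedigree$mother_id %in% genotyped
  data.frame(family_id = pedigree$family_id[sel],
             offspring = pedigree$individual_id[sel],
             father = pedigree$father_id[sel],
             mother = pedigree$mother_id[sel],
             phenotype = pedigree$phenotype[sel],
             stringsAsFactors = FALSE)
}

#' Minimum de novo CNV rate per trio
#'
#' The rate is the number of unambiguously de novo-classified CNVs among
#' trio offspring divided by the number of trios ("per offspring per
#' generation"); only trios with both parents genotyped contribute, and no
#' imputation is performed, so the estimate is a minimum.  Note the
#' denominator convention is per trio, not per transmission opportunity, so
#' rates are not directly comparable across studies that count differently.
#'
#' @param trios trio table from [build_trios()].
#' @param calls CNV calls to classify (typically the kept rare CNVs).
#' @param pedigree a `cnv_pedigree`.
#' @param thr overlap threshold (default 0.5).
#' @param stratify_by_phenotype split rates by offspring phenotype
#'   (default TRUE).
#' @param genotyped genotyped individual ids.
#' @return data frame `stratum`, `n_trios`, `n_de_novo`, `rate`, plus a
#'   `denominator` attribute documenting the convention.
#' @export
de_novo_rate <- function(trios, calls, pedigree, thr = 0.5,
                         stratify_by_phenotype = TRUE, genotyped = NULL) {
  if (nrow(trios) == 0L) stop("empty trio set", call. = FALSE)
  off_calls <- calls[calls$sample_id %in% trios$offspring, , drop = FALSE]
  cls <- classify_transmissions(off_calls, pedigree, calls, thr, genotyped)
  dn <- cls[cls$status == "de_novo", , drop = FALSE]
  strata <- if (stratify_by_phenotype) {
    split(seq_len(nrow(trios)), trios$phenotype)
  } else {
    list(all = seq_len(nrow(trios)))
  }
  out <- do.call(rbind, lapply(names(strata), function(sn) {
    tr <- trios[strata[[sn]], , drop = FALSE]
    ndn <- sum(dn$individual_id %in% tr$offspring)
    data.frame(stratum = sn, n_trios = nrow(tr), n_de_novo = ndn,
               rate = ndn / nrow(tr), stringsAsFactors = FALSE)
  }))
  attr(out, "denominator") <- "de novo CNV calls per trio (per offspring per generation)"
  out
}

#' Scan familial CNV events for cosegregation with the phenotype
#'
#' Operates on the post-filter kept set (which carries `event_id`s from the
#' family-consistency stage).  An event segregates when at least two
#' affected relatives of one family carry it; events spanning several
#' families are reported per family.
#'
#' @param kept_cnvs kept CNV data frame with an `event_id` column.
#' @param pedigree a `cnv_pedigree`.
#' @return data frame `family_id`, `event_id`, `chrom`, `start`, `end`,
#'   `state`, `n_affected_carriers`, `n_unaffected_carriers`, `segregates`.
#' @export
cosegregation_scan <- function(kept_cnvs, pedigree) {
  if (is.null(kept_cnvs$event_id)) {
    stop("kept_cnvs must carry event_id (run family_consistency_filter)",
         call. = FALSE)
  }
  if (nrow(kept_cnvs) == 0L) {
    return(data.frame(family_id = character(), event_id = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      n_affected_carriers = integer(),
                      n_unaffected_carriers = integer(),
                      segregates = logical(), stringsAsFactors = FALSE))
  }
  pheno <- setNames(pedigree$phenotype, pedigree$individual_id)
  grp <- split(seq_len(nrow(kept_cnvs)),
               paste(kept_cnvs$family_id, kept_cnvs$event_id))
  out <- do.call(rbind, lapply(grp, function(ii) {
    sub <- kept_cnvs[ii, , drop = FALSE]
    carriers <- unique(sub$sample_id)
    ph <- pheno[carriers]
    data.frame(family_id = sub$family_id[1], event_id = sub$event_id[1],
               chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), state = sub$state[1],
               n_affected_carriers = sum(ph == "affected", na.rm = TRUE),
               n_unaffected_carriers = sum(ph == "unaffected",
                                           na.rm = TRUE),
               segregates = sum(ph == "affected", na.rm = TRUE) >= 2L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$family_id, out$event_id), , drop = FALSE]
}
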