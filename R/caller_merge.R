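## Two-caller consensus merging.  A consensus CNV requires one call from each
## caller, same sample and same copy-state direction, overlapping by at least
## `min_overlap` (fraction of the caller-A segment by default); its boundaries
## are the outer envelope of the two source calls.  Consensus CNVs shorter
## than `min_size` or supported by fewer than `min_probes` probes are dropped.

#' Population normal state of a common copy-number polymorphism
#'
#' The normal copy state of a common CNP need not be two in a given
#' population; it is estimated as the mean copy number over all individuals,
#' rounded to the closest integer (halves away from zero).  Individuals are
#' then flagged relative to that state.
#'
#' @param copies named integer vector of copy numbers, one per individual.
#' @return list with `normal_state` (integer) and `deltas` (named character
#'   vector, `loss`/`gain`/`normal` per individual).
#' @export
#' @examples
#' canary_normal_state(c(a = 2, b = 2, c = 2, d = 3))  # normal 2, d = gain
#' canary_normal_state(c(a = 3, b = 3, c = 3))         # normal 3, none flagged
canary_normal_state <- function(copies) {
  if (length(copies) == 0L) stop("no individuals supplied", call. = FALSE)
  normal <- as.integer(round_half_away(mean(copies)))
  deltas <- ifelse(copies > normal, "gain",
                   ifelse(copies < normal, "loss", "normal"))
  names(deltas) <- names(copies)
  list(normal_state = normal, deltas = deltas)
}

#' Copy-state of a rare or de novo CNV call
#'
#' Rare calls are compared against the fixed reference state: two on
#' autosomes; on X, one for males and two for females; on Y, one for males
#' and zero for females.  Sex-chromosomal calls for individuals of unknown
#' sex get an `NA` state.
#'
#' @param copy_number non-negative integer vector.
#' @param chrom chromosome label(s); defaults to autosomal behaviour.
#' @param sex `male`/`female`/`unknown`, recycled.
#' @return character vector of `loss`/`gain`/`normal` (or `NA`).
#' @export
#' @examples
#' rare_cnv_delta(0)                      # loss
#' rare_cnv_delta(3)                      # gain
#' rare_cnv_delta(2, chrom = "X", sex = "male")  # gain (male X reference 1)
rare_cnv_delta <- function(copy_number, chrom = "1", sex = "female") {
  if (any(copy_number < 0)) stop("negative copy number", call. = FALSE)
  n <- length(copy_number)
  chrom <- rep_len(normalize_chrom(chrom), n)
  sex <- rep_len(sex, n)
  ref <- rep(2, n)
  ref[chrom == "X" & sex == "male"] <- 1
  ref[chrom == "Y" & sex == "male"] <- 1
  ref[chrom == "Y" & sex == "female"] <- 0
  ref[(chrom %in% c("X", "Y")) & sex == "unknown"] <- NA
  ifelse(is.na(ref), NA_character_,
         ifelse(copy_number < ref, "loss",
                ifelse(copy_number > ref, "gain", "normal")))
}

#' Merge two callers' CNV calls for one sample
#'
#' Candidate pairs (one call per caller, same state) whose overlap fraction
#' reaches `min_overlap` are matched one-to-one greedily by descending
#' overlap (ties broken by leftmost caller-A start, then caller-B start);
#' each source call contributes to at most one consensus CNV.  The consensus
#' interval is the outer envelope of the pair, its probe count the maximum of
#' the two sources, its copy number taken from the caller-A call.  Caller-B
#' calls below the `min_conf_b` confidence are ignored up front.
#'
#' @param calls_a,calls_b call data frames for the same single sample.
#' @param min_overlap minimum overlap fraction (default 0.5).
#' @param min_size minimum consensus length in bp (default 20000).
#' @param min_probes minimum probe support (default 5).
#' @param mode overlap denominator: `"of_a"` (fraction of the caller-A
#'   segment, default) or `"reciprocal"`.
#' @param min_conf_b confidence pre-filter on caller-B calls (default 10).
#' @return data frame of consensus CNVs (`family_id`, `sample_id`, `chrom`,
#'   `start`, `end`, `state`, `copy_number`, `n_probes`, `confidence`,
#'   `caller` = "A+B", `overlap`).
#' @export
merge_two_callers <- function(calls_a, calls_b, min_overlap = 0.5,
                              min_size = 20000, min_probes = 5,
                              mode = c("of_a", "reciprocal"),
                              min_conf_b = 10) {
  mode <- match.arg(mode)
  samples <- unique(c(calls_a$sample_id, calls_b$sample_id))
  if (length(samples) > 1L) {
    stop("merge_two_callers expects calls of a single sample; got ",
         length(samples), call. = FALSE)
  }
  calls_b <- calls_b[calls_b$confidence >= min_conf_b, , drop = FALSE]
  out <- empty_merged_table()
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) return(out)

  for (st in c("loss", "gain")) {
    a <- calls_a[!is.na(calls_a$state) & calls_a$state == st, , drop = FALSE]
    b <- calls_b[!is.na(calls_b$state) & calls_b$state == st, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    ## all candidate pairs above threshold
    hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b))
    ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
    if (!length(ai)) next
    ov <- intersect_length(a$start[ai], a$end[ai], b$start[bi], b$end[bi])
    frac <- ov / interval_length(a$start[ai], a$end[ai])
    if (mode == "reciprocal") {
      frac <- pmin(frac, ov / interval_length(b$start[bi], b$end[bi]))
    }
    keep <- frac >= min_overlap
    ai <- ai[keep]; bi <- bi[keep]; frac <- frac[keep]
    if (!length(ai)) next
    ord <- order(-frac, a$start[ai], b$start[bi])
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (j in ord) {
      if (used_a[ai[j]] || used_b[bi[j]]) next
      used_a[ai[j]] <- TRUE; used_b[bi[j]] <- TRUE
      ra <- a[ai[j], ]; rb <- b[bi[j], ]
      merged <- data.frame(
        family_id = ra$family_id, sample_id = ra$sample_id,
        chrom = ra$chrom,
        start = min(ra$start, rb$start), end = max(ra$end, rb$end),
        state = st, copy_number = ra$copy_number,
        n_probes = max(ra$n_probes, rb$n_probes),
        confidence = min(ra$confidence, rb$confidence),
        caller = "A+B", overlap = frac[j], stringsAsFactors = FALSE
      )
      out <- rbind(out, merged)
    }
  }
  if (nrow(out)) {
    out <- out[interval_length(out$start, out$end) >= min_size &
                 out$n_probes >= min_probes, , drop = FALSE]
    out <- out[order(chrom_order(out$chrom), out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

empty_merged_table <- function() {
  data.frame(family_id = character(), sample_id = character(),
             chrom = character(), start = numeric(), end = numeric(),
             state = character(), copy_number = integer(),
             n_probes = integer(), confidence = numeric(),
             caller = character(), overlap = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge two callers' call tables across a cohort
#'
#' Applies [merge_two_callers()] sample by sample; samples present in only
#' one caller's output yield no consensus calls.
#'
#' @inheritParams merge_two_callers
#' @return consensus call data frame with a `cnv_id` column.
#' @export
merge_cohort <- function(calls_a, calls_b, min_overlap = 0.5,
                         min_size = 20000, min_probes = 5,
                         mode = c("of_a", "reciprocal"), min_conf_b = 10) {
  mode <- match.arg(mode)
  samples <- sort(intersect(unique(calls_a$sample_id),
                            unique(calls_b$sample_id)))
  pieces <- lapply(samples, function(s) {
    merge_two_callers(calls_a[calls_a$sample_id == s, , drop = FALSE],
                      calls_b[calls_b$sample_id == s, , drop = FALSE],
                      min_overlap, min_size, min_probes, mode, min_conf_b)
  })
  out <- do.call(rbind, c(list(empty_merged_table()), pieces))
  rownames(out) <- NULL
  ensure_cnv_ids(out)
}
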