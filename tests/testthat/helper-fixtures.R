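# In-code fixtures shared across the suite.

mk_cnv <- function(sample_id, chrom, start, end, copy_number = 3,
                   family_id = "F1", n_probes = 10, confidence = 20,
                   caller = "A",
                   state = if (copy_number < 2) "loss" else "gain") {
  data.frame(family_id = family_id, sample_id = sample_id,
             chrom = as.character(chrom), start = start, end = end,
             copy_number = as.integer(copy_number), state = state,
             n_probes = as.integer(n_probes), confidence = confidence,
             caller = caller, stringsAsFactors = FALSE)
}

mk_cnvs <- function(...) do.call(rbind, list(...))

mk_track <- function(chrom, start, end, name = NULL) {
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = name %||% sprintf("rec%d", seq_along(start)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A nuclear family: founder couple P1/P2, offspring S1 (affected), S2
# (unaffected); optionally more children.
mk_nuclear_ped <- function(fid = "F1",
                           pheno = c(P1 = "unaffected", P2 = "unaffected",
                                     S1 = "affected", S2 = "unaffected")) {
  ids <- names(pheno)
  founders <- c("P1", "P2")
  as_pedigree(data.frame(
    family_id = fid, individual_id = ids,
    father_id = ifelse(ids %in% founders, NA, "P1"),
    mother_id = ifelse(ids %in% founders, NA, "P2"),
    sex = ifelse(ids == "P1", "male",
                 ifelse(ids == "P2", "female", "male")),
    phenotype = unname(pheno), stringsAsFactors = FALSE))
}

# Multi-family cohort pedigree of unrelated sib groups for association and
# permutation tests: n_fam families, sibs per family, all founder pairs.
mk_cohort_ped <- function(n_fam, n_sib = 4, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_fam), function(f) {
    fid <- sprintf("F%03d", f)
    ids <- sprintf("%s_S%d", fid, seq_len(n_sib))
    data.frame(
      family_id = fid,
      individual_id = c(sprintf("%s_P1", fid), sprintf("%s_P2", fid), ids),
      father_id = c(NA, NA, rep(sprintf("%s_P1", fid), n_sib)),
      mother_id = c(NA, NA, rep(sprintf("%s_P2", fid), n_sib)),
      sex = c("male", "female",
              sample(c("male", "female"), n_sib, replace = TRUE)),
      phenotype = sample(c("affected", "unaffected"), n_sib + 2,
                         replace = TRUE),
      stringsAsFactors = FALSE)
  })
  as_pedigree(do.call(rbind, rows))
}

# Brute-force oracle: overlap length by enumerating covered bases on a
# scaled-down copy of the intervals (scale must divide the coordinates).
enumerate_overlap <- function(s1, e1, s2, e2, scale = 1) {
  length(intersect(seq(s1 / scale, e1 / scale), seq(s2 / scale, e2 / scale)))
}

# Brute-force one-sided Fisher p by explicit binomial-coefficient
# enumeration of the hypergeometric upper tail (independent of phyper).
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  hi <- min(m, k)
  if (a > hi) return(0)
  j <- a:hi
  sum(exp(lchoose(m, j) + lchoose(n, k - j) - lchoose(m + n, k)))
}

# Exhaustive maximum-total-overlap one-to-one matching between two small
# call sets (oracle for the greedy merge), returning the maximal total
# overlap fraction achievable.
exhaustive_best_matching <- function(frac_mat, thr) {
  frac_mat[frac_mat < thr] <- NA
  best <- 0
  recurse <- function(ai, used_b, tot) {
    if (ai > nrow(frac_mat)) {
      best <<- max(best, tot)
      return(invisible())
    }
    recurse(ai + 1L, used_b, tot)  # leave A unmatched
    for (bi in seq_len(ncol(frac_mat))) {
      if (!used_b[bi] && !is.na(frac_mat[ai, bi])) {
        used_b[bi] <- TRUE
        recurse(ai + 1L, used_b, tot + frac_mat[ai, bi])
        used_b[bi] <- FALSE
      }
    }
  }
  recurse(1L, logical(ncol(frac_mat)), 0)
  best
}
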