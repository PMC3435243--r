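## Pooling of overlapping CNVs into loci and affected-versus-unaffected
## association under three copy-state models, with a family random intercept
## (Laplace-fitted logistic mixed model) and a one-sided Fisher exact
## fallback when the mixed fit does not converge.

#' Pool overlapping CNVs into loci
#'
#' Pools are the connected components of the interval-overlap graph (>= 1 bp
#' overlap on the same chromosome; abutting intervals do not pool).  Pool
#' ids are assigned deterministically by (chromosome, envelope start).
#'
#' @param cnvs merged CNV data frame.
#' @return a `cnv_pools`: list with `pools` (pool_id, chrom, start, end,
#'   n_members) and `assignments` (the input rows plus a `pool_id` column).
#' @export
build_pools <- function(cnvs) {
  cnvs <- ensure_cnv_ids(cnvs)
  if (nrow(cnvs) == 0L) {
    pools <- data.frame(pool_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        n_members = integer(), stringsAsFactors = FALSE)
    res <- list(pools = pools, assignments = cbind(cnvs,
                  pool_id = character(0)))
    class(res) <- "cnv_pools"
    return(res)
  }
  gr <- as_granges(cnvs)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ord <- order(chrom_order(as.character(GenomicRanges::seqnames(red))),
               GenomicRanges::start(red))
  red <- red[ord]
  hits <- GenomicRanges::findOverlaps(gr, red)
  pool_idx <- integer(nrow(cnvs))
  pool_idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  ids <- sprintf("POOL%04d", seq_along(red))
  cnvs$pool_id <- ids[pool_idx]
  pools <- data.frame(
    pool_id = ids,
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red), end = GenomicRanges::end(red),
    n_members = as.integer(table(factor(pool_idx,
                                        levels = seq_along(red)))),
    stringsAsFactors = FALSE
  )
  res <- list(pools = pools, assignments = cnvs)
  class(res) <- "cnv_pools"
  res
}

#' @export
print.cnv_pools <- function(x, ...) {
  cat(sprintf("%d CNV pool(s) over %d CNV call(s)\n",
              nrow(x$pools), nrow(x$assignments)))
  print(head(x$pools, 10), row.names = FALSE)
  if (nrow(x$pools) > 10) cat("...\n")
  invisible(x)
}

#' One-sided Fisher exact p for carrier enrichment in affecteds
#'
#' The one-sided Fisher exact p of a 2x2 carrier-by-phenotype table is the
#' upper hypergeometric tail of the affected-carrier count given the table
#' margins.
#'
#' @param a affected carriers.
#' @param b unaffected carriers.
#' @param c_ affected non-carriers.
#' @param d unaffected non-carriers.
#' @return p-value for the alternative "carriers enriched in affecteds".
#' @export
fisher_one_sided <- function(a, b, c_, d) {
  ## X ~ Hypergeom(m = carriers, n = non-carriers, k = affecteds); P(X >= a)
  phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
}

## Logistic association of phenotype on a per-sample predictor with a family
## random intercept; Wald (default) or likelihood-ratio p.  Falls back to the
## one-sided Fisher exact test when the mixed fit does not converge or the
## predictor is degenerate.  `x` may be 0/1 or a copy-number dosage.
family_logistic_test <- function(y, x, family_id,
                                 test = c("wald", "lrt"), max_iter = 100) {
  test <- match.arg(test)
  if (all(y) || !any(y)) {
    stop("no variation in phenotype", call. = FALSE)
  }
  carrier <- x > 0
  fallback <- function() {
    tab <- table(factor(carrier, levels = c(TRUE, FALSE)),
                 factor(y, levels = c(TRUE, FALSE)))
    p <- fisher_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    list(estimate = NA_real_, p_value = p, method = "fisher_one_sided",
         converged = FALSE)
  }
  if (length(unique(x)) < 2L) return(fallback())

  fit <- NULL
  bad <- FALSE
  withCallingHandlers(
    message = function(m) {
      ## a boundary (singular) random-effect fit is a valid outcome, not a
      ## convergence failure; keep the log quiet
      if (grepl("singular", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    },
    fit <- tryCatch(
      lme4::glmer(y ~ x + (1 | fam), family = binomial(),
                  data = data.frame(y = y, x = x, fam = family_id),
                  control = lme4::glmerControl(
                    optCtrl = list(maxfun = 100 * max_iter),
                    check.conv.grad =
                      lme4::.makeCC("warning", tol = 2e-3, relTol = NULL))),
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge|Hessian|singular fit|unable to evaluate",
                conditionMessage(w), ignore.case = TRUE) &&
          !grepl("boundary", conditionMessage(w))) {
        bad <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || bad) return(fallback())
  sm <- summary(fit)$coefficients
  if (!("x" %in% rownames(sm))) return(fallback())
  est <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  if (!is.finite(est) || !is.finite(se) || abs(est) > 15 || se > 50) {
    return(fallback())  # quasi-separation
  }
  p <- if (test == "wald") {
    sm["x", "Pr(>|z|)"]
  } else {
    fit0 <- tryCatch(
      lme4::glmer(y ~ 1 + (1 | fam), family = binomial(),
                  data = data.frame(y = y, fam = family_id)),
      error = function(e) NULL)
    if (is.null(fit0)) return(fallback())
    stats::pchisq(2 * (as.numeric(stats::logLik(fit)) -
                         as.numeric(stats::logLik(fit0))),
                  df = 1, lower.tail = FALSE)
  }
  list(estimate = est, p_value = as.numeric(p),
       method = "random_effect_logistic", converged = TRUE)
}

## Fixed-covariate variant used for the case-versus-control contrast, where
## the family random intercept is replaced by the first two PC coordinates.
pc_logistic_test <- function(y, x, pcs) {
  if (all(y) || !any(y)) stop("no variation in phenotype", call. = FALSE)
  carrier <- x > 0
  fallback <- function() {
    tab <- table(factor(carrier, levels = c(TRUE, FALSE)),
                 factor(y, levels = c(TRUE, FALSE)))
    p <- fisher_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    list(estimate = NA_real_, p_value = p, method = "fisher_one_sided",
         converged = FALSE)
  }
  if (length(unique(x)) < 2L) return(fallback())
  dat <- data.frame(y = y, x = x, pc1 = pcs[, 1], pc2 = pcs[, 2])
  fit <- suppressWarnings(glm(y ~ x + pc1 + pc2, binomial(), data = dat))
  sm <- summary(fit)$coefficients
  if (!fit$converged || !("x" %in% rownames(sm))) return(fallback())
  est <- sm["x", "Estimate"]
  if (!is.finite(est) || abs(est) > 15 || sm["x", "Std. Error"] > 50) {
    return(fallback())
  }
  list(estimate = est, p_value = sm["x", "Pr(>|z|)"],
       method = "pc_adjusted_logistic", converged = TRUE)
}

carrier_vector <- function(pool_members, samples, model, coding) {
  st <- switch(model, dup_vs_normal = "gain", del_vs_normal = "loss",
               any_vs_normal = c("loss", "gain"))
  mem <- pool_members[pool_members$state %in% st, , drop = FALSE]
  if (coding == "indicator") {
    as.numeric(samples %in% mem$sample_id)
  } else {
    dose <- tapply(abs(mem$copy_number - 2), mem$sample_id, max)
    out <- numeric(length(samples))
    hit <- match(names(dose), samples)
    out[hit[!is.na(hit)]] <- as.numeric(dose[!is.na(hit)])
    out
  }
}

#' Test one CNV pool for enrichment in affected individuals
#'
#' Fits a logistic model of affection status on carrier status with a
#' family-level random intercept (Laplace approximation, Wald p by default).
#' When the mixed fit fails to converge — or the carrier predictor is
#' degenerate — a one-sided Fisher exact test on the 2x2 carrier-by-
#' phenotype table is used instead (alternative: carriers enriched in
#' affecteds).
#'
#' @param pools a `cnv_pools` from [build_pools()].
#' @param pool_id pool to test.
#' @param pedigree a `cnv_pedigree` giving phenotypes and families.
#' @param model `"dup_vs_normal"`, `"del_vs_normal"` or `"any_vs_normal"`.
#' @param samples optional sample universe (default: phenotyped pedigree
#'   members).
#' @param test `"wald"` (default) or `"lrt"`.
#' @param carrier_coding `"indicator"` (0/1 carrier, default) or
#'   `"copy_number"` (absolute dosage deviation from two).
#' @return one-row data frame: `pool_id`, `model`, `estimate` (log-odds),
#'   `p_value`, `method`, `converged`, `n_carriers_affected`,
#'   `n_carriers_unaffected`.
#' @export
pool_association <- function(pools, pool_id, pedigree,
                             model = c("any_vs_normal", "dup_vs_normal",
                                       "del_vs_normal"),
                             samples = NULL, test = c("wald", "lrt"),
                             carrier_coding = c("indicator", "copy_number")) {
  model <- match.arg(model)
  test <- match.arg(test)
  carrier_coding <- match.arg(carrier_coding)
  ped <- pedigree[pedigree$phenotype != "unknown", , drop = FALSE]
  if (!is.null(samples)) {
    ped <- ped[ped$individual_id %in% samples, , drop = FALSE]
  }
  mem <- pools$assignments[pools$assignments$pool_id == pool_id, ,
                           drop = FALSE]
  x <- carrier_vector(mem, ped$individual_id, model, carrier_coding)
  y <- ped$phenotype == "affected"
  r <- family_logistic_test(y, x, ped$family_id, test)
  data.frame(pool_id = pool_id, model = model, estimate = r$estimate,
             p_value = r$p_value, method = r$method, converged = r$converged,
             n_carriers_affected = sum(x > 0 & y),
             n_carriers_unaffected = sum(x > 0 & !y),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1].
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 535)  # 9.346e-05
#' bonferroni_threshold(0.05, 9)    # 5.556e-03
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]",
                                       call. = FALSE)
  if (length(m) != 1L || m < 1 || m != floor(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Screen all CNV pools under the three copy-state models
#'
#' Runs [pool_association()] for every pool under the duplication, deletion
#' and any-CNV models.  With `covariate_pcs` supplied the family random
#' effect is replaced by the first two PC coordinates as fixed covariates
#' (case-versus-control contrast mode).  Results carry significance flags at
#' the nominal level and at the Bonferroni threshold over the number of
#' pools tested; the threshold over pools x models is attached as an
#' attribute, since either denominator is defensible.
#'
#' @inheritParams pool_association
#' @param covariate_pcs optional data frame/matrix of per-sample 2-D PC
#'   coordinates with rownames or an `individual_id` column.
#' @param alpha nominal significance level (default 0.05).
#' @return data frame of association results ordered by p-value, with
#'   columns `significant_nominal` and `significant_bonferroni`; attributes
#'   `bonferroni_pools` and `bonferroni_tests` hold the two thresholds.
#' @export
enrichment_screen <- function(pools, pedigree, covariate_pcs = NULL,
                              alpha = 0.05, samples = NULL,
                              test = c("wald", "lrt"),
                              carrier_coding = c("indicator",
                                                 "copy_number")) {
  test <- match.arg(test)
  carrier_coding <- match.arg(carrier_coding)
  ids <- pools$pools$pool_id
  if (!length(ids)) {
    out <- data.frame(pool_id = character(), model = character(),
                      estimate = numeric(), p_value = numeric(),
                      method = character(), converged = logical(),
                      n_carriers_affected = integer(),
                      n_carriers_unaffected = integer(),
                      significant_nominal = logical(),
                      significant_bonferroni = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "bonferroni_pools") <- NA_real_
    attr(out, "bonferroni_tests") <- NA_real_
    return(out)
  }
  ped <- pedigree[pedigree$phenotype != "unknown", , drop = FALSE]
  if (!is.null(samples)) {
    ped <- ped[ped$individual_id %in% samples, , drop = FALSE]
  }
  pcs <- NULL
  if (!is.null(covariate_pcs)) {
    if (is.data.frame(covariate_pcs) &&
        !is.null(covariate_pcs$individual_id)) {
      rn <- covariate_pcs$individual_id
      pcs <- as.matrix(covariate_pcs[, setdiff(names(covariate_pcs),
                                               "individual_id")])
      rownames(pcs) <- rn
    } else {
      pcs <- as.matrix(covariate_pcs)
    }
    pcs <- pcs[match(ped$individual_id, rownames(pcs)), , drop = FALSE]
    if (anyNA(pcs)) stop("missing PC coordinates for some samples",
                         call. = FALSE)
  }
  y <- ped$phenotype == "affected"
  models <- c("dup_vs_normal", "del_vs_normal", "any_vs_normal")
  rows <- list()
  for (pid in ids) {
    mem <- pools$assignments[pools$assignments$pool_id == pid, ,
                             drop = FALSE]
    for (mdl in models) {
      x <- carrier_vector(mem, ped$individual_id, mdl, carrier_coding)
      if (!any(x > 0)) next  # no carriers under this state model
      r <- if (is.null(pcs)) {
        family_logistic_test(y, x, ped$family_id, test)
      } else {
        pc_logistic_test(y, x, pcs)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pool_id = pid, model = mdl, estimate = r$estimate,
        p_value = r$p_value, method = r$method, converged = r$converged,
        n_carriers_affected = sum(x > 0 & y),
        n_carriers_unaffected = sum(x > 0 & !y),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  bon_pools <- bonferroni_threshold(alpha, length(ids))
  bon_tests <- bonferroni_threshold(alpha, length(ids) * length(models))
  out$significant_nominal <- out$p_value < alpha
  out$significant_bonferroni <- out$p_value < bon_pools
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bonferroni_pools") <- bon_pools
  attr(out, "bonferroni_tests") <- bon_tests
  out
}
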