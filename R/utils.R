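#' @importFrom methods is
#' @importFrom stats sd rbinom rpois runif rnorm rlnorm qnorm pnorm phyper
#'   binomial coef glm ks.test rank setNames
#' @importFrom utils read.table write.table head
NULL

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

#' Round half away from zero
#'
#' Rounding convention used wherever a displayed value has to match a
#' fixed-precision rendering (copy-state means, percentage tables).  Unlike
#' [base::round()], which rounds half to even, halves move away from zero
#' (2.5 -> 3, -2.5 -> -3).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(2.5)   # 3, where round(2.5) == 2
#' round_half_away(10.95, 1)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Normalize chromosome labels: strip "chr", validate against 1..22, X, Y.
normalize_chrom <- function(chrom, context = "chromosome") {
  chrom <- sub("^chr", "", as.character(chrom))
  bad <- !(chrom %in% CHROM_LEVELS)
  if (any(bad)) {
    stop(sprintf("unknown %s label(s): %s", context,
                 paste(unique(chrom[bad]), collapse = ", ")), call. = FALSE)
  }
  chrom
}

chrom_order <- function(chrom) match(chrom, CHROM_LEVELS)

is_autosome <- function(chrom) chrom %in% as.character(1:22)

## GRanges from a data.frame with chrom/start/end (internal 1-based inclusive).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = CHROM_LEVELS),
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

## Stable per-row CNV identifiers.  Existing ids are kept.
ensure_cnv_ids <- function(cnvs, prefix = "CNV") {
  if (is.null(cnvs$cnv_id)) {
    cnvs$cnv_id <- sprintf("%s%05d", prefix, seq_len(nrow(cnvs)))
  } else if (anyDuplicated(cnvs$cnv_id)) {
    stop("duplicated cnv_id values", call. = FALSE)
  }
  cnvs
}

## Minimal union-find used for familial event grouping.
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in edges) {
      ri <- find(e[1]); rj <- find(e[2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
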