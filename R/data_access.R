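#' Published candidate-gene evidence values
#'
#' Loads the printed evidence values for the 25 left-sided CHD candidate
#' genes shipped with the package (rank-fusion p, SAGE outflow-tract fold
#' enrichment, curated in-situ expression flag, transmission pattern and
#' genomic location).  `nd`/`NA` entries become `NA`.  All 25 genes were
#' reported as candidates, so the expected verdict is `TRUE` throughout;
#' feeding these values to [build_evidence_profiles()] reproduces that
#' verdict under the 2-of-3 rule.
#'
#' @return data frame with columns `gene`, `fusion_p`, `sage_fold`, `flag`,
#'   `transmission`, `location`.
#' @export
candidate_evidence_table <- function() {
  path <- system.file("extdata", "lschd_candidate_evidence.tsv",
                      package = "cnvfam", mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("nd", "NA"))
  df$fusion_p <- as.numeric(df$fusion_p)
  df$sage_fold <- as.numeric(df$sage_fold)
  df
}
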