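## Readers and writers for the external files the pipeline touches.
## Conventions:
##   * CNV tables follow the PLINK .cnv dialect with a header row:
##     FID IID CHR BP1 BP2 TYPE NPROBES CONF [SOURCE] [STATE]
##     TYPE is the integer copy number; coordinates are 1-based inclusive.
##   * Pedigrees are 6-column PED (FID IID PAT MAT SEX PHENO), no header;
##     SEX 1=male 2=female 0=unknown; PHENO 2=affected 1=unaffected
##     0/-9=unknown; founder parent ids are "0".
##   * BED is 0-based half-open on disk and converted to 1-based inclusive
##     internally at this boundary (and back on write).

#' Read a PLINK-style CNV call table
#'
#' @param path path to a whitespace-delimited file with header columns
#'   `FID IID CHR BP1 BP2 TYPE NPROBES CONF` and optional `SOURCE`/`STATE`.
#' @param caller_tag source tag (`"A"` or `"B"`) attached to every call;
#'   ignored when the file carries a `SOURCE` column.
#' @return a `data.frame` of calls with columns `family_id`, `sample_id`,
#'   `chrom`, `start`, `end`, `copy_number`, `state`, `n_probes`,
#'   `confidence`, `caller`.  Copy states on autosomes are derived against
#'   the reference state of two; sex-chromosomal states are left `NA` unless
#'   a `STATE` column is present (see [assign_cnv_states()]).
#' @export
read_cnv_table <- function(path, caller_tag = c("A", "B")) {
  caller_tag <- match.arg(caller_tag)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("FID", "IID", "CHR", "BP1", "BP2", "TYPE", "NPROBES", "CONF")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CNV table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  if (n == 0L) return(empty_cnv_table())
  line_no <- seq_len(n) + 1L  # header is line 1

  num <- function(col, what, integerish = TRUE) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | (integerish & v != floor(v))
    if (any(bad)) {
      stop(sprintf("parse error at line %d: bad %s '%s'",
                   line_no[which(bad)[1]], what, df[[col]][which(bad)[1]]),
           call. = FALSE)
    }
    v
  }
  bp1 <- num("BP1", "BP1"); bp2 <- num("BP2", "BP2")
  cn <- num("TYPE", "copy number")
  np <- num("NPROBES", "probe count")
  conf <- num("CONF", "confidence", integerish = FALSE)

  bad <- which(bp1 > bp2)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: BP1 > BP2", line_no[bad[1]]),
         call. = FALSE)
  }
  if (any(bp1 < 1)) {
    stop(sprintf("parse error at line %d: start < 1",
                 line_no[which(bp1 < 1)[1]]), call. = FALSE)
  }
  if (any(cn < 0)) {
    stop(sprintf("parse error at line %d: negative copy number",
                 line_no[which(cn < 0)[1]]), call. = FALSE)
  }
  if (any(np < 1)) {
    stop(sprintf("parse error at line %d: probe count < 1",
                 line_no[which(np < 1)[1]]), call. = FALSE)
  }
  chrom <- normalize_chrom(df$CHR)

  calls <- data.frame(
    family_id = df$FID, sample_id = df$IID, chrom = chrom,
    start = bp1, end = bp2, copy_number = as.integer(cn),
    state = NA_character_, n_probes = as.integer(np), confidence = conf,
    caller = if (is.null(df$SOURCE)) caller_tag else df$SOURCE,
    stringsAsFactors = FALSE
  )
  if (!is.null(df$STATE)) {
    st <- df$STATE
    bad <- !(st %in% c("loss", "gain", "normal"))
    if (any(bad)) {
      stop(sprintf("parse error at line %d: unknown state '%s'",
                   line_no[which(bad)[1]], st[which(bad)[1]]), call. = FALSE)
    }
    calls$state <- st
  } else {
    auto <- is_autosome(calls$chrom)
    calls$state[auto] <- rare_cnv_delta(calls$copy_number[auto])
  }
  flat <- which(is_autosome(calls$chrom) & calls$state == "normal")
  if (length(flat)) {
    stop(sprintf(paste0("parse error at line %d: autosomal copy number equals",
                        " the reference state (2); normal-state rows are not",
                        " CNV calls"), line_no[flat[1]]), call. = FALSE)
  }
  calls
}

empty_cnv_table <- function() {
  data.frame(family_id = character(), sample_id = character(),
             chrom = character(), start = numeric(), end = numeric(),
             copy_number = integer(), state = character(),
             n_probes = integer(), confidence = numeric(),
             caller = character(), stringsAsFactors = FALSE)
}

#' Write a CNV call table in the PLINK-style dialect
#'
#' @param calls a call `data.frame` as returned by [read_cnv_table()] or
#'   [merge_two_callers()] (an `overlap` column, if present, is written too).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(calls, path) {
  out <- data.frame(FID = calls$family_id, IID = calls$sample_id,
                    CHR = calls$chrom, BP1 = calls$start, BP2 = calls$end,
                    TYPE = calls$copy_number, NPROBES = calls$n_probes,
                    CONF = calls$confidence, SOURCE = calls$caller,
                    STATE = calls$state, stringsAsFactors = FALSE)
  if (!is.null(calls$overlap)) out$OVERLAP <- calls$overlap
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Assign loss/gain/normal states to CNV calls
#'
#' Autosomal calls are compared against the reference state of two; X and Y
#' calls against the sex-specific reference (X: male 1, female 2; Y: male 1,
#' female 0), with sexes looked up in `pedigree`.
#'
#' @param calls a CNV call `data.frame`.
#' @param pedigree a pedigree (see [read_pedigree()]); may be omitted when
#'   all calls are autosomal.
#' @return `calls` with the `state` column filled in.
#' @export
assign_cnv_states <- function(calls, pedigree = NULL) {
  if (nrow(calls) == 0L) return(calls)
  sex <- rep("unknown", nrow(calls))
  if (!is.null(pedigree)) {
    sex <- pedigree$sex[match(calls$sample_id, pedigree$individual_id)]
    sex[is.na(sex)] <- "unknown"
  }
  calls$state <- rare_cnv_delta(calls$copy_number, calls$chrom, sex)
  calls
}

#' Read a BED track
#'
#' BED coordinates (0-based, half-open) are converted to the internal 1-based
#' inclusive convention: `start = bed_start + 1`, `end = bed_end`.
#'
#' @param path path to a BED3+ file (no header).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr8\t999\t1100\tregion1", f)
#' read_bed_track(f)  # interval 1000..1100, length 101
read_bed_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(df) < 3L) stop("BED track needs >= 3 columns", call. = FALSE)
  bs <- suppressWarnings(as.numeric(df[[2]]))
  be <- suppressWarnings(as.numeric(df[[3]]))
  if (any(is.na(bs) | is.na(be))) {
    stop("non-numeric BED coordinates", call. = FALSE)
  }
  if (any(bs < 0 | be < 0)) stop("negative BED coordinates", call. = FALSE)
  if (any(be <= bs)) stop("BED end must exceed start", call. = FALSE)
  data.frame(
    chrom = normalize_chrom(df[[1]]),
    start = bs + 1, end = be,
    name = if (ncol(df) >= 4L) as.character(df[[4]])
           else sprintf("rec%d", seq_len(nrow(df))),
    stringsAsFactors = FALSE
  )
}

#' Write a BED track
#'
#' Internal 1-based inclusive intervals are converted back to BED's 0-based
#' half-open coordinates, with a `chr` prefix restored on the chromosome.
#'
#' @param track a track `data.frame` (`chrom`, `start`, `end`, `name`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(track, path) {
  out <- data.frame(chrom = paste0("chr", track$chrom),
                    start = track$start - 1, end = track$end,
                    name = track$name, stringsAsFactors = FALSE)
  write.table(out, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column PED pedigree
#'
#' Validates parental references (a named father must be a male individual of
#' the same family, symmetrically for mothers), rejects parent cycles, and
#' maps the numeric sex/phenotype codes to labels.
#'
#' @param path whitespace-delimited PED file, no header.
#' @return a `cnv_pedigree` data frame with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id` (`NA` for founders), `sex`
#'   (`male`/`female`/`unknown`) and `phenotype`
#'   (`affected`/`unaffected`/`unknown`).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 6L) stop("pedigree needs 6 columns", call. = FALSE)
  ped <- data.frame(
    family_id = df[[1]], individual_id = df[[2]],
    father_id = ifelse(df[[3]] == "0", NA_character_, df[[3]]),
    mother_id = ifelse(df[[4]] == "0", NA_character_, df[[4]]),
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[df[[5]]],
    phenotype = c("0" = "unknown", "-9" = "unknown",
                  "1" = "unaffected", "2" = "affected")[df[[6]]],
    stringsAsFactors = FALSE
  )
  if (anyNA(ped$sex)) {
    stop("invalid sex code: ", df[[5]][which(is.na(ped$sex))[1]],
         call. = FALSE)
  }
  if (anyNA(ped$phenotype)) {
    stop("invalid phenotype code: ", df[[6]][which(is.na(ped$phenotype))[1]],
         call. = FALSE)
  }
  as_pedigree(ped)
}

#' Validate a pedigree data frame
#'
#' @param ped data frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype`.
#' @return the validated `cnv_pedigree` object.
#' @export
as_pedigree <- function(ped) {
  key <- paste(ped$family_id, ped$individual_id)
  if (anyDuplicated(key)) {
    stop("duplicated (family, individual) id: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  check_parent <- function(pid_col, expected_sex, what) {
    has <- !is.na(ped[[pid_col]])
    idx <- match(paste(ped$family_id, ped[[pid_col]])[has], key)
    if (anyNA(idx)) {
      missing_id <- ped[[pid_col]][has][which(is.na(idx))[1]]
      stop(sprintf("%s id '%s' not found in family", what, missing_id),
           call. = FALSE)
    }
    wrong <- ped$sex[idx] != expected_sex
    if (any(wrong)) {
      stop(sprintf("%s id '%s' is not %s", what,
                   ped[[pid_col]][has][which(wrong)[1]], expected_sex),
           call. = FALSE)
    }
  }
  check_parent("father_id", "male", "father")
  check_parent("mother_id", "female", "mother")

  ## cycle check: repeatedly peel individuals whose parents are all peeled
  n <- nrow(ped)
  fi <- match(paste(ped$family_id, ped$father_id), key)
  mi <- match(paste(ped$family_id, ped$mother_id), key)
  done <- logical(n)
  repeat {
    ready <- !done &
      (is.na(fi) | done[ifelse(is.na(fi), 1L, fi)]) &
      (is.na(mi) | done[ifelse(is.na(mi), 1L, mi)])
    if (!any(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done)) {
    stop("pedigree contains a parent cycle involving individual ",
         ped$individual_id[which(!done)[1]], call. = FALSE)
  }
  class(ped) <- c("cnv_pedigree", "data.frame")
  ped
}

#' Write a pedigree as 6-column PED
#'
#' @param ped a `cnv_pedigree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    c(unknown = "0", male = "1", female = "2")[ped$sex],
    c(unknown = "0", unaffected = "1", affected = "2")[ped$phenotype]
  )
  write.table(out, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SAGE tag-count table
#'
#' @param path TSV with header `gene compartment tag_count library_size`;
#'   compartments must be `outflow_tract`, `atrium` or `ventricle`.
#' @return validated `data.frame`.
#' @export
read_sage_table <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "compartment", "tag_count", "library_size")
  if (!all(need %in% names(df))) {
    stop("SAGE table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok <- df$compartment %in% c("outflow_tract", "atrium", "ventricle")
  if (!all(ok)) {
    stop("unknown compartment: ", df$compartment[which(!ok)[1]],
         call. = FALSE)
  }
  if (any(df$tag_count < 0) || any(df$library_size <= 0) ||
      any(df$tag_count > df$library_size)) {
    stop("invalid SAGE counts (need 0 <= tag_count <= library_size)",
         call. = FALSE)
  }
  df
}

#' Read a per-source gene score table
#'
#' @param path TSV with header `gene source score` (higher score = more
#'   similar to the training profile).
#' @return `data.frame`.
#' @export
read_score_table <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "source", "score")
  if (!all(need %in% names(df))) {
    stop("score table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a curated expression-flag table
#'
#' @param path TSV with header `gene flag`, flags `+` or `-`.
#' @return `data.frame`.
#' @export
read_flag_table <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("gene", "flag") %in% names(df))) {
    stop("flag table needs columns: gene, flag", call. = FALSE)
  }
  ok <- df$flag %in% c("+", "-")
  if (!all(ok)) stop("flags must be '+' or '-'", call. = FALSE)
  df
}
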