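## Seeded synthetic-cohort generator with planted ground truth.
##
## The generator emulates the study conditions the pipeline targets:
## three-generation multiplex pedigrees with ~37.5% affected members,
## ~15 autosomal CNV calls per individual (mostly common CNPs drifting
## through the pedigree by Mendelian transmission), recurrent artifact
## calls embedded in segmental duplications, caller-specific boundary
## jitter and false calls, and a handful of rare planted causal CNVs
## transmitted with the phenotype or arising de novo.  The genome is a
## single abstract coordinate system (22 "chromosomes" of configurable
## length): tests need controlled geometry, not real human coordinates.

#' Simulation configuration
#'
#' Defaults mirror the target cohort: 60 families over 3 generations,
#' affected fraction 0.375, ~15 autosomal calls per sample, 50 common CNP
#' loci, de novo probability 0.02 per offspring, caller boundary jitter of
#' 10% of the CNV length per end, and planted causal CNVs of complete
#' penetrance (the filter chain removes anything carried by an unaffected
#' relative, so only fully penetrant events are discoverable by design).
#'
#' @param seed RNG seed (mandatory).
#' @param n_families number of families (default 60).
#' @param generations pedigree depth (default 3).
#' @param affected_target_fraction target affected fraction (default 0.375).
#' @param mean_children mean extra children per couple beyond the first
#'   (Poisson; default 1.2).
#' @param marry_prob probability a lineage child founds the next generation
#'   (default 0.5).
#' @param n_common_cnps number of common CNP loci (default 50).
#' @param cnp_freq_range allele-frequency range of CNPs (default 0.05-0.30,
#'   giving ~15 carrier calls per sample).
#' @param n_segdup_regions segmental-duplication regions (default 10).
#' @param n_artifact_events recurrent segdup-embedded artifact call events
#'   (default 10).
#' @param n_planted_causal planted causal CNVs (default 5).
#' @param causal_penetrance P(affected | causal carrier) (default 1).
#' @param causal_founder_prob probability a causal event originates in a
#'   founder rather than arising de novo in an offspring (default 0.6).
#' @param de_novo_probability neutral de novo CNV probability per offspring
#'   (default 0.02).
#' @param jitter caller boundary jitter, fraction of CNV length per end
#'   (default 0.10).
#' @param fp_rate mean false-positive calls per sample per caller
#'   (default 1).
#' @param fn_rate per-caller false-negative (dropout) rate (default 0).
#'   The consensus merge demands both callers, so any dropout makes
#'   single-carrier planted events unrecoverable in proportion to
#'   `2 * fn_rate`; the default therefore emulates the validated consensus
#'   scenario in which both callers detect every true CNV, and dropout is
#'   studied through this knob rather than baked into the default planted
#'   truth.
#' @param n_controls control individuals (default 200).
#' @param n_genes genes in the gene track (default 400).
#' @param n_chrom,chrom_length abstract genome geometry (default 22 x 10 Mb).
#' @param probe_spacing array probe spacing in bp (default 2000).
#' @param evidence_fold SAGE outflow-tract boost for causal genes
#'   (default 6).
#' @param evidence_score_shift per-source score shift for causal genes
#'   (default 2.5).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_families = 60, generations = 3,
                       affected_target_fraction = 0.375,
                       mean_children = 1.2, marry_prob = 0.5,
                       n_common_cnps = 50,
                       cnp_freq_range = c(0.05, 0.30),
                       n_segdup_regions = 10, n_artifact_events = 10,
                       n_planted_causal = 5, causal_penetrance = 1,
                       causal_founder_prob = 0.6,
                       de_novo_probability = 0.02,
                       jitter = 0.10, fp_rate = 1, fn_rate = 0,
                       n_controls = 200, n_genes = 400,
                       n_chrom = 22, chrom_length = 1e7,
                       probe_spacing = 2000,
                       evidence_fold = 6, evidence_score_shift = 2.5) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_families < 1) stop("need at least one family", call. = FALSE)
  probs <- c(affected_target_fraction, marry_prob, causal_penetrance,
             causal_founder_prob, de_novo_probability, fn_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (jitter < 0 || jitter > 0.5) {
    stop("jitter must lie in [0, 0.5]", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate multiplex pedigrees
#'
#' Each family starts from a founder couple; lineage children found the
#' next generation with a married-in founder spouse.  Individuals are
#' emitted parents-before-children.  Phenotypes are set to `unknown` here
#' and assigned by [simulate_genome_and_cnvs()].
#'
#' @param config a [sim_config()].
#' @return a `cnv_pedigree`.
#' @export
simulate_pedigrees <- function(config) {
  set.seed(derive_seed(config$seed, 11L))
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("F%03d", f)
    counter <- 0L
    nid <- function() {
      counter <<- counter + 1L
      sprintf("%s_I%02d", fid, counter)
    }
    add <- function(id, fa, mo, sex) {
      rows[[length(rows) + 1L]] <<- data.frame(
        family_id = fid, individual_id = id,
        father_id = fa, mother_id = mo, sex = sex,
        phenotype = "unknown", stringsAsFactors = FALSE)
    }
    p1 <- nid(); add(p1, NA, NA, "male")
    p2 <- nid(); add(p2, NA, NA, "female")
    couples <- list(c(p1, p2))
    for (g in seq_len(config$generations - 1L)) {
      nxt <- list()
      for (cp in couples) {
        n_child <- 1L + min(rpois(1, config$mean_children), 4L)
        for (k in seq_len(n_child)) {
          sex <- sample(c("male", "female"), 1)
          child <- nid(); add(child, cp[1], cp[2], sex)
          if (g < config$generations - 1L &&
              runif(1) < config$marry_prob) {
            sp_sex <- if (sex == "male") "female" else "male"
            sp <- nid(); add(sp, NA, NA, sp_sex)
            nxt[[length(nxt) + 1L]] <-
              if (sex == "male") c(child, sp) else c(sp, child)
          }
        }
      }
      couples <- nxt
      if (!length(couples)) break
    }
  }
  as_pedigree(do.call(rbind, rows))
}

## Place n non-overlapping intervals with lengths drawn uniformly from
## len_range, avoiding `avoid` (with margin); rejection sampling.
place_intervals <- function(n, len_range, n_chrom, chrom_length,
                            avoid = NULL, margin = 0, max_tries = 10000) {
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), stringsAsFactors = FALSE)
  tries <- 0
  while (nrow(out) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("could not place intervals; genome too crowded", call. = FALSE)
    }
    len <- round(runif(1, len_range[1], len_range[2]))
    chrom <- as.character(sample.int(n_chrom, 1))
    start <- floor(runif(1, 1, chrom_length - len))
    cand <- data.frame(chrom = chrom, start = start - margin,
                       end = start + len - 1 + margin,
                       stringsAsFactors = FALSE)
    clash <- FALSE
    for (blk in list(avoid, out)) {
      if (!is.null(blk) && nrow(blk) &&
          max_overlap_fraction(cand, blk) > 0) clash <- TRUE
    }
    if (!clash) {
      out <- rbind(out, data.frame(chrom = chrom, start = start,
                                   end = start + len - 1,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Simulate the genome annotation, CNV landscape and phenotypes
#'
#' Generates segmental duplications, common CNP loci (with a DGV-like
#' known-variant track mirroring them), genes (two designated causal genes
#' inside every planted causal locus), planted causal events (founder-origin
#' or de novo, transmitted Mendelian through the pedigree), neutral de novo
#' events, recurrent segdup-embedded artifact events, control-cohort CNP
#' genotypes, and phenotypes (carriers affected at the configured
#' penetrance; background prevalence solved to hit the target affected
#' fraction).
#'
#' @param config a [sim_config()].
#' @param pedigree pedigree from [simulate_pedigrees()].
#' @return list with `tracks` (segdup, known, genes, cnp_loci), `truth`
#'   (a `cnv_truth`: `events`, `individual_cnvs`, `control_cnvs`) and
#'   `pedigree` (phenotypes filled in).
#' @export
simulate_genome_and_cnvs <- function(config, pedigree) {
  set.seed(derive_seed(config$seed, 12L))
  nc <- config$n_chrom; cl <- config$chrom_length

  segdup <- place_intervals(config$n_segdup_regions, c(1e5, 5e5), nc, cl,
                            margin = 5e4)
  segdup$name <- sprintf("SEGDUP%02d", seq_len(nrow(segdup)))
  cnp <- place_intervals(config$n_common_cnps, c(3e4, 1.2e5), nc, cl,
                         avoid = segdup, margin = 5e4)
  cnp$name <- sprintf("CNP%03d", seq_len(nrow(cnp)))
  cnp$cnp_state <- sample(c("gain", "loss"), nrow(cnp), replace = TRUE)
  cnp$freq <- runif(nrow(cnp), config$cnp_freq_range[1],
                    config$cnp_freq_range[2])
  causal <- place_intervals(config$n_planted_causal, c(5e4, 3e5), nc, cl,
                            avoid = rbind(segdup[, 1:3], cnp[, 1:3]),
                            margin = 1e5)
  if (nrow(causal)) {
    causal$name <- sprintf("CAUSAL%02d", seq_len(nrow(causal)))
    causal$state <- sample(c("gain", "loss"), nrow(causal), replace = TRUE)
    causal$family_id <- sample(unique(pedigree$family_id),
                               nrow(causal))
  }

  ## genes: two causal genes inside each causal locus, background elsewhere
  genes <- list()
  for (j in seq_len(nrow(causal))) {
    w <- causal$end[j] - causal$start[j] + 1
    for (kk in 1:2) {
      gs <- causal$start[j] + floor((kk - 1) * w / 2 + w * 0.05)
      ge <- min(causal$end[j], gs + floor(w * 0.35))
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = causal$chrom[j], start = gs, end = ge,
        name = sprintf("GC%02d_%d", j, kk), causal = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  n_bg <- max(0L, config$n_genes - length(genes))
  bg <- place_intervals(n_bg, c(1e4, 1e5), nc, cl,
                        avoid = if (nrow(causal)) causal[, 1:3] else NULL)
  if (nrow(bg)) {
    bg$name <- sprintf("GENE%04d", seq_len(nrow(bg)))
    bg$causal <- FALSE
    genes[[length(genes) + 1L]] <- bg
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL

  known <- cnp[, c("chrom", "start", "end")]
  known$name <- sprintf("DGV%03d", seq_len(nrow(known)))

  ## --- CNP genotypes through the pedigree ------------------------------
  n_ind <- nrow(pedigree)
  key <- pedigree$individual_id
  fa_idx <- match(pedigree$father_id, key)
  mo_idx <- match(pedigree$mother_id, key)
  cnp_alleles <- matrix(0L, n_ind, nrow(cnp))
  for (i in seq_len(n_ind)) {            # parents precede children
    if (is.na(fa_idx[i])) {
      cnp_alleles[i, ] <- rbinom(nrow(cnp), 2L, cnp$freq)
    } else {
      from_fa <- rbinom(nrow(cnp), 1L, cnp_alleles[fa_idx[i], ] / 2)
      from_mo <- rbinom(nrow(cnp), 1L, cnp_alleles[mo_idx[i], ] / 2)
      cnp_alleles[i, ] <- from_fa + from_mo
    }
  }

  ## --- planted causal events ------------------------------------------
  events <- list()
  ind_rows <- list()
  causal_carrier <- rep(FALSE, n_ind)
  add_event <- function(type, chrom, start, end, state, family, origin) {
    eid <- sprintf("EV%03d", length(events) + 1L)
    events[[length(events) + 1L]] <<- data.frame(
      event_id = eid, type = type, chrom = chrom, start = start,
      end = end, state = state, family_id = family, origin = origin,
      stringsAsFactors = FALSE)
    eid
  }
  add_cnv <- function(i, eid, chrom, start, end, state, cn, origin,
                      truth_transmission, parent = NA_character_) {
    ind_rows[[length(ind_rows) + 1L]] <<- data.frame(
      family_id = pedigree$family_id[i], sample_id = key[i],
      chrom = chrom, start = start, end = end, state = state,
      copy_number = cn, event_id = eid, origin = origin,
      truth_transmission = truth_transmission,
      transmitting_parent = parent, stringsAsFactors = FALSE)
  }
  descend <- function(i, eid, ev, label_parent) {
    ## transmit to each child of individual i with probability 1/2
    kids <- which(fa_idx == i | mo_idx == i)
    for (kid in kids) {
      if (runif(1) < 0.5) {
        causal_carrier[kid] <<- TRUE
        add_cnv(kid, eid, ev$chrom, ev$start, ev$end, ev$state,
                if (ev$state == "gain") 3L else 1L, "causal",
                "inherited", key[i])
        descend(kid, eid, ev, key[i])
      }
    }
  }
  for (j in seq_len(nrow(causal))) {
    fam_members <- which(pedigree$family_id == causal$family_id[j])
    founder <- runif(1) < config$causal_founder_prob
    ev <- list(chrom = causal$chrom[j], start = causal$start[j],
               end = causal$end[j], state = causal$state[j])
    if (founder) {
      origin_i <- sample(fam_members[is.na(fa_idx[fam_members])], 1)
      eid <- add_event("causal", ev$chrom, ev$start, ev$end, ev$state,
                       causal$family_id[j], key[origin_i])
      causal_carrier[origin_i] <- TRUE
      add_cnv(origin_i, eid, ev$chrom, ev$start, ev$end, ev$state,
              if (ev$state == "gain") 3L else 1L, "causal", "founder")
    } else {
      cand <- fam_members[!is.na(fa_idx[fam_members])]
      origin_i <- if (length(cand) > 1L) sample(cand, 1) else cand[1]
      eid <- add_event("causal", ev$chrom, ev$start, ev$end, ev$state,
                       causal$family_id[j], key[origin_i])
      causal_carrier[origin_i] <- TRUE
      add_cnv(origin_i, eid, ev$chrom, ev$start, ev$end, ev$state,
              if (ev$state == "gain") 3L else 1L, "causal", "de_novo")
    }
    descend(origin_i, eid, ev, key[origin_i])
  }

  ## --- neutral de novo events -----------------------------------------
  blocked <- rbind(segdup[, 1:3], cnp[, 1:3],
                   if (nrow(causal)) causal[, 1:3] else NULL)
  for (i in which(!is.na(fa_idx))) {
    if (runif(1) < config$de_novo_probability) {
      loc <- place_intervals(1, c(5e4, 2e5), nc, cl, avoid = blocked,
                             margin = 5e4)
      blocked <- rbind(blocked, loc)
      st <- sample(c("gain", "loss"), 1)
      eid <- add_event("de_novo_background", loc$chrom, loc$start,
                       loc$end, st, pedigree$family_id[i], key[i])
      add_cnv(i, eid, loc$chrom, loc$start, loc$end, st,
              if (st == "gain") 3L else 1L, "denovo_background", "de_novo")
    }
  }

  ## --- phenotypes ------------------------------------------------------
  carrier_n <- sum(causal_carrier)
  bg_prev <- if (carrier_n < n_ind) {
    min(1, max(0, (config$affected_target_fraction * n_ind -
                     config$causal_penetrance * carrier_n) /
                 (n_ind - carrier_n)))
  } else 0
  p_aff <- ifelse(causal_carrier, config$causal_penetrance, bg_prev)
  pedigree$phenotype <- ifelse(runif(n_ind) < p_aff,
                               "affected", "unaffected")

  ## --- recurrent artifact events in segdups (assigned to affecteds) ---
  affected_idx <- which(pedigree$phenotype == "affected")
  for (j in seq_len(if (nrow(segdup)) config$n_artifact_events else 0L)) {
    sd_j <- segdup[1L + (j - 1L) %% nrow(segdup), ]
    sd_len <- sd_j$end - sd_j$start + 1
    len <- floor(sd_len * runif(1, 0.3, 0.5))
    start <- sd_j$start + floor((sd_len - len) / 2)
    carriers <- sample(affected_idx, min(length(affected_idx),
                                         sample(1:3, 1)))
    eid <- add_event("artifact", sd_j$chrom, start, start + len - 1,
                     "gain", NA_character_, NA_character_)
    for (i in carriers) {
      add_cnv(i, eid, sd_j$chrom, start, start + len - 1, "gain", 3L,
              "artifact", NA_character_)
    }
  }

  ## --- CNP carrier calls (vectorized per locus) ------------------------
  cnp_call_rows <- function(alleles_mat, sample_ids, family_ids) {
    pieces <- lapply(seq_len(nrow(cnp)), function(j) {
      carr <- which(alleles_mat[, j] > 0L)
      if (!length(carr)) return(NULL)
      al <- alleles_mat[carr, j]
      cn <- if (cnp$cnp_state[j] == "gain") 2L + al else 2L - al
      data.frame(family_id = family_ids[carr], sample_id = sample_ids[carr],
                 chrom = cnp$chrom[j], start = cnp$start[j],
                 end = cnp$end[j], state = cnp$cnp_state[j],
                 copy_number = as.integer(cn), event_id = cnp$name[j],
                 origin = "cnp", truth_transmission = NA_character_,
                 transmitting_parent = NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  }
  ind_rows[[length(ind_rows) + 1L]] <-
    cnp_call_rows(cnp_alleles, key, pedigree$family_id)

  ## --- control cohort (unrelated; CNP genotypes only) ------------------
  ctrl_ids <- sprintf("C%04d", seq_len(config$n_controls))
  ctrl_alleles <- matrix(
    rbinom(config$n_controls * nrow(cnp), 2L,
           rep(cnp$freq, each = config$n_controls)),
    nrow = config$n_controls)
  ctrl_rows <- list(cnp_call_rows(ctrl_alleles, ctrl_ids, ctrl_ids))

  truth <- list(
    events = do.call(rbind, events),
    individual_cnvs = do.call(rbind, ind_rows),
    control_cnvs = do.call(rbind, ctrl_rows),
    causal_carriers = key[causal_carrier],
    background_prevalence = bg_prev
  )
  class(truth) <- "cnv_truth"
  list(tracks = list(segdup = segdup, known = known, genes = genes,
                     cnp_loci = cnp),
       truth = truth, pedigree = pedigree)
}

## Jitter one caller's rendition of the true CNV table.
jitter_calls <- function(true_cnvs, config, caller, conf_range) {
  n <- nrow(true_cnvs)
  keep <- runif(n) >= config$fn_rate
  sub <- true_cnvs[keep, , drop = FALSE]
  if (!nrow(sub)) return(empty_cnv_table())
  len <- interval_length(sub$start, sub$end)
  d1 <- round(runif(nrow(sub), -config$jitter, config$jitter) * len)
  d2 <- round(runif(nrow(sub), -config$jitter, config$jitter) * len)
  start <- pmax(1, sub$start + d1)
  end <- pmax(start, sub$end + d2)
  data.frame(
    family_id = sub$family_id, sample_id = sub$sample_id,
    chrom = sub$chrom, start = start, end = end,
    copy_number = sub$copy_number, state = sub$state,
    n_probes = pmax(3L, as.integer(interval_length(start, end) %/%
                                     config$probe_spacing)),
    confidence = runif(nrow(sub), conf_range[1], conf_range[2]),
    caller = caller, stringsAsFactors = FALSE)
}

## Caller-specific false-positive calls; half land inside segdups.
fp_calls <- function(sample_ids, family_ids, config, segdup, caller) {
  rows <- list()
  for (i in seq_along(sample_ids)) {
    n_fp <- rpois(1, config$fp_rate)
    for (k in seq_len(n_fp)) {
      if (runif(1) < 0.5 && nrow(segdup)) {
        sd_j <- segdup[sample.int(nrow(segdup), 1), ]
        sd_len <- sd_j$end - sd_j$start + 1
        len <- floor(runif(1, 0.2, 0.4) * sd_len)
        start <- sd_j$start + floor(runif(1, 0, sd_len - len))
        chrom <- sd_j$chrom
      } else {
        len <- round(runif(1, 2e4, 1e5))
        chrom <- as.character(sample.int(config$n_chrom, 1))
        start <- floor(runif(1, 1, config$chrom_length - len))
      }
      cn <- sample(c(1L, 3L), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = family_ids[i], sample_id = sample_ids[i],
        chrom = chrom, start = start, end = start + len - 1,
        copy_number = cn, state = if (cn > 2L) "gain" else "loss",
        n_probes = pmax(3L, as.integer(len %/% config$probe_spacing)),
        confidence = runif(1, 5, 40), caller = caller,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(list(empty_cnv_table()), rows))
}

#' Simulate the two callers' outputs
#'
#' Every true CNV is emitted by each caller independently with boundary
#' jitter (uniform within +/- `jitter` x length per end) and dropped at the
#' false-negative rate; caller-specific false-positive calls are added at
#' `fp_rate` per sample, half of them inside segmental duplications.  Probe
#' counts are proportional to call length with a floor of 3.
#'
#' @param truth `cnv_truth` from [simulate_genome_and_cnvs()].
#' @param tracks track list from the same call.
#' @param pedigree phenotyped pedigree.
#' @param config a [sim_config()].
#' @return list of call tables: `cohort_a`, `cohort_b`, `controls_a`,
#'   `controls_b`.
#' @export
simulate_caller_outputs <- function(truth, tracks, pedigree, config) {
  set.seed(derive_seed(config$seed, 13L))
  segdup <- tracks$segdup
  mk <- function(true_cnvs, ids, fids) {
    a <- rbind(jitter_calls(true_cnvs, config, "A", c(15, 40)),
               fp_calls(ids, fids, config, segdup, "A"))
    b <- rbind(jitter_calls(true_cnvs, config, "B", c(12, 40)),
               fp_calls(ids, fids, config, segdup, "B"))
    list(a = a, b = b)
  }
  coh <- mk(truth$individual_cnvs, pedigree$individual_id,
            pedigree$family_id)
  ctrl_ids <- unique(truth$control_cnvs$sample_id)
  ctl <- mk(truth$control_cnvs, ctrl_ids, ctrl_ids)
  list(cohort_a = coh$a, cohort_b = coh$b,
       controls_a = ctl$a, controls_b = ctl$b)
}

#' Simulate the prioritization evidence tables
#'
#' Causal genes receive an outflow-tract SAGE boost (`evidence_fold`),
#' favorable per-source scores (`evidence_score_shift`), and a positive
#' expression flag with probability 0.9; background genes draw from null
#' distributions (flag positive with probability 0.1).
#'
#' @param tracks track list with the gene track (`causal` column).
#' @param config a [sim_config()].
#' @return list with `sage`, `scores`, `flags` data frames.
#' @export
simulate_evidence_tables <- function(tracks, config) {
  set.seed(derive_seed(config$seed, 14L))
  genes <- tracks$genes
  libs <- c(outflow_tract = 60000L, atrium = 55000L, ventricle = 58000L)
  base_tpm <- rlnorm(nrow(genes), log(50), 0.8)
  ## causal genes are modeled as robustly expressed in the heart so their
  ## planted outflow-tract boost is identifiable above Poisson count noise
  base_tpm[genes$causal] <- pmax(base_tpm[genes$causal], 150)
  sage <- do.call(rbind, lapply(names(libs), function(comp) {
    tpm <- base_tpm
    if (comp == "outflow_tract") {
      tpm[genes$causal] <- tpm[genes$causal] * config$evidence_fold
    }
    data.frame(gene = genes$name, compartment = comp,
               tag_count = rpois(nrow(genes), unname(libs[comp]) * tpm / 1e6),
               library_size = unname(libs[comp]), stringsAsFactors = FALSE)
  }))
  sources <- c("S1", "S2", "S3")
  scores <- do.call(rbind, lapply(sources, function(s) {
    sc <- rnorm(nrow(genes))
    sc[genes$causal] <- sc[genes$causal] + config$evidence_score_shift
    data.frame(gene = genes$name, source = s, score = sc,
               stringsAsFactors = FALSE)
  }))
  flags <- data.frame(
    gene = genes$name,
    flag = ifelse(runif(nrow(genes)) <
                    ifelse(genes$causal, 0.9, 0.1), "+", "-"),
    stringsAsFactors = FALSE)
  list(sage = sage, scores = scores, flags = flags)
}

#' Simulate a full synthetic cohort bundle
#'
#' Orchestrates [simulate_pedigrees()], [simulate_genome_and_cnvs()],
#' [simulate_caller_outputs()] and [simulate_evidence_tables()] and adds
#' per-sample PC coordinates drawn around the reference-cluster center.
#' Fully deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `cnv_simulation`: list with `config`, `pedigree`, `tracks`,
#'   `truth`, `calls`, `evidence`, `pcs` and `oval_spec`.
#' @export
simulate_cohort <- function(config) {
  ped0 <- simulate_pedigrees(config)
  g <- simulate_genome_and_cnvs(config, ped0)
  calls <- simulate_caller_outputs(g$truth, g$tracks, g$pedigree, config)
  evidence <- simulate_evidence_tables(g$tracks, config)
  set.seed(derive_seed(config$seed, 15L))
  axis_sd <- c(0.01, 0.012)
  pcs <- data.frame(
    individual_id = g$pedigree$individual_id,
    pc1 = rnorm(nrow(g$pedigree), 0, axis_sd[1]),
    pc2 = rnorm(nrow(g$pedigree), 0, axis_sd[2]),
    stringsAsFactors = FALSE)
  res <- list(config = config, pedigree = g$pedigree, tracks = g$tracks,
              truth = g$truth, calls = calls, evidence = evidence,
              pcs = pcs,
              oval_spec = oval_filter_spec(c(0, 0), axis_sd, 10))
  class(res) <- "cnv_simulation"
  res
}

#' @export
print.cnv_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic CNV cohort: %d individuals in %d families (%.1f%% affected)\n",
    nrow(x$pedigree), length(unique(x$pedigree$family_id)),
    100 * mean(x$pedigree$phenotype == "affected")))
  cat(sprintf("truth: %d events, %d per-individual CNVs; %d controls\n",
              nrow(x$truth$events), nrow(x$truth$individual_cnvs),
              x$config$n_controls))
  invisible(x)
}
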