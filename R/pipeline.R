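#' Pipeline configuration
#'
#' Bundles the simulation world, the detection thresholds fixed by the
#' method (usable-sample floor 50, 20 hidden factors, 1000 permutations,
#' FDR 0.05 with a 0.05 permutation-fraction ceiling, driver FDR 0.1) and
#' the model sizes for the prediction and disease stages.
#'
#' @param sim a \code{\link{sim_config}} for synthetic input generation
#' @param n_tissues number of tissues simulated from the shared cohort
#' @param fdr,perm_threshold,n_perm,n_factors,min_samples detection-core
#'   settings
#' @param driver_fdr enrichment q threshold for driver calls
#' @param stable_p_floor nominal-p floor of the stable trend class
#' @param n_components MDS components for the age models (30 at full scale)
#' @param n_repeats,n_folds repeated-CV settings for the clock
#' @param n_disease_components components per block in the nested disease
#'   models (the full-scale analysis uses 100; the default 20 keeps the
#'   sample-to-parameter ratio healthy at simulation scale)
#' @param seed master pipeline seed
#' @return object of class \code{pipeline_config}
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_tissues = 2,
                            fdr = 0.05, perm_threshold = 0.05,
                            n_perm = 1000, n_factors = 20,
                            min_samples = 50, driver_fdr = 0.1,
                            stable_p_floor = 0.5,
                            n_components = 30, n_repeats = 100,
                            n_folds = 10,
                            n_disease_components = 20,
                            seed = 1L) {
  for (v in c(fdr, perm_threshold, driver_fdr, stable_p_floor)) {
    if (!(v > 0 && v <= 1)) stopf("thresholds must lie in (0, 1]")
  }
  if (min_samples < 2) stopf("min_samples must be >= 2")
  structure(list(sim = sim, n_tissues = n_tissues, fdr = fdr,
                 perm_threshold = perm_threshold, n_perm = n_perm,
                 n_factors = n_factors, min_samples = min_samples,
                 driver_fdr = driver_fdr, stable_p_floor = stable_p_floor,
                 n_components = n_components, n_repeats = n_repeats,
                 n_folds = n_folds,
                 n_disease_components = n_disease_components,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, manifest, expr) {
  res <- tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
  manifest$stages <- c(manifest$stages, name)
  list(result = res, manifest = manifest)
}

#' Run the complete synthetic-data analysis pipeline
#'
#' Simulates the configured world, runs the age-association scan on every
#' tissue's PSI matrix and on the gene / transcript / transcript-ratio
#' modalities of tissue 1, compares the four modalities' gene sets,
#' computes cross-tissue Jaccard similarity with a clustering tree, fits the
#' splicing and gene-expression age clocks, runs the motif-enrichment driver
#' analysis, and quantifies splicing's independent disease contribution with
#' the nested LLR test. All result files plus a reproducibility manifest are
#' written under \code{out_dir}; outputs are byte-identical under a fixed
#' seed.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir output directory (created if needed)
#' @return (invisibly) a list with the in-memory results of every stage
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  manifest <- list(package = "spliceage",
                   version = as.character(utils::packageVersion("spliceage")),
                   seed = config$seed,
                   thresholds = config[c("fdr", "perm_threshold", "n_perm",
                                         "n_factors", "min_samples",
                                         "driver_fdr", "stable_p_floor")],
                   stages = character(0), notes = character(0))
  out <- list()
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 7L)

  ## --- simulate ----------------------------------------------------------
  st <- run_stage("simulate", manifest, {
    cohort <- simulate_cohort(sim)
    tissues <- lapply(seq_len(config$n_tissues), function(t) {
      simulate_psi(cohort, sim, seed = derive_seed(sim$seed, 20L + t))
    })
    names(tissues) <- paste0("tissue", seq_len(config$n_tissues))
    expr <- simulate_expression(cohort, sim)
    regsf <- simulate_regions_and_sf(tissues[[1]]$truth, cohort, sim)
    disease <- simulate_disease(cohort, tissues[[1]]$psi, expr$gene, sim)
    ph <- data.frame(cohort[, c("sample_id", "donor_id", "age", "gender")],
                     disease = as.integer(disease),
                     stringsAsFactors = FALSE)
    write_phenotypes(ph, pth("phenotypes.tsv"))
    for (t in names(tissues)) {
      write_psi_table(tissues[[t]]$psi, pth(sprintf("psi_%s.tsv", t)))
    }
    write_psi_table(expr$gene, pth("gene_tpm.tsv"))
    write_psi_table(expr$transcript, pth("transcript_tpm.tsv"))
    write_regions_fasta(regsf$regions, pth("regions_tissue1.fa"))
    write_json_result(lapply(tissues, function(t) t$truth$events),
                      pth("ground_truth_events.json"))
    list(cohort = cohort, tissues = tissues, expr = expr, regsf = regsf,
         phenotypes = ph)
  })
  manifest <- st$manifest
  out$sim <- st$result
  ph <- out$sim$phenotypes

  ## --- per-tissue PSI scans ---------------------------------------------
  st <- run_stage("scan_psi", manifest, {
    scans <- lapply(seq_along(out$sim$tissues), function(t) {
      res <- scan_age_association(
        out$sim$tissues[[t]]$psi, ph,
        n_factors = config$n_factors, n_perm = config$n_perm,
        min_samples = config$min_samples, fdr = config$fdr,
        perm_threshold = config$perm_threshold,
        seed = derive_seed(config$seed, 30L + t))
      utils::write.table(res, pth(sprintf("scan_psi_tissue%d.tsv", t)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
    names(scans) <- names(out$sim$tissues)
    scans
  })
  manifest <- st$manifest
  out$psi_scans <- st$result

  ## --- modality scans (tissue 1) ----------------------------------------
  st <- run_stage("modality_scans", manifest, {
    mats <- list(psi = out$sim$tissues[[1]]$psi,
                 gene = out$sim$expr$gene,
                 transcript = out$sim$expr$transcript,
                 tx2gene = out$sim$expr$tx2gene)
    scans <- list(psi = out$psi_scans[[1]])
    for (mod in c("gene", "transcript", "ratio")) {
      scans[[mod]] <- run_modality_scan(
        mod, mats, ph,
        n_factors = config$n_factors, n_perm = config$n_perm,
        min_samples = config$min_samples, fdr = config$fdr,
        perm_threshold = config$perm_threshold,
        seed = derive_seed(config$seed, 40L))
      utils::write.table(scans[[mod]], pth(sprintf("scan_%s.tsv", mod)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    scans
  })
  manifest <- st$manifest
  out$modalities <- st$result

  ## --- modality overlap --------------------------------------------------
  st <- run_stage("overlap", manifest, {
    tx2gene <- out$sim$expr$tx2gene
    fmap <- c(event_to_gene(rownames(out$sim$tissues[[1]]$psi)), tx2gene)
    ov <- modality_overlap(out$modalities, fmap)
    utils::write.table(ov$membership, pth("modality_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ov
  })
  manifest <- st$manifest
  out$overlap <- st$result

  ## --- cross-tissue similarity -------------------------------------------
  if (config$n_tissues >= 2) {
    st <- run_stage("similarity", manifest, {
      sets <- lapply(out$psi_scans, function(res) {
        unique(event_to_gene(res$event_id[res$significant]))
      })
      sim_t <- tissue_similarity(sets)
      utils::write.table(sim_t$jaccard, pth("tissue_jaccard.tsv"),
                         sep = "\t", quote = FALSE)
      write_tissue_tree(sim_t, pth("tissue_tree.nwk"))
      sim_t
    })
    manifest <- st$manifest
    out$similarity <- st$result
  } else {
    manifest$notes <- c(manifest$notes, "similarity skipped: one tissue")
  }

  ## --- age prediction -----------------------------------------------------
  st <- run_stage("predict_age", manifest, {
    psi_feat <- mds_reduce(out$sim$tissues[[1]]$psi, config$n_components)
    ge_feat <- mds_reduce(log2(out$sim$expr$gene + 1), config$n_components)
    cv_psi <- cv_age_prediction(psi_feat, ph$age,
                                n_repeats = config$n_repeats,
                                n_folds = config$n_folds,
                                seed = derive_seed(config$seed, 50L))
    cv_ge <- cv_age_prediction(ge_feat, ph$age,
                               n_repeats = config$n_repeats,
                               n_folds = config$n_folds,
                               seed = derive_seed(config$seed, 51L))
    res <- list(splicing_accuracy = cv_psi$accuracy,
                gene_accuracy = cv_ge$accuracy,
                n_components = config$n_components,
                n_repeats = config$n_repeats)
    write_json_result(res, pth("age_prediction.json"))
    res
  })
  manifest <- st$manifest
  out$prediction <- st$result

  ## --- drivers ------------------------------------------------------------
  res1 <- out$psi_scans[[1]]
  ann <- parse_event_id(res1$event_id)
  se_res <- res1[!is.na(ann$type) & ann$type == "SE", , drop = FALSE]
  classes <- classify_trend(se_res, config$stable_p_floor)
  class_n <- table(factor(classes, c("up", "stable", "down")))
  if (any(class_n < 10)) {
    manifest$notes <- c(manifest$notes, sprintf(
      "drivers skipped: trend class sizes %s below the 10-event floor",
      paste(sprintf("%s=%d", names(class_n), class_n), collapse = ", ")))
  } else {
  st <- run_stage("drivers", manifest, {
    counts <- count_motif_table(out$sim$regsf$regions, sim$motif_set)
    enr <- motif_enrichment_scan(counts, classes, fdr = config$driver_fdr)
    drv <- identify_drivers(enr, out$sim$regsf$sf_expr, ph, sim$motif_set,
                            fdr = config$driver_fdr,
                            min_samples = config$min_samples)
    utils::write.table(enr, pth("motif_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(drv, pth("driver_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(enrichment = enr, drivers = drv)
  })
  manifest <- st$manifest
  out$drivers <- st$result
  }

  ## --- disease LLR --------------------------------------------------------
  sig_events <- out$psi_scans[[1]]$event_id[out$psi_scans[[1]]$significant]
  if (length(sig_events) >= 2) {
    st <- run_stage("disease_llr", manifest, {
      llr <- disease_llr(ph$disease, ph, out$sim$expr$gene,
                         out$sim$tissues[[1]]$psi, sig_events,
                         n_ge_components = config$n_disease_components,
                         n_psi_components = config$n_disease_components)
      write_json_result(llr[c("ll_null", "ll_alt", "llr", "df", "p_value",
                              "family", "separation")],
                        pth("disease_llr.json"))
      llr
    })
    manifest <- st$manifest
    out$disease <- st$result
  } else {
    manifest$notes <- c(manifest$notes,
                        "disease_llr skipped: fewer than 2 significant events")
  }

  write_json_result(manifest, pth("manifest.json"))
  out$manifest <- manifest
  invisible(out)
}
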