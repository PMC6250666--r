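#' Default run configuration
#'
#' All thresholds at their published defaults: 1 Mb cis window, B = 2000
#' permutations, q < 0.05 eGenes, r^2 > 0.8 proxies, RTC >= 0.9, MR
#' instrument selection r^2 < 0.2 & P < 0.08, Bonferroni family size 7.
#'
#' @param ... overrides of individual fields.
#' @return named list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = unclass(simulationConfig()),
    cis_window = 1e6,
    permutations = 2000L,
    egene_fdr = 0.05,
    proxy_r2 = 0.8,
    rtc_threshold = 0.9,
    mr_r2_max = 0.2,
    mr_p_max = 0.08,
    mr_family_m = 7L,
    n_genotype_pcs = 3L,
    # NA = sample-size tiering (defaultHiddenFactorK), meant for
    # transcriptome-wide matrices; the synthetic default uses a small fixed
    # k since factor counts approaching the gene count absorb the signal
    hidden_factors = 5L,
    maf_min = 0.05,
    hwe_p_min = 0.001,
    tpm_min = 0.1,
    tpm_frac = 0.5,
    trait_scenario = "shared")
  utils::modifyList(cfg, list(...))
}

.manifest_hashes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$|\\.json$",
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  h <- tools::md5sum(files)
  names(h) <- basename(files)
  as.list(h)
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> QC/normalise -> per-study eQTL -> meta -> permutation
#' calibration -> eGene calling -> trait GWAS -> proxy overlap -> RTC -> MR
#' in dependency order, writing each stage's artefacts as TSV/JSON into
#' \code{out_dir} together with a manifest (package version, seed, file
#' hashes). Reruns with the same config are bit-identical.
#'
#' @param config list from [defaultRunConfig()] (or [readRunConfig()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the main in-memory results (meta table,
#'   calibration, egene calls, rtc, mr) and the manifest.
#' @export
runPipeline <- function(config = defaultRunConfig(), out_dir,
                        quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    scfg <- do.call(simulationConfig,
                    utils::modifyList(config$sim,
                                      list(seed = config$seed)))
    say("[%s] two cohorts, %d+%d samples", stage,
        scfg$n_samples_study1, scfg$n_samples_study2)
    sim <- simulateCohorts(scfg)
    writeGroundTruth(sim$truth, file.path(out_dir, "ground_truth.json"))
    writeGenotypeTsv(sim$study1$geno, out_dir, "study1_genotypes")
    writeGenotypeTsv(sim$study2$geno, out_dir, "study2_genotypes")

    stage <- "qc_norm"
    studies <- lapply(list(sim$study1, sim$study2), function(st) {
      vq <- filterVariants(st$geno, maf_min = config$maf_min,
                           hwe_p_min = config$hwe_p_min)
      gq <- filterGenes(st$expr, tpm_min = config$tpm_min,
                        frac = config$tpm_frac)
      si <- sampleInfo(st$geno)
      base_cov <- cbind(age = si$age, sex = si$sex)
      norm <- normalizeExpression(gq$expr, covariates = base_cov)
      n <- ncol(norm)
      k <- if (is.na(config$hidden_factors)) defaultHiddenFactorK(n)
           else config$hidden_factors
      # never let the factors approach the gene count: they would absorb
      # the cis signal itself on small panels
      k <- max(0L, min(k, n - 5L, nrow(norm) %/% 4L))
      hf <- estimateHiddenFactors(norm, base_cov, k = k)
      pcs <- genotypePCs(vq$geno, k = config$n_genotype_pcs)
      list(geno = vq$geno, expr = norm,
           covar_perm = cbind(base_cov, hf), covar_fixed = pcs,
           reports = list(variants = vq$report, genes = gq$report))
    })
    say("[%s] %d+%d variants, %d+%d genes post-QC", stage,
        nrow(studies[[1]]$geno), nrow(studies[[2]]$geno),
        nrow(studies[[1]]$expr), nrow(studies[[2]]$expr))
    jsonlite::write_json(
      lapply(studies, function(s) lapply(s$reports, unclass)),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)

    stage <- "eqtl"
    pairs <- mapCisPairs(studies[[1]]$expr, studies[[1]]$geno,
                         window = config$cis_window)
    scans <- lapply(studies, function(s)
      runStudyEqtl(s$expr, s$geno,
                   covariates = cbind(s$covar_perm, s$covar_fixed),
                   pairs = pairs[pairs$gene %in% rownames(s$expr) &
                                 pairs$snp %in% rownames(s$geno), ]))
    meta <- runMetaEqtl(scans[[1]], scans[[2]])
    vinfo <- variantInfo(sim$study1$geno)
    meta$pos <- vinfo$pos[match(meta$snp, vinfo$id)]
    .write_tsv(meta, file.path(out_dir, "eqtl_meta.tsv"))
    say("[%s] %d cis pairs tested", stage, nrow(meta))

    stage <- "calibrate"
    null <- permuteMinP(
      lapply(studies, function(s)
        list(Y = s$expr, G = s$geno, covar_perm = s$covar_perm,
             covar_fixed = s$covar_fixed)),
      pairs, B = config$permutations, seed = config$seed + 100L)
    calib <- calibratePermutations(meta, null, target = config$egene_fdr)
    calls <- callEgenes(meta, calib, fdr = config$egene_fdr)
    .write_tsv(data.frame(gene = rownames(null),
                          obs_min_p = calib@observed,
                          adjusted_p = calib@adjusted,
                          q = calib@qvalue,
                          p_t_i = calib@pt_gene),
               file.path(out_dir, "egenes.tsv"))
    .write_tsv(calls$pairs, file.path(out_dir, "significant_pairs.tsv"))
    say("[%s] B=%d, P_t=%.3g, %d eGenes", stage, config$permutations,
        calib@pt, length(calls$egenes))

    stage <- "trait_gwas"
    tr <- simulateTrait(sim$study1$geno, sim$study1$expr, sim$truth,
                        scenario = config$trait_scenario,
                        seed = config$seed + 2L)
    .write_tsv(tr$gwas, file.path(out_dir, "gwas_summary.tsv"))

    stage <- "overlap"
    gwas_lead <- tr$gwas$snp[which.min(tr$gwas$p)]
    proxies <- expandProxies(sim$study1$geno, gwas_lead,
                             r2_min = config$proxy_r2)
    ov <- overlapGwasEsnps(gwas_lead, proxies,
                           esnp_set = unique(calls$pairs$snp),
                           best_esnp_set = calls$best$snp)
    jsonlite::write_json(list(lead = gwas_lead,
                              n_overlap = ov$n_overlap,
                              n_overlap_best = ov$n_overlap_best),
                         file.path(out_dir, "overlap.json"),
                         auto_unbox = TRUE)

    stage <- "rtc"
    rtc <- NULL
    driver <- tr$truth$trait_model$driver_gene
    if (!is.null(driver) && driver %in% rownames(studies[[1]]$expr) &&
        nrow(calls$best) && driver %in% calls$best$gene) {
      esnp <- calls$best$snp[calls$best$gene == driver]
      blk <- vinfo$block[match(esnp, vinfo$id)]
      interval <- vinfo$id[vinfo$block == blk]
      interval <- interval[interval %in% rownames(studies[[1]]$geno)]
      if (length(interval) >= 2 && gwas_lead %in% interval &&
          esnp %in% interval) {
        rtc <- rtcScore(interval, studies[[1]]$geno,
                        exprValues(studies[[1]]$expr)[driver, ],
                        gwas_snp = gwas_lead, eqtl_snp = esnp,
                        covariates = cbind(studies[[1]]$covar_perm,
                                           studies[[1]]$covar_fixed),
                        threshold = config$rtc_threshold)
        .write_tsv(rtc, file.path(out_dir, "rtc.tsv"))
        say("[%s] score %.2f (colocalised: %s)", stage, rtc$rtc,
            rtc$colocalised)
      }
    }

    stage <- "mr"
    mr <- NULL
    if (!is.null(driver)) {
      gene_eqtl <- meta[meta$gene == driver, ]
      iv <- tryCatch(
        selectInstruments(data.frame(snp = gene_eqtl$snp,
                                     p = gene_eqtl$p_meta),
                          studies[[1]]$geno, r2_max = config$mr_r2_max,
                          p_max = config$mr_p_max),
        error = function(e) character(0))
      gw <- tr$gwas
      if (length(iv) >= 3) {
        expo <- data.frame(snp = iv, effect_allele = "G",
                           other_allele = "A",
                           beta = gene_eqtl$beta_meta[match(iv,
                                                            gene_eqtl$snp)],
                           se = gene_eqtl$se_meta[match(iv, gene_eqtl$snp)])
        outc <- data.frame(snp = gw$snp, effect_allele = gw$effect_allele,
                           other_allele = gw$other_allele,
                           beta = gw$beta, se = gw$se)
        ins <- harmonise(expo, outc, drop_palindromic = FALSE)
        if (length(ins) >= 3) {
          mr <- runMr(ins, m = config$mr_family_m, n_boot = 500L,
                      seed = config$seed + 3L)
          .write_tsv(mr$estimates, file.path(out_dir, "mr_estimates.tsv"))
          say("[%s] %d instruments, causal: %s", stage, length(ins),
              mr$verdict$causal)
        }
      }
    }

    list(meta = meta, calibration = calib, calls = calls, rtc = rtc,
         mr = mr, truth = tr$truth)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "nephroQTL",
    version = as.character(utils::packageVersion("nephroQTL")),
    seed = config$seed,
    config = config,
    hashes = .manifest_hashes(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete in %.1fs",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(c(res, list(manifest = manifest)))
}
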