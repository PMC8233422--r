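# End-to-end orchestration: simulate (or load) -> QC -> relationship matrices
# -> per-parity threshold fits -> window scans -> cross-parity correlations ->
# gene-set enrichment, with a run manifest (config hash, per-file checksums,
# timings, warnings) for reproducibility audits. All parities share the QC'd
# panel and the H-inverse built from all genotyped animals; each parity is an
# independent fit on its own records.

#' Pipeline configuration
#'
#' Assembles per-stage parameter blocks with the package defaults. Either a
#' simulation block (the default) or a set of input file paths drives the
#' run.
#'
#' @param sim List of [sim_config()] overrides (ignored when `inputs` is
#'   given).
#' @param inputs Optional named list of file paths: `pedigree`, `raw`, `map`,
#'   `phenotypes`, `genes`, `gmt` (named character vector of collections).
#' @param qc List of [qc_thresholds()] overrides.
#' @param blend Genomic blending weight for `G*` and the back-solve kernel.
#' @param gibbs List of [gibbs_config()] overrides applied to every parity.
#' @param span_bp,window_mode Window span and mode for [window_partition()].
#' @param annotation Overrides for [simulate_annotation()] (`n_genes`,
#'   `n_terms`, `genes_per_term`) in simulation-driven runs.
#' @param flank_bp,top_fraction,min_term_size Enrichment parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), inputs = NULL, qc = list(),
                            blend = 0.95, gibbs = list(),
                            span_bp = 2e6, window_mode = "sliding",
                            annotation = list(),
                            flank_bp = 15000, top_fraction = 0.05,
                            min_term_size = 10L) {
  structure(list(sim = sim, inputs = inputs, qc = qc, blend = blend,
                 gibbs = gibbs, span_bp = span_bp, window_mode = window_mode,
                 annotation = annotation, flank_bp = flank_bp,
                 top_fraction = top_fraction,
                 min_term_size = as.integer(min_term_size)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    config_error("unknown pipeline configuration key(s): %s",
                 paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE),
             tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes all artifacts under `out_dir`.
#' Given the same configuration and seed, a re-run reproduces every output
#' file bit-identically (the manifest's `timing` block aside). Any stage
#' error aborts the run with the stage named.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing every stochastic stage.
#' @return The run manifest (class `run_manifest`), invisibly written to
#'   `manifest.json`: config hash, seed, per-stage output checksums,
#'   timings and warnings.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = md5_of_object(unclass(config)),
                   seed = as.integer(seed),
                   stages = list())
  timing <- list()
  warnings <- character(0)
  files <- character(0)
  note <- function(msg, ...) message(sprintf(paste0("[liabscan] ", msg), ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, sprintf("%s: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(path) { files <<- c(files, path); path }
  p <- function(...) file.path(out_dir, ...)

  # ---- stage: inputs (simulate or load) ------------------------------------
  io <- stage("inputs", {
    if (is.null(config$inputs)) {
      scfg <- do.call(sim_config, modifyList(list(seed = seed), config$sim))
      note("simulating study (seed %d)", seed)
      study <- simulate_study(scfg)
      ann_args <- modifyList(
        list(n_genes = 40L * scfg$n_chromosomes, n_terms = 30L,
             genes_per_term = c(10L, 30L)), config$annotation)
      ann <- simulate_annotation(
        study$snp_map, ann_args$n_genes, ann_args$n_terms,
        ann_args$genes_per_term, seed = seed + 7L,
        qtl_snps = study$snp_map[study$true_qtl$snp_index, , drop = FALSE])
      emit(write_pedigree(study$pedigree, p("pedigree.csv")))
      emit(write_plink_raw(study$genotypes, p("genotypes.raw")))
      emit(write_plink_map(study$snp_map, p("genotypes.map")))
      emit(write_phenotypes(study$phenotypes, p("phenotypes.csv")))
      emit(write_gene_models_gff3(ann$genes, p("genes.gff3")))
      emit(write_gmt(ann$sets, p("genesets.gmt")))
      list(pedigree = p("pedigree.csv"), raw = p("genotypes.raw"),
           map = p("genotypes.map"), phenotypes = p("phenotypes.csv"),
           genes = p("genes.gff3"), gmt = c(simulated = p("genesets.gmt")))
    } else config$inputs
  })
  ped <- read_pedigree(io$pedigree)
  geno <- read_plink_raw(io$raw)
  snp_map <- read_plink_map(io$map)
  pheno <- read_phenotypes(io$phenotypes)

  # ---- stage: qc -----------------------------------------------------------
  qcres <- stage("qc", {
    if (!identical(colnames(geno), snp_map$snp_id))
      data_error("RAW and MAP files disagree on SNP ids/order")
    th <- do.call(qc_thresholds, config$qc)
    note("QC thresholds: animal call rate %g, SNP call rate %g, MAF %g, HWE P %g",
         th$animal_call_rate, th$snp_call_rate, th$maf, th$hwe_p)
    r <- qc_filter(geno, snp_map, th)
    jsonlite::write_json(
      list(n_animals_in = r$report$n_animals_in,
           n_animals_out = r$report$n_animals_out,
           n_snps_in = r$report$n_snps_in, n_snps_out = r$report$n_snps_out,
           removals = as.list(r$report$removals)),
      emit(p("qc_report.json")), auto_unbox = TRUE, pretty = TRUE)
    r
  })
  geno_qc <- impute_missing(qcres$genotypes)
  map_qc <- qcres$snp_map

  # ---- stage: relationship matrices ----------------------------------------
  rel <- stage("relationships", {
    note("blending weight on G: %g", config$blend)
    ai <- a_inverse(ped)
    A22 <- a22(ped, rownames(geno_qc))
    G <- g_matrix(geno_qc)
    H_inv <- h_inverse(ai$A_inv, A22, G, blend = config$blend)
    emit(write_matrix_coo(H_inv, p("hinv.txt")))
    list(A_inv = ai$A_inv, F = ai$F, A22 = A22, G = G, H_inv = H_inv)
  })

  # ---- stage: per-parity threshold fits ------------------------------------
  parities <- unique(pheno$parity)
  fits <- list()
  for (k in seq_along(parities)) {
    par_k <- parities[k]
    fits[[par_k]] <- stage(paste0("fit_", par_k), {
      sub <- pheno[pheno$parity == par_k, , drop = FALSE]
      fct <- c("year_season", "breed_type")
      for (extra in c("dim_class", "uterine_disease"))
        if (!all(is.na(sub[[extra]]))) fct <- c(fct, extra)
      fml <- stats::as.formula(paste("y ~", paste(fct, collapse = " + ")))
      gcfg <- do.call(gibbs_config,
                      modifyList(list(seed = seed + 10L + k), config$gibbs))
      note("fitting %s: %d records, formula %s", par_k, nrow(sub),
           deparse(fml))
      fit <- fit_threshold(fml, sub, rel$H_inv, config = gcfg)
      st <- summary(fit)
      jsonlite::write_json(
        list(parity = par_k, h2_denominator = fit$h2_denominator,
             posterior = as.data.frame(cbind(parameter = rownames(st$table),
                                             as.data.frame(st$table)))),
        emit(p(sprintf("posterior_%s.json", par_k))),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write.table(data.frame(sample = seq_len(nrow(fit$samples)),
                             fit$samples[, 1:2], h2 = fit$h2_samples),
                  emit(p(sprintf("traces_%s.tsv", par_k))), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(data.frame(animal_id = names(fit$gebv), gebv = fit$gebv),
                  emit(p(sprintf("gebv_%s.tsv", par_k))), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      fit
    })
  }

  # ---- stage: window scans -------------------------------------------------
  windows <- window_partition(map_qc, config$span_bp, config$window_mode)
  effects <- list()
  scans <- list()
  for (par_k in parities) {
    scans[[par_k]] <- stage(paste0("scan_", par_k), {
      fit <- fits[[par_k]]
      a_g <- fit$gebv[rownames(geno_qc)]
      s <- backsolve_snp_effects(a_g, geno_qc, blend = config$blend,
                                 A22 = rel$A22)
      effects[[par_k]] <- s
      sig2a <- mean(fit$samples[, "sigma2_a"])
      wt <- window_variance_percent(windows, geno_qc, s, sig2a)
      write.table(data.frame(chrom = wt$chrom, start_bp = wt$start_bp,
                             end_bp = wt$end_bp, index_snp = wt$index_snp,
                             n_snps = wt$n_snps, var_u = wt$var_u,
                             pct_var = wt$pct_var),
                  emit(p(sprintf("windows_%s.tsv", par_k))), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(data.frame(snp_id = names(s), effect = as.numeric(s)),
                  emit(p(sprintf("snp_effects_%s.tsv", par_k))), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      manhattan_plot(wt, file = p(sprintf("manhattan_%s.png", par_k)),
                     main = sprintf("Pregnancy-loss scan: %s", par_k))
      wt
    })
  }

  # ---- stage: parity-by-parity genetic parameter table ---------------------
  tab2 <- stage("parameter_table", {
    np <- length(parities)
    m <- matrix(NA_real_, np, np, dimnames = list(parities, parities))
    for (i in seq_len(np)) {
      m[i, i] <- mean(fits[[parities[i]]]$h2_samples)
      if (i < np) for (j in seq.int(i + 1L, np))
        m[i, j] <- cross_parity_correlation(effects[[parities[i]]],
                                            effects[[parities[j]]])
    }
    write.table(cbind(parity = rownames(m), as.data.frame(round(m, 4))),
                emit(p("genetic_parameters.tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
    m
  })

  # ---- stage: gene-set enrichment ------------------------------------------
  enr <- stage("enrichment", {
    genes <- read_gene_models(io$genes)
    sgm <- map_snps_to_genes(map_qc, genes, flank_bp = config$flank_bp)
    note("enrichment: flank %g bp, top fraction %g, min term size %d",
         config$flank_bp, config$top_fraction, config$min_term_size)
    out <- list()
    for (par_k in parities) {
      flags <- flag_significant_genes(effects[[par_k]], sgm,
                                      top_fraction = config$top_fraction)
      res_all <- list()
      for (db in names(io$gmt)) {
        coll <- read_gmt(io$gmt[[db]])
        res_all[[db]] <- enrich_terms(flags, coll,
                                      min_term_size = config$min_term_size,
                                      database = db)
      }
      res <- do.call(rbind, res_all)
      write.table(res, emit(p(sprintf("enrichment_%s.tsv", par_k))),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      if (nrow(res))
        enrichment_dotplot(res, file = p(sprintf("enrichment_%s.png", par_k)))
      out[[par_k]] <- res
    }
    out
  })

  manifest$stages <- NULL
  manifest$files <- lapply(sort(unique(files)), function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  manifest$warnings <- warnings
  manifest$timing <- timing
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(list(manifest = manifest, qc = qcres$report,
                           fits = fits, scans = scans, windows = windows,
                           parameters = tab2, enrichment = enr,
                           out_dir = out_dir),
                      class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("liabscan pipeline run\n")
  cat(sprintf("  outputs: %s (%d files)\n", x$out_dir,
              length(x$manifest$files)))
  cat("  genetic parameters (h2 diagonal, SNP-effect correlations above):\n")
  print(round(x$parameters, 4))
  invisible(x)
}
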