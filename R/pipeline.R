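# End-to-end orchestration: simulate -> reconstruct -> process ->
# heritability -> scan -> annotate. Every stage writes plain files into
# the output directory so any stage can be rerun standalone, and the run
# manifest records parameters, seeds and per-file checksums.

#' Build a pipeline configuration
#'
#' Returns the default configuration, with any supplied values merged
#' in. A configuration can also be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param ... named overrides of the defaults (see Details).
#' @details Fields: `seed`; `sim` (simulation block: `n_lines`,
#'   `n_markers_per_chr`, `chr_lengths_cM`, `allele_freq`,
#'   `n_inbreeding_gens`, `error_rate`, `missing_rate`, `n_per_line`,
#'   `sigma_g2`, `sigma_e2`, `qtl` list, covariate betas); `hmm`
#'   (`error_rate`, `expansion`, `prune`); `pheno` (`correct`,
#'   `normalize`); `scan` (`n_perm`, `alpha`); `annotate` (`n_genes` or
#'   `genes`/`ranking` paths); `outdir`; `quiet`.
#' @return List of class `cc_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = list(n_lines = 20L, n_markers_per_chr = c(250L, 250L),
               chr_lengths_cM = c(80, 70), allele_freq = 0.5,
               n_inbreeding_gens = 20L, error_rate = 0.002,
               missing_rate = 0.02, n_per_line = 5L,
               sigma_g2 = 0, sigma_e2 = 1, qtl = list(),
               beta_age = 0, beta_batch = NULL, beta_origin = NULL,
               trait = "trait"),
    hmm = list(error_rate = 0.01, expansion = 2, prune = NULL),
    pheno = list(correct = TRUE, normalize = TRUE),
    scan = list(n_perm = 200L, alpha = c(0.05, 0.1, 0.5)),
    annotate = list(n_genes = 500L, genes = NULL, ranking = NULL),
    outdir = "ccqg_run", quiet = FALSE)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- c("cc_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with the same structure.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.log_stage <- function(quiet, ...) {
  if (!quiet)
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full pipeline
#'
#' Executes simulate, reconstruct, phenotype processing, heritability,
#' QTL scan (with permutations and LogP-1 intervals) and gene
#' annotation, writing all stage outputs under `config$outdir` and
#' returning a manifest. Identical configurations (including seeds)
#' produce byte-identical stage files.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest (list), invisibly also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cc_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  q <- isTRUE(config$quiet)
  seed <- as.integer(config$seed)
  s <- config$sim

  .log_stage(q, "simulate: ", s$n_lines, " lines, ",
             sum(s$n_markers_per_chr), " markers")
  panel <- simulate_cc_panel(s$n_lines, s$n_markers_per_chr,
                             s$chr_lengths_cM, allele_freq = s$allele_freq,
                             n_inbreeding_gens = s$n_inbreeding_gens,
                             error_rate = s$error_rate,
                             missing_rate = s$missing_rate,
                             seed = seed)
  spec <- qtl_spec(qtl = s$qtl, sigma_g2 = s$sigma_g2,
                   sigma_e2 = s$sigma_e2, beta_age = s$beta_age %||% 0,
                   beta_batch = s$beta_batch, beta_origin = s$beta_origin,
                   trait = s$trait)
  K_true <- kinship_from_descent(true_descent(panel$mosaics,
                                              panel$founders$map))
  pheno <- simulate_phenotypes(panel$mosaics, unclass(K_true), spec,
                               n_per_line = s$n_per_line,
                               seed = seed + 1L)
  write_founders(panel$founders, file.path(out, "founders.csv"))
  write_genotypes(panel$genotypes, file.path(out, "genotypes.csv"))
  write_mosaics(panel$mosaics, panel$founders$map,
                file.path(out, "mosaics_true.tsv"))
  utils::write.csv(pheno, file.path(out, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)

  .log_stage(q, "reconstruct: HMM over ", s$n_lines, " lines")
  params <- hmm_params(error_rate = config$hmm$error_rate,
                       expansion = config$hmm$expansion)
  probs <- reconstruct_descent(panel$genotypes, panel$founders, params,
                               viterbi = TRUE)
  if (!is.null(config$hmm$prune))
    probs <- prune_intervals(probs, config$hmm$prune)
  write_descent(probs, file.path(out, "descent_probs.tsv"))

  .log_stage(q, "pheno: covariate correction / quantile normalization")
  trait <- stats::setNames(pheno[[s$trait]], pheno$animal)
  processed <- trait
  if (isTRUE(config$pheno$correct))
    processed <- adjust_covariates(processed,
                                   pheno[, c("age", "batch", "origin")])
  if (isTRUE(config$pheno$normalize))
    processed <- quantile_normalize(processed)
  summ <- line_summaries(processed, pheno$line)
  utils::write.csv(summ, file.path(out, "line_summaries.csv"),
                   row.names = FALSE, quote = FALSE)

  .log_stage(q, "heritability: kinship + variance components")
  K <- kinship_from_descent(probs)
  utils::write.csv(data.frame(line = rownames(K),
                              as.data.frame(unclass(K))),
                   file.path(out, "kinship.csv"), row.names = FALSE,
                   quote = FALSE)
  vc_raw <- fit_varcomp(trait, pheno$line, K)
  vc_proc <- fit_varcomp(processed, pheno$line, K)
  bh_raw <- anova_broad_h2(trait, pheno$line)
  bh_proc <- anova_broad_h2(processed, pheno$line)
  herit <- list(trait = s$trait,
                raw = list(h2 = vc_raw$h2, sigma_g2 = vc_raw$sigma_g2,
                           sigma_e2 = vc_raw$sigma_e2, H2 = bh_raw$H2,
                           MSb = bh_raw$MS_between, MSw = bh_raw$MS_within,
                           n = bh_raw$n, anova_P = bh_raw$P),
                processed = list(h2 = vc_proc$h2,
                                 sigma_g2 = vc_proc$sigma_g2,
                                 sigma_e2 = vc_proc$sigma_e2,
                                 H2 = bh_proc$H2, MSb = bh_proc$MS_between,
                                 MSw = bh_proc$MS_within, n = bh_proc$n,
                                 anova_P = bh_proc$P))
  jsonlite::write_json(herit, file.path(out, "heritability.json"),
                       auto_unbox = TRUE, digits = NA)

  .log_stage(q, "scan: ", config$scan$n_perm, " permutations")
  means <- stats::setNames(summ$mean, summ$line)
  wts <- stats::setNames(as.numeric(summ$n), summ$line)
  scan <- scan_genome(means, wts, probs)
  write_scan(scan, file.path(out, "scan.tsv"))
  perm <- permutation_threshold(means, wts, probs,
                                n_perm = config$scan$n_perm,
                                alpha = config$scan$alpha,
                                seed = seed + 2L)
  utils::write.table(data.frame(perm = seq_along(perm$max_logp),
                                max_logp = perm$max_logp),
                     file.path(out, "perm_maxima.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  peaks <- lapply(unique(scan$chr), function(ch) {
    i <- which(scan$chr == ch)
    define_qtl_interval(scan, i[which.max(scan$LogP[i])], perm = perm)
  })
  pp <- vapply(peaks, `[[`, numeric(1), "perm_p")
  sig <- peaks[pp < min(config$scan$alpha[1], 0.05)]
  qtl_tab <- do.call(rbind, lapply(peaks, function(p)
    data.frame(trait = s$trait, chrom = p$chr, start = p$bp_start,
               end = p$bp_end, peak_marker = p$peak_marker,
               peak_LogP = p$peak_logp, permP = p$perm_p,
               significant = p$perm_p < min(config$scan$alpha[1], 0.05),
               stringsAsFactors = FALSE)))
  utils::write.table(qtl_tab, file.path(out, "qtl.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  .log_stage(q, "annotate: ", length(sig), " significant QTL(s)")
  ann <- config$annotate
  if (!is.null(ann$genes)) {
    genes <- read_gene_table(ann$genes)
    ranking <- read_ranking(ann$ranking)
  } else {
    gt <- simulate_gene_table(panel$founders$map,
                              n_genes = ann$n_genes %||% 500L,
                              seed = seed + 3L)
    genes <- gt$genes
    ranking <- gt$ranking
  }
  enr_rows <- lapply(sig, function(p) {
    memb <- genes_in_interval(p, genes)
    if (nrow(memb) == 0L ||
        !any(memb$gene_id %in% ranking$gene_id)) return(NULL)
    e <- rank_enrichment(memb$gene_id, ranking, seed = seed + 4L)
    data.frame(chrom = p$chr, start = p$bp_start, end = p$bp_end,
               n_genes = nrow(memb), enrichment_P = e$p,
               stringsAsFactors = FALSE)
  })
  enr_tab <- do.call(rbind, enr_rows)
  if (!is.null(enr_tab))
    utils::write.table(enr_tab, file.path(out, "enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  files <- list.files(out, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("ccqg")),
    r_version = R.version.string,
    config = unclass(config),
    seeds = list(simulate = seed, phenotypes = seed + 1L,
                 permutations = seed + 2L, genes = seed + 3L,
                 enrichment = seed + 4L),
    true_h2 = attr(pheno, "true_h2"),
    n_significant_qtl = length(sig),
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_stage(q, "done: outputs in ", out)
  invisible(manifest)
}
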