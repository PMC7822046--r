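default_config <- function() {
  list(
    input = list(genotypes = NULL, genotype_format = "matrix_tsv",
                 phenotypes = NULL, gff = NULL),
    synthetic = NULL,
    qc = list(max_missing = 0.20, max_het = 0.20, min_maf = 0.01),
    gwas = list(mode = "p3d", fdr_cutoff = 0.05, candidate_p = 1e-4,
                n_pcs = 0),
    ld = list(maf_min = 0.01, cutoff = 0.1, statistic = "r2",
              d_prime_min = 0.80, flank_bp = 150000, max_pairs = 20000),
    stabsel = list(alpha = 1, B = 100, theta = 1, B_perm = 20,
                   run_empirical = FALSE),
    sweep = list(rates = c(0.05, seq(0.10, 1.0, by = 0.10))),
    seed = 1,
    output_dir = "gwaspect_run"
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) abort(paste0("unknown config key: ", full))
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_range <- function(value, key, lo, hi) {
  if (!is.numeric(value) || value < lo || value > hi) {
    abort(sprintf("config key %s = %s out of range [%g, %g]",
                  key, format(value), lo, hi))
  }
}

#' Validate and normalize a run configuration
#'
#' Reads a YAML config file (or takes a list), injects defaults for every
#' unset key, rejects unknown keys, and range-checks thresholds. The
#' defaults are the customary values of this analysis: QC at 20% missing,
#' 20% heterozygosity, MAF 0.01; FDR cutoff 0.05 with candidate p < 1e-4;
#' LD with MAF > 0.01, r-squared decay cutoff 0.1, strong-LD D' 0.80,
#' 150 kb candidate flank; LASSO stability selection with B = 100 and
#' theta = 1; heterozygosity sweep at 5%, 10%, then every 10% to 100%.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return The normalized config list (class `gwaspect_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  cfg <- merge_config(default_config(), config)
  check_range(cfg$qc$max_missing, "qc.max_missing", 0, 1)
  check_range(cfg$qc$max_het, "qc.max_het", 0, 1)
  check_range(cfg$qc$min_maf, "qc.min_maf", 0, 1)
  check_range(cfg$gwas$fdr_cutoff, "gwas.fdr_cutoff", 0, 1)
  check_range(cfg$gwas$candidate_p, "gwas.candidate_p", 0, 1)
  check_range(cfg$ld$maf_min, "ld.maf_min", 0, 0.5)
  check_range(cfg$ld$d_prime_min, "ld.d_prime_min", 0, 1)
  check_range(cfg$stabsel$alpha, "stabsel.alpha", 0, 1)
  if (cfg$stabsel$theta <= 0) abort("config key stabsel.theta must be > 0")
  if (!cfg$gwas$mode %in% c("p3d", "full_reml")) {
    abort("config key gwas.mode must be 'p3d' or 'full_reml'")
  }
  structure(cfg, class = c("gwaspect_config", "list"))
}

#' Run the full association pipeline
#'
#' Executes QC, population structure, the kinship mixed-model scan, LD
#' analysis around the top marker, and stability selection, writing every
#' stage's table plus a JSON manifest (parameters, seeds, file hashes) to
#' the output directory. A rerun with the same config and seed is
#' bit-reproducible. The root seed expands deterministically into per-stage
#' seeds so stages can be rerun in isolation.
#'
#' @param config a config list or YAML path; see [validate_config()].
#' @return The output directory path, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  if (is.null(cfg$synthetic) &&
      (is.null(cfg$input$genotypes) || is.null(cfg$input$phenotypes))) {
    abort("config needs either a synthetic block or input genotype and phenotype paths")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  stage_seeds <- with_seed(cfg$seed, sample.int(2^30, 5))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    inform(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- "load"
  res <- tryCatch({
    if (!is.null(cfg$synthetic)) {
      say("simulating panel: %s", paste(names(cfg$synthetic), unlist(cfg$synthetic),
                                        sep = "=", collapse = ", "))
      syn <- cfg$synthetic
      panel_args <- syn[setdiff(names(syn), c("causal", "h2_polygenic",
                                              "noise_sd", "baseline"))]
      panel_args$seed <- panel_args$seed %||% stage_seeds[1]
      panel <- do.call(simulate_panel, panel_args)
      G <- panel$genotypes
      causal <- syn$causal %||% tibble(snp_id = character(), effect = numeric())
      if (is.list(causal) && !is.data.frame(causal)) causal <- as_tibble(causal)
      phen <- simulate_phenotype(
        G, causal = causal, h2_polygenic = syn$h2_polygenic %||% 0.3,
        noise_sd = syn$noise_sd %||% 0.05, baseline = syn$baseline %||% 1.63,
        seed = stage_seeds[2]
      )$phenotypes
      write_genotypes(G, out("genotypes.tsv"))
      readr::write_csv(phen, out("phenotypes.csv"), progress = FALSE)
    } else {
      G <- read_genotypes(cfg$input$genotypes, cfg$input$genotype_format)
      phen <- read_phenotypes(cfg$input$phenotypes)
    }

    stage <- "qc"
    flt <- filter_snps(G, cfg$qc$max_missing, cfg$qc$max_het, cfg$qc$min_maf)
    say("qc: %d of %d SNPs retained (missing %d, het %d, maf %d removed)",
        flt$log$n_retained, flt$log$n_input, flt$log$n_removed_missing,
        flt$log$n_removed_het, flt$log$n_removed_maf)
    write_results(flt$stats, out("qc_report.tsv"))
    Gf <- flt$genotypes

    stage <- "popstruct"
    D <- genetic_distance(Gf)
    pc <- pcoa(D, n_axes = max(2, cfg$gwas$n_pcs))
    say("pcoa: axis variance %s",
        paste(sprintf("%.1f%%", 100 * pc$variance_fraction), collapse = ", "))
    write_results(tidy(pc), out("pcoa_coordinates.tsv"))

    stage <- "gwas"
    K <- kinship(Gf)
    covar <- if (cfg$gwas$n_pcs > 0) {
      pc$coordinates[, seq_len(cfg$gwas$n_pcs), drop = FALSE]
    }
    scan <- mlm_scan(Gf, phen, K, mode = cfg$gwas$mode, covariates = covar)
    sig_rep <- significance_report(scan, cfg$gwas$fdr_cutoff, cfg$gwas$candidate_p)
    say("gwas: %d significant at FDR %.2g, %d candidates at p < %.2g",
        nrow(sig_rep$significant), cfg$gwas$fdr_cutoff,
        nrow(sig_rep$candidates), cfg$gwas$candidate_p)
    write_results(scan, out("association.tsv"))
    pd <- gwas_plot_data(scan)
    write_results(pd$manhattan, out("manhattan.tsv"))
    write_results(pd$qq, out("qq.tsv"))

    stage <- "ld"
    top <- scan$snp_id[1]
    win <- strong_ld_window(Gf, top, cfg$ld$d_prime_min)
    say("ld: strong-LD window around %s spans %s:%d-%d (%d SNPs)",
        top, win$chrom, win$start, win$end, win$n_snps)
    pairs <- pairwise_ld(Gf, scope = "chromosome", maf_min = cfg$ld$maf_min,
                         max_pairs = cfg$ld$max_pairs, seed = stage_seeds[3])
    dec <- decay_fit(pairs, statistic = cfg$ld$statistic, cutoff = cfg$ld$cutoff,
                     n = 2 * n_accessions(Gf))
    say("ld: %s decay to %.2g at %s bp", cfg$ld$statistic, cfg$ld$cutoff,
        format(dec$decay_distance_bp, big.mark = ","))
    write_results(pairs, out("ld_pairs.tsv"))
    write_results(win, out("strong_ld_window.tsv"))
    genes <- NULL
    if (!is.null(cfg$input$gff)) {
      genes <- read_gff(cfg$input$gff)
      cand <- candidate_genes(genes, chrom = win$chrom,
                              center = Gf$map$pos[match(top, Gf$map$snp_id)],
                              flank_bp = cfg$ld$flank_bp)
      say("ld: %d candidate gene(s) within %d bp of %s", nrow(cand),
          cfg$ld$flank_bp, top)
      write_results(cand, out("candidate_genes.tsv"))
    }

    stage <- "stabsel"
    prof <- selection_probability(
      Gf, phen, penalty_config(alpha = cfg$stabsel$alpha),
      B = cfg$stabsel$B, seed = stage_seeds[4]
    )
    prof$theta <- cfg$stabsel$theta
    prof$theoretical_threshold <- theoretical_threshold(
      prof$q_avg, cfg$stabsel$theta, prof$p
    )
    if (isTRUE(cfg$stabsel$run_empirical)) {
      prof$empirical_threshold <- empirical_threshold(
        Gf, phen, penalty_config(alpha = cfg$stabsel$alpha),
        theta = cfg$stabsel$theta, B_perm = cfg$stabsel$B_perm,
        B_bootstrap = cfg$stabsel$B, seed = stage_seeds[5],
        lambda = prof$lambda
      )
    }
    say("stabsel: q_avg = %.2f, theoretical threshold = %.3f%s", prof$q_avg,
        prof$theoretical_threshold,
        if (!is.na(prof$empirical_threshold))
          sprintf(", empirical threshold = %.3f", prof$empirical_threshold) else "")
    write_results(tidy(prof), out("selection_probability.tsv"))
    jsonlite::write_json(glance(prof), out("stabsel_summary.json"),
                         auto_unbox = TRUE, digits = NA)

    list(scan = scan, report = sig_rep, pcoa = pc, decay = dec, window = win,
         profile = prof)
  }, error = function(e) {
    writeLines(c(log_lines, paste0("FAILED at stage ", stage, ": ",
                                   conditionMessage(e))), out("run.log"))
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })

  stage_files <- list.files(cfg$output_dir, pattern = "\\.(tsv|csv|json)$")
  manifest <- list(
    package = "gwaspect",
    version = as.character(utils::packageVersion("gwaspect")),
    config = unclass(cfg),
    stage_seeds = stage_seeds,
    files = lapply(setNames(stage_files, stage_files), function(f) {
      unname(tools::md5sum(out(f)))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, out("run.log"))
  invisible(cfg$output_dir)
}
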