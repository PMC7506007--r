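# Configuration-driven orchestration of the full synthetic study:
# simulate -> markers -> ancestry -> sex -> de -> ase -> cistrans -> fd
# -> behaviour. Each stage writes its outputs plus a manifest recording
# parameters, seed and output checksums; identical config + seed give
# byte-identical outputs.

PIPELINE_STAGES <- c("simulate", "markers", "ancestry", "sex", "de", "ase",
                     "cistrans", "fd", "behaviour")

STAGE_DEPS <- list(
  simulate = character(0),
  markers = "simulate", ancestry = c("simulate", "markers"),
  sex = "simulate", de = "simulate", ase = "simulate",
  cistrans = c("de", "ase"), fd = character(0), behaviour = "simulate"
)

#' Default pipeline configuration
#'
#' A compact end-to-end study: a reduced genome (5 autosomes + Z, the
#' selected marker and QTL placed on chr5), 10 + 10 species samples for
#' marker discovery, a small backcross cohort, a parental + F1 expression
#' experiment and a courtship-trial experiment.
#'
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param outdir output directory.
#' @return a named list (`run_config`).
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("crosskit_run")) {
  list(
    seed = seed,
    outdir = outdir,
    stages = PIPELINE_STAGES,
    map = list(n_autosomes = 5, length_cM = 50, length_bp = 5e6),
    panel = list(sites_per_chrom = 400, n_haps = 20, diagnostic_frac = 0.7),
    pedigree = list(n_bc = 4, marker_chrom = "chr5", marker_pos = 360000),
    cohort = list(n_bc3 = 6),
    ancestry = list(window_bp = 1e6, min_informative = 30),
    expression = list(n_genes = 300, n_per_group = 6, frac_de = 0.1,
                      effect_log2 = 1.5, alpha = 0.05, mean_q = 200),
    ase = list(n_individuals = 8, depth = 500),
    qtl = list(chrom = "chr5", start = 0, end = 2.75e6),
    fd = list(n_sites = 4000, window_bp = 1e5, step_bp = 2e4,
              min_sites = 20),
    behaviour = list(n_males = 60, trials_per_male = 5, chr18_effect = 1.5,
                     sigma_male = 0.5, n_draws = 400, n_warmup = 300,
                     n_chains = 2)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_run_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, cfg)
  out
}

stage_seed <- function(seed, stage) {
  (seed * 131L + match(stage, PIPELINE_STAGES) * 7919L) %% .Machine$integer.max
}

validate_stages <- function(stages) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stages: ", paste(unknown, collapse = ", "))
  done <- character(0)
  for (s in stages) {
    missing <- setdiff(intersect(STAGE_DEPS[[s]], stages), done)
    if (length(missing))
      stop("stage '", s, "' scheduled before its dependency: ",
           paste(missing, collapse = ", "))
    done <- c(done, s)
  }
  invisible(TRUE)
}

write_manifest <- function(outdir, stage, params, seed, files) {
  files <- files[file.exists(files)]
  manifest <- list(stage = stage, seed = seed, parameters = params,
                   outputs = as.list(setNames(
                     unname(tools::md5sum(files)), basename(files))))
  write_json_summary(manifest,
                     file.path(outdir, paste0("manifest_", stage, ".json")))
}

#' Run the synthetic study pipeline
#'
#' Executes the configured stages in order (dependencies validated
#' up-front), writing TSV/VCF/JSON outputs and a per-stage manifest into
#' `config$outdir`. Reruns with the same config and seed produce
#' byte-identical tables.
#'
#' @param config a `run_config` list ([default_run_config] /
#'   [read_run_config]).
#' @return invisible list of key in-memory results (a run report).
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_stages(config$stages)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  report <- list()
  out <- function(...) file.path(config$outdir, ...)
  need <- function(what, stage) {
    if (!exists(what, envir = env))
      stop("stage '", stage, "' is missing upstream output '", what, "'")
    get(what, envir = env)
  }

  for (stage in config$stages) {
    sseed <- stage_seed(config$seed, stage)
    files <- character(0)

    if (stage == "simulate") {
      map <- do.call(default_genetic_map, config$map)
      marker <- list(chrom = config$pedigree$marker_chrom,
                     pos_bp = config$pedigree$marker_pos)
      panel <- simulate_species_panel(
        map, config$panel$sites_per_chrom, config$panel$n_haps,
        config$panel$diagnostic_frac, seed = sseed)
      ped <- pedigree_spec(n_bc = config$pedigree$n_bc, marker = marker)
      bc3 <- simulate_pedigree(ped, map, n = config$cohort$n_bc3,
                               seed = sseed + 1)
      names(bc3) <- sprintf("bc3_%02d", seq_along(bc3))
      controls <- list(f1_control = f1_genome(map),
                       cyd_control = pure_genome(map, "cyd"))
      species <- c(lapply(seq_len(5), function(i) pure_genome(map, "mel")),
                   lapply(seq_len(5), function(i) pure_genome(map, "cyd")))
      names(species) <- c(sprintf("mel_%02d", 1:5), sprintf("cyd_%02d", 1:5))
      sexes <- setNames(rep_len(c("male", "female"), length(species)),
                        names(species))
      rec <- simulate_genotype_records(
        c(species, controls, bc3), panel, coverage_model(error_rate = 0.005),
        map = map, sex = sexes, seed = sseed + 2)
      n_genes <- config$expression$n_genes
      n_de <- round(config$expression$frac_de * n_genes)
      cis <- c(rep(config$expression$effect_log2, n_de),
               rep(0, n_genes - n_de))
      arch <- regulatory_architecture(
        n_genes, q = config$expression$mean_q, cis_log2 = cis,
        alpha = config$expression$alpha)
      expr <- simulate_expression(
        arch, parental_design(config$expression$n_per_group),
        seed = sseed + 3)
      acounts <- simulate_allele_counts(
        arch, config$ase$n_individuals, config$ase$depth, seed = sseed + 4)
      eff <- behaviour_effects(
        beta = matrix(c(0, 0, config$behaviour$chr18_effect, 0, 0, 0),
                      3, 2, dimnames = list(c("chr1", "chr17", "chr18"),
                                            c("mel_only", "both"))),
        sigma_male = config$behaviour$sigma_male)
      trials <- simulate_trials(eff, config$behaviour$n_males,
                                config$behaviour$trials_per_male,
                                seed = sseed + 5)
      gene_coords <- data.frame(
        gene = arch$gene, chrom = config$qtl$chrom,
        start = round(seq(0, config$qtl$end * 2, length.out = n_genes)),
        stringsAsFactors = FALSE)
      gene_coords$end <- gene_coords$start + 2000
      assign("map", map, env); assign("panel", panel, env)
      assign("records", rec$records, env); assign("truth", rec$truth, env)
      assign("bc3", bc3, env); assign("arch", arch, env)
      assign("expr", expr, env); assign("acounts", acounts, env)
      assign("trials", trials, env); assign("gene_coords", gene_coords, env)
      files <- c(out("genotypes.vcf"), out("counts.tsv"),
                 out("allele_counts.tsv"), out("trials.tsv"),
                 out("truth_labels.json"))
      write_records_vcf(rec$records, files[1])
      write_counts(expr$counts, files[2])
      write_tsv_table(acounts, files[3])
      write_tsv_table(trials, files[4])
      write_json_summary(list(
        de_genes = arch$gene[arch$cis_log2 != 0],
        diagnostic_sites = nrow(panel_diagnostic_sites(panel))), files[5])
      report$simulate <- list(n_records = nrow(rec$records))
    }

    if (stage == "markers") {
      records <- need("records", stage)
      sp_rec <- records[grepl("^(mel|cyd)_", records$sample), ]
      flt <- filter_rna_genotypes(sp_rec)
      spmap <- setNames(sub("_.*", "", unique(flt$sample)),
                        unique(flt$sample))
      summ <- summarize_sites(flt, spmap)
      markers <- diagnostic_markers(call_fixed(summ, "mel"),
                                    call_fixed(summ, "cyd"))
      assign("markers", markers, env)
      files <- out("markers.tsv")
      write_tsv_table(markers, files)
      report$markers <- list(n_markers = nrow(markers))
    }

    if (stage == "ancestry") {
      records <- need("records", stage)
      markers <- need("markers", stage)
      map <- need("map", stage)
      wsf <- function(sm) window_share_fractions(
        records[records$sample == sm, ], markers,
        window_bp = config$ancestry$window_bp,
        min_informative = config$ancestry$min_informative)
      f1p <- wsf("f1_control"); cyp <- wsf("cyd_control")
      bc3_names <- grep("^bc3_", unique(records$sample), value = TRUE)
      win <- lapply(bc3_names, function(sm)
        classify_windows(wsf(sm), f1p, cyp))
      names(win) <- bc3_names
      het <- vapply(win, genome_het_fraction,
                    exclude_chrom = config$pedigree$marker_chrom, 0)
      assign("windows", win, env)
      files <- c(out("ancestry_windows.tsv"), out("genome_composition.json"))
      write_tsv_table(do.call(rbind, Map(function(w, nm)
        cbind(sample = nm, w), win, names(win))), files[1])
      write_json_summary(list(het_fraction_outside_selected = as.list(het),
                              mean = mean(het)), files[2])
      report$ancestry <- list(mean_het = mean(het))
    }

    if (stage == "sex") {
      records <- need("records", stage)
      map <- need("map", stage)
      z <- map_z_chrom(map)
      sp <- grep("^(mel|cyd)_", unique(records$sample), value = TRUE)
      calls <- do.call(rbind, lapply(sp, function(sm)
        sex_from_z_heterozygosity(
          records[records$sample == sm & records$chrom == z, ], sm)))
      files <- out("sex_calls.tsv")
      write_tsv_table(calls, files)
      report$sex <- list(calls = table(calls$call))
    }

    if (stage == "de") {
      expr <- need("expr", stage)
      de <- nb_de_test(expr$counts, expr$meta, c("group", "mel", "cyd"))
      assign("de", de, env)
      files <- out("de_results.tsv")
      write_tsv_table(de, files)
      report$de <- list(n_called = length(de_call(de)))
    }

    if (stage == "ase") {
      acounts <- need("acounts", stage)
      ase <- ase_test(acounts)
      bias <- assignment_bias_check(acounts)
      assign("ase", ase, env)
      files <- c(out("ase_results.tsv"), out("ase_bias_check.json"))
      write_tsv_table(ase, files[1])
      write_json_summary(bias, files[2])
      report$ase <- list(n_called = sum(ase$called), bias = bias)
    }

    if (stage == "cistrans") {
      de <- need("de", stage); ase <- need("ase", stage)
      ct <- cis_trans_classify(de, ase)
      files <- out("cis_trans_classes.tsv")
      write_tsv_table(ct, files)
      report$cistrans <- list(classes = table(ct$class))
    }

    if (stage == "fd") {
      freqs <- simulate_freq_table(
        config$fd$n_sites, chrom_length = 1e6, chroms = "chr18",
        admixed = data.frame(chrom = "chr18", start = 4e5, end = 6e5,
                             rate = 0.8),
        seed = sseed)
      fdw <- fd_windows(freqs, config$fd$window_bp, config$fd$step_bp,
                        config$fd$min_sites)
      files <- out("fd_windows.tsv")
      write_tsv_table(fdw, files)
      report$fd <- list(n_windows = sum(!is.na(fdw$fd)))
    }

    if (stage == "behaviour") {
      trials <- need("trials", stage)
      b <- config$behaviour
      full <- fit_multinomial(trials, c("chr1", "chr17", "chr18"),
                              n_draws = b$n_draws, n_warmup = b$n_warmup,
                              n_chains = b$n_chains, seed = sseed,
                              check_convergence = FALSE)
      red <- fit_multinomial(trials, c("chr1", "chr17"),
                             n_draws = b$n_draws, n_warmup = b$n_warmup,
                             n_chains = b$n_chains, seed = sseed,
                             check_convergence = FALSE)
      cmp <- compare_models(full, red)
      pp <- do.call(rbind, lapply(c("cyd/cyd", "cyd/melp"), function(gt) {
        p <- predicted_proportions(full, c(chr1 = "cyd/cyd",
                                           chr17 = "cyd/cyd", chr18 = gt),
                                   seed = sseed)
        cbind(geno_chr18 = gt, p)
      }))
      files <- c(out("behaviour_comparison.tsv"),
                 out("predicted_proportions.csv"),
                 out("behaviour_posterior.json"))
      write_tsv_table(data.frame(comparison = "drop_chr18",
                                 delta_elpd = cmp$delta_elpd,
                                 se_delta = cmp$se_delta,
                                 se_units = cmp$se_units,
                                 retained = cmp$retained), files[1])
      write.table(pp, files[2], sep = ",", quote = FALSE, row.names = FALSE)
      write_json_summary(fixed_effect_summary(full), files[3])
      report$behaviour <- list(se_units = cmp$se_units,
                               retained = cmp$retained)
    }

    write_manifest(config$outdir, stage,
                   config[setdiff(names(config), c("outdir", "stages"))],
                   sseed, files)
  }
  invisible(report)
}
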