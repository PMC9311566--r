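#' Default pipeline configuration
#'
#' All analysis constants appear here with their standard values: call
#' rate 0.95, MAF 0.005, pruning window 50 kbp at r 0.98, projection age
#' 8, 5000 permutations at family-wise alpha 0.05, ROH minimum 1 Mb, HRR
#' minimum 100 kb. The configuration round-trips through YAML.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param outdir output directory for stage files.
#' @param ... overrides for any default listed below.
#' @return a named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("crossherd_run_"),
                            ...) {
  cfg <- list(
    seed = seed, outdir = outdir,
    n_breeds = 3, n_founders_per_breed = 25, n_generations = 3,
    n_per_mating = 40, n_variants = 2000, n_chromosomes = 5,
    chrom_length = 1e8, fst = 0.12, map_cm_per_mb = 1,
    min_call_rate = 0.95, min_maf = 0.005,
    prune_window_bp = 50000, prune_r = 0.98,
    basis_order = 1, age_range = c(2, 8), include_pe = FALSE,
    reml_tol = 1e-6, reml_max_iter = 200,
    projection_age = 8,
    n_permutations = 5000, alpha = 0.05,
    roh_min_bp = 1e6, roh_min_snp = 15,
    hrr_min_bp = 1e5, hrr_min_snp = 3,
    max_gap_bp = 1e6,
    sim_mode = "variant", dom_mean = 0.6, conception_het = 2,
    var_a_cw = 900, var_d_cw = 60, var_a_wtw = 250, var_d_wtw = 500,
    sigma2_e_cw = 900, sigma2_e_wtw = 1500,
    qtl_table = NULL, qtl_dialect = "csv",
    stages = c("simulate", "records", "grm", "fit", "effects",
               "heterosis", "qtl"))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$age_range <- unlist(cfg$age_range)
  do.call(pipeline_config, c(cfg[intersect(names(cfg),
                                           names(pipeline_config()))]))
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if ("qtl" %in% cfg$stages && !is.null(cfg$qtl_table) &&
      !file.exists(cfg$qtl_table)) {
    stop("config error: qtl_table '", cfg$qtl_table, "' does not exist")
  }
  if ("grm" %in% cfg$stages && !"simulate" %in% cfg$stages) {
    # genotypes must come from somewhere
    geno_path <- file.path(cfg$outdir, "genotypes.tsv")
    if (!file.exists(geno_path)) {
      stop("config error: grm stage enabled without genotype input (",
           geno_path, " missing and simulate stage disabled)")
    }
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order -- simulate herd,
#' build records, filter genotypes and build GRMs, fit both traits by
#' random-regression GREML, back-solve variant effects with permutation
#' significance, compute heterosis metrics and group summaries, and
#' intersect significant variants with a QTL table when one is supplied.
#' Stage outputs are written under `cfg$outdir` and a manifest records
#' parameters, per-stage dimensions, and md5 hashes of every file, so
#' re-runs with the same config and seed are reproducible.
#'
#' @param cfg a [pipeline_config()].
#' @param keep_objects return in-memory stage objects alongside the
#'   manifest (default TRUE).
#' @return list with `manifest` and (optionally) `objects`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), keep_objects = TRUE) {
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, config = unclass(cfg), stages = list())
  obj <- list()
  t_all <- proc.time()[3]

  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(...),
                                   elapsed_s = round(proc.time()[3] - t0, 2))
  }

  if ("simulate" %in% cfg$stages) {
    t0 <- proc.time()[3]
    panel <- simulate_breed_panel(cfg$n_breeds, cfg$n_variants,
                                  cfg$n_chromosomes, cfg$chrom_length,
                                  cfg$fst, seed = cfg$seed)
    plan <- default_cross_plan(panel$breeds,
                               n_generations = cfg$n_generations,
                               n_per_mating = cfg$n_per_mating)
    ped <- simulate_pedigree(plan, cfg$n_founders_per_breed,
                             cfg$n_generations, seed = cfg$seed + 1)
    geno <- drop_genotypes(ped, panel, cfg$map_cm_per_mb,
                           seed = cfg$seed + 2)
    params <- true_params(
      K_a = diag(2, cfg$basis_order + 1), K_d = NULL,
      sigma2_e = cfg$sigma2_e_cw, dom_mean = cfg$dom_mean,
      conception_het = cfg$conception_het, order = cfg$basis_order,
      age_range = cfg$age_range, causal_frac = 0.2,
      var_a = cfg$var_a_cw, var_d = cfg$var_d_cw)
    ev_cw <- simulate_events(ped, geno, params, mode = cfg$sim_mode,
                             seed = cfg$seed + 3)
    params_wtw <- true_params(
      K_a = diag(2, cfg$basis_order + 1), K_d = NULL,
      sigma2_e = cfg$sigma2_e_wtw, dom_mean = cfg$dom_mean,
      conception_het = cfg$conception_het, order = cfg$basis_order,
      age_range = cfg$age_range, causal_frac = 0.2,
      var_a = cfg$var_a_wtw, var_d = cfg$var_d_wtw,
      calf_sd = 30)
    ev_wtw <- simulate_events(ped, geno, params_wtw, mode = cfg$sim_mode,
                              seed = cfg$seed + 3)
    write_pedigree_csv(ped, file.path(cfg$outdir, "pedigree.csv"))
    write_genotypes_tsv(geno, file.path(cfg$outdir, "genotypes.tsv"))
    write_events_csv(ev_wtw, file.path(cfg$outdir, "events.csv"))
    obj$panel <- panel; obj$pedigree <- ped; obj$genotypes <- geno
    obj$events_cw <- ev_cw; obj$events_wtw <- ev_wtw
    note("simulate", n_animals = nrow(ped), n_variants = ncol(geno$calls),
         n_cows = length(unique(ev_cw$events$cow_id)))
  }

  if ("records" %in% cfg$stages) {
    t0 <- proc.time()[3]
    rec_cw <- build_records(obj$events_cw, obj$pedigree)$cw
    rec_wtw <- build_records(obj$events_wtw, obj$pedigree)$wtw
    utils::write.csv(rec_cw, file.path(cfg$outdir, "records_cw.csv"),
                     row.names = FALSE)
    utils::write.csv(rec_wtw, file.path(cfg$outdir, "records_wtw.csv"),
                     row.names = FALSE)
    obj$records <- list(cw = rec_cw, wtw = rec_wtw)
    note("records", n_cw = nrow(rec_cw), n_wtw = nrow(rec_wtw))
  }

  if ("grm" %in% cfg$stages) {
    t0 <- proc.time()[3]
    cows <- unique(obj$records$cw$cow_id)
    sub <- geno_matrix(obj$genotypes$calls[cows, , drop = FALSE],
                       obj$genotypes$map)
    qc <- qc_filter(sub, cfg$min_call_rate, cfg$min_maf)
    pr <- ld_prune(qc, cfg$prune_window_bp, cfg$prune_r)
    ga <- additive_grm(pr$genotypes)
    gd <- dominance_grm(pr$genotypes)
    utils::write.csv(pr$map, file.path(cfg$outdir, "redundancy_map.csv"),
                     row.names = FALSE)
    obj$qc <- qc; obj$pruned <- pr; obj$grm_add <- ga; obj$grm_dom <- gd
    note("grm", n_animals = nrow(ga$G), n_variants = ncol(ga$M),
         n_pruned = nrow(pr$map))
  }

  if ("fit" %in% cfg$stages) {
    t0 <- proc.time()[3]
    fit_cw <- rr_greml(obj$records$cw, obj$grm_add$G, obj$grm_dom$D,
                       order = cfg$basis_order, age_range = cfg$age_range,
                       include_pe = cfg$include_pe, trait = "CW",
                       tol = cfg$reml_tol, max_iter = cfg$reml_max_iter)
    fit_wtw <- rr_greml(obj$records$wtw, obj$grm_add$G, obj$grm_dom$D,
                        order = cfg$basis_order, age_range = cfg$age_range,
                        include_pe = cfg$include_pe, trait = "WtW",
                        tol = cfg$reml_tol, max_iter = cfg$reml_max_iter)
    obj$fit <- list(cw = fit_cw, wtw = fit_wtw)
    obj$proj <- list(cw = project_to_age(fit_cw, cfg$projection_age),
                     wtw = project_to_age(fit_wtw, cfg$projection_age))
    utils::write.csv(obj$proj$cw, file.path(cfg$outdir, "proj_cw.csv"),
                     row.names = FALSE)
    utils::write.csv(obj$proj$wtw, file.path(cfg$outdir, "proj_wtw.csv"),
                     row.names = FALSE)
    h8 <- rbind(cbind(trait = "CW",
                      heritability_curve(fit_cw, cfg$projection_age)),
                cbind(trait = "WtW",
                      heritability_curve(fit_wtw, cfg$projection_age)))
    utils::write.csv(h8, file.path(cfg$outdir, "varcomp_age8.csv"),
                     row.names = FALSE)
    note("fit", cw_logL = fit_cw$logLik, wtw_logL = fit_wtw$logLik,
         cw_converged = fit_cw$converged, wtw_converged = fit_wtw$converged)
  }

  if ("effects" %in% cfg$stages) {
    t0 <- proc.time()[3]
    tabs <- lapply(c(cw = "cw", wtw = "wtw"), function(tr) {
      variant_effect_table(obj$grm_add, obj$grm_dom, obj$proj[[tr]],
                           obj$pruned$genotypes, B = cfg$n_permutations,
                           seed = cfg$seed + 10, alpha = cfg$alpha,
                           redundancy_map = obj$pruned$map)
    })
    for (tr in names(tabs)) {
      utils::write.table(tabs[[tr]],
                         file.path(cfg$outdir,
                                   paste0("variant_effects_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    obj$variant_effects <- tabs
    note("effects",
         n_sig_cw = sum(tabs$cw$sig_a | tabs$cw$sig_d),
         n_sig_wtw = sum(tabs$wtw$sig_a | tabs$wtw$sig_d))
  }

  if ("heterosis" %in% cfg$stages) {
    t0 <- proc.time()[3]
    prof <- heterosis_profile(
      obj$pruned$genotypes, obj$grm_add$G, obj$pedigree,
      roh_args = list(min_length_bp = cfg$roh_min_bp,
                      min_snp = cfg$roh_min_snp,
                      max_gap_bp = cfg$max_gap_bp),
      hrr_args = list(min_length_bp = cfg$hrr_min_bp,
                      min_snp = cfg$hrr_min_snp,
                      max_gap_bp = cfg$max_gap_bp))
    groups <- group_cows(obj$proj$cw, obj$proj$wtw)
    summ <- summarize_groups(prof, groups)
    effects <- data.frame(id = obj$proj$cw$id,
                          dom_cw = obj$proj$cw$u_d,
                          tot_cw = obj$proj$cw$total,
                          dom_wtw = obj$proj$wtw$u_d[
                            match(obj$proj$cw$id, obj$proj$wtw$id)],
                          tot_wtw = obj$proj$wtw$total[
                            match(obj$proj$cw$id, obj$proj$wtw$id)])
    r2 <- regress_metrics(effects, prof)
    utils::write.csv(prof, file.path(cfg$outdir, "heterosis_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(cfg$outdir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(effect = rownames(r2), r2),
                     file.path(cfg$outdir, "r2_table.csv"),
                     row.names = FALSE)
    write_segments_bed(attr(prof, "roh"),
                       file.path(cfg$outdir, "roh_segments.bed"))
    write_segments_bed(attr(prof, "hrr"),
                       file.path(cfg$outdir, "hrr_segments.bed"))
    obj$heterosis <- prof; obj$groups <- groups; obj$group_summary <- summ
    obj$r2 <- r2
    note("heterosis", n_cows = nrow(groups),
         n_roh_segments = nrow(attr(prof, "roh")),
         n_hrr_segments = nrow(attr(prof, "hrr")))
  }

  if ("qtl" %in% cfg$stages && !is.null(cfg$qtl_table)) {
    t0 <- proc.time()[3]
    qtl <- load_qtl_table(cfg$qtl_table, cfg$qtl_dialect)
    ve <- obj$variant_effects
    sig <- data.frame(chrom = ve$cw$chrom, pos = ve$cw$pos,
                      sig_a_cw = ve$cw$sig_a, sig_d_cw = ve$cw$sig_d,
                      sig_a_wtw = ve$wtw$sig_a, sig_d_wtw = ve$wtw$sig_d)
    oc <- overlap_counts(sig, qtl)
    utils::write.csv(cbind(category = rownames(oc$counts), oc$counts),
                     file.path(cfg$outdir, "qtl_counts.csv"),
                     row.names = FALSE)
    obj$qtl <- oc
    note("qtl", n_intervals = nrow(qtl))
  }

  files <- list.files(cfg$outdir, full.names = TRUE)
  manifest$files <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  manifest$elapsed_s <- round(proc.time()[3] - t_all, 2)
  yaml::write_yaml(manifest[c("seed", "stages", "elapsed_s")],
                   file.path(cfg$outdir, "manifest.yaml"))
  if (keep_objects) list(manifest = manifest, objects = obj)
  else list(manifest = manifest)
}
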