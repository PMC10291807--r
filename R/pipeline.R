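#' Pipeline configuration
#'
#' Declarative configuration for an end-to-end run on a synthetic scenario:
#' simulate, train, xWAS screen, conditional signal decomposition,
#' colocalization, region merging and conditional prioritization.
#'
#' @param scenario a [scenario_spec()] (or a list of its fields).
#' @param out_dir output directory.
#' @param alpha family-wise error level for the xWAS screen.
#' @param p_entry COJO entry threshold (default 5e-8).
#' @param collinearity COJO r-squared cutoff (default 0.1).
#' @param flank colocalization window flank in bp (default 250 kb).
#' @param pad region-merging pad in bp (default 500 kb).
#' @param pp4 H4 reporting threshold (default 0.8).
#' @param rho_bound collinearity bound on the cis genetic correlation.
#' @param seed integer seed for every stage.
#' @return Object of class `PipelineConfig`.
#' @export
pipeline_config <- function(scenario = scenario_spec("single_shared"),
                            out_dir = tempfile("coloxwas_run_"),
                            alpha = 0.05, p_entry = 5e-8,
                            collinearity = 0.1, flank = 2.5e5, pad = 5e5,
                            pp4 = 0.8, rho_bound = 0.9, seed = 1L) {
  if (is.list(scenario) && !inherits(scenario, "ScenarioSpec"))
    scenario <- do.call(scenario_spec, scenario)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  if (p_entry <= 0 || p_entry >= 1)
    stop("p_entry must lie in (0,1)", call. = FALSE)
  if (collinearity <= 0 || collinearity > 1)
    stop("collinearity must lie in (0,1]", call. = FALSE)
  if (pp4 <= 0 || pp4 >= 1) stop("pp4 must lie in (0,1)", call. = FALSE)
  if (flank < 0 || pad < 0) stop("flank/pad must be >= 0", call. = FALSE)
  structure(list(scenario = scenario, out_dir = out_dir, alpha = alpha,
                 p_entry = p_entry, collinearity = collinearity,
                 flank = flank, pad = pad, pp4 = pp4,
                 rho_bound = rho_bound, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$scenario <- do.call(scenario_spec, y$scenario)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$scenario <- unclass(y$scenario)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Stages, in order: simulate the scenario bundle; train elastic-net weight
#' models on the QTL panel; run the xWAS screen; decompose each trait's
#' region into independent signals; conditional colocalization per
#' (feature, trait); merge significant features into genomic regions and
#' assemble trait support; pairwise conditional prioritization within
#' supported regions.  Every stage writes a TSV under `out_dir` and is
#' listed in `manifest.json` with an md5 content hash.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return Invisibly, a list with the in-memory stage outputs and the
#'   manifest (stage, file, md5, n_rows).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  say <- function(...) if (!quiet) message("[coloxwas] ", ...)
  note <- function(stage, file, n) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, file = basename(file),
                 md5 = unname(tools::md5sum(file)), n_rows = n)
  }
  fail <- function(stage, e) {
    part <- do.call(rbind, manifest)
    jsonlite::write_json(part, file.path(cfg$out_dir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    say("stage ", stage)
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  sc <- cfg$scenario
  sc$seed <- cfg$seed

  # 1. simulate
  bundle <- run_stage("simulate", {
    b <- make_scenario(sc)
    write_scenario(b, file.path(cfg$out_dir, "scenario"))
    b
  })
  note("simulate", file.path(cfg$out_dir, "scenario", "truth.json"),
       length(bundle$features))
  say("  scenario ", sc$name, ": ", length(bundle$features), " feature(s), ",
      length(bundle$gwas), " trait(s), seed ", cfg$seed)

  # 2. train
  models <- run_stage("train", {
    tc <- cis_training_config(seed = cfg$seed)
    ms <- lapply(names(bundle$features), function(id) {
      f <- bundle$features[[id]]
      fit_weights(bundle$qtl_panel, f$values,
                  c(1, f$model$start, f$model$stop), tc,
                  feature_id = id, tissue = f$model$tissue,
                  modality = f$model$modality)
    })
    names(ms) <- names(bundle$features)
    ms <- Filter(function(m) !m$untrainable, ms)
    if (length(ms) == 0L) stop("no trainable feature", call. = FALSE)
    write_weight_manifest(ms, file.path(cfg$out_dir, "weights"))
    ms
  })
  note("train", file.path(cfg$out_dir, "weights", "manifest.tsv"),
       length(models))
  say("  trained ", length(models), " model(s)")

  # 3. xwas
  xwas <- run_stage("xwas", {
    x <- run_xwas_screen(models, bundle$gwas, bundle$panel,
                         alpha = cfg$alpha)
    write_results_table(x, file.path(cfg$out_dir, "xwas.tsv"))
    x
  })
  note("xwas", file.path(cfg$out_dir, "xwas.tsv"), nrow(xwas))
  say("  ", sum(xwas$significant), " significant association(s) of ",
      nrow(xwas))

  # 4. cojo (per trait, over the scenario region)
  signals <- run_stage("cojo", {
    rows <- list()
    for (tr in names(bundle$gwas)) {
      st <- marginal_stats(bundle$gwas[[tr]], bundle$panel)
      ss <- cojo_slct(st, bundle$panel, p_entry = cfg$p_entry,
                      collinearity = cfg$collinearity)
      if (length(ss$lead_snps))
        rows[[tr]] <- cbind(trait_id = tr, ss$joint)
    }
    out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(trait_id = character(), snp_id = character(),
                    b_joint = numeric(), se_joint = numeric(),
                    p_joint = numeric())
    write_results_table(out, file.path(cfg$out_dir, "signals.tsv"))
    out
  })
  note("cojo", file.path(cfg$out_dir, "signals.tsv"), nrow(signals))
  say("  ", nrow(signals), " independent trait signal(s)")

  # 5. coloc (per significant feature x trait)
  coloc <- run_stage("coloc", {
    ccfg <- coloc_config(pp4_report = cfg$pp4)
    rows <- list()
    sig <- xwas[xwas$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      id <- sig$feature_id[i]; tr <- sig$trait_id[i]
      m <- models[[id]]
      cr <- conditional_coloc(bundle$qtl_sumstats[[id]],
                              bundle$gwas[[tr]], bundle$panel,
                              c(1, m$start, m$stop), ccfg,
                              flank = cfg$flank, p_entry = cfg$p_entry,
                              collinearity = cfg$collinearity)
      rows[[length(rows) + 1L]] <-
        cbind(feature_id = id, tissue = m$tissue, trait_id = tr, cr)
    }
    out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(feature_id = character(), tissue = character(),
                    trait_id = character(), qtl_signal = character(),
                    trait_signal = character(), pp_h0 = numeric(),
                    pp_h1 = numeric(), pp_h2 = numeric(),
                    pp_h3 = numeric(), pp_h4 = numeric(),
                    n_snps_common = integer(), low_coverage = logical(),
                    colocalized = logical())
    write_results_table(out, file.path(cfg$out_dir, "coloc.tsv"))
    out
  })
  note("coloc", file.path(cfg$out_dir, "coloc.tsv"), nrow(coloc))
  say("  ", sum(coloc$colocalized), " colocalized signal pair(s) of ",
      nrow(coloc))

  # 6. regions
  regions_out <- run_stage("regions", {
    sig <- xwas[xwas$significant, , drop = FALSE]
    feats <- unique(data.frame(
      feature_id = sig$feature_id, tissue = sig$tissue, chr = 1,
      start = vapply(sig$feature_id, function(id) models[[id]]$start, 0),
      stop = vapply(sig$feature_id, function(id) models[[id]]$stop, 0)))
    regs <- merge_regions(feats, pad = cfg$pad)
    sup <- assemble_trait_support(regs, xwas, coloc, bundle$gwas,
                                  pp4 = cfg$pp4)
    write_results_table(regs, file.path(cfg$out_dir, "regions.tsv"))
    write_results_table(sup$support, file.path(cfg$out_dir, "support.tsv"))
    write_results_table(sup$venn, file.path(cfg$out_dir, "venn.tsv"))
    list(regions = regs, support = sup$support, venn = sup$venn)
  })
  note("regions", file.path(cfg$out_dir, "regions.tsv"),
       nrow(regions_out$regions))
  say("  ", nrow(regions_out$regions), " genomic region(s), ",
      sum(regions_out$support$supported), " supported region-trait pair(s)")

  # 7. prioritize
  prioritized <- run_stage("prioritize", {
    rows <- list()
    sup <- regions_out$support
    for (k in which(sup$supported)) {
      rid <- sup$region_id[k]; tr <- sup$trait_id[k]
      mem <- .region_members(
        regions_out$regions[regions_out$regions$region_id == rid, ])
      ids <- vapply(strsplit(mem, "@", fixed = TRUE), `[[`, "", 1L)
      cand <- models[intersect(ids, names(models))]
      if (length(cand) < 2L) next
      xr <- xwas[xwas$trait_id == tr, , drop = FALSE]
      pr <- prioritize_region(cand, xr, bundle$panel,
                              collinearity_bound = cfg$rho_bound)
      if (nrow(pr))
        rows[[length(rows) + 1L]] <- cbind(region_id = rid, trait_id = tr,
                                           pr)
    }
    out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(region_id = integer(), trait_id = character(),
                    target = character(), conditioned_on = character(),
                    rho = numeric(), z_marginal = numeric(),
                    z_conditional = numeric(), verdict = character())
    write_results_table(out, file.path(cfg$out_dir, "conditional.tsv"))
    out
  })
  note("prioritize", file.path(cfg$out_dir, "conditional.tsv"),
       nrow(prioritized))

  man <- do.call(rbind, manifest)
  jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  say("done: ", nrow(man), " stage outputs in ", cfg$out_dir)
  invisible(list(bundle = bundle, models = models, xwas = xwas,
                 signals = signals, coloc = coloc,
                 regions = regions_out$regions,
                 support = regions_out$support, venn = regions_out$venn,
                 conditional = prioritized, manifest = man))
}
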