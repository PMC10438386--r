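pipeline_defaults <- function() list(
  filter = list(max_missing = 0.2, min_maf = 0.01, ld_r2 = 0.5,
                ld_window = 5000),
  env = list(cor_threshold = 0.7, pcnm = "auto"),
  structure = list(k_range = 1:15, reps = 10, max_iter = 200, alpha = 10,
                   mask_fraction = 0.05, plateau_tol = 0.01),
  gea = list(k_latent = NULL, reps = 3, z_thresh = 2, q_thresh = 0.01),
  gf = list(n_trees = 500, min_node = 5, cor_threshold = 0.5),
  offset = list(sqrt = TRUE),
  similarity = list(site = NULL),
  seed = 1L
)

#' Validate a pipeline configuration
#'
#' Reads a configuration list (or YAML file), injects defaults for every
#' missing setting (warning once per injected group), warns on unknown
#' keys, and rejects out-of-range thresholds and missing input paths.
#'
#' @param cfg named list or path to a YAML file.
#' @return the validated, fully defaulted configuration (invisible
#'   attribute `warnings` collects the messages).
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg)) cfg <- list()
  defs <- pipeline_defaults()
  known <- c(names(defs), "out_dir", "simulate", "paths", "scenarios")
  unknown <- setdiff(names(cfg), known)
  warnings <- character(0)
  for (k in unknown) {
    w <- sprintf("unknown configuration key '%s' ignored", k)
    warning(w, call. = FALSE)
    warnings <- c(warnings, w)
  }
  for (grp in names(defs)) {
    if (is.null(cfg[[grp]])) {
      cfg[[grp]] <- defs[[grp]]
      injected <- if (is.list(defs[[grp]]))
        paste(sprintf("%s=%s", names(defs[[grp]]),
                      vapply(defs[[grp]], function(v)
                        paste(format(v, trim = TRUE), collapse = ","), "")),
              collapse = ", ")
      else format(defs[[grp]])
      w <- sprintf("using default %s settings (%s)", grp, injected)
      warning(w, call. = FALSE)
      warnings <- c(warnings, w)
    } else if (is.list(defs[[grp]])) {
      for (k in setdiff(names(defs[[grp]]), names(cfg[[grp]]))) {
        if (is.null(defs[[grp]][[k]])) next
        cfg[[grp]][[k]] <- defs[[grp]][[k]]
        w <- sprintf("using default %s$%s = %s", grp, k,
                     paste(format(defs[[grp]][[k]]), collapse = ":"))
        warning(w, call. = FALSE)
        warnings <- c(warnings, w)
      }
    }
  }
  f <- cfg$filter
  if (f$max_missing < 0 || f$max_missing > 1) stopf("filter$max_missing out of [0, 1]")
  if (f$min_maf < 0 || f$min_maf > 1) stopf("filter$min_maf out of [0, 1]")
  if (f$ld_r2 < 0 || f$ld_r2 > 1) stopf("filter$ld_r2 out of [0, 1]")
  if (f$ld_window <= 0) stopf("filter$ld_window must be positive")
  if (cfg$gea$q_thresh < 0 || cfg$gea$q_thresh > 1) stopf("gea$q_thresh out of [0, 1]")
  if (!is.null(cfg$paths)) {
    for (k in names(cfg$paths)) {
      p <- cfg$paths[[k]]
      if (is.character(p) && length(p) == 1 && !file.exists(p))
        stopf("configured path '%s' does not exist: %s", k, p)
    }
  }
  if (is.null(cfg$paths) && is.null(cfg$simulate))
    stopf("configuration needs either input 'paths' or a 'simulate' block")
  attr(cfg, "warnings") <- warnings
  invisible(cfg)
}

#' Bundled synthetic end-to-end demonstration configuration
#'
#' A small simulated species run exercising every pipeline stage in a few
#' minutes: a 40 x 40 landscape with four environmental layers, 10
#' populations of 8 individuals, 240 neutral and 20 adaptive loci driven by
#' the first temperature layer, and one future scenario shifting the
#' temperature layers by +1 s.d.
#'
#' @param out_dir output directory (default a fresh temporary directory).
#' @param seed integer master seed.
#' @return configuration list for [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("landgea_demo_"), seed = 42L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(grid_rows = 40, grid_cols = 40, n_env = 4,
                    autocorr_range = 4, n_pops = 18, n_per_pop = 10,
                    n_neutral = 240, n_adaptive = 25, causal_env = "temp1",
                    effect_size = 3, ancestral_K = 3, target_fst = 0.15,
                    missing_rate = 0.05),
    structure = list(k_range = 1:4, reps = 2, max_iter = 100, alpha = 10,
                     mask_fraction = 0.05, plateau_tol = 0.01),
    gf = list(n_trees = 200, min_node = 5, cor_threshold = 0.5),
    similarity = list(site = c(20, 20))
  )
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Sequences the analysis end to end: input acquisition (simulation or
#' files) -> SNP filtering, imputation and LD pruning -> environmental
#' extraction, correlation pruning and PCNM -> ancestry and K selection ->
#' latent-factor gene-environment association and adaptive classification
#' -> gradient-forest turnover models for the adaptive and neutral SNP
#' sets -> grid projection and Procrustes comparison -> genomic offset and
#' cross-scenario scaling -> optional seed-source similarity.  Every
#' output file is recorded in a JSON manifest with stage, parameters, seed
#' and md5 checksum; deterministic stages reproduce identical checksums on
#' rerun.
#'
#' @param cfg configuration list or YAML path (see [validate_config()],
#'   [demo_config()]).
#' @param quiet suppress progress messages.
#' @return the manifest (list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- suppressWarnings(validate_config(cfg))
  out <- cfg$out_dir %||% tempfile("landgea_run_")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  manifest <- list()
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  add_stage <- function(stage, outputs, params = list(), used_seed = NULL) {
    manifest[[stage]] <<- list(
      stage = stage,
      inputs = if (length(manifest)) names(manifest[[length(manifest)]]$outputs) else character(0),
      params = params, seed = used_seed,
      outputs = lapply(outputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
    names(manifest[[stage]]$outputs) <<- basename(unlist(outputs))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # -- stage 1: inputs (simulation or files) ------------------------------
  say("stage simulate/input ...")
  sim <- cfg$simulate
  stage1 <- run_stage("input", {
    if (!is.null(sim)) {
      spec <- landscape_spec(sim$grid_rows, sim$grid_cols, sim$n_env,
                             autocorr_range = sim$autocorr_range %||% 5,
                             seed = child_seed(seed, 1))
      land <- simulate_landscape(spec)
      samples <- simulate_samples(sim$n_pops, sim$n_per_pop, land$current,
                                  seed = child_seed(seed, 2))
      truth <- make_truth(sim$ancestral_K, sim$target_fst, sim$n_adaptive,
                          sim$causal_env %||% names(land$current$layers)[1],
                          sim$effect_size %||% 2)
      g <- simulate_genotypes(samples, land$current, sim$n_neutral, truth,
                              missing_rate = sim$missing_rate %||% 0,
                              seed = child_seed(seed, 3))
      vcf <- file.path(out, "genotypes.vcf")
      write_vcf(g$genotypes, vcf)
      st <- write_tsv(samples, file.path(out, "samples.tsv"))
      tj <- write_truth_json(truth, file.path(out, "truth.json"))
      rasters <- character(0)
      for (nm in names(land$current$layers))
        rasters <- c(rasters, write_ascii_grid(land$current$layers[[nm]],
                                               file.path(out, sprintf("current_%s.asc", nm))))
      for (sc in names(land$future))
        for (nm in names(land$future[[sc]]$layers))
          rasters <- c(rasters, write_ascii_grid(land$future[[sc]]$layers[[nm]],
                                                 file.path(out, sprintf("%s_%s.asc", sc, nm))))
      list(gm = g$genotypes, truth = g$truth, land = land, samples = samples,
           files = c(vcf, st, tj, rasters))
    } else {
      p <- cfg$paths
      samples <- read.table(p$sample_table, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
      gm <- read_vcf(p$vcf, sample_meta = samples)
      cur_layers <- lapply(p$current_rasters, read_ascii_grid)
      land <- list(current = env_stack(cur_layers),
                   future = lapply(p$future_rasters %||% list(), function(fr)
                     env_stack(lapply(fr, read_ascii_grid))))
      list(gm = gm, truth = NULL, land = land, samples = samples,
           files = character(0))
    }
  })
  add_stage("input", as.list(stage1$files), params = sim, used_seed = seed)

  # -- stage 2: filter ----------------------------------------------------
  say("stage filter ...")
  fcfg <- cfg$filter
  st2 <- run_stage("filter", {
    f1 <- filter_genotypes(stage1$gm, fcfg$max_missing, fcfg$min_maf)
    gm_i <- impute_missing(f1$genotypes, seed = child_seed(seed, 4))
    f2 <- ld_prune(gm_i, fcfg$ld_r2, fcfg$ld_window)
    report <- filter_report(n_input = f1$report$n_input,
                            n_removed_missing = f1$report$n_removed_missing,
                            n_removed_maf = f1$report$n_removed_maf,
                            n_removed_ld = f2$report$n_removed_ld,
                            n_output = f2$report$n_output)
    rp <- write_filter_report(report, file.path(out, "filter_report.json"))
    vf <- write_vcf(f2$genotypes, file.path(out, "filtered.vcf"))
    list(gm = f2$genotypes, files = c(rp, vf))
  })
  add_stage("filter", as.list(st2$files), params = fcfg,
            used_seed = child_seed(seed, 4))
  gm <- st2$gm

  # -- stage 3: env -------------------------------------------------------
  say("stage env ...")
  st3 <- run_stage("env", {
    coords <- data.frame(x = gm$sample_meta$longitude,
                         y = gm$sample_meta$latitude)
    ext <- extract_at_points(stage1$land$current, coords)
    env_tab <- ext[, setdiff(names(ext), "in_mask"), drop = FALSE]
    pr <- prune_correlated(env_tab, cfg$env$cor_threshold)
    sv <- pcnm_vectors(coords, cfg$env$pcnm %||% "auto")
    pred <- cbind(pr$table, as.data.frame(sv$vectors))
    f1 <- write_tsv(cbind(gm$sample_meta["id"], pred),
                    file.path(out, "predictors.tsv"))
    list(env = pr$table, removed = pr$removed, sv = sv, coords = coords,
         predictors = pred, files = f1)
  })
  add_stage("env", as.list(st3$files),
            params = list(cor_threshold = cfg$env$cor_threshold,
                          removed = st3$removed))

  # -- stage 4: structure -------------------------------------------------
  say("stage structure ...")
  scfg <- cfg$structure
  st4 <- run_stage("structure", {
    sel <- select_k(gm, k_range = scfg$k_range, reps = scfg$reps,
                    alpha = scfg$alpha, max_iter = scfg$max_iter,
                    mask_fraction = scfg$mask_fraction,
                    seed = child_seed(seed, 5), plateau_tol = scfg$plateau_tol)
    f1 <- write_tsv(sel$curve, file.path(out, "cross_entropy.tsv"))
    best <- sel$models[[match(sel$K, sel$curve$K)]]
    qd <- as.data.frame(best$Q)
    names(qd) <- paste0("Q", seq_len(ncol(qd)))
    f2 <- write_tsv(cbind(gm$sample_meta["id"], qd), file.path(out, "ancestry_Q.tsv"))
    list(sel = sel, K = sel$K, files = c(f1, f2))
  })
  add_stage("structure", as.list(st4$files), params = scfg,
            used_seed = child_seed(seed, 5))

  # -- stage 5: gea -------------------------------------------------------
  say("stage gea ...")
  gcfg <- cfg$gea
  st5 <- run_stage("gea", {
    k_lat <- gcfg$k_latent %||% st4$K
    res <- gea_scan(gm, st3$env, K_latent = k_lat, reps = gcfg$reps,
                    seed = child_seed(seed, 6), z_thresh = gcfg$z_thresh,
                    q_thresh = gcfg$q_thresh)
    f1 <- write_gea_tsv(res, file.path(out, "gea.tsv"))
    list(res = res, files = f1)
  })
  add_stage("gea", as.list(st5$files),
            params = c(gcfg[c("z_thresh", "q_thresh")],
                       list(k_latent = gcfg$k_latent %||% st4$K)),
            used_seed = child_seed(seed, 6))

  # -- stage 6: gradient forest ------------------------------------------
  say("stage gf ...")
  fcfg2 <- cfg$gf
  st6 <- run_stage("gf", {
    adaptive_idx <- which(st5$res$adaptive_any)
    if (length(adaptive_idx) < 5) {
      # too few classified hits to fit a forest set: take the strongest
      # associations so both models remain defined
      score <- apply(abs(st5$res$z), 1, max)
      adaptive_idx <- order(score, decreasing = TRUE)[seq_len(min(20, n_snps(gm)))]
    }
    neutral_idx <- setdiff(seq_len(n_snps(gm)), adaptive_idx)
    models <- list(
      adaptive = fit_gradient_forest(subset_snps(gm, adaptive_idx),
                                     st3$predictors, n_trees = fcfg2$n_trees,
                                     min_node = fcfg2$min_node,
                                     cor_threshold = fcfg2$cor_threshold,
                                     seed = child_seed(seed, 7),
                                     snp_set_label = "adaptive"),
      neutral = fit_gradient_forest(subset_snps(gm, neutral_idx),
                                    st3$predictors, n_trees = fcfg2$n_trees,
                                    min_node = fcfg2$min_node,
                                    cor_threshold = fcfg2$cor_threshold,
                                    seed = child_seed(seed, 8),
                                    snp_set_label = "neutral"))
    f <- c(write_turnover_json(models$adaptive, file.path(out, "turnover_adaptive.json")),
           write_turnover_json(models$neutral, file.path(out, "turnover_neutral.json")))
    list(models = models, files = f)
  })
  add_stage("gf", as.list(st6$files), params = fcfg2,
            used_seed = child_seed(seed, 7))

  # -- stage 7: projection + procrustes ----------------------------------
  say("stage project ...")
  st7 <- run_stage("project", {
    pl <- pcnm_layers(st3$sv, st3$coords, stage1$land$current)
    cur_stack <- env_stack(c(stage1$land$current$layers, pl),
                           mask = stage1$land$current$mask)
    grids <- lapply(st6$models, project_turnover, stack = cur_stack)
    proc <- procrustes_residuals(grids$adaptive, grids$neutral)
    f1 <- write_ascii_grid(proc$grid, file.path(out, "procrustes_residuals.asc"))
    fut_stacks <- lapply(stage1$land$future, function(fs)
      env_stack(c(fs$layers, pl), mask = fs$mask))
    list(cur_stack = cur_stack, fut_stacks = fut_stacks, grids = grids,
         proc = proc, files = f1)
  })
  add_stage("project", as.list(st7$files))

  # -- stage 8: offset (+ similarity) ------------------------------------
  say("stage offset ...")
  st8 <- run_stage("offset", {
    offs <- lapply(st7$fut_stacks, function(fs) {
      fut_grid <- project_turnover(st6$models$adaptive, fs)
      genomic_offset(st7$grids$adaptive, fut_grid, sqrt = cfg$offset$sqrt)
    })
    offs <- scale_offsets(offs)
    files <- character(0)
    for (sc in names(offs))
      files <- c(files, write_ascii_grid(offs[[sc]]$scaled_grid,
                                         file.path(out, sprintf("offset_%s.asc", sc))))
    sims <- NULL
    if (!is.null(cfg$similarity$site) && length(st7$fut_stacks)) {
      sims <- similarity_map(cfg$similarity$site, st6$models$adaptive,
                             st7$cur_stack, st7$fut_stacks[[1]])
      files <- c(files, write_ascii_grid(sims$grid,
                                         file.path(out, "similarity.asc")))
    }
    list(offsets = offs, similarity = sims, files = files)
  })
  add_stage("offset", as.list(st8$files), params = cfg$offset)

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  say("pipeline complete: %s", manifest_path)
  invisible(structure(manifest,
                      out_dir = out,
                      results = list(gm = gm, gea = st5$res, models = st6$models,
                                     grids = st7$grids, proc = st7$proc,
                                     offsets = st8$offsets,
                                     similarity = st8$similarity,
                                     K = st4$K, truth = stage1$truth)))
}
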