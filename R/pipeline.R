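#' Pipeline configuration
#'
#' Describes a full study run for [runPipeline()]: a simulation design (or a
#' PLINK prefix to load), per-stage toggles and parameter blocks, an output
#' directory and one root seed from which every stage derives a named
#' substream seed. The config round-trips through JSON
#' (`jsonlite::toJSON`/`fromJSON`) apart from the simulation design, which
#' is echoed as a serialisable list.
#'
#' @param out_dir output directory (created if missing)
#' @param seed root seed; stage k uses `(seed + 1009 * k) mod 2^31`
#' @param simulation a [simulationConfig()], or `NULL` with `panel_prefix`
#' @param panel_prefix PLINK text prefix to load instead of simulating
#' @param stages character vector of stages to run, any of `"filter"`,
#'   `"diversity"`, `"distance_tree"`, `"pca"`, `"fst"`, `"ld"`, `"roh"`,
#'   `"selection"`
#' @param params named list of per-stage parameter blocks; recognised
#'   entries: `filter` (min_call_rate, min_maf), `diversity` (maf_subset,
#'   groups), `pca` (prune_r2, k), `fst` (grouping), `ld` (population,
#'   n_per_pop), `roh` ([rohConfig()] arguments), `selection` (contrast,
#'   config arguments incl. `fast`)
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(out_dir, seed = 1, simulation = NULL,
                           panel_prefix = NULL,
                           stages = c("filter", "diversity", "distance_tree",
                                      "pca", "fst", "ld", "roh", "selection"),
                           params = list()) {
  known <- c("filter", "diversity", "distance_tree", "pca", "fst", "ld",
             "roh", "selection")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(simulation) && is.null(panel_prefix))
    stop("either a simulation design or a panel prefix is required")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation, panel_prefix = panel_prefix,
                 stages = stages, params = params),
            class = "PipelineConfig")
}

.stageSeed <- function(seed, k) as.integer((seed + 1009 * k) %% 2147483647)

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on a simulated or
#' loaded panel: QC filter, then (independently) diversity summaries,
#' allele-sharing distances + NJ tree, LD-pruned PCA, Weir-Cockerham F_ST,
#' LD decay with Sved fits, ROH detection and the Bayesian outlier scan.
#' Every stage writes TSV/JSON artifacts into `out_dir`; a failing stage is
#' recorded and its dependents skipped while independent stages continue.
#' A `manifest.json` lists every output file with its md5 checksum and row
#' count, plus the per-stage status, parameters and seeds; `summary.tsv`
#' collects the per-population headline table (sample size, N_SNP at
#' MAF >= 0.2, P_N, A_R, H_E and the LD extent r2_0.3 where computed).
#'
#' @param config a [pipelineConfig()]
#' @return the manifest, invisibly; also written as JSON
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- Sys.time()
  files <- list(); status <- list(); errors <- list()
  pars <- config$params
  note <- function(stage, fs) files[[stage]] <<- c(files[[stage]], fs)
  logmsg <- function(...) message(sprintf("[pipeline] %s", sprintf(...)))

  runStage <- function(stage, deps, fun) {
    if (!stage %in% c(config$stages, "simulate", "load")) {
      status[[stage]] <<- "disabled"; return(invisible())
    }
    failed_dep <- deps[vapply(deps, function(d)
      !identical(status[[d]], "ok"), logical(1))]
    if (length(failed_dep)) {
      status[[stage]] <<- paste0("skipped (", failed_dep[1], " failed)")
      return(invisible())
    }
    t0 <- Sys.time()
    tryCatch({ fun(); status[[stage]] <<- "ok" },
                    error = function(e) {
                      status[[stage]] <<- "failed"
                      errors[[stage]] <<- conditionMessage(e)
                      logmsg("stage %s FAILED: %s", stage,
                             conditionMessage(e))
                    })
    logmsg("stage %-14s %-8s %5.1fs", stage, status[[stage]],
           as.numeric(Sys.time() - t0, units = "secs"))
  }

  panel <- NULL; filtered <- NULL
  out <- function(name) file.path(config$out_dir, name)

  if (!is.null(config$simulation)) {
    runStage("simulate", character(), function() {
      sim <- config$simulation
      sim$seed <- .stageSeed(config$seed, 0L)
      panel <<- simulateGenotypes(sim)
      writePlinkPanel(panel, out("panel"))
      writeLines(jsonlite::toJSON(.configAsList(sim), auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE, null = "null"),
                 out("sim_config.json"))
      note("simulate", c(out("panel.ped"), out("panel.map"),
                         out("panel.pop"), out("sim_config.json")))
    })
  } else {
    runStage("load", character(), function() {
      panel <<- readPlinkPanel(config$panel_prefix)
    })
  }
  src <- if (!is.null(config$simulation)) "simulate" else "load"

  runStage("filter", src, function() {
    fp <- modifyList(list(min_call_rate = 0.9, min_maf = 0.05),
                     pars$filter %||% list())
    filtered <<- filterSnps(panel, filterConfig(fp$min_call_rate,
                                                fp$min_maf))
    rep <- filterReport(filtered)
    note("filter", .writeTsv(rep[!rep$keep, c("snp_id", "reason")],
                             out("dropped_snps.tsv")))
    note("filter", .writeTsv(data.frame(snp_id = rownames(filtered)),
                             out("kept_snps.tsv")))
  })

  runStage("diversity", "filter", function() {
    dp <- pars$diversity %||% list()
    groups <- dp$groups %||% list(all = populationNames(filtered))
    sub <- mafSubset(filtered, groups, min_maf = dp$maf_subset %||% 0.2)
    div <- diversitySummary(sub)
    note("diversity", .writeTsv(div, out("diversity.tsv")))
    metadata(filtered)$diversity <<- div
  })

  runStage("distance_tree", "filter", function() {
    D <- ibsDistanceMatrix(filtered)
    tree <- neighborJoining(D)
    dfile <- out("distance_matrix.tsv")
    write.table(round(D, 6), dfile, sep = "\t", quote = FALSE,
                col.names = NA)
    ape::write.tree(tree, out("nj_tree.nwk"))
    note("distance_tree", c(dfile, out("nj_tree.nwk")))
  })

  runStage("pca", "filter", function() {
    pp <- modifyList(list(prune_r2 = 0.2, k = 10), pars$pca %||% list())
    pruned <- ldPrune(filtered, r2_threshold = pp$prune_r2)
    pca <- panelPca(pruned, k = min(pp$k, ncol(pruned) - 1L))
    scores <- data.frame(sample = rownames(pca$scores),
                         population = populations(pruned),
                         pca$scores, check.names = FALSE)
    note("pca", .writeTsv(scores, out("pca_scores.tsv")))
    note("pca", .writeTsv(data.frame(component = seq_along(pca$eigenvalues),
                                     eigenvalue = pca$eigenvalues),
                          out("pca_eigenvalues.tsv")))
    note("pca", .writeTsv(data.frame(snp_id = rownames(pruned)),
                          out("pruned_snps.tsv")))
  })

  runStage("fst", "filter", function() {
    fpars <- pars$fst %||% list()
    res <- groupMeanFst(filtered, grouping = fpars$grouping)
    note("fst", .writeTsv(res$table, out("fst_per_snp.tsv")))
    pw <- pairwiseFst(filtered, grouping = fpars$grouping)
    pwfile <- out("fst_pairwise.tsv")
    write.table(round(pw, 6), pwfile, sep = "\t", quote = FALSE,
                col.names = NA)
    note("fst", pwfile)
    note("fst", .writeTsv(
      data.frame(statistic = c("mean_per_snp", "sd_per_snp", "multilocus",
                               "n_snps", "n_excluded"),
                 value = c(res$mean, res$sd, res$multilocus, res$n_snps,
                           res$n_excluded)),
      out("fst_summary.tsv")))
  })

  ld_extents <- NULL
  runStage("ld", "filter", function() {
    lp <- pars$ld %||% list()
    pops <- lp$population %||% populationNames(filtered)
    rows <- list()
    for (pp in pops) {
      rec <- pairwiseR2(filtered, population = pp)
      if (nrow(rec) < 2) next
      bins <- binLd(rec)
      fit <- fitSved(rec)
      note("ld", .writeTsv(bins, out(sprintf("ld_bins_%s.tsv", pp))))
      writeLines(jsonlite::toJSON(unclass(fit), auto_unbox = TRUE,
                                  digits = NA), out(sprintf(
                                    "ld_fit_%s.json", pp)))
      note("ld", out(sprintf("ld_fit_%s.json", pp)))
      rows[[pp]] <- data.frame(population = pp,
                               beta_per_kb = fit$beta_per_kb,
                               extent_kb = fit$extent_kb,
                               n_pairs = fit$n_pairs)
    }
    ld_extents <<- do.call(rbind, rows)
    note("ld", .writeTsv(ld_extents, out("ld_extents.tsv")))
  })

  runStage("roh", "filter", function() {
    rp <- do.call(rohConfig, pars$roh %||% list())
    segs <- detectRohAll(filtered, rp)
    summ <- rohSummary(segs, panel = filtered)
    note("roh", .writeTsv(segs, out("roh_segments.tsv")))
    note("roh", .writeTsv(summ$per_sample, out("roh_per_sample.tsv")))
    if (!is.null(summ$per_population))
      note("roh", .writeTsv(summ$per_population,
                            out("roh_per_population.tsv")))
    writeLines(jsonlite::toJSON(unclass(rp), auto_unbox = TRUE, digits = NA),
               out("roh_config.json"))
    note("roh", out("roh_config.json"))
  })

  runStage("selection", "filter", function() {
    sp <- pars$selection %||% list()
    contrast <- sp$contrast
    if (is.null(contrast)) {
      pn <- populationNames(filtered)
      if (length(pn) < 2) stop("selection contrast undefined")
      contrast <- list(group1 = pn[1], group2 = pn[-1])
    }
    cfgargs <- sp[setdiff(names(sp), "contrast")]
    cfgargs$seed <- cfgargs$seed %||% .stageSeed(config$seed, 8L)
    scfg <- do.call(outlierScanConfig, cfgargs)
    counts <- alleleCountTable(filtered, grouping = contrast)
    scan <- runOutlierScan(counts, scfg)
    note("selection", .writeTsv(scan, out("selection_scan.tsv")))
    note("selection", .writeTsv(scan[, c("snp_id", "chromosome",
                                         "position_bp", "log10_bf")],
                                out("selection_track.tsv")))
  })

  # headline per-population summary table
  if (identical(status[["diversity"]], "ok")) {
    div <- metadata(filtered)$diversity
    if (!is.null(ld_extents)) {
      div$r2_0.3_kb <- ld_extents$extent_kb[
        match(div$population, ld_extents$population)]
    }
    files[["summary"]] <- .writeTsv(div, out("summary.tsv"))
    status[["summary"]] <- "ok"
  }

  all_files <- sort(unique(unlist(files)))
  manifest <- list(
    created_by = "arraypopgen runPipeline",
    seed = config$seed,
    stages = status,
    errors = errors,
    params = pars,
    wall_seconds = round(as.numeric(Sys.time() - t_all, units = "secs"), 2),
    files = lapply(all_files, function(f) list(
      path = basename(f),
      md5 = unname(tools::md5sum(f)),
      bytes = file.info(f)$size)))
  manifest$wall_seconds <- NULL   # keep the manifest byte-reproducible
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             out("manifest.json"))
  failed <- any(vapply(status, identical, logical(1), "failed"))
  if (failed) warning("one or more pipeline stages failed; see manifest")
  invisible(manifest)
}

.configAsList <- function(x) {
  x <- unclass(x)
  lapply(x, function(el) if (is.data.frame(el)) as.list(el) else el)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
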