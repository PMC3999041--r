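## End-to-end orchestration: simulate/load -> score -> profile ->
## associate -> compare -> networks -> windows -> report, with a
## deterministic manifest.

#' Pipeline run configuration
#'
#' A single declarative home for every threshold the analysis uses.  The
#' defaults are the reference thresholds: 65/70/75 taxa hit filter,
#' 65/90 functional hit filter, core rule > 0.01 abundance in >= 50% of
#' samples, edge-calling alpha 0.05 (whole cohort) and 0.01 (per class),
#' ReBoot z threshold 1.97, class cut-points -6/-9, 7-sample windows at
#' step 1, and 4 taxon pattern groups (7 for CAZyme families).
#'
#' @param inputDir directory with `metadata.tsv` + counts TSVs to analyse
#'   (as written by [writeCohort()]); `NULL` simulates a cohort instead.
#' @param cohort list of [syntheticConfig()] overrides for simulation.
#' @param coreMinAbundance,corePrevalence core-feature rule.
#' @param alphaWhole,alphaGroup edge-calling levels.
#' @param zThreshold PC/NC |z| cut-off.
#' @param clusterGroupsTaxa,clusterGroupsCazyme pattern-group counts.
#' @param cazyCombineGroups CAZyme pattern groups pooled for the
#'   cumulative-abundance correlation.
#' @param windowSize,windowStep sliding-window parameters.
#' @param nPermutations,nBootstraps ReBoot resampling sizes.
#' @param seed global seed for every stochastic stage.
#' @return a named list (class `"RunConfig"`), YAML-serialisable.
#' @export
runConfig <- function(inputDir = NULL, cohort = list(),
                      coreMinAbundance = 0.01, corePrevalence = 0.5,
                      alphaWhole = 0.05, alphaGroup = 0.01,
                      zThreshold = 1.97, clusterGroupsTaxa = 4L,
                      clusterGroupsCazyme = 7L,
                      cazyCombineGroups = c(3L, 6L, 7L),
                      windowSize = 7L, windowStep = 1L,
                      nPermutations = 1000L, nBootstraps = 1000L,
                      seed = 1L) {
  cfg <- list(inputDir = inputDir, cohort = cohort,
              coreMinAbundance = coreMinAbundance,
              corePrevalence = corePrevalence, alphaWhole = alphaWhole,
              alphaGroup = alphaGroup, zThreshold = zThreshold,
              clusterGroupsTaxa = as.integer(clusterGroupsTaxa),
              clusterGroupsCazyme = as.integer(clusterGroupsCazyme),
              cazyCombineGroups = as.integer(cazyCombineGroups),
              windowSize = as.integer(windowSize),
              windowStep = as.integer(windowStep),
              nPermutations = as.integer(nPermutations),
              nBootstraps = as.integer(nBootstraps),
              seed = as.integer(seed))
  stopifnot(cfg$coreMinAbundance >= 0, cfg$corePrevalence > 0,
            cfg$corePrevalence <= 1, cfg$alphaWhole >= 0,
            cfg$alphaWhole <= 1, cfg$alphaGroup >= 0, cfg$alphaGroup <= 1,
            cfg$zThreshold >= 0, cfg$windowSize >= 1, cfg$windowStep >= 1)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip unchanged through serialisation.
#'
#' @param path YAML file path.
#' @param config a [runConfig()] list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw))
    stop("not a run-configuration YAML file: ", path)
  do.call(runConfig, raw)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## small rolling polynomial hash for the manifest (fingerprint only)
.configHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage <- function(name, log, fn) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fn(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  cat(sprintf("[%s] done in %.1fs\n", name,
              proc.time()[["elapsed"]] - t0), file = log, append = TRUE)
  res
}

#' Run the full pipeline
#'
#' Executes simulate/load -> nutrition scoring -> profiling ->
#' association -> group comparison -> networks (whole cohort and per
#' class) -> sliding windows -> report, writing every stage's outputs
#' under `outDir` along with a manifest recording the seed, the
#' configuration and its hash.  Runs are deterministic: the same config
#' produces byte-identical output trees.
#'
#' @param config a [runConfig()] list.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(config = runConfig(), outDir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outDir, "pipeline.log")
  cat("", file = log)  # fresh log
  params <- rebootParams(config$nPermutations, config$nBootstraps,
                         seed = config$seed,
                         zThreshold = config$zThreshold)

  ## --- simulate or load ---------------------------------------------------
  cohortDir <- file.path(outDir, "cohort")
  inputs <- .stage("simulate", log, function() {
    if (is.null(config$inputDir)) {
      cfg <- do.call(syntheticConfig,
                     c(config$cohort, list(seed = config$seed)))
      cohort <- generateCohort(cfg)
      writeCohort(cohort, cohortDir)
      list(metadata = cohort@metadata, genus = cohort@genusCounts,
           functional = cohort@functionalTables,
           categoryMap = cohort@categoryMap)
    } else {
      md <- readMetadata(file.path(config$inputDir, "metadata.tsv"))
      genus <- readFeatureTable(file.path(config$inputDir,
                                          "genus_counts.tsv"),
                                kind = "taxon-genus")
      fun <- list()
      for (kind in c("cog", "cazyme", "vf")) {
        p <- file.path(config$inputDir, sprintf("%s_counts.tsv", kind))
        if (file.exists(p)) fun[[kind]] <- readFeatureTable(p, kind = kind)
      }
      catPath <- file.path(config$inputDir, "cog_categories.tsv")
      cmap <- if (file.exists(catPath)) {
        cm <- utils::read.delim(catPath, stringsAsFactors = FALSE)
        stats::setNames(cm$category, cm$feature_id)
      } else character()
      list(metadata = md, genus = genus, functional = fun,
           categoryMap = cmap)
    }
  })

  ## --- nutrition scoring --------------------------------------------------
  metadata <- .stage("zscore", log, function() {
    md <- computeZScores(inputs$metadata, toyGrowthReference())
    writeMetadata(md, file.path(outDir, "scored_metadata.tsv"))
    md
  })
  index <- stats::setNames(metadata$cumulative_index, metadata$sample_id)

  ## --- profiling ----------------------------------------------------------
  prof <- .stage("profile", log, function() {
    norm <- normalizeAbundance(inputs$genus, metadata)
    core <- coreFeatures(norm, config$coreMinAbundance,
                         config$corePrevalence)
    writeLines(core, file.path(outDir, "core_genera.txt"))
    if (length(core) < 2L)
      stop("fewer than 2 core genera survive the abundance/prevalence rule")
    coreNorm <- norm[core, ]
    ranked <- rankNormalize(coreNorm)
    writeFeatureTable(norm, file.path(outDir, "genus_normalized.tsv"))
    writeFeatureTable(ranked, file.path(outDir, "genus_ranked.tsv"))
    groups <- clusterAbundancePatterns(ranked,
                                       min(config$clusterGroupsTaxa,
                                           nrow(ranked)))
    utils::write.table(
      data.frame(feature_id = names(groupLabels(groups)),
                 group = paste0("G", groupLabels(groups))),
      file.path(outDir, "taxa_pattern_groups.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    funNorm <- lapply(inputs$functional, normalizeAbundance, metadata)
    for (kind in names(funNorm))
      writeFeatureTable(funNorm[[kind]],
                        file.path(outDir,
                                  sprintf("%s_normalized.tsv", kind)))
    list(norm = norm, coreNorm = coreNorm, ranked = ranked,
         groups = groups, funNorm = funNorm)
  })

  ## --- association --------------------------------------------------------
  assoc <- .stage("associate", log, function() {
    res <- suppressWarnings(
      associateWithIndex(prof$coreNorm, index, params))
    utils::write.table(res, file.path(outDir, "genus_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(genus = res)
    if (!is.null(prof$funNorm$cog)) {
      cogRes <- suppressWarnings(
        associateWithIndex(prof$funNorm$cog, index, params))
      utils::write.table(cogRes, file.path(outDir, "cog_associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pcnc <- classifyPcNc(cogRes, config$zThreshold)
      writeLines(pcnc$pc, file.path(outDir, "cog_pc.txt"))
      writeLines(pcnc$nc, file.path(outDir, "cog_nc.txt"))
      for (set in c("pc", "nc")) {
        comp <- suppressWarnings(
          categoryComposition(pcnc[[set]], inputs$categoryMap))
        utils::write.table(comp,
                           file.path(outDir,
                                     sprintf("cog_%s_categories.tsv", set)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out$cog <- cogRes
      out$pcnc <- pcnc
    }
    if (!is.null(prof$funNorm$cazyme)) {
      caz <- prof$funNorm$cazyme
      k <- min(config$clusterGroupsCazyme, nrow(caz))
      cazGroups <- clusterAbundancePatterns(rankNormalize(caz), k)
      rows <- lapply(sort(unique(groupLabels(cazGroups))), function(gl) {
        cum <- groupCumulativeAbundance(caz, cazGroups, gl)
        ct <- suppressWarnings(stats::cor.test(cum, index[names(cum)],
                                               method = "spearman",
                                               exact = FALSE))
        data.frame(group = gl, n_families = sum(groupLabels(cazGroups) == gl),
                   rho = unname(ct$estimate), p_value = ct$p.value)
      })
      cazTab <- do.call(rbind, rows)
      comb <- intersect(config$cazyCombineGroups,
                        unique(groupLabels(cazGroups)))
      if (length(comb)) {
        cum <- groupCumulativeAbundance(caz, cazGroups, comb)
        ct <- suppressWarnings(stats::cor.test(cum, index[names(cum)],
                                               method = "spearman",
                                               exact = FALSE))
        cazTab <- rbind(cazTab, data.frame(
          group = paste(comb, collapse = "+"),
          n_families = sum(groupLabels(cazGroups) %in% comb),
          rho = unname(ct$estimate), p_value = ct$p.value))
      }
      utils::write.table(cazTab,
                         file.path(outDir, "cazyme_group_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$cazyme <- cazTab
    }
    if (!is.null(prof$funNorm$vf)) {
      vfTotal <- colSums(abundanceValues(prof$funNorm$vf))
      ct <- suppressWarnings(stats::cor.test(vfTotal, index[names(vfTotal)],
                                             method = "spearman",
                                             exact = FALSE))
      vfTab <- data.frame(measure = "vf_total_abundance",
                          rho = unname(ct$estimate), p_value = ct$p.value)
      utils::write.table(vfTab, file.path(outDir, "vf_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$vf <- vfTab
    }
    out
  })

  ## --- group comparison ---------------------------------------------------
  .stage("compare", log, function() {
    sizes <- table(metadata$nutrition_class)
    if (length(sizes) < 3L || any(sizes < 2L)) {
      cat(sprintf("[compare] skipped: class sizes (%s) too small\n",
                  paste(sprintf("%s=%d", names(sizes), sizes),
                        collapse = ", ")),
          file = log, append = TRUE)
      return(NULL)
    }
    cmp <- groupCompare(prof$ranked, metadata)
    utils::write.table(cmp$tests, file.path(outDir, "group_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cmp$tukey, file.path(outDir, "group_tukey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp
  })

  ## --- networks -----------------------------------------------------------
  .stage("network", log, function() {
    contexts <- list(list(name = "whole-cohort", samples = NULL,
                          alpha = config$alphaWhole))
    for (cl in intersect(.NUTRITION_CLASSES, metadata$nutrition_class)) {
      ids <- metadata$sample_id[metadata$nutrition_class == cl]
      if (length(ids) >= 4L)
        contexts <- c(contexts, list(list(name = cl, samples = ids,
                                          alpha = config$alphaGroup)))
      else
        cat(sprintf("[network] skipped class %s: %d sample(s) < 4\n",
                    cl, length(ids)), file = log, append = TRUE)
    }
    propRows <- list()
    for (ctx in contexts) {
      net <- suppressWarnings(
        buildNetwork(prof$coreNorm, subset = ctx$samples,
                     alpha = ctx$alpha, params = params,
                     context = ctx$name))
      writeEdgeList(net, file.path(outDir,
                                   sprintf("network_%s_edges.tsv", ctx$name)))
      exportGraphML(net, file.path(outDir,
                                   sprintf("network_%s.graphml", ctx$name)))
      propRows[[ctx$name]] <- cbind(data.frame(context = ctx$name),
                                    graphProperties(net))
    }
    props <- do.call(rbind, propRows)
    rownames(props) <- NULL
    utils::write.table(props, file.path(outDir, "network_properties.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    props
  })

  ## --- sliding windows ----------------------------------------------------
  .stage("windows", log, function() {
    if (nrow(metadata) < config$windowSize) {
      cat("[windows] skipped: fewer samples than the window size\n",
          file = log, append = TRUE)
      return(NULL)
    }
    series <- windowSeries(prof$coreNorm, metadata,
                           windowSize = config$windowSize,
                           step = config$windowStep,
                           alpha = config$alphaWhole, params = params)
    utils::write.table(series@properties,
                       file.path(outDir, "window_properties.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(series@trends,
                       file.path(outDir, "window_trends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    series
  })

  ## --- manifest + report --------------------------------------------------
  cfgText <- yaml::as.yaml(unclass(config))
  manifest <- list(seed = config$seed, config_hash = .configHash(cfgText),
                   config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("nutrinet")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .stage("report", log, function() summaryReport(outDir))
  invisible(outDir)
}

.reportSection <- function(con, title, path, what) {
  if (!file.exists(path)) return(FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cat("\n## ", title, "\n\n", sep = "", file = con)
  cat(what, "\n\n", sep = "", file = con)
  txt <- utils::capture.output(print(tab, row.names = FALSE))
  cat(paste0("    ", txt, collapse = "\n"), "\n", sep = "", file = con)
  TRUE
}

#' Summarise a completed pipeline run
#'
#' Regenerates `report.md` in the run directory from the stage outputs:
#' the gradient-association tables, the group-comparison table, the PC/NC
#' functional-category composition, the CAZyme group correlations, the
#' virulence-factor correlation and the sliding-window trend table.  The
#' report is a pure function of the stage outputs (no timestamps), so
#' regenerating it leaves it unchanged.
#'
#' @param runDir a directory produced by [runPipeline()].
#' @return path of `report.md`, invisibly.
#' @export
summaryReport <- function(runDir) {
  if (!file.exists(file.path(runDir, "scored_metadata.tsv")))
    stop("not a pipeline run directory (missing scored_metadata.tsv): ",
         runDir)
  path <- file.path(runDir, "report.md")
  con <- file(path, open = "wt")
  on.exit(close(con))
  cat("# Pipeline summary\n", file = con)
  sections <- list(
    list("Genus associations with the nutritional index",
         "genus_associations.tsv",
         "Spearman rho, ReBoot z/p and arctanh power per core genus."),
    list("COG associations with the nutritional index",
         "cog_associations.tsv", "Per-COG gradient associations."),
    list("PC category composition", "cog_pc_categories.tsv",
         "Functional categories of positively correlated COGs (%)."),
    list("NC category composition", "cog_nc_categories.tsv",
         "Functional categories of negatively correlated COGs (%)."),
    list("CAZyme group correlations", "cazyme_group_correlations.tsv",
         "Cumulative pattern-group abundances vs the index."),
    list("Virulence-factor correlation", "vf_correlation.tsv",
         "Total VF abundance vs the index."),
    list("Group comparison (AH/BL/SM)", "group_comparison.tsv",
         "ANOVA and Kruskal-Wallis with BH q-values and eta-squared."),
    list("Network properties", "network_properties.tsv",
         "Graph properties per context."),
    list("Sliding-window trends", "window_trends.tsv",
         "Spearman trend of each graph property vs mean window index."))
  missing <- character()
  for (s in sections)
    if (!.reportSection(con, s[[1]], file.path(runDir, s[[2]]), s[[3]]))
      missing <- c(missing, s[[2]])
  if (length(missing))
    cat("\n## Missing stage outputs\n\n",
        paste("-", missing, collapse = "\n"), "\n", sep = "", file = con)
  invisible(path)
}
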