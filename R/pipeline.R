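#' @include io.R
NULL

.knownConfigKeys <- c("out_dir", "seed", "human", "genes", "mouse",
                      "similarity", "nodal_stats", "pls", "covnet", "stages")

.configHash <- function(config) {
  config$out_dir <- NULL  # hash the parameters, not the output location
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.requireSeed <- function(block, name) {
  if (is.null(block$seed))
    stop("config block '", name, "' lacks an explicit seed; ",
         "every random stage must be seeded", call. = FALSE)
  invisible(block$seed)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes, as configured: cohort simulation, KLS connectome construction,
#' nodal-strength group statistics, PLS imaging-transcriptomics, and the
#' rodent covariance-network analysis, writing every artifact under
#' \code{config$out_dir} together with a JSON manifest carrying the config
#' hash. Reruns with an identical config reproduce identical outputs. All
#' randomness flows from the explicit per-stage seeds; a missing seed is a
#' validation error raised before any computation, and unknown config keys
#' are rejected.
#'
#' @param config nested list (or path to a JSON/YAML file) with blocks
#'   \code{human}, \code{genes}, \code{mouse} (synthetic specs, each with a
#'   seed), \code{similarity} (n_grid, bandwidth_method, epsilon),
#'   \code{nodal_stats} (fdr_alpha), \code{pls} (n_perm, n_boot, z_threshold,
#'   seed), \code{covnet} (n_perm, alphas, seed), plus \code{out_dir} and
#'   optionally \code{stages} (subset of simulate, klsnet, nodal-stats, pls,
#'   covnet).
#' @return invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), .knownConfigKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config lacks 'out_dir'")
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "klsnet", "nodal-stats", "pls", "covnet")

  # fail-fast seed validation before any computation
  for (blk in intersect(c("human", "genes", "mouse", "pls", "covnet"),
                        names(config)))
    .requireSeed(config[[blk]], blk)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  manifest <- list(config_hash = hash,
                   package_version = as.character(utils::packageVersion("SynDensityNet")),
                   stages = stages, artifacts = character(0L))
  addArtifact <- function(p) manifest$artifacts <<- c(manifest$artifacts, basename(p))
  outPath <- function(f) file.path(config$out_dir, f)
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$error <<- paste0("stage '", name, "': ", conditionMessage(e))
      writeJSONSummary(manifest, outPath("manifest.json"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- genes <- mouse <- NULL
  if ("simulate" %in% stages) runStage("simulate", {
    h <- config$human
    spec <- humanCohortSpec(
      nCases = h$n_cases, nControls = h$n_controls,
      nRoi = if (is.null(h$n_roi)) 246L else h$n_roi,
      voxelsPerRoi = if (is.null(h$voxels_per_roi)) 200L else h$voxels_per_roi,
      effectRois = if (is.null(h$effect_rois)) integer() else h$effect_rois,
      effectShift = if (is.null(h$effect_shift)) 0 else h$effect_shift,
      noiseSd = if (is.null(h$noise_sd)) 0.1 else h$noise_sd,
      seed = h$seed)
    cohort <- generateHumanCohort(spec)
    writeROISamplesTSV(cohort$subjects, outPath("roi_samples.tsv"))
    addArtifact("roi_samples.tsv")
    utils::write.table(cohort$design, outPath("design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    addArtifact("design.tsv")
    if (!is.null(config$mouse)) {
      m <- config$mouse
      mspec <- mouseCohortSpec(
        nPerGroup = if (is.null(m$n_per_group)) 12L else m$n_per_group,
        nRegions = if (is.null(m$n_regions)) 22L else m$n_regions,
        blockStructure = if (is.null(m$blocks)) list() else m$blocks,
        seed = m$seed)
      mouse <- generateMouseCohort(mspec,
        blockStructureB = m$blocks_group_b)
      writeMatrixTSV(mouse$groupA, outPath("mouse_groupA.tsv"))
      writeMatrixTSV(mouse$groupB, outPath("mouse_groupB.tsv"))
      addArtifact("mouse_groupA.tsv"); addArtifact("mouse_groupB.tsv")
    }
  })

  strengths <- NULL
  if ("klsnet" %in% stages) runStage("klsnet", {
    if (is.null(cohort))
      cohort <- list(subjects = readROISamplesTSV(outPath("roi_samples.tsv")),
                     design = readDesignTSV(outPath("design.tsv")))
    sim <- config$similarity
    mats <- lapply(cohort$subjects, buildSimilarityMatrix,
      nGrid = if (is.null(sim$n_grid)) 512L else sim$n_grid,
      bandwidthMethod = if (is.null(sim$bandwidth_method)) "silverman" else sim$bandwidth_method,
      epsilon = if (is.null(sim$epsilon)) 1e-12 else sim$epsilon)
    writeMatrixTSV(similarityValues(mats[[1L]]), outPath("kls_subject1.tsv"))
    addArtifact("kls_subject1.tsv")
    strengths <- do.call(rbind, lapply(mats, nodalStrength))
    rownames(strengths) <- vapply(cohort$subjects,
                                  function(s) s@subjectId, character(1L))
  })

  dmap <- NULL
  if ("nodal-stats" %in% stages && !is.null(strengths)) runStage("nodal-stats", {
    ns <- config$nodal_stats
    alpha <- if (is.null(ns$fdr_alpha)) 0.05 else ns$fdr_alpha
    design <- cohort$design[match(rownames(strengths),
                                  cohort$design$subject_id), ]
    dmap <- compareGroups(strengths, design, fdrAlpha = alpha)
    writeDifferenceMapTSV(dmap, outPath("difference_map.tsv"))
    addArtifact("difference_map.tsv")
  })

  if ("pls" %in% stages && !is.null(dmap)) runStage("pls", {
    pc <- config$pls
    g <- config$genes
    gspec <- geneMatrixSpec(
      nRegions = length(dmap@labels),
      nGenes = if (is.null(g$n_genes)) 2000L else g$n_genes,
      nPlantedPos = if (is.null(g$n_planted_pos)) 0L else g$n_planted_pos,
      nPlantedNeg = if (is.null(g$n_planted_neg)) 0L else g$n_planted_neg,
      plantedR = if (is.null(g$planted_r)) 0.8 else g$planted_r,
      seed = g$seed)
    gm <- generateGeneMatrix(gspec, tValues(dmap))
    fit <- permutationTestComponent(gm$expression, dmap@tValue,
      nPerm = if (is.null(pc$n_perm)) 5000L else pc$n_perm, seed = pc$seed)
    boot <- bootstrapGeneZ(gm$expression, dmap@tValue,
      nBoot = if (is.null(pc$n_boot)) 1000L else pc$n_boot, seed = pc$seed)
    sets <- selectGeneSets(geneZ(boot),
      zThreshold = if (is.null(pc$z_threshold)) 3 else pc$z_threshold)
    perGene <- data.frame(gene = boot@genes, weight = boot@weights,
                          z = boot@geneZ)
    utils::write.table(perGene, outPath("pls_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    addArtifact("pls_genes.tsv")
    writeLines(sets$plsPlus, outPath("pls_plus_genes.txt"))
    writeLines(sets$plsMinus, outPath("pls_minus_genes.txt"))
    addArtifact("pls_plus_genes.txt"); addArtifact("pls_minus_genes.txt")
    writeJSONSummary(list(component_r = fit@componentR,
                          component_p = fit@componentP,
                          n_perm = fit@nPerm, n_boot = boot@nBoot,
                          n_pls_plus = length(sets$plsPlus),
                          n_pls_minus = length(sets$plsMinus),
                          config_hash = hash),
                     outPath("pls_summary.json"))
    addArtifact("pls_summary.json")
  })

  if ("covnet" %in% stages && !is.null(config$mouse)) runStage("covnet", {
    if (is.null(mouse))
      mouse <- list(groupA = readMatrixTSV(outPath("mouse_groupA.tsv")),
                    groupB = readMatrixTSV(outPath("mouse_groupB.tsv")))
    cv <- config$covnet
    nPerm <- if (is.null(cv$n_perm)) 10000L else cv$n_perm
    alphas <- if (is.null(cv$alphas)) c(0.05, 0.01) else unlist(cv$alphas)
    for (gname in c("groupA", "groupB")) {
      net <- buildCovarianceNetwork(mouse[[gname]], group = gname,
                                    nPerm = nPerm, alphas = alphas,
                                    seed = cv$seed)
      writeMatrixTSV(net@rMatrix, outPath(paste0("covnet_r_", gname, ".tsv")))
      writeMatrixTSV(net@edgeP, outPath(paste0("covnet_p_", gname, ".tsv")))
      addArtifact(paste0("covnet_r_", gname, ".tsv"))
      addArtifact(paste0("covnet_p_", gname, ".tsv"))
    }
  })

  manifest$config <- config
  writeJSONSummary(manifest, outPath("manifest.json"))
  invisible(manifest)
}
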