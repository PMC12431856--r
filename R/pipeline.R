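#' Default pipeline configuration
#'
#' All analysis defaults in one place: 61-pixel box, 200 um^3 volume
#' cutoff, bottom-1/3 low-expression exclusion, k = 6, LOESS span 0.3.
#' Synthetic-stage sizes are kept small enough for a desk run while
#' exercising every stage.
#'
#' @param masterSeed integer master seed; one seed per stochastic stage is
#'   derived from it by stage-name hashing, so adding a stage never
#'   perturbs another stage's draws.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(masterSeed = 1L) {
  list(
    masterSeed = as.integer(masterSeed),
    boxSize = 61L,
    volumeCutoffUm3 = 200,
    lowExpressionFraction = 1 / 3,
    k = 6L,
    loessSpan = 0.3,
    channels = list(reporter = "reporter", target = "partner",
                    dapi = "dapi"),
    simulate = list(nStacks = 3L, nPunctaPerNucleus = 8L,
                    colocFraction = 1, nFrapCells = 6L,
                    selexReadsPerRound = 2000L),
    segment = list(minVolumeVox = 2000L, smoothingSigma = c(1, 2, 2),
                   thresholdQuantile = 0.995, minSpotVox = 5L)
  )
}

write_profile <- function(profile, dir, name) {
  mat_path <- file.path(dir, paste0(name, ".csv"))
  utils::write.table(profile@matrix, mat_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(mode = profile@mode, channel = profile@channel,
               n_loci = profile@nLoci, n_skipped = profile@nSkipped,
               enrichment = enrichmentSummary(profile))
  meta$enrichment$ratio <- unname(meta$enrichment$ratio)
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(mat_path)
}

punctasets_to_csv <- function(sets, dir, prefix) {
  pl <- lapply(sets, function(ps) {
    p <- ps@puncta
    if (!nrow(p)) return(NULL)
    cbind(cell_id = ps@cellId, condition = ps@condition, p)
  })
  pdf <- do.call(rbind, Filter(Negate(is.null), pl))
  if (is.null(pdf)) pdf <- data.frame()
  utils::write.csv(pdf, file.path(dir, paste0(prefix, "_puncta.csv")),
                   row.names = FALSE)
  cells <- do.call(rbind, lapply(sets, function(ps) data.frame(
    cell_id = ps@cellId, condition = ps@condition,
    nucleus_volume = ps@nucleusVolume, n_puncta = nrow(ps@puncta))))
  utils::write.csv(cells, file.path(dir, paste0(prefix, "_cells.csv")),
                   row.names = FALSE)
}

#' Run the condensate analysis pipeline end to end
#'
#' Stages: \code{simulate} (synthetic stacks, FRAP traces and SELEX
#' pools with ground truth), \code{segment} (nuclei, puncta, geometry),
#' \code{quantify} (density + QC filters), \code{coloc}
#' (condensate-centered and random-null box profiles), \code{fish}
#' (target-locus-centered reporter profiles), \code{frap} (double
#' normalization, ensemble, fit), \code{csi} (demultiplex through
#' enrichment ranking), or \code{all}. Outputs are written under
#' \code{outputDir} with a \code{manifest.json} recording the config,
#' derived per-stage seeds, package version and md5 checksum of every
#' artifact. No stage mutates its inputs; a rerun with the same master
#' seed reproduces identical checksums for all deterministic artifacts.
#'
#' @param outputDir output directory (created; default a new directory
#'   under \code{tempdir()}).
#' @param stages character vector of stage names, or \code{"all"}.
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or a YAML file path.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(outputDir = tempfile("condensate_run"),
                        stages = "all",
                        config = defaultPipelineConfig()) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- utils::modifyList(defaultPipelineConfig(), yaml::read_yaml(config))
  all_stages <- c("simulate", "segment", "quantify", "coloc", "fish",
                  "frap", "csi")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stats::setNames(
    lapply(all_stages, function(s) derive_seed(config$masterSeed, s)),
    all_stages)
  state <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) {
    sim_dir <- file.path(outputDir, "simulate")
    dir.create(sim_dir, showWarnings = FALSE)
    stacks <- list()
    for (i in seq_len(config$simulate$nStacks)) {
      prm <- syntheticImageParams(
        nPunctaPerNucleus = config$simulate$nPunctaPerNucleus,
        colocFraction = config$simulate$colocFraction,
        seed = derive_seed(seeds$simulate, paste0("stack", i)))
      sim <- simulateStack(prm)
      path <- file.path(sim_dir, sprintf("stack%02d.tiff", i))
      writeStack(sim$stack, path)
      jsonlite::write_json(
        list(centers = sim$truth$centers,
             partnerCenters = sim$truth$partnerCenters),
        paste0(path, ".truth.json"), digits = NA)
      stacks[[i]] <- list(sim = sim, path = path)
    }
    state$stacks <- stacks
    frap_sims <- lapply(seq_len(config$simulate$nFrapCells), function(i)
      simulateFrap(syntheticFrapParams(
        noiseSd = 5, photobleachRate = 0.01,
        seed = derive_seed(seeds$simulate, paste0("frap", i))),
        cellId = sprintf("frap%02d", i)))
    frap_df <- do.call(rbind, lapply(frap_sims, function(fs) data.frame(
      cell_id = fs$trace@cellId, frame = seq_along(fs$trace@time),
      time = fs$trace@time, roi = fs$trace@roiMean,
      nucleus = fs$trace@nucleusMean, background = fs$trace@backgroundMean)))
    utils::write.csv(frap_df, file.path(sim_dir, "frap_traces.csv"),
                     row.names = FALSE)
    state$frap_sims <- frap_sims
    selex_params <- syntheticSelexParams(
      nReadsPerRound = config$simulate$selexReadsPerRound,
      seed = derive_seed(seeds$simulate, "selex"))
    state$selex <- simulateSelex(selex_params, file.path(sim_dir, "selex"))
    state$selex_params <- selex_params
  }

  if (any(c("segment", "quantify", "coloc", "fish") %in% stages)) {
    if (is.null(state$stacks)) stop("segment stage needs the simulate stage")
    seg_dir <- file.path(outputDir, "segment")
    dir.create(seg_dir, showWarnings = FALSE)
    per_stack <- lapply(seq_along(state$stacks), function(i) {
      st <- state$stacks[[i]]$sim$stack
      dapi <- getChannel(st, config$channels$dapi)
      reporter <- getChannel(st, config$channels$reporter)
      nuc <- segmentNuclei(dapi, config$segment$minVolumeVox,
                           config$segment$smoothingSigma, voxelSize(st))
      pm <- segmentPuncta(rescale16bit(reporter), nuc,
                          config$segment$thresholdQuantile,
                          config$segment$minSpotVox)
      sets <- extractPuncta(pm, nuc, reporter, stack = st,
                            condition = "synthetic")
      for (s in seq_along(sets))
        sets[[s]]@cellId <- sprintf("stack%02d_%s", i, sets[[s]]@cellId)
      writeMask(nuc, file.path(seg_dir, sprintf("nuclei%02d.tiff", i)))
      writeMask(pm, file.path(seg_dir, sprintf("puncta%02d.tiff", i)))
      list(stack = st, nuc = nuc, pm = pm, sets = sets)
    })
    state$per_stack <- per_stack
    all_sets <- unlist(lapply(per_stack, `[[`, "sets"), recursive = FALSE)
    punctasets_to_csv(all_sets, seg_dir, "detected")
    state$all_sets <- all_sets
  }

  if ("quantify" %in% stages) {
    q_dir <- file.path(outputDir, "quantify")
    dir.create(q_dir, showWarnings = FALSE)
    rec <- computeCellMetrics(state$all_sets)
    qc <- applyQCFilters(rec, config$volumeCutoffUm3,
                         config$lowExpressionFraction)
    utils::write.csv(rec, file.path(q_dir, "cell_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(qc$kept, file.path(q_dir, "cells_kept.csv"),
                     row.names = FALSE)
    utils::write.csv(qc$flagged, file.path(q_dir, "cells_flagged.csv"),
                     row.names = FALSE)
    utils::write.csv(summarizeConditions(qc$kept),
                     file.path(q_dir, "condition_summary.csv"),
                     row.names = FALSE)
  }

  if ("coloc" %in% stages) {
    c_dir <- file.path(outputDir, "coloc")
    dir.create(c_dir, showWarnings = FALSE)
    mats <- list(); nulls <- list()
    for (i in seq_along(state$per_stack)) {
      ps <- state$per_stack[[i]]
      target <- getChannel(ps$stack, config$channels$target)
      mats[[i]] <- profilePuncta(ps$sets, target, config$boxSize,
                                 channelLabel = config$channels$target)
      nulls[[i]] <- profileRandomNull(target, ps$nuc, ps$sets,
                                      config$boxSize, seeds$coloc,
                                      channelLabel = config$channels$target)
    }
    pool <- function(profiles, mode) {
      ms <- unlist(lapply(profiles, function(p)
        rep(list(p@matrix), p@nLoci)), recursive = FALSE)
      averageProfiles(ms, mode = mode, channel = config$channels$target,
                      nSkipped = sum(vapply(profiles, function(p)
                        p@nSkipped, integer(1))))
    }
    write_profile(pool(mats, "condensate-centered"), c_dir,
                  "condensate_profile")
    write_profile(pool(nulls, "random-null"), c_dir, "null_profile")
  }

  if ("fish" %in% stages) {
    f_dir <- file.path(outputDir, "fish")
    dir.create(f_dir, showWarnings = FALSE)
    ps <- state$per_stack[[1L]]
    target <- getChannel(ps$stack, config$channels$target)
    reporter <- getChannel(ps$stack, config$channels$reporter)
    fish_pm <- segmentPuncta(rescale16bit(target), ps$nuc,
                             config$segment$thresholdQuantile,
                             config$segment$minSpotVox)
    fish_sets <- extractPuncta(fish_pm, ps$nuc, target,
                               condition = "fish")
    fp <- fishLocusProfiles(fish_sets, reporter, ps$nuc,
                            config$boxSize, seeds$fish)
    write_profile(fp$profile, f_dir, "fish_profile")
    write_profile(fp$null, f_dir, "fish_null_profile")
  }

  if ("frap" %in% stages) {
    if (is.null(state$frap_sims)) stop("frap stage needs the simulate stage")
    fr_dir <- file.path(outputDir, "frap")
    dir.create(fr_dir, showWarnings = FALSE)
    normalized <- lapply(state$frap_sims, function(fs)
      normalizeFrap(fs$trace))
    ens <- aggregateFrap(normalized, config$loessSpan)
    norm_df <- do.call(rbind, lapply(normalized, function(tr) data.frame(
      cell_id = tr@cellId, time = tr@time, value = tr@value)))
    utils::write.csv(norm_df, file.path(fr_dir, "normalized_traces.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(time = ens@time, mean = ens@meanCurve, sd = ens@sdCurve,
                 smooth = ens@smoothCurve),
      file.path(fr_dir, "ensemble.csv"), row.names = FALSE)
    fit <- fitRecovery(ens)
    jsonlite::write_json(fit, file.path(fr_dir, "recovery_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("csi" %in% stages) {
    if (is.null(state$selex)) stop("csi stage needs the simulate stage")
    cs_dir <- file.path(outputDir, "csi")
    dir.create(cs_dir, showWarnings = FALSE)
    design <- designFromParams(state$selex_params)
    files <- state$selex$files
    report <- list()
    tables <- list()
    for (r in design$rounds) {
      dm <- demultiplex(files$path[files$round == r], design)
      for (s in names(design$barcodes)) {
        ex <- extractVariableRegion(dm$reads[[s]], s, design)
        tables[[paste(s, r, sep = "_")]] <-
          countKmers(ex$regions, config$k, sample = s, round = r)
        report[[paste(s, r, sep = "_")]] <-
          c(as.list(dm$counts), as.list(ex$tallies))
      }
    }
    pos_name <- setdiff(names(design$barcodes), "neg")[1L]
    final_r <- design$rounds[length(design$rounds)]
    et <- computeEnrichment(tables[[paste(pos_name, final_r, sep = "_")]],
                            tables[[paste("neg", final_r, sep = "_")]])
    utils::write.table(et@table,
                       file.path(cs_dir, "enrichment_final_round.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    traj <- roundTrajectory(
      lapply(design$rounds, function(r) tables[[paste(pos_name, r, sep = "_")]]),
      lapply(design$rounds, function(r) tables[[paste("neg", r, sep = "_")]]))
    utils::write.table(traj, file.path(cs_dir, "round_trajectory.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(cs_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(topMotif(et), file.path(cs_dir, "top_motif.txt"))
  }

  artifacts <- list.files(outputDir, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "manifest.json"]
  checksums <- as.list(tools::md5sum(artifacts))
  rel <- sub(outputDir, "", names(checksums), fixed = TRUE)
  names(checksums) <- sub("^/", "", rel)
  manifest <- list(
    package_version = as.character(utils::packageVersion("condensateR")),
    config = config, stage_seeds = seeds, stages_run = stages,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
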