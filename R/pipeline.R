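#' Read a run configuration from YAML or JSON
#'
#' A configuration must carry an integer `seed` and a `scenario` from
#' [scenarioNames()]; every other block is optional and overrides the
#' defaults of the corresponding stage (see [runPipeline()]).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$seed))
    stop("config error: 'seed' is mandatory", call. = FALSE)
  if (is.null(cfg$scenario)) cfg$scenario <- "paper_mimic_Q2Q5"
  if (!cfg$scenario %in% scenarioNames())
    stop("config error: unknown scenario '", cfg$scenario, "'",
         call. = FALSE)
  defaults <- list(
    footprint = list(noiseCV = 0.1, positions = c(101L, 600L),
                     fold = 2.5,
                     laneScales = c(V1_control = 1, V1_ligand = 1.2,
                                    T2_control = 0.9, T2_ligand = 1.1)),
    index = list(pseudocount = 0, sdMult = 2, logBase = 10,
                 robustNull = FALSE),
    laneQuant = list(fromTraces = FALSE, minProminence = 0.02,
                     anchorEvery = 10L),
    spliceGel = list(noiseCV = 0.02),
    fluor = list(noiseSD = 0)
  )
  for (blk in names(defaults)) {
    user <- if (is.null(cfg[[blk]])) list() else cfg[[blk]]
    merged <- defaults[[blk]]
    merged[names(user)] <- user
    cfg[[blk]] <- merged
  }
  cfg
}

#' Run the full simulate-quantify-index-summarize pipeline
#'
#' One reproducible end-to-end run: builds the synthetic transcript,
#' simulates the four footprinting lanes under the scenario's planted
#' effects (optionally rendering lane traces and re-quantifying them through
#' band detection and position assignment), computes the cleavage index,
#' fits the empirical null, calls significant positions at the configured SD
#' multiple, summarizes flags per region, quantifies the scenario's splicing
#' gel with guanine correction, classifies the fluorescence domain panel,
#' and writes every table plus a manifest and a human-readable report under
#' `outDir`. Deterministic for a fixed `(config, seed)`.
#'
#' @param config config list (see [readRunConfig()]) or path to one.
#' @param outDir output directory (created; must not exist unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the in-memory results (`transcript`,
#'   `bandTable`, `records`, `null`, `regionSummary`, `splice`,
#'   `binding`, `g4`, `manifest`).
#' @examples
#' \donttest{
#' out <- runPipeline(list(seed = 1, scenario = "paper_mimic_Q2Q5"),
#'                    outDir = file.path(tempdir(), "run1"),
#'                    overwrite = TRUE)
#' out$regionSummary
#' }
#' @export
runPipeline <- function(config, outDir, overwrite = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- validateRunConfig(config)
  if (dir.exists(outDir) && !overwrite)
    stop("output directory exists: ", outDir, call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  stage <- "transcript"
  res <- try({
    plan <- if (is.null(cfg$transcriptPlan)) defaultTranscriptPlan()
            else cfg$transcriptPlan
    tx <- makeTranscript(plan, seed = deriveSeed(seed, 1L))
    writeTranscriptFasta(tx, file.path(outDir, "transcript.fa"))
    writeRegionsBed(tx, file.path(outDir, "regions.bed"))

    stage <- "g4_scan"
    g4 <- scanG4(as.character(transcriptSeq(tx)))
    g4Ann <- overlapAnnotate(g4, tx)
    utils::write.table(g4Ann, file.path(outDir, "g4_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "simulate_footprint"
    fp <- cfg$footprint
    posRange <- seq.int(fp$positions[1L], fp$positions[2L])
    effects <- if (cfg$scenario == "custom") cfg$effects
               else scenarioEffects(cfg$scenario, tx, fold = fp$fold)
    sim <- simulateFootprint(tx, effects = effects,
                             laneScales = unlist(fp$laneScales),
                             noiseCV = fp$noiseCV, positions = posRange,
                             seed = deriveSeed(seed, 2L))
    bt <- sim$bandTable

    stage <- "lane_quant"
    laneQuantStats <- list(used = FALSE)
    if (isTRUE(cfg$laneQuant$fromTraces)) {
      traces <- simulateLaneTraces(bt)
      sets <- lapply(traces, function(tr) {
        ps <- detectBands(tr, minProminence = cfg$laneQuant$minProminence)
        assignPositions(ps, traceAnchors(tr, cfg$laneQuant$anchorEvery))
      })
      bt <- buildBandTable(sets)
      laneQuantStats <- list(
        used = TRUE,
        n_quantified = nrow(bt),
        n_missing = S4Vectors::metadata(bt)$missing$n)
    }
    writeBandTableTsv(bt, file.path(outDir, "band_table.tsv"))

    stage <- "reactivity_index"
    ix <- cfg$index
    records <- computeIndex(bt, pseudocount = ix$pseudocount,
                            logBase = ix$logBase)
    null <- fitNull(records, k = ix$sdMult, robust = ix$robustNull)
    records <- callSignificant(records, null)
    writeReactivityTsv(records, file.path(outDir, "reactivity.tsv"))
    rs <- regionSummary(records, tx)
    utils::write.table(rs, file.path(outDir, "region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "splice_quant"
    splice <- NULL
    if (cfg$scenario != "custom") {
      preset <- spliceGelPreset(cfg$scenario)
      results <- list()
      for (i in seq_along(preset$conditions)) {
        cond <- names(preset$conditions)[i]
        gel <- simulateSpliceGel(preset$conditions[[i]], preset$gCounts,
                                 noiseCV = cfg$spliceGel$noiseCV,
                                 seed = deriveSeed(seed, 10L + i))
        results[[cond]] <- correctAndFraction(
          gel, ligand = if (preset$concentrations[[cond]] > 0)
            "ligand" else "control",
          concentration = preset$concentrations[[cond]])
      }
      splice <- doseResponse(results)
      splice$relative_change_xs <- c(NA_real_, vapply(
        results[-1L], relativeChange, numeric(1),
        resultControl = results[[1L]], site = "XS"))[
          seq_len(nrow(splice))]
      splice$relative_change_xl <- c(NA_real_, vapply(
        results[-1L], relativeChange, numeric(1),
        resultControl = results[[1L]], site = "XL"))[
          seq_len(nrow(splice))]
      utils::write.table(splice, file.path(outDir, "splice.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "fluor_binding"
    binding <- NULL
    if (cfg$scenario != "custom") {
      panel <- fluorPanelPreset(cfg$scenario,
                                noiseSD = cfg$fluor$noiseSD,
                                seed = deriveSeed(seed, 20L))
      binding <- do.call(rbind, lapply(panel$samples, compareToFree,
                                       free = panel$free))
      rownames(binding) <- NULL
      writeBindingTsv(binding, file.path(outDir, "binding.tsv"))
    }

    stage <- "report"
    manifest <- list(
      package = "quadfoot",
      version = as.character(utils::packageVersion("quadfoot")),
      seed = seed, scenario = cfg$scenario,
      parameters = cfg[c("footprint", "index", "laneQuant", "spliceGel",
                         "fluor")],
      stages = list(
        transcript = list(length = length(transcriptSeq(tx)),
                          n_regions = length(regions(tx))),
        g4_scan = list(n_candidates = length(g4)),
        lane_quant = laneQuantStats,
        reactivity_index = list(
          n_positions = nrow(records),
          n_excluded = S4Vectors::metadata(records)$n_excluded,
          n_flagged = sum(records$flag != "none"),
          null_mean = null@mean, null_sd = null@sd)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeReport(file.path(outDir, "report.txt"), cfg, tx, g4Ann, records,
                null, rs, splice, binding)
    list(transcript = tx, g4 = g4Ann, bandTable = bt, truth = sim$truth,
         records = records, null = null, regionSummary = rs,
         splice = splice, binding = binding, manifest = manifest)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message, call. = FALSE)
  invisible(res)
}

writeReport <- function(path, cfg, tx, g4Ann, records, null, rs, splice,
                        binding) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  w("quadfoot run report")
  w("===================")
  w("scenario: ", cfg$scenario, "   seed: ", cfg$seed)
  w("")
  w("transcript: ", tx@id, " (", length(tx@seq), " nt), ",
    length(tx@regions), " regions")
  w("G4 candidates: ",
    length(unique(g4Ann$candidate)), " (",
    paste(unique(g4Ann$regions[g4Ann$regions != ""]), collapse = ", "),
    ")")
  w("")
  w(sprintf("cleavage index: %d positions, null mean %.4f sd %.4f, %d flagged (%.1f%%)",
            nrow(records), null@mean, null@sd,
            sum(records$flag != "none"),
            100 * mean(records$flag != "none")))
  for (i in seq_len(nrow(rs)))
    w(sprintf("  %-14s n=%4d flagged=%3d (+%d/-%d) density=%.3f",
              rs$region[i], rs$n_positions[i], rs$n_flagged[i],
              rs$n_positive[i], rs$n_negative[i],
              ifelse(is.na(rs$density[i]), 0, rs$density[i])))
  if (!is.null(splice)) {
    w("")
    w("splicing (guanine-corrected):")
    for (i in seq_len(nrow(splice)))
      w(sprintf("  %s %g uM: fraction_xs=%.3f spliced=%.3f",
                splice$ligand[i], splice$concentration[i],
                splice$fraction_xs[i], splice$spliced_fraction[i]))
  }
  if (!is.null(binding)) {
    w("")
    w("fluorescence binding panel:")
    for (i in seq_len(nrow(binding)))
      w(sprintf("  %-12s fold=%.2f shift=%+.1f nm -> %s",
                binding$sample_id[i], binding$fold_vs_free[i],
                binding$shift_nm[i], binding$call[i]))
  }
  invisible(path)
}
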