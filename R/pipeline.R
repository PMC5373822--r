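.PIPELINE_STAGES <- c("synth", "simulate", "fit", "chip_summarize",
                      "classify_rnap2", "fish_glm", "mnase_profile")

.scheduleFromConfig <- function(cfg) {
    if (is.null(cfg)) return(stepSchedule(0.1, 1))
    mode <- cfg$mode %||% "step"
    if (mode == "step")
        stepSchedule(cfg$start %||% 0.1, cfg$target %||% 1, cfg$at %||% 0)
    else
        incrementalSchedule(cfg$start %||% 0.1, cfg$increment %||% 2,
                            cfg$intervalMin %||% 5, cfg$nSteps %||% 12L,
                            sub("incremental-", "", mode),
                            cfg$cap %||% Inf)
}

.ratesFromConfig <- function(cfg) {
    if (is.null(cfg)) return(RateParameters())
    do.call(RateParameters, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration
#'
#' Checks the stage list and per-stage sections before anything runs; a
#' schema violation therefore produces zero outputs.
#'
#' @param config a configuration list (see [runPipeline()]).
#' @return The config, invisibly, or an error.
#' @export
validateRunConfig <- function(config) {
    if (is.null(config$stages) || !length(config$stages))
        stop("config error: 'stages' must list at least one stage")
    unknown <- setdiff(config$stages, .PIPELINE_STAGES)
    if (length(unknown))
        stop("config error: unknown stage(s) ",
             paste(unknown, collapse = ", "), "; known stages are ",
             paste(.PIPELINE_STAGES, collapse = ", "))
    if (!is.null(config$seed) &&
        (!is.numeric(config$seed) || config$seed != round(config$seed)))
        stop("config error: seed must be an integer")
    known <- c("stages", "seed", "outdir", "simulate", "fit", "synth",
               "chip_summarize", "classify_rnap2", "fish_glm",
               "mnase_profile")
    bad <- setdiff(names(config), known)
    if (length(bad))
        stop("config error: unknown config section(s) ",
             paste(bad, collapse = ", "))
    invisible(config)
}

#' A ready-to-run demonstration pipeline configuration
#'
#' @param seed integer seed driving every stochastic stage.
#' @param outdir output directory.
#' @return A configuration list accepted by [runPipeline()].
#' @export
demoPipelineConfig <- function(seed = 7L, outdir = tempfile("pipeline")) {
    list(seed = as.integer(seed), outdir = outdir,
         stages = c("synth", "simulate", "chip_summarize",
                    "classify_rnap2", "fish_glm", "mnase_profile"),
         simulate = list(model = "four_state",
                         schedule = list(mode = "incremental-additive"),
                         times = c(0, 5, 15, 30, 60, 120, 360)))
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the requested stages in dependency order
#' (synth -> simulate/fit -> chip_summarize -> classify_rnap2 ->
#' fish_glm -> mnase_profile), writing every output as TSV/BED under
#' `config$outdir`, and returns a run manifest recording the seed, a hash
#' of the configuration, the package version and an md5 checksum of every
#' output file. All randomness flows from the single top-level seed.
#' Replaying the same config reproduces the checksums of all
#' deterministic stages.
#'
#' @param config a configuration list or path to a JSON file. Fields:
#'   `stages` (subset of `r paste(.PIPELINE_STAGES, collapse = ", ")`),
#'   `seed`, `outdir`, and optional per-stage sections (`simulate`:
#'   `model`, `rates`, `init`, `schedule`, `times`; `synth`: arguments of
#'   the generators; `classify_rnap2`: `alpha`, `delta`; `mnase_profile`:
#'   `minLen`, `maxLen`, `flank`).
#' @return The manifest (list), invisibly written to
#'   `manifest.json` in `outdir`.
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    validateRunConfig(config)
    seed <- as.integer(config$seed %||% 1L)
    outdir <- config$outdir %||% tempfile("pipeline")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stages <- intersect(.PIPELINE_STAGES, config$stages)
    manifest <- list(seed = seed,
                     configHash = unname(tools::md5sum(
                         {f <- tempfile(); writeLines(jsonlite::toJSON(
                             config[setdiff(names(config), "outdir")],
                             auto_unbox = TRUE, digits = NA), f); f})),
                     version = as.character(packageVersion(
                         "RepressionKinetics")),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     stages = list())
    outfile <- function(name) file.path(outdir, name)
    record <- function(stage, files, params = NULL) {
        manifest$stages[[stage]] <<- list(
            outputs = lapply(files, function(f) list(
                file = basename(f), md5 = unname(tools::md5sum(f)))),
            params = params)
    }

    synthFiles <- list(chip = outfile("chip_timecourse.tsv"),
                       counts = outfile("rnap2_counts.tsv"),
                       truth = outfile("rnap2_truth.tsv"),
                       fish = outfile("fish_counts.tsv"),
                       mnaseBefore = outfile("mnase_before.bed"),
                       mnaseAfter = outfile("mnase_after.bed"))

    if ("synth" %in% stages) {
        sc <- config$synth %||% list()
        chip <- do.call(simulateChipTimeCourses,
                        c(sc$chip %||% list(), list(seed = seed)))
        writeTimeCourseTable(chip, synthFiles$chip)
        occ <- do.call(simulateGeneOccupancy,
                       c(sc$rnap2 %||% list(), list(seed = seed + 1L)))
        writeRegionCounts(occ$counts, synthFiles$counts)
        write.table(occ$truth, synthFiles$truth, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        fish <- do.call(simulateFishCounts,
                        c(sc$fish %||% list(), list(seed = seed + 2L)))
        writeFishCounts(fish, synthFiles$fish)
        mn <- do.call(simulateMnaseFragments,
                      c(sc$mnase %||% list(), list(seed = seed + 3L)))
        writeBed3(mn$before, synthFiles$mnaseBefore)
        writeBed3(mn$after, synthFiles$mnaseAfter)
        record("synth", synthFiles, params = list(seed = seed))
    }

    if ("simulate" %in% stages) {
        sc <- config$simulate %||% list()
        tr <- simulatePromoter(sc$model %||% "three_state",
                               .ratesFromConfig(sc$rates),
                               .scheduleFromConfig(sc$schedule),
                               if (is.null(sc$init)) promoterState()
                               else .asState(unlist(sc$init)),
                               sc$times %||% c(0, 5, 15, 30, 60, 120))
        f <- outfile("trajectory.tsv")
        writeTrajectoryTable(tr, f)
        record("simulate", list(f), params = sc["model"])
    }

    if ("fit" %in% stages) {
        sc <- config$fit %||% list()
        tcs <- readTimeCourseTable(sc$data %||% synthFiles$chip)
        names(tcs) <- vapply(tcs, function(tc) tc@factorName, character(1))
        spec <- kineticFitSpec(sc$model %||% "three_state",
                               schedule = .scheduleFromConfig(sc$schedule),
                               fitScales = isTRUE(sc$fitScales))
        fit <- fitKineticModel(tcs, spec, seed = seed,
                               nStarts = sc$nStarts %||% 10L)
        f <- outfile("fit.json")
        jsonlite::write_json(list(
            converged = fit@converged, ssr = fitSSR(fit), aic = fitAIC(fit),
            estimates = fitEstimates(fit)), f, auto_unbox = TRUE,
            digits = NA, dataframe = "rows")
        record("fit", list(f))
    }

    if ("chip_summarize" %in% stages) {
        sc <- config$chip_summarize %||% list()
        tcs <- readTimeCourseTable(sc$data %||% synthFiles$chip)
        files <- lapply(names(tcs), function(nm) {
            f <- outfile(sprintf("chip_summary_%s.tsv",
                                 gsub("[ /]+", "_", nm)))
            write.table(summarizeTimeCourse(tcs[[nm]]), f, sep = "\t",
                        quote = FALSE, row.names = FALSE)
            f
        })
        record("chip_summarize", files)
    }

    if ("classify_rnap2" %in% stages) {
        sc <- config$classify_rnap2 %||% list()
        counts <- readRegionCounts(sc$counts %||% synthFiles$counts)
        cls <- classifyOccupancy(counts, alpha = sc$alpha %||% 0.05,
                                 delta = sc$delta %||% 1.0)
        truthPath <- sc$labels %||% synthFiles$truth
        f1 <- outfile("rnap2_classified.tsv")
        write.table(cls, f1, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- list(f1)
        if (file.exists(truthPath)) {
            truth <- read.delim(truthPath)
            merged <- merge(truth[c("gene", "expression_class")],
                            cls[c("gene", "occupancy_class")], by = "gene")
            ct <- occupancyCrosstab(merged)
            f2 <- outfile("rnap2_crosstab.tsv")
            write.table(ct, f2, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            files <- list(f1, f2)
        }
        record("classify_rnap2", files,
               params = list(alpha = sc$alpha %||% 0.05,
                             delta = sc$delta %||% 1.0))
    }

    if ("fish_glm" %in% stages) {
        sc <- config$fish_glm %||% list()
        fish <- readFishCounts(sc$counts %||% synthFiles$fish)
        res <- repositioningTest(fish)
        f <- outfile("fish_glm.json")
        jsonlite::write_json(list(waldP = as.list(res$waldP), lrP = res$lrP,
                                  proportions = as.list(res$proportions),
                                  separation = res$separation), f,
                             auto_unbox = TRUE, digits = NA)
        record("fish_glm", list(f))
    }

    if ("mnase_profile" %in% stages) {
        sc <- config$mnase_profile %||% list()
        minLen <- sc$minLen %||% 110; maxLen <- sc$maxLen %||% 170
        flank <- sc$flank %||% 300
        peaks <- if (!is.null(sc$peaks)) readBed3(sc$peaks) else NULL
        files <- lapply(c(before = sc$before %||% synthFiles$mnaseBefore,
                          after = sc$after %||% synthFiles$mnaseAfter),
                        function(bed) bed)
        outs <- list()
        for (cond in names(files)) {
            frags <- filterFragmentsByLength(readBed3(files[[cond]]),
                                             minLen, maxLen)
            track <- normalizedCoverage(frags)
            if (is.null(peaks)) {
                # default peak: the centre of the covered region
                rng <- range(readBed3(files[[cond]]))
                peaks0 <- rng
            } else peaks0 <- peaks
            prof <- profileOverPeaks(track, peaks0, flank = flank)
            f <- outfile(sprintf("mnase_profile_%s.tsv", cond))
            write.table(prof, f, sep = "\t", quote = FALSE,
                        row.names = FALSE)
            outs <- c(outs, f)
        }
        record("mnase_profile", outs,
               params = list(minLen = minLen, maxLen = maxLen,
                             flank = flank))
    }

    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
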