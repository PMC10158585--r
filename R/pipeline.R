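## End-to-end orchestration: simulate -> events -> preprocess -> decompose
## -> cluster -> spectral -> time-frequency -> resampling statistics.

#' Analysis parameters
#'
#' Central parameter list for [runPipeline()] and the stage helpers; the
#' defaults are the study's canonical settings (0.75 g hit threshold, 2 s
#' CCA windows at r2 > 0.85 / 0.40, window rejection 30 / 0.3, 3 SD
#' channel rejection, 250 Hz analysis rate, 3-40 Hz spectral fit with
#' width limits [1, 8] / min height 0.05 / max 2 peaks, [-1.0, 2.5] s
#' epochs with 10% amplitude rejection, 3 to 64 wavelet cycles, 2000
#' resampling iterations at alpha = q = 0.05, 70-epoch subsampling, and
#' [-0.5, 1.0] s coherence epochs).  Unknown names are rejected.
#'
#' @param ... overrides of the defaults, by name.
#' @return named list of parameters.
#' @export
analysisParams <- function(...) {
  p <- list(
    hitThreshold = 0.75, refractory = 0.5, refTol = 0.200,
    hpCutoff = 1.0, lineFreq = 60, targetFs = 250, chanZ = 3,
    ccaWindow = 2.0, ccaR2Noise = 0.85, ccaR2Muscle = 0.40,
    rwSd = 30, rwCrit = 0.3,
    epochWindow = c(-1.0, 2.5), rejectFrac = 0.10,
    freqRange = c(3, 50), nFreqs = 60, cycleRange = c(3, 64), tfDecim = 4,
    psdWin = 250, fitRange = c(3, 40), peakWidthLimits = c(1, 8),
    minPeakHeight = 0.05, maxPeaks = 2, q = 0.05,
    alpha = 0.05, nBoot = 2000, nPerm = 2000,
    subsampleN = 70, cohWindow = c(-0.5, 1.0),
    kRange = 2:15, outlierSd = 3, minBrainComps = 5, minAbsCor = 0.6,
    minClusterFrac = 0.5, maxClusters = Inf,
    clusterFocus = defaultSourceCentroids(), focusRadius = 30,
    doCoherence = TRUE, doMasks = TRUE, doSpectral = TRUE,
    rallyServe = FALSE, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    scStop("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

## Detect hits from the paddle IMU, filter against the reference hit
## markers, and assemble swing cycles with condition labels.
detectStudyEvents <- function(study, params) {
  out <- list()
  for (id in names(study$imu)) {
    tr <- study$imu[[id]]
    hits <- detectHits(resultantAcceleration(tr), tr@fs,
                       params$hitThreshold, params$refractory,
                       condition = tr@condition)
    ev <- study$truth$events[[id]]
    ref <- ev[ev$type == "participant_hit", , drop = FALSE]
    hits <- filterByReference(hits, ref, params$refTol)
    appear <- ev[ev$type == "ball_appear", , drop = FALSE]
    sc <- buildSwingCycles(appear, hits)
    cyc <- sc$cycles
    cyc$condition <- tr@condition
    ## subcondition of the owning ball-appear event
    cyc$subcondition <- vapply(cyc$t_appear, function(t0) {
      i <- which.min(abs(appear$onset - t0))
      appear$subcondition[i]
    }, character(1))
    out[[id]] <- list(cycles = cyc, nDropped = sc$nDropped,
                      nHits = nrow(hits))
  }
  allLat <- do.call(rbind, lapply(out, function(o)
    cbind(o$cycles$t_hit - o$cycles$t_appear,
          o$cycles$t_next - o$cycles$t_appear)))
  template <- c(appear = 0, hit = median(allLat[, 1]),
                next_appear = median(allLat[, 2]))
  list(byId = out, template = template)
}

## Per-participant rank-reduced ICA on the concatenated cleaned scalp
## data of both conditions (bad windows excluded from fitting, weights
## applied to the full timeline of each condition).
decomposeParticipant <- function(p, cleaned, params) {
  ids <- paste(p, c("machine", "human"), sep = "_")
  scalpIdx <- channelsWithRole(cleaned[[ids[1]]]$recording, "scalp")
  segs <- lapply(ids, function(id)
    cleaned[[id]]$recording@data[scalpIdx, !cleaned[[id]]$mask, drop = FALSE])
  fitData <- do.call(cbind, segs)
  maxInterp <- max(vapply(ids, function(id)
    length(cleaned[[id]]$recording@interpolated), integer(1)))
  red <- pcaReduce(fitData, maxInterp)
  csR <- fitIca(red$reduced, nComp = red$k,
                seed = deriveSeed(params$seed, paste0(p, ":ica")),
                participant = p, fs = params$targetFs)
  ## lift the reduced-space decomposition back to channel space and
  ## re-fix signs there (the reduced-space convention does not survive
  ## the basis change, and grand averages need consistent polarity)
  unmixing <- csR@unmixing %*% t(red$basis)
  mixing <- red$basis %*% csR@mixing
  for (i in seq_len(ncol(mixing))) {
    j <- which.max(abs(mixing[, i]))
    if (mixing[j, i] < 0) {
      mixing[, i] <- -mixing[, i]
      unmixing[i, ] <- -unmixing[i, ]
    }
  }
  acts <- lapply(ids, function(id)
    unmixing %*% cleaned[[id]]$recording@data[scalpIdx, , drop = FALSE])
  names(acts) <- c("machine", "human")
  cs <- new("ComponentSet", unmixing = unmixing, mixing = mixing,
            activations = acts$machine, fs = params$targetFs,
            participant = p,
            positions = matrix(NA_real_, red$k, 3),
            labels = rep("unknown", red$k),
            varianceExplained = csR@varianceExplained)
  list(cs = cs, activations = acts)
}

## Participant-level time-frequency analysis of one component.
participantTf <- function(x, fs, cycles, mask, params, template,
                          participant, clusterName) {
  ep <- makeEpochs(x, fs, cycles, params$epochWindow, mask = mask,
                   participant = participant, cluster = clusterName)
  ep <- rejectEpochsByMax(ep, params$rejectFrac)
  grid <- defaultFreqGrid(params$freqRange, params$nFreqs)
  tf <- morletTransform(ep, grid, params$cycleRange, decim = params$tfDecim)
  tfW <- timeWarp(tf, template)
  list(epochs = ep, tf = tf, tfWarped = tfW)
}

#' Run the full analysis pipeline on a (synthetic) study
#'
#' Executes, in order: study generation, hit-event detection and swing
#' cycle construction, continuous cleaning (filtering, line noise,
#' resampling, channel hygiene, referencing/interpolation, dual-layer CCA,
#' window rejection), per-participant rank-reduced ICA with ground-truth
#' component annotation, brain-component selection, k-means source
#' clustering, per-cluster spectral parameterisation and condition
#' comparison, time-warped ERSP / unwarped ITPC and ERP with bootstrap
#' masks and cluster-permutation condition contrasts, and (optionally)
#' pairwise inter-cluster event-related coherence.
#'
#' @param cfg a [SimConfig] (ignored when `study` is supplied).
#' @param params parameter list from [analysisParams()].
#' @param study optionally, a pre-generated study from [generateStudy()].
#' @param verbose print stage progress.
#' @return a list of class `StudyResults`; see the vignette for the
#'   layout.
#' @export
runPipeline <- function(cfg = simConfig(), params = analysisParams(),
                        study = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(study)) {
    say("generating synthetic study ...")
    study <- generateStudy(cfg)
  }
  truth <- study$truth
  cfg <- truth$cfg
  say("detecting hit events ...")
  events <- detectStudyEvents(study, params)
  say("preprocessing %d recordings ...", length(study$recordings))
  cleaned <- lapply(study$recordings, preprocessRecording, params = params)
  participants <- truth$participants
  say("decomposing %d participants ...", length(participants))
  dec <- lapply(participants, decomposeParticipant, cleaned = cleaned,
                params = params)
  names(dec) <- participants
  csList <- lapply(dec, function(d)
    annotateComponentsFromTruth(d$cs, truth, minAbsCor = params$minAbsCor,
                                seed = params$seed))
  brain <- selectBrainComponents(csList, params$minBrainComps)
  posTab <- componentPositionTable(brain)
  say("clustering %d brain components ...", nrow(posTab))
  clusters <- clusterComponents(posTab, kRange = params$kRange,
                                outlierSd = params$outlierSd,
                                seed = params$seed)
  memb <- clusters$membership[clusters$membership$retained, , drop = FALSE]
  ## analyse clusters drawing on more than minClusterFrac of participants
  ## (the canonical rule: more than half), largest first, at most
  ## maxClusters of them
  sizes <- vapply(split(memb$participant, memb$cluster),
                  function(p) length(unique(p)), integer(1))
  keepCl <- as.integer(names(sizes))[sizes > params$minClusterFrac *
                                       length(participants)]
  ## restrict to the anatomical region of interest (default: the four
  ## parieto-occipital centroids), as the downstream analysis focuses there
  if (!is.null(params$clusterFocus) && length(keepCl)) {
    nearFocus <- vapply(keepCl, function(cl) {
      d <- sqrt(rowSums(sweep(params$clusterFocus, 2,
                              clusters$centroids[cl, ])^2))
      min(d) <= params$focusRadius
    }, logical(1))
    if (any(nearFocus)) keepCl <- keepCl[nearFocus]
  }
  keepCl <- keepCl[order(-sizes[as.character(keepCl)])]
  if (is.finite(params$maxClusters))
    keepCl <- head(keepCl, params$maxClusters)
  if (!length(keepCl))
    keepCl <- as.integer(names(sizes))[which.max(sizes)]
  conditions <- c("machine", "human")
  clusterResults <- list()
  tfStore <- list()
  for (cl in sort(keepCl)) {
    rows <- memb[memb$cluster == cl, , drop = FALSE]
    clName <- sprintf("cluster%02d", cl)
    say("analysing %s (%d participants) ...", clName, nrow(rows))
    perPart <- list()
    for (ri in seq_len(nrow(rows))) {
      p <- rows$participant[ri]
      comp <- rows$component[ri]
      res <- list()
      for (cond in conditions) {
        id <- paste(p, cond, sep = "_")
        x <- dec[[p]]$activations[[cond]][comp, ]
        tfres <- participantTf(x, params$targetFs,
                               events$byId[[id]]$cycles,
                               cleaned[[id]]$mask, params,
                               events$template, p, clName)
        spec <- if (params$doSpectral) {
          psd <- welchPsd(x[!cleaned[[id]]$mask], params$targetFs,
                          params$psdWin)
          model <- fitSpectralModel(psd, params$fitRange,
                                    params$peakWidthLimits,
                                    params$minPeakHeight, params$maxPeaks)
          list(psd = psd, model = model, flat = flattenPsd(psd, model))
        } else list()
        res[[cond]] <- c(tfres, spec)
      }
      perPart[[p]] <- res
    }
    base <- lapply(perPart, function(r)
      pooledBaseline(list(r$machine$tfWarped, r$human$tfWarped)))
    erspPart <- list(); itpcPart <- list(); erpPart <- list()
    for (cond in conditions) {
      erspPart[[cond]] <- lapply(names(perPart), function(p)
        ersp(perPart[[p]][[cond]]$tfWarped, base[[p]]))
      itpcPart[[cond]] <- lapply(names(perPart), function(p)
        itpc(perPart[[p]][[cond]]$tf))
      erpPart[[cond]] <- erp(lapply(perPart, function(r) r[[cond]]$epochs))
    }
    grid <- tfFreqs(perPart[[1]]$machine$tf)
    timesW <- tfTimes(perPart[[1]]$machine$tfWarped)
    times <- tfTimes(perPart[[1]]$machine$tf)
    nP <- length(perPart)
    stats <- list()
    if (nP >= 5 && params$doMasks) {
      for (cond in conditions) {
        stats[[paste0("erspMask_", cond)]] <-
          bootstrapMask(erspPart[[cond]], params$nBoot, params$alpha,
                        seed = deriveSeed(params$seed, paste0(clName, cond, "e")))
        stats[[paste0("itpcMask_", cond)]] <-
          bootstrapMask(itpcPart[[cond]], params$nBoot, params$alpha,
                        seed = deriveSeed(params$seed, paste0(clName, cond, "i")))
      }
    }
    if (nP >= 8) {
      stats$erspContrast <- clusterPermutation(
        erspPart$machine, erspPart$human, params$nPerm, params$alpha,
        seed = deriveSeed(params$seed, paste0(clName, "ce")))
      stats$itpcContrast <- clusterPermutation(
        itpcPart$machine, itpcPart$human, params$nPerm, params$alpha,
        seed = deriveSeed(params$seed, paste0(clName, "ci")))
    }
    psdCompare <- if (nP >= 5 && params$doSpectral)
      compareConditionsPerFreq(
        lapply(perPart, function(r) r$machine$flat),
        lapply(perPart, function(r) r$human$flat), q = params$q)
    else NULL
    grand <- list()
    for (cond in conditions) {
      grand[[cond]] <- list(
        ersp = Reduce(`+`, erspPart[[cond]]) / nP,
        itpc = Reduce(`+`, itpcPart[[cond]]) / nP,
        erp = erpPart[[cond]]$grand)
    }
    rallyServe <- if (params$rallyServe)
      rallyServeAnalysis(perPart, base, params) else NULL
    clusterResults[[clName]] <- list(
      cluster = cl, participants = names(perPart),
      freqs = grid, timesWarped = timesW, times = times,
      erpTimes = erpPart$machine$times,
      perParticipant = list(ersp = erspPart, itpc = itpcPart),
      grand = grand, stats = stats, psdCompare = psdCompare,
      rallyServe = rallyServe)
    tfStore[[clName]] <- perPart
  }
  coherence <- NULL
  if (params$doCoherence && length(clusterResults) >= 2)
    coherence <- interClusterCoherence(memb, dec, events, cleaned, params)
  counts <- list(
    epochsPerId = vapply(events$byId, function(o) nrow(o$cycles),
                         integer(1)),
    componentsPerParticipant = vapply(csList, function(cs)
      sum(cs@labels == "brain"), integer(1)),
    participantsPerCluster = table(memb$cluster),
    rejectedChannels = lapply(cleaned, `[[`, "rejectedChannels"),
    maskFraction = vapply(cleaned, `[[`, "fractionRejected", FUN.VALUE = 0))
  structure(list(truth = truth, params = params, events = events,
                 components = csList, clusters = clusters,
                 clusterResults = clusterResults, coherence = coherence,
                 counts = counts),
            class = "StudyResults")
}

## Rally-vs-serve sub-analysis of one cluster: partition each
## participant's trials by subcondition, subsample to the common count so
## cells are comparable, and recompute grand ERSP / ITPC / ERP per
## condition x subcondition cell.
rallyServeAnalysis <- function(perPart, base, params) {
  cells <- expand.grid(condition = c("machine", "human"),
                       subcondition = c("rally", "serve"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    cond <- cells$condition[ci]; sub <- cells$subcondition[ci]
    ersps <- list(); itpcs <- list(); erps <- list()
    for (p in names(perPart)) {
      r <- perPart[[p]][[cond]]
      idx <- which(trialInfo(r$tf)$subcondition == sub)
      if (length(idx) < 2) next
      keep <- if (length(idx) > params$subsampleN)
        sort(withSeed(deriveSeed(params$seed, paste0(p, cond, sub, "rs")),
                      sample(idx, params$subsampleN)))
      else idx
      ersps[[p]] <- ersp(subsetTrials(r$tfWarped, keep), base[[p]])
      itpcs[[p]] <- itpc(subsetTrials(r$tf, keep))
      erps[[p]] <- colMeans(subsetTrials(r$epochs, keep)@data)
    }
    if (!length(ersps)) next
    out[[paste(cond, sub, sep = "_")]] <- list(
      n = length(ersps),
      ersp = Reduce(`+`, ersps) / length(ersps),
      itpc = Reduce(`+`, itpcs) / length(itpcs),
      erp = Reduce(`+`, erps) / length(erps))
  }
  out
}

## Event-related coherence between all cluster pairs, on matched
## [-0.5, 1.0] s epochs, restricted to participants contributing a
## retained component to both clusters.
interClusterCoherence <- function(memb, dec, events, cleaned, params) {
  grid <- defaultFreqGrid(params$freqRange, params$nFreqs)
  clIds <- sort(unique(memb$cluster))
  out <- list()
  for (a in seq_along(clIds)) for (b in seq_along(clIds)) {
    if (b <= a) next
    clA <- clIds[a]; clB <- clIds[b]
    pa <- memb[memb$cluster == clA, ]
    pb <- memb[memb$cluster == clB, ]
    shared <- intersect(pa$participant, pb$participant)
    if (length(shared) < 2) next
    maps <- list(machine = list(), human = list())
    for (p in shared) {
      compA <- pa$component[pa$participant == p]
      compB <- pb$component[pb$participant == p]
      for (cond in c("machine", "human")) {
        id <- paste(p, cond, sep = "_")
        cyc <- events$byId[[id]]$cycles
        mkTf <- function(comp) {
          x <- dec[[p]]$activations[[cond]][comp, ]
          ep <- makeEpochs(x, params$targetFs, cyc, params$cohWindow,
                           mask = cleaned[[id]]$mask, participant = p)
          morletTransform(ep, grid, params$cycleRange,
                          decim = params$tfDecim)
        }
        maps[[cond]][[p]] <- eventRelatedCoherence(mkTf(compA), mkTf(compB))
      }
    }
    key <- sprintf("cluster%02d_x_cluster%02d", clA, clB)
    out[[key]] <- list(
      participants = shared,
      machine = Reduce(`+`, maps$machine) / length(shared),
      human = Reduce(`+`, maps$human) / length(shared),
      perParticipant = maps)
  }
  out
}

#' @export
print.StudyResults <- function(x, ...) {
  cat(sprintf("StudyResults: %d participants, k = %d clusters, %d analysed\n",
              length(x$components), x$clusters$k, length(x$clusterResults)))
  invisible(x)
}

#' Headline condition contrast of a pipeline run
#'
#' Summarises, for the most populated cluster: the peak ITPC around the
#' evoked latency (0-500 ms, 3-13 Hz) per condition, the peak absolute
#' grand ERP deflection 100-350 ms post-ball-appear per condition, and
#' whether the machine-vs-human ITPC and ERSP contrasts contain a
#' significant cluster.
#'
#' @param results a `StudyResults` from [runPipeline()].
#' @return named list of scalars.
#' @export
headlineSummary <- function(results) {
  sizes <- vapply(results$clusterResults, function(cr)
    length(cr$participants), integer(1))
  cr <- results$clusterResults[[which.max(sizes)]]
  fSel <- cr$freqs >= 3 & cr$freqs <= 13
  tSel <- cr$times >= 0 & cr$times <= 0.5
  eSel <- cr$erpTimes >= 0.1 & cr$erpTimes <= 0.35
  itpcPeak <- vapply(c("machine", "human"), function(cond)
    max(cr$grand[[cond]]$itpc[fSel, tSel]), numeric(1))
  erpPeak <- vapply(c("machine", "human"), function(cond)
    max(abs(cr$grand[[cond]]$erp[eSel])), numeric(1))
  sigItpc <- !is.null(cr$stats$itpcContrast) &&
    any(cr$stats$itpcContrast$clusters$p <= cr$stats$itpcContrast$alpha)
  sigErsp <- !is.null(cr$stats$erspContrast) &&
    any(cr$stats$erspContrast$clusters$p <= cr$stats$erspContrast$alpha)
  list(cluster = cr$cluster, nParticipants = length(cr$participants),
       itpcPeakMachine = itpcPeak[["machine"]],
       itpcPeakHuman = itpcPeak[["human"]],
       erpPeakMachine = erpPeak[["machine"]],
       erpPeakHuman = erpPeak[["human"]],
       significantItpcContrast = sigItpc,
       significantErspContrast = sigErsp)
}

#' Write a run report
#'
#' Markdown summary plus CSV exports of the grand maps and masks of every
#' analysed cluster.
#'
#' @param results a `StudyResults`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# Swing-cycle analysis report", "",
             sprintf("Participants: %d", length(results$components)),
             sprintf("Clusters (k by silhouette): %d", results$clusters$k), "",
             "## Epochs per session", "")
  for (id in names(results$counts$epochsPerId))
    lines <- c(lines, sprintf("- %s: %d swing cycles", id,
                              results$counts$epochsPerId[[id]]))
  lines <- c(lines, "", "## Brain components per participant", "")
  for (p in names(results$counts$componentsPerParticipant))
    lines <- c(lines, sprintf("- %s: %d", p,
                              results$counts$componentsPerParticipant[[p]]))
  lines <- c(lines, "", "## Headline contrast", "")
  hs <- headlineSummary(results)
  for (nm in names(hs))
    lines <- c(lines, sprintf("- %s: %s", nm, format(hs[[nm]])))
  writeLines(lines, file.path(dir, "report.md"))
  ## machine-readable run manifest: seed, parameters and counts
  manifest <- list(
    package = "swingcycle",
    version = as.character(utils::packageVersion("swingcycle")),
    seed = results$params$seed,
    parameters = results$params[order(names(results$params))],
    counts = list(
      epochsPerSession = as.list(results$counts$epochsPerId),
      brainComponentsPerParticipant =
        as.list(results$counts$componentsPerParticipant),
      participantsPerCluster =
        as.list(setNames(as.integer(results$counts$participantsPerCluster),
                         names(results$counts$participantsPerCluster)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (clName in names(results$clusterResults)) {
    cr <- results$clusterResults[[clName]]
    for (cond in c("machine", "human")) {
      writeMapCsv(cr$grand[[cond]]$ersp, cr$freqs, cr$timesWarped,
                  file.path(dir, sprintf("%s_%s_ersp.csv", clName, cond)))
      writeMapCsv(cr$grand[[cond]]$itpc, cr$freqs, cr$times,
                  file.path(dir, sprintf("%s_%s_itpc.csv", clName, cond)))
    }
  }
  invisible(dir)
}
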