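#' Run the full characterization pipeline
#'
#' Executes detection -> confidence filter -> NMS -> bounding-box-size
#' filter -> cropping -> pose estimation -> pose confidence gate -> angle
#' measurement -> angular distribution -> Boltzmann inversion -> torque,
#' over either simulated micrographs (with ground truth, enabling
#' evaluation) or a directory of image files. Per-stage box counts are
#' logged and returned, and all randomness derives from `config$seed`.
#'
#' @param config a configuration list (see [defaultRunConfig()] /
#'   [readRunConfig()]); scalar overrides may be supplied directly.
#' @param simConfig optional [SimulationConfig-class] used when simulation
#'   is enabled (its seed is re-derived from `config$seed` per image).
#' @return (invisibly) a results list: `angles`, `distribution`,
#'   `landscape`, `torque`, `counts` (per-image stage counts),
#'   `detections`, `poses`, and — when ground truth is available —
#'   `groundTruth`, `detectionMetrics`, `meanAngleError`, `ks`,
#'   `spatial`. If `config$outDir` is set, predictions, keypoints, the
#'   landscape CSV and a JSON summary are written there.
#' @export
runPipeline <- function(config = defaultRunConfig(), simConfig = NULL) {
  config <- .mergeConfig(defaultRunConfig(), config)
  det <- config$detection; pos <- config$pose; mech <- config$mechanics
  schema <- getSchema(config$schema)
  simulated <- isTRUE(config$simulation$enabled)
  if (simulated && is.null(simConfig))
    simConfig <- simulationConfig(nmPerPx = config$nmPerPx)
  images <- list()
  if (simulated) {
    for (i in seq_len(config$simulation$nImages)) {
      cfg <- simConfig
      cfg@seed <- deriveSeed(config$seed, paste0("image", i))
      gen <- generateMicrograph(cfg)
      images[[sprintf("img_%03d", i)]] <- gen
    }
  } else {
    if (is.null(config$input$imageDir))
      stop("either enable simulation or provide input$imageDir")
    files <- sort(list.files(config$input$imageDir,
                             pattern = config$input$pattern,
                             full.names = TRUE))
    if (!length(files)) stop("no images found in ", config$input$imageDir)
    for (f in files)
      images[[tools::file_path_sans_ext(basename(f))]] <-
        list(micrograph = readMicrograph(f, nmPerPx = config$nmPerPx),
             truth = NULL, poses = list())
  }
  detParams <- if (!is.null(det$params)) do.call(detectionParams, det$params)
    else if (simulated) detectionParams(
      armLengthPx = simConfig@armLengthNm / simConfig@nmPerPx,
      armWidthPx = simConfig@armWidthNm / simConfig@nmPerPx)
    else detectionParams()
  poseParms <- if (!is.null(pos$params)) do.call(poseParams, pos$params)
    else poseParams()

  counts <- list(); detections <- list(); posesOut <- list()
  angles <- numeric(); angleIds <- character()
  gtBoxes <- list(); finalBoxes <- list()
  for (imgName in names(images)) {
    entry <- images[[imgName]]
    m <- entry$micrograph
    raw <- classicalDetect(m, detParams)
    kept <- filterByConfidence(raw, det$confThreshold)
    supp <- nms(kept, det$iouThreshold)
    final <- bbfFilter(supp, det$bbfAspect, det$boxSize)
    counts[[imgName]] <- data.frame(
      image = imgName, detected = nrow(raw), afterConfidence = nrow(kept),
      afterNms = nrow(supp), afterBbf = nrow(final), posed = 0L,
      afterPoseGate = 0L)
    detections[[imgName]] <- final
    finalBoxes[[imgName]] <- final
    crops <- cropParticles(m, final, pos$cropSize)
    poses <- list()
    for (cr in crops) {
      pid <- sprintf("%s_p%02d", imgName, cr$provenance$index)
      p <- classicalPose(cr$image, schema, poseParms, particleId = pid)
      p <- mapPoseToMicrograph(p, cr$provenance)
      poses[[pid]] <- p
    }
    counts[[imgName]]$posed <- length(poses)
    gated <- suppressMessages(
      filterPoseConfidence(poses, pos$confThreshold))
    counts[[imgName]]$afterPoseGate <- length(gated)
    posesOut[[imgName]] <- gated
    for (p in gated) {
      if (poseComplete(p)) {
        angles <- c(angles, unname(poseAngles(p)[1]))
        angleIds <- c(angleIds, p@particleId)
      }
    }
    if (!is.null(entry$truth)) {
      tgt <- entry$truth[entry$truth$class == "target_hinge", , drop = FALSE]
      gtBoxes[[imgName]] <- tgt
    }
  }
  countsDf <- do.call(rbind, counts); rownames(countsDf) <- NULL
  res <- list(angles = setNames(angles, angleIds), counts = countsDf,
              detections = detections, poses = posesOut, config = config)
  if (length(angles) >= 1) {
    dist <- anglesToDistribution(angles, mech$binWidth)
    land <- boltzmannInvert(dist, kT = mech$kT)
    res$distribution <- dist
    res$landscape <- land
    res$torque <- tryCatch(torqueFromEnergy(land), error = function(e) NULL)
  }
  if (simulated) {
    res$groundTruth <- lapply(images, `[[`, "truth")
    ev <- evaluatePipeline(images, finalBoxes, posesOut,
                           iouThreshold = det$iouThreshold,
                           nmPerPx = config$nmPerPx)
    res <- c(res, ev)
    if (length(angles) >= 2) {
      ref <- sampleAngles(simConfig@angleLaw, max(2000, length(angles)),
                          seed = deriveSeed(config$seed, "ks-reference"))
      res$ks <- ksTwoSample(angles, ref)
    }
  }
  if (!is.null(config$outDir)) .writePipelineOutputs(res, images, config)
  invisible(res)
}

# Detection metrics, angle error and spatial errors of a finished run
# against simulator ground truth.
evaluatePipeline <- function(images, finalBoxes, posesOut, iouThreshold,
                             nmPerPx) {
  tp <- 0L; fp <- 0L; fn <- 0L
  predPaired <- list(); gtPaired <- list()
  for (imgName in names(images)) {
    truth <- images[[imgName]]$truth
    if (is.null(truth)) next
    tgt <- truth[truth$class == "target_hinge", , drop = FALSE]
    gtB <- boundingBoxes(cx = tgt$cx, cy = tgt$cy, w = tgt$w, h = tgt$h,
                         confidence = rep(1, nrow(tgt)))
    pred <- finalBoxes[[imgName]]
    mt <- matchDetections(pred, gtB, iouThreshold)
    tp <- tp + mt$tp; fp <- fp + mt$fp; fn <- fn + mt$fn
    poses <- posesOut[[imgName]]
    pids <- vapply(poses, function(p) p@particleId, character(1))
    for (r in seq_len(nrow(mt$matches))) {
      pid <- sprintf("%s_p%02d", imgName, mt$matches$predIndex[r])
      k <- match(pid, pids)
      if (is.na(k) || !poseComplete(poses[[k]])) next
      gtPose <- images[[imgName]]$poses[[tgt$particle_id[mt$matches$gtIndex[r]]]]
      if (is.null(gtPose)) next
      # align ids so the pair survives id-based matching downstream
      gtPose <- keypointPose(pid, gtPose@schema, gtPose@points)
      predPaired[[pid]] <- poses[[k]]
      gtPaired[[pid]] <- gtPose
    }
  }
  out <- list(detectionMetrics = precisionRecallF1(tp, fp, fn))
  if (length(predPaired) >= 2) {
    out$meanAngleError <- meanAngleError(predPaired, gtPaired)
    out$spatial <- spatialErrors(predPaired, gtPaired, nmPerPx)
    out$pairedPoses <- list(pred = predPaired, gt = gtPaired)
  }
  out
}

.writePipelineOutputs <- function(res, images, config) {
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (imgName in names(res$detections))
    writeYoloLabels(res$detections[[imgName]],
                    file.path(outDir, paste0(imgName, "_pred.txt")),
                    imageSize = c(imageWidth(images[[imgName]]$micrograph),
                                  imageHeight(images[[imgName]]$micrograph)))
  allPoses <- unlist(unname(res$poses), recursive = FALSE)
  imgOf <- sub("_p[0-9]+$", "", names(allPoses))
  writeKeypointCsv(allPoses, file.path(outDir, "keypoints.csv"),
                   image = if (length(allPoses)) imgOf else "")
  if (length(res$angles))
    write.csv(data.frame(particle_id = names(res$angles),
                         angle_deg = unname(res$angles)),
              file.path(outDir, "angles.csv"), row.names = FALSE)
  if (!is.null(res$landscape)) {
    land <- res$landscape
    write.csv(data.frame(bin_center_deg = land@binCenters,
                         probability = res$distribution@probabilities,
                         energy_kT = land@energy,
                         torque_kT_per_deg =
                           if (is.null(res$torque))
                             rep(NA_real_, length(land@energy))
                           else res$torque),
              file.path(outDir, "landscape.csv"), row.names = FALSE)
  }
  summary <- list(
    n_images = nrow(res$counts),
    n_angles = length(res$angles),
    bin_width_deg = config$mechanics$binWidth,
    seed = config$seed,
    stage_counts = res$counts
  )
  if (!is.null(res$detectionMetrics))
    summary$detection <- res$detectionMetrics[c("tp", "fp", "fn",
                                                "precision", "recall", "f1")]
  if (!is.null(res$meanAngleError))
    summary$mean_angle_error_deg <- res$meanAngleError
  if (!is.null(res$ks))
    summary$ks <- list(statistic = res$ks$statistic,
                       p_value = res$ks$pValue)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(outDir)
}
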