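# Pipeline drivers: synthesize / analyze / compare. Each stage writes a
# JSON run manifest (config snapshot, input hashes, seed, package version,
# output paths) before its outputs, and every output file carries a
# '#'-prefixed header with the package version, config hash and the
# parameters used. These functions are also the surface wrapped by the
# command-line script in inst/scripts/.

.writeManifest <- function(outDir, stage, config = NULL, inputs = character(),
                           seed = NA, outputs = character()) {
  manifest <- list(
    stage = stage,
    package = "DomainDynamics",
    version = as.character(utils::packageVersion("DomainDynamics")),
    seed = seed,
    config = if (!is.null(config)) .configSnapshot(config) else NULL,
    config_hash = if (!is.null(config)) .configHash(config) else NULL,
    input_hashes = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    outputs = as.list(outputs))
  path <- file.path(outDir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Synthesize a two-state trajectory run
#'
#' Generates a synthetic two-state trajectory, writing the topology PDB,
#' the trajectory (multi-model PDB or DCD), the ground-truth label TSV and
#' a run manifest into \code{outDir}.
#'
#' @param spec A \code{\link{SyntheticSpec}}; its seed slot is overridden
#'   by \code{seed}.
#' @param outDir Output directory (created if missing).
#' @param seed Integer seed controlling all generator randomness.
#' @param format Trajectory format, "pdb" or "dcd".
#' @param initialState Passed to \code{\link{generateTwoStateTrajectory}}.
#' @return Invisibly, a list with the generated \code{trajectory},
#'   \code{truth} and output \code{paths}.
#' @export
runSynthesize <- function(spec, outDir, seed = NULL, format = c("pdb", "dcd"),
                          initialState = "stationary") {
  format <- match.arg(format)
  if (!is.null(seed)) spec@seed <- as.numeric(seed)
  validObject(spec)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  paths <- c(topology = file.path(outDir, "topology.pdb"),
             trajectory = file.path(outDir,
                                    paste0("trajectory.", format)),
             truth = file.path(outDir, "ground_truth.tsv"))
  .writeManifest(outDir, "synthesize", seed = spec@seed, outputs = paths)
  run <- generateTwoStateTrajectory(spec, initialState = initialState)
  writeStructure(topology(run$trajectory), paths["topology"])
  writeTrajectory(run$trajectory, paths["trajectory"], format = format)
  writeGroundTruth(run$truth, paths["truth"])
  invisible(list(trajectory = run$trajectory, truth = run$truth,
                 paths = paths))
}

#' Analyze a trajectory: descriptors, PCA, free energy, states
#'
#' Runs the full single-system pipeline: alignment onto the reference,
#' covariance/PCA with per-frame PC scores and a PC1/PC2 free-energy
#' surface, interdomain-distance and salt-bridge descriptor series,
#' interhelix angles, descriptor distributions and state classification,
#' RMSF/B-factor profile, coordination-shell profile and the mean CA-CA
#' distance matrix. All outputs are TSV (matrices whitespace-delimited)
#' under \code{outDir}.
#'
#' @param config An \code{\link{AnalysisConfig}} (or path to its YAML).
#' @param topology A \code{\link{Structure}} or PDB path (also the
#'   alignment reference).
#' @param trajectory A \code{\link{Trajectory}} or trajectory file path.
#' @param outDir Output directory.
#' @return Invisibly, a list of the computed objects (\code{aligned},
#'   \code{model}, \code{scores}, \code{surface}, \code{distance},
#'   \code{states}, \code{fluctuations}, \code{shell}, \code{meanDist},
#'   \code{correlation}, \code{summary}).
#' @export
runAnalyze <- function(config, topology, trajectory, outDir) {
  if (is.character(config)) config <- loadConfig(config)
  if (is.character(topology)) topology <- readStructure(topology, chain = if (!is.na(config@chain)) config@chain else NULL)
  validateConfig(config, topology)
  inputPaths <- character()
  if (is.character(trajectory)) {
    inputPaths <- trajectory
    trajectory <- readTrajectory(topology, trajectory,
                                 frameInterval = config@frameInterval,
                                 productionLength = config@productionLength)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- config@params
  meta <- .outputMeta(config)
  .writeManifest(outDir, "analyze", config = config, inputs = inputPaths)

  stage <- "alignment"
  result <- tryCatch({
    dnames <- names(config@domains)
    if (length(dnames) < 2) stop("config must define at least two domains")
    ## domain order: first and last domain ranges bracket the linker
    dA <- config@domains[[1]]
    dB <- config@domains[[length(config@domains)]]
    pcaRange <- if (length(config@pcaRange)) config@pcaRange else
      range(atoms(topology)$resno)
    sel <- selectCalpha(topology, pcaRange)
    aligned <- alignTrajectory(trajectory, topology, sel)

    stage <- "pca"
    model <- eigenDecompose(computeCovariance(aligned, sel))
    scores <- projectFrames(aligned, model, pcs = 1:2)
    .writeTSV(data.frame(frame = seq_len(nrow(scores)), scores),
              file.path(outDir, "pc_scores.tsv"),
              meta = c(meta, list(pca_residue_range = pcaRange)))
    kT <- thermalEnergy(config@temperature)
    surface <- freeEnergySurface(scores, bins = p$fes_bins, kT = kT,
                                 pcIndices = 1:2)
    .writeSurface(surface, file.path(outDir, "free_energy_surface.tsv"), meta)

    stage <- "descriptors"
    dser <- interdomainDistance(trajectory, dA, dB)
    .writeTSV(data.frame(frame = seq_along(values(dser)),
                         value = values(dser)),
              file.path(outDir, "interdomain_distance.tsv"),
              meta = c(meta, list(units = "Angstrom")))
    sbTables <- list()
    if (nrow(config@saltBridges)) {
      for (i in seq_len(nrow(config@saltBridges))) {
        sb <- config@saltBridges[i, ]
        ss <- saltBridgeDistance(trajectory, sb$acidic, sb$basic)
        sbTables[[sprintf("%d_%d", sb$acidic, sb$basic)]] <- values(ss)
      }
      .writeTSV(cbind(data.frame(frame = seq_len(nFrames(trajectory))),
                      as.data.frame(sbTables)),
                file.path(outDir, "salt_bridge_distances.tsv"),
                meta = c(meta, list(units = "Angstrom",
                                    formed_threshold = p$salt_bridge_threshold)))
    }
    angles <- list()
    hx <- config@helices
    if (length(hx) >= 2) {
      for (i in seq_len(length(hx) - 1)) {
        nm <- sprintf("%s_%s", names(hx)[i], names(hx)[i + 1])
        angles[[nm]] <- values(interhelixAngleSeries(aligned, hx[[i]],
                                                     hx[[i + 1]], name = nm))
      }
      .writeTSV(cbind(data.frame(frame = seq_len(nFrames(trajectory))),
                      as.data.frame(angles)),
                file.path(outDir, "interhelix_angles.tsv"),
                meta = c(meta, list(units = "degrees")))
    }

    stage <- "states"
    dd <- estimateDistribution(dser, "histogram", p$distance_bin_width)
    .writeTSV(data.frame(grid = densityGrid(dd), density = densityValues(dd)),
              file.path(outDir, "interdomain_distribution.tsv"),
              meta = c(meta, list(bin_width = p$distance_bin_width)))
    st <- classifyStates(dser, dd,
                         minProminence = p$min_prominence_fraction *
                           max(densityValues(dd)))
    .writeTSV(data.frame(frame = seq_along(stateLabels(st)),
                         label = stateLabels(st)),
              file.path(outDir, "state_labels.tsv"), meta = meta)

    stage <- "fluctuations"
    prof <- rmsf(aligned, sel)
    .writeTSV(data.frame(residue = residueNumbers(prof),
                         rmsf = prof@rmsf, bfactor = prof@bfactor),
              file.path(outDir, "fluctuation_profile.tsv"),
              meta = c(meta, list(alignment = "global")))

    stage <- "coordination_shell"
    shell <- coordinationShellRadius(trajectory, sel,
                                     cutoff = p$shell_cutoff)
    .writeTSV(data.frame(residue = shell@resno,
                         n_neighbors = shell@nNeighbors,
                         Rg = shell@radius),
              file.path(outDir, "coordination_shell.tsv"),
              meta = c(meta, list(cutoff = p$shell_cutoff,
                                  average_Rg = shell@average)))

    stage <- "mean_distances"
    mdm <- meanDistanceMatrix(trajectory, sel)
    .writeSquareMatrix(mdm@matrix, mdm@resno,
                       file.path(outDir, "mean_distance_matrix.tsv"), meta)
    corr <- correlationMatrix(model,
                              resno = atoms(topology)$resno[sel])
    .writeSquareMatrix(corr@matrix, corr@resno,
                       file.path(outDir, "correlation_matrix.tsv"), meta)

    peaks <- peakLocations(st)
    summary <- data.frame(
      n_frames = nFrames(trajectory),
      n_peaks = length(peaks),
      peak_extended = if (length(peaks)) max(peaks) else NA_real_,
      peak_compact = if (length(peaks) == 2) min(peaks) else NA_real_,
      boundary = stateBoundary(st),
      fraction_compact = fractionCompact(st),
      average_Rg = shell@average)
    .writeTSV(summary, file.path(outDir, "state_summary.tsv"), meta = meta)
    list(aligned = aligned, model = model, scores = scores,
         surface = surface, distance = dser, distribution = dd, states = st,
         fluctuations = prof, shell = shell, meanDist = mdm,
         correlation = corr, summary = summary)
  }, error = function(e) {
    stop(sprintf("analysis stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

.writeSurface <- function(surface, path, meta) {
  ed <- binEdges(surface)
  ctr <- lapply(ed, function(e) (e[-1] + e[-length(e)]) / 2)
  if (length(ctr) == 2) {
    g <- expand.grid(bin_center_1 = ctr[[1]], bin_center_2 = ctr[[2]])
    g$density <- as.vector(surface@density)
    g$energy <- as.vector(surface@energy)
  } else {
    g <- data.frame(bin_center_1 = ctr[[1]],
                    density = as.vector(surface@density),
                    energy = as.vector(surface@energy))
  }
  .writeTSV(g, path, meta = c(meta, list(kT_kcal_mol = surface@kT)))
}

#' Compare two analyzed runs
#'
#' Reads the mean distance and correlation matrices plus state summaries
#' written by \code{\link{runAnalyze}} for a wild-type-like and a
#' mutant-like run, and writes the residue-pair distance-change map, the
#' anticorrelation-difference map and a combined summary table.
#'
#' @param config An \code{\link{AnalysisConfig}} (or YAML path).
#' @param wtDir,mutDir Directories produced by \code{\link{runAnalyze}}.
#' @param outDir Output directory.
#' @return Invisibly, a list with \code{distanceMap}, \code{anticorrMap}
#'   and \code{summary}.
#' @export
runCompare <- function(config, wtDir, mutDir, outDir) {
  if (is.character(config)) config <- loadConfig(config)
  p <- config@params
  need <- c("mean_distance_matrix.tsv", "correlation_matrix.tsv",
            "state_summary.tsv")
  for (d in c(wtDir, mutDir))
    for (f in need)
      if (!file.exists(file.path(d, f)))
        stop("missing ", f, " in ", d, " (run runAnalyze first)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeManifest(outDir, "compare", config = config,
                 inputs = file.path(rep(c(wtDir, mutDir), each = 3), need))
  rdW <- .readSquareMatrix(file.path(wtDir, "mean_distance_matrix.tsv"))
  rdM <- .readSquareMatrix(file.path(mutDir, "mean_distance_matrix.tsv"))
  if (!identical(rdW$resno, rdM$resno))
    stop(sprintf("selection mismatch between runs: %d vs %d residues",
                 length(rdW$resno), length(rdM$resno)))
  mW <- new("MeanDistanceMatrix", resno = rdW$resno,
            matrix = .symmetrize(rdW$matrix))
  mM <- new("MeanDistanceMatrix", resno = rdM$resno,
            matrix = .symmetrize(rdM$matrix))
  dmap <- distanceChangeMap(mM, mW, windows = p$distance_change_windows,
                            mode = p$distance_change_mode)
  ccW <- .readSquareMatrix(file.path(wtDir, "correlation_matrix.tsv"))
  ccM <- .readSquareMatrix(file.path(mutDir, "correlation_matrix.tsv"))
  cW <- new("CorrelationMatrix", resno = ccW$resno,
            matrix = .symmetrize(ccW$matrix), context = "global",
            undefined = integer())
  cM <- new("CorrelationMatrix", resno = ccM$resno,
            matrix = .symmetrize(ccM$matrix), context = "global",
            undefined = integer())
  amap <- anticorrelationDifferenceMap(cW, cM,
                                       threshold = p$anticorrelation_threshold,
                                       margin = p$anticorrelation_margin)
  meta <- .outputMeta(config,
                      list(windows = p$distance_change_windows,
                           anticorrelation_threshold = p$anticorrelation_threshold,
                           margin = p$anticorrelation_margin))
  writeDifferenceMap(dmap, file.path(outDir, "distance_change_map.tsv"), meta)
  writeDifferenceMap(amap, file.path(outDir, "anticorrelation_difference_map.tsv"),
                     meta)
  sW <- .readTSV(file.path(wtDir, "state_summary.tsv"))
  sM <- .readTSV(file.path(mutDir, "state_summary.tsv"))
  summary <- cbind(system = c("wt", "mut"), rbind(sW, sM))
  .writeTSV(summary, file.path(outDir, "comparison_summary.tsv"), meta)
  invisible(list(distanceMap = dmap, anticorrMap = amap, summary = summary))
}

.symmetrize <- function(M) {
  M <- (M + t(M)) / 2
  M
}

#' Write a difference map as long-format TSV
#'
#' One row per classified pair (i < j): res_i, res_j, delta, class.
#'
#' @param map A \code{\link{DifferenceMap}}.
#' @param path Output path.
#' @param meta Named list of header metadata.
#' @export
writeDifferenceMap <- function(map, path, meta = list()) {
  ut <- which(upper.tri(map@delta), arr.ind = TRUE)
  keep <- !map@classification[ut] %in% c("excluded")
  df <- data.frame(res_i = map@resno[ut[keep, 1]],
                   res_j = map@resno[ut[keep, 2]],
                   delta = map@delta[ut][keep],
                   class = map@classification[ut][keep])
  .writeTSV(df, path, meta = c(list(kind = map@kind), meta))
}
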