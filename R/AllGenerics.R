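# Accessor generics and show methods. Slots are never accessed with @ by
# user code; these accessors are the supported surface.

#' @rdname Structure
#' @param object,x A package object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname Structure
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)
#' @rdname Trajectory
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname Structure
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))
#' @rdname Structure
#' @export
setMethod("coords", "Structure", function(x, ...) x@xyz)
#' @rdname Trajectory
#' @param frame Frame index; omit for the full array.
#' @export
setMethod("coords", "Trajectory", function(x, frame = NULL, ...) {
  if (is.null(frame)) x@coords else x@coords[, , frame, drop = TRUE]
})

#' @rdname Structure
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname Structure
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
#' @rdname Trajectory
#' @export
setMethod("nAtoms", "Trajectory", function(x) nrow(x@topology@atoms))

#' @rdname Trajectory
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname Trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname Trajectory
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname Trajectory
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname Trajectory
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname Trajectory
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' @rdname Trajectory
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))
#' @rdname Trajectory
#' @export
setMethod("isAligned", "Trajectory", function(x) isTRUE(x@aligned))

#' @rdname GroundTruth
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname GroundTruth
#' @export
setMethod("stateLabels", "GroundTruth", function(x) x@labels)
#' @rdname StateAssignment
#' @export
setMethod("stateLabels", "StateAssignment", function(x) x@labels)

#' @rdname GroundTruth
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname GroundTruth
#' @export
setMethod("occupancy", "GroundTruth", function(x) x@occupancy)

#' @rdname GroundTruth
#' @export
setGeneric("basinReference", function(x, which) standardGeneric("basinReference"))
#' @rdname GroundTruth
#' @export
setMethod("basinReference", "GroundTruth", function(x, which) x@basinRefs[[which]])

#' @rdname CovarianceModel
#' @export
setGeneric("covarianceMatrix", function(x) standardGeneric("covarianceMatrix"))
#' @rdname CovarianceModel
#' @export
setMethod("covarianceMatrix", "CovarianceModel", function(x) x@matrix)

#' @rdname CovarianceModel
#' @export
setGeneric("meanConfiguration", function(x) standardGeneric("meanConfiguration"))
#' @rdname CovarianceModel
#' @export
setMethod("meanConfiguration", "CovarianceModel", function(x) x@mean)

#' @rdname CovarianceModel
#' @export
setGeneric("principalComponents", function(x) standardGeneric("principalComponents"))
#' @rdname CovarianceModel
#' @export
setMethod("principalComponents", "CovarianceModel", function(x) x@components)

#' @rdname CovarianceModel
#' @export
setGeneric("variances", function(x) standardGeneric("variances"))
#' @rdname CovarianceModel
#' @export
setMethod("variances", "CovarianceModel", function(x) x@variances)

#' @rdname CovarianceModel
#' @export
setGeneric("selection", function(x) standardGeneric("selection"))
#' @rdname CovarianceModel
#' @export
setMethod("selection", "CovarianceModel", function(x) x@selection)

#' @rdname DescriptorSeries
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname DescriptorSeries
#' @export
setMethod("values", "DescriptorSeries", function(x) x@values)

#' @rdname DescriptorSeries
#' @export
setGeneric("units", function(x) standardGeneric("units"))
#' @rdname DescriptorSeries
#' @export
setMethod("units", "DescriptorSeries", function(x) x@units)

#' @rdname FluctuationProfile
#' @export
setGeneric("rmsfValues", function(x) standardGeneric("rmsfValues"))
#' @rdname FluctuationProfile
#' @export
setMethod("rmsfValues", "FluctuationProfile", function(x)
  stats::setNames(x@rmsf, x@resno))

#' @rdname FluctuationProfile
#' @export
setGeneric("bfactors", function(x) standardGeneric("bfactors"))
#' @rdname FluctuationProfile
#' @export
setMethod("bfactors", "FluctuationProfile", function(x)
  stats::setNames(x@bfactor, x@resno))

#' @rdname HelixAxis
#' @export
setGeneric("axisVector", function(x) standardGeneric("axisVector"))
#' @rdname HelixAxis
#' @export
setMethod("axisVector", "HelixAxis", function(x) x@axis)

#' @rdname CoordinationShellProfile
#' @export
setGeneric("shellRadii", function(x) standardGeneric("shellRadii"))
#' @rdname CoordinationShellProfile
#' @export
setMethod("shellRadii", "CoordinationShellProfile", function(x)
  stats::setNames(x@radius, x@resno))

#' @rdname CoordinationShellProfile
#' @export
setGeneric("averageShellRadius", function(x) standardGeneric("averageShellRadius"))
#' @rdname CoordinationShellProfile
#' @export
setMethod("averageShellRadius", "CoordinationShellProfile", function(x) x@average)

#' @rdname MeanDistanceMatrix
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))
#' @rdname MeanDistanceMatrix
#' @export
setMethod("distanceMatrix", "MeanDistanceMatrix", function(x) x@matrix)

#' @rdname CorrelationMatrix
#' @export
setGeneric("correlationValues", function(x) standardGeneric("correlationValues"))
#' @rdname CorrelationMatrix
#' @export
setMethod("correlationValues", "CorrelationMatrix", function(x) x@matrix)

#' @rdname MeanDistanceMatrix
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))
#' @rdname MeanDistanceMatrix
#' @export
setMethod("residueNumbers", "MeanDistanceMatrix", function(x) x@resno)
#' @rdname CorrelationMatrix
#' @export
setMethod("residueNumbers", "CorrelationMatrix", function(x) x@resno)
#' @rdname DifferenceMap
#' @export
setMethod("residueNumbers", "DifferenceMap", function(x) x@resno)
#' @rdname FluctuationProfile
#' @export
setMethod("residueNumbers", "FluctuationProfile", function(x) x@resno)

#' @rdname DifferenceMap
#' @export
setGeneric("deltaMatrix", function(x) standardGeneric("deltaMatrix"))
#' @rdname DifferenceMap
#' @export
setMethod("deltaMatrix", "DifferenceMap", function(x) x@delta)

#' @rdname DifferenceMap
#' @export
setGeneric("classMatrix", function(x) standardGeneric("classMatrix"))
#' @rdname DifferenceMap
#' @export
setMethod("classMatrix", "DifferenceMap", function(x) x@classification)

#' @rdname DistributionEstimate
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))
#' @rdname DistributionEstimate
#' @export
setMethod("densityGrid", "DistributionEstimate", function(x) x@grid)

#' @rdname DistributionEstimate
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @rdname DistributionEstimate
#' @export
setMethod("densityValues", "DistributionEstimate", function(x) x@density)

#' @rdname StateAssignment
#' @export
setGeneric("fractionCompact", function(x) standardGeneric("fractionCompact"))
#' @rdname StateAssignment
#' @export
setMethod("fractionCompact", "StateAssignment", function(x) x@fractionCompact)

#' @rdname StateAssignment
#' @export
setGeneric("stateBoundary", function(x) standardGeneric("stateBoundary"))
#' @rdname StateAssignment
#' @export
setMethod("stateBoundary", "StateAssignment", function(x) x@boundary)

#' @rdname StateAssignment
#' @export
setGeneric("peakLocations", function(x) standardGeneric("peakLocations"))
#' @rdname StateAssignment
#' @export
setMethod("peakLocations", "StateAssignment", function(x) x@peaks)

#' @rdname FreeEnergySurface
#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))
#' @rdname FreeEnergySurface
#' @export
setMethod("energyValues", "FreeEnergySurface", function(x) x@energy)

#' @rdname FreeEnergySurface
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname FreeEnergySurface
#' @export
setMethod("binEdges", "FreeEnergySurface", function(x) x@edges)

# --- show methods -----------------------------------------------------------

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure: %d atoms, %d residues, chain(s) %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = ",")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms%s%s\n",
              nFrames(object), nAtoms(object),
              if (!is.na(object@frameInterval))
                sprintf(", %g ps/frame", object@frameInterval) else "",
              if (isAligned(object)) " (aligned)" else ""))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat("  domains: ",
      paste(sprintf("%s %d-%d", names(object@domains),
                    vapply(object@domains, `[`, 0, 1),
                    vapply(object@domains, `[`, 0, 2)), collapse = "; "),
      "\n", sep = "")
  cat(sprintf("  helices: %d; salt bridges: %d; T = %g K\n",
              length(object@helices), nrow(object@saltBridges),
              object@temperature))
})

setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf("CovarianceModel: %d atoms (3N = %d)", length(object@selection),
              nrow(object@matrix)))
  if (length(object@variances))
    cat(sprintf(", %d PCs, PC1 variance %.4g A^2",
                length(object@variances), object@variances[1]))
  cat("\n")
})

setMethod("show", "DescriptorSeries", function(object) {
  cat(sprintf("DescriptorSeries '%s': %d frames, %s; mean %.3f\n",
              object@name, length(object@values), object@units,
              mean(object@values)))
})

setMethod("show", "DistributionEstimate", function(object) {
  cat(sprintf("DistributionEstimate (%s, width %.3g): %d grid points, n = %d\n",
              object@estimator, object@width, length(object@grid), object@n))
})

setMethod("show", "StateAssignment", function(object) {
  cat(sprintf("StateAssignment: %d frames, %.1f%% compact, boundary %.2f, peaks [%s]\n",
              length(object@labels), 100 * object@fractionCompact,
              object@boundary, paste(sprintf("%.2f", object@peaks),
                                     collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frames, occupancy %s\n", length(object@labels),
              paste(sprintf("%s %.3f", names(object@occupancy),
                            object@occupancy), collapse = ", ")))
})

setMethod("show", "DifferenceMap", function(object) {
  tab <- table(object@classification[upper.tri(object@classification)])
  cat(sprintf("DifferenceMap (%s): %d residues; %s\n", object@kind,
              length(object@resno),
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

setMethod("show", "FreeEnergySurface", function(object) {
  cat(sprintf("FreeEnergySurface on PC(%s): %s bins, kT = %.4g kcal/mol\n",
              paste(object@pcIndices, collapse = ","),
              paste(dim(object@energy), collapse = " x "), object@kT))
})
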