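# Distribution estimation, peak finding, extended/compact classification
# and population free-energy differences.

#' Estimate the normalized distribution of a descriptor
#'
#' Histogram (default) or Gaussian KDE on a regular grid spanning the data
#' plus three widths on each side. Histogram density is reported at bin
#' centers; the default widths are 0.5 Angstrom for distances and 2
#' degrees for angles (set via \code{width}).
#'
#' @param values A \code{\link{DescriptorSeries}} or numeric vector
#'   (>= 2 finite values).
#' @param estimator "histogram" or "kde".
#' @param width Bin width (histogram) or bandwidth (KDE) in descriptor
#'   units; \code{NULL} picks 0.5 for histograms and the Silverman rule
#'   for KDE.
#' @return A \code{\link{DistributionEstimate}}.
#' @examples
#' d <- estimateDistribution(rnorm(2000), "histogram", width = 0.25)
#' sum(densityValues(d)) * 0.25  # 1
#' @export
estimateDistribution <- function(values, estimator = c("histogram", "kde"),
                                 width = NULL) {
  estimator <- match.arg(estimator)
  v <- if (is(values, "DescriptorSeries")) values@values else as.numeric(values)
  if (length(v) < 2) stop("need at least 2 values")
  if (!all(is.finite(v))) stop("non-finite descriptor values")
  if (estimator == "histogram") {
    if (is.null(width)) width <- 0.5
    stopifnot(width > 0)
    lo <- min(v) - 3 * width
    hi <- max(v) + 3 * width
    nb <- ceiling((hi - lo) / width)
    edges <- lo + width * (0:nb)
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nb)
    counts <- tabulate(idx, nbins = nb)
    dens <- counts / (length(v) * width)
    grid <- (edges[-1] + edges[-length(edges)]) / 2
  } else {
    bw <- if (is.null(width) || identical(width, "silverman"))
      stats::bw.nrd0(v) else width
    if (bw <= 0) bw <- 1e-3
    de <- stats::density(v, bw = bw, n = 512, cut = 3)
    grid <- de$x
    width <- bw
    dens <- de$y / (sum(de$y) * diff(grid[1:2]))  # renormalize on the grid
  }
  new("DistributionEstimate", grid = grid, density = dens,
      estimator = estimator, width = width, n = length(v))
}

#' Find peaks of a distribution estimate
#'
#' Local maxima of the density (plateaus collapse to their center) with
#' topographic prominence above \code{minProminence}. Peaks are returned
#' sorted by density, highest first.
#'
#' @param dist A \code{\link{DistributionEstimate}}.
#' @param minProminence Minimum prominence in density units; the default
#'   is 5\% of the maximum density.
#' @return List with \code{locations}, \code{heights}, \code{prominences}
#'   (possibly empty, all sorted by height descending).
#' @export
findPeaks <- function(dist, minProminence = NULL) {
  y <- dist@density
  x <- dist@grid
  if (is.null(minProminence)) minProminence <- 0.05 * max(y)
  n <- length(y)
  ## candidate local maxima: plateaus collapse to their center and must
  ## have at least one strictly lower neighbor (a flat density has none)
  cand <- integer()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    hasLower <- (i > 1 && y[i - 1] < y[i]) || (j < n && y[j + 1] < y[i])
    noHigherAdj <- (i == 1 || y[i - 1] < y[i]) && (j == n || y[j + 1] < y[i])
    if (hasLower && noHigherAdj && y[i] > 0)
      cand <- c(cand, as.integer(floor((i + j) / 2)))
    i <- j + 1
  }
  if (!length(cand))
    return(list(locations = numeric(), heights = numeric(),
                prominences = numeric()))
  prom <- vapply(cand, function(p) {
    h <- y[p]
    ## key saddle on each side: minimum along the walk to the nearest
    ## strictly higher point; walking off the edge drops to zero ground
    saddle <- function(idxs) {
      m <- h
      for (k in idxs) {
        if (y[k] > h) return(m)
        m <- min(m, y[k])
      }
      0
    }
    leftMin <- if (p > 1) saddle((p - 1):1) else 0
    rightMin <- if (p < n) saddle((p + 1):n) else 0
    h - max(leftMin, rightMin)
  }, numeric(1))
  keep <- which(prom >= minProminence)
  ord <- keep[order(y[cand[keep]], decreasing = TRUE)]
  list(locations = x[cand[ord]], heights = y[cand[ord]],
       prominences = prom[ord])
}

#' Classify frames into extended and compact states
#'
#' With a bimodal distribution the state boundary is the density minimum
#' between the two peaks; frames with descriptor value below the boundary
#' are "compact" (the compact form has the smaller interdomain distance),
#' ties are assigned "extended". With a unimodal distribution every frame
#' is assigned the single observed state (\code{singleState}, default
#' "extended", the crystal-like form) and the absent state's fraction
#' is 0. More than two peaks is an error suggesting a wider bandwidth.
#'
#' @param values A \code{\link{DescriptorSeries}} or numeric vector.
#' @param dist A \code{\link{DistributionEstimate}} of the same values.
#' @param minProminence Passed to \code{\link{findPeaks}}.
#' @param singleState State assigned to all frames when only one peak is
#'   found.
#' @return A \code{\link{StateAssignment}}.
#' @export
classifyStates <- function(values, dist, minProminence = NULL,
                           singleState = c("extended", "compact")) {
  singleState <- match.arg(singleState)
  v <- if (is(values, "DescriptorSeries")) values@values else as.numeric(values)
  name <- if (is(values, "DescriptorSeries")) values@name else "descriptor"
  pk <- findPeaks(dist, minProminence)
  npk <- length(pk$locations)
  if (npk > 2)
    stop(sprintf("%d peaks above prominence: increase the bin width or bandwidth", npk))
  if (npk == 2) {
    lo <- min(pk$locations); hi <- max(pk$locations)
    between <- which(dist@grid > lo & dist@grid < hi)
    if (!length(between))
      between <- which.min(abs(dist@grid - (lo + hi) / 2))
    bnd <- dist@grid[between[which.min(dist@density[between])]]
    labels <- ifelse(v < bnd, "compact", "extended")
  } else {
    bnd <- NA_real_
    labels <- rep(singleState, length(v))
  }
  new("StateAssignment", labels = labels, boundary = bnd,
      fractionCompact = mean(labels == "compact"), peaks = pk$locations,
      descriptor = name)
}

#' Free-energy difference between state populations
#'
#' Delta A (compact -> extended) = -kT ln(f_extended / f_compact) in
#' kcal/mol; positive when the extended state is the minority. A zero
#' fraction gives an infinite difference (reported as +-Inf).
#'
#' @param assignment A \code{\link{StateAssignment}}.
#' @param kT Thermal energy in kcal/mol.
#' @return Delta A in kcal/mol.
#' @examples
#' # 70% extended / 30% compact at 310 K:
#' # compact sits higher by 0.616 * ln(7/3) kcal/mol
#' @export
populationFreeEnergyDifference <- function(assignment, kT) {
  stopifnot(kT > 0)
  fc <- assignment@fractionCompact
  fe <- 1 - fc
  if (fc == 0) return(-Inf)
  if (fe == 0) return(Inf)
  -kT * log(fe / fc)
}
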