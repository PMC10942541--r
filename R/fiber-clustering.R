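# Grouping ROIs into putative single-afferent fibers from co-occurrence of
# fluorescence events during quiet wakefulness.

#' Event-correlation graph between ROIs
#'
#' Builds per-ROI binary event-indicator series, restricts them to quiet
#' (stillness) samples, computes the pairwise Pearson correlation, thresholds
#' it at `corrThreshold` (default 0.7) into a binary adjacency, and computes
#' the cosine dissimilarity between adjacency rows. ROIs with no quiet events
#' have zero indicator variance; their correlations are defined as 0 and the
#' ROI is flagged.
#'
#' @param eventTrains List of `EventTrain` objects (one per ROI).
#' @param quietMask Logical quiet-wakefulness mask over frames.
#' @param corrThreshold Adjacency threshold on the correlation (default 0.7).
#' @return A `CorrelationGraph` list with `corr`, `adjacency`,
#'   `dissimilarity` (all nRois x nRois) and `flagged` (ROIs without quiet
#'   events).
#' @export
eventCorrelation <- function(eventTrains, quietMask, corrThreshold = 0.7) {
  nRoi <- length(eventTrains)
  if (nRoi < 2) stop("need at least 2 ROIs", call. = FALSE)
  if (!any(quietMask)) stop("quietMask is empty", call. = FALSE)
  ind <- vapply(eventTrains, function(ev)
    eventIndicator(ev, length(quietMask))[quietMask],
    logical(sum(quietMask)))
  x <- ind * 1
  sds <- apply(x, 2, sd)
  flagged <- which(sds == 0)
  corr <- matrix(0, nRoi, nRoi)
  ok <- sds > 0
  if (any(ok)) corr[ok, ok] <- cor(x[, ok, drop = FALSE])
  diag(corr) <- 1
  adjacency <- corr > corrThreshold
  a <- adjacency * 1
  norms <- sqrt(rowSums(a^2))            # >= 1: the diagonal is always TRUE
  cosSim <- (a %*% t(a)) / outer(norms, norms)
  diss <- 1 - cosSim
  diss[diss < 0] <- 0
  diag(diss) <- 0
  structure(list(corr = corr, adjacency = adjacency, dissimilarity = diss,
                 flagged = flagged),
            class = "CorrelationGraph")
}

# Inconsistency coefficient of each dendrogram link: (height - mean)/sd over
# the heights of the link and its descendant links down to `depth` levels
# (depth counts the link itself as level 1, matching MATLAB's inconsistent()
# and scipy's inconsistent() at the same d); 0 where the sd vanishes. Note
# the depth-2 statistic is bounded by 2/sqrt(3) ~ 1.15.
#' @noRd
.linkInconsistency <- function(merge, height, depth = 2L) {
  nLinks <- nrow(merge)
  inc <- numeric(nLinks)
  for (k in seq_len(nLinks)) {
    hs <- numeric(0)
    frontier <- k
    for (d in seq_len(depth)) {
      hs <- c(hs, height[frontier])
      nxt <- integer(0)
      for (j in frontier) {
        ch <- merge[j, ]
        nxt <- c(nxt, ch[ch > 0])
      }
      frontier <- nxt
      if (!length(frontier)) break
    }
    s <- sd(hs)
    inc[k] <- if (length(hs) < 2 || !is.finite(s) || s == 0) 0
              else (height[k] - mean(hs)) / s
  }
  inc
}

#' Cluster ROIs into putative fibers
#'
#' Agglomerative clustering (average linkage by default) on the cosine
#' dissimilarity between thresholded correlation rows, cut into flat
#' clusters. The default cut is at cophenetic distance 0.5 on the cosine
#' scale, half-way between identical (0) and orthogonal (1) event profiles:
#' because the dissimilarity between binary adjacency rows is bounded by 1,
#' a distance cutoff of 2 (the cosine maximum) would never split, and the
#' dendrogram-inconsistency criterion at 2 is bounded below its cutoff for
#' small subtrees, so neither can separate few-ROI fibers (see the methods
#' vignette). The inconsistency criterion remains available via
#' `criterion = "inconsistent"`. Singleton clusters are allowed.
#'
#' @param graph A `CorrelationGraph` from [eventCorrelation()].
#' @param cutoff Cut height (distance criterion, default 0.5) or
#'   inconsistency cutoff.
#' @param method Linkage method passed to [stats::hclust()] (default
#'   "average").
#' @param criterion Flat-cluster criterion, "distance" (default) or
#'   "inconsistent" (MATLAB-style, depth-2 neighborhood).
#' @return A `FiberMap`: integer vector of 0-based fiber labels, contiguous
#'   from 0, ordered by first member ROI.
#' @export
clusterFibers <- function(graph, cutoff = 0.5, method = "average",
                          criterion = c("distance", "inconsistent")) {
  criterion <- match.arg(criterion)
  diss <- graph$dissimilarity
  n <- nrow(diss)
  if (n == 1L) return(structure(0L, class = "FiberMap"))
  hc <- hclust(as.dist(diss), method = method)
  labels <- integer(n)
  if (max(hc$height) <= 1e-12) {
    labels[] <- 0L                        # all-zero dissimilarity: one cluster
  } else if (criterion == "distance") {
    labels <- cutree(hc, h = cutoff) - 1L
  } else {
    inc <- .linkInconsistency(hc$merge, hc$height)
    # max inconsistency over each subtree, bottom-up (merges are height-ordered)
    maxinc <- inc
    for (k in seq_len(nrow(hc$merge)))
      for (ch in hc$merge[k, ])
        if (ch > 0) maxinc[k] <- max(maxinc[k], maxinc[ch])
    nextLab <- 0L
    assign_subtree <- function(node, lab) {
      if (node < 0) labels[-node] <<- lab
      else for (ch in hc$merge[node, ]) assign_subtree(ch, lab)
    }
    walk <- function(node) {
      if (node < 0 || maxinc[node] <= cutoff) {
        assign_subtree(node, nextLab)
        nextLab <<- nextLab + 1L
      } else {
        for (ch in hc$merge[node, ]) walk(ch)
      }
    }
    walk(nrow(hc$merge))
  }
  # relabel contiguously in order of first member ROI
  first <- tapply(seq_len(n), labels, min)
  remap <- integer(length(first))
  remap[order(first)] <- seq_along(first) - 1L
  structure(remap[match(labels, sort(unique(labels)))], class = "FiberMap")
}

#' Mean standardized trace of one fiber
#'
#' @param zTraces Matrix [nRois x nFrames] of standardized traces.
#' @param members ROI indices belonging to the fiber.
#' @return Mean z series across members.
#' @export
fiberTrace <- function(zTraces, members) {
  if (!length(members)) stop("empty fiber", call. = FALSE)
  if (any(members < 1 | members > nrow(zTraces)))
    stop("fiber member index out of range", call. = FALSE)
  colMeans(zTraces[members, , drop = FALSE])
}
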