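#' Vertex-wise correlation between depth-sampled AFD and behavior
#'
#' Fits, at every vertex, the linear model AFD_i = b0 + b1 * behavior
#' across subjects and reports the equivalent Pearson correlation, its
#' square (coefficient of determination), and the two-tailed p value from
#' the t transform with df = n_complete - 2. Vertices with fewer than 4
#' complete subjects, or zero variance, are missing (and counted).
#'
#' @param samples subjects x vertices matrix of one AFD metric at one depth
#'   (NA allowed)
#' @param behavior per-subject scalar (e.g. mean absolute asynchrony)
#' @param depth_mm,metric optional annotations carried through
#' @return object of class `vertex_stats`: `r_map`, `r2_map`, `p_map`,
#'   `n_complete`, `df`, `n_zero_variance`, `clusters` (NULL until
#'   [cluster_correction()])
#' @export
vertexwise_correlation <- function(samples, behavior, depth_mm = NA_real_,
                                   metric = NA_character_) {
  stopifnot(nrow(samples) == length(behavior))
  nv <- ncol(samples)
  r <- rep(NA_real_, nv)
  ncomp <- integer(nv)
  has_na <- anyNA(samples) || anyNA(behavior)
  if (!has_na) {
    n <- nrow(samples)
    sdc <- apply(samples, 2, stats::sd)
    ok <- sdc > 0 & stats::sd(behavior) > 0
    if (any(ok)) r[ok] <- as.vector(stats::cor(samples[, ok, drop = FALSE], behavior))
    ncomp[] <- n
  } else {
    for (v in seq_len(nv)) {
      cc <- stats::complete.cases(samples[, v], behavior)
      ncomp[v] <- sum(cc)
      if (ncomp[v] < 4) next
      if (stats::sd(samples[cc, v]) == 0 || stats::sd(behavior[cc]) == 0) next
      r[v] <- stats::cor(samples[cc, v], behavior[cc])
    }
  }
  zero_var <- sum(is.na(r) & ncomp >= 4)
  df <- ncomp - 2L
  tt <- r * sqrt(df / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  p[ncomp < 4] <- NA_real_
  structure(list(r_map = r, r2_map = r^2, p_map = p, n_complete = ncomp,
                 df = df, n_zero_variance = zero_var, clusters = NULL,
                 depth_mm = depth_mm, metric = metric,
                 samples = samples, behavior = behavior),
            class = "vertex_stats")
}

#' @export
print.vertex_stats <- function(x, ...) {
  cat(sprintf("vertex-wise correlation: %d vertices (%d defined), depth %s mm\n",
              length(x$r_map), sum(!is.na(x$r_map)), format(x$depth_mm)))
  if (!is.null(x$clusters))
    cat(sprintf("  %d supra-threshold clusters, %d significant\n",
                length(x$clusters), sum(vapply(x$clusters, `[[`, logical(1), "significant"))))
  invisible(x)
}

#' Critical Pearson correlation for a two-tailed test
#'
#' Smallest |r| with two-tailed p <= alpha under the t transform
#' \eqn{t = r \sqrt{df / (1 - r^2)}}. At df = 29 and alpha = 0.05 this is
#' 0.355, the significance threshold quoted for 31 subjects.
#'
#' @param df degrees of freedom (n - 2)
#' @param alpha two-tailed level
#' @return critical |r|
#' @export
critical_r <- function(df, alpha = 0.05) {
  if (alpha >= 1) return(0)
  tcrit <- stats::qt(1 - alpha / 2, df)
  sqrt(tcrit^2 / (df + tcrit^2))
}

#' Permutation cluster correction on the surface
#'
#' Supra-threshold vertices (p below the cluster-forming threshold) are
#' grouped into edge-connected components on the mesh; the null
#' distribution of the maximum cluster extent (vertex count) is built by
#' recomputing the full vertex-wise map under random permutations of the
#' behavior vector, and each observed cluster gets
#' \eqn{p_{cluster} = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @param result a [vertexwise_correlation()] result (carries its samples
#'   and behavior)
#' @param surface mesh list with `faces`
#' @param p_cft cluster-forming threshold on the vertex p value
#' @param n_perm number of permutations (>= 100)
#' @param alpha_cluster cluster-level significance threshold
#' @param seed integer
#' @return the `vertex_stats` object with `clusters` filled: each a list
#'   `vertices`, `size`, `p_cluster`, `peak_vertex`, `mean_r`,
#'   `significant`; plus `null_max_size`
#' @export
cluster_correction <- function(result, surface, p_cft = 0.001, n_perm = 999,
                               alpha_cluster = 0.001, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  edges <- mesh_edges(surface$faces)
  nv <- length(result$r_map)
  gr <- igraph::make_empty_graph(n = nv, directed = FALSE)
  gr <- igraph::add_edges(gr, t(edges))

  comp_sizes <- function(supra) {
    idx <- which(supra)
    if (!length(idx)) return(list(sizes = integer(0), membership = NULL, idx = idx))
    sub <- igraph::induced_subgraph(gr, idx)
    cm <- igraph::components(sub)
    list(sizes = as.integer(cm$csize), membership = cm$membership, idx = idx)
  }

  obs <- comp_sizes(!is.na(result$p_map) & result$p_map < p_cft)

  ## permutation null of the max cluster extent; complete-case vertices only
  X <- result$samples
  b <- result$behavior
  cc <- stats::complete.cases(X) & !is.na(b)
  Xc <- X[cc, , drop = FALSE]
  bc <- b[cc]
  n <- nrow(Xc)
  sdc <- apply(Xc, 2, stats::sd)
  usable <- which(sdc > 0)
  Zs <- scale(Xc[, usable, drop = FALSE])
  rthr <- critical_r(n - 2, p_cft)
  null_max <- integer(n_perm)
  if (stats::sd(bc) > 0 && length(usable)) {
    null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      zb <- as.vector(scale(bc[sample.int(n)]))
      rp <- as.vector(crossprod(Zs, zb)) / (n - 1)
      supra <- rep(FALSE, nv)
      supra[usable[abs(rp) > rthr]] <- TRUE
      s <- comp_sizes(supra)$sizes
      if (length(s)) max(s) else 0L
    }, integer(1)))
  }

  clusters <- list()
  if (length(obs$sizes)) {
    for (k in seq_along(obs$sizes)) {
      vs <- obs$idx[obs$membership == k]
      pk <- vs[which.max(abs(result$r_map[vs]))]
      pcl <- (1 + sum(null_max >= length(vs))) / (1 + n_perm)
      clusters[[k]] <- list(vertices = vs, size = length(vs),
                            p_cluster = pcl, peak_vertex = pk,
                            mean_r = mean(result$r_map[vs]),
                            significant = pcl < alpha_cluster)
    }
    ord <- order(-vapply(clusters, `[[`, integer(1), "size"))
    clusters <- clusters[ord]
  }
  result$clusters <- clusters
  result$null_max_size <- null_max
  result$p_cft <- p_cft
  result$alpha_cluster <- alpha_cluster
  result
}

#' Aggregate cluster results over ROI labels
#'
#' For every ROI: the fraction of its vertices lying inside significant
#' clusters and the mean correlation over those vertices (how Fig-5-style
#' correlation circles are sized and colored).
#'
#' @param result a [cluster_correction()] result
#' @param roi_labels per-vertex integer labels (0 = background, skipped)
#' @return data frame of class `roi_summary`: roi, n_vertices,
#'   n_significant, fraction_significant, mean_r_significant
#' @export
roi_aggregate <- function(result, roi_labels) {
  sig <- rep(FALSE, length(result$r_map))
  if (!is.null(result$clusters)) {
    for (cl in result$clusters) if (cl$significant) sig[cl$vertices] <- TRUE
  }
  rois <- sort(unique(roi_labels[roi_labels > 0]))
  out <- do.call(rbind, lapply(rois, function(rr) {
    vs <- roi_labels == rr
    ns <- sum(sig & vs)
    data.frame(roi = rr, n_vertices = sum(vs), n_significant = ns,
               fraction_significant = ns / sum(vs),
               mean_r_significant = if (ns) mean(result$r_map[sig & vs]) else NA_real_)
  }))
  class(out) <- c("roi_summary", class(out))
  out
}
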