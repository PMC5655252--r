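#' Cluster-forming threshold specification
#'
#' Default thresholds of the mapping approach: voxel p < 0.005, peak |Z| >=
#' 1, and cluster extent >= 10 voxels — a combination chosen in the method
#' literature to balance false positives and negatives. Meta-regression maps
#' use the more conservative p < 0.0005 with extent > 10.
#'
#' @param p_voxel voxel-level p threshold (default 0.005).
#' @param min_peak_abs_z minimum cluster peak |Z| (default 1).
#' @param min_extent_voxels minimum cluster extent in voxels (default 10).
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(p_voxel = 0.005, min_peak_abs_z = 1,
                           min_extent_voxels = 10) {
  stopifnot(p_voxel > 0, min_peak_abs_z > 0, min_extent_voxels > 0)
  structure(list(p_voxel = p_voxel, min_peak_abs_z = min_peak_abs_z,
                 min_extent_voxels = as.integer(min_extent_voxels)),
            class = "threshold_spec")
}

# 26-connectivity connected components over a set of linear voxel indices.
# Edges are built vectorized over the 26 neighbor offsets and components
# come from igraph. Returns an integer label per input index.
connected_components <- function(idx, shape) {
  n <- length(idx)
  if (!n) return(integer())
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  pos <- integer(prod(shape))
  pos[idx] <- seq_len(n)
  ijk <- arrayInd(idx, shape)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(off))) {
    q1 <- ijk[, 1] + off[o, 1]; q2 <- ijk[, 2] + off[o, 2]
    q3 <- ijk[, 3] + off[o, 3]
    ok <- q1 >= 1 & q1 <= nx & q2 >= 1 & q2 <= ny & q3 >= 1 & q3 <= nz
    li <- q1[ok] + nx * ((q2[ok] - 1) + ny * (q3[ok] - 1))
    m <- pos[li]
    hit <- m > 0
    from <- c(from, which(ok)[hit])
    to <- c(to, m[hit])
  }
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
  as.integer(igraph::components(gr)$membership[seq_len(n)])
}

#' Extract suprathreshold clusters from a statistical map
#'
#' Voxels with `p < p_voxel` are partitioned into 26-connected components,
#' separately for negative (gray-matter reduction) and positive (increase)
#' Z. Components whose peak |Z| falls below `min_peak_abs_z` or whose extent
#' falls below `min_extent_voxels` are discarded. The cluster peak is the
#' voxel of maximum |Z|, ties broken by smallest linear index; clusters are
#' sorted by extent, descending.
#'
#' @param z_map,p_map [volume_map()]s on one grid.
#' @param spec a [threshold_spec()].
#' @param signs which signs to extract: `"both"` (default), `"negative"`,
#'   `"positive"`.
#' @return data.frame of class `cluster_table`: one row per cluster with
#'   columns `sign`, `extent`, `peak_x`, `peak_y`, `peak_z` (MNI mm),
#'   `peak_zstat`, `peak_p`, plus a `voxels` list-column of in-mask voxel
#'   positions (indices into the grid's mask order).
#' @export
extract_clusters <- function(z_map, p_map, spec = threshold_spec(),
                             signs = c("both", "negative", "positive")) {
  signs <- match.arg(signs)
  if (!same_grid(z_map$grid, p_map$grid)) stop("z and p maps must share a grid")
  g <- z_map$grid
  out <- list()
  want <- if (signs == "both") c(-1, 1) else if (signs == "negative") -1 else 1
  for (sgn in want) {
    sel <- which(p_map$values < spec$p_voxel &
                 sign(z_map$values) == sgn & z_map$values != 0)
    if (!length(sel)) next
    lin <- g$mask_idx[sel]
    labels <- connected_components(lin, g$shape)
    for (lb in seq_len(max(labels))) {
      memb <- sel[labels == lb]
      if (length(memb) < spec$min_extent_voxels) next
      az <- abs(z_map$values[memb])
      if (max(az) < spec$min_peak_abs_z) next
      # peak: max |z|, ties by smallest linear index (mask order follows it)
      pk <- memb[which.max(az)]
      mm <- voxel_to_mm(g, g$mask_idx[pk])
      out[[length(out) + 1L]] <- data.frame(
        sign = if (sgn < 0) "reduction" else "increase",
        extent = length(memb),
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        peak_zstat = z_map$values[pk],
        peak_p = p_map$values[pk],
        voxels = I(list(memb)))
    }
  }
  if (!length(out)) {
    res <- data.frame(sign = character(), extent = integer(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), peak_zstat = numeric(),
                      peak_p = numeric())
    res$voxels <- list()
  } else {
    res <- do.call(rbind, out)
    res <- res[order(-res$extent), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("cluster_table", "data.frame")
  res
}

#' Leave-one-out jackknife sensitivity analysis
#'
#' Repeats the pooled analysis k times, discarding one study each time, and
#' records for every main-analysis cluster whether a suprathreshold cluster
#' of the same sign overlaps it (at least one shared voxel) in each repeat.
#'
#' @param maps output of [reconstruct_all_studies()].
#' @param clusters the main analysis `cluster_table`.
#' @param spec a [threshold_spec()].
#' @return list with `table`, a k x n_clusters logical matrix (rows = study
#'   omitted), and `replication`, the "k out of N" count per cluster.
#' @export
jackknife <- function(maps, clusters, spec = threshold_spec()) {
  mm <- as_map_matrices(maps)
  k <- nrow(mm$effects)
  if (k < 3L) stop("jackknife requires at least 3 studies")
  nc <- nrow(clusters)
  rep_mat <- matrix(FALSE, k, nc,
                    dimnames = list(rownames(mm$effects),
                                    if (nc) paste0("cluster", seq_len(nc))))
  for (i in seq_len(k)) {
    sub <- list(effects = mm$effects[-i, , drop = FALSE],
                variances = mm$variances[-i, , drop = FALSE],
                grid = mm$grid)
    pm <- pooled_maps(sub)
    cl <- extract_clusters(pm$z, pm$p, spec)
    for (j in seq_len(nc)) {
      main_vox <- clusters$voxels[[j]]
      same_sign <- cl$sign == clusters$sign[j]
      rep_mat[i, j] <- any(vapply(cl$voxels[same_sign],
                                  function(v) length(intersect(v, main_vox)) > 0,
                                  logical(1)))
    }
  }
  list(table = rep_mat, replication = colSums(rep_mat), n = k)
}

#' Egger test of publication bias at meta-analytic peaks
#'
#' At each cluster's peak voxel the per-study effect `g_i` and its standard
#' error `s_i` are extracted from the reconstructed study maps, and the
#' Egger regression `g_i/s_i ~ 1/s_i` is fit by ordinary least squares; the
#' intercept's two-tailed t test (k-2 df) indexes funnel-plot asymmetry.
#' Funnel coordinates (`g_i`, precision `1/s_i`) are returned for plotting.
#'
#' @param maps output of [reconstruct_all_studies()].
#' @param clusters a `cluster_table` (non-empty).
#' @return data.frame, one row per cluster: `intercept`, `intercept_se`,
#'   `t`, `p`, `n_studies`; the per-cluster funnel data is attached as the
#'   `funnel` attribute (list of data.frames with `g` and `precision`).
#' @export
egger_at_peaks <- function(maps, clusters) {
  mm <- as_map_matrices(maps)
  if (nrow(mm$effects) < 3L) stop("Egger test requires at least 3 studies")
  if (!nrow(clusters)) stop("no clusters supplied")
  funnels <- vector("list", nrow(clusters))
  rows <- vector("list", nrow(clusters))
  for (j in seq_len(nrow(clusters))) {
    pkv <- mask_pos_of_peak(mm$grid, clusters[j, ])
    g <- mm$effects[, pkv]
    s <- sqrt(mm$variances[, pkv])
    er <- egger_test(g, s)
    funnels[[j]] <- data.frame(g = g, precision = 1 / s)
    rows[[j]] <- data.frame(intercept = er$intercept,
                            intercept_se = er$intercept_se,
                            t = er$t, p = er$p, n_studies = er$n_studies)
  }
  res <- do.call(rbind, rows)
  attr(res, "funnel") <- funnels
  res
}

mask_pos_of_peak <- function(grid, cluster_row) {
  lin <- mm_to_voxel(grid, c(cluster_row$peak_x, cluster_row$peak_y,
                             cluster_row$peak_z))
  match(lin, grid$mask_idx)
}

#' Egger regression on effect sizes and standard errors
#'
#' @param g study effect sizes.
#' @param se their standard errors (> 0).
#' @return list `intercept`, `intercept_se`, `t`, `p` (two-tailed, k-2 df),
#'   `n_studies`.
#' @export
egger_test <- function(g, se) {
  keep <- is.finite(g) & is.finite(se) & se > 0
  g <- g[keep]; se <- se[keep]
  k <- length(g)
  if (k < 3L) {
    return(list(intercept = NA_real_, intercept_se = NA_real_, t = NA_real_,
                p = NA_real_, n_studies = k, computable = FALSE))
  }
  y <- g / se
  x <- 1 / se
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # identical studies: a single funnel point carries no asymmetry signal
    return(list(intercept = 0, intercept_se = NA_real_, t = 0, p = 1,
                n_studies = k, computable = TRUE))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  # degenerate case: identical studies leave zero residual variance
  int <- unname(sm[1, 1]); ise <- unname(sm[1, 2])
  tt <- unname(sm[1, 3]); p <- unname(sm[1, 4])
  if (!is.finite(ise) || ise == 0) { tt <- 0; p <- 1 }
  list(intercept = int, intercept_se = ise, t = tt, p = p, n_studies = k,
       computable = TRUE)
}
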