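# Spatial proximity between FoxP3- T cells (by Ki67 status) and Tregs.
#
# Two summary modes: "pairwise" counts every (T cell, Treg) pair within the
# radius (the within-radius pair census behind the mean-distance dot plots),
# while "nearest" contributes each T cell's nearest-Treg distance if within
# the radius (the per-T-cell distance-probability curves).

#' Proximity analysis configuration
#'
#' @param radius_um Search radius in um (default 100).
#' @param mode `"pairwise"` or `"nearest"` (see module description).
#' @param bin_width_um Histogram bin width for distance distributions.
#' @param drop_border Exclude T cells within `radius_um` of the field border
#'   (a conservative edge correction for simulation studies; off by default,
#'   matching whole-slide analysis with no correction).
#' @param field_width_um,field_height_um Field size, needed only when
#'   `drop_border` is TRUE.
#' @return A `proximity_config` list.
#' @export
proximity_config <- function(radius_um = 100,
                             mode = c("pairwise", "nearest"),
                             bin_width_um = 5,
                             drop_border = FALSE,
                             field_width_um = NULL,
                             field_height_um = NULL) {
  .check_number(radius_um, "radius_um", lower = 1e-9)
  .check_number(bin_width_um, "bin_width_um", lower = 1e-9)
  mode <- match.arg(mode)
  structure(list(radius_um = radius_um, mode = mode,
                 bin_width_um = bin_width_um, drop_border = drop_border,
                 field_width_um = field_width_um,
                 field_height_um = field_height_um),
            class = "proximity_config")
}

# Grid-bucketed radius search.  For each query point (ax, ay) returns the
# distances to all target points (bx, by) within `radius`, in increasing
# target-index order so results are bit-identical to a dense double loop.
.radius_search <- function(ax, ay, bx, by, radius) {
  na <- length(ax)
  nb <- length(bx)
  out <- vector("list", na)
  if (na == 0L) return(out)
  if (nb == 0L) {
    for (i in seq_len(na)) out[[i]] <- numeric(0)
    return(out)
  }
  ox <- min(ax, bx); oy <- min(ay, by)
  gbx <- floor((bx - ox) / radius)
  gby <- floor((by - oy) / radius)
  key <- paste(gbx, gby)
  buckets <- split(seq_len(nb), key)
  gax <- floor((ax - ox) / radius)
  gay <- floor((ay - oy) / radius)
  for (i in seq_len(na)) {
    cand <- integer(0)
    for (dx in -1:1) {
      for (dy in -1:1) {
        b <- buckets[[paste(gax[i] + dx, gay[i] + dy)]]
        if (!is.null(b)) cand <- c(cand, b)
      }
    }
    if (length(cand) == 0L) { out[[i]] <- numeric(0); next }
    cand <- sort(cand)
    d <- sqrt((ax[i] - bx[cand])^2 + (ay[i] - by[cand])^2)
    out[[i]] <- d[d <= radius]
  }
  out
}

#' Distances between a T cell subset and Tregs
#'
#' In pairwise mode the result holds every (T cell, Treg) Euclidean distance
#' not exceeding the radius; in nearest mode each T cell contributes its
#' distance to the nearest Treg when that distance is within the radius.  The
#' grid-accelerated neighbor search is exact: results are bit-identical to an
#' exhaustive O(n x m) computation.
#'
#' @param tcells,tregs data.frames with `x_um`, `y_um` columns on a common
#'   coordinate frame.
#' @param config A [proximity_config()].
#' @return List with `n_pairs`, `mean_distance_um` (NA when `n_pairs` is 0,
#'   including the no-Tregs-on-slide case), and `distances`.
#' @export
proximity_pairs <- function(tcells, tregs, config = proximity_config()) {
  ax <- tcells$x_um; ay <- tcells$y_um
  if (isTRUE(config$drop_border)) {
    if (is.null(config$field_width_um) || is.null(config$field_height_um)) {
      .param_error("drop_border requires field_width_um and field_height_um")
    }
    r <- config$radius_um
    keep <- ax >= r & ax <= config$field_width_um - r &
      ay >= r & ay <= config$field_height_um - r
    ax <- ax[keep]; ay <- ay[keep]
  }
  hits <- .radius_search(ax, ay, tregs$x_um, tregs$y_um, config$radius_um)
  d <- if (config$mode == "pairwise") {
    unlist(hits, use.names = FALSE)
  } else {
    mins <- vapply(hits, function(h) if (length(h)) min(h) else NA_real_,
                   numeric(1))
    mins[!is.na(mins)]
  }
  if (is.null(d)) d <- numeric(0)
  list(n_pairs = length(d),
       mean_distance_um = if (length(d)) mean(d) else NA_real_,
       distances = d)
}

# Subset helper: conventional T cells of one proximity class on a slide.
.tcell_class_subset <- function(cells, class) {
  pheno <- switch(sub("^Ki67[+-]", "", class),
                  "CD8" = "CD8 T cell", "CD4" = "CD4 T cell",
                  .param_error("unknown proximity class: ", class))
  want_ki67 <- startsWith(class, "Ki67+")
  cells[cells$phenotype == pheno & cells$ki67 == want_ki67, , drop = FALSE]
}

PROXIMITY_CLASSES <- c("Ki67+CD8", "Ki67-CD8", "Ki67+CD4", "Ki67-CD4")

#' Per-class proximity results for one slide
#'
#' @param cells Phenotyped cell table (needs `phenotype` and `ki67`).
#' @param config A [proximity_config()].
#' @param classes T cell classes to evaluate.
#' @return Named list of [proximity_pairs()] results, one per class.
#' @export
proximity_by_class <- function(cells, config = proximity_config(),
                               classes = PROXIMITY_CLASSES) {
  tregs <- cells[cells$phenotype == "Treg", , drop = FALSE]
  res <- lapply(classes, function(cl) {
    proximity_pairs(.tcell_class_subset(cells, cl), tregs, config)
  })
  names(res) <- classes
  res
}

#' Mean T cell-to-Treg distance by class
#'
#' @param results Named list from [proximity_by_class()] (or any named list
#'   of [proximity_pairs()] results).
#' @return data.frame with columns `class`, `n_pairs`, `mean_distance_um`.
#' @export
mean_distance_by_class <- function(results) {
  data.frame(class = names(results),
             n_pairs = vapply(results, `[[`, integer(1), "n_pairs"),
             mean_distance_um = vapply(results, `[[`, numeric(1),
                                       "mean_distance_um"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Distance-probability distribution
#'
#' Histogram of distances on \[0, radius\] with fixed-width bins, normalized
#' to sum to 1; optionally smoothed with a Gaussian kernel over bin centers
#' (renormalized after smoothing).
#'
#' @param distances Numeric vector of distances (um).
#' @param bin_width_um Bin width (um).
#' @param radius_um Upper limit of the support.
#' @param smooth_bw Gaussian kernel bandwidth in um, or `NULL` for the raw
#'   histogram.
#' @return data.frame with `bin_center_um` and `probability` (empty for an
#'   empty input).
#' @export
distance_distribution <- function(distances, bin_width_um = 5,
                                  radius_um = 100, smooth_bw = NULL) {
  if (length(distances) == 0L) {
    return(data.frame(bin_center_um = numeric(0), probability = numeric(0)))
  }
  .check_number(bin_width_um, "bin_width_um", lower = 1e-9)
  breaks <- seq(0, bin_width_um * ceiling(radius_um / bin_width_um),
                by = bin_width_um)
  idx <- findInterval(distances, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[distances == 0] <- 1L  # zero distances belong to the first bin
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  p <- counts / sum(counts)
  centers <- breaks[-length(breaks)] + bin_width_um / 2
  if (!is.null(smooth_bw)) {
    w <- outer(centers, centers, function(a, b) stats::dnorm(a - b, sd = smooth_bw))
    p <- as.numeric(w %*% p)
    p <- p / sum(p)
  }
  data.frame(bin_center_um = centers, probability = p)
}

#' Pre/post shift in mean T cell-to-Treg distance
#'
#' `log2((post_mean + d0) / (pre_mean + d0))`; returns NA (undefined-result
#' sentinel) when either timepoint has no contributing pairs.
#'
#' @param pre,post [proximity_pairs()] results for the same class and config.
#' @param pseudodistance Additive guard distance in um (default 0).
#' @return log2 fold change of the mean distance, or NA.
#' @export
proximity_shift <- function(pre, post, pseudodistance = 0) {
  if (pre$n_pairs == 0L || post$n_pairs == 0L) return(NA_real_)
  log2((post$mean_distance_um + pseudodistance) /
         (pre$mean_distance_um + pseudodistance))
}
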