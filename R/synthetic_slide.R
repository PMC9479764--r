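# Synthetic MIF slide generator.
#
# Emulates the cell tables produced by segmenting a multiplex
# immunofluorescence slide: tumor cells inside circular nests, immune
# phenotypes (CD8 T, CD4 T, Treg, PMN, macrophage) as homogeneous Poisson
# point patterns in each compartment, and a planted repulsion between Tregs
# and proliferating (Ki67+) conventional T cells.

PHENOTYPE_LABELS <- c(cd8_t = "CD8 T cell", cd4_t = "CD4 T cell",
                      treg = "Treg", pmn = "PMN", macrophage = "Macrophage")

# TRUE for points inside any tumor nest
.in_nest <- function(x, y, nests) {
  inside <- rep(FALSE, length(x))
  if (is.null(nests) || nrow(nests) == 0L) return(inside)
  for (i in seq_len(nrow(nests))) {
    inside <- inside |
      ((x - nests$cx[i])^2 + (y - nests$cy[i])^2 <= nests$r[i]^2)
  }
  inside
}

# Sample n points uniformly within one compartment by rejection from the field
.sample_in_compartment <- function(n, compartment, nests, width, height,
                                   max_rounds = 200L) {
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  rounds <- 0L
  while (length(xs) < n && rounds < max_rounds) {
    m <- max(2L * (n - length(xs)), 32L)
    cx <- stats::runif(m, 0, width)
    cy <- stats::runif(m, 0, height)
    keep <- if (compartment == "tumor") .in_nest(cx, cy, nests) else
      !.in_nest(cx, cy, nests)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    rounds <- rounds + 1L
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Generate a synthetic segmented-cell table for one slide
#'
#' Produces one row per cell with coordinates (um, origin top-left, y
#' increasing downward), compartment (tumor parenchyma inside a nest, else
#' stroma), marker booleans consistent with exactly one phenotype definition,
#' Ki67 and PD-L1 status, an intensity bin in 0..3, a diameter, roundness and
#' a cytokeratin flag (tumor cells CK+, immune cells CK-).
#'
#' Tregs are placed last: any Treg falling within
#' `params$treg_exclusion_radius_um` of a Ki67+ conventional T cell is
#' resampled within its compartment (up to 100 attempts, then dropped), so no
#' Ki67+ T cell lies closer than the exclusion radius to any Treg.  With the
#' radius at 0 the Treg pattern is completely spatially random with respect to
#' Ki67 status.
#'
#' @param params A [slide_pattern_params()] object.
#' @param seed Integer seed; fixed seed gives an identical table.
#' @return A data.frame of cells with attributes `tumor_area_mm2`,
#'   `stroma_area_mm2` and `nests`.
#' @export
generate_cell_slide <- function(params, seed = 1L) {
  if (!inherits(params, "slide_pattern_params")) {
    params <- do.call(slide_pattern_params, as.list(params))
  } else {
    params <- do.call(slide_pattern_params, unclass(params))  # revalidate
  }
  set.seed(as.integer(seed))
  W <- params$field_width_um
  H <- params$field_height_um
  field_mm2 <- W * H / 1e6

  # tumor nests: random discs; compartment area estimated on a fine grid
  n_nest <- params$tumor_nest_count
  nests <- if (n_nest > 0L) {
    data.frame(cx = stats::runif(n_nest, 0, W),
               cy = stats::runif(n_nest, 0, H),
               r = stats::runif(n_nest, params$nest_radius_range_um[1],
                                params$nest_radius_range_um[2]))
  } else {
    data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  }
  step <- max(2, min(W, H) / 250)
  gx <- seq(step / 2, W, by = step)
  gy <- seq(step / 2, H, by = step)
  grid <- expand.grid(x = gx, y = gy)
  tumor_frac <- mean(.in_nest(grid$x, grid$y, nests))
  tumor_area_mm2 <- tumor_frac * field_mm2
  stroma_area_mm2 <- field_mm2 - tumor_area_mm2

  rows <- list()

  place <- function(n, compartment, phenotype) {
    pts <- .sample_in_compartment(n, compartment, nests, W, H)
    if (nrow(pts) == 0L) return(NULL)
    data.frame(x_um = pts$x, y_um = pts$y, compartment = compartment,
               phenotype = phenotype, stringsAsFactors = FALSE)
  }

  # tumor cells
  if (tumor_area_mm2 > 0) {
    n_t <- stats::rpois(1, params$tumor_cell_density * tumor_area_mm2)
    rows$tumor <- place(n_t, "tumor", "tumor cell")
  }

  # immune phenotypes except Tregs (placed after exclusion targets exist)
  for (ph in c("cd8_t", "cd4_t", "pmn", "macrophage")) {
    n_s <- stats::rpois(1, params$stromal_density[[ph]] * stroma_area_mm2)
    rows[[paste0(ph, "_s")]] <- place(n_s, "stroma", PHENOTYPE_LABELS[[ph]])
    if (tumor_area_mm2 > 0) {
      n_i <- stats::rpois(1, params$intratumoral_density[[ph]] * tumor_area_mm2)
      rows[[paste0(ph, "_t")]] <- place(n_i, "tumor", PHENOTYPE_LABELS[[ph]])
    }
  }
  cells <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cells)) {
    cells <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        compartment = character(0), phenotype = character(0),
                        stringsAsFactors = FALSE)
  }

  # Ki67 status: conventional T cells and tumor cells only
  is_tcell <- cells$phenotype %in% c("CD8 T cell", "CD4 T cell")
  is_tumor <- cells$phenotype == "tumor cell"
  cells$ki67 <- rep(FALSE, nrow(cells))
  cells$ki67[is_tcell] <- stats::runif(sum(is_tcell)) < params$ki67_fraction_tcell
  cells$ki67[is_tumor] <- stats::runif(sum(is_tumor)) < params$ki67_fraction_tumor

  # Tregs with exclusion around Ki67+ conventional T cells
  kx <- cells$x_um[is_tcell & cells$ki67]
  ky <- cells$y_um[is_tcell & cells$ki67]
  r_excl <- params$treg_exclusion_radius_um
  treg_rows <- list()
  for (comp in c("stroma", "tumor")) {
    area <- if (comp == "stroma") stroma_area_mm2 else tumor_area_mm2
    if (area <= 0) next
    dens <- if (comp == "stroma") params$stromal_density[["treg"]] else
      params$intratumoral_density[["treg"]]
    n_tr <- stats::rpois(1, dens * area)
    if (n_tr == 0L) next
    pts <- .sample_in_compartment(n_tr, comp, nests, W, H)
    if (r_excl > 0 && length(kx) > 0) {
      keep <- rep(TRUE, nrow(pts))
      for (i in seq_len(nrow(pts))) {
        attempt <- 0L
        repeat {
          d2min <- min((kx - pts$x[i])^2 + (ky - pts$y[i])^2)
          if (d2min >= r_excl^2) break
          attempt <- attempt + 1L
          if (attempt > 100L) { keep[i] <- FALSE; break }
          p <- .sample_in_compartment(1L, comp, nests, W, H)
          pts$x[i] <- p$x; pts$y[i] <- p$y
        }
      }
      pts <- pts[keep, , drop = FALSE]
    }
    if (nrow(pts) > 0L) {
      treg_rows[[comp]] <- data.frame(x_um = pts$x, y_um = pts$y,
                                      compartment = comp, phenotype = "Treg",
                                      ki67 = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(treg_rows) > 0L) cells <- rbind(cells, do.call(rbind, treg_rows))

  n <- nrow(cells)
  ph <- cells$phenotype
  is_myeloid <- ph %in% c("PMN", "Macrophage")
  cells$cd3 <- ph %in% c("CD8 T cell", "CD4 T cell", "Treg")
  cells$cd8 <- ph == "CD8 T cell"
  cells$cd4 <- ph %in% c("CD4 T cell", "Treg")
  cells$foxp3 <- ph == "Treg"
  cells$ck <- ph == "tumor cell"
  cells$pmn_marker <- ph == "PMN"
  cells$macro_marker <- ph == "Macrophage"
  cells$pdl1 <- rep(FALSE, n)
  cells$pdl1[is_myeloid] <- stats::runif(sum(is_myeloid)) <
    params$pdl1_fraction_myeloid
  cells$intensity_bin <- sample(0:3, n, replace = TRUE,
                                prob = params$intensity_bin_probs)
  dia_mean <- ifelse(ph == "tumor cell", 2 * params$cell_diameter_mean_um,
                     params$cell_diameter_mean_um)
  dia_sd <- ifelse(ph == "tumor cell", 2 * params$cell_diameter_sd_um,
                   params$cell_diameter_sd_um)
  cells$diameter_um <- pmax(2, stats::rnorm(n, dia_mean, dia_sd))
  cells$roundness <- ifelse(ph == "tumor cell",
                            stats::runif(n, 0.35, 0.9),
                            stats::runif(n, 0.75, 1.0))
  cells$cell_id <- sprintf("c%05d", seq_len(max(n, 0)))

  cells <- cells[, c("cell_id", "x_um", "y_um", "compartment", "phenotype",
                     "cd3", "cd8", "cd4", "foxp3", "ki67", "pdl1", "ck",
                     "pmn_marker", "macro_marker", "intensity_bin",
                     "diameter_um", "roundness")]
  rownames(cells) <- NULL
  attr(cells, "tumor_area_mm2") <- tumor_area_mm2
  attr(cells, "stroma_area_mm2") <- stroma_area_mm2
  attr(cells, "nests") <- nests
  cells
}
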