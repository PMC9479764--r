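# Multiplex immunofluorescence quantification: phenotype gating, compartment
# densities, H-scores, the stromal immune fraction, and pre/post fold changes.

#' Default immune phenotype panel
#'
#' Marker-gating definitions (required-positive / required-negative markers)
#' for the T cell and myeloid panels.  Definitions are pairwise mutually
#' exclusive: every pair is separated by at least one marker required positive
#' in one and negative in the other.
#'
#' @return List of definitions, each `list(name, pos, neg)` over the marker
#'   columns `cd3, cd8, cd4, foxp3, ck, pmn_marker, macro_marker`.
#' @export
default_phenotype_panel <- function() {
  list(
    list(name = "CD8 T cell", pos = c("cd3", "cd8"),
         neg = c("cd4", "foxp3", "ck")),
    list(name = "CD4 T cell", pos = c("cd3", "cd4"),
         neg = c("cd8", "foxp3", "ck")),
    list(name = "Treg", pos = c("cd3", "cd4", "foxp3"),
         neg = c("cd8", "ck")),
    list(name = "PMN", pos = "pmn_marker",
         neg = c("cd3", "macro_marker", "ck")),
    list(name = "Macrophage", pos = "macro_marker",
         neg = c("cd3", "pmn_marker", "ck"))
  )
}

# Pairwise satisfiability check: two definitions can both match a cell only if
# no marker is required positive by one and negative by the other.
.check_panel_exclusive <- function(defs) {
  n <- length(defs)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      sep <- length(intersect(defs[[i]]$pos, defs[[j]]$neg)) +
        length(intersect(defs[[j]]$pos, defs[[i]]$neg))
      if (sep == 0L) {
        .param_error("overlapping phenotype definitions: '", defs[[i]]$name,
                     "' and '", defs[[j]]$name, "' are jointly satisfiable")
      }
    }
  }
  invisible(TRUE)
}

#' Assign phenotype labels from marker states
#'
#' Each cell receives the label of the unique definition whose
#' required-positive markers are all TRUE and required-negative markers all
#' FALSE.  Cells matching no immune definition are labelled `"tumor cell"` if
#' cytokeratin-positive, `"other"` otherwise.
#'
#' @param cells Cell table with logical marker columns.
#' @param defs Panel from [default_phenotype_panel()] or the same shape.
#' @return `cells` with a (re)computed `phenotype` column.
#' @export
assign_phenotypes <- function(cells, defs = default_phenotype_panel()) {
  .check_panel_exclusive(defs)
  n <- nrow(cells)
  label <- rep(NA_character_, n)
  for (def in defs) {
    m <- rep(TRUE, n)
    for (mk in def$pos) m <- m & cells[[mk]]
    for (mk in def$neg) m <- m & !cells[[mk]]
    if (any(m & !is.na(label))) {
      .param_error("configuration error: a cell matches multiple definitions")
    }
    label[m] <- def$name
  }
  label[is.na(label)] <- ifelse(cells$ck[is.na(label)], "tumor cell", "other")
  cells$phenotype <- label
  cells
}

#' Cell density for a phenotype within a compartment
#'
#' @param cells Phenotyped cell table.
#' @param phenotype Phenotype label to count.
#' @param compartment `"tumor"`, `"stroma"`, or `"whole"`.
#' @param area_mm2 Surface area of that compartment (mm^2, > 0).
#' @return List with `phenotype`, `compartment`, `count`, `area_mm2` and
#'   `density` (cells per mm^2).
#' @export
cell_density <- function(cells, phenotype, compartment, area_mm2) {
  .check_number(area_mm2, "area_mm2")
  if (area_mm2 <= 0) .param_error("degenerate input: area_mm2 must be > 0")
  keep <- cells$phenotype == phenotype
  if (compartment != "whole") keep <- keep & cells$compartment == compartment
  count <- sum(keep)
  list(phenotype = phenotype, compartment = compartment, count = count,
       area_mm2 = area_mm2, density = count / area_mm2)
}

#' Intensity-weighted H-score
#'
#' `(% 1+ cells x 1) + (% 2+ cells x 2) + (% 3+ cells x 3)`, range 0-300.
#'
#' @param fractions Numeric length-3 vector: percentages of 1+, 2+ and 3+
#'   cells (each >= 0, summing to at most 100).
#' @return H-score in \[0, 300\].
#' @export
h_score <- function(fractions) {
  if (length(fractions) != 3L || any(!is.finite(fractions))) {
    .param_error("fractions must be three finite percentages (1+, 2+, 3+)")
  }
  if (any(fractions < 0) || sum(fractions) > 100 + 1e-9) {
    .param_error("fractions must be >= 0 and sum to at most 100")
  }
  sum(fractions * 1:3)
}

#' H-score from per-cell intensity bins
#'
#' @param intensity_bins Integer vector of per-cell bins in 0..3.
#' @return H-score in \[0, 300\]; NA for an empty input.
#' @export
h_score_from_bins <- function(intensity_bins) {
  if (length(intensity_bins) == 0L) return(NA_real_)
  if (any(!intensity_bins %in% 0:3)) {
    .param_error("intensity bins must be in 0..3")
  }
  fr <- vapply(1:3, function(b) 100 * mean(intensity_bins == b), numeric(1))
  h_score(fr)
}

#' Stromal immune cell fraction
#'
#' Fraction of stromal cells that look like immune cells morphologically:
#' cytokeratin-negative, rounded (roundness >= `roundness_min`) and with a
#' maximum diameter of `max_diameter_um`.
#'
#' @param cells Cell table (any compartments; the stroma subset is used).
#' @param roundness_min Roundness threshold (default 0.8; "rounded
#'   morphology" is qualitative, so this is configurable).
#' @param max_diameter_um Maximum diameter in um (default 15).
#' @return Proportion in \[0, 1\]; NA if there are no stromal cells.
#' @export
stromal_immune_fraction <- function(cells, roundness_min = 0.8,
                                    max_diameter_um = 15) {
  s <- cells[cells$compartment == "stroma", , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  mean(!s$ck & s$roundness >= roundness_min & s$diameter_um <= max_diameter_um)
}

# shared pseudocount rule: eps applied only when either value is zero
.auto_eps <- function(a, b, pseudocount) {
  if (!is.null(pseudocount)) return(pseudocount)
  ifelse(a == 0 | b == 0, 1, 0)
}

#' Log2 fold change of a nonnegative metric
#'
#' `log2((post + eps) / (pre + eps))`.  By default the pseudocount is 1 (in
#' the metric's own units) and applied only when either value is zero, so
#' strictly positive pairs are untouched.
#'
#' @param pre,post Nonnegative values (vectorized).
#' @param pseudocount Fixed pseudocount, or `NULL` for the zero-guard rule.
#' @return log2 fold change(s).
#' @export
log2_fc <- function(pre, post, pseudocount = NULL) {
  if (any(pre < 0) || any(post < 0)) .param_error("values must be >= 0")
  eps <- .auto_eps(pre, post, pseudocount)
  log2((post + eps) / (pre + eps))
}

#' CD8/Treg density ratio
#'
#' `(cd8 + eps) / (treg + eps)` with the same zero-guard pseudocount rule as
#' [log2_fc()].
#'
#' @param cd8_density,treg_density Densities in cells/mm^2 (>= 0).
#' @param pseudocount Fixed pseudocount, or `NULL` for the zero-guard rule.
#' @return Ratio.
#' @export
cd8_treg_ratio <- function(cd8_density, treg_density, pseudocount = NULL) {
  if (any(cd8_density < 0) || any(treg_density < 0)) {
    .param_error("densities must be >= 0")
  }
  eps <- .auto_eps(cd8_density, treg_density, pseudocount)
  (cd8_density + eps) / (treg_density + eps)
}
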