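#' Delta-Cq between a target and a reference gene
#'
#' Technical replicates are averaged per (sample, gene) first, then
#' `Cq(target) - Cq(reference)` is returned.  Normalizing to a neuronal
#' housekeeping transcript (Snap25 in the geniculate preparation) makes Cq
#' values comparable across samples.
#'
#' @param records data.frame with columns `sample_id`, `gene`, `cq` (one
#'   row per replicate; a `replicate` column may be present but is not
#'   required).
#' @param sample sample id.
#' @param target,reference gene names.
#' @return Delta-Cq in cycles.
#' @export
delta_cq <- function(records, sample, target, reference) {
  stopifnot(all(c("sample_id", "gene", "cq") %in% names(records)))
  if (any(records$cq <= 0 | records$cq > 45))
    stop("Cq values must lie in (0, 45]")
  one <- function(g) {
    v <- records$cq[records$sample_id == sample & records$gene == g]
    if (!length(v))
      stop("gene '", g, "' not measured in sample '", sample, "'")
    mean(v)
  }
  one(target) - one(reference)
}

#' Fold depletion from two delta-Cq values
#'
#' `2^(dCq_after - dCq_before)` assuming perfect doubling per PCR cycle: a
#' target that moves from dCq 5 to dCq 22 relative to the reference gene is
#' depleted 2^17-fold (~1.3e5), the arithmetic behind the reported >= 1e5
#' glial (Gfap) depletion.  Values below 1 indicate enrichment.
#'
#' @param dcq_before,dcq_after delta-Cq before and after the treatment.
#' @return Fold depletion (> 1 = depleted, < 1 = enriched).
#' @export
depletion_fold <- function(dcq_before, dcq_after) {
  stopifnot(is.finite(dcq_before), is.finite(dcq_after))
  2^(dcq_after - dcq_before)
}

#' Normalize immunofluorescence ROI intensities within an image
#'
#' Background is the mean of the four weakest neuronal ROIs of the image;
#' each intensity is background-subtracted (negative values clamped to 0)
#' and divided by the maximum background-subtracted value, so the brightest
#' ROI maps to 1.  The output is invariant to adding a constant to all ROIs
#' and to positive rescaling.
#'
#' @param intensities numeric vector of >= 5 ROI intensities (fixed ROI
#'   size; 4 background + at least 1 measured).
#' @return Numeric vector in \[0, 1\], same order and names as the input.
#' @export
normalize_rois <- function(intensities) {
  if (length(intensities) < 5)
    stop("need at least 5 ROIs (4 background + 1 measured), got ",
         length(intensities))
  if (anyNA(intensities) || any(intensities <= 0))
    stop("ROI intensities must be positive and complete")
  bg <- mean(sort(intensities)[1:4])
  sub <- pmax(intensities - bg, 0)
  mx <- max(sub)
  if (mx == 0)
    stop("no dynamic range: all ROIs at or below background")
  sub / mx
}
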