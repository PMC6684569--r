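#' @include AllClasses.R
NULL

## Printed per-network ROI counts of the 499-ROI functional parcellation:
## 142 RSN nodes across 14 canonical networks, 357 "other" ROIs.
.rsnCounts <- c(
  auditory            = 4L,
  basal_ganglia       = 7L,
  dorsal_DMN          = 21L,
  ventral_DMN         = 13L,
  high_visual         = 4L,
  language            = 9L,
  LECN                = 10L,
  RECN                = 14L,
  sensorimotor        = 12L,
  posterior_salience  = 13L,
  precuneus           = 6L,
  primary_visual      = 2L,
  anterior_salience   = 12L,
  visuospatial        = 15L)

#' Default 499-ROI functional parcellation
#'
#' Builds the package's default parcellation: 142 nodes assigned to the 14
#' canonical resting-state networks (auditory 4, basal ganglia 7, dorsal DMN
#' 21, ventral DMN 13, high visual 4, language 9, left executive control 10,
#' right executive control 14, sensorimotor 12, posterior salience 13,
#' precuneus 6, primary visual 2, anterior salience 12, visuospatial 15) and
#' 357 further ROIs covering the rest of cortex and subcortex, labelled
#' `"other"`, for 499 ROIs in total.
#'
#' @param includeOther logical; drop the non-RSN ROIs to obtain the 142-node
#'   RSN-only subset used by network-level connectivity summaries.
#' @return a [Parcellation-class] object.
#' @examples
#' parc <- defaultParcellation()
#' nNodes(parc)                     # 499
#' nNodes(defaultParcellation(FALSE))  # 142
#' @export
defaultParcellation <- function(includeOther = TRUE) {
  nets <- c(rep(names(.rsnCounts), .rsnCounts),
            if (includeOther) rep("other", 499L - sum(.rsnCounts)))
  rois <- data.frame(
    roi_id = sprintf("ROI_%03d", seq_along(nets)),
    network = nets,
    stringsAsFactors = FALSE)
  new("Parcellation", rois = rois, networks = names(.rsnCounts))
}

#' Construct a parcellation from an ROI table
#'
#' @param rois data.frame with columns `roi_id`, `network`.
#' @param networks character RSN names; defaults to every network label in
#'   `rois` other than `"other"`.
#' @return a [Parcellation-class] object.
#' @export
parcellation <- function(rois, networks = NULL) {
  stopIfNot(is.data.frame(rois) && nrow(rois) > 0,
            "'rois' must be a non-empty data.frame")
  if (is.null(networks))
    networks <- setdiff(unique(rois$network), "other")
  new("Parcellation",
      rois = data.frame(roi_id = as.character(rois$roi_id),
                        network = as.character(rois$network),
                        stringsAsFactors = FALSE),
      networks = as.character(networks))
}

#' Indices of the nodes belonging to one network
#' @param parc a [Parcellation-class].
#' @param network single network label.
#' @return integer vector of node positions in parcellation order.
#' @export
networkNodes <- function(parc, network) {
  stopIfNot(is(parc, "Parcellation"), "'parc' must be a Parcellation")
  which(parc@rois$network == network)
}

#' Audit a parcellation against the canonical per-network counts
#'
#' Tallies ROIs per network and compares the RSN blocks with the canonical
#' counts of the default 499-ROI parcellation, reporting the RSN-assigned
#' total and the `"other"` remainder.
#'
#' @param parc a [Parcellation-class].
#' @return list with `counts` (data.frame: network, n, expected, match),
#'   `n_rsn`, `n_other`, `n_total`, and `ok` (all RSN counts match).
#' @export
validateParcellation <- function(parc) {
  stopIfNot(is(parc, "Parcellation"), "'parc' must be a Parcellation")
  stopIfNot(nrow(parc@rois) > 0, "empty parcellation")
  stopIfNot(!anyDuplicated(parc@rois$roi_id), "duplicate roi_id")
  tab <- table(factor(parc@rois$network,
                      levels = c(names(.rsnCounts), "other")))
  counts <- data.frame(
    network = names(.rsnCounts),
    n = as.integer(tab[names(.rsnCounts)]),
    expected = as.integer(.rsnCounts),
    stringsAsFactors = FALSE)
  counts$match <- counts$n == counts$expected
  nOther <- sum(parc@rois$network == "other")
  list(counts = counts,
       n_rsn = sum(counts$n),
       n_other = nOther,
       n_total = nrow(parc@rois),
       ok = all(counts$match))
}
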