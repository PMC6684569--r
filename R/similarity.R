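#' @include AllClasses.R utils.R
NULL

#' Eta-squared similarity between two spatial maps
#'
#' A voxelwise similarity statistic in \[0, 1\]:
#' \deqn{\eta^2 = 1 - \frac{\sum_i [(a_i - m_i)^2 + (b_i - m_i)^2]}
#'                        {\sum_i [(a_i - \bar M)^2 + (b_i - \bar M)^2]}}
#' where \eqn{m_i = (a_i + b_i)/2} is the per-voxel mean image and
#' \eqn{\bar M} its grand mean over the V compared voxels. It equals 1 iff
#' the maps are identical and 0 when the mean image is constant at the
#' grand mean (e.g. `b = -a`). Unlike a correlation it is sensitive to
#' scale: `etaSquared(a, 2 * a) < 1` for non-constant `a`.
#'
#' @param a,b numeric arrays/vectors of equal shape, or two
#'   [SpatialMapSet-class] maps extracted with [spatialMaps()].
#' @param mask optional logical array selecting the voxels compared; by
#'   default voxels where either map is nonzero (all voxels when both maps
#'   are dense). The choice of mask changes V and hence the statistic.
#' @return the similarity value in \[0, 1\].
#' @examples
#' a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
#' etaSquared(a, b)   # 1 - 2/12
#' @export
etaSquared <- function(a, b, mask = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopIfNot(length(a) == length(b) && length(a) > 0,
            "'a' and 'b' must be non-empty and of equal shape")
  stopIfNot(all(is.finite(a)) && all(is.finite(b)), "non-finite voxel values")
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    stopIfNot(length(mask) == length(a), "mask shape differs from maps")
    a <- a[mask]; b <- b[mask]
  } else {
    keep <- a != 0 | b != 0
    if (any(keep) && !all(keep)) { a <- a[keep]; b <- b[keep] }
  }
  m <- (a + b) / 2
  Mbar <- mean(m)
  den <- sum((a - Mbar)^2 + (b - Mbar)^2)
  if (den <= 0)
    stop("eta-squared undefined: both maps constant and equal", call. = FALSE)
  num <- sum((a - m)^2 + (b - m)^2)
  1 - num / den
}

#' Build young-adult reference maps
#'
#' The reference for each network is the voxelwise mean of the
#' subject-specific maps of all subjects at or below the cutoff age
#' (default 30 years; 40 gives approximately the same downstream findings
#' on this kind of data and is available as an override).
#'
#' @param subjectMaps named list of [SpatialMapSet-class], one per subject.
#' @param demographics data.frame with `subject_id` and `age`, covering
#'   every name of `subjectMaps`.
#' @param cutoffAge inclusive age cutoff in years.
#' @return list with `reference` (a [SpatialMapSet-class]), `cutoff_age`,
#'   and `n_reference_subjects`.
#' @export
buildReference <- function(subjectMaps, demographics, cutoffAge = 30) {
  stopIfNot(length(subjectMaps) > 0 && !is.null(names(subjectMaps)),
            "'subjectMaps' must be a named list")
  stopIfNot(all(names(subjectMaps) %in% demographics$subject_id),
            "demographics missing some subjects")
  ages <- demographics$age[match(names(subjectMaps),
                                 demographics$subject_id)]
  young <- which(ages <= cutoffAge)
  if (!length(young))
    stop(sprintf("no subject at or below the cutoff age (%g years)",
                 cutoffAge), call. = FALSE)
  first <- subjectMaps[[young[1L]]]
  labels <- networkLabels(first)
  maps <- lapply(labels, function(lab) {
    Reduce(`+`, lapply(young, function(i)
      spatialMaps(subjectMaps[[i]], lab))) / length(young)
  })
  ref <- new("SpatialMapSet", maps = maps, labels = labels,
             mask = first@mask)
  list(reference = ref, cutoff_age = cutoffAge,
       n_reference_subjects = length(young))
}

#' Per-subject, per-network similarity table
#'
#' Computes the eta-squared statistic of every subject's map for every
#' network against the corresponding reference map. A subject missing a
#' network's map is recorded as NA and excluded pairwise downstream.
#'
#' @param subjectMaps named list of [SpatialMapSet-class], one per subject.
#' @param reference result of [buildReference()], or a
#'   [SpatialMapSet-class] of reference maps.
#' @param mask optional logical array forwarded to [etaSquared()].
#' @return data.frame with columns subject_id, rsn_label, eta_sq.
#' @export
similarityTable <- function(subjectMaps, reference, mask = NULL) {
  ref <- if (is(reference, "SpatialMapSet")) reference else reference$reference
  stopIfNot(is(ref, "SpatialMapSet"), "'reference' must hold a SpatialMapSet")
  labels <- networkLabels(ref)
  rows <- lapply(names(subjectMaps), function(sid) {
    sm <- subjectMaps[[sid]]
    eta <- vapply(labels, function(lab) {
      if (!lab %in% networkLabels(sm)) return(NA_real_)
      etaSquared(spatialMaps(sm, lab), spatialMaps(ref, lab), mask = mask)
    }, numeric(1))
    data.frame(subject_id = sid, rsn_label = labels, eta_sq = eta,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
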