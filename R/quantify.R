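#' Composite compound trajectory
#'
#' Result of combining several ridges annotated to one compound: each ridge
#' is rescaled so that all ridge means agree over the shared timepoint
#' support, then averaged per timepoint.
#'
#' @param compound compound name.
#' @param ridge_ids contributing ridge ids.
#' @param scale_factors per-ridge scale factor (highest-mean ridge gets 1).
#' @param support timepoint indices used for scaling.
#' @param times_h times of the composite values, hours.
#' @param value composite relative intensity per time.
#' @param n_contributing number of ridges contributing at each time.
#' @return An object of class `compound_trajectory`.
#' @export
new_compound_trajectory <- function(compound, ridge_ids, scale_factors,
                                    support, times_h, value, n_contributing) {
  structure(list(compound = compound, ridge_ids = ridge_ids,
                 scale_factors = scale_factors, support = support,
                 times_h = times_h, value = value,
                 n_contributing = n_contributing),
            class = "compound_trajectory")
}

#' @export
print.compound_trajectory <- function(x, ...) {
  cat(sprintf("<compound_trajectory %s> %d ridges, %d timepoints\n",
              x$compound, length(x$ridge_ids), length(x$times_h)))
  invisible(x)
}

ridge_time_indices <- function(ridge) ridge$points$time_index

#' Timepoints shared by the most ridges
#'
#' Counts, per timepoint, how many of the given ridges have a point there
#' and returns the timepoints attained by the maximal number of ridges (the
#' union over ties). This is the support on which ridge scale factors are
#' computed.
#'
#' @param ridges non-empty list of ridges.
#' @return Sorted integer vector of timepoint indices.
#' @export
shared_timepoints <- function(ridges) {
  assert_that(length(ridges) >= 1, "need at least one ridge",
              "civmtrace_empty_error")
  idx <- unlist(lapply(ridges, ridge_time_indices))
  counts <- table(idx)
  if (length(ridges) > 1 && max(counts) == 1)
    stop_civm("candidate ridges share no timepoints: cannot compute a common scaling support",
              "civmtrace_scaling_error")
  sort(as.integer(names(counts)[counts == max(counts)]))
}

#' Per-ridge scale factors over a shared support
#'
#' Computes the mean raw intensity of each ridge over the support
#' timepoints; each ridge's factor is the ratio of the highest of those
#' means to its own mean, so the highest-mean ridge keeps factor 1 and after
#' scaling all ridge means over the support are equal.
#'
#' @param ridges list of ridges.
#' @param support timepoint indices (from [shared_timepoints()]).
#' @return Numeric vector of scale factors, one per ridge.
#' @export
scale_factors <- function(ridges, support) {
  assert_that(length(support) >= 1, "empty support", "civmtrace_scaling_error")
  means <- vapply(seq_along(ridges), function(i) {
    p <- ridges[[i]]$points
    on_sup <- p$time_index %in% support
    if (!any(on_sup))
      stop_civm(sprintf("ridge %s has no points on the shared support",
                        ridges[[i]]$id), "civmtrace_scaling_error")
    mean(p$raw_intensity[on_sup])
  }, numeric(1))
  bad <- which(!is.finite(means) | means <= 0)
  if (length(bad))
    stop_civm(sprintf("nonpositive support mean for ridge %s",
                      ridges[[bad[1]]]$id), "civmtrace_scaling_error")
  max(means) / means
}

#' Combine scaled ridges into one compound trajectory
#'
#' At every timepoint attained by at least one ridge, the composite value is
#' the mean of the scaled ridge intensities present there. Timepoints
#' covered by no ridge are absent from the result; `n_contributing` exposes
#' partial coverage so low-support times can be masked downstream.
#'
#' @param ridges list of ridges annotated to one compound.
#' @param factors per-ridge scale factors, aligned with `ridges`
#'   (default: computed via [shared_timepoints()] + [scale_factors()]).
#' @param compound compound name; default taken from the first ridge's
#'   annotation.
#' @param include_interpolated logical; if `FALSE`, interpolated ridge
#'   points are excluded from the composite mean. Default `TRUE`.
#' @return A [new_compound_trajectory].
#' @export
composite_trajectory <- function(ridges, factors = NULL, compound = NULL,
                                 include_interpolated = TRUE) {
  assert_that(length(ridges) >= 1, "need at least one ridge",
              "civmtrace_empty_error")
  support <- shared_timepoints(ridges)
  if (is.null(factors)) factors <- scale_factors(ridges, support)
  assert_that(length(factors) == length(ridges),
              "one scale factor per ridge is required", "civmtrace_dim_error")
  compound <- compound %||% ridges[[1]]$annotation %||% "unknown"

  rows <- do.call(rbind, lapply(seq_along(ridges), function(i) {
    p <- ridges[[i]]$points
    if (!include_interpolated) p <- p[!p$interpolated, , drop = FALSE]
    data.frame(time_index = p$time_index, time_h = p$time_h,
               scaled = factors[i] * p$raw_intensity)
  }))
  by_t <- split(rows, rows$time_index)
  ti <- as.integer(names(by_t))
  ord <- order(ti)
  new_compound_trajectory(
    compound = compound,
    ridge_ids = vapply(ridges, `[[`, character(1), "id"),
    scale_factors = factors,
    support = support,
    times_h = unname(vapply(by_t, function(g) g$time_h[1], numeric(1))[ord]),
    value = unname(vapply(by_t, function(g) mean(g$scaled), numeric(1))[ord]),
    n_contributing = unname(vapply(by_t, nrow, integer(1))[ord])
  )
}

#' Composite trajectories for an annotation map
#'
#' Groups ridges by compound annotation and builds one composite trajectory
#' per compound.
#'
#' @param ridges list of ridges.
#' @param annotation named character vector or two-column data.frame
#'   (`ridge_id`, `compound`) mapping ridge ids to compound names;
#'   unannotated ridges are skipped.
#' @return Named list of [new_compound_trajectory] objects.
#' @export
quantify_compounds <- function(ridges, annotation) {
  if (is.data.frame(annotation))
    annotation <- stats::setNames(annotation$compound, annotation$ridge_id)
  ids <- vapply(ridges, `[[`, character(1), "id")
  ann <- annotation[ids]
  keep <- !is.na(ann)
  out <- lapply(split(ridges[keep], ann[keep]), function(rs) {
    rs <- lapply(rs, function(r) r)  # drop split attrs
    composite_trajectory(rs, compound = NULL)
  })
  for (nm in names(out)) out[[nm]]$compound <- nm
  out
}
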