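# Cohort morphometry: connected-component filtering of segmented volumes,
# bilateral (left/right) volume asymmetry, hemisphere symmetry, and
# cross-model consistency.

# 3D connected components of a binary mask via igraph.
# Returns list(idx = linear voxel indices (sorted), membership, n_components).
label_components <- function(mask, connectivity = 26) {
  if (inherits(mask, "label_volume")) mask <- mask$data
  d <- dim(mask)
  assert_that(length(d) == 3, "mask must be a 3D array")
  idx <- which(mask > 0)
  if (length(idx) == 0) return(list(idx = idx, membership = integer(0), n_components = 0L))
  Z <- d[1]; Y <- d[2]; X <- d[3]
  i0 <- idx - 1
  z <- i0 %% Z; rest <- i0 %/% Z; y <- rest %% Y; x <- rest %/% Y
  offsets <- switch(as.character(connectivity),
    `6` = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    `26` = {
      o <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
      o <- o[order(o$dx, o$dy, o$dz), ]
      o <- o[13 + 2:14, ]      # forward half of the 26-neighbourhood
      lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
    },
    stopf("connectivity must be 6 or 26"))
  edges <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    dzyx <- offsets[[k]]
    ok <- z + dzyx[1] >= 0 & z + dzyx[1] < Z &
          y + dzyx[2] >= 0 & y + dzyx[2] < Y &
          x + dzyx[3] >= 0 & x + dzyx[3] < X
    nidx <- idx[ok] + dzyx[1] + dzyx[2] * Z + dzyx[3] * Z * Y
    pos <- findInterval(nidx, idx)
    hit <- pos >= 1 & idx[pmax(pos, 1)] == nidx
    edges[[k]] <- rbind(which(ok)[hit], pos[hit])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(em)) g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)
  list(idx = idx, membership = comp$membership, n_components = comp$no)
}

#' Filter a segmented volume by its connected-component structure
#'
#' A segmentation of a bilateral structure is kept for volumetric analysis
#' only if it consists of exactly two closed 3D objects (26-connectivity)
#' and the larger does not exceed twice the volume of the second.
#'
#' @param mask binary [label_volume()] or 3D array.
#' @param connectivity 26 (default) or 6.
#' @return An object of class `filter_decision`: `n_components`, `volumes`
#'   (component voxel counts, sorted descending), `passed`.
#' @export
component_filter <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  vols <- if (lab$n_components == 0) numeric(0) else
    sort(as.numeric(tabulate(lab$membership, lab$n_components)), decreasing = TRUE)
  passed <- lab$n_components == 2 && vols[1] <= 2 * vols[2]
  structure(list(n_components = lab$n_components, volumes = vols,
                 passed = passed),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(sprintf("<filter: %d component(s) [%s] -> %s>\n", x$n_components,
              paste(x$volumes, collapse = ", "),
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Left/right volumes and signed percent difference of a bilateral structure
#'
#' The component whose X centroid lies left of the midline column is the
#' left structure.  The signed percent volume difference is
#' `100 * (V_R - V_L) / ((V_L + V_R) / 2)`; negative values indicate a
#' larger left structure.
#'
#' @param mask binary mask with exactly two components (it should have
#'   passed [component_filter()]).
#' @param midline_x 0-based pixel column of the sagittal midline.
#' @param voxel_size optional (dx, dy, dz) in micrometres; when given,
#'   volumes are also reported in cubic micrometres.
#' @param connectivity 26 (default) or 6.
#' @return An object of class `bilateral_volumes`: `v_left`, `v_right`
#'   (voxel counts), `percent_diff`, optional `v_left_um3`/`v_right_um3`,
#'   and `side_flag` (`TRUE` when both centroids fell on the same side and
#'   assignment fell back to relative order).
#' @export
bilateral_volumes <- function(mask, midline_x, voxel_size = NULL, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  assert_that(lab$n_components == 2,
              "expected exactly 2 components, found %d", lab$n_components)
  d <- if (inherits(mask, "label_volume")) dim(mask$data) else dim(mask)
  x_coord <- (lab$idx - 1) %/% (d[1] * d[2])    # 0-based X column
  cx <- tapply(x_coord, lab$membership, mean)
  vols <- tabulate(lab$membership, 2)
  side_flag <- FALSE
  left_of <- cx < midline_x
  if (sum(left_of) == 1) {
    v_left <- vols[which(left_of)]
    v_right <- vols[which(!left_of)]
  } else {
    warning("both component centroids on the same side of the midline; ",
            "assigning left/right by relative order")
    side_flag <- TRUE
    v_left <- vols[which.min(cx)]
    v_right <- vols[which.max(cx)]
  }
  pd <- 100 * (v_right - v_left) / ((v_left + v_right) / 2)
  out <- list(v_left = v_left, v_right = v_right, percent_diff = pd,
              side_flag = side_flag)
  if (!is.null(voxel_size)) {
    vv <- prod(voxel_size)
    out$v_left_um3 <- v_left * vv
    out$v_right_um3 <- v_right * vv
  }
  structure(out, class = "bilateral_volumes")
}

#' @export
print.bilateral_volumes <- function(x, ...) {
  cat(sprintf("<bilateral volumes: L %d, R %d, diff %+.2f%%>\n",
              x$v_left, x$v_right, x$percent_diff))
  invisible(x)
}

#' Signed percent volume difference between hemispheres
#'
#' The bilateral percent-difference formula applied to all mask voxels left
#' and right of the midline column (left = columns < `midline_x`).
#'
#' @param mask binary tissue mask ([label_volume()] or array).
#' @param midline_x 0-based midline column.
#' @return Signed percent difference (positive = right larger).
#' @export
hemisphere_difference <- function(mask, midline_x) {
  if (inherits(mask, "label_volume")) mask <- mask$data
  d <- dim(mask)
  assert_that(length(d) == 3, "mask must be a 3D array")
  idx <- which(mask > 0)
  x_coord <- (idx - 1) %/% (d[1] * d[2])
  v_left <- sum(x_coord < midline_x)
  v_right <- length(idx) - v_left
  assert_that(v_left > 0 && v_right > 0,
              "empty hemisphere (midline_x = %g): left %d, right %d voxels",
              midline_x, v_left, v_right)
  100 * (v_right - v_left) / ((v_left + v_right) / 2)
}

#' Summarize bilateral asymmetry over a cohort
#'
#' Counts and fraction of brains whose absolute percent volume difference
#' exceeds a threshold, with an optional valid-fraction extrapolation: when
#' a manually inspected sample shows validity rate `r` out of a population
#' of `N` filtered brains, the estimated valid count is
#' `N_hat = trunc(r * N)` and the reported exceedance fraction is
#' `k / N_hat` for `k` valid exceedances.
#'
#' @param results list of [bilateral_volumes()] or a numeric vector of
#'   signed percent differences.
#' @param threshold_pct exceedance threshold in percent (default 10).
#' @param validity_rate,population optional `r` and `N` for the
#'   extrapolation.
#' @param valid_exceed optional count of manually verified valid
#'   exceedances `k`; defaults to the observed exceedance count.
#' @return An object of class `cohort_summary`: `n`, `n_exceed`,
#'   `fraction_exceed`, `histogram` (a [hist()] object of signed percent
#'   differences), and when extrapolating, `n_valid_hat` and
#'   `extrapolated_fraction`.
#' @export
cohort_summary <- function(results, threshold_pct = 10,
                           validity_rate = NULL, population = NULL,
                           valid_exceed = NULL) {
  pd <- if (is.numeric(results)) results
        else vapply(results, function(r) r$percent_diff, numeric(1))
  assert_that(length(pd) >= 1, "empty cohort")
  n_exceed <- sum(abs(pd) > threshold_pct)
  out <- list(n = length(pd), threshold_pct = threshold_pct,
              n_exceed = n_exceed, fraction_exceed = n_exceed / length(pd),
              histogram = graphics::hist(pd, breaks = 30, plot = FALSE))
  if (!is.null(validity_rate) && !is.null(population)) {
    out$n_valid_hat <- trunc(validity_rate * population)
    k <- valid_exceed %||% n_exceed
    out$extrapolated_fraction <- k / out$n_valid_hat
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort of %d: %d (%.2f%%) exceed |diff| > %g%%\n",
              x$n, x$n_exceed, 100 * x$fraction_exceed, x$threshold_pct))
  if (!is.null(x$extrapolated_fraction))
    cat(sprintf("extrapolated: %.2f%% of %d estimated valid brains\n",
                100 * x$extrapolated_fraction, x$n_valid_hat))
  invisible(x)
}

#' Cross-model consistency of paired asymmetry estimates
#'
#' Ordinary least squares of model B's signed percent differences on model
#' A's, plus their Pearson correlation.  Slopes near 1 indicate that the
#' measured asymmetry is not a model-specific artifact.
#'
#' @param diffs_a,diffs_b equal-length paired numeric vectors (n >= 3).
#' @return List with `slope`, `intercept`, `correlation`, `n`.
#' @export
cross_model_consistency <- function(diffs_a, diffs_b) {
  assert_that(length(diffs_a) == length(diffs_b), "paired lists must have equal length")
  assert_that(length(diffs_a) >= 3, "need at least 3 pairs")
  assert_that(stats::var(diffs_a) > 0, "zero variance in diffs_a")
  fit <- stats::lm(diffs_b ~ diffs_a)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = stats::cor(diffs_a, diffs_b),
       n = length(diffs_a))
}
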