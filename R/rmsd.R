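# Rigid-body superposition and RMSD-based rigidity analysis.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired point sets.  Reflections are excluded:
#' the returned rotation always has determinant +1.
#'
#' The fitted mobile coordinates are `mobile %*% rotation + translation`
#' (rows are points).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3 and not
#'   collinear for a unique rotation.
#' @param weights optional non-negative n-vector of fitting weights.
#' @return list with `rotation` (3 x 3), `translation` (length-3) and
#'   `rmsd_after_fit` (Angstrom, weighted if weights given).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have identical dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  if (ncol(mobile) != 3L) stop("coordinates must be n x 3")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("weights must be a non-negative n-vector with positive sum")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  C <- t(X) %*% (Y * w)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- X %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R),
       rmsd_after_fit = rmsd)
}

# Plain (unfitted) RMSD between two coordinate matrices.
rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a trajectory against a reference
#'
#' @param traj an [md_trajectory].
#' @param reference a [pdb_structure], an n x 3 coordinate matrix on the
#'   full topology, or `NULL` for the first frame of `traj` (the default
#'   reference used throughout the package).
#' @param selection atom selection (see [select_atoms()]); default
#'   `"heavy"` — superposition and RMSD over non-hydrogen atoms.
#' @param fit superpose each frame on the reference before measuring?
#' @param run_id identifier stored in the result.
#' @return object of class `rmsd_series`: list with `run_id`, `values`
#'   (Angstrom, one per frame), `selection`, `fitted`.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = "heavy",
                        fit = TRUE, run_id = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) < 3L)
    stop("selection resolves to fewer than 3 atoms")
  ref_xyz <- if (is.null(reference)) {
    traj$frames[[1]]
  } else if (inherits(reference, "pdb_structure")) {
    if (nrow(reference$atoms) != nrow(traj$topology$atoms))
      stop("reference atom count does not match the trajectory topology")
    coords(reference)
  } else {
    as.matrix(reference)
  }
  ref_sel <- ref_xyz[idx, , drop = FALSE]
  values <- vapply(traj$frames, function(fr) {
    mob <- fr[idx, , drop = FALSE]
    if (fit) superpose(mob, ref_sel)$rmsd_after_fit
    else rmsd_between(mob, ref_sel)
  }, numeric(1))
  structure(list(run_id = run_id %||% traj$run_id, values = values,
                 selection = if (is.character(selection)) selection else "custom",
                 fitted = isTRUE(fit)),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series>%s %d frames, %s, %s: mean %.3f A, sd %.3f A\n",
              if (is.null(x$run_id)) "" else paste0(" run ", x$run_id),
              length(x$values), x$selection,
              if (x$fitted) "fitted" else "unfitted",
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Pooled RMSD histogram over replicate runs
#'
#' Bins all frames of all runs into fixed-width bins starting at 0, the
#' layout used to compare conformational spread between systems.
#'
#' @param series_list list of [rmsd_series] objects (>= 1).
#' @param bin_width bin width, Angstrom (> 0).
#' @return object of class `rmsd_histogram`: `bin_edges`, `counts`,
#'   `n_runs`.
#' @export
rmsd_histogram <- function(series_list, bin_width = 0.1) {
  if (inherits(series_list, "rmsd_series")) series_list <- list(series_list)
  if (!length(series_list)) stop("need at least one RMSD series")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  values <- unlist(lapply(series_list, `[[`, "values"))
  n_bins <- max(1L, ceiling(max(values) / bin_width + 1e-12))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  # right-open bins [a, b); the final edge is above every value
  bin <- findInterval(values, edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 n_runs = length(series_list)),
            class = "rmsd_histogram")
}

#' @export
print.rmsd_histogram <- function(x, ...) {
  cat(sprintf("<rmsd_histogram> %d bins of %.3g A, %d frames from %d runs\n",
              length(x$counts), diff(x$bin_edges[1:2]), sum(x$counts),
              x$n_runs))
  invisible(x)
}

#' @export
plot.rmsd_histogram <- function(x, main = "RMSD histogram", ...) {
  mids <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
  graphics::barplot(x$counts, names.arg = sprintf("%.2f", mids),
                    xlab = "RMSD (A)", ylab = "frames", main = main, ...)
  invisible(x)
}

#' Compare conformational rigidity between two groups of runs
#'
#' Pools all frames per group and compares mean and standard deviation of
#' the RMSD.  The variant group is called more rigid when both its pooled
#' mean and pooled sd are lower; when the sds tie (|difference| < 1e-12)
#' the verdict falls back to the means alone.
#'
#' @param wt,mut lists of [rmsd_series] for the wild-type and the
#'   substituted (mutant) systems.
#' @return object of class `rigidity_summary` with per-group `mean`, `sd`,
#'   `n_frames`, the `mean_difference` (mut - wt) and a `verdict` among
#'   `"mut_more_rigid"`, `"wt_more_rigid"`, `"inconclusive"`.
#' @export
rigidity_summary <- function(wt, mut) {
  if (inherits(wt, "rmsd_series")) wt <- list(wt)
  if (inherits(mut, "rmsd_series")) mut <- list(mut)
  if (!length(wt) || !length(mut)) stop("both groups must be non-empty")
  pool <- function(g) unlist(lapply(g, `[[`, "values"))
  vw <- pool(wt); vm <- pool(mut)
  mw <- mean(vw); mm <- mean(vm)
  sw <- stats::sd(vw); sm <- stats::sd(vm)
  sd_tie <- is.finite(sw) && is.finite(sm) && abs(sm - sw) < 1e-12
  verdict <- if (sd_tie) {
    if (mm < mw) "mut_more_rigid" else if (mw < mm) "wt_more_rigid"
    else "inconclusive"
  } else if (mm < mw && sm < sw) {
    "mut_more_rigid"
  } else if (mw < mm && sw < sm) {
    "wt_more_rigid"
  } else "inconclusive"
  structure(list(wt = list(mean = mw, sd = sw, n_frames = length(vw)),
                 mut = list(mean = mm, sd = sm, n_frames = length(vm)),
                 mean_difference = mm - mw, verdict = verdict),
            class = "rigidity_summary")
}

#' @export
print.rigidity_summary <- function(x, ...) {
  cat("<rigidity_summary>\n")
  cat(sprintf("  wild-type: mean %.4f A, sd %.4f A (%d frames)\n",
              x$wt$mean, x$wt$sd, x$wt$n_frames))
  cat(sprintf("  mutant:    mean %.4f A, sd %.4f A (%d frames)\n",
              x$mut$mean, x$mut$sd, x$mut$n_frames))
  cat(sprintf("  mean difference (mut - wt): %+.4f A -> %s\n",
              x$mean_difference, x$verdict))
  invisible(x)
}
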