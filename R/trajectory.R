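# Native-fold preservation diagnostics on C-alpha trajectories: RMSD series
# against a reference frame, the mutant-minus-native RMSD difference, and
# per-residue RMSF.

#' C-alpha trajectory
#'
#' @param frames list of n x 3 coordinate matrices (A), constant n.
#' @param times frame times, ps (default 0, 1, 2, ...).
#' @param label trajectory label.
#' @return object of class `ff_trajectory`.
#' @export
trajectory <- function(frames, times = seq_along(frames) - 1,
                       label = "trajectory") {
  if (!length(frames)) stop("trajectory needs at least one frame")
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == n))
    stop("inconsistent atom count across frames")
  stopifnot(length(times) == length(frames))
  structure(list(frames = frames, times = times, label = label,
                 n_particles = n),
            class = "ff_trajectory")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  cat(sprintf("<ff_trajectory> '%s': %d frames x %d particles\n",
              x$label, length(x$frames), x$n_particles))
  invisible(x)
}

#' Per-frame C-alpha RMSD against a reference
#'
#' Each frame is first optimally superposed on the reference (least-squares
#' rigid fit), removing rigid-body motion.
#'
#' @param traj an `ff_trajectory`.
#' @param reference n x 3 reference coordinates (default: first frame).
#' @param fit superpose before measuring (default TRUE).
#' @return numeric vector of RMSDs, A (one per frame).
#' @export
rmsd_series <- function(traj, reference = traj$frames[[1]], fit = TRUE) {
  if (nrow(reference) != traj$n_particles)
    stop("reference has ", nrow(reference), " particles, trajectory has ",
         traj$n_particles)
  vapply(traj$frames, function(f) {
    if (fit) kabsch_fit(f, reference)$rmsd else raw_rmsd(f, reference)
  }, numeric(1))
}

#' Mutant-minus-native RMSD difference
#'
#' delta_rmsd(t) = RMSD_mutant(t) - RMSD_native(t), element-wise over
#' matching frames. Exactly antisymmetric under argument swap.
#'
#' @param mutant_series,native_series equal-length RMSD series.
#' @return numeric vector of differences.
#' @export
delta_rmsd <- function(mutant_series, native_series) {
  if (length(mutant_series) != length(native_series))
    stop("series lengths differ (", length(mutant_series), " vs ",
         length(native_series), "); align the trajectories first")
  mutant_series - native_series
}

#' Per-residue fluctuation (RMSF)
#'
#' Mean squared deviation of each particle from its reference position over
#' the run: RMSF_i = (1/T) * sum_t (x_i(t) - x~_i)^2 (A^2); the reference
#' x~_i defaults to the time-average position. The square-root variant is
#' available behind `sqrt = TRUE`. Frames are superposed on the first frame
#' beforehand (disable with `fit = FALSE`) so rigid-body drift does not
#' masquerade as fluctuation.
#'
#' @param traj an `ff_trajectory` (>= 2 frames for a meaningful result).
#' @param reference "mean" or an n x 3 matrix of reference positions.
#' @param fit superpose frames on the first frame beforehand.
#' @param sqrt return the root variant, A.
#' @return numeric vector, one value per particle.
#' @export
rmsf <- function(traj, reference = "mean", fit = TRUE, sqrt = FALSE) {
  frames <- traj$frames
  if (length(frames) < 2 && identical(reference, "mean"))
    warning("single frame with mean reference: RMSF is identically zero")
  if (fit && length(frames) > 1) {
    ref0 <- frames[[1]]
    frames <- lapply(frames, function(f) kabsch_fit(f, ref0)$fitted)
  }
  arr <- simplify2array(frames)  # n x 3 x T
  xref <- if (identical(reference, "mean")) apply(arr, c(1, 2), mean)
          else reference
  # dev2 is n x 3 x T; per particle, mean over frames of squared distance
  dev2 <- sweep(arr, c(1, 2), xref)^2
  out <- rowMeans(apply(dev2, 3, rowSums))
  if (sqrt) base::sqrt(out) else out
}

#' Export per-frame and per-residue trajectory metrics as TSV
#' @param traj an `ff_trajectory`.
#' @param path output file.
#' @param reference reference frame for the RMSD series.
#' @export
write_trajectory_metrics <- function(traj, path,
                                     reference = traj$frames[[1]]) {
  r <- rmsd_series(traj, reference)
  f <- rmsf(traj)
  utils::write.table(
    data.frame(kind = c(rep("rmsd", length(r)), rep("rmsf", length(f))),
               index = c(seq_along(r), seq_along(f)),
               time_ps = c(traj$times, rep(NA, length(f))),
               value = c(r, f)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
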