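# Trial quality control: mechanises the visual discard rules for quiet
# standing (limb unloading, gross body shifts, short trials).

#' Default QC thresholds
#'
#' @param unload_share Paw-region load share below which a limb counts as
#'   unloaded (fraction of total load, default 0.05).
#' @param unload_dwell Minimum sustained unload duration, s (default 0.2).
#' @param shift_limit Maximum allowed CoP excursion from the trial median,
#'   cm (default 5).
#' @param min_duration Minimum trial duration, s (default 9).
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(unload_share = 0.05, unload_dwell = 0.2,
                          shift_limit = 5, min_duration = 9) {
  list(unload_share = unload_share, unload_dwell = unload_dwell,
       shift_limit = shift_limit, min_duration = min_duration)
}

#' Quality-control decision for one trial
#'
#' Rejects a trial when (a) any paw region's share of the total mat load
#' stays below `unload_share` for longer than `unload_dwell`
#' (`"limb_unload"`), (b) the plate CoP strays more than `shift_limit` from
#' the trial median position (`"body_shift"`), or (c) the recording is
#' shorter than `min_duration` (`"duration"`). Paw regions are found by
#' connected-component labelling of the time-averaged sensel loads (the four
#' largest components), mechanising what an operator spots visually on the
#' per-paw load display.
#'
#' @param recording A `trial_recording`.
#' @param thresholds A [qc_thresholds()] list.
#' @return A list `list(decision = "accept"|"reject", reason = NULL|string)`.
#' @export
qc_trial <- function(recording, thresholds = qc_thresholds()) {
  stopifnot(inherits(recording, "trial_recording"))
  th <- thresholds
  dur <- diff(range(recording$force$time))
  if (dur < th$min_duration) {
    return(list(decision = "reject", reason = "duration"))
  }
  # sustained paw-region unload on the mat; checked before the excursion
  # rule because a full unload also drags the CoP toward the loaded paws
  ps <- recording$pressure
  d <- dim(ps$frames)
  flat <- matrix(ps$frames, d[1] * d[2], d[3])
  mean_img <- matrix(rowMeans(flat), d[1], d[2])
  labels <- label_components(mean_img > 0.05 * max(mean_img))
  sizes <- tabulate(labels[labels > 0])
  regions <- order(sizes, decreasing = TRUE)[seq_len(min(4L, sum(sizes > 0)))]
  totals <- colSums(flat)
  frame_dt <- 1 / ps$spec$rate
  need <- ceiling(th$unload_dwell / frame_dt)
  for (r in regions) {
    share <- colSums(flat[as.vector(labels == r), , drop = FALSE]) / pmax(totals, .Machine$double.eps)
    if (longest_run(share < th$unload_share) > need) {
      return(list(decision = "reject", reason = "limb_unload"))
    }
  }
  # gross CoP excursion on the plate
  traj <- cop_from_forceplate(recording$force)
  dx <- traj$x_ap - stats::median(traj$x_ap)
  dy <- traj$y_ml - stats::median(traj$y_ml)
  if (max(sqrt(dx^2 + dy^2)) > th$shift_limit) {
    return(list(decision = "reject", reason = "body_shift"))
  }
  list(decision = "accept", reason = NULL)
}

# 4-connectivity component labelling of a logical matrix (iterative BFS).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (nb in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                   if (c > 1) p - nr, if (c < nc) p + nr)) {
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}
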