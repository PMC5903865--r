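#' Locomotor index of a 30-fps position trace
#'
#' A per-frame movement statistic over a 9-frame (~300 ms) window centered on
#' the frame. Two readings of the definition ship:
#' \describe{
#'   \item{`"coord-sd"` (default)}{pooled standard deviation of the x and y
#'     coordinates over the 9 frames — a smoothed representation of speed
#'     (zero only when the animal is still).}
#'   \item{`"diff-sd"`}{standard deviation of the 8 inter-frame displacement
#'     magnitudes — the literal frame-to-frame-difference reading, which is
#'     zero for perfectly uniform motion.}
#' }
#' The first 4 and last 4 frames have no defined window and get `NA`.
#'
#' @param trace A `tracking_trace` or a data frame with columns `t`, `x`,
#'   `y`.
#' @param method `"coord-sd"` or `"diff-sd"`.
#' @param half_width Window half-width in frames (default 4).
#' @return A `locomotor_series`: `t`, `li`, `fps`, `method`, `half_width`,
#'   `threshold` (NA until set).
#' @export
locomotor_index <- function(trace, method = c("coord-sd", "diff-sd"),
                            half_width = 4) {
  method <- match.arg(method)
  frames <- if (inherits(trace, "tracking_trace")) trace$frames else trace
  n <- nrow(frames)
  if (n < 2 * half_width + 1) stop("trace shorter than the LI window")
  if (any(!is.finite(frames$x)) || any(!is.finite(frames$y)))
    stop("missing coordinates inside the trace; interpolate upstream")
  x <- frames$x; y <- frames$y
  li <- rep(NA_real_, n)
  idx <- (half_width + 1):(n - half_width)
  if (method == "coord-sd") {
    for (i in idx) {
      w <- (i - half_width):(i + half_width)
      li[i] <- sqrt((sum((x[w] - mean(x[w]))^2) +
                       sum((y[w] - mean(y[w]))^2)) / (2 * length(w) - 2))
    }
  } else {
    d <- sqrt(diff(x)^2 + diff(y)^2)
    for (i in idx) {
      w <- (i - half_width):(i + half_width - 1)
      li[i] <- stats::sd(d[w])
    }
  }
  fps <- if (inherits(trace, "tracking_trace")) trace$fps else
    round(1 / stats::median(diff(frames$t)))
  structure(list(t = frames$t, li = li, fps = fps, method = method,
                 half_width = half_width, threshold = NA_real_),
            class = "locomotor_series")
}

# interior minimum of a two-component Gaussian mixture density between the
# component means (dense grid scan); NA when the minimum sits at an edge
mixture_interior_minimum <- function(means, sds, weights, n_grid = 4096) {
  o <- order(means)
  means <- means[o]; sds <- sds[o]; weights <- weights[o]
  grid <- seq(means[1], means[2], length.out = n_grid)
  dens <- weights[1] * stats::dnorm(grid, means[1], sds[1]) +
    weights[2] * stats::dnorm(grid, means[2], sds[2])
  i <- which.min(dens)
  if (i == 1 || i == n_grid) return(NA_real_)
  grid[i]
}

#' Still/moving threshold from the locomotor-index distribution
#'
#' Fits a two-component Gaussian mixture (unequal variances) to the defined
#' LI values and places the threshold at the mixture-density minimum strictly
#' between the two component means; frames below it are "still", above it
#' "moving". When the density has no interior minimum the midpoint of the
#' means is used; when the component means are closer than the smaller
#' component SD the distribution is treated as unimodal and no threshold is
#' returned.
#'
#' @param series A `locomotor_series` (needs >= 500 defined LI values).
#' @return The input series with `threshold` set (or `NA` with attribute
#'   `unimodal = TRUE`), plus `mixture` (means, sds, weights).
#' @export
movement_threshold <- function(series) {
  li <- series$li[!is.na(series$li)]
  if (length(li) < 500) stop("need at least 500 defined LI values")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(li, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  means <- fit$parameters$mean
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, 2)
  weights <- fit$parameters$pro
  series$mixture <- list(means = means, sds = sds, weights = weights)
  if (abs(diff(means)) < min(sds)) {
    series$threshold <- NA_real_
    attr(series, "unimodal") <- TRUE
    return(series)
  }
  thr <- mixture_interior_minimum(means, sds, weights)
  series$threshold <- if (is.na(thr)) mean(means) else thr
  series
}

#' Latency to movement onset after a cue
#'
#' Time from cue onset to the first following frame whose locomotor index
#' exceeds the still/moving threshold (event times mapped to frames by
#' nearest neighbor). Returns `NA` when no supra-threshold frame occurs
#' before `deadline`.
#'
#' @param series A `locomotor_series` with a defined threshold.
#' @param cue_onset Cue time, seconds.
#' @param deadline Latest time considered (e.g. the next cue onset); default
#'   end of trace.
#' @return Latency in seconds (>= 0) or `NA`.
#' @export
movement_onset_latency <- function(series, cue_onset, deadline = Inf) {
  if (is.na(series$threshold)) stop("series has no movement threshold")
  i0 <- which.min(abs(series$t - cue_onset))  # nearest-neighbor frame
  after <- which(series$t >= series$t[i0] & series$t <= deadline &
                   !is.na(series$li) & series$li > series$threshold)
  if (!length(after)) return(NA_real_)
  max(series$t[after[1]] - cue_onset, 0)
}

#' Per-trial approach-vigor covariates from tracking
#'
#' The three regressors of the vigor count model, measured from the position
#' trace: Euclidean distance from the receptacle at the cue-onset frame,
#' latency from cue onset to the frame of maximum speed, and average speed —
#' both computed over `[cue onset, receptacle entry)` for responded trials
#' and over the cue window otherwise. Speed is per-frame displacement times
#' fps. Gaps up to 3 frames are linearly interpolated; longer gaps yield
#' absent covariates.
#'
#' @param trace A `tracking_trace` or data frame (`t`, `x`, `y`).
#' @param cue_onset Cue onset, seconds.
#' @param end Window end, seconds (receptacle entry for responded trials,
#'   else cue offset).
#' @param receptacle_position Length-2 numeric, cm.
#' @return List with `distance`, `latency_max_speed`, `avg_speed` (all `NA`
#'   when the trace cannot cover the window).
#' @export
trial_vigor_covariates <- function(trace, cue_onset, end,
                                   receptacle_position = c(0, 0)) {
  frames <- if (inherits(trace, "tracking_trace")) trace$frames else trace
  fps <- round(1 / stats::median(diff(frames$t)))
  frames <- interpolate_gaps(frames, max_gap = 3)
  if (is.null(frames) || cue_onset < frames$t[1] || end > frames$t[nrow(frames)])
    return(list(distance = NA_real_, latency_max_speed = NA_real_,
                avg_speed = NA_real_))
  i0 <- which.min(abs(frames$t - cue_onset))
  sel <- which(frames$t >= cue_onset & frames$t < end)
  if (length(sel) < 2)
    return(list(distance = NA_real_, latency_max_speed = NA_real_,
                avg_speed = NA_real_))
  dx <- frames$x[i0] - receptacle_position[1]
  dy <- frames$y[i0] - receptacle_position[2]
  speed <- sqrt(diff(frames$x[sel])^2 + diff(frames$y[sel])^2) * fps
  list(distance = sqrt(dx^2 + dy^2),
       latency_max_speed = frames$t[sel[which.max(speed)]] - cue_onset,
       avg_speed = mean(speed))
}

interpolate_gaps <- function(frames, max_gap = 3) {
  miss <- !is.finite(frames$x) | !is.finite(frames$y)
  if (!any(miss)) return(frames)
  r <- rle(miss)
  if (any(r$values & r$lengths > max_gap)) return(NULL)
  ok <- which(!miss)
  frames$x <- stats::approx(frames$t[ok], frames$x[ok], xout = frames$t,
                            rule = 2)$y
  frames$y <- stats::approx(frames$t[ok], frames$y[ok], xout = frames$t,
                            rule = 2)$y
  frames
}
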