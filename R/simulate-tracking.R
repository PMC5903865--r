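#' Simulate a 30-fps position trace for a session
#'
#' The animal rests at a random position in the arena with Gaussian jitter;
#' on each responded trial it approaches the receptacle (at the origin) along
#' a straight line with a smooth bell-shaped speed profile, arriving at the
#' receptacle-entry time, stays there for the consumption epoch, then returns
#' to a fresh rest position. Per-trial ground-truth vigor covariates
#' (distance at cue onset, latency to maximum speed, average approach speed)
#' are recorded for every responded CS+ trial.
#'
#' Uses the ambient RNG; seed upstream for reproducibility.
#'
#' @param trials A `trial_table`.
#' @param session_length Session length, seconds.
#' @param fps Frame rate (default 30).
#' @param still_sd Per-coordinate jitter SD during stillness, cm.
#' @param min_distance,max_distance Range of rest-position distances from the
#'   receptacle, cm.
#' @param reaction_frac Fraction of the response latency spent still before
#'   movement onset.
#' @return A `tracking_trace`: data frame `frames` (`frame`, `t`, `x`, `y`),
#'   `fps`, and `covariates` — a data frame with one row per responded CS+
#'   trial (`trial`, `distance`, `latency_max_speed`, `avg_speed`).
#' @export
simulate_tracking <- function(trials, session_length, fps = 30,
                              still_sd = 0.05, min_distance = 8,
                              max_distance = 30, reaction_frac = 0.2) {
  t <- seq(0, session_length, by = 1 / fps)
  nf <- length(t)
  x <- numeric(nf); y <- numeric(nf)

  rest_pos <- function() {
    ang <- stats::runif(1, 0, 2 * pi)
    d <- stats::runif(1, min_distance, max_distance)
    c(cos(ang), sin(ang)) * d
  }
  # smoothstep easing: speed is bell-shaped, max at the midpoint
  ease <- function(u) 3 * u^2 - 2 * u^3

  pos <- rest_pos()
  seg_from <- 1
  cov_rows <- list()

  resp <- trials[trials$responded, , drop = FALSE]
  resp <- resp[order(resp$cue_onset), , drop = FALSE]
  for (i in seq_len(nrow(resp))) {
    onset <- resp$cue_onset[i]
    entry <- onset + resp$response_latency[i]
    move_start <- onset + reaction_frac * resp$response_latency[i]
    exit <- if (!is.na(resp$rewarded_entry_time[i])) {
      e <- resp$cue_off[i] + 3  # lower bound; refined below if exit known
      e
    } else entry + 1
    if (entry > session_length) break
    i_still_end <- max(seg_from, min(nf, floor(move_start * fps) + 1))
    idx <- seg_from:i_still_end
    x[idx] <- pos[1]; y[idx] <- pos[2]
    i_entry <- min(nf, floor(entry * fps) + 1)
    if (i_entry > i_still_end) {
      idx <- (i_still_end + 1):i_entry
      u <- (t[idx] - move_start) / (entry - move_start)
      u <- pmin(pmax(u, 0), 1)
      s <- ease(u)
      x[idx] <- pos[1] * (1 - s); y[idx] <- pos[2] * (1 - s)
    }
    i_exit <- min(nf, floor(min(exit, session_length) * fps) + 1)
    if (i_exit > i_entry) { idx <- (i_entry + 1):i_exit; x[idx] <- 0; y[idx] <- 0 }
    d <- sqrt(sum(pos^2))
    if (resp$cue_type[i] == "cs_plus") {
      cov_rows[[length(cov_rows) + 1]] <- data.frame(
        trial = resp$trial[i], distance = d,
        latency_max_speed = (move_start - onset) + 0.5 * (entry - move_start),
        avg_speed = d / (entry - onset))
    }
    pos <- rest_pos()
    seg_from <- i_exit + 1
    if (seg_from > nf) break
  }
  if (seg_from <= nf) { idx <- seg_from:nf; x[idx] <- pos[1]; y[idx] <- pos[2] }
  x <- x + stats::rnorm(nf, 0, still_sd)
  y <- y + stats::rnorm(nf, 0, still_sd)
  covariates <- if (length(cov_rows)) do.call(rbind, cov_rows) else
    data.frame(trial = integer(0), distance = numeric(0),
               latency_max_speed = numeric(0), avg_speed = numeric(0))
  structure(list(frames = data.frame(frame = seq_len(nf) - 1L, t = t,
                                     x = x, y = y),
                 fps = fps, covariates = covariates),
            class = "tracking_trace")
}
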