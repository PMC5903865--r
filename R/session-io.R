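#' Write / read a session to delimited files
#'
#' A session directory holds UTF-8 tab-delimited files with one header line:
#' \describe{
#'   \item{events.tsv}{`time`, `kind`, `detail`}
#'   \item{spikes.tsv}{`unit_id`, `time`}
#'   \item{units.tsv}{`unit_id`, `amplitude_uV`, `hemisphere`,
#'     `drug_exposure`, `state`}
#'   \item{tracking.tsv}{`frame`, `t`, `x`, `y` (optional)}
#'   \item{config.tsv}{`key`, `value` — task and behavior parameters}
#' }
#' `read_session` validates the schema and event structure (every cue onset
#' must be followed by a `cue_off` within the cue duration) and rebuilds the
#' trial table, so `write_session` then `read_session` round-trips the
#' recorded data exactly.
#'
#' @param bundle A `session_bundle`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_session` returns `dir` invisibly; `read_session` returns a
#'   `session_bundle` (without ground-truth profiles/covariates).
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  wt(format_num(as.data.frame(bundle$events), "time"), "events.tsv")
  spikes <- do.call(rbind, lapply(bundle$units, function(u)
    if (length(u$times)) data.frame(unit_id = u$unit_id, time = u$times) else
      NULL))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), time = numeric(0))
  wt(format_num(spikes, "time"), "spikes.tsv")
  units_meta <- do.call(rbind, lapply(bundle$units, function(u)
    data.frame(unit_id = u$unit_id, amplitude_uV = u$amplitude_uV,
               hemisphere = u$hemisphere, drug_exposure = u$drug_exposure,
               state = u$state)))
  wt(units_meta, "units.tsv")
  if (!is.null(bundle$tracking))
    wt(format_num(bundle$tracking$frames, c("t", "x", "y")), "tracking.tsv")
  cfg <- c(session_length = bundle$config$session_length,
           cue_duration = bundle$config$cue_duration,
           state = bundle$behavior$state,
           infusion_start = if (is.null(bundle$infusion)) NA else bundle$infusion[1],
           infusion_end = if (is.null(bundle$infusion)) NA else bundle$infusion[2])
  wt(data.frame(key = names(cfg), value = unname(cfg)), "config.tsv")
  invisible(dir)
}

format_num <- function(df, cols) {
  # 17 significant digits round-trips IEEE doubles exactly
  for (c in cols) df[[c]] <- formatC(df[[c]], digits = 17, format = "g")
  df
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")))
  df
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  ev <- read_tsv_checked(file.path(dir, "events.tsv"),
                         c("time", "kind", "detail"))
  bad <- !ev$kind %in% event_kinds()
  if (any(bad))
    stop(sprintf("events.tsv line %d: unknown event kind '%s'",
                 which(bad)[1] + 1L, ev$kind[which(bad)[1]]))
  cfg_df <- read_tsv_checked(file.path(dir, "config.tsv"), c("key", "value"))
  cfg <- stats::setNames(cfg_df$value, cfg_df$key)
  cue_duration <- as.numeric(cfg[["cue_duration"]])
  events <- new_event_log(ev$time, ev$kind, ev$detail)
  validate_event_log(events, cue_duration)

  sp <- read_tsv_checked(file.path(dir, "spikes.tsv"), c("unit_id", "time"))
  um <- read_tsv_checked(file.path(dir, "units.tsv"),
                         c("unit_id", "amplitude_uV", "hemisphere",
                           "drug_exposure", "state"))
  units <- lapply(seq_len(nrow(um)), function(i) {
    times <- sort(sp$time[sp$unit_id == um$unit_id[i]])
    spike_train(um$unit_id[i], times, um$amplitude_uV[i], um$hemisphere[i],
                um$drug_exposure[i], um$state[i])
  })
  trace <- NULL
  tpath <- file.path(dir, "tracking.tsv")
  if (file.exists(tpath)) {
    tr <- read_tsv_checked(tpath, c("frame", "t", "x", "y"))
    fps <- if (nrow(tr) > 1) round(1 / stats::median(diff(tr$t))) else 30
    trace <- structure(list(frames = tr, fps = fps, covariates = NULL),
                       class = "tracking_trace")
  }
  infusion <- if (!is.na(cfg[["infusion_start"]]))
    as.numeric(c(cfg[["infusion_start"]], cfg[["infusion_end"]])) else NULL
  trials <- build_trial_table(events, cue_duration)
  structure(list(events = events, trials = trials, units = units,
                 profiles = NULL, covariates = NULL, tracking = trace,
                 config = task_config(
                   session_length = as.numeric(cfg[["session_length"]]),
                   cue_duration = cue_duration),
                 behavior = behavior_model(cfg[["state"]]),
                 infusion = infusion),
            class = "session_bundle")
}

validate_event_log <- function(events, cue_duration) {
  onsets <- which(events$kind %in% c("cs_plus_on", "cs_minus_on"))
  offs <- events$time[events$kind == "cue_off"]
  for (i in onsets) {
    t0 <- events$time[i]
    if (!any(offs > t0 & offs <= t0 + cue_duration + 1e-9))
      stop(sprintf(
        "events.tsv: cue onset at t=%g has no cue_off within %g s", t0,
        cue_duration))
  }
  invisible(events)
}
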