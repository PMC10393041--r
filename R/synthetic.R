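#' Specify a synthetic CGM cohort
#'
#' Describes a cohort of T1DM and T2DM patients monitored by CGM sensors at a
#' fixed resolution, with record lengths drawn independently from a range.
#' Defaults emulate the structure reported for a two-hospital CGM cohort:
#' a small T1DM group and a large, more volatile T2DM group, 15-minute
#' resolution, lengths between 247 and 1339 points.
#'
#' @param n_t1dm,n_t2dm Number of T1DM / T2DM records.
#' @param length_range Integer vector `c(min, max)` of record lengths (points).
#' @param resolution_minutes Sampling resolution in minutes.
#' @param glucose_floor,glucose_ceiling Physical sensor bounds, mg/dL.
#' @param baseline_t1dm,baseline_t2dm Mean baseline glucose per type, mg/dL.
#' @param volatility_t1dm,volatility_t2dm AR(1) innovation scale per type, mg/dL.
#' @param meal_spike_rate Expected postprandial spike events per day.
#' @param seed Integer RNG seed; fixed seed gives a bit-identical cohort.
#' @return A `cgm_cohort_spec` object.
#' @export
cohort_spec <- function(n_t1dm = 12L, n_t2dm = 100L,
                        length_range = c(247L, 1339L),
                        resolution_minutes = 15L,
                        glucose_floor = 40, glucose_ceiling = 400,
                        baseline_t1dm = 120, baseline_t2dm = 150,
                        volatility_t1dm = 6, volatility_t2dm = 12,
                        meal_spike_rate = 3, seed = 1L) {
  spec <- list(
    n_t1dm = as.integer(n_t1dm), n_t2dm = as.integer(n_t2dm),
    length_range = as.integer(length_range),
    resolution_minutes = as.integer(resolution_minutes),
    glucose_floor = glucose_floor, glucose_ceiling = glucose_ceiling,
    baseline_t1dm = baseline_t1dm, baseline_t2dm = baseline_t2dm,
    volatility_t1dm = volatility_t1dm, volatility_t2dm = volatility_t2dm,
    meal_spike_rate = meal_spike_rate, seed = as.integer(seed)
  )
  class(spec) <- "cgm_cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cgm_cohort_spec"))
  if (spec$n_t1dm < 0L || spec$n_t2dm < 0L || spec$n_t1dm + spec$n_t2dm < 1L)
    stop("cohort_spec: need at least one record", call. = FALSE)
  if (length(spec$length_range) != 2L || spec$length_range[1] < 2L ||
      spec$length_range[2] < spec$length_range[1])
    stop("cohort_spec: length_range must be c(min >= 2, max >= min)", call. = FALSE)
  if (spec$resolution_minutes < 1L)
    stop("cohort_spec: resolution_minutes must be positive", call. = FALSE)
  if (!(spec$glucose_floor > 0) || !(spec$glucose_ceiling > spec$glucose_floor))
    stop("cohort_spec: need ceiling > floor > 0", call. = FALSE)
  if (spec$volatility_t1dm < 0 || spec$volatility_t2dm < 0)
    stop("cohort_spec: volatility must be >= 0", call. = FALSE)
  if (spec$meal_spike_rate < 0)
    stop("cohort_spec: meal_spike_rate must be >= 0", call. = FALSE)
  invisible(spec)
}

#' Construct a CGM record
#'
#' @param patient_id Character id.
#' @param diabetes_type `"T1DM"` or `"T2DM"`.
#' @param values Numeric glucose series, mg/dL, at fixed spacing.
#' @param start_time POSIXct start of monitoring.
#' @param resolution_minutes Sampling resolution, minutes.
#' @return A `cgm_record` object.
#' @export
cgm_record <- function(patient_id, diabetes_type, values,
                       start_time = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                       resolution_minutes = 15L) {
  diabetes_type <- match.arg(diabetes_type, c("T1DM", "T2DM"))
  if (length(values) < 2L) stop("cgm_record: need at least 2 points", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 diabetes_type = diabetes_type,
                 values = as.numeric(values),
                 start_time = start_time,
                 resolution_minutes = as.integer(resolution_minutes)),
            class = "cgm_record")
}

#' @export
print.cgm_record <- function(x, ...) {
  cat(sprintf("<cgm_record %s [%s], %d points @ %d min, %.0f-%.0f mg/dL>\n",
              x$patient_id, x$diabetes_type, length(x$values),
              x$resolution_minutes, min(x$values), max(x$values)))
  invisible(x)
}

# One synthetic trace: per-patient baseline + 24 h circadian sinusoid +
# Poisson-timed postprandial spikes with exponential decay + AR(1) noise,
# clipped to the sensor range. T2DM additionally drifts slowly.
simulate_trace <- function(len, type, spec) {
  steps_per_day <- (24 * 60) %/% spec$resolution_minutes
  baseline_mu <- if (type == "T1DM") spec$baseline_t1dm else spec$baseline_t2dm
  vol <- if (type == "T1DM") spec$volatility_t1dm else spec$volatility_t2dm
  baseline <- rnorm(1, baseline_mu, 15)
  phase <- runif(1, 0, 2 * pi)
  amp <- runif(1, 10, 30)
  t <- seq_len(len)
  circadian <- amp * sin(2 * pi * t / steps_per_day + phase)

  n_days <- len / steps_per_day
  n_spikes <- rpois(1, spec$meal_spike_rate * n_days)
  spikes <- numeric(len)
  if (n_spikes > 0) {
    onset <- sample.int(len, n_spikes, replace = TRUE)
    height <- runif(n_spikes, 30, 90)
    decay <- runif(n_spikes, 0.85, 0.95)  # per-step decay ~ 1-2 h half-life
    for (k in seq_len(n_spikes)) {
      idx <- onset[k]:len
      spikes[idx] <- spikes[idx] + height[k] * decay[k]^(idx - onset[k])
    }
  }

  ar <- numeric(len)
  innov <- rnorm(len, 0, vol)
  ar[1] <- innov[1]
  for (i in 2:len) ar[i] <- 0.8 * ar[i - 1] + innov[i]

  drift <- if (type == "T2DM") {
    cumsum(rnorm(len, 0, vol / 50))
  } else 0

  pmin(pmax(baseline + circadian + spikes + ar + drift, spec$glucose_floor),
       spec$glucose_ceiling)
}

#' Simulate a heterogeneous CGM cohort
#'
#' Generates `n_t1dm + n_t2dm` records with lengths drawn independently and
#' uniformly from `length_range`. Each trace is a per-patient baseline plus a
#' 24-hour circadian sinusoid, randomly timed postprandial spikes with
#' exponential decay, and AR(1) noise whose innovation scale is type-specific
#' (T2DM more volatile); T2DM records carry an additional slow random-walk
#' drift. Values are clipped to the sensor range.
#'
#' @param spec A [cohort_spec()].
#' @return List of [cgm_record()] objects (T1DM first).
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  withr::with_seed(spec$seed, {
    types <- c(rep("T1DM", spec$n_t1dm), rep("T2DM", spec$n_t2dm))
    ids <- c(sprintf("t1dm_%03d", seq_len(spec$n_t1dm)),
             sprintf("t2dm_%03d", seq_len(spec$n_t2dm)))
    lens <- sample(spec$length_range[1]:spec$length_range[2],
                   length(types), replace = TRUE)
    lapply(seq_along(types), function(i) {
      cgm_record(ids[i], types[i],
                 simulate_trace(lens[i], types[i], spec),
                 resolution_minutes = spec$resolution_minutes)
    })
  })
}

#' Summarize a cohort
#'
#' @param records Non-empty list of [cgm_record()] objects.
#' @return data.frame with one row per diabetes type: count and min/mean/max
#'   record length.
#' @export
cohort_summary <- function(records) {
  if (length(records) == 0L) stop("cohort_summary: empty cohort", call. = FALSE)
  type <- vapply(records, function(r) r$diabetes_type, character(1))
  len <- vapply(records, function(r) length(r$values), integer(1))
  out <- do.call(rbind, lapply(split(len, type), function(l) {
    data.frame(n = length(l), min_length = min(l),
               mean_length = mean(l), max_length = max(l))
  }))
  out <- cbind(diabetes_type = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as long-format CSV
#'
#' Long format columns: `patient_id, diabetes_type, timestamp, glucose_mg_dl`.
#' A `# key: value` metadata header carries tool version and resolution.
#'
#' @param records List of [cgm_record()] objects.
#' @param path CSV file path.
#' @return `write_cohort_csv`: the path, invisibly. `read_cohort_csv`: list of
#'   [cgm_record()] objects.
#' @export
write_cohort_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    ts <- r$start_time + (seq_along(r$values) - 1) * r$resolution_minutes * 60
    data.frame(patient_id = r$patient_id, diabetes_type = r$diabetes_type,
               timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               glucose_mg_dl = r$values)
  }))
  res <- records[[1]]$resolution_minutes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(artifact_header(), sprintf("# resolution_minutes: %d", res)), con)
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("patient_id", "diabetes_type", "timestamp", "glucose_mg_dl")
  if (!all(needed %in% names(df)))
    stop("read_cohort_csv: missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  lapply(split(df, factor(df$patient_id, levels = unique(df$patient_id))),
         function(d) {
           ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
           res <- if (nrow(d) > 1) as.integer(round(diff(as.numeric(ts[1:2])) / 60)) else 15L
           cgm_record(d$patient_id[1], d$diabetes_type[1], d$glucose_mg_dl,
                      start_time = ts[1], resolution_minutes = res)
         })
}

artifact_header <- function(extra = character()) {
  c(sprintf("# tool: hetercgm %s",
            as.character(utils::packageVersion("hetercgm"))), extra)
}
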