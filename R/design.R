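# Factorial experiment layout: drought levels x salinity levels x
# replicates, each pot sampled repeatedly at fixed intervals.

#' Define a factorial stress experiment design
#'
#' Describes a greenhouse experiment in which every combination of a
#' drought level and a salinity level is grown in `replicates` pots and
#' each pot is sampled `time_points` times at `sampling_interval_days`-day
#' intervals. The default is the 4 x 4 x 3 design with 5 sampling dates
#' (48 pots, 240 records) used for the cucumber stress dataset.
#'
#' Severity is encoded as the integer level index 0..3 (`W0`/`S0` are the
#' unstressed controls; salinity levels nominally correspond to 0/20/40/60
#' mM NaCl and drought levels to watering at 100/80/60/40% of field
#' capacity). Pots are enumerated deterministically with drought level as
#' the outermost factor, then salinity level, then replicate; records are
#' pots crossed with time points, time point innermost.
#'
#' @param drought_levels Character vector of ordered drought level labels;
#'   severity is the position minus one.
#' @param salinity_levels Character vector of ordered salinity level labels.
#' @param replicates Positive integer, pots per treatment combination.
#' @param time_points Positive integer, sampling dates per pot.
#' @param sampling_interval_days Positive number, days between samplings.
#' @return An object of class `stress_design`: a list with the level
#'   labels, a `pots` data frame (`pot_id`, `drought_level`, `drought`,
#'   `salinity_level`, `salinity`, `replicate`) and a `records` data frame
#'   (pots crossed with `time_point`).
#' @export
#' @examples
#' d <- stress_design()
#' d$n_pots     # 48
#' d$n_records  # 240
stress_design <- function(drought_levels = paste0("W", 0:3),
                          salinity_levels = paste0("S", 0:3),
                          replicates = 3,
                          time_points = 5,
                          sampling_interval_days = 3) {
  if (length(drought_levels) < 1L || length(salinity_levels) < 1L)
    stop("invalid design: need at least one drought and one salinity level")
  if (anyDuplicated(drought_levels) || anyDuplicated(salinity_levels))
    stop("invalid design: level labels must be unique")
  replicates <- as.integer(replicates)
  time_points <- as.integer(time_points)
  if (is.na(replicates) || replicates < 1L)
    stop("invalid design: 'replicates' must be a positive integer")
  if (is.na(time_points) || time_points < 1L)
    stop("invalid design: 'time_points' must be a positive integer")
  if (!is.numeric(sampling_interval_days) || sampling_interval_days <= 0)
    stop("invalid design: 'sampling_interval_days' must be positive")

  nw <- length(drought_levels); ns <- length(salinity_levels)
  pots <- expand.grid(replicate = seq_len(replicates),
                      salinity = seq_len(ns) - 1L,
                      drought = seq_len(nw) - 1L,
                      KEEP.OUT.ATTRS = FALSE)
  # reorder columns: drought outermost in enumeration
  pots <- pots[, c("drought", "salinity", "replicate")]
  pots <- pots[order(pots$drought, pots$salinity, pots$replicate), ,
               drop = FALSE]
  rownames(pots) <- NULL
  pots$drought_level <- drought_levels[pots$drought + 1L]
  pots$salinity_level <- salinity_levels[pots$salinity + 1L]
  pots$pot_id <- sprintf("P%03d", seq_len(nrow(pots)))
  pots <- pots[, c("pot_id", "drought_level", "drought",
                   "salinity_level", "salinity", "replicate")]

  records <- pots[rep(seq_len(nrow(pots)), each = time_points), , drop = FALSE]
  records$time_point <- rep(seq_len(time_points), times = nrow(pots))
  records$day <- (records$time_point - 1L) * sampling_interval_days
  rownames(records) <- NULL

  structure(list(
    drought_levels = drought_levels,
    salinity_levels = salinity_levels,
    replicates = replicates,
    time_points = time_points,
    sampling_interval_days = sampling_interval_days,
    pots = pots,
    records = records,
    n_pots = nrow(pots),
    n_records = nrow(records)
  ), class = "stress_design")
}

#' @export
print.stress_design <- function(x, ...) {
  cat("Factorial stress design\n")
  cat(sprintf("  drought levels : %s\n", paste(x$drought_levels, collapse = " ")))
  cat(sprintf("  salinity levels: %s\n", paste(x$salinity_levels, collapse = " ")))
  cat(sprintf("  replicates     : %d\n", x$replicates))
  cat(sprintf("  time points    : %d (every %g days)\n",
              x$time_points, x$sampling_interval_days))
  cat(sprintf("  pots = %d, records = %d\n", x$n_pots, x$n_records))
  invisible(x)
}
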