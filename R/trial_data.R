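# Data model and I/O for per-trial choice logs.
#
# A trial is one T-maze passage: a choice between the left and right arm,
# one of which holds the higher-value solution ("high side"). Bottle swaps
# define sessions: maximal runs of constant high side.

#' Construct a single-animal choice record
#'
#' Bundles one animal's ordered trial sequence with its session table and
#' observation metadata. Sessions are reconstructed from maximal runs of
#' constant `high_side` unless an explicit session table (carrying reward
#' values) is supplied.
#'
#' @param mouse_id character scalar.
#' @param trials data.frame with columns `index` (1-based, strictly
#'   increasing), `session_id`, `chosen_side` and `high_side` (both `"L"` or
#'   `"R"`). An `outcome_label` column (`"high"` when the chosen side is the
#'   high side, else `"low"`) is derived.
#' @param sessions optional data.frame with columns `session_id`,
#'   `high_side`, `value_low`, `value_high`; defaults to runs of
#'   `trials$high_side` with water/sucrose values 1 and 3.
#' @param days_observed positive number of days the animal was observed
#'   (used by [filter_by_trial_rate()]).
#' @param value_low,value_high default reward values used when `sessions`
#'   is reconstructed.
#' @return an object of class `mouse_record`.
#' @export
mouse_record <- function(mouse_id, trials, sessions = NULL,
                         days_observed = NA_real_,
                         value_low = 1, value_high = 3) {
  stopifnot(is.character(mouse_id), length(mouse_id) == 1L)
  trials <- as.data.frame(trials)
  req <- c("index", "session_id", "chosen_side", "high_side")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop2("trials is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(trials)) {
    bad <- which(!(trials$chosen_side %in% .sides) | !(trials$high_side %in% .sides))
    if (length(bad)) stop2("unknown side code in trials of '", mouse_id,
                           "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    if (any(diff(trials$index) <= 0))
      stop2("trial index not strictly increasing for '", mouse_id, "'")
    hs_per_sess <- tapply(trials$high_side, trials$session_id,
                          function(x) length(unique(x)))
    if (any(hs_per_sess > 1))
      stop2("high_side not constant within a session for '", mouse_id, "'")
  }
  trials$outcome_label <- ifelse(trials$chosen_side == trials$high_side, "high", "low")
  if (is.null(sessions)) {
    sessions <- .sessions_from_trials(trials, value_low, value_high)
  } else {
    sessions <- as.data.frame(sessions)
    sreq <- c("session_id", "high_side", "value_low", "value_high")
    smiss <- setdiff(sreq, names(sessions))
    if (length(smiss)) stop2("sessions is missing column(s): ", paste(smiss, collapse = ", "))
    if (!all(trials$session_id %in% sessions$session_id))
      stop2("trial session_id missing from session table for '", mouse_id, "'")
    nt <- table(factor(trials$session_id, levels = sessions$session_id))
    sessions$n_trials <- as.integer(nt)
  }
  structure(list(mouse_id = mouse_id, trials = trials, sessions = sessions,
                 days_observed = as.numeric(days_observed)),
            class = "mouse_record")
}

.sessions_from_trials <- function(trials, value_low = 1, value_high = 3) {
  if (!nrow(trials)) {
    return(data.frame(session_id = integer(), high_side = character(),
                      value_low = numeric(), value_high = numeric(),
                      n_trials = integer(), stringsAsFactors = FALSE))
  }
  ids <- unique(trials$session_id)
  data.frame(
    session_id = ids,
    high_side = trials$high_side[match(ids, trials$session_id)],
    value_low = value_low, value_high = value_high,
    n_trials = as.integer(table(factor(trials$session_id, levels = ids))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mouse_record <- function(x, ...) {
  cat("<mouse_record>", x$mouse_id, "-", nrow(x$trials), "trials in",
      nrow(x$sessions), "sessions;", "days_observed =", x$days_observed, "\n")
  invisible(x)
}

#' Construct a cohort of choice records
#'
#' @param records list of [mouse_record()] objects with unique ids.
#' @param group_id optional character label.
#' @return an object of class `cohort` (a named list of records).
#' @export
cohort <- function(records, group_id = NULL) {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$mouse_id, character(1))
  if (anyDuplicated(ids)) stop2("duplicate mouse_id in cohort: ",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(records) <- ids
  structure(list(records = records, group_id = group_id), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x$records), "mice",
      if (!is.null(x$group_id)) paste0("(group ", x$group_id, ")"), "\n")
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$records)

#' Read a trial log from delimited text
#'
#' Expected columns: `mouse_id`, `trial_index`, `session_id`, `chosen_side`,
#' `high_side`; optional `days_observed`, `value_low`, `value_high`
#' (repeated per row) and `timestamp`. Sides are coded `L`/`R`.
#'
#' @param path file path.
#' @param sep field separator; comma by default, tab accepted.
#' @return a [cohort()].
#' @export
read_trial_log <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("mouse_id", "trial_index", "session_id", "chosen_side", "high_side")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop2("trial log is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(df$chosen_side %in% .sides) | !(df$high_side %in% .sides))
  if (length(bad)) stop2("unknown side code at data row(s) ",
                         paste(utils::head(bad, 5), collapse = ", "), " of ", path)
  recs <- lapply(split(df, factor(df$mouse_id, levels = unique(df$mouse_id))),
                 function(d) {
    d <- d[order(d$trial_index), , drop = FALSE]
    trials <- data.frame(index = d$trial_index, session_id = d$session_id,
                         chosen_side = d$chosen_side, high_side = d$high_side,
                         stringsAsFactors = FALSE)
    vlo <- if ("value_low" %in% names(d)) d$value_low[1] else 1
    vhi <- if ("value_high" %in% names(d)) d$value_high[1] else 3
    mouse_record(d$mouse_id[1], trials,
                 days_observed = if ("days_observed" %in% names(d))
                   d$days_observed[1] else NA_real_,
                 value_low = vlo, value_high = vhi)
  })
  cohort(unname(recs))
}

#' Write a cohort to a delimited trial log
#'
#' Inverse of [read_trial_log()]: `read_trial_log(write_trial_log(x, p))`
#' reproduces `x` field for field.
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(x$records, function(r) {
    if (!nrow(r$trials)) return(NULL)
    vlo <- r$sessions$value_low[match(r$trials$session_id, r$sessions$session_id)]
    vhi <- r$sessions$value_high[match(r$trials$session_id, r$sessions$session_id)]
    data.frame(mouse_id = r$mouse_id, trial_index = r$trials$index,
               session_id = r$trials$session_id,
               chosen_side = r$trials$chosen_side, high_side = r$trials$high_side,
               days_observed = r$days_observed,
               value_low = vlo, value_high = vhi, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(mouse_id = character(), trial_index = integer(),
                     session_id = integer(), chosen_side = character(),
                     high_side = character(), days_observed = numeric(),
                     value_low = numeric(), value_high = numeric())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep animals exceeding a trials-per-day threshold
#'
#' Inclusion rule for T-maze analyses: an animal is retained when its total
#' trial count divided by days observed is strictly greater than
#' `min_trials_per_day` (default 5/day).
#'
#' @param x a [cohort()].
#' @param min_trials_per_day strict lower bound on trials/day.
#' @return a filtered [cohort()]; the input is unmodified.
#' @export
filter_by_trial_rate <- function(x, min_trials_per_day = 5) {
  stopifnot(inherits(x, "cohort"))
  keep <- vapply(x$records, function(r) {
    if (is.na(r$days_observed) || r$days_observed <= 0)
      stop2("days_observed must be > 0 for '", r$mouse_id, "'")
    nrow(r$trials) / r$days_observed > min_trials_per_day
  }, logical(1))
  cohort(unname(x$records[keep]), group_id = x$group_id)
}

#' Segment a trial table into sessions
#'
#' Maximal runs of constant `high_side` become sessions with consecutive
#' ids starting at 1. Alternatively a swap schedule (data.frame with
#' `start` trial positions and `high_side`) defines the boundaries; when
#' both are available they must agree.
#'
#' @param trials data.frame with at least `chosen_side`; `high_side`
#'   per-trial or via `swap_schedule`.
#' @param swap_schedule optional data.frame(`start`, `high_side`), `start`
#'   being 1-based positions in `trials` with `start[1] == 1`.
#' @param value_low,value_high reward values attached to every session.
#' @return data.frame(`session_id`, `high_side`, `value_low`, `value_high`,
#'   `n_trials`).
#' @export
segment_sessions <- function(trials, swap_schedule = NULL,
                             value_low = 1, value_high = 3) {
  trials <- as.data.frame(trials)
  n <- nrow(trials)
  if (!is.null(swap_schedule)) {
    ss <- as.data.frame(swap_schedule)
    stopifnot(all(c("start", "high_side") %in% names(ss)))
    if (n && ss$start[1] != 1L) stop2("swap schedule must start at trial 1")
    hs <- rep(ss$high_side, times = diff(c(ss$start, n + 1L)))
    if ("high_side" %in% names(trials) && n &&
        !all(trials$high_side == hs))
      stop2("high_side contradicts the declared swap schedule")
  } else {
    if (!("high_side" %in% names(trials)))
      stop2("either per-trial high_side or a swap_schedule is required")
    hs <- trials$high_side
  }
  if (!n) {
    return(data.frame(session_id = integer(), high_side = character(),
                      value_low = numeric(), value_high = numeric(),
                      n_trials = integer(), stringsAsFactors = FALSE))
  }
  r <- rle(hs)
  data.frame(session_id = seq_along(r$lengths), high_side = r$values,
             value_low = value_low, value_high = value_high,
             n_trials = r$lengths, stringsAsFactors = FALSE)
}
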