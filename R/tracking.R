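# Home-cage RFID analytics.
#
# The cage has five zones: N (nest), F (feeder), S (stairs/gate toward the
# test zone), all connected through the central hub C, and T (the T-maze
# entrance reached from S). An event stream is one detection row per zone
# entry: mouse_id, time in seconds, location. Metrics derived per animal:
# NbD (zone transitions per day), EnA (Shannon entropy, in nats, of the
# occupancy-time distribution over the five zones), occupancy fractions,
# and conditional transition probabilities of first order (between
# consecutive zones) and second order (from a non-hub zone to the next
# non-hub zone reached via the hub).

.zones <- c("N", "F", "C", "S", "T")

#' Read an RFID event log
#'
#' Delimited text with columns `mouse_id`, `time_s`, `location`.
#'
#' @param path file path.
#' @param sep separator.
#' @return data.frame sorted by animal and time.
#' @export
read_event_log <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("mouse_id", "time_s", "location"), names(df))
  if (length(miss)) stop2("event log is missing column(s): ",
                          paste(miss, collapse = ", "))
  .validate_events(df)
}

#' Write an RFID event log
#'
#' @param events event data.frame.
#' @param path output path.
#' @param sep separator.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, sep = ",") {
  utils::write.table(events[, c("mouse_id", "time_s", "location")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.validate_events <- function(events) {
  events <- as.data.frame(events)
  bad <- !(events$location %in% .zones)
  if (any(bad)) stop2("unknown location code(s): ",
                      paste(unique(events$location[bad]), collapse = ", "))
  # per-animal times must be non-decreasing in the order recorded
  dec <- tapply(events$time_s, events$mouse_id, function(t) any(diff(t) < 0))
  if (any(unlist(dec))) stop2("decreasing timestamps within an animal")
  events <- events[order(events$mouse_id, events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  events
}

.collapse_runs <- function(d) {
  # merge consecutive same-location detections into residency episodes
  r <- rle(d$location)
  starts_idx <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  start <- d$time_s[starts_idx]
  dur <- c(start[-1], d$time_s[nrow(d)])[seq_along(start)] - start
  open <- c(rep(FALSE, length(start) - 1), TRUE)
  data.frame(location = r$values, start = start, duration = dur,
             open = open, stringsAsFactors = FALSE)
}

#' Residency episodes from an event stream
#'
#' Maximal runs of identical location collapse into one episode; an
#' episode's duration runs to the start of the next episode. The final
#' episode is closed at the last event time and flagged `open`.
#'
#' @param events event data.frame (`mouse_id`, `time_s`, `location`).
#' @return data.frame `mouse_id`, `location`, `start`, `duration`, `open`.
#' @export
residency_episodes <- function(events) {
  events <- .validate_events(events)
  out <- lapply(split(events, events$mouse_id), function(d) {
    ep <- .collapse_runs(d)
    data.frame(mouse_id = d$mouse_id[1], ep, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Occupancy-time fractions over the five zones
#'
#' Episode durations (the final open episode contributes its duration up
#' to the last event) aggregated per zone; fractions sum to 1 per animal.
#'
#' @param events event data.frame.
#' @return data.frame `mouse_id`, `occ_N` ... `occ_T` (NA row when an
#'   animal has no observed dwell time at all).
#' @export
occupancy_fractions <- function(events) {
  ep <- residency_episodes(events)
  out <- lapply(split(ep, ep$mouse_id), function(d) {
    tot <- sum(d$duration)
    fr <- if (tot > 0)
      as.numeric(tapply(d$duration, factor(d$location, levels = .zones),
                        sum, default = 0)) / tot
    else rep(NA_real_, 5)
    stats::setNames(data.frame(d$mouse_id[1] %||% NA, t(fr),
                               stringsAsFactors = FALSE),
                    c("mouse_id", paste0("occ_", .zones)))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Conditional transition probabilities between zones
#'
#' Order 1: over consecutive episodes, `P(to | from)`. Order 2 describes
#' hub-mediated moves: from a source zone X other than the hub C, the next
#' non-hub zone Y reached (any number of intervening hub visits),
#' `P(Y | leave X)`. Rows for sources never left are absent (undefined).
#'
#' @param events event data.frame.
#' @param order 1 or 2.
#' @return data.frame `mouse_id`, `from`, `to`, `n`, `p`; within each
#'   (animal, from), `p` sums to 1.
#' @export
transition_probabilities <- function(events, order = 1) {
  stopifnot(order %in% c(1, 2))
  events <- .validate_events(events)
  out <- lapply(split(events, events$mouse_id), function(d) {
    s <- rle(d$location)$values
    if (order == 2) s <- s[s != "C"]
    if (length(s) < 2) return(NULL)
    from <- s[-length(s)]; to <- s[-1]
    tab <- table(from, to)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    data.frame(mouse_id = d$mouse_id[1], from = df$from, to = df$to,
               n = df$Freq, p = df$Freq / rowSums(tab)[df$from],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Activity summary: detections per day, circadian profile, entropy
#'
#' NbD counts zone transitions (changes of location) per day over the
#' observed span; the circadian histogram bins transitions by hour of day
#' normalized per observed day; EnA is the Shannon entropy (nats) of the
#' occupancy-time distribution, between 0 (single zone) and `log(5)`.
#'
#' @param events event data.frame; time 0 is midnight of day 1.
#' @param day_length seconds per day.
#' @return list `per_animal` (data.frame `mouse_id`, `nbd`, `ena`,
#'   `days_observed`), `circadian` (data.frame `mouse_id`, `hour`,
#'   `transitions_per_day`).
#' @export
activity_summary <- function(events, day_length = 86400) {
  events <- .validate_events(events)
  occ <- occupancy_fractions(events)
  per <- lapply(split(events, events$mouse_id), function(d) {
    span <- diff(range(d$time_s))
    if (span < day_length)
      warning("observation span under one day for '", d$mouse_id[1],
              "'; metrics computed over the actual span")
    days <- max(span, 1e-9) / day_length
    chg <- which(diff(as.integer(factor(d$location, levels = .zones))) != 0) + 1L
    fr <- as.numeric(occ[occ$mouse_id == d$mouse_id[1], -1])
    ena <- if (all(is.na(fr))) NA_real_ else {
      p <- fr[fr > 0]
      -sum(p * log(p))
    }
    hours <- floor((d$time_s[chg] %% day_length) / 3600)
    circ <- as.numeric(table(factor(hours, levels = 0:23))) / days
    list(row = data.frame(mouse_id = d$mouse_id[1],
                          nbd = length(chg) / days, ena = ena,
                          days_observed = days, stringsAsFactors = FALSE),
         circ = data.frame(mouse_id = d$mouse_id[1], hour = 0:23,
                           transitions_per_day = circ,
                           stringsAsFactors = FALSE))
  })
  list(per_animal = do.call(rbind, c(lapply(per, `[[`, "row"),
                                     list(make.row.names = FALSE))),
       circadian = do.call(rbind, c(lapply(per, `[[`, "circ"),
                                    list(make.row.names = FALSE))))
}

#' Full per-animal metrics table
#'
#' Combines NbD, EnA, occupancy fractions and selected first-order
#' (`CtoN`, `CtoF`, `CtoS`, `StoT`) and second-order (`NtoF`, `NtoS`,
#' `FtoN`, `FtoS`, `StoN`, `StoF`) transition probabilities.
#'
#' @param events event data.frame.
#' @return data.frame, one row per animal; undefined transitions are NA.
#' @export
metrics_table <- function(events) {
  act <- activity_summary(events)$per_animal
  occ <- occupancy_fractions(events)
  t1 <- transition_probabilities(events, 1)
  t2 <- transition_probabilities(events, 2)
  pick <- function(tp, from, to) {
    v <- tp$p[tp$from == from & tp$to == to]
    key <- tp$mouse_id[tp$from == from & tp$to == to]
    stats::setNames(v, key)
  }
  firsts <- list(CtoN = c("C", "N"), CtoF = c("C", "F"), CtoS = c("C", "S"),
                 StoT = c("S", "T"))
  seconds <- list(NtoF = c("N", "F"), NtoS = c("N", "S"), FtoN = c("F", "N"),
                  FtoS = c("F", "S"), StoN = c("S", "N"), StoF = c("S", "F"))
  out <- merge(act, occ, by = "mouse_id")
  for (nm in names(firsts)) {
    v <- pick(t1, firsts[[nm]][1], firsts[[nm]][2])
    out[[nm]] <- as.numeric(v[out$mouse_id])
  }
  for (nm in names(seconds)) {
    v <- pick(t2, seconds[[nm]][1], seconds[[nm]][2])
    out[[nm]] <- as.numeric(v[out$mouse_id])
  }
  out
}

#' Daily fluid consumption estimator
#'
#' Consumption is the bottle-weight change on the chosen side minus the
#' change on the non-selected side (which captures evaporation and
#' handling loss), averaged over days. Days missing either measurement are
#' excluded; physically implausible negative raw deltas are flagged, not
#' clipped.
#'
#' @param daily data.frame `mouse_id`, `day`, `chosen_delta`,
#'   `nonchosen_delta` (ml).
#' @param tol negative values beyond this magnitude raise the flag.
#' @return data.frame `mouse_id`, `consumption_ml_day`, `n_days`,
#'   `n_flagged`.
#' @export
estimate_consumption <- function(daily, tol = 0.05) {
  daily <- as.data.frame(daily)
  out <- lapply(split(daily, daily$mouse_id), function(d) {
    ok <- !is.na(d$chosen_delta) & !is.na(d$nonchosen_delta)
    flagged <- ok & (d$chosen_delta < -tol | d$nonchosen_delta < -tol)
    cons <- d$chosen_delta[ok] - d$nonchosen_delta[ok]
    data.frame(mouse_id = d$mouse_id[1],
               consumption_ml_day = if (any(ok)) mean(cons) else NA_real_,
               n_days = sum(ok), n_flagged = sum(flagged),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Correlate home-cage metrics with archetypal composition
#'
#' Pearson correlation (with two-sided p) of every metric column against
#' every composition column, plus ordinary least-squares regression
#' statistics (slope, adjusted R-squared, slope p) for the same pairs.
#' Cells with fewer than 3 complete pairs are NA.
#'
#' @param metrics data.frame with `mouse_id` and numeric metric columns.
#' @param composition data.frame with `mouse_id` and composition columns
#'   (`alpha_Tr`, `alpha_Ex`, `alpha_NS` by default).
#' @param metric_cols,comp_cols column selections; defaults: all numeric
#'   metric columns, the three composition weights.
#' @return list `r` (matrix), `p` (matrix), `regression` (data.frame
#'   `metric`, `composition`, `slope`, `adj_r2`, `slope_p`, `n`).
#' @export
correlate_with_composition <- function(metrics, composition,
                                       metric_cols = NULL,
                                       comp_cols = c("alpha_Tr", "alpha_Ex",
                                                     "alpha_NS")) {
  m <- as.data.frame(metrics); cpo <- as.data.frame(composition)
  if (is.null(metric_cols))
    metric_cols <- setdiff(names(m)[vapply(m, is.numeric, logical(1))],
                           "mouse_id")
  j <- merge(m[, c("mouse_id", metric_cols)], cpo[, c("mouse_id", comp_cols)],
             by = "mouse_id")
  r <- p <- matrix(NA_real_, length(metric_cols), length(comp_cols),
                   dimnames = list(metric_cols, comp_cols))
  reg <- list()
  for (mc in metric_cols) for (cc in comp_cols) {
    ok <- stats::complete.cases(j[[mc]], j[[cc]])
    if (sum(ok) < 3 || stats::sd(j[[mc]][ok]) == 0 || stats::sd(j[[cc]][ok]) == 0) {
      reg[[paste(mc, cc)]] <- data.frame(metric = mc, composition = cc,
                                         slope = NA_real_, adj_r2 = NA_real_,
                                         slope_p = NA_real_, n = sum(ok))
      next
    }
    ct <- stats::cor.test(j[[mc]][ok], j[[cc]][ok])
    r[mc, cc] <- unname(ct$estimate); p[mc, cc] <- ct$p.value
    fit <- stats::lm(j[[mc]][ok] ~ j[[cc]][ok])
    sm <- summary(fit)
    reg[[paste(mc, cc)]] <- data.frame(
      metric = mc, composition = cc,
      slope = unname(stats::coef(fit)[2]),
      adj_r2 = sm$adj.r.squared,
      slope_p = sm$coefficients[2, 4], n = sum(ok),
      stringsAsFactors = FALSE)
  }
  list(r = r, p = p, regression = do.call(rbind, c(reg, list(make.row.names = FALSE))))
}

#' Grouped nonparametric comparisons with Holm correction
#'
#' Thin reporting helper: pairwise Wilcoxon rank-sum tests (or a global
#' Kruskal-Wallis test) on per-animal values grouped by archetype, with
#' Holm-adjusted p-values. Groups with fewer than 2 values give NA rows.
#'
#' @param values numeric vector.
#' @param group factor/character of the same length.
#' @param method `"wilcoxon"` (pairwise) or `"kruskal"` (global).
#' @return data.frame `test`, `group1`, `group2`, `statistic`, `p`,
#'   `p_adj`.
#' @export
report_group_stats <- function(values, group, method = c("wilcoxon", "kruskal")) {
  method <- match.arg(method)
  group <- as.character(group)
  gs <- unique(group)
  if (method == "kruskal") {
    kt <- stats::kruskal.test(values, factor(group))
    return(data.frame(test = "kruskal", group1 = NA, group2 = NA,
                      statistic = unname(kt$statistic), p = kt$p.value,
                      p_adj = kt$p.value, stringsAsFactors = FALSE))
  }
  if (length(gs) < 2)
    return(data.frame(test = "wilcoxon", group1 = gs[1] %||% NA, group2 = NA,
                      statistic = NA_real_, p = NA_real_, p_adj = NA_real_))
  pairs <- utils::combn(gs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[group == pairs[1, i]]; b <- values[group == pairs[2, i]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(test = "wilcoxon", group1 = pairs[1, i],
                        group2 = pairs[2, i], statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    data.frame(test = "wilcoxon", group1 = pairs[1, i], group2 = pairs[2, i],
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}
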