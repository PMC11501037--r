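# The five per-animal choice descriptors.
#
# Switch    - global side balance: 1 - |p_L - p_R| over all trials, so 0
#             means one side only and 1 means perfectly balanced visits.
# SwWat     - probability of switching side after a low-value outcome
#             (water in the water/sucrose period).
# SwSuc     - probability of switching side after a high-value outcome.
# Pref      - mean over sessions of the fraction of choices on the
#             high-value side.
# SideBias  - |2 m - 1| with m the mean over sessions of the left-choice
#             fraction; averaging across sessions cancels reward tracking
#             because the high side alternates.
#
# All descriptors live on [0, 1]; rendering as percent is left to reports.
# Undefined cases (no qualifying data) are returned as NA.

.descriptor_cols <- c("switch", "sw_low", "sw_high", "pref", "side_bias")

#' Global switching index
#'
#' `1 - |p_L - p_R|` over the pooled trials of a record: 0 when the animal
#' visits one side only, 1 when side proportions are exactly equal.
#'
#' @param record a [mouse_record()].
#' @return fraction in `[0, 1]`, or `NA` for an empty record.
#' @export
switch_index <- function(record) {
  ch <- record$trials$chosen_side
  if (!length(ch)) return(NA_real_)
  pL <- mean(ch == "L")
  1 - abs(pL - (1 - pL))
}

#' Conditional switch probability after a low- or high-value outcome
#'
#' Over consecutive within-session trial pairs (t, t+1) whose trial-t
#' outcome matches `outcome_class`, the fraction where the side changed.
#' Pairs spanning a session boundary are excluded by default so the
#' outcome label of trial t is unambiguous.
#'
#' @param record a [mouse_record()].
#' @param outcome_class `"low"` (SwWat) or `"high"` (SwSuc).
#' @param within_session_only exclude pairs that span a bottle swap.
#' @return fraction in `[0, 1]`, or `NA` when no pair qualifies.
#' @export
conditional_switch <- function(record, outcome_class = c("low", "high"),
                               within_session_only = TRUE) {
  outcome_class <- match.arg(outcome_class)
  tr <- record$trials
  n <- nrow(tr)
  if (n < 2) return(NA_real_)
  i <- seq_len(n - 1)
  ok <- tr$outcome_label[i] == outcome_class
  if (within_session_only) ok <- ok & tr$session_id[i] == tr$session_id[i + 1]
  if (!any(ok)) return(NA_real_)
  mean(tr$chosen_side[i][ok] != tr$chosen_side[i + 1][ok])
}

.session_fractions <- function(record, side_of = c("high", "L")) {
  side_of <- match.arg(side_of)
  tr <- record$trials
  if (!nrow(tr)) return(numeric())
  tgt <- if (side_of == "high") tr$chosen_side == tr$high_side else tr$chosen_side == "L"
  as.numeric(tapply(tgt, factor(tr$session_id, levels = unique(tr$session_id)), mean))
}

#' High-value-side preference
#'
#' Unweighted mean over sessions of the fraction of that session's trials
#' on the high-value side; empty sessions are excluded.
#'
#' @param record a [mouse_record()].
#' @return fraction in `[0, 1]`, or `NA` when no session has trials.
#' @export
preference <- function(record) {
  f <- .session_fractions(record, "high")
  if (!length(f)) return(NA_real_)
  mean(f)
}

#' Side bias
#'
#' `|2 m - 1|` with m the mean over sessions of the left-choice fraction:
#' 0 = no spatial bias, 1 = exclusive use of one side across sessions.
#'
#' @param record a [mouse_record()].
#' @return fraction in `[0, 1]`, or `NA` when no session has trials.
#' @export
side_bias <- function(record) {
  f <- .session_fractions(record, "L")
  if (!length(f)) return(NA_real_)
  abs(2 * mean(f) - 1)
}

#' All five descriptors of one record
#'
#' @param record a [mouse_record()].
#' @return named numeric vector `switch`, `sw_low`, `sw_high`, `pref`,
#'   `side_bias`.
#' @export
descriptor_vector <- function(record) {
  c(switch = switch_index(record),
    sw_low = conditional_switch(record, "low"),
    sw_high = conditional_switch(record, "high"),
    pref = preference(record),
    side_bias = side_bias(record))
}

#' Descriptor matrix of a cohort
#'
#' Assembles the n x 5 matrix (columns `switch`, `sw_low`, `sw_high`,
#' `pref`, `side_bias`) used by the archetypal analysis. With
#' `scaling = "minmax"` each column is mapped onto `[0, 1]`; constant
#' columns map to 0 with a warning. The original column minima/maxima are
#' kept as attributes so archetypes can be reported in raw units.
#'
#' @param x a [cohort()].
#' @param scaling `"minmax"` (default, the display convention of the
#'   descriptor fingerprints) or `"raw"`.
#' @param na_action `"error"` (default) lists animals with undefined
#'   descriptors; `"omit"` drops them.
#' @return numeric matrix with attributes `mouse_ids`, `scaling`,
#'   `col_mins`, `col_maxs`.
#' @export
descriptor_matrix <- function(x, scaling = c("minmax", "raw"),
                              na_action = c("error", "omit")) {
  stopifnot(inherits(x, "cohort"))
  scaling <- match.arg(scaling)
  na_action <- match.arg(na_action)
  M <- t(vapply(x$records, descriptor_vector, numeric(5)))
  ids <- names(x$records)
  bad <- rowSums(is.na(M)) > 0
  if (any(bad)) {
    if (na_action == "error")
      stop2("undefined descriptor(s) for: ", paste(ids[bad], collapse = ", "))
    M <- M[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  colnames(M) <- .descriptor_cols
  mins <- apply(M, 2, min)
  maxs <- apply(M, 2, max)
  if (scaling == "minmax") {
    rng <- maxs - mins
    const <- rng == 0
    if (any(const))
      warning("constant descriptor column(s) mapped to 0: ",
              paste(.descriptor_cols[const], collapse = ", "))
    rng[const] <- 1
    M <- sweep(sweep(M, 2, mins, "-"), 2, rng, "/")
  }
  structure(M, mouse_ids = ids, scaling = scaling,
            col_mins = mins, col_maxs = maxs)
}

#' Classify where a persistent side preference originated
#'
#' For a Non-Switcher-like animal, compares its preferred side during the
#' water/sucrose (WS) period against (i) the side where it first found
#' sucrose and (ii) its majority side during a water/water (WW) period,
#' giving a 2 x 2 category.
#'
#' @param ws_record [mouse_record()] of the WS period.
#' @param ww_record [mouse_record()] of the WW period.
#' @return one of `"first-sucrose & same-WW"`,
#'   `"first-sucrose & opposite-WW"`, `"opposite-first-sucrose & same-WW"`,
#'   `"opposite-first-sucrose & opposite-WW"`, or `NA` when the animal has
#'   no high-value outcome in WS or an exact 50/50 majority.
#' @export
classify_nonswitcher_origin <- function(ws_record, ww_record) {
  maj <- function(rec) {
    ch <- rec$trials$chosen_side
    if (!length(ch)) return(NA_character_)
    pL <- mean(ch == "L")
    if (pL == 0.5) NA_character_ else if (pL > 0.5) "L" else "R"
  }
  pref_side <- maj(ws_record)
  ww_side <- maj(ww_record)
  hi <- which(ws_record$trials$outcome_label == "high")
  if (!length(hi) || is.na(pref_side) || is.na(ww_side)) return(NA_character_)
  first_suc_side <- ws_record$trials$high_side[hi[1]]
  paste0(if (pref_side == first_suc_side) "first-sucrose" else "opposite-first-sucrose",
         " & ",
         if (pref_side == ww_side) "same-WW" else "opposite-WW")
}

#' Write a descriptor table to delimited text
#'
#' @param M matrix from [descriptor_matrix()].
#' @param path output path.
#' @param sep separator.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(M, path, sep = ",") {
  df <- data.frame(mouse_id = attr(M, "mouse_ids"), as.data.frame(unclass(M)[, ]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  meta <- paste0("scaling: ", attr(M, "scaling"), "\n",
                 "col_mins: ", paste(attr(M, "col_mins"), collapse = " "), "\n",
                 "col_maxs: ", paste(attr(M, "col_maxs"), collapse = " "), "\n")
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
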