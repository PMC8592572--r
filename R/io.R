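trial_cols <- c("subject", "group", "trial", "r_left", "r_right",
                "ov_condition", "vd", "choice", "rt_s", "g_left",
                "g_right", "dwell_advantage_s")
fixation_cols <- c("subject", "trial", "index", "location",
                   "duration_ms", "ordinal_class")

new_gaze_dataset <- function(trials, fixations, exclusions, provenance) {
  structure(list(trials = trials, fixations = fixations,
                 exclusions = exclusions, provenance = provenance),
            class = "gaze_dataset")
}

#' @export
print.gaze_dataset <- function(x, ...) {
  cat("<gaze_dataset>", nrow(x$trials), "trials,",
      length(unique(x$trials$subject)), "subjects,",
      nrow(x$fixations), "fixations;",
      nrow(x$exclusions), "excluded\n")
  invisible(x)
}

#' Load and validate a trial/fixation dataset
#'
#' Reads the tidy trial and fixation CSVs, type-checks them, normalizes
#' units (RT to seconds, dwells to ms), recomputes gaze summaries from
#' the fixation table and cross-checks them against any provided
#' columns, and applies the exclusion rule: trials with no gaze time on
#' any item are dropped and logged.
#'
#' @param trials_path,fixations_path CSV paths. The trial table needs
#'   columns `subject, group, trial, r_left, r_right, ov_condition, vd,
#'   choice, rt` (or `rt_s`/`rt_ms`); the fixation table needs
#'   `subject, trial, index, location, duration_ms`.
#' @param rt_unit Declared RT unit of the trial table, `"s"` or `"ms"`.
#' @param tol Tolerance for the gaze-summary cross-check.
#' @return A `gaze_dataset` (see [generate_dataset()]).
#' @export
load_dataset <- function(trials_path, fixations_path, rt_unit = c("s", "ms"),
                         tol = 0.01) {
  rt_unit <- match.arg(rt_unit)
  trials <- read.csv(trials_path, stringsAsFactors = FALSE)
  fixations <- read.csv(fixations_path, stringsAsFactors = FALSE)

  rt_col <- intersect(c("rt_s", "rt_ms", "rt"), names(trials))[1]
  need_t <- c("subject", "group", "trial", "r_left", "r_right",
              "ov_condition", "vd", "choice")
  miss <- setdiff(c(need_t, if (is.na(rt_col)) "rt_s"), names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(setdiff(fixation_cols, "ordinal_class"), names(fixations))
  if (length(miss))
    stop("fixation table is missing column(s): ", paste(miss, collapse = ", "))

  rt <- trials[[rt_col]]
  if (identical(rt_col, "rt_ms") || rt_unit == "ms") rt <- rt / 1000
  if (any(rt <= 0)) stop("non-positive RTs found")
  if (median(rt) > 60 || median(rt) < 0.05)
    stop("RTs implausible for declared unit '", rt_unit,
         "' (median ", signif(median(rt), 3), " s after conversion)")
  trials$rt_s <- rt

  if (any(fixations$duration_ms <= 0))
    stop("non-positive fixation durations found")
  if (any(!fixations$location %in% c("left", "right")))
    stop("fixation locations must be 'left' or 'right'")

  tkey <- paste(trials$subject, trials$trial)
  fkey <- paste(fixations$subject, fixations$trial)
  orphan <- !fkey %in% tkey
  if (any(orphan))
    stop(sum(orphan), " fixation row(s) do not join to any trial")

  # recompute gaze summaries from item-directed dwells
  dl <- tapply(fixations$duration_ms *
                 (fixations$location == "left"), fkey, sum)
  dtot <- tapply(fixations$duration_ms, fkey, sum)
  dl <- as.vector(dl[tkey]); dtot <- as.vector(dtot[tkey])
  dl[is.na(dl)] <- 0; dtot[is.na(dtot)] <- 0
  g_left <- ifelse(dtot > 0, dl / dtot, NA_real_)
  for (col in c("g_left", "g_right", "dwell_advantage_s")) {
    if (!col %in% names(trials)) next
    ref <- switch(col, g_left = g_left, g_right = 1 - g_left,
                  dwell_advantage_s = (2 * dl - dtot) / 1000)
    bad <- abs(trials[[col]] - ref) > tol
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      stop("column '", col, "' disagrees with the fixation table on ",
           sum(bad), " trial(s)")
  }
  trials$g_left <- g_left
  trials$g_right <- 1 - g_left
  trials$dwell_advantage_s <- (2 * dl - dtot) / 1000

  drop <- dtot == 0
  exclusions <- data.frame(subject = trials$subject[drop],
                           trial = trials$trial[drop],
                           reason = rep("no gaze time on any item",
                                        sum(drop)))
  if (any(drop)) {
    message("excluded ", sum(drop),
            " trial(s) with no gaze time on any item")
    keep_keys <- tkey[!drop]
    fixations <- fixations[fkey %in% keep_keys, , drop = FALSE]
    trials <- trials[!drop, , drop = FALSE]
  }
  if (!"ordinal_class" %in% names(fixations)) {
    fixations <- fixations[order(fixations$subject, fixations$trial,
                                 fixations$index), , drop = FALSE]
    fkey2 <- paste(fixations$subject, fixations$trial)
    nfix <- ave(fixations$index, fkey2, FUN = length)
    fixations$ordinal_class <- ifelse(
      fixations$index == 1, "first",
      ifelse(fixations$index == nfix, "last", "middle"))
  }
  rownames(trials) <- rownames(fixations) <- NULL
  new_gaze_dataset(trials, fixations, exclusions,
                   provenance = list(source = c(trials_path,
                                                fixations_path)))
}

#' Write a dataset's trial and fixation tables as CSV
#'
#' @param dataset A `gaze_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- file.path(dir, "trials.csv")
  fp <- file.path(dir, "fixations.csv")
  write.csv(dataset$trials[, trial_cols], tp, row.names = FALSE)
  write.csv(dataset$fixations[, fixation_cols], fp, row.names = FALSE)
  invisible(c(trials = tp, fixations = fp))
}
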