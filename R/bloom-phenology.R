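#' Detect coccolithophore bloom periods on a [PIC] matchup series
#'
#' Candidate bloom periods are maximal runs of records where [PIC] exceeds
#' `baseline_factor` times the series median (a standard
#' baseline-crossing phenology construction); runs separated by fewer than
#' `merge_gap` records are merged and runs shorter than `min_length`
#' records are discarded. A candidate is retained as a coccolithophore
#' bloom only if, within the period, [PIC] exceeds `pic_threshold`
#' (0.7 mmol m^-3) AND the calcite fraction %PIC exceeds
#' `pctpic_threshold` (10%) -- the constraints that separate genuine
#' calcite pulses from chlorophyll-dominated blooms.
#'
#' @param dates Date vector (strictly increasing, >= 15 records).
#' @param pic Gap-free [PIC] series, mmol m^-3.
#' @param pctpic Gap-free %PIC series (percent).
#' @param pic_threshold Within-period maximum [PIC] constraint
#'   (mmol m^-3, default 0.7).
#' @param pctpic_threshold Within-period maximum %PIC constraint
#'   (percent, default 10).
#' @param baseline_factor Baseline-crossing factor on the series median
#'   (default 1.05).
#' @param merge_gap Runs separated by fewer than this many records are
#'   merged (default 3).
#' @param min_length Minimum run length in records (default 3).
#' @return Tibble of retained `bloom_period`s ordered by start:
#'   `start_date`, `end_date`, `peak_pic`, `passed_pic_constraint`,
#'   `passed_pctpic_constraint`.
#' @export
detect_bloom_periods <- function(dates, pic, pctpic,
                                 pic_threshold = 0.7,
                                 pctpic_threshold = 10,
                                 baseline_factor = 1.05,
                                 merge_gap = 3L, min_length = 3L) {
  stopifnot(length(dates) == length(pic), length(pic) == length(pctpic))
  if (any(!is.finite(pic)) || any(!is.finite(pctpic)))
    stop("detect_bloom_periods(): series has gaps; run build_series() first")
  if (length(pic) < 15)
    stop("detect_bloom_periods(): need at least 15 records")
  above <- pic > baseline_factor * median(pic)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(empty_periods())
  # merge runs separated by < merge_gap records
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1 >= min_length, , drop = FALSE]
  if (nrow(merged) == 0) return(empty_periods())
  out <- lapply(seq_len(nrow(merged)), function(k) {
    idx <- merged$start[k]:merged$end[k]
    tibble::tibble(
      start_date = dates[merged$start[k]], end_date = dates[merged$end[k]],
      peak_pic = max(pic[idx]),
      passed_pic_constraint = max(pic[idx]) > pic_threshold,
      passed_pctpic_constraint = max(pctpic[idx]) > pctpic_threshold)
  })
  out <- dplyr::bind_rows(out)
  out <- out[out$passed_pic_constraint & out$passed_pctpic_constraint, ,
             drop = FALSE]
  out[order(out$start_date), , drop = FALSE]
}

empty_periods <- function() {
  tibble::tibble(start_date = as.Date(character()),
                 end_date = as.Date(character()),
                 peak_pic = numeric(),
                 passed_pic_constraint = logical(),
                 passed_pctpic_constraint = logical())
}

#' Label float surface records against detected bloom periods
#'
#' A record is labelled in-bloom when its date falls inside any period
#' (closed interval ends). The `phase` column places each record relative
#' to the first period: `before` its start, `during` any period, `after`
#' otherwise -- the grouping used for before/during/after distribution
#' summaries.
#'
#' @param records Surface-record tibble (needs a `date` column).
#' @param periods Bloom-period tibble from [detect_bloom_periods()].
#' @return The records with `bloom_label` (logical) and `phase` (factor
#'   before/during/after) appended.
#' @export
label_records <- function(records, periods) {
  records <- tibble::as_tibble(records)
  lab <- rep(FALSE, nrow(records))
  if (!is.null(periods) && nrow(periods) > 0) {
    for (k in seq_len(nrow(periods)))
      lab <- lab | (records$date >= periods$start_date[k] &
                      records$date <= periods$end_date[k])
  }
  phase <- rep("before", nrow(records))
  if (!is.null(periods) && nrow(periods) > 0) {
    phase[records$date > periods$start_date[1]] <- "after"
  }
  phase[lab] <- "during"
  records$bloom_label <- lab
  records$phase <- factor(phase, levels = c("before", "during", "after"))
  records
}
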