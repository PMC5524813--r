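# Live/dead viability bookkeeping and the geometric expected-cell-death
# estimate for 3D phantoms.

#' Live-cell fraction from fluorescence counts
#'
#' Percentage of live cells from manual counts of calcein-AM-positive
#' (live) and ethidium-homodimer-positive (dead) cells:
#' `100 * live / (live + dead)`.
#'
#' @param calcein_positive Live-cell count (>= 0).
#' @param ethidium_positive Dead-cell count (>= 0). Vectorised.
#' @return Percent live cells.
#' @examples
#' live_fraction(75, 25)  # 75
#' @export
live_fraction <- function(calcein_positive, ethidium_positive) {
  if (any(calcein_positive < 0) || any(ethidium_positive < 0))
    stop("counts must be non-negative")
  total <- calcein_positive + ethidium_positive
  if (any(total == 0)) stop("total cell count must be positive")
  100 * calcein_positive / total
}

#' Expected 3D cell death from 2D exposure rates
#'
#' Geometric scaling of 2D per-exposure death rates to a 3D phantom where
#' only a fraction of cells experience the insult (bubble contact or
#' elevated oxygen partial pressure): expected death = contact fraction x
#' per-exposure death rate. E.g. 50% of cells contacting a bubble at a 30%
#' 2D contact-death rate predicts 15% death; 20% of cells seeing 2D-level
#' ppO2 at a 20% rate predicts 4%.
#'
#' @param contact_fraction Fraction of cells exposed, in \[0, 1\].
#' @param per_exposure_death Death rate among exposed cells, percent in
#'   \[0, 100\].
#' @return Expected cell death, percent.
#' @examples
#' expected_cell_death(0.5, 30)  # 15
#' expected_cell_death(0.2, 20)  # 4
#' @export
expected_cell_death <- function(contact_fraction, per_exposure_death) {
  if (any(contact_fraction < 0 | contact_fraction > 1))
    stop("contact_fraction must lie in [0, 1]")
  if (any(per_exposure_death < 0 | per_exposure_death > 100))
    stop("per_exposure_death must lie in [0, 100] percent")
  contact_fraction * per_exposure_death
}

#' Summarise a viability counts table
#'
#' Per-condition (and optionally per-orientation) live-fraction summaries
#' from a tabulated counts table, as group mean and sd; inferential
#' statistics are out of scope.
#'
#' @param counts Tibble/data.frame with columns `sample_id, condition,
#'   orientation, calcein_n, ethidium_n`; `condition` in
#'   `pre | sham | post`, `orientation` in `bubbles_up | bubbles_down |
#'   none`.
#' @param by Grouping columns (default condition; add `"orientation"` for
#'   the orientation split).
#' @return Tibble with one row per group: `n`, `mean_live_pct`,
#'   `sd_live_pct`.
#' @export
viability_summary <- function(counts, by = "condition") {
  need <- c("sample_id", "condition", "calcein_n", "ethidium_n")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  bad_cond <- setdiff(unique(counts$condition), c("pre", "sham", "post"))
  if (length(bad_cond) > 0)
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  live <- live_fraction(counts$calcein_n, counts$ethidium_n)
  key <- interaction(counts[by], drop = TRUE, sep = ":")
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    g <- counts[sel, by, drop = FALSE][1, , drop = FALSE]
    cbind(tibble::as_tibble(g),
          tibble::tibble(n = sum(sel),
                         mean_live_pct = mean(live[sel]),
                         sd_live_pct = stats::sd(live[sel])))
  })
  do.call(rbind, rows)
}
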