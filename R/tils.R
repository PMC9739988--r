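# The four electronic TILs variables computed from classified cell counts
# and the analyzed tumor area:
#   eTILs%  = 100 T / (T + tumor)
#   esTILs% = 100 T / (T + stroma)
#   etTILs% = 100 T / (T + tumor + stroma)      [optionally + ignore]
#   eaTILs  = T / area (per mm^2)
# where T is the lymphocyte (IMMUNE) count.

#' Compute the four TILs variables for one region
#'
#' @param counts named counts with entries `IMMUNE`, `TUMOR`, `STROMA` and
#'   optionally `IGNORE` (missing entries count as 0); all non-negative
#'   integers.
#' @param areaMm2 analyzed tumor area in mm^2 (> 0).
#' @param includeIgnoreInTotal when `TRUE`, IGNORE-class detections enter
#'   the etTILs% denominator ("all detected cells"); the default excludes
#'   them as false detections and background.
#' @return A [TILsReport-class]. Ratios with a zero denominator are defined
#'   as 0 and flagged in `qcFlags`.
#' @examples
#' computeTILsReport(c(IMMUNE = 50, TUMOR = 450, STROMA = 300), areaMm2 = 2)
#' @export
computeTILsReport <- function(counts, areaMm2, includeIgnoreInTotal = FALSE) {
  if (length(areaMm2) != 1L || !is.finite(areaMm2) || areaMm2 <= 0)
    stop("areaMm2 must be a single positive number", call. = FALSE)
  get0i <- function(nm) {
    v <- if (nm %in% names(counts)) counts[[nm]] else 0
    if (is.na(v) || v < 0) stop("counts must be >= 0", call. = FALSE)
    as.integer(round(v))
  }
  tl <- get0i("IMMUNE"); tu <- get0i("TUMOR")
  st <- get0i("STROMA"); ig <- get0i("IGNORE")
  qc <- character()
  ratio <- function(num, den, what) {
    if (den == 0) {
      qc <<- c(qc, paste0("zero_denominator_", what))
      0
    } else num / den
  }
  total <- tl + tu + st + if (includeIgnoreInTotal) ig else 0L
  new("TILsReport",
      nTILs = tl, nTumor = tu, nStroma = st, nIgnore = ig,
      areaMm2 = as.numeric(areaMm2),
      eTILs = 100 * ratio(tl, tl + tu, "eTILs"),
      esTILs = 100 * ratio(tl, tl + st, "esTILs"),
      etTILs = 100 * ratio(tl, total, "etTILs"),
      eaTILs = tl / areaMm2,
      qcFlags = qc)
}

#' Pool per-region reports into a patient-level report
#'
#' Counts and areas are summed and the four variables recomputed from the
#' pooled counts (never averaged across regions).
#'
#' @param reports list of [TILsReport-class] objects (>= 1).
#' @param includeIgnoreInTotal see [computeTILsReport()].
#' @return A pooled [TILsReport-class].
#' @export
aggregateTILsReports <- function(reports, includeIgnoreInTotal = FALSE) {
  if (!length(reports)) stop("empty report list", call. = FALSE)
  stopifnot(all(vapply(reports, is, TRUE, "TILsReport")))
  counts <- c(
    IMMUNE = sum(vapply(reports, slot, 0L, "nTILs")),
    TUMOR = sum(vapply(reports, slot, 0L, "nTumor")),
    STROMA = sum(vapply(reports, slot, 0L, "nStroma")),
    IGNORE = sum(vapply(reports, slot, 0L, "nIgnore")))
  computeTILsReport(counts, sum(vapply(reports, slot, 0, "areaMm2")),
                    includeIgnoreInTotal)
}

#' One-row data.frame view of a TILs report
#' @param report A [TILsReport-class]. @param id optional patient/region id.
#' @export
tilsReportRow <- function(report, id = NA) {
  data.frame(id = id, n_tils = report@nTILs, n_tumor = report@nTumor,
             n_stroma = report@nStroma, n_ignore = report@nIgnore,
             area_mm2 = report@areaMm2, eTILs_pct = report@eTILs,
             esTILs_pct = report@esTILs, etTILs_pct = report@etTILs,
             eaTILs_per_mm2 = report@eaTILs,
             qc = paste(report@qcFlags, collapse = ";"),
             stringsAsFactors = FALSE)
}
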