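# Feature annotation against an RI library.
#
# Matching is two-stage: accurate mass alone (m/z within an absolute or ppm
# tolerance of a candidate adduct m/z), then optionally filtered by retention
# index agreement. RI is orthogonal to m/z, so the second stage removes
# isobaric/isomeric false positives — e.g. the three C7H6O3 hydroxybenzoic
# acid isomers share one [M+H]+ m/z and are separable only by retention.

#' Relative error between a library value and an observed value
#'
#' Computes `100 * |reference - observed| / observed`: the denominator is the
#' observed (query-system) value, so the error expresses how far the library
#' value lies from what was measured on the current system.
#'
#' @param reference Library/reference value(s).
#' @param observed Observed value(s), > 0.
#' @return Percent relative error (numeric, full precision). Use
#'   [format_relative_error()] for conventional rounding.
#' @examples
#' relative_error(474, 472)  # ~0.42 -> printed as 0.4
#' @export
relative_error <- function(reference, observed) {
  stopifnot(is.numeric(reference), is.numeric(observed))
  if (any(observed <= 0)) stop("`observed` must be > 0")
  100 * abs(reference - observed) / observed
}

#' @rdname relative_error
#' @param pct Percent value(s) from `relative_error`.
#' @details `format_relative_error` applies the conventional reporting
#'   precision: one decimal below 10 percent, integer at or above.
#' @export
format_relative_error <- function(pct) {
  ifelse(pct < 10, round(pct, 1), round(pct, 0))
}

# candidate m/z per library row: explicit mz column wins, else neutral
# formula + adduct
.library_mz <- function(library) {
  if ("mz" %in% names(library) && !all(is.na(library$mz)))
    return(as.numeric(library$mz))
  if (!("formula" %in% names(library)))
    stop("library needs an `mz` column or a `formula` column")
  vapply(seq_len(nrow(library)), function(i) {
    f <- library$formula[i]
    if (is.na(f) || !nzchar(f))
      stop("library entry '", library$compound_id[i],
           "' has neither m/z nor formula")
    adduct_mz(monoisotopic_mass(f), library$adduct[i])
  }, numeric(1))
}

#' Match features against an RI library by m/z
#'
#' Reports every (feature, library entry) pair whose m/z difference is within
#' the tolerance and whose polarities agree. Candidate m/z comes from the
#' library's `mz` column or is computed from a neutral `formula` plus the
#' entry's adduct. Tolerance comparisons are inclusive, so a difference of
#' exactly `mz_tol` is retained.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `polarity`,
#'   and (for RI filtering and error reporting) `ri` and `rt_min`.
#' @param library An `ri_library` or data.frame with `compound_id`,
#'   `adduct`, `polarity`, `mean_ri` and `mz` or `formula` (optionally
#'   `mean_rt_min`).
#' @param mz_tol Absolute m/z tolerance in Da (default 0.005). Set to `NULL`
#'   when using `ppm`.
#' @param ppm Relative tolerance in parts per million; mutually exclusive
#'   with `mz_tol`.
#' @return data.frame of hits: `feature_id`, `compound_id`, `adduct`,
#'   `delta_mz`, `delta_ri`, `rel_err_ri_pct`, `rel_err_rt_pct` (the last
#'   three `NA` where feature RI / library RT are unavailable), sorted by
#'   feature then |delta_mz|.
#' @export
match_mz <- function(features, library, mz_tol = 0.005, ppm = NULL) {
  if (!is.null(mz_tol) && !is.null(ppm))
    stop("give either `mz_tol` (Da) or `ppm`, not both")
  if (is.null(mz_tol) && is.null(ppm)) stop("a tolerance is required")
  if (!is.null(mz_tol)) stopifnot(mz_tol > 0) else stopifnot(ppm > 0)
  need_f <- c("feature_id", "mz", "polarity")
  if (!all(need_f %in% names(features)))
    stop("features must have columns: ", paste(need_f, collapse = ", "))
  if (nrow(library) == 0L || nrow(features) == 0L) return(.empty_hits())

  lib_mz <- .library_mz(library)
  hits <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    tol <- if (is.null(ppm)) mz_tol else f$mz * ppm * 1e-6
    ok <- library$polarity == f$polarity & abs(f$mz - lib_mz) <= tol
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    out <- data.frame(
      feature_id = f$feature_id,
      compound_id = library$compound_id[idx],
      adduct = library$adduct[idx],
      delta_mz = f$mz - lib_mz[idx],
      stringsAsFactors = FALSE
    )
    if (!is.null(f$ri) && !is.na(f$ri) && "mean_ri" %in% names(library)) {
      out$delta_ri <- f$ri - library$mean_ri[idx]
      out$rel_err_ri_pct <- relative_error(library$mean_ri[idx], f$ri)
    } else {
      out$delta_ri <- NA_real_
      out$rel_err_ri_pct <- NA_real_
    }
    rtcol <- intersect(c("mean_rt_min", "rt_min"), names(library))[1]
    if (!is.null(f$rt_min) && !is.na(rtcol)) {
      out$rel_err_rt_pct <- relative_error(library[[rtcol]][idx], f$rt_min)
    } else out$rel_err_rt_pct <- NA_real_
    out[order(abs(out$delta_mz)), ]
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) return(.empty_hits())
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(feature_id = character(), compound_id = character(),
             adduct = character(), delta_mz = numeric(),
             delta_ri = numeric(), rel_err_ri_pct = numeric(),
             rel_err_rt_pct = numeric(), stringsAsFactors = FALSE)
}

#' Match features by combined m/z and retention index
#'
#' Runs [match_mz()] and keeps only hits whose retention-index difference is
#' within `ri_tol` (inclusive). Features without a retention index are
#' skipped with a warning — they cannot be RI-filtered and would otherwise
#' silently pass.
#'
#' @inheritParams match_mz
#' @param ri_tol Maximum |RI difference| in index units (default 10).
#' @return Hits as in [match_mz()]; always a subset of the m/z-only hits.
#' @examples
#' lib <- data.frame(compound_id = c("4-HBA", "3-HBA", "salicylic"),
#'                   adduct = "[M+H]+", polarity = "pos",
#'                   formula = "C7H6O3", mean_ri = c(511, 561, 561))
#' feat <- data.frame(feature_id = "F1", mz = 139.0389, polarity = "pos",
#'                    ri = 513)
#' nrow(match_mz(feat, lib))                # 3 isomer hits by mass alone
#' nrow(match_mz_ri(feat, lib))             # 1 hit after RI filtering
#' @export
match_mz_ri <- function(features, library, mz_tol = 0.005, ppm = NULL,
                        ri_tol = 10) {
  stopifnot(is.numeric(ri_tol), ri_tol > 0)
  if (!("ri" %in% names(features))) {
    warning("no feature has a retention index; returning zero hits")
    return(.empty_hits())
  }
  no_ri <- is.na(features$ri)
  if (any(no_ri)) {
    warning(sum(no_ri), " feature(s) without retention index skipped")
    features <- features[!no_ri, , drop = FALSE]
  }
  hits <- match_mz(features, library, mz_tol = mz_tol, ppm = ppm)
  hits <- hits[!is.na(hits$delta_ri) & abs(hits$delta_ri) <= ri_tol, ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
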