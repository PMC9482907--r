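# Ion suppression of co-eluting features by spiked NAPS.
#
# NAPS carry two permanent charges and can suppress the ESI response of
# co-eluting metabolites. Suppression is quantified by pairing features
# between a NAPS-spiked and an unspiked injection of the same matrix and
# expressing the spiked intensity as a percentage of the unspiked one within
# a +/- 0.20 min window around each NAPS apex: 100% means no suppression,
# < 100% suppression, > 100% enhancement. The C1-C3 standards elute with the
# void-volume crowd where suppression is confounded, so only windows with
# RI > 300 are evaluated.

#' Pair features between a spiked and an unspiked run
#'
#' Greedy one-to-one pairing: candidate pairs within both tolerances are
#' ranked by |m/z difference|, ties broken by |RT difference|, and assigned
#' in that order so each feature is used at most once. The procedure is
#' deterministic and order-independent after the internal sort.
#'
#' @param spiked,unspiked Feature data.frames with columns `mz`, `rt_min`,
#'   `intensity` (and anything else, carried along).
#' @param mz_tol m/z tolerance in Da (default 0.005).
#' @param rt_tol RT tolerance in minutes (default 0.1).
#' @return List with `pairs` (one row per matched pair: `mz`, `rt_min` from
#'   the unspiked run, `intensity_spiked`, `intensity_unspiked`), and the
#'   unmatched `unpaired_spiked` / `unpaired_unspiked` tables.
#' @export
pair_runs <- function(spiked, unspiked, mz_tol = 0.005, rt_tol = 0.1) {
  need <- c("mz", "rt_min", "intensity")
  stopifnot(all(need %in% names(spiked)), all(need %in% names(unspiked)),
            mz_tol > 0, rt_tol > 0)
  empty <- data.frame(mz = numeric(), rt_min = numeric(),
                      intensity_spiked = numeric(),
                      intensity_unspiked = numeric())
  if (nrow(spiked) == 0L || nrow(unspiked) == 0L)
    return(list(pairs = empty, unpaired_spiked = spiked,
                unpaired_unspiked = unspiked))

  cand <- NULL
  for (i in seq_len(nrow(spiked))) {
    dmz <- abs(spiked$mz[i] - unspiked$mz)
    drt <- abs(spiked$rt_min[i] - unspiked$rt_min)
    j <- which(dmz <= mz_tol & drt <= rt_tol)
    if (length(j))
      cand <- rbind(cand, data.frame(i = i, j = j, dmz = dmz[j],
                                     drt = drt[j]))
  }
  if (is.null(cand))
    return(list(pairs = empty, unpaired_spiked = spiked,
                unpaired_unspiked = unspiked))
  cand <- cand[order(cand$dmz, cand$drt), ]
  used_i <- logical(nrow(spiked)); used_j <- logical(nrow(unspiked))
  sel <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_i[cand$i[k]] && !used_j[cand$j[k]]) {
      sel[k] <- TRUE
      used_i[cand$i[k]] <- TRUE
      used_j[cand$j[k]] <- TRUE
    }
  }
  cand <- cand[sel, ]
  pairs <- data.frame(
    mz = unspiked$mz[cand$j],
    rt_min = unspiked$rt_min[cand$j],
    intensity_spiked = spiked$intensity[cand$i],
    intensity_unspiked = unspiked$intensity[cand$j]
  )
  list(pairs = pairs,
       unpaired_spiked = spiked[!used_i, , drop = FALSE],
       unpaired_unspiked = unspiked[!used_j, , drop = FALSE])
}

#' Define suppression evaluation windows around NAPS apexes
#'
#' @param naps_apexes data.frame with columns `n_carbons` (or `n`) and
#'   `rt_min` (or `rt`): apex retention times of the spiked NAPS.
#' @param half_width Half-width of the evaluation window in minutes
#'   (default 0.20; NAPS peaks span about 0.2 min).
#' @param min_ri Only NAPS with RI strictly above this are evaluated
#'   (default 300, excluding the void-volume C1-C3).
#' @return data.frame with columns `ri`, `apex_rt`, `half_width`, sorted by
#'   apex RT.
#' @export
suppression_windows <- function(naps_apexes, half_width = 0.20,
                                min_ri = 300) {
  stopifnot(half_width > 0)
  run <- .as_naps_run(naps_apexes, "naps_apexes")
  out <- data.frame(ri = 100 * run$n, apex_rt = run$rt,
                    half_width = half_width)
  out <- out[out$ri > min_ri, ]
  out <- out[order(out$apex_rt), ]
  rownames(out) <- NULL
  out
}

#' Suppression profile of paired features around NAPS apexes
#'
#' For every feature pair eluting within a window (inclusive at both edges),
#' reports the signed RT distance to the nearest NAPS apex and the spiked
#' intensity as a percentage of the unspiked intensity. A feature falling in
#' two overlapping windows is assigned to the nearer apex. Pairs with zero
#' unspiked intensity are flagged `undefined` and should be excluded from
#' summaries.
#'
#' @param pairs Pair table from [pair_runs()] (the `pairs` element), or a
#'   compatible data.frame.
#' @param windows Window table from [suppression_windows()].
#' @param dilution Optional dilution label (e.g. `"1:20"`) recorded per row.
#' @return data.frame with columns `mz`, `rt_min`, `window_ri`, `apex_rt`,
#'   `delta_rt_to_apex`, `pct_of_unspiked`, `undefined`, `dilution`.
#' @export
suppression_profile <- function(pairs, windows, dilution = NA_character_) {
  need <- c("mz", "rt_min", "intensity_spiked", "intensity_unspiked")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs) == 0L || nrow(windows) == 0L) return(.empty_profile())

  out <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- pairs$rt_min[i] - windows$apex_rt
    # inclusive at both edges, robust to floating-point representation
    inside <- abs(d) - windows$half_width <= 1e-9
    if (!any(inside)) return(NULL)
    w <- which(inside)[which.min(abs(d[inside]))]
    undef <- pairs$intensity_unspiked[i] <= 0
    data.frame(
      mz = pairs$mz[i], rt_min = pairs$rt_min[i],
      window_ri = windows$ri[w], apex_rt = windows$apex_rt[w],
      delta_rt_to_apex = d[w],
      pct_of_unspiked = if (undef) NA_real_ else
        100 * pairs$intensity_spiked[i] / pairs$intensity_unspiked[i],
      undefined = undef,
      dilution = dilution,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_profile())
  rownames(out) <- NULL
  out
}

.empty_profile <- function() {
  data.frame(mz = numeric(), rt_min = numeric(), window_ri = numeric(),
             apex_rt = numeric(), delta_rt_to_apex = numeric(),
             pct_of_unspiked = numeric(), undefined = logical(),
             dilution = character(), stringsAsFactors = FALSE)
}

#' Median suppression per window across dilution levels
#'
#' Summarises suppression profiles from several spike dilutions: the median
#' percent-of-unspiked per (window, dilution), plus a per-window check
#' whether the median increases monotonically with dilution (more dilute
#' NAPS should suppress less).
#'
#' @param profiles Either a list of profile data.frames named by dilution
#'   label (`"1:20"`, ...) or one data.frame with a `dilution` column.
#' @return List with `medians` (data.frame `window_ri` x `dilution`:
#'   `median_pct`, `n`) and `monotone_increasing` (named logical per
#'   window, `NA` where a dilution level has no data).
#' @export
dilution_trend <- function(profiles) {
  if (is.data.frame(profiles)) prof <- profiles
  else {
    stopifnot(length(profiles) >= 2L, !is.null(names(profiles)))
    for (nm in names(profiles)) profiles[[nm]]$dilution <- nm
    prof <- do.call(rbind, profiles)
  }
  prof <- prof[!prof$undefined & !is.na(prof$pct_of_unspiked), ]
  dils <- unique(prof$dilution)
  if (length(dils) < 2L) stop("need >= 2 dilution levels")
  # order dilutions by numeric factor: "1:20" < "1:40" < "1:80"
  factor_of <- function(d) {
    num <- suppressWarnings(as.numeric(sub("^\\s*1\\s*:\\s*", "", d)))
    ifelse(is.na(num), suppressWarnings(as.numeric(d)), num)
  }
  dils <- dils[order(factor_of(dils))]

  grid <- expand.grid(window_ri = sort(unique(prof$window_ri)),
                      dilution = dils, stringsAsFactors = FALSE)
  grid$median_pct <- NA_real_
  grid$n <- 0L
  for (r in seq_len(nrow(grid))) {
    sel <- prof$window_ri == grid$window_ri[r] &
      prof$dilution == grid$dilution[r]
    if (any(sel)) {
      grid$median_pct[r] <- stats::median(prof$pct_of_unspiked[sel])
      grid$n[r] <- sum(sel)
    }
  }
  mono <- vapply(split(grid, grid$window_ri), function(g) {
    g <- g[match(dils, g$dilution), ]
    if (any(is.na(g$median_pct))) return(NA)
    all(diff(g$median_pct) > 0)
  }, logical(1))
  list(medians = grid, monotone_increasing = mono)
}
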