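# RI library construction from replicate standard runs.
#
# Each replicate run carries its own bracketing NAPS anchors; retention
# indices are calculated per replicate with that run's own calibration and
# only then averaged across replicates, so run-to-run RT drift (column
# ageing, solvent composition) is absorbed by the calibration rather than
# the library statistics.

#' Define a standard run
#'
#' Bundles one replicate's measurements with its bracketing NAPS anchor
#' runs. `measurements` must have one retention time per
#' (compound, adduct, polarity).
#'
#' @param measurements data.frame with columns `compound_id`, `adduct`,
#'   `polarity`, `rt_min`.
#' @param naps_before,naps_after NAPS runs as accepted by [make_anchors()];
#'   `naps_after` may be `NULL` when the calibration policy is `"before"`.
#' @param run_id Optional identifier.
#' @return A `standard_run` list.
#' @export
standard_run <- function(measurements, naps_before, naps_after = NULL,
                         run_id = NULL) {
  need <- c("compound_id", "adduct", "polarity", "rt_min")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  key <- interaction(measurements$compound_id, measurements$adduct,
                     measurements$polarity, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (compound, adduct, polarity) in one run")
  structure(list(measurements = measurements, naps_before = naps_before,
                 naps_after = naps_after, run_id = run_id),
            class = "standard_run")
}

#' Build an RI library from replicate standard runs
#'
#' Converts every replicate's retention times to indices with that
#' replicate's own calibration (method and bracketing policy applied per
#' run), then aggregates per (compound, adduct, polarity): mean and sample
#' standard deviation (n - 1) of the index, relative standard deviations of
#' index and retention time, and the replicate count. Entries whose mean
#' index is at or below `usable_ri_min` are kept but marked `usable = FALSE`
#' — robust indices require elution after the C3 homologue.
#'
#' @param runs List of [standard_run()] objects (length >= 1).
#' @param method Interpolation method for the per-run calibrations
#'   (`"linear"`, `"cubic"`, `"akima"`).
#' @param policy Bracketing policy for [make_anchors()].
#' @param usable_ri_min Usability threshold on the mean index (default 300).
#' @return An `ri_library` data.frame with columns `compound_id`, `adduct`,
#'   `polarity`, `mean_ri`, `sd_ri`, `rsd_ri_pct`, `mean_rt_min`,
#'   `rsd_rt_pct`, `n_replicates`, `usable`.
#' @export
build_ri_library <- function(runs, method = "linear", policy = "average",
                             usable_ri_min = 300) {
  if (inherits(runs, "standard_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, logical(1), "standard_run")))

  per_rep <- lapply(runs, function(run) {
    anchors <- make_anchors(run$naps_before, run$naps_after, policy = policy)
    cal <- ri_calibration(anchors, method = method,
                          usable_ri_min = usable_ri_min)
    m <- run$measurements
    cbind(m, ri = rt_to_ri(cal, m$rt_min)$ri)
  })
  all <- do.call(rbind, per_rep)
  key <- interaction(all$compound_id, all$adduct, all$polarity, drop = TRUE)

  agg <- lapply(split(all, key), function(g) {
    data.frame(
      compound_id = g$compound_id[1],
      adduct = g$adduct[1],
      polarity = g$polarity[1],
      mean_ri = mean(g$ri),
      sd_ri = if (nrow(g) > 1L) stats::sd(g$ri) else 0,
      mean_rt_min = mean(g$rt_min),
      sd_rt = if (nrow(g) > 1L) stats::sd(g$rt_min) else 0,
      n_replicates = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out$rsd_ri_pct <- 100 * out$sd_ri / out$mean_ri
  out$rsd_rt_pct <- 100 * out$sd_rt / out$mean_rt_min
  out$usable <- out$mean_ri > usable_ri_min
  out <- out[order(out$compound_id, out$polarity, out$adduct),
             c("compound_id", "adduct", "polarity", "mean_ri", "sd_ri",
               "rsd_ri_pct", "mean_rt_min", "rsd_rt_pct", "n_replicates",
               "usable")]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "policy") <- policy
  attr(out, "usable_ri_min") <- usable_ri_min
  class(out) <- c("ri_library", "data.frame")
  out
}

#' Merge two RI libraries
#'
#' Union keyed on (compound, adduct, polarity); entries present in both are
#' combined by the pooled mean weighted by replicate counts, with the pooled
#' standard deviation accounting for within- and between-library variance.
#'
#' @param a,b `ri_library` data.frames (or plain data.frames with the same
#'   columns).
#' @return Merged `ri_library`.
#' @export
merge_ri_libraries <- function(a, b) {
  if (nrow(b) == 0L) return(a)
  if (nrow(a) == 0L) return(b)
  keyify <- function(x) paste(x$compound_id, x$adduct, x$polarity, sep = "\r")
  ka <- keyify(a); kb <- keyify(b)
  common <- intersect(ka, kb)
  out <- rbind(as.data.frame(a)[!(ka %in% common), ],
               as.data.frame(b)[!(kb %in% common), ])
  for (k in common) {
    ra <- as.data.frame(a)[ka == k, ]; rb <- as.data.frame(b)[kb == k, ]
    n <- ra$n_replicates + rb$n_replicates
    pooled <- ra
    pooled$mean_ri <- (ra$n_replicates * ra$mean_ri +
                         rb$n_replicates * rb$mean_ri) / n
    pooled$mean_rt_min <- (ra$n_replicates * ra$mean_rt_min +
                             rb$n_replicates * rb$mean_rt_min) / n
    pooled$sd_ri <- .pooled_sd(ra$mean_ri, ra$sd_ri, ra$n_replicates,
                               rb$mean_ri, rb$sd_ri, rb$n_replicates)
    pooled$sd_rt <- NULL
    pooled$rsd_ri_pct <- 100 * pooled$sd_ri / pooled$mean_ri
    sd_rt <- .pooled_sd(ra$mean_rt_min, ra$rsd_rt_pct * ra$mean_rt_min / 100,
                        ra$n_replicates,
                        rb$mean_rt_min, rb$rsd_rt_pct * rb$mean_rt_min / 100,
                        rb$n_replicates)
    pooled$rsd_rt_pct <- 100 * sd_rt / pooled$mean_rt_min
    pooled$n_replicates <- n
    out <- rbind(out, pooled[names(out)])
  }
  out <- out[order(out$compound_id, out$polarity, out$adduct), ]
  rownames(out) <- NULL
  for (at in c("method", "policy", "usable_ri_min"))
    attr(out, at) <- attr(a, at)
  usable_min <- attr(a, "usable_ri_min")
  if (!is.null(usable_min)) out$usable <- out$mean_ri > usable_min
  class(out) <- c("ri_library", "data.frame")
  out
}

# exact pooled sample sd of two groups given group means/sds/sizes
.pooled_sd <- function(m1, s1, n1, m2, s2, n2) {
  n <- n1 + n2
  if (n < 2L) return(0)
  m <- (n1 * m1 + n2 * m2) / n
  ss <- (n1 - 1) * s1^2 + (n2 - 1) * s2^2 +
    n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  sqrt(ss / (n - 1))
}

#' Summarise detection modes of an RI library
#'
#' Partitions compounds by the ionisation modes in which they appear:
#' detected in both modes, only in positive, or only in negative mode.
#'
#' @param library An `ri_library` (or compatible data.frame).
#' @return Named integer vector with elements `both`, `pos_only`,
#'   `neg_only`.
#' @export
detection_mode_summary <- function(library) {
  if (nrow(library) == 0L)
    return(c(both = 0L, pos_only = 0L, neg_only = 0L))
  pol <- split(library$polarity, library$compound_id)
  has_pos <- vapply(pol, function(p) "pos" %in% p, logical(1))
  has_neg <- vapply(pol, function(p) "neg" %in% p, logical(1))
  c(both = sum(has_pos & has_neg),
    pos_only = sum(has_pos & !has_neg),
    neg_only = sum(!has_pos & has_neg))
}

#' @export
print.ri_library <- function(x, ...) {
  cat("RI library: ", nrow(x), " entries, ",
      length(unique(x$compound_id)), " compounds (",
      sum(x$usable), " usable)\n", sep = "")
  cat("  calibration: ", attr(x, "method") %||% "?", " / ",
      attr(x, "policy") %||% "?", "\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write / read an RI library CSV
#'
#' The CSV is the interchange surface for downstream matching; a JSON
#' sidecar (`<path>.json`) records provenance (calibration method,
#' bracketing policy, usability threshold).
#'
#' @param library An `ri_library`.
#' @param path CSV file path.
#' @return `write_ri_library` returns `path` invisibly; `read_ri_library`
#'   an `ri_library`.
#' @export
write_ri_library <- function(library, path) {
  df <- as.data.frame(library)
  digits <- c(mean_ri = 1, sd_ri = 2, rsd_ri_pct = 2, mean_rt_min = 3,
              rsd_rt_pct = 2, mz = 6)
  for (col in intersect(names(digits), names(df)))
    df[[col]] <- round(df[[col]], digits[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(method = attr(library, "method") %||% "unknown",
         policy = attr(library, "policy") %||% "unknown",
         usable_ri_min = attr(library, "usable_ri_min") %||% 300,
         n_entries = nrow(library)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ri_library
#' @export
read_ri_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(df, "method") <- meta$method
    attr(df, "policy") <- meta$policy
    attr(df, "usable_ri_min") <- meta$usable_ri_min
  }
  class(df) <- c("ri_library", "data.frame")
  df
}
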