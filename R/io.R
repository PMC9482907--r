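# Tabular I/O. CSV (RFC 4180, UTF-8, "." decimal separator) is the sole
# tabular interchange format; retention times are minutes everywhere.

.feature_required <- c("feature_id", "mz", "rt_min", "intensity", "polarity")

#' Read a feature table CSV
#'
#' Validates the header and column types of an LC-MS feature table.
#' Required columns: `feature_id`, `mz` (Da), `rt_min` (minutes),
#' `intensity`, `polarity` (`pos`/`neg`); optional: `ri`, `extrapolated`,
#' `below_usable`, `compound_id`. Type errors report the offending row
#' number.
#'
#' @param path CSV file path.
#' @return data.frame of features.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.feature_required, names(df))
  if (length(missing))
    stop("feature table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  for (col in c("mz", "rt_min", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in ", path, " at data row ", bad[1])
    df[[col]] <- v
  }
  bad_pol <- which(!df$polarity %in% c("pos", "neg"))
  if (length(bad_pol))
    stop("polarity must be 'pos' or 'neg' in ", path, " at data row ",
         bad_pol[1])
  df
}

#' Write a feature table CSV
#'
#' Deterministic formatting: m/z with 6 decimals, retention times with 3,
#' retention indices as integers, percentages with 1 decimal. Identical
#' input always yields a byte-identical file.
#'
#' @param features Feature data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- features
  fmt <- function(x, d) ifelse(is.na(x), "", formatC(x, digits = d,
                                                     format = "f"))
  if ("mz" %in% names(df)) df$mz <- fmt(df$mz, 6)
  for (col in intersect(c("rt_min", "mean_rt_min", "apex_rt",
                          "delta_rt_to_apex"), names(df)))
    df[[col]] <- fmt(as.numeric(df[[col]]), 3)
  for (col in intersect(c("ri", "mean_ri"), names(df)))
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        formatC(round(as.numeric(df[[col]])), format = "d"))
  for (col in grep("pct$", names(df), value = TRUE))
    df[[col]] <- fmt(as.numeric(df[[col]]), 1)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NAPS anchor CSV
#'
#' Columns `n_carbons` and `rt_min`.
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_naps_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("n_carbons", "rt_min")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("NAPS table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}
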