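# RT <-> RI calibration against bracketing NAPS anchors.
#
# The retention index of a compound is obtained by interpolating its retention
# time between the bracketing members of the NAPS homologous series, whose
# indices are fixed at 100 * n. The linear method implements
#   RI = RI0 + (RI1 - RI0) * (RT - RT0) / (RT1 - RT0)
# on the bracketing anchor pair; the spline methods fit a natural cubic or an
# Akima cubic interpolant through all anchors.

#' Build a calibration anchor set from bracketing NAPS injections
#'
#' Reference-standard injections are placed before and after a block of
#' samples. The anchor retention time used for calibration is either the
#' "before" run, the "after" run, or (default) the average RT of the two
#' bracketing runs per homologue. The retention index of homologue n is
#' 100 * n.
#'
#' Early homologues (C1-C3) elute in or close to the void volume and can have
#' nearly identical retention times. Anchors closer than `min_rt_gap` minutes
#' to their predecessor are collapsed, keeping the highest-n anchor of the
#' run, so that the anchor RTs are strictly increasing as every interpolant
#' requires.
#'
#' @param naps_before data.frame with columns `n_carbons` (or `n`) and
#'   `rt_min` (or `rt`): the NAPS run before the sample block.
#' @param naps_after Same layout, the run after the block; may be `NULL` for
#'   policies `"before"`.
#' @param policy `"average"` (default), `"before"` or `"after"`.
#' @param min_rt_gap Minimum RT spacing (minutes) between consecutive anchors
#'   after which they are kept separate; closer anchors are collapsed
#'   (default 0.01).
#' @return A `naps_anchors` data.frame with columns `n`, `ri`, `rt`, sorted
#'   by `ri`, carrying the policy as an attribute.
#' @examples
#' before <- data.frame(n_carbons = 4:6, rt_min = c(4.0, 5.0, 6.5))
#' after  <- data.frame(n_carbons = 4:6, rt_min = c(4.2, 5.1, 6.6))
#' make_anchors(before, after, policy = "average")
#' @export
make_anchors <- function(naps_before, naps_after = NULL,
                         policy = c("average", "before", "after"),
                         min_rt_gap = 0.01) {
  policy <- match.arg(policy)
  before <- .as_naps_run(naps_before, "naps_before")
  after <- if (!is.null(naps_after)) .as_naps_run(naps_after, "naps_after")

  if (policy == "average") {
    if (is.null(after))
      stop("policy 'average' requires both bracketing runs")
    miss_a <- setdiff(before$n, after$n)
    miss_b <- setdiff(after$n, before$n)
    if (length(miss_a) || length(miss_b))
      stop("bracketing runs cover different homologues; only in before: {",
           paste(miss_a, collapse = ","), "}, only in after: {",
           paste(miss_b, collapse = ","), "}")
    after <- after[match(before$n, after$n), ]
    rt <- (before$rt + after$rt) / 2
    n <- before$n
  } else if (policy == "before") {
    n <- before$n; rt <- before$rt
  } else {
    if (is.null(after)) stop("policy 'after' requires `naps_after`")
    n <- after$n; rt <- after$rt
  }

  ord <- order(n)
  n <- n[ord]; rt <- rt[ord]

  # collapse near-coeluting (possibly jitter-inverted) anchors, keeping the
  # highest-n member; larger inversions are a data error
  keep <- rep(TRUE, length(n))
  prev <- 1L
  for (i in seq_along(n)[-1]) {
    d <- rt[i] - rt[prev]
    if (d <= -min_rt_gap)
      stop("anchor RT decreases with homologue number (C", n[prev], " -> C",
           n[i], "); check the run")
    if (d < min_rt_gap) keep[prev] <- FALSE
    prev <- i
  }
  n <- n[keep]; rt <- rt[keep]
  if (any(diff(rt) <= 0))
    stop("anchor RT not strictly increasing after collapsing co-elution")
  if (length(n) < 2L)
    stop("need at least 2 distinct anchors after collapsing co-elution")

  out <- data.frame(n = n, ri = 100 * n, rt = rt)
  rownames(out) <- NULL
  attr(out, "policy") <- policy
  attr(out, "min_rt_gap") <- min_rt_gap
  class(out) <- c("naps_anchors", "data.frame")
  out
}

.as_naps_run <- function(x, what) {
  if (!is.data.frame(x)) stop("`", what, "` must be a data.frame")
  ncol_name <- intersect(c("n_carbons", "n"), names(x))[1]
  rtcol <- intersect(c("rt_min", "rt"), names(x))[1]
  if (is.na(ncol_name) || is.na(rtcol))
    stop("`", what, "` needs columns n_carbons (or n) and rt_min (or rt)")
  n <- as.integer(x[[ncol_name]]); rt <- as.numeric(x[[rtcol]])
  if (any(is.na(n)) || any(is.na(rt)) || any(rt <= 0))
    stop("`", what, "` has missing or non-positive values")
  if (anyDuplicated(n)) stop("`", what, "` lists a homologue twice")
  data.frame(n = n, rt = rt)[order(n), ]
}

.as_anchor_df <- function(anchors) {
  if (inherits(anchors, "naps_anchors")) return(anchors)
  if (!is.data.frame(anchors)) stop("`anchors` must be a data.frame")
  ricol <- intersect(c("ri", "index"), names(anchors))[1]
  rtcol <- intersect(c("rt", "rt_min"), names(anchors))[1]
  if (is.na(ricol) || is.na(rtcol))
    stop("`anchors` needs columns ri and rt (or rt_min)")
  out <- data.frame(ri = as.numeric(anchors[[ricol]]),
                    rt = as.numeric(anchors[[rtcol]]))
  out[order(out$ri), ]
}

#' Fit an RT-to-RI calibration model
#'
#' Fits an interpolant through calibration anchors (retention index,
#' retention time). Three methods are supported:
#' \describe{
#'   \item{`linear`}{Piecewise-linear bracketing: the index is interpolated
#'     linearly between the two anchors whose RTs bracket the query RT.}
#'   \item{`cubic`}{Natural cubic spline (second derivative zero at the
#'     boundary anchors), so collinear anchors reproduce the line exactly.}
#'   \item{`akima`}{Akima's 1970 piecewise-cubic interpolant, which limits
#'     the overshoot that natural cubic splines show where anchor spacing
#'     changes abruptly (e.g. the C1-C3 void-volume pile-up followed by
#'     gradient-spread anchors).}
#' }
#' All methods reproduce the anchors exactly. Queries outside the anchor RT
#' range are linearly extrapolated from the terminal segment slope and
#' flagged, so batch conversion never aborts.
#'
#' @param anchors A `naps_anchors` object from [make_anchors()], or any
#'   data.frame with columns `ri` and `rt` (strictly increasing RT).
#' @param method `"linear"` (default), `"cubic"` or `"akima"`.
#' @param usable_ri_min Indices at or below this value are flagged
#'   `below_usable` on conversion (default 300): robust indices require
#'   elution after the C3 homologue, which brackets the void volume.
#' @return An object of class `ri_calibration` with methods `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `fitted` and `plot`.
#' @seealso [rt_to_ri()], [ri_to_rt()], [compare_methods()]
#' @examples
#' cal <- ri_calibration(data.frame(ri = c(400, 500), rt = c(4, 6)))
#' predict(cal, rt = 5)  # RI 450
#' @export
ri_calibration <- function(anchors, method = c("linear", "cubic", "akima"),
                           usable_ri_min = 300) {
  method <- match.arg(method)
  a <- .as_anchor_df(anchors)
  if (nrow(a) < 2L) stop("need at least 2 anchors")
  if (any(diff(a$ri) <= 0)) stop("anchor ri must be strictly increasing")
  if (any(diff(a$rt) <= 0))
    stop("anchor rt must be strictly increasing; collapse duplicates first ",
         "(see make_anchors)")
  stopifnot(is.numeric(usable_ri_min), length(usable_ri_min) == 1L)
  structure(
    list(anchors = a, method = method, usable_ri_min = usable_ri_min,
         policy = attr(anchors, "policy")),
    class = "ri_calibration"
  )
}

# Evaluate the interpolant at rt (numeric vector), full precision.
.cal_eval <- function(model, rt) {
  a <- model$anchors
  switch(model$method,
    linear = .interp_linear(a$rt, a$ri, rt),
    cubic = stats::splinefun(a$rt, a$ri, method = "natural")(rt),
    akima = .akima_eval(a$rt, a$ri, rt)
  )
}

# Piecewise-linear bracketing with terminal-segment extrapolation.
.interp_linear <- function(x, y, xout) {
  i <- findInterval(xout, x, all.inside = TRUE)
  y[i] + (y[i + 1] - y[i]) * (xout - x[i]) / (x[i + 1] - x[i])
}

# Akima (1970) slopes with two-point quadratic endpoint extension.
.akima_slopes <- function(x, y) {
  n <- length(x)
  d <- diff(y) / diff(x)                       # segment slopes d_1..d_{n-1}
  dd <- c(2 * d[1] - d[min(2, length(d))],     # d_0, d_{-1} by extension
          d,
          2 * d[length(d)] - d[max(1, length(d) - 1)])
  dd <- c(2 * dd[1] - dd[2], dd, 2 * dd[length(dd)] - dd[length(dd) - 1])
  # dd has slopes indexed -1 .. n+1 ; point i uses dd[i+1] as its left slope
  t <- numeric(n)
  for (i in seq_len(n)) {
    d_m2 <- dd[i]; d_m1 <- dd[i + 1]; d_p1 <- dd[i + 2]; d_p2 <- dd[i + 3]
    w1 <- abs(d_p2 - d_p1); w2 <- abs(d_m1 - d_m2)
    t[i] <- if (w1 + w2 == 0) (d_m1 + d_p1) / 2 else
      (w1 * d_m1 + w2 * d_p1) / (w1 + w2)
  }
  t
}

.akima_eval <- function(x, y, xout) {
  n <- length(x)
  t <- .akima_slopes(x, y)
  i <- findInterval(xout, x, all.inside = TRUE)
  h <- x[i + 1] - x[i]
  s <- (xout - x[i]) / h
  below <- xout < x[1]; above <- xout > x[n]
  # Hermite cubic on each interior interval
  h00 <- (1 + 2 * s) * (1 - s)^2; h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s); h11 <- s^2 * (s - 1)
  out <- h00 * y[i] + h10 * h * t[i] + h01 * y[i + 1] + h11 * h * t[i + 1]
  # linear extrapolation with endpoint slopes
  out[below] <- y[1] + t[1] * (xout[below] - x[1])
  out[above] <- y[n] + t[n] * (xout[above] - x[n])
  out
}

#' Convert retention times to retention indices
#'
#' Evaluates a fitted calibration at the query retention times. Conversion
#' never fails on out-of-range input: values beyond the anchor RT range are
#' linearly extrapolated and flagged `extrapolated`, and indices at or below
#' `usable_ri_min` (default 300, the C3 void-volume boundary) are flagged
#' `below_usable`.
#'
#' @param model An `ri_calibration`.
#' @param rt Numeric vector of retention times (minutes), all > 0.
#' @param digits Indices are conventionally reported as integers
#'   (`digits = 0`); use `digits = NULL` for full precision.
#' @return data.frame with columns `rt`, `ri`, `extrapolated`,
#'   `below_usable`.
#' @export
rt_to_ri <- function(model, rt, digits = NULL) {
  stopifnot(inherits(model, "ri_calibration"), is.numeric(rt), all(rt > 0))
  ri <- .cal_eval(model, rt)
  if (!is.null(digits)) ri <- round(ri, digits)
  a <- model$anchors
  data.frame(
    rt = rt,
    ri = ri,
    extrapolated = rt < min(a$rt) | rt > max(a$rt),
    below_usable = ri <= model$usable_ri_min
  )
}

#' Convert retention indices back to retention times
#'
#' Inverse mapping of [rt_to_ri()], used e.g. to project library indices onto
#' a target system's time axis. For the linear method the bracketing formula
#' is inverted algebraically; for the spline methods the root of the fitted
#' interpolant is found numerically to |delta RI| < 1e-6. The query index
#' must lie within the anchor index range; a spline segment that is not
#' monotone and crosses the query index more than once raises an error
#' naming the segment.
#'
#' @param model An `ri_calibration`.
#' @param ri Numeric vector of retention indices within the anchor range.
#' @return Numeric vector of retention times (minutes).
#' @export
ri_to_rt <- function(model, ri) {
  stopifnot(inherits(model, "ri_calibration"), is.numeric(ri))
  a <- model$anchors
  if (any(ri < min(a$ri) | ri > max(a$ri)))
    stop("ri outside the anchor index range [", min(a$ri), ", ",
         max(a$ri), "]")
  vapply(ri, function(r) .invert_one(model, r), numeric(1))
}

.invert_one <- function(model, r) {
  a <- model$anchors
  hit <- which(a$ri == r)
  if (length(hit)) return(a$rt[hit[1]])
  seg <- findInterval(r, a$ri, all.inside = TRUE)
  lo <- a$rt[seg]; hi <- a$rt[seg + 1]
  if (model$method == "linear") {
    return(lo + (hi - lo) * (r - a$ri[seg]) / (a$ri[seg + 1] - a$ri[seg]))
  }
  f <- function(x) .cal_eval(model, x) - r
  grid <- seq(lo, hi, length.out = 257L)
  fg <- f(grid)
  sign_changes <- which(fg[-1] * fg[-length(fg)] < 0)
  roots_at_grid <- sum(abs(fg) < 1e-12)
  if (length(sign_changes) + roots_at_grid > 1L)
    stop("interpolant is not monotone on anchor segment ", seg,
         " (RI ", a$ri[seg], "-", a$ri[seg + 1],
         "); the index ", r, " maps to multiple retention times")
  if (length(sign_changes) == 0L) {
    # root sits at a grid point
    return(grid[which.min(abs(fg))])
  }
  i <- sign_changes[1]
  stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                 tol = 1e-10)$root
}

#' Compare interpolation methods on a retention-time grid
#'
#' Fits all three calibration methods on the same anchors and evaluates them
#' on a grid, for diagnosing where the methods disagree. Natural cubic
#' splines can overshoot where anchor spacing changes abruptly — typically
#' in the early-eluting region below RI ~750 when C1-C3 nearly co-elute —
#' while the Akima interpolant stays closer to linear bracketing.
#'
#' @param anchors Anchors accepted by [ri_calibration()].
#' @param rt_grid Numeric vector of retention times within the anchor range.
#' @param usable_ri_min Passed to [ri_calibration()].
#' @return data.frame with columns `rt`, `ri_linear`, `ri_cubic`,
#'   `ri_akima`.
#' @export
compare_methods <- function(anchors, rt_grid, usable_ri_min = 300) {
  stopifnot(is.numeric(rt_grid))
  fits <- lapply(c("linear", "cubic", "akima"), function(m)
    ri_calibration(anchors, method = m, usable_ri_min = usable_ri_min))
  data.frame(
    rt = rt_grid,
    ri_linear = .cal_eval(fits[[1]], rt_grid),
    ri_cubic = .cal_eval(fits[[2]], rt_grid),
    ri_akima = .cal_eval(fits[[3]], rt_grid)
  )
}

#' @export
print.ri_calibration <- function(x, ...) {
  a <- x$anchors
  cat("RT/RI calibration (", x$method, ")\n", sep = "")
  cat("  anchors: ", nrow(a), "  RI ", min(a$ri), "-", max(a$ri),
      "  RT ", format(min(a$rt), digits = 4), "-",
      format(max(a$rt), digits = 4), " min\n", sep = "")
  if (!is.null(x$policy)) cat("  bracketing policy:", x$policy, "\n")
  cat("  usable above RI", x$usable_ri_min, "\n")
  invisible(x)
}

#' @export
summary.ri_calibration <- function(object, ...) {
  a <- object$anchors
  res <- stats::residuals(object)
  out <- list(
    method = object$method,
    n_anchors = nrow(a),
    ri_range = range(a$ri),
    rt_range = range(a$rt),
    usable_ri_min = object$usable_ri_min,
    max_abs_residual = max(abs(res)),
    anchor_spacing_min = stats::setNames(
      as.numeric(summary(diff(a$rt))), names(summary(diff(a$rt))))
  )
  class(out) <- "summary.ri_calibration"
  out
}

#' @export
print.summary.ri_calibration <- function(x, ...) {
  cat("RT/RI calibration (", x$method, "), ", x$n_anchors, " anchors\n",
      sep = "")
  cat("  RI range: ", x$ri_range[1], "-", x$ri_range[2],
      ";  RT range: ", format(x$rt_range[1], digits = 4), "-",
      format(x$rt_range[2], digits = 4), " min\n", sep = "")
  cat("  anchor RT spacing (min):\n")
  print(signif(x$anchor_spacing_min, 4))
  cat("  max |anchor residual|: ",
      format(x$max_abs_residual, digits = 3), " RI units\n", sep = "")
  invisible(x)
}

#' @export
coef.ri_calibration <- function(object, ...) {
  as.matrix(object$anchors[, c("ri", "rt")])
}

#' Predict retention indices from a fitted calibration
#'
#' @param object An `ri_calibration`.
#' @param rt Numeric retention times (minutes), or a data.frame with an
#'   `rt`/`rt_min` column.
#' @param ... Passed to [rt_to_ri()] (e.g. `digits`).
#' @return See [rt_to_ri()].
#' @export
predict.ri_calibration <- function(object, rt, ...) {
  if (is.data.frame(rt)) {
    rtcol <- intersect(c("rt", "rt_min"), names(rt))[1]
    if (is.na(rtcol)) stop("data.frame `rt` needs an rt or rt_min column")
    rt <- as.numeric(rt[[rtcol]])
  }
  rt_to_ri(object, rt, ...)
}

#' @export
fitted.ri_calibration <- function(object, ...) {
  .cal_eval(object, object$anchors$rt)
}

#' @export
residuals.ri_calibration <- function(object, ...) {
  object$anchors$ri - stats::fitted(object)
}

#' Plot a calibration curve
#'
#' Draws the fitted RT-to-RI curve with the anchors; optionally overlays the
#' other interpolation methods for an overshoot diagnostic.
#'
#' @param x An `ri_calibration`.
#' @param compare Logical; overlay all three methods (default `FALSE`).
#' @param n_grid Grid resolution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ri_calibration <- function(x, compare = FALSE, n_grid = 400L, ...) {
  a <- x$anchors
  grid <- seq(min(a$rt), max(a$rt), length.out = n_grid)
  graphics::plot(grid, .cal_eval(x, grid), type = "l",
                 xlab = "retention time (min)", ylab = "retention index",
                 ...)
  if (compare) {
    cmp <- compare_methods(a, grid, x$usable_ri_min)
    graphics::lines(grid, cmp$ri_cubic, lty = 2)
    graphics::lines(grid, cmp$ri_akima, lty = 3)
    graphics::legend("bottomright", c(x$method, "cubic", "akima"),
                     lty = 1:3, bty = "n")
  }
  graphics::points(a$rt, a$ri, pch = 19)
  graphics::abline(h = x$usable_ri_min, col = "grey60", lty = 4)
  invisible(x)
}

#' Write / read a calibration as JSON
#'
#' Serialises the anchors, method, bracketing policy and usable-index
#' threshold; the interpolant is refitted on read, so the file is a portable
#' record of the calibration.
#'
#' @param model An `ri_calibration`.
#' @param path File path of the JSON document.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns an `ri_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "ri_calibration"))
  a <- model$anchors
  doc <- list(
    method = model$method,
    policy = if (is.null(model$policy)) "unknown" else model$policy,
    usable_ri_min = model$usable_ri_min,
    anchors = data.frame(
      n = if ("n" %in% names(a)) a$n else as.integer(a$ri / 100),
      ri = a$ri, rt_min = a$rt)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("method", "anchors")
  if (!all(need %in% names(doc)))
    stop("calibration JSON must contain fields: ",
         paste(need, collapse = ", "))
  anchors <- data.frame(ri = as.numeric(doc$anchors$ri),
                        rt = as.numeric(doc$anchors$rt_min))
  usable <- if (is.null(doc$usable_ri_min)) 300 else doc$usable_ri_min
  model <- ri_calibration(anchors, method = doc$method,
                          usable_ri_min = usable)
  if (!is.null(doc$policy) && doc$policy != "unknown")
    model$policy <- doc$policy
  model
}
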