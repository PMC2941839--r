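# Reference ranges: per-analyte, per-group and per-ratio mean / 5th / 95th
# centiles from a cohort of normal 24-h profiles, plus flagging against them.

#' Empirical centile with linear interpolation between order statistics
#'
#' Plotting position `(n - 1) * p + 1`: the centile is read off the sorted
#' sample by linear interpolation between the two bracketing order
#' statistics. Distribution-free; no log transform is applied.
#'
#' @param x numeric vector (finite values).
#' @param p probabilities in `[0, 1]`.
#' @return numeric vector of centiles, same length as `p`.
#' @export
centile <- function(x, p) {
  stopifnot(length(x) > 0, all(is.finite(x)), all(p >= 0 & p <= 1))
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

#' Build a reference set from a cohort of normal profiles
#'
#' For every analyte measured in at least `min_n` profiles, every report
#' group, and every diagnostic ratio evaluable in at least `min_n` profiles,
#' computes the cohort mean and the empirical 5th and 95th centiles
#' ([centile()]). Group totals use the fixed primary-group partition of the
#' registry; ratios are the registry's diagnostic ratio panel.
#'
#' @param cohort list of [steroid_profile()] objects, all 24-h collections.
#' @param registry registry from [load_registry()].
#' @param min_n minimum number of observations behind any reference range
#'   (default 20, the smallest n at which the 5th centile is interpolation
#'   rather than extrapolation).
#' @return an object of class `ssc_reference`: data.frame with columns
#'   `kind` (`analyte`/`group`/`ratio`), `key`, `n`, `mean`, `p5`, `p95`,
#'   and attributes `registry_version` and `min_n`.
#' @export
build_reference <- function(cohort, registry, min_n = 20) {
  stopifnot(all(vapply(cohort, inherits, TRUE, "ssc_profile")))
  if (length(cohort) < min_n)
    stop("cohort too small for key 'cohort': ", length(cohort), " < ", min_n,
         call. = FALSE)
  if (any(vapply(cohort, function(p) p$collection, "") != "24h"))
    stop("reference construction requires 24-h collections", call. = FALSE)

  rows <- list()
  add <- function(kind, key, v) {
    v <- v[!is.na(v)]
    if (length(v) >= min_n)
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, key = key, n = length(v), mean = mean(v),
        p5 = centile(v, 0.05), p95 = centile(v, 0.95),
        stringsAsFactors = FALSE)
  }

  for (ab in registry$metabolites$abbr) {
    v <- vapply(cohort, function(p)
      if (ab %in% names(p$amounts)) p$amounts[[ab]] else NA_real_, 0)
    add("analyte", ab, v)
  }
  gt <- lapply(cohort, group_totals, registry = registry)
  for (g in registry$group_order)
    add("group", g, vapply(gt, `[[`, 0, g))
  for (i in seq_len(nrow(registry$ratios))) {
    def <- registry$ratios[i, ]
    v <- vapply(cohort, function(p) {
      r <- compute_ratio(p, def, registry)
      if (is.na(r$value)) NA_real_ else r$value
    }, 0)
    add("ratio", def$id, v)
  }
  ranges <- do.call(rbind, rows)
  structure(ranges, class = c("ssc_reference", "data.frame"),
            registry_version = registry$version, min_n = min_n)
}

# internal: fetch one range row by key (and optionally kind); NULL if absent
lookup_range <- function(reference, key, kind = NULL) {
  i <- if (is.null(kind)) which(reference$key == key)
       else which(reference$key == key & reference$kind == kind)
  if (length(i) == 0) NULL else reference[i[1L], ]
}

#' Flag an observed value against a reference range
#'
#' Boundary convention: values equal to either centile are `normal`
#' (conservative). An `NA` observation (not measured / undefined ratio)
#' yields `undefined`.
#'
#' @param value numeric scalar or `NA`.
#' @param range one-row reference range (with `p5`, `p95`), or `NULL`.
#' @return one of `"low"`, `"normal"`, `"high"`, `"undefined"`.
#' @export
flag_value <- function(value, range) {
  if (is.null(range) || length(value) != 1L || is.na(value))
    return("undefined")
  if (value < range$p5) "low"
  else if (value > range$p95) "high"
  else "normal"
}

#' Serialize a reference set to JSON
#'
#' The registry version the reference was built under is embedded;
#' [read_reference()] restores it and [evaluate_panel()] refuses to apply a
#' reference built under a different registry version.
#'
#' @param reference `ssc_reference` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "ssc_reference"))
  ranges <- lapply(seq_len(nrow(reference)), function(i)
    list(kind = reference$kind[i], n = reference$n[i],
         mean = reference$mean[i], p5 = reference$p5[i],
         p95 = reference$p95[i]))
  names(ranges) <- reference$key
  x <- list(registry_version = attr(reference, "registry_version"),
            min_n = attr(reference, "min_n"),
            ranges = ranges)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a reference set written by [write_reference()]
#'
#' @param path JSON file path.
#' @return an `ssc_reference` object.
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path)
  ranges <- do.call(rbind, lapply(names(x$ranges), function(k) {
    r <- x$ranges[[k]]
    data.frame(kind = r$kind, key = k, n = as.integer(r$n),
               mean = as.numeric(r$mean), p5 = as.numeric(r$p5),
               p95 = as.numeric(r$p95), stringsAsFactors = FALSE)
  }))
  structure(ranges, class = c("ssc_reference", "data.frame"),
            registry_version = x$registry_version,
            min_n = as.integer(x$min_n))
}

#' @export
print.ssc_reference <- function(x, ...) {
  cat("reference set (registry", attr(x, "registry_version"), "):",
      sum(x$kind == "analyte"), "analytes,", sum(x$kind == "group"),
      "groups,", sum(x$kind == "ratio"), "ratios\n")
  invisible(x)
}
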