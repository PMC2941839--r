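# Structured clinical reports: the grouped quantitative report (per-analyte
# and per-group excretion against reference centiles) and the diagnostic
# ratio panel report, plus a thin graphics layer. Reports are primarily
# structured objects; figures are a rendering of them and are never the
# tested artifact.

#' Grouped quantitative report
#'
#' One row per registry analyte in fixed group order (androgens, androgen
#' precursors, mineralocorticoids and precursors, glucocorticoid precursors,
#' glucocorticoids; registry order within group), with the observed 24-h
#' excretion, the reference mean / 5th / 95th centiles, and a low / normal /
#' high flag. Analytes without a measurement or without a reference range
#' are listed with flag `undefined`. Group totals are reported the same way.
#'
#' @param profile a 24-h [steroid_profile()].
#' @param reference an `ssc_reference` built under the same registry version.
#' @param registry registry from [load_registry()].
#' @return list of class `ssc_quant_report` with `sample_id`, `rows` and
#'   `group_rows` data.frames.
#' @export
render_quant_report <- function(profile, reference, registry) {
  stopifnot(inherits(profile, "ssc_profile"),
            inherits(reference, "ssc_reference"))
  if (profile$collection != "24h")
    stop("quantitative report requires a 24-h collection", call. = FALSE)
  if (!identical(attr(reference, "registry_version"), registry$version))
    stop("reference/registry version mismatch", call. = FALSE)

  m <- registry$metabolites
  ord <- order(match(m$group, registry$group_order), seq_len(nrow(m)))
  one <- function(kind, key, group, amount) {
    rng <- lookup_range(reference, key, kind)
    data.frame(
      key = key, group = group,
      amount = if (is.null(amount)) NA_real_ else amount,
      ref_mean = if (is.null(rng)) NA_real_ else rng$mean,
      ref_p5 = if (is.null(rng)) NA_real_ else rng$p5,
      ref_p95 = if (is.null(rng)) NA_real_ else rng$p95,
      flag = flag_value(if (is.null(amount)) NA_real_ else amount, rng),
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(ord, function(i) {
    ab <- m$abbr[i]
    amt <- if (ab %in% names(profile$amounts)) profile$amounts[[ab]] else NULL
    one("analyte", ab, m$group[i], amt)
  }))
  names(rows)[names(rows) == "key"] <- "analyte"
  gt <- group_totals(profile, registry)
  measured_groups <- unique(m$group[m$abbr %in% names(profile$amounts)])
  group_rows <- do.call(rbind, lapply(registry$group_order, function(g)
    one("group", g, g,
        if (g %in% measured_groups) gt[[g]] else NULL)))
  names(group_rows)[names(group_rows) == "key"] <- "group_label"
  group_rows$group <- NULL
  row.names(rows) <- row.names(group_rows) <- NULL
  structure(list(sample_id = profile$sample_id, rows = rows,
                 group_rows = group_rows,
                 registry_version = registry$version),
            class = "ssc_quant_report")
}

#' Diagnostic ratio panel report
#'
#' Wraps [evaluate_panel()] into one section per disorder (fixed panel
#' order), each holding the disorder's evaluated ratios and its call.
#'
#' @inheritParams render_quant_report
#' @return list of class `ssc_ratio_report` with `sample_id`, `sections`
#'   (named list per disorder: `ratios` data.frame + `call` row) and the
#'   underlying `panel`.
#' @export
render_ratio_panel <- function(profile, reference, registry) {
  panel <- evaluate_panel(profile, registry, reference)
  disorders <- unique(registry$ratios$disorder)
  sections <- lapply(disorders, function(d) {
    list(ratios = panel$ratios[panel$ratios$disorder == d, , drop = FALSE],
         call = panel$calls[panel$calls$disorder == d, , drop = FALSE])
  })
  names(sections) <- disorders
  structure(list(sample_id = profile$sample_id, sections = sections,
                 panel = panel, registry_version = registry$version),
            class = "ssc_ratio_report")
}

#' Serialize a report to JSON
#'
#' @param report an `ssc_quant_report` or `ssc_ratio_report`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  x <- if (inherits(report, "ssc_quant_report")) {
    list(type = "quant", sample_id = report$sample_id,
         registry_version = report$registry_version,
         rows = report$rows, group_rows = report$group_rows)
  } else if (inherits(report, "ssc_ratio_report")) {
    list(type = "ratio_panel", sample_id = report$sample_id,
         registry_version = report$registry_version,
         ratios = report$panel$ratios, calls = report$panel$calls)
  } else stop("not a report object", call. = FALSE)
  js <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      na = "null"))
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

#' Plot a report
#'
#' Dots for the observed values over a shaded 5th-95th centile band on a
#' log-scaled value axis. Zero or undefined observations are drawn as open
#' markers at the axis floor, never dropped. A structured JSON sidecar
#' (`<out_path>.json`) carries the exact plotted values; tests assert on the
#' sidecar, not on pixels.
#'
#' @param report an `ssc_quant_report` or `ssc_ratio_report`.
#' @param out_path output figure path.
#' @param format `"svg"` or `"png"`.
#' @return `out_path`, invisibly.
#' @export
plot_reports <- function(report, out_path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (inherits(report, "ssc_quant_report")) {
    keys <- report$rows$analyte
    obs <- report$rows$amount
    lo <- report$rows$ref_p5
    hi <- report$rows$ref_p95
    main <- paste("Urinary steroid quantitation (ug/24 h):",
                  report$sample_id)
  } else if (inherits(report, "ssc_ratio_report")) {
    keys <- report$panel$ratios$id
    obs <- report$panel$ratios$value
    lo <- vapply(keys, function(k) NA_real_, 0)  # band from reference p95
    hi <- report$panel$ratios$p95
    main <- paste("Diagnostic ratio panel:", report$sample_id)
  } else stop("not a report object", call. = FALSE)

  floor_val <- max(min(c(obs[obs > 0], hi[hi > 0], lo[lo > 0]),
                       na.rm = TRUE) / 10, 1e-6)
  clip <- function(x) ifelse(is.na(x) | x <= 0, floor_val, x)
  if (format == "svg") grDevices::svg(out_path, width = 10, height = 5)
  else grDevices::png(out_path, width = 1000, height = 500)
  op <- graphics::par(mar = c(8, 4, 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  n <- length(keys)
  ymax <- max(clip(c(obs, hi)), na.rm = TRUE) * 2
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(floor_val, ymax),
                 log = "y", xaxt = "n", xlab = "", ylab = "value",
                 main = main)
  ok <- !is.na(hi)
  graphics::segments(which(ok), clip(lo[ok]), which(ok), clip(hi[ok]),
                     col = "grey70", lwd = 6)
  undef <- is.na(obs) | obs <= 0
  graphics::points(which(!undef), obs[!undef], pch = 16)
  if (any(undef))
    graphics::points(which(undef), rep(floor_val, sum(undef)), pch = 1,
                     col = "grey40")
  graphics::axis(1, at = seq_len(n), labels = keys, las = 2, cex.axis = 0.6)

  sidecar <- list(keys = keys, observed = obs, p5 = lo, p95 = hi,
                  n_markers = length(keys), sample_id = report$sample_id)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                              na = "null"),
             paste0(out_path, ".json"), useBytes = TRUE)
  invisible(out_path)
}

#' @export
print.ssc_quant_report <- function(x, ...) {
  cat("quantitative steroid report for", x$sample_id, "\n")
  print(x$group_rows, digits = 4)
  invisible(x)
}

#' @export
print.ssc_ratio_report <- function(x, ...) {
  print(x$panel)
  invisible(x)
}
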