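# Diagnostic engine: evaluate precursor/product ratios on a profile, flag
# them against a reference set, call disorders, and compute the grouped
# totals used by the quantitative report.

#' Evaluate one diagnostic ratio on a profile
#'
#' Numerator and denominator are sums over the analytes the profile actually
#' measured; analytes absent from the profile contribute nothing and are
#' recorded in `missing`. The value is undefined (`NA`) when no numerator
#' analyte was measured, when no denominator analyte was measured, or when
#' the measured denominator sum is zero (below-detection denominators do not
#' support a ratio). Undefined is a value, not an error.
#'
#' @param profile a [steroid_profile()].
#' @param definition one row of `registry$ratios` (or a list with the same
#'   fields).
#' @param registry registry from [load_registry()].
#' @return list of class `ssc_ratio_result`: `ratio_id`, `disorder`, `value`,
#'   `numerator_sum`, `denominator_sum`, `missing` (character vector).
#' @export
compute_ratio <- function(profile, definition, registry) {
  stopifnot(inherits(profile, "ssc_profile"))
  num <- resolve_abbr(unlist(definition$numerator), registry)
  den <- resolve_abbr(unlist(definition$denominator), registry)
  amounts <- profile$amounts
  num_in <- num[num %in% names(amounts)]
  den_in <- den[den %in% names(amounts)]
  ns <- sum(amounts[num_in])
  ds <- sum(amounts[den_in])
  value <- if (length(num_in) == 0 || length(den_in) == 0 || ds <= 0)
    NA_real_ else ns / ds
  structure(list(ratio_id = as.character(definition$id),
                 disorder = as.character(definition$disorder),
                 value = value, numerator_sum = ns, denominator_sum = ds,
                 missing = c(setdiff(num, num_in), setdiff(den, den_in))),
            class = "ssc_ratio_result")
}

#' Grouped 24-h excretion totals
#'
#' Adds each measured analyte's amount to its single primary report group.
#' The five group totals always sum to the total measured excretion.
#'
#' @inheritParams compute_ratio
#' @return named numeric vector over the five report groups, in fixed report
#'   order.
#' @export
group_totals <- function(profile, registry) {
  stopifnot(inherits(profile, "ssc_profile"))
  if (profile$collection != "24h")
    stop("quantitative grouping requires a 24-h collection", call. = FALSE)
  out <- stats::setNames(numeric(length(registry$group_order)),
                         registry$group_order)
  if (length(profile$amounts)) {
    g <- registry$metabolites$group[match(names(profile$amounts),
                                          registry$metabolites$abbr)]
    for (i in seq_along(profile$amounts))
      out[[g[i]]] <- out[[g[i]]] + profile$amounts[[i]]
  }
  out
}

#' Evaluate the full diagnostic ratio panel and call disorders
#'
#' Every registry ratio is evaluated on the profile and flagged against the
#' reference set. Ratio abnormality is one-sided: a ratio is `high` when it
#' exceeds the cohort 95th centile (boundary equality is `normal`). A
#' disorder is called positive only when all of its ratios are high and none
#' is undefined. Positive calls are ranked by the geometric mean of
#' `value / p95` over the disorder's ratios.
#'
#' @param profile a [steroid_profile()].
#' @param registry registry from [load_registry()].
#' @param reference an `ssc_reference` built under the same registry version.
#' @return list of class `ssc_panel` with elements `sample_id`, `ratios`
#'   (data.frame: id, disorder, value, numerator_sum, denominator_sum, p95,
#'   centile_excess, flag) and `calls` (data.frame: disorder, gene, n_ratios,
#'   n_high, n_undefined, positive, rank_score; positive calls first, in
#'   descending rank_score).
#' @export
evaluate_panel <- function(profile, registry, reference) {
  stopifnot(inherits(reference, "ssc_reference"))
  if (!identical(attr(reference, "registry_version"), registry$version))
    stop("reference was built under registry version '",
         attr(reference, "registry_version"), "' but registry is '",
         registry$version, "'", call. = FALSE)

  defs <- registry$ratios
  res <- lapply(seq_len(nrow(defs)), function(i)
    compute_ratio(profile, defs[i, ], registry))
  p95 <- vapply(defs$id, function(id) {
    r <- lookup_range(reference, id, "ratio")
    if (is.null(r)) NA_real_ else r$p95
  }, 0)
  value <- vapply(res, `[[`, 0, "value")
  excess <- ifelse(is.na(value) | is.na(p95), NA_real_, value / p95)
  flag <- ifelse(is.na(value) | is.na(p95), "undefined",
                 ifelse(value > p95, "high", "normal"))
  ratios <- data.frame(
    id = defs$id, disorder = defs$disorder,
    value = value,
    numerator_sum = vapply(res, `[[`, 0, "numerator_sum"),
    denominator_sum = vapply(res, `[[`, 0, "denominator_sum"),
    p95 = p95, centile_excess = excess, flag = flag,
    stringsAsFactors = FALSE, row.names = NULL)

  disorders <- unique(defs$disorder)
  calls <- do.call(rbind, lapply(disorders, function(d) {
    sub <- ratios[ratios$disorder == d, ]
    n_undef <- sum(sub$flag == "undefined")
    n_high <- sum(sub$flag == "high")
    rank_score <- if (n_undef > 0) NA_real_
                  else exp(mean(log(sub$centile_excess)))
    data.frame(disorder = d,
               gene = defs$gene[match(d, defs$disorder)],
               n_ratios = nrow(sub), n_high = n_high,
               n_undefined = n_undef,
               positive = n_high == nrow(sub) && n_undef == 0,
               rank_score = rank_score,
               stringsAsFactors = FALSE)
  }))
  ord <- order(!calls$positive,
               ifelse(is.na(calls$rank_score), -Inf, -calls$rank_score),
               match(calls$disorder, disorders))
  calls <- calls[ord, ]
  row.names(calls) <- NULL
  structure(list(sample_id = profile$sample_id, ratios = ratios,
                 calls = calls,
                 registry_version = registry$version),
            class = "ssc_panel")
}

#' Top-ranked positive disorder call of a panel
#'
#' @param panel an `ssc_panel` from [evaluate_panel()].
#' @return disorder id of the highest-ranked positive call, or `NA_character_`
#'   when no call is positive.
#' @export
top_call <- function(panel) {
  stopifnot(inherits(panel, "ssc_panel"))
  pos <- panel$calls[panel$calls$positive, , drop = FALSE]
  if (nrow(pos) == 0) NA_character_ else pos$disorder[1L]
}

#' Serialize a panel result to JSON
#'
#' @param panel an `ssc_panel`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
panel_json <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "ssc_panel"))
  x <- list(sample_id = panel$sample_id,
            registry_version = panel$registry_version,
            ratios = panel$ratios, calls = panel$calls)
  js <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      na = "null"))
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

#' @export
print.ssc_panel <- function(x, ...) {
  cat("diagnostic ratio panel for sample", x$sample_id, "\n")
  pos <- x$calls[x$calls$positive, , drop = FALSE]
  if (nrow(pos) == 0) {
    cat("  no positive disorder call\n")
  } else {
    for (i in seq_len(nrow(pos)))
      cat(sprintf("  POSITIVE %s (%s): %d/%d ratios high, rank score %.2f\n",
                  pos$disorder[i], pos$gene[i], pos$n_high[i],
                  pos$n_ratios[i], pos$rank_score[i]))
  }
  invisible(x)
}
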