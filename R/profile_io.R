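# Reading/writing quantified urinary steroid profiles (long or wide tabular
# dialect, TSV preferred, comma accepted). Absent analyte = not measured;
# explicit 0 = measured below detection. Delimiter is sniffed from the header.

#' Construct a steroid profile
#'
#' @param sample_id non-empty sample identifier.
#' @param amounts named numeric vector, analyte abbreviation -> excretion
#'   (ug/24 h for 24-h collections, ug/L for spot samples). Names may use
#'   Greek-letter aliases; they are canonicalized against the registry.
#' @param registry registry from [load_registry()].
#' @param collection `"24h"` or `"spot"`.
#' @param meta named character vector of free-form annotations.
#' @return an object of class `ssc_profile`.
#' @export
steroid_profile <- function(sample_id, amounts, registry,
                            collection = c("24h", "spot"),
                            meta = character()) {
  collection <- match.arg(collection)
  if (!is.character(sample_id) || length(sample_id) != 1L ||
      is.na(sample_id) || !nzchar(sample_id))
    stop("sample_id must be a non-empty string", call. = FALSE)
  amounts <- unlist(amounts)
  if (length(amounts)) {
    if (is.null(names(amounts)) || any(!nzchar(names(amounts))))
      stop("amounts must be named by analyte abbreviation", call. = FALSE)
    if (any(!is.finite(amounts)) || any(amounts < 0))
      stop("amounts must be finite and >= 0", call. = FALSE)
    names(amounts) <- resolve_abbr(names(amounts), registry)
    if (anyDuplicated(names(amounts)))
      stop("duplicate analyte in profile ", sample_id, call. = FALSE)
    amounts <- amounts[order(match(names(amounts),
                                   registry$metabolites$abbr))]
  } else {
    amounts <- stats::setNames(numeric(0), character(0))
  }
  structure(list(sample_id = sample_id, collection = collection,
                 amounts = amounts, meta = meta),
            class = "ssc_profile")
}

#' @export
print.ssc_profile <- function(x, ...) {
  cat("steroid profile", x$sample_id, sprintf("(%s collection)", x$collection),
      "-", length(x$amounts), "analytes\n")
  invisible(x)
}

# internal: sniff the field delimiter from a header line
sniff_sep <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

#' Read steroid profiles from a tabular file
#'
#' Two dialects are auto-detected from the header: long format with columns
#' `sample_id`, `metabolite`, `amount_ug_per_24h` (one row per measurement),
#' or wide format with `sample_id` plus one column per analyte abbreviation.
#' An optional `collection` column (`24h`/`spot`) is honoured in both
#' dialects. Unknown analyte columns abort with an error; analytes absent
#' from a sample are "not measured" (absent from the map, not zero).
#'
#' @param path file path.
#' @param registry registry from [load_registry()].
#' @return list of [steroid_profile()] objects, one per distinct sample_id in
#'   file order.
#' @export
read_profiles <- function(path, registry) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- sniff_sep(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", encoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("header must name a sample_id column", call. = FALSE)

  parse_amount <- function(x, rows) {
    suppressWarnings(v <- as.numeric(x))  # "." decimal only, locale-free
    bad <- (!is.na(x) & nzchar(x)) & (is.na(v) | v < 0)
    if (any(bad))
      stop("non-numeric or negative amount at data row ",
           paste(rows[bad], collapse = ", "), call. = FALSE)
    v
  }

  long <- all(c("metabolite", "amount_ug_per_24h") %in% names(df)) ||
    all(c("metabolite", "amount") %in% names(df))
  profiles <- list()
  if (long) {
    amt_col <- if ("amount_ug_per_24h" %in% names(df)) "amount_ug_per_24h"
               else "amount"
    df$.amount <- parse_amount(df[[amt_col]], seq_len(nrow(df)))
    if (anyNA(df$.amount))
      stop("missing amount in long-format file", call. = FALSE)
    resolve_abbr(unique(df$metabolite), registry)  # fail fast on unknowns
    for (sid in unique(df$sample_id)) {
      rows <- df[df$sample_id == sid, , drop = FALSE]
      if (anyDuplicated(resolve_abbr(rows$metabolite, registry)))
        stop("duplicate (sample, analyte) pair for sample ", sid,
             call. = FALSE)
      collection <- if ("collection" %in% names(rows))
        unique(rows$collection)[1] else "24h"
      profiles[[length(profiles) + 1L]] <- steroid_profile(
        sid, stats::setNames(rows$.amount, rows$metabolite), registry,
        collection = collection)
    }
  } else {
    keep <- setdiff(names(df), c("sample_id", "collection"))
    resolve_abbr(keep, registry)  # unknown analyte columns are an error
    if (anyDuplicated(df$sample_id))
      stop("duplicate sample_id rows in wide-format file", call. = FALSE)
    for (i in seq_len(nrow(df))) {
      vals <- parse_amount(unlist(df[i, keep, drop = TRUE]),
                           rep(i, length(keep)))
      names(vals) <- keep
      vals <- vals[!is.na(vals)]  # empty cell = not measured
      collection <- if ("collection" %in% names(df)) df$collection[i]
                    else "24h"
      profiles[[length(profiles) + 1L]] <- steroid_profile(
        df$sample_id[i], vals, registry, collection = collection)
    }
  }
  profiles
}

#' Write steroid profiles to a tabular file
#'
#' Inverse of [read_profiles()]: `read_profiles(write_profiles(x))` recovers
#' the profiles (amounts to full double precision via `format(..., digits =
#' 17)`). Canonical ASCII abbreviations are always used on output.
#'
#' @param profiles list of [steroid_profile()] objects.
#' @param path output file path.
#' @param format `"long"` or `"wide"`.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("long", "wide"),
                           sep = "\t") {
  format <- match.arg(format)
  if (inherits(profiles, "ssc_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "ssc_profile")))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "long") {
    writeLines(paste(c("sample_id", "collection", "metabolite",
                       "amount_ug_per_24h"), collapse = sep), con)
    for (p in profiles) {
      if (length(p$amounts))
        writeLines(paste(p$sample_id, p$collection, names(p$amounts),
                         fmt(p$amounts), sep = sep), con)
    }
  } else {
    cols <- unique(unlist(lapply(profiles, function(p) names(p$amounts))))
    writeLines(paste(c("sample_id", "collection", cols), collapse = sep), con)
    for (p in profiles) {
      vals <- vapply(cols, function(ab)
        if (ab %in% names(p$amounts)) fmt(p$amounts[[ab]]) else "",
        "")
      writeLines(paste(c(p$sample_id, p$collection, vals), collapse = sep),
                 con)
    }
  }
  invisible(path)
}
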