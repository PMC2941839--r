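# Versioned knowledge base: urinary steroid metabolites, the steroidogenesis
# pathway (enzymes, cofactors, back-door branch), and the diagnostic ratio
# panel for inborn errors of steroidogenesis and steroid metabolism.

# md5 of each bundled registry release, recorded when the artifact is built
.registry_checksums <- c(v1 = "b705bdef399758fe295449ec6340eab3")

.registry_groups <- c("androgens", "androgen_precursors",
                      "mineralocorticoids_and_precursors",
                      "glucocorticoid_precursors", "glucocorticoids")

#' Load a bundled steroid registry release
#'
#' Reads the versioned registry artifact shipped with the package and returns
#' the validated, effectively immutable knowledge base used by every other
#' function: the metabolite table (analyte abbreviation, trivial name, parent
#' hormones, report group), the steroidogenesis pathway graph (hormones as
#' nodes, enzyme-catalysed conversions as edges annotated with cofactor
#' dependencies and back-door membership), and the diagnostic ratio panel
#' (per-disorder precursor-metabolite / product-metabolite ratios).
#'
#' @param version_tag name of a bundled registry release (currently `"v1"`).
#' @return an object of class `ssc_registry`: a list with elements
#'   `version`, `checksum`, `group_order`, `hormones` (data.frame),
#'   `reactions` (data.frame with list-column `cofactors`), `metabolites`
#'   (data.frame with list-columns `parents` and `aliases`) and `ratios`
#'   (data.frame with list-columns `numerator` and `denominator`).
#' @examples
#' reg <- load_registry()
#' nrow(reg$metabolites)   # 33 analytes
#' @export
load_registry <- function(version_tag = "v1") {
  if (!is.character(version_tag) || length(version_tag) != 1L ||
      !version_tag %in% names(.registry_checksums)) {
    stop("unknown registry version tag: ", paste(version_tag, collapse = ","),
         " (available: ", paste(names(.registry_checksums), collapse = ", "),
         ")", call. = FALSE)
  }
  path <- system.file("extdata",
                      sprintf("steroid_registry_%s.json", version_tag),
                      package = "steroidscreen", mustWork = TRUE)
  checksum <- unname(tools::md5sum(path))
  if (!identical(checksum, unname(.registry_checksums[version_tag]))) {
    stop("registry artifact for version ", version_tag,
         " does not match its recorded checksum", call. = FALSE)
  }
  raw <- jsonlite::read_json(path)

  hormones <- data.frame(
    id = vapply(raw$hormones, `[[`, "", "id"),
    class_label = vapply(raw$hormones, `[[`, "", "class_label"),
    stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    substrate = vapply(raw$reactions, `[[`, "", "substrate"),
    product = vapply(raw$reactions, `[[`, "", "product"),
    enzyme = vapply(raw$reactions, `[[`, "", "enzyme"),
    backdoor = vapply(raw$reactions, `[[`, FALSE, "backdoor"),
    reversible_pair = vapply(raw$reactions, `[[`, FALSE, "reversible_pair"),
    base_rate = vapply(raw$reactions, function(r) as.numeric(r$base_rate), 0),
    stringsAsFactors = FALSE
  )
  reactions$cofactors <- lapply(raw$reactions, function(r)
    as.character(unlist(r$cofactors)))
  metabolites <- data.frame(
    abbr = vapply(raw$metabolites, `[[`, "", "abbr"),
    trivial_name = vapply(raw$metabolites, `[[`, "", "trivial_name"),
    group = vapply(raw$metabolites, `[[`, "", "group"),
    a_ring_note = vapply(raw$metabolites, `[[`, "", "a_ring_note"),
    stringsAsFactors = FALSE
  )
  metabolites$parents <- lapply(raw$metabolites, function(m)
    as.character(unlist(m$parents)))
  metabolites$aliases <- lapply(raw$metabolites, function(m)
    as.character(unlist(m$aliases)))
  ratios <- data.frame(
    id = vapply(raw$ratios, `[[`, "", "id"),
    disorder = vapply(raw$ratios, `[[`, "", "disorder"),
    gene = vapply(raw$ratios, `[[`, "", "gene"),
    direction = vapply(raw$ratios, `[[`, "", "direction"),
    stringsAsFactors = FALSE
  )
  ratios$numerator <- lapply(raw$ratios, function(r)
    as.character(unlist(r$numerator)))
  ratios$denominator <- lapply(raw$ratios, function(r)
    as.character(unlist(r$denominator)))

  reg <- structure(
    list(version = raw$version,
         checksum = checksum,
         group_order = as.character(unlist(raw$group_order)),
         hormones = hormones,
         reactions = reactions,
         metabolites = metabolites,
         ratios = ratios),
    class = "ssc_registry"
  )
  validate_registry(reg)
  reg
}

# internal: enforce the registry type invariants; stops on first violation
validate_registry <- function(reg) {
  m <- reg$metabolites
  if (anyDuplicated(tolower(m$abbr)))
    stop("metabolite abbreviations must be unique case-insensitively")
  if (!all(m$group %in% .registry_groups))
    stop("metabolite with unknown report group")
  if (!setequal(reg$group_order, .registry_groups))
    stop("group_order must enumerate the five report groups")
  bad <- !vapply(m$parents, function(p)
    length(p) > 0 && all(p %in% reg$hormones$id), TRUE)
  if (any(bad))
    stop("metabolite(s) with missing/unknown parent hormones: ",
         paste(m$abbr[bad], collapse = ", "))
  if (anyDuplicated(reg$hormones$id)) stop("duplicate hormone ids")
  rxn <- reg$reactions
  if (anyDuplicated(rxn[c("substrate", "product", "enzyme")]))
    stop("duplicate (substrate, product, enzyme) reaction")
  if (!all(c(rxn$substrate, rxn$product) %in% reg$hormones$id))
    stop("reaction references an unknown hormone")
  # POR tags exactly the microsomal type II CYP set; b5 only the 17,20-lyase
  por <- vapply(rxn$cofactors, function(x) "POR" %in% x, TRUE)
  type2 <- rxn$enzyme %in% c("CYP17A1_hydroxylase", "CYP17A1_lyase",
                             "CYP21A2", "CYP19A1")
  if (!identical(por, type2))
    stop("POR cofactor tags must match the microsomal type II CYP reactions")
  b5 <- vapply(rxn$cofactors, function(x) "b5" %in% x, TRUE)
  if (!identical(b5, rxn$enzyme == "CYP17A1_lyase"))
    stop("b5 cofactor must tag exactly the 17,20-lyase reactions")
  for (i in seq_len(nrow(reg$ratios))) {
    ab <- c(reg$ratios$numerator[[i]], reg$ratios$denominator[[i]])
    if (length(reg$ratios$numerator[[i]]) == 0 ||
        length(reg$ratios$denominator[[i]]) == 0)
      stop("ratio with empty numerator or denominator: ", reg$ratios$id[i])
    if (!all(ab %in% m$abbr))
      stop("ratio ", reg$ratios$id[i], " references unknown analyte(s): ",
           paste(setdiff(ab, m$abbr), collapse = ", "))
  }
  invisible(reg)
}

# internal: alias/case-insensitive resolution to canonical ASCII abbreviations.
# Returns NA for unresolvable input.
resolve_abbr <- function(abbr, registry, error = TRUE) {
  m <- registry$metabolites
  canon <- m$abbr
  lut <- c(stats::setNames(canon, tolower(canon)),
           unlist(Map(function(al, ab) stats::setNames(rep(ab, length(al)),
                                                       tolower(al)),
                      m$aliases, canon)))
  out <- unname(lut[tolower(trimws(as.character(abbr)))])
  if (error && anyNA(out)) {
    stop("unknown analyte abbreviation(s): ",
         paste(unique(abbr[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Parent hormones of a urinary analyte
#'
#' @param abbr analyte abbreviation (canonical ASCII, Greek-letter alias, or
#'   any case variant).
#' @param registry registry from [load_registry()].
#' @return character vector of hormone ids the analyte is a metabolite of.
#' @examples
#' reg <- load_registry()
#' parents_of("THE", reg)   # cortisol, cortisone
#' @export
parents_of <- function(abbr, registry) {
  ab <- resolve_abbr(abbr, registry)
  registry$metabolites$parents[[match(ab, registry$metabolites$abbr)]]
}

#' Report group of a urinary analyte
#'
#' Each analyte belongs to exactly one of the five report groups used by the
#' grouped quantitative report: androgens, androgen precursors,
#' mineralocorticoids and precursors, glucocorticoid precursors,
#' glucocorticoids.
#'
#' @inheritParams parents_of
#' @return length-1 character, one of the five group labels.
#' @export
group_of <- function(abbr, registry) {
  ab <- resolve_abbr(abbr, registry)
  registry$metabolites$group[match(ab, registry$metabolites$abbr)]
}

#' Serialize a registry to its canonical JSON form
#'
#' Used for round-trip checks and for the CLI `registry show` subcommand.
#' Serializing the same registry twice yields byte-identical output.
#'
#' @param registry registry object.
#' @return a length-1 character scalar of JSON.
#' @export
registry_json <- function(registry) {
  stopifnot(inherits(registry, "ssc_registry"))
  x <- list(
    version = registry$version,
    group_order = registry$group_order,
    hormones = registry$hormones,
    reactions = registry$reactions[
      c("substrate", "product", "enzyme", "cofactors", "backdoor",
        "reversible_pair", "base_rate")],
    metabolites = registry$metabolites[
      c("abbr", "trivial_name", "parents", "group", "aliases", "a_ring_note")],
    ratios = registry$ratios[
      c("id", "disorder", "gene", "numerator", "denominator", "direction")]
  )
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' @export
print.ssc_registry <- function(x, ...) {
  cat("steroid registry", x$version, "\n")
  cat("  metabolites:", nrow(x$metabolites), "\n")
  cat("  hormones:   ", nrow(x$hormones), "\n")
  cat("  reactions:  ", nrow(x$reactions), "\n")
  cat("  ratios:     ", nrow(x$ratios), "across",
      length(unique(x$ratios$disorder)), "disorders\n")
  invisible(x)
}
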