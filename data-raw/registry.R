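# Builds the versioned registry artifact shipped in inst/extdata/.
# Run from the package root:  Rscript data-raw/registry.R
# The JSON file is the authoritative on-disk form; this script is its source.

suppressMessages(library(jsonlite))

# -- hormones -----------------------------------------------------------------
# class labels follow the colour classes of the pathway figure
hormones <- list(
  list(id = "cholesterol",          class_label = "common_intermediate"),
  list(id = "pregnenolone",         class_label = "common_intermediate"),
  list(id = "progesterone",         class_label = "common_intermediate"),
  list(id = "17OH-pregnenolone",    class_label = "glucocorticoid_preliminary"),
  list(id = "17OHP",                class_label = "glucocorticoid_preliminary"),
  list(id = "11-deoxycortisol",     class_label = "glucocorticoid_preliminary"),
  list(id = "21-deoxycortisol",     class_label = "glucocorticoid_preliminary"),
  list(id = "DOC",                  class_label = "mineralocorticoid"),
  list(id = "corticosterone",       class_label = "mineralocorticoid"),
  list(id = "aldosterone",          class_label = "mineralocorticoid"),
  list(id = "cortisol",             class_label = "glucocorticoid"),
  list(id = "cortisone",            class_label = "glucocorticoid"),
  list(id = "DHEA",                 class_label = "androgen"),
  list(id = "androstenedione",      class_label = "androgen"),
  list(id = "testosterone",         class_label = "androgen"),
  list(id = "DHT",                  class_label = "androgen"),
  list(id = "11OH-androstenedione", class_label = "androgen"),
  # back-door (alternative androgen) pathway intermediates
  list(id = "5a-17OH-pregnanolone", class_label = "androgen"),
  list(id = "androsterone",         class_label = "androgen"),
  list(id = "estrone",              class_label = "estrogen"),
  list(id = "estradiol",            class_label = "estrogen")
)

# -- reactions ----------------------------------------------------------------
# base_rate is the default branch weight used by the flux simulator; the
# aromatase edges default to 0 because the estrogen branch carries no urinary
# analytes in this registry (mass routed there could never be excreted onto an
# analyte). reversible_pair marks the cortisol<->cortisone interconversion,
# which the simulator resolves through the 11-oxo partition instead of as flux.
rx <- function(substrate, product, enzyme, cofactors = character(),
               backdoor = FALSE, reversible_pair = FALSE, base_rate = 1) {
  list(substrate = substrate, product = product, enzyme = enzyme,
       cofactors = as.list(cofactors), backdoor = backdoor,
       reversible_pair = reversible_pair, base_rate = base_rate)
}

reactions <- list(
  rx("cholesterol", "pregnenolone", "CYP11A1", "ADR_Adx"),
  rx("pregnenolone", "progesterone", "HSD3B2"),
  rx("pregnenolone", "17OH-pregnenolone", "CYP17A1_hydroxylase", "POR"),
  rx("17OH-pregnenolone", "17OHP", "HSD3B2"),
  rx("17OH-pregnenolone", "DHEA", "CYP17A1_lyase", c("POR", "b5")),
  rx("progesterone", "17OHP", "CYP17A1_hydroxylase", "POR"),
  rx("progesterone", "DOC", "CYP21A2", "POR"),
  rx("17OHP", "11-deoxycortisol", "CYP21A2", "POR"),
  rx("17OHP", "21-deoxycortisol", "CYP11B1", "ADR_Adx"),
  rx("DOC", "corticosterone", "CYP11B1", "ADR_Adx"),
  rx("corticosterone", "aldosterone", "CYP11B2", "ADR_Adx"),
  rx("11-deoxycortisol", "cortisol", "CYP11B1", "ADR_Adx"),
  rx("DHEA", "androstenedione", "HSD3B2"),
  rx("androstenedione", "testosterone", "HSD17B3"),
  rx("testosterone", "DHT", "SRD5A2"),
  rx("androstenedione", "estrone", "CYP19A1", "POR", base_rate = 0),
  rx("testosterone", "estradiol", "CYP19A1", "POR", base_rate = 0),
  rx("androstenedione", "11OH-androstenedione", "CYP11B1", "ADR_Adx"),
  rx("cortisol", "cortisone", "HSD11B2", reversible_pair = TRUE),
  rx("cortisone", "cortisol", "HSD11B1", "H6PDH", reversible_pair = TRUE),
  rx("17OHP", "5a-17OH-pregnanolone", "SRD5A2", backdoor = TRUE,
     base_rate = 0.5),
  rx("5a-17OH-pregnanolone", "androsterone", "CYP17A1_lyase", c("POR", "b5"),
     backdoor = TRUE),
  rx("androsterone", "DHT", "HSD17B3", backdoor = TRUE)
)

# -- metabolites --------------------------------------------------------------
a_ring <- "3a,5b A-ring configuration unless the abbreviation states otherwise"
met <- function(abbr, trivial_name, parents, group, aliases = character()) {
  list(abbr = abbr, trivial_name = trivial_name, parents = as.list(parents),
       group = group, aliases = as.list(aliases), a_ring_note = a_ring)
}

metabolites <- list(
  met("An", "androsterone",
      c("androstenedione", "testosterone", "DHT", "DHEA"), "androgens"),
  met("Et", "etiocholanolone", c("testosterone", "DHEA"), "androgens"),
  met("DHEA", "dehydroepiandrosterone (and sulfate)", "DHEA",
      "androgen_precursors"),
  met("11b-OH-An", "11b-hydroxy-androsterone",
      c("11OH-androstenedione", "cortisol"), "androgens", "11β-OH-An"),
  met("11b-OH-Et", "11b-hydroxy-etiocholanolone", "cortisol", "androgens",
      "11β-OH-Et"),
  met("11-OXO-Et", "11-oxo-etiocholanolone", "cortisol", "androgens"),
  met("16a-DHEA", "16a-hydroxy-DHEA", "DHEA", "androgen_precursors",
      "16α-DHEA"),
  met("PD", "pregnanediol", c("progesterone", "DOC"),
      "glucocorticoid_precursors"),
  met("5PD", "pregnenediol", "pregnenolone", "androgen_precursors"),
  met("Pregnadienol", "pregnadienol (chemical artifact of pregnenediol)",
      "pregnenolone", "androgen_precursors"),
  met("17HP", "17-hydroxy-pregnanolone", "17OHP", "glucocorticoid_precursors"),
  met("3a5a17HP", "3a,5a-17-hydroxy-pregnanolone", "17OHP",
      "glucocorticoid_precursors", "3α5α17HP"),
  met("PT", "pregnanetriol", "17OHP", "glucocorticoid_precursors"),
  met("5PT", "5-pregnenetriol", "17OH-pregnenolone", "androgen_precursors"),
  met("PTONE", "pregnanetriolone", "21-deoxycortisol",
      "glucocorticoid_precursors"),
  met("THDOC", "tetrahydrodeoxycorticosterone", "DOC",
      "mineralocorticoids_and_precursors"),
  met("5aTHDOC", "5a-tetrahydrodeoxycorticosterone", "DOC",
      "mineralocorticoids_and_precursors", "5αTHDOC"),
  met("THS", "tetrahydro-11-deoxycortisol", "11-deoxycortisol",
      "glucocorticoid_precursors"),
  met("THA", "tetrahydro-11-dehydrocorticosterone", "corticosterone",
      "mineralocorticoids_and_precursors"),
  met("5aTHA", "5a-tetrahydro-11-dehydrocorticosterone", "corticosterone",
      "mineralocorticoids_and_precursors", "5αTHA"),
  met("THB", "tetrahydrocorticosterone", "corticosterone",
      "mineralocorticoids_and_precursors"),
  met("5aTHB", "5a-tetrahydrocorticosterone", "corticosterone",
      "mineralocorticoids_and_precursors", "5αTHB"),
  met("THALDO", "tetrahydroaldosterone", "aldosterone",
      "mineralocorticoids_and_precursors"),
  met("THE", "tetrahydrocortisone", c("cortisol", "cortisone"),
      "glucocorticoids"),
  met("THF", "tetrahydrocortisol", "cortisol", "glucocorticoids"),
  met("5aTHF", "5a-tetrahydrocortisol", "cortisol", "glucocorticoids",
      "5αTHF"),
  met("a-cortolone", "alpha-cortolone", c("cortisol", "cortisone"),
      "glucocorticoids", "α-cortolone"),
  met("b-cortolone", "beta-cortolone", c("cortisol", "cortisone"),
      "glucocorticoids", "β-cortolone"),
  met("a-cortol", "alpha-cortol", "cortisol", "glucocorticoids",
      "α-cortol"),
  met("b-cortol", "beta-cortol", "cortisol", "glucocorticoids",
      "β-cortol"),
  met("6b-OH-cortisol", "6b-hydroxy-cortisol", "cortisol", "glucocorticoids",
      "6β-OH-cortisol"),
  # urinary free hormones, measurable analytes beyond the tetrahydro list
  met("F", "cortisol (urinary free)", "cortisol", "glucocorticoids"),
  met("E", "cortisone (urinary free)", "cortisone", "glucocorticoids")
)

# -- diagnostic ratios (precursor metabolites / product metabolites) ----------
cortmet <- c("THE", "THF", "5aTHF")
rat <- function(id, disorder, gene, numerator, denominator) {
  list(id = id, disorder = disorder, gene = gene,
       numerator = as.list(numerator), denominator = as.list(denominator),
       direction = "elevated_in_disorder")
}

ratios <- list(
  rat("21OHD_1", "21OHD", "CYP21A2", "17HP", cortmet),
  rat("21OHD_2", "21OHD", "CYP21A2", "PT", cortmet),
  rat("21OHD_3", "21OHD", "CYP21A2", "PTONE", cortmet),
  rat("11bOHD_1", "11bOHD", "CYP11B1", "THS", cortmet),
  rat("17aOHD_1", "17aOHD", "CYP17A1",
      c("THA", "5aTHA", "THB", "5aTHB"), cortmet),
  rat("17aOHD_2", "17aOHD", "CYP17A1",
      c("THA", "5aTHA", "THB", "5aTHB"), c("An", "Et")),
  rat("HSD3B2_1", "HSD3B2", "HSD3B2", "DHEA", cortmet),
  rat("HSD3B2_2", "HSD3B2", "HSD3B2", "5PT", cortmet),
  rat("ORD_1", "ORD", "POR", c("17HP", "PT"), c("An", "Et")),
  rat("ORD_2", "ORD", "POR", c("17HP", "PT"), cortmet),
  rat("ORD_3", "ORD", "POR", "PD", cortmet),
  rat("ORD_4", "ORD", "POR", "5PD", cortmet),
  rat("ORD_5", "ORD", "POR", c("THA", "5aTHA", "THB", "5aTHB"), cortmet),
  rat("AME_1", "AME", "HSD11B2", "F", "E"),
  rat("AME_2", "AME", "HSD11B2", c("THF", "5aTHF"), "THE"),
  rat("AME_3", "AME", "HSD11B2",
      c("a-cortol", "b-cortol"), c("a-cortolone", "b-cortolone")),
  rat("AME_4", "AME", "HSD11B2", c("F", "E"), c("THF", "5aTHF", "THE")),
  rat("ACRD_1", "ACRD", "H6PDH", "THE", c("THF", "5aTHF")),
  rat("ACRD_2", "ACRD", "H6PDH",
      c("a-cortolone", "b-cortolone"), c("a-cortol", "b-cortol")),
  rat("SRD5A2_1", "SRD5A2", "SRD5A2", "Et", "An"),
  rat("SRD5A2_2", "SRD5A2", "SRD5A2", "THB", "5aTHB"),
  rat("SRD5A2_3", "SRD5A2", "SRD5A2", "THF", "5aTHF"),
  rat("HSD17B3_1", "HSD17B3", "HSD17B3", c("An", "Et"), cortmet)
)

registry <- list(
  version = "v1",
  schema = "steroidscreen-registry/1",
  group_order = list("androgens", "androgen_precursors",
                     "mineralocorticoids_and_precursors",
                     "glucocorticoid_precursors", "glucocorticoids"),
  hormones = hormones,
  reactions = reactions,
  metabolites = metabolites,
  ratios = ratios
)

out <- file.path("inst", "extdata", "steroid_registry_v1.json")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
writeLines(toJSON(registry, auto_unbox = TRUE, pretty = TRUE, digits = NA),
           out, useBytes = TRUE)
cat("md5:", unname(tools::md5sum(out)), "\n")
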