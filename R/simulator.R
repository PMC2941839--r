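# Pathway-flux simulator: steady-state linear branch competition over the
# steroidogenesis graph, post-synthesis metabolism partitioning (5a/5b A-ring
# reduction, 11-oxo/11-hydroxy interconversion, free-hormone escape), yield
# mapping onto the urinary analytes, and multiplicative log-normal noise.
#
# The model is deliberately linear: at every hormone node the inflow splits
# among the outgoing enzymatic edges and a unit-weight excretion sink in
# proportion to base_rate * drive * activity (times por_activity on
# POR-dependent reactions). That is the minimal structure reproducing the
# precursor build-up / product depletion that the diagnostic ratios read out,
# and it is exactly solvable.

#' Construct a simulation scenario
#'
#' @param name scenario label (used in simulated sample ids).
#' @param activities named numeric vector, enzyme id -> residual activity in
#'   `[0, 1]`; enzymes not named keep activity 1.
#' @param por_activity activity of P450 oxidoreductase, applied
#'   multiplicatively to every POR-dependent (microsomal type II CYP)
#'   reaction.
#' @param rho_5alpha fraction of A-ring reduction going 5a (vs 5b) in the
#'   paired urinary metabolites (An/Et, 5aTHF/THF, 5aTHB/THB, 5aTHA/THA,
#'   5aTHDOC/THDOC).
#' @param beta_11oxo fraction of the cortisol/cortisone-derived pool carried
#'   by 11-oxo (cortisone-side) analytes; resolves the reversible
#'   cortisol-cortisone pair instead of graph flux.
#' @param free_escape fraction of the cortisol/cortisone pool excreted as the
#'   free hormones F and E rather than as ring-reduced metabolites. The
#'   apparent-mineralocorticoid-excess preset raises it, standing in for the
#'   reduced metabolic clearance (elevated urinary free cortisol) of
#'   11b-HSD2 deficiency.
#' @param enable_backdoor route part of the 17OHP pool down the back-door
#'   (5a-reduced) androgen pathway.
#' @param input_flux total pregnenolone production entering the network
#'   (ug/24 h equivalents).
#' @param noise_sigma standard deviation of the log-scale multiplicative
#'   noise applied per analyte by [simulate_cohort()].
#' @param drive named numeric vector, enzyme id -> branch-rate multiplier
#'   `>= 0` (default 1), modelling trophic over-stimulation of a branch; the
#'   17b-HSD3 preset uses it for the gonadotropin-driven androgen backbone.
#' @param seed default RNG seed for [simulate_cohort()].
#' @return an object of class `ssc_scenario`.
#' @export
simulation_scenario <- function(name = "custom",
                                activities = numeric(),
                                por_activity = 1,
                                rho_5alpha = 0.4,
                                beta_11oxo = 0.55,
                                free_escape = 0.04,
                                enable_backdoor = FALSE,
                                input_flux = 10000,
                                noise_sigma = 0.3,
                                drive = numeric(),
                                seed = 1L) {
  activities <- unlist(activities)
  drive <- unlist(drive)
  frac_ok <- function(x) all(is.finite(x)) && all(x >= 0 & x <= 1)
  if (length(activities) && (is.null(names(activities)) ||
                             !frac_ok(activities)))
    stop("activities must be a named vector of fractions in [0, 1]",
         call. = FALSE)
  if (!frac_ok(por_activity) || !frac_ok(rho_5alpha) ||
      !frac_ok(beta_11oxo) || !frac_ok(free_escape))
    stop("por_activity, rho_5alpha, beta_11oxo and free_escape must lie in ",
         "[0, 1]", call. = FALSE)
  if (!is.finite(input_flux) || input_flux <= 0)
    stop("input_flux must be > 0", call. = FALSE)
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be >= 0", call. = FALSE)
  if (length(drive) && (is.null(names(drive)) || any(!is.finite(drive)) ||
                        any(drive < 0)))
    stop("drive must be a named vector of non-negative multipliers",
         call. = FALSE)
  structure(list(name = name, activities = activities,
                 por_activity = por_activity, rho_5alpha = rho_5alpha,
                 beta_11oxo = beta_11oxo, free_escape = free_escape,
                 enable_backdoor = isTRUE(enable_backdoor),
                 input_flux = input_flux, noise_sigma = noise_sigma,
                 drive = drive, seed = as.integer(seed)),
            class = "ssc_scenario")
}

.preset_names <- c("normal", "21OHD", "11bOHD", "17aOHD", "HSD3B2", "ORD",
                   "ORD_pregnancy", "AME", "ACRD", "SRD5A2", "HSD17B3")

# memoized registry for preset construction (trophic compensation needs the
# pathway; loading/validating the artifact on every call would be wasteful)
.preset_env <- new.env(parent = emptyenv())
preset_registry <- function() {
  if (is.null(.preset_env$registry))
    .preset_env$registry <- load_registry()
  .preset_env$registry
}

#' Disorder scenario presets
#'
#' Enzymatic disorders keep a residual activity of 0.05 (not 0) so every
#' diagnostic ratio stays finite. P450 oxidoreductase deficiency (ORD) sets
#' `por_activity = 0.05`, leaving the mitochondrial (ADR/Adx-dependent)
#' CYP11B enzymes untouched; the pregnancy variant additionally opens the
#' back-door androgen route. The metabolism disorders act on the
#' post-synthesis partitions: AME shifts the 11-oxo balance to the hydroxy
#' side (`beta_11oxo = 0.15`) and raises the free-hormone escape; ACRD
#' shifts it to the oxo side (`beta_11oxo = 0.95`); 5a-reductase deficiency
#' sets `rho_5alpha = 0.05` alongside the enzyme block. 17b-HSD3 deficiency
#' combines the enzyme block with gonadotropin drive of the androgen
#' backbone.
#'
#' Presets model the intact pituitary feedback of non-stressed patients:
#' `input_flux` is scaled so that total glucocorticoid output matches the
#' normal scenario (ACTH drives precursor production up until cortisol
#' output is restored). Diagnostic ratios are invariant under this scaling;
#' it is what makes the grouped quantitative report show the classic
#' picture of e.g. ORD (normal glucocorticoids, elevated corticosterone and
#' 17OHP metabolites, low androgens) instead of a uniform collapse. The
#' applied factor is recorded in the scenario's `gc_compensation` field.
#'
#' @param name one of `r paste0('"', paste(.preset_names, collapse = '", "'), '"')`.
#' @param ... overrides passed to [simulation_scenario()] (e.g. `seed`,
#'   `noise_sigma`).
#' @return an `ssc_scenario`.
#' @export
scenario_preset <- function(name, ...) {
  if (length(name) != 1L || !name %in% .preset_names)
    stop("unknown preset '", paste(name, collapse = ","), "'; available: ",
         paste(.preset_names, collapse = ", "), call. = FALSE)
  args <- switch(name,
    normal = list(),
    "21OHD" = list(activities = c(CYP21A2 = 0.05)),
    "11bOHD" = list(activities = c(CYP11B1 = 0.05)),
    "17aOHD" = list(activities = c(CYP17A1_hydroxylase = 0.05,
                                   CYP17A1_lyase = 0.05)),
    HSD3B2 = list(activities = c(HSD3B2 = 0.05)),
    ORD = list(por_activity = 0.05),
    ORD_pregnancy = list(por_activity = 0.05, enable_backdoor = TRUE),
    AME = list(beta_11oxo = 0.15, free_escape = 0.30),
    ACRD = list(beta_11oxo = 0.95),
    SRD5A2 = list(activities = c(SRD5A2 = 0.05), rho_5alpha = 0.05),
    HSD17B3 = list(activities = c(HSD17B3 = 0.05),
                   drive = c(CYP17A1_lyase = 8))
  )
  sc <- do.call(simulation_scenario, c(list(name = name), args, list(...)))
  reg <- preset_registry()
  gc_out <- function(x) {
    s <- steady_state_flux(reg, x)$sink
    (s[["cortisol"]] + s[["cortisone"]]) / x$input_flux
  }
  norm <- do.call(simulation_scenario, list(name = "normal"))
  k <- gc_out(norm) / gc_out(sc)
  sc$input_flux <- sc$input_flux * k
  sc$gc_compensation <- k
  sc
}

#' Steady-state flux through the steroidogenesis pathway
#'
#' Drops the reversible cortisol/cortisone pair (resolved downstream by
#' `beta_11oxo`) and back-door edges when disabled, then solves the node
#' balance exactly as a linear system: each node's inflow splits among its
#' outgoing edges and a unit excretion sink in proportion to
#' `base_rate * drive * activity` (POR-dependent edges additionally carry
#' `por_activity`). Input enters at pregnenolone. Deterministic.
#'
#' @param registry registry from [load_registry()].
#' @param scenario an `ssc_scenario`.
#' @return list of class `ssc_flux` with named vectors `inflow` and `sink`
#'   over hormone nodes; `sum(sink)` equals `input_flux` (mass balance).
#' @export
steady_state_flux <- function(registry, scenario) {
  stopifnot(inherits(scenario, "ssc_scenario"))
  enzymes <- unique(registry$reactions$enzyme)
  bad <- setdiff(c(names(scenario$activities), names(scenario$drive)),
                 enzymes)
  if (length(bad))
    stop("scenario references unknown enzyme(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  rxn <- registry$reactions[!registry$reactions$reversible_pair, ]
  act <- function(e) {
    a <- if (e %in% names(scenario$activities)) scenario$activities[[e]] else 1
    d <- if (e %in% names(scenario$drive)) scenario$drive[[e]] else 1
    a * d
  }
  por <- vapply(rxn$cofactors, function(x) "POR" %in% x, TRUE)
  w <- rxn$base_rate * vapply(rxn$enzyme, act, 0) *
    ifelse(por, scenario$por_activity, 1)
  w[rxn$backdoor & !scenario$enable_backdoor] <- 0

  nodes <- registry$hormones$id
  n <- length(nodes)
  sink_w <- rep(1, n)
  out_total <- sink_w + as.vector(
    tapply(w, factor(rxn$substrate, levels = nodes), sum, default = 0))
  out_total[is.na(out_total)] <- 1
  # transfer fractions: frac[u, v] of node u's inflow routed to v
  frac <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(rxn)))
    frac[rxn$substrate[i], rxn$product[i]] <-
      frac[rxn$substrate[i], rxn$product[i]] +
      w[i] / out_total[match(rxn$substrate[i], nodes)]
  b <- stats::setNames(rep(0, n), nodes)
  b[["pregnenolone"]] <- scenario$input_flux
  inflow <- solve(diag(n) - t(frac), b)
  inflow <- stats::setNames(as.vector(inflow), nodes)
  sink <- inflow * sink_w / out_total
  structure(list(inflow = inflow, sink = sink,
                 input_flux = scenario$input_flux),
            class = "ssc_flux")
}

# fixed analyte targets of each hormone's excretion sink; pool tags mark mass
# that is re-partitioned afterwards (see excrete)
.an_et_pair <- c("An", "Et")          # 5a member first
.oxo_side <- c("THE", "a-cortolone", "b-cortolone", "11-OXO-Et")
.oh_side <- c("THF", "5aTHF", "a-cortol", "b-cortol", "6b-OH-cortisol",
              "11b-OH-Et", "11b-OH-An")

#' Map a flux state onto a noise-free urinary steroid profile
#'
#' Each hormone's excretion-sink flux is distributed uniformly across its
#' urinary metabolites (pregnadienol is a fixed artifact fraction, 0.2, of
#' the pregnenediol channel). Afterwards the 5a/5b pairs are re-partitioned
#' by `rho_5alpha`, and the cortisol/cortisone pool is split into a
#' free-hormone fraction (`free_escape`, giving urinary free F and E) and a
#' metabolite fraction divided between the 11-oxo analytes (THE, cortolones,
#' 11-oxo-etiocholanolone, free E) and the 11-hydroxy analytes (THF, 5aTHF,
#' cortols, 6b-OH-cortisol, 11b-OH-Et, 11b-OH-An, free F) by `beta_11oxo`.
#' Back-door mass (3a5a-17HP from the 5a-17OH-pregnanolone intermediate,
#' androsterone from the back-door androsterone/DHT route) is assigned
#' directly and bypasses the 5a/5b re-partition. Total analyte mass equals
#' `input_flux`.
#'
#' @param flux an `ssc_flux` from [steady_state_flux()].
#' @param scenario the scenario that produced it.
#' @param registry registry from [load_registry()].
#' @param sample_id sample identifier for the returned profile.
#' @return a noise-free [steroid_profile()] covering all registry analytes.
#' @export
excrete <- function(flux, scenario, registry,
                    sample_id = paste0(scenario$name, "_noisefree")) {
  stopifnot(inherits(flux, "ssc_flux"), inherits(scenario, "ssc_scenario"))
  s <- flux$sink
  rho <- scenario$rho_5alpha
  beta <- scenario$beta_11oxo
  fe <- scenario$free_escape
  a <- stats::setNames(numeric(nrow(registry$metabolites)),
                       registry$metabolites$abbr)
  pair <- function(a5, a5b, mass) {   # 5a member, 5b member
    a[[a5]] <<- a[[a5]] + rho * mass
    a[[a5b]] <<- a[[a5b]] + (1 - rho) * mass
  }

  a[["Pregnadienol"]] <- 0.2 * s[["pregnenolone"]]
  a[["5PD"]] <- 0.8 * s[["pregnenolone"]]
  a[["PD"]] <- s[["progesterone"]] + s[["DOC"]] / 3
  a[["5PT"]] <- s[["17OH-pregnenolone"]]
  third <- s[["17OHP"]] / 3
  a[["17HP"]] <- third
  a[["3a5a17HP"]] <- third + s[["5a-17OH-pregnanolone"]]
  a[["PT"]] <- third
  a[["PTONE"]] <- s[["21-deoxycortisol"]]
  a[["THS"]] <- s[["11-deoxycortisol"]]
  pair("5aTHDOC", "THDOC", 2 * s[["DOC"]] / 3)
  pair("5aTHA", "THA", s[["corticosterone"]] / 2)
  pair("5aTHB", "THB", s[["corticosterone"]] / 2)
  a[["THALDO"]] <- s[["aldosterone"]]
  a[["DHEA"]] <- s[["DHEA"]] / 4
  a[["16a-DHEA"]] <- s[["DHEA"]] / 4
  an_et_pool <- s[["DHEA"]] / 2 + s[["androstenedione"]] +
    s[["testosterone"]] + s[["DHT"]]
  pair("An", "Et", an_et_pool)
  # back-door androsterone is 5a by construction and bypasses the partition
  a[["An"]] <- a[["An"]] + s[["androsterone"]]
  a[["11b-OH-An"]] <- s[["11OH-androstenedione"]]

  gc_pool <- s[["cortisol"]] + s[["cortisone"]]
  a[["F"]] <- fe * (1 - beta) * gc_pool
  a[["E"]] <- fe * beta * gc_pool
  met <- (1 - fe) * gc_pool
  oxo_each <- beta * met / length(.oxo_side)
  for (ab in .oxo_side) a[[ab]] <- a[[ab]] + oxo_each
  oh_each <- (1 - beta) * met / length(.oh_side)
  thf_pool <- 2 * oh_each                    # THF + 5aTHF combined slot
  pair("5aTHF", "THF", thf_pool)
  for (ab in setdiff(.oh_side, c("THF", "5aTHF")))
    a[[ab]] <- a[[ab]] + oh_each

  unmapped <- s[["estrone"]] + s[["estradiol"]]
  if (unmapped > 1e-9 * flux$input_flux)
    warning("estrogen-branch flux carries no urinary analytes; ",
            "analyte mass closure does not include it")
  steroid_profile(sample_id, a, registry, collection = "24h")
}

#' Simulate a cohort of urinary steroid profiles
#'
#' Noise-free excretion from [steady_state_flux()] + [excrete()], multiplied
#' per analyte by `exp(N(0, noise_sigma))` with a deterministic per-sample
#' substream of the seed; reproducible bit-for-bit for a given (scenario, n,
#' seed).
#'
#' @param scenario an `ssc_scenario`.
#' @param n number of profiles (>= 1).
#' @param registry registry from [load_registry()].
#' @param seed integer seed; defaults to the scenario's seed.
#' @return list of `n` [steroid_profile()] objects.
#' @export
simulate_cohort <- function(scenario, n, registry, seed = scenario$seed) {
  stopifnot(inherits(scenario, "ssc_scenario"), n >= 1)
  base <- excrete(steady_state_flux(registry, scenario), scenario, registry)
  amounts <- base$amounts
  lapply(seq_len(n), function(i) {
    sid <- sprintf("%s_%04d", scenario$name, i)
    if (scenario$noise_sigma > 0) {
      sub <- (as.numeric(seed) %% 2100000000 + 7919 * i) %% 2147483629
      set.seed(as.integer(sub))
      eps <- stats::rnorm(length(amounts), 0, scenario$noise_sigma)
      vals <- amounts * exp(eps)
    } else {
      vals <- amounts
    }
    steroid_profile(sid, vals, registry, collection = "24h")
  })
}

#' @export
print.ssc_scenario <- function(x, ...) {
  cat("simulation scenario '", x$name, "'\n", sep = "")
  if (length(x$activities))
    cat("  activities:", paste(names(x$activities), x$activities,
                               sep = "=", collapse = ", "), "\n")
  cat(sprintf(
    "  por=%.2f rho_5a=%.2f beta_11oxo=%.2f free_escape=%.2f backdoor=%s\n",
    x$por_activity, x$rho_5alpha, x$beta_11oxo, x$free_escape,
    x$enable_backdoor))
  cat(sprintf("  input_flux=%g noise_sigma=%g seed=%d\n",
              x$input_flux, x$noise_sigma, x$seed))
  invisible(x)
}
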