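#' Default treatment labels
#'
#' CK = uncultivated control, GF = tall wheatgrass, JA = chicory,
#' CP = alfalfa -- the four plots of the saline-alkaline revegetation
#' trial the simulator emulates.
#' @keywords internal
sq_treatments <- c("CK", "GF", "JA", "CP")

#' Soil chemistry indicators carried by a chemistry table
#' @keywords internal
sq_indicators <- c("SOM", "AN", "AP", "AK", "pH", "EC")

.default_chemistry_means <- function() {
  m <- rbind(
    CK = c(25.76, 50.09,  1.52, 172.67, 8.37, 6.70),
    GF = c(24.69, 44.04, 15.95, 197.33, 8.41, 1.92),
    JA = c(35.14, 77.19, 15.64, 265.00, 8.27, 1.95),
    CP = c(29.60, 65.71, 11.87, 117.33, 8.51, 1.81)
  )
  colnames(m) <- sq_indicators
  m
}

.default_chemistry_sds <- function() {
  m <- rbind(
    CK = c(2.27, 5.32, 0.56, 25.03, 0.38, 1.94),
    GF = c(1.80, 0.75, 0.03,  6.66, 0.04, 0.05),
    JA = c(3.63, 4.53, 0.97,  6.35, 0.15, 0.18),
    CP = c(3.56, 2.20, 0.25,  3.79, 0.02, 0.018)
  )
  colnames(m) <- sq_indicators
  m
}

# Richness fold-changes vs CK: bacterial Chao1 +50.43/55.09/45.24 % and
# fungal Chao1 +118.07/138.91/136.95 % for GF/JA/CP.
.default_richness_multiplier <- function() {
  m <- cbind(
    bacteria = c(1, 1.5043, 1.5509, 1.4524),
    fungi    = c(1, 2.1807, 2.3891, 2.3695)
  )
  rownames(m) <- sq_treatments
  m
}

# Per-treatment phylum composition targets. The bacterial percentages for
# the four dominant phyla are completed with an "Other" remainder (floored
# at 5%, since minor phyla are present everywhere at < 10%) and
# renormalized so each row is a composition. Fungal per-treatment values
# are not published as a full composition; these fixed profiles honor the
# qualitative pattern (Ascomycota dominant everywhere but reduced under
# plants; Mortierellomycota peak under chicory; Basidiomycota peak under
# tall wheatgrass).
.default_phylum_profiles <- function() {
  bact <- rbind(
    CK = c(Pseudomonadota = 20, Actinomycetota = 19, Acidobacteriota = 4,
           Chloroflexi = 24, Other = 33),
    GF = c(22, 28, 39, 29, 5),
    JA = c(28, 29, 28, 24, 5),
    CP = c(30, 24, 30, 24, 5)
  )
  fung <- rbind(
    CK = c(Ascomycota = 88, Mortierellomycota = 9, Basidiomycota = 2, Other = 1),
    GF = c(72, 12, 14, 2),
    JA = c(62, 28, 7, 3),
    CP = c(70, 18, 9, 3)
  )
  list(bacteria = bact / rowSums(bact), fungi = fung / rowSums(fung))
}

# Planted correlated OTU blocks per domain: each block shares one latent
# Gaussian factor on the log-abundance scale. sign = "positive" gives all
# members the same loading sign; "negative" alternates signs so pairs of
# opposite sign are anticorrelated. rho is the within-block latent
# correlation implied by the loading/noise ratio.
.default_blocks <- function() {
  list(
    bacteria = list(
      list(size = 8L, sign = "positive", rho = 0.95),
      list(size = 6L, sign = "negative", rho = 0.95)
    ),
    fungi = list(
      list(size = 5L, sign = "positive", rho = 0.95)
    )
  )
}

#' Define a synthetic field-trial scenario
#'
#' Bundles every parameter of the synthetic-data generator: treatment
#' structure, soil chemistry means/SDs, per-domain richness fold-changes
#' vs the control, phylum composition targets, planted correlated OTU
#' blocks, and sequencing depth. Defaults reproduce the statistical
#' structure of the 4-treatment x 3-replicate saline-alkaline trial the
#' package is built around (the trial's published chemistry; bacterial richness
#' up ~50/55/45 % and fungal richness up ~118/139/137 % under tall
#' wheatgrass/chicory/alfalfa).
#'
#' @param treatments ordered character vector of treatment labels; the
#'   first is the control all fold-changes are relative to.
#' @param replicates_per_treatment integer >= 2, plots per treatment.
#' @param chemistry_means,chemistry_sds treatment x indicator matrices
#'   (g/kg for SOM, mg/kg for AN/AP/AK, pH unitless, EC in mS/m).
#' @param richness_multiplier treatment x domain matrix of Chao1
#'   fold-changes vs the control row (control row must be 1).
#' @param n_otus_base named integer vector: OTUs with nonzero abundance
#'   in the control, per domain.
#' @param library_size reads per sample, single value or named per
#'   domain; defaults are the study's mean per-sample depths (46,026
#'   quality 16S reads, 68,464 18S reads).
#' @param phylum_profiles list per domain of treatment x phylum
#'   relative-abundance target matrices (rows sum to 1).
#' @param correlated_blocks list per domain of planted blocks; each block
#'   is a list with `size`, `sign` ("positive"/"negative") and `rho`
#'   (latent within-block correlation).
#' @param concentration Dirichlet concentration per taxon: the Dirichlet
#'   drawn around each sample's expected composition uses total mass
#'   `concentration` x number of active OTUs, giving mild multinomial
#'   overdispersion at the default 50.
#' @param lognormal_sd SD of the per-OTU baseline log-abundance.
#' @param seed integer seed all generator streams derive from.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(treatments = sq_treatments,
                          replicates_per_treatment = 3L,
                          chemistry_means = .default_chemistry_means(),
                          chemistry_sds = .default_chemistry_sds(),
                          richness_multiplier = .default_richness_multiplier(),
                          n_otus_base = c(bacteria = 300L, fungi = 150L),
                          library_size = c(bacteria = 46026L, fungi = 68464L),
                          phylum_profiles = .default_phylum_profiles(),
                          correlated_blocks = .default_blocks(),
                          concentration = 50,
                          lognormal_sd = 1,
                          seed = 1L) {
  spec <- structure(
    list(
      treatments = as.character(treatments),
      replicates_per_treatment = as.integer(replicates_per_treatment),
      chemistry_means = as.matrix(chemistry_means),
      chemistry_sds = as.matrix(chemistry_sds),
      richness_multiplier = as.matrix(richness_multiplier),
      n_otus_base = n_otus_base,
      library_size = library_size,
      phylum_profiles = phylum_profiles,
      correlated_blocks = correlated_blocks,
      concentration = concentration,
      lognormal_sd = lognormal_sd,
      seed = as.integer(seed)
    ),
    class = "scenario_spec"
  )
  validate_scenario_spec(spec)
  spec
}

#' Validate a scenario specification
#'
#' Checks the structural invariants a generator run relies on and stops
#' with the offending field's name on violation.
#' @param spec a `scenario_spec`.
#' @return `spec`, invisibly.
#' @export
validate_scenario_spec <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tr <- spec$treatments
  if (length(tr) < 2L || anyDuplicated(tr))
    stop("invalid scenario field 'treatments': need >= 2 unique labels")
  if (spec$replicates_per_treatment < 2L)
    stop("invalid scenario field 'replicates_per_treatment': must be >= 2")
  for (fld in c("chemistry_means", "chemistry_sds")) {
    m <- spec[[fld]]
    if (!all(tr %in% rownames(m)))
      stop("invalid scenario field '", fld, "': rows must cover all treatments")
  }
  if (any(spec$chemistry_sds < 0))
    stop("invalid scenario field 'chemistry_sds': negative sd")
  rm <- spec$richness_multiplier
  if (!all(tr %in% rownames(rm)))
    stop("invalid scenario field 'richness_multiplier': rows must cover all treatments")
  if (any(abs(rm[tr[1L], ] - 1) > 1e-12))
    stop("invalid scenario field 'richness_multiplier': control row must equal 1")
  if (any(rm < 1))
    stop("invalid scenario field 'richness_multiplier': fold-changes vs control must be >= 1")
  domains <- names(spec$n_otus_base)
  if (is.null(domains) || any(spec$n_otus_base < 1))
    stop("invalid scenario field 'n_otus_base': need named positive counts")
  for (d in domains) {
    pp <- spec$phylum_profiles[[d]]
    if (is.null(pp) || !all(tr %in% rownames(pp)))
      stop("invalid scenario field 'phylum_profiles': missing domain ", d)
    if (any(pp < 0) || any(abs(rowSums(pp) - 1) > 1e-9))
      stop("invalid scenario field 'phylum_profiles': rows must be compositions summing to 1 (domain ",
           d, ")")
    for (b in spec$correlated_blocks[[d]]) {
      if (!is.list(b) || is.null(b$size) || is.null(b$sign) || is.null(b$rho) ||
          b$size < 2L || !(b$sign %in% c("positive", "negative")) ||
          b$rho <= 0 || b$rho >= 1)
        stop("invalid scenario field 'correlated_blocks': each block needs size >= 2, ",
             "sign positive/negative, rho in (0,1) (domain ", d, ")")
    }
  }
  if (any(unlist(spec$library_size) < 1))
    stop("invalid scenario field 'library_size': must be positive")
  if (spec$concentration <= 0)
    stop("invalid scenario field 'concentration': must be positive")
  if (spec$lognormal_sd < 0)
    stop("invalid scenario field 'lognormal_sd': must be non-negative")
  invisible(spec)
}

#' Read a scenario specification from a YAML config file
#'
#' Any field of [scenario_spec()] may appear in the file; omitted fields
#' keep their defaults. Matrices are given as named lists of named lists
#' (treatment -> indicator/phylum -> value).
#' @param path YAML file path.
#' @return a `scenario_spec`.
#' @export
read_scenario_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scenario_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown scenario config keys: ", paste(unknown, collapse = ", "))
  to_matrix <- function(x) {
    if (is.matrix(x) || !is.list(x)) return(x)
    do.call(rbind, lapply(x, function(r) unlist(r)))
  }
  for (fld in c("chemistry_means", "chemistry_sds", "richness_multiplier"))
    if (!is.null(cfg[[fld]])) cfg[[fld]] <- to_matrix(cfg[[fld]])
  if (!is.null(cfg$phylum_profiles))
    cfg$phylum_profiles <- lapply(cfg$phylum_profiles, to_matrix)
  if (!is.null(cfg$n_otus_base)) cfg$n_otus_base <- unlist(cfg$n_otus_base)
  do.call(scenario_spec, cfg)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", length(x$treatments), "treatments x",
      x$replicates_per_treatment, "replicates;",
      paste(names(x$n_otus_base), x$n_otus_base, collapse = ", "),
      "base OTUs; seed", x$seed, "\n")
  invisible(x)
}

# Derive a substream seed from the scenario seed by fixed offset,
# kept inside the 32-bit integer range.
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
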