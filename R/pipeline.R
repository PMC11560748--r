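#' Default pipeline configuration
#'
#' @param seed global seed; every stochastic stage derives its stream
#'   from it by fixed offsets.
#' @param outdir output directory (`NULL` = write nothing).
#' @return named list of configuration defaults.
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  list(
    input = "synthetic",          # or list(chemistry=, bacteria=, fungi=) paths
    scenario = list(),            # scenario_spec() overrides
    stages = list(chemistry = TRUE, diversity = TRUE, sqi = TRUE,
                  network = TRUE),
    seed = as.integer(seed),
    outdir = outdir,
    alpha = 0.05,
    rank = "phylum",
    top_n = 100,
    r_threshold = 0.9,
    p_threshold = 0.05,
    permutations = 999,
    sqi = list(m = 4L, entity_mode = "treatment",
               alpha_metrics = c("chao1", "shannon"))
  )
}

.merge_config <- function(base, override) {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- utils::modifyList(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> chemistry summary -> diversity and
#' ordination -> SQI -> co-occurrence networks, writing every
#' intermediate as TSV when `outdir` is set, and returns a
#' machine-readable report. Re-running with the same config and seed
#' reproduces the report exactly (up to the timestamp).
#'
#' @param config a list of overrides to [default_config()], or a path
#'   to a YAML file of the same shape.
#' @param seed optional seed override (highest precedence).
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    cfg$outdir
  } else NULL
  emit <- function(obj, name, writer = utils::write.table) {
    if (is.null(out)) return(invisible(NULL))
    path <- file.path(out, name)
    if (identical(writer, utils::write.table))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else writer(obj, path)
    invisible(path)
  }
  report <- list(seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("sqiome")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 stages = list(), warnings = character())
  note <- function(w) report$warnings <<- c(report$warnings, w)

  ## -- inputs -------------------------------------------------------
  if (identical(cfg$input, "synthetic")) {
    spec <- do.call(scenario_spec, c(cfg$scenario, list(seed = cfg$seed)))
    chem <- generate_chemistry(spec)
    communities <- withCallingHandlers(
      generate_communities(spec, chem),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    report$stages$simulate <- list(status = "ok",
                                   treatments = spec$treatments,
                                   replicates = spec$replicates_per_treatment)
  } else {
    chem <- read_chemistry(cfg$input$chemistry)
    communities <- list()
    for (dom in setdiff(names(cfg$input), "chemistry"))
      communities[[dom]] <- read_community(cfg$input[[dom]], domain = dom)
    report$stages$simulate <- list(status = "loaded")
  }
  diags <- validate_inputs(chem, communities)
  if (length(diags)) {
    report$stages$validate <- list(status = "failed", diagnostics = diags)
    stop("input validation failed: ", paste(diags, collapse = "; "))
  }
  report$stages$validate <- list(status = "ok")
  emit(chem, "chemistry.tsv")
  if (!is.null(out))
    for (dom in names(communities))
      write_community(communities[[dom]],
                      file.path(out, paste0("community_", dom, ".tsv")))

  ## -- chemistry ----------------------------------------------------
  if (isTRUE(cfg$stages$chemistry)) {
    summ <- summarize_chemistry(chem, alpha = cfg$alpha)
    changes <- list()
    control <- chem$treatment[1L]
    for (ind in sq_indicators)
      for (t in setdiff(unique(chem$treatment), control))
        changes[[length(changes) + 1L]] <-
          change_report(summ, ind, t, control)
    changes <- do.call(rbind, changes)
    emit(summ, "chemistry_summary.tsv")
    emit(changes, "chemistry_changes_vs_control.tsv")
    report$stages$chemistry <- list(
      status = "ok",
      summary = summ,
      changes_vs_control = changes)
  } else report$stages$chemistry <- list(status = "skipped")

  ## -- diversity ----------------------------------------------------
  alpha_div <- NULL
  dists <- list()
  if (isTRUE(cfg$stages$diversity) || isTRUE(cfg$stages$sqi)) {
    alpha_div <- lapply(communities, alpha_diversity)
  }
  if (isTRUE(cfg$stages$diversity)) {
    div_report <- list()
    for (dom in names(communities)) {
      cm <- communities[[dom]]
      ad <- alpha_div[[dom]]
      emit(ad, paste0("alpha_diversity_", dom, ".tsv"))
      d <- bray_curtis(cm)
      dists[[dom]] <- d
      if (!is.null(out))
        write_distance(d, file.path(out, paste0("bray_curtis_", dom, ".tsv")))
      ord <- pcoa_ordination(d)
      comp <- composition_by_rank(cm, rank = cfg$rank, chem = chem)
      emit(data.frame(treatment = rownames(comp), comp, check.names = FALSE),
           paste0("composition_", cfg$rank, "_", dom, ".tsv"))
      rda <- rda_ordination(cm, chem)
      chem_d <- stats::dist(scale(chem[, sq_indicators]))
      mt <- mantel_test(d, chem_d, permutations = cfg$permutations,
                        seed = .substream(cfg$seed, 7100 + match(dom, names(communities))))
      div_report[[dom]] <- list(
        pcoa_axis_explained = ord$explained[seq_len(min(2L, length(ord$explained)))],
        rda_total_explained = rda$total_explained,
        mantel_chemistry = mt[c("r", "p")],
        composition = comp)
    }
    report$stages$diversity <- c(list(status = "ok"), div_report)
  } else report$stages$diversity <- list(status = "skipped")

  ## -- SQI ----------------------------------------------------------
  if (isTRUE(cfg$stages$sqi)) {
    sp <- run_sqi_pipeline(chem, alpha_div,
                           entity_mode = cfg$sqi$entity_mode,
                           alpha_metrics = cfg$sqi$alpha_metrics,
                           m = cfg$sqi$m)
    emit(sp$sqi, "sqi.tsv")
    emit(data.frame(entity = rownames(sp$membership), sp$membership,
                    check.names = FALSE), "sqi_membership.tsv")
    emit(data.frame(indicator = rownames(sp$weighting$weights),
                    sp$weighting$weights, check.names = FALSE),
         "sqi_weights.tsv")
    report$stages$sqi <- list(
      status = "ok",
      entity_mode = sp$entity_mode,
      contribution = sp$weighting$contribution[seq_len(sp$weighting$m)],
      result = sp$sqi)
  } else report$stages$sqi <- list(status = "skipped")

  ## -- networks -----------------------------------------------------
  if (isTRUE(cfg$stages$network)) {
    nets <- withCallingHandlers(
      per_treatment_networks(communities, chem, top_n = cfg$top_n,
                             r_threshold = cfg$r_threshold,
                             p_threshold = cfg$p_threshold,
                             seed = .substream(cfg$seed, 7300)),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    emit(data.frame(metric = rownames(nets$summaries), nets$summaries,
                    check.names = FALSE), "network_summaries.tsv")
    if (!is.null(out))
      for (nm in names(nets$networks))
        write_network(nets$networks[[nm]],
                      graphml_path = file.path(out, paste0("network_", nm, ".graphml")),
                      edges_path = file.path(out, paste0("edges_", nm, ".tsv")))
    report$stages$network <- list(status = "ok",
                                  summaries = nets$summaries,
                                  caveats = nets$caveats)
  } else report$stages$network <- list(status = "skipped")

  if (!is.null(out))
    jsonlite::write_json(.serializable(report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "run_report"
  report
}

# data.frames -> lists of rows so the JSON report is plain.
.serializable <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .serializable))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("sqiome run (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages))
    cat("  ", nm, ": ", x$stages[[nm]]$status, "\n", sep = "")
  if (!is.null(x$stages$sqi$result)) {
    cat("SQI ranking:\n")
    print(x$stages$sqi$result[order(x$stages$sqi$result$rank), ],
          row.names = FALSE)
  }
  invisible(x)
}
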