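#' Study configuration for the end-to-end pipeline
#'
#' Declarative configuration covering every stage. Defaults reproduce the
#' standard analysis of the default synthetic study; any field can be
#' overridden, and a YAML file with the same nesting can be loaded via
#' [read_study_config()].
#'
#' @param outdir output directory.
#' @param seed master seed; stage seeds derive from it deterministically.
#' @param stages stages to run, in order, from `simulate`, `pressure`,
#'   `dom`, `community`, `couple`.
#' @param simulate list of scenario overrides (`pressure`, `dom`,
#'   `community`), each itself a list of arguments to the scenario
#'   constructor.
#' @param inputs optional externally supplied input files (`pressure_csv`,
#'   `peaks_manifest`, `asv_tsv`); when present they replace the simulated
#'   data for the downstream stages.
#' @param pressure,dom,community,couple per-stage parameter lists; see the
#'   corresponding analysis functions for meanings and defaults.
#' @return object of class `ces_study_config`.
#' @export
study_config <- function(outdir = tempfile("ces_run_"),
                         seed = 1,
                         stages = c("simulate", "pressure", "dom",
                                    "community", "couple"),
                         simulate = list(),
                         inputs = list(),
                         pressure = list(),
                         dom = list(),
                         community = list(),
                         couple = list()) {
  known <- c("simulate", "pressure", "dom", "community", "couple")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  user_phases <- pressure$phases   # phase lists replace, never merge
  pressure <- utils::modifyList(
    list(control_id = "CONTROL",
         phases = list(phase1 = c(1, 8), phase2a = c(31, 45),
                       phase2b = c(46, 54)),
         smoothing_window = 600, method = "light_rise", max_gap = 300),
    pressure
  )
  if (!is.null(user_phases)) pressure$phases <- user_phases
  dom <- utils::modifyList(
    list(tolerance_ppm = 1.0, weighting = "intensity"), dom
  )
  community <- utils::modifyList(
    list(min_total_reads = 2, top_genera = 20, permutations = 999), community
  )
  couple <- utils::modifyList(
    list(bin_width = 50, mass_range = c(200, 600), threshold = 0.3,
         permutations = 999), couple
  )
  structure(
    list(outdir = outdir, seed = seed, stages = stages, simulate = simulate,
         inputs = inputs, pressure = pressure, dom = dom,
         community = community, couple = couple),
    class = "ces_study_config"
  )
}

#' @rdname study_config
#' @param path YAML file with the same nesting as [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

# Stage seeds derived from the master seed (kept within 32-bit range).
stage_seed <- function(seed, k) (seed * 7919 + k * 104729) %% 2147483647

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (simulate, pressure, dom,
#' community, couple), writing each stage's outputs before the next starts
#' and a run report last. Every stochastic result records its seed and
#' permutation count; identical configurations and seeds yield identical
#' report payloads.
#'
#' @param config a `ces_study_config` (or path to a YAML configuration).
#' @return invisible run report (list): per-stage parameter echo, input
#'   checksums, key result tables, warnings.
#' @export
run_pipeline <- function(config = study_config()) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "ces_study_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list(), warnings = character(0))
  state <- new.env(parent = emptyenv())

  runners <- list(simulate = stage_simulate, pressure = stage_pressure,
                  dom = stage_dom, community = stage_community,
                  couple = stage_couple)
  for (stage in config$stages) {
    message(sprintf("[%s] running", stage))
    result <- tryCatch(
      runners[[stage]](config, state),
      error = function(e) stopf("stage '%s' failed: %s", stage,
                                conditionMessage(e))
    )
    report$stages[[stage]] <- result
  }
  report$generated_at <- format(Sys.time(), tz = "UTC")
  write_results_json(report, file.path(config$outdir, "report.json"))
  invisible(report)
}

stage_simulate <- function(config, state) {
  sim <- config$simulate
  # plain concatenation, not modifyList: an explicit NULL override (e.g.
  # collapse_window) must reach the scenario constructor
  scn_args <- function(overrides, seed) {
    a <- overrides %||% list()
    if (!"seed" %in% names(a)) a <- c(a, list(seed = seed))
    a
  }
  p_scn <- do.call(pressure_scenario,
                   scn_args(sim$pressure, stage_seed(config$seed, 1)))
  d_scn <- do.call(dom_scenario,
                   scn_args(sim$dom, stage_seed(config$seed, 2)))
  c_scn <- do.call(community_scenario,
                   scn_args(sim$community, stage_seed(config$seed, 3)))
  bundle <- gen_study_bundle(file.path(config$outdir, "data"),
                             pressure = p_scn, dom = d_scn, community = c_scn)
  state$pressure_experiment <- bundle$pressure
  state$dom_data <- bundle$dom
  state$community_data <- bundle$community
  list(
    parameters = list(pressure_seed = p_scn$seed, dom_seed = d_scn$seed,
                      community_seed = c_scn$seed),
    files = lapply(bundle$files, basename),
    checksums = {
      cks <- tools::md5sum(c(bundle$files$pressure, bundle$files$asv_table))
      names(cks) <- basename(names(cks))
      as.list(cks)
    }
  )
}

stage_pressure <- function(config, state) {
  pc <- config$pressure
  if (!is.null(config$inputs$pressure_csv)) {
    traces <- read_pressure_csv(config$inputs$pressure_csv)
    control <- traces[[pc$control_id]]
    traces <- traces[setdiff(names(traces), pc$control_id)]
  } else if (!is.null(state$pressure_experiment)) {
    traces <- state$pressure_experiment$traces
    control <- state$pressure_experiment$control
  } else {
    stopf("no pressure input: run `simulate` or set inputs$pressure_csv")
  }
  res <- analyze_pressure_experiment(
    traces, control, phases = pc$phases,
    smoothing_window = pc$smoothing_window, method = pc$method,
    max_gap = pc$max_gap
  )
  out <- file.path(config$outdir, "pressure")
  dir.create(out, showWarnings = FALSE)
  utils::write.table(res$metrics, file.path(out, "cycle_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  phases_df <- do.call(rbind, lapply(res$phases, as.data.frame))
  phases_df <- cbind(phase = names(res$phases), phases_df)
  write_results_json(phases_df, file.path(out, "phase_summary.json"))
  state$pressure_result <- res
  list(
    parameters = pc[c("smoothing_window", "method", "max_gap")],
    calibration = unclass(res$calibration),
    phases = phases_df
  )
}

stage_dom <- function(config, state) {
  dc <- config$dom
  acfg <- assignment_config(tolerance_ppm = dc$tolerance_ppm)
  if (!is.null(config$inputs$peaks_manifest)) {
    manifest <- utils::read.csv(config$inputs$peaks_manifest,
                                stringsAsFactors = FALSE)
    base <- dirname(config$inputs$peaks_manifest)
    peaklists <- lapply(manifest$sample, function(s) {
      read_peaklist_csv(file.path(base, paste0(s, ".csv")))
    })
    names(peaklists) <- manifest$sample
  } else if (!is.null(state$dom_data)) {
    peaklists <- state$dom_data$peaklists
    manifest <- state$dom_data$samples
  } else {
    stopf("no DOM input: run `simulate` or set inputs$peaks_manifest")
  }
  assigned <- lapply(peaklists, assign_peaklist, config = acfg)
  out <- file.path(config$outdir, "dom")
  dir.create(out, showWarnings = FALSE)
  summaries <- lapply(names(assigned), function(s) {
    a <- assigned[[s]]$assigned
    utils::write.table(
      a[, c("mz", "intensity", "formula", "ppm_error", "neutral_mass",
            "hc", "oc", "dbe", "nosc", "series", "compound_class")],
      file.path(out, paste0(s, "_assignments.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    list(
      sample = s,
      n_peaks = assigned[[s]]$n_input,
      n_assigned = nrow(a),
      series_counts = as.list(table(a$series)),
      class_fractions = as.list(class_abundance(assigned[[s]],
                                                weighting = dc$weighting)),
      chemodiversity = chemodiversity(assigned[[s]])
    )
  })
  names(summaries) <- names(assigned)
  write_results_json(summaries, file.path(out, "sample_summaries.json"))
  state$assigned <- assigned
  state$dom_manifest <- manifest
  list(parameters = dc, samples = summaries)
}

stage_community <- function(config, state) {
  cc <- config$community
  if (!is.null(config$inputs$asv_tsv)) {
    md <- NULL
    if (!is.null(config$inputs$samples_csv)) {
      md <- utils::read.csv(config$inputs$samples_csv, stringsAsFactors = FALSE)
    }
    tab <- read_asv_tsv(config$inputs$asv_tsv, metadata = md)
  } else if (!is.null(state$community_data)) {
    tab <- state$community_data$table
  } else {
    stopf("no ASV input: run `simulate` or set inputs$asv_tsv")
  }
  tab <- filter_asv_table(tab, min_total_reads = cc$min_total_reads)
  genus_ab <- genus_top_abundance(tab, n = cc$top_genera)
  alpha <- sample_shannon(tab)
  d <- bray_curtis(tab)
  ord <- pcoa_ordination(d)
  groups <- tab$metadata$time_point
  seed_pn <- stage_seed(config$seed, 4)
  pn <- dn <- NULL
  if (!is.null(groups)) {
    pn <- permanova(d, groups, permutations = cc$permutations, seed = seed_pn)
    dn <- beta_dispersion(d, groups, permutations = cc$permutations,
                          seed = stage_seed(config$seed, 5))
  }
  out <- file.path(config$outdir, "community")
  dir.create(out, showWarnings = FALSE)
  write_matrix_tsv(as.matrix(d), file.path(out, "bray_curtis.tsv"), "sample")
  write_matrix_tsv(ord$coordinates, file.path(out, "pcoa_coordinates.tsv"),
                   "sample")
  write_matrix_tsv(genus_ab, file.path(out, "genus_abundance.tsv"), "genus")
  write_results_json(
    list(shannon = as.list(alpha), permanova = pn,
         dispersion = if (!is.null(dn)) {
           utils::modifyList(dn, list(group_mean_distance =
                                        as.list(dn$group_mean_distance)))
         },
         pcoa_eigenvalues = ord$eigenvalues),
    file.path(out, "tests.json")
  )
  state$asv_filtered <- tab
  state$genus_abundance <- genus_ab
  state$alpha <- alpha
  state$bray <- d
  list(parameters = cc, shannon = as.list(alpha), permanova = pn,
       dispersion = if (!is.null(dn)) dn["p_value"])
}

stage_couple <- function(config, state) {
  if (is.null(state$assigned) || is.null(state$asv_filtered)) {
    stopf("couple stage needs the dom and community stages first")
  }
  kc <- config$couple
  bins <- dom_series_bins(state$assigned, bin_width = kc$bin_width,
                          mass_range = kc$mass_range)
  genus_ab <- state$genus_abundance
  shared <- intersect(colnames(genus_ab), colnames(bins))
  grid <- genus_dom_correlation_grid(genus_ab, bins, threshold = kc$threshold)
  mantel <- mantel_test(
    bray_curtis(t(genus_ab[, shared, drop = FALSE])),
    stats::dist(t(bins[, shared, drop = FALSE])),
    permutations = kc$permutations, seed = stage_seed(config$seed, 6)
  )

  # NOSC distribution shift between the first and last time points
  tp_of <- state$dom_manifest$time_point[match(names(state$assigned),
                                               state$dom_manifest$sample)]
  tps <- unique(tp_of)
  nosc_pool <- function(tp) {
    unlist(lapply(state$assigned[tp_of == tp], function(a) a$assigned$nosc))
  }
  ks <- ks_two_sample(nosc_pool(tps[1]), nosc_pool(tps[length(tps)]))

  chem <- vapply(state$assigned, chemodiversity, 0)[shared]
  fit <- diversity_fit(state$alpha[shared], chem)

  out <- file.path(config$outdir, "couple")
  dir.create(out, showWarnings = FALSE)
  grid_out <- grid$display
  write_matrix_tsv(grid_out, file.path(out, "correlation_grid.tsv"), "genus")
  write_results_json(
    list(mantel = mantel, ks_nosc = ks, fit = unclass(fit),
         diversity = list(microbial = as.list(state$alpha[shared]),
                          chemodiversity = as.list(chem))),
    file.path(out, "coupling.json")
  )
  list(parameters = kc, mantel = mantel, ks_nosc = ks, fit = unclass(fit))
}
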