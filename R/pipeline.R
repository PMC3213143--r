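## pipeline_cli module: simulate -> map -> classify -> deplete ->
## duplex/phasing -> homology as one reproducible run with a consolidated
## JSON report. All randomness flows from the configuration seed; the same
## config yields a byte-identical report.

#' Pipeline configuration
#'
#' Bundles the simulation configuration with the analysis thresholds:
#' feature calls need >= `rpm_threshold` wild-type RPM and >= 67% depletion
#' (ratio <= 1/3) in every genotype of `require`; individual 26G calls use
#' `sirna_rpm_threshold`; homology uses the strict >82% identity and >= 27
#' nt perfect-stretch criteria on 500 nt-flanked sequences; genome tracks
#' use 5 kb windows stepped 1 kb with a 1 RPM pseudocount.
#'
#' @param sim A [sim_config()].
#' @param rpm_threshold,sirna_rpm_threshold,depletion Depletion-call
#'   thresholds.
#' @param require Genotypes that must show depletion for an embryo target
#'   call.
#' @param adult_require Genotypes required for adult calls.
#' @param identity_threshold,stretch_threshold,flank Homology thresholds.
#' @param duplex_flank Window flank for passenger inference (nt).
#' @param window,step,pseudocount Genome-track parameters.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            rpm_threshold = 10, sirna_rpm_threshold = 1,
                            depletion = DEFAULT_DEPLETION,
                            require = c("eri-7", "eri-1"),
                            adult_require = "eri-7",
                            identity_threshold = 82, stretch_threshold = 27L,
                            flank = 500L, duplex_flank = 14L,
                            window = 5000L, step = 1000L, pseudocount = 1) {
  structure(list(sim = sim, rpm_threshold = rpm_threshold,
                 sirna_rpm_threshold = sirna_rpm_threshold,
                 depletion = depletion, require = require,
                 adult_require = adult_require,
                 identity_threshold = identity_threshold,
                 stretch_threshold = stretch_threshold, flank = flank,
                 duplex_flank = duplex_flank, window = window, step = step,
                 pseudocount = pseudocount),
            class = "pipeline_config")
}

#' @noRd
log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[erisift] ", fmt), ...))
}

#' Run the full pipeline on a simulated dataset
#'
#' Simulates the genome and libraries, maps and profiles every library,
#' computes the genotype-by-class depletion matrix, calls depleted target
#' features in embryos and adults (and their overlap), calls individual
#' depleted 26G siRNAs, infers duplex records and consensus per embryo
#' library with passenger fold changes versus wild type, summarises 26G
#' phasing over the target genes, clusters called targets by homology, and
#' writes per-stage TSVs plus a consolidated JSON report. Rerunning with
#' the same configuration yields a byte-identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; NULL runs in memory only.
#' @param verbose Log stage progress to stderr.
#' @return The report, invisibly a list (also written as `report.json` when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(nm, expr) {
    log_stage(verbose, "stage %s ...", nm)
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", nm, conditionMessage(e))
    })
  }
  notices <- character(0)

  genome <- stage("simulate", simulate_genome(config$sim))
  sim <- stage("simulate", simulate_libraries(genome, config$sim))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write-inputs", write_simulation(genome, sim, file.path(out_dir, "inputs")))
  }

  profiles <- stage("map+classify", {
    lapply(stats::setNames(names(sim$libraries), names(sim$libraries)), function(nm) {
      mapped <- map_reads(sim$libraries[[nm]], genome)
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      library_profile(mapped, genome,
                      genotype = paste(parts[-length(parts)], collapse = "_"),
                      stage = parts[length(parts)])
    })
  })

  by_stage <- split(names(profiles),
                    vapply(profiles, function(p) p$stage, ""))
  wt_of <- function(st) profiles[[paste0("wt_", st)]]
  mutants_of <- function(st) {
    nms <- setdiff(by_stage[[st]], paste0("wt_", st))
    stats::setNames(lapply(nms, function(n) profiles[[n]]),
                    vapply(nms, function(n) profiles[[n]]$genotype, ""))
  }

  ## class depletion matrix (genotype x stage x class)
  class_matrix <- list()
  for (st in names(by_stage)) {
    wt <- wt_of(st)
    if (is.null(wt)) next
    for (nm in setdiff(by_stage[[st]], paste0("wt_", st))) {
      p <- profiles[[nm]]
      row <- lapply(stats::setNames(SIRNA_CLASSES, SIRNA_CLASSES), function(cl) {
        if (wt$class_rpm[[cl]] > 0) class_depletion(wt, p, class = cl) else NA
      })
      class_matrix[[nm]] <- row
    }
  }

  have_mutants <- any(vapply(names(by_stage), function(st)
    length(setdiff(by_stage[[st]], paste0("wt_", st))) > 0, TRUE))
  calls <- list(); sirnas <- NULL; overlap <- NULL
  if (!have_mutants) {
    notices <- c(notices, "no mutant libraries configured; depletion stages skipped")
  } else {
    calls <- stage("deplete", {
      out <- list()
      if ("embryo" %in% names(by_stage)) {
        req <- intersect(config$require, names(mutants_of("embryo")))
        out$embryo <- call_targets(wt_of("embryo"), mutants_of("embryo"),
                                   rpm_threshold = config$rpm_threshold,
                                   depletion = config$depletion, require = req)
      }
      if ("adult" %in% names(by_stage) && length(mutants_of("adult"))) {
        req <- intersect(config$adult_require, names(mutants_of("adult")))
        out$adult <- call_targets(wt_of("adult"), mutants_of("adult"),
                                  rpm_threshold = config$rpm_threshold,
                                  depletion = config$depletion, require = req)
      }
      out
    })
    if (!is.null(calls$embryo) && !is.null(calls$adult)) {
      overlap <- target_overlap(calls$embryo, calls$adult)
    }
    if ("embryo" %in% names(by_stage)) {
      req <- intersect(config$require, names(mutants_of("embryo")))
      if (length(req)) {
        sirnas <- stage("deplete", call_sirnas(
          wt_of("embryo"), mutants_of("embryo")[req],
          rpm_threshold = config$sirna_rpm_threshold,
          depletion = config$depletion, require = req))
      }
    }
  }

  ## duplex inference on embryo libraries
  duplex <- stage("duplex", {
    out <- list()
    if ("embryo" %in% names(by_stage)) {
      for (nm in by_stage$embryo) {
        recs <- duplex_records(profiles[[nm]], flank = config$duplex_flank)
        if (nrow(recs[recs$guide_rpm >= config$sirna_rpm_threshold, ])) {
          cons <- duplex_consensus(recs, guide_rpm_threshold = config$sirna_rpm_threshold)
          out[[nm]] <- list(records = recs, consensus = unclass(cons))
        }
      }
    }
    out
  })
  foldchanges <- NULL
  if (!is.null(duplex[["wt_embryo"]])) {
    wtr <- duplex[["wt_embryo"]]$records
    foldchanges <- lapply(duplex[setdiff(names(duplex), "wt_embryo")],
                          function(d) passenger_foldchange(wtr, d$records))
  }

  ## phasing over ergo1 target genes in the wild-type embryo library
  phasing <- NULL
  if (!is.null(wt_of("embryo"))) {
    phasing <- stage("phasing", {
      tgt <- genome$features$feature_id[genome$features$class %in% "ergo1_target"]
      profs <- lapply(tgt, function(f)
        phasing_profile(f, wt_of("embryo"), genome))
      fr <- vapply(profs, function(p) p$fraction_in_range, 0)
      list(per_feature = stats::setNames(fr, tgt),
           mean_fraction_in_range = mean(fr, na.rm = TRUE),
           n_intervals = sum(vapply(profs, function(p) length(p$intervals), 0L)))
    })
  }

  ## homology over called embryo targets
  homology <- NULL
  if (!is.null(calls$embryo) && sum(calls$embryo$called) >= 2L) {
    homology <- stage("homology", {
      ids <- calls$embryo$feature_id[calls$embryo$called]
      edges <- homology_edges(ids, genome, genome$genome, flank = config$flank,
                              stretch_threshold = config$stretch_threshold)
      groups <- homology_groups(ids, edges,
                                identity_threshold = config$identity_threshold,
                                stretch_threshold = config$stretch_threshold)
      stats <- gene_structure_stats(ids, genome)
      list(edges = edges, groups = groups, structure = stats)
    })
  }

  report <- list(
    config = list(seed = config$sim$seed, library_depth = config$sim$library_depth,
                  rpm_threshold = config$rpm_threshold,
                  sirna_rpm_threshold = config$sirna_rpm_threshold,
                  depletion = config$depletion, require = config$require),
    libraries = lapply(profiles, function(p)
      list(genotype = p$genotype, stage = p$stage,
           total_mapped_reads = p$scale$total_mapped_reads)),
    class_depletion_percent = class_matrix,
    target_calls = lapply(calls, function(cc)
      list(n_called = sum(cc$called), called = cc$feature_id[cc$called])),
    embryo_adult_overlap = overlap[c("n_a", "n_b", "n_shared", "n_union")],
    n_sirnas_called = if (!is.null(sirnas)) sum(sirnas$called) else NULL,
    duplex_consensus = lapply(duplex, function(d) d$consensus),
    passenger_foldchange_vs_wt = foldchanges,
    phasing = if (!is.null(phasing)) phasing[c("mean_fraction_in_range", "n_intervals")] else NULL,
    homology = if (!is.null(homology)) list(
      n_groups = length(homology$groups), groups = homology$groups,
      target_median_exons = homology$structure$set$median_exons,
      target_mean_length = homology$structure$set$mean_length,
      genome_median_exons = homology$structure$genome$median_exons,
      genome_mean_length = homology$structure$genome$mean_length) else NULL,
    notices = notices)

  if (!is.null(out_dir)) {
    stage("write-report", {
      for (st in names(calls)) {
        utils::write.table(calls[[st]], file.path(out_dir, paste0("targets_", st, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(sirnas)) {
        utils::write.table(sirnas, file.path(out_dir, "sirnas_embryo.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      for (nm in names(duplex)) {
        utils::write.table(duplex[[nm]]$records,
                           file.path(out_dir, paste0("duplex_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(homology)) {
        utils::write.table(homology$edges, file.path(out_dir, "homology_edges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      ## 5 kb / 1 kb genome tracks, embryo mutants vs wt
      if ("embryo" %in% names(by_stage)) {
        for (nm in setdiff(by_stage$embryo, "wt_embryo")) {
          wt <- wt_of("embryo")
          tr <- window_track(wt, profiles[[nm]], width = config$window,
                             step = config$step, pseudocount = config$pseudocount)
          utils::write.table(tr, file.path(out_dir, paste0("track_", nm, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
    })
  }
  log_stage(verbose, "done in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(report)
}
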