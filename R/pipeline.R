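#' Run the full analysis pipeline from a config file
#'
#' Executes the stages in dependency order — simulate (or load tables),
#' lineage, organization, flipping, colocalization, retention — writing
#' per-stage CSV/JSON outputs and a run manifest (config hash, seed, package
#' version, per-stage files, timestamps, exclusion tallies).  Re-running an
#' identical config reproduces identical outputs.
#'
#' Config (JSON): `preset` (name) or `preset_file`, `mode`, `layout`,
#' `n_lineages`, `duration`, `frame_interval`, `seed`, optional `edu_pulse`
#' (`start`, `duration`, `chase`), `stages` (subset of the five analysis
#' stages; default all), `out_dir`, and for analyze-only runs `cell_table` /
#' `focus_table` paths instead of simulation parameters.
#'
#' @param config path to a JSON config, or an equivalent named list.
#' @param out_dir overrides the config's output directory.
#' @return the manifest, invisibly; outputs are written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config))
    jsonlite::read_json(config, simplifyVector = TRUE) else config
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% c("lineage", "organization", "flipping",
                              "colocalization", "retention")
  manifest <- list(package_version = as.character(packageVersion("chromolin")),
                   seed = cfg$seed %||% NA, started = format(Sys.time()),
                   stages = stages, files = list(), tallies = list())
  on_fail <- function(e) {
    # remove partial outputs so a failed run leaves no half-written state
    unlink(unlist(manifest$files), force = TRUE)
    stop(e)
  }
  tryCatch({
    if (!is.null(cfg$cell_table)) {
      if (is.null(cfg$focus_table))
        stop("config error: focus_table required in analyze-only mode")
      dt <- cfg$frame_interval %||% stop("config error: frame_interval required")
      ct <- fread(cfg$cell_table)
      ft <- fread(cfg$focus_table)
      sim <- NULL
    } else {
      pr <- if (!is.null(cfg$preset_file)) read_preset(cfg$preset_file)
            else preset(cfg$preset %||% "WT",
                        mode = cfg$mode %||% "phenomenological")
      sim <- simulate_experiment(pr, layout = cfg$layout %||% "mother_machine",
                                 n_lineages = cfg$n_lineages %||% 10,
                                 duration = cfg$duration,
                                 frame_interval = cfg$frame_interval,
                                 seed = cfg$seed %||% 1)
      if (!is.null(cfg$edu_pulse))
        sim <- apply_edu_pulse_chase(sim, cfg$edu_pulse$start,
                                     cfg$edu_pulse$duration,
                                     cfg$edu_pulse$chase)
      write_sim_output(sim, file.path(out_dir, "simulation"))
      manifest$files$simulation <-
        list.files(file.path(out_dir, "simulation"), full.names = TRUE)
      ct <- sim$cell_table; ft <- sim$focus_table
      dt <- sim$params$frame_interval
    }

    forest <- build_forest(ct, frame_interval = dt)
    summary <- list()

    if ("lineage" %in% stages) {
      an <- detect_anucleate_divisions(forest, ft)
      cm <- cycle_metrics(forest)
      f1 <- file.path(out_dir, "lineage_divisions.csv")
      f2 <- file.path(out_dir, "lineage_cycle_metrics.csv")
      if (nrow(an$records)) fwrite(an$records, f1) else fwrite(data.table(), f1)
      if (nrow(cm$metrics)) fwrite(cm$metrics, f2) else fwrite(data.table(), f2)
      manifest$files$lineage <- c(f1, f2)
      manifest$tallies$lineage <- list(excluded_divisions = an$n_excluded,
                                       censored_cells = cm$n_censored)
      summary$anucleate_rate <- an$rate
      summary$generation_time_mean <-
        if (nrow(cm$metrics)) mean(cm$metrics$generation_time_min) else NA
    }
    if ("organization" %in% stages) {
      ori <- orient_cells(ft, "L3_negative")
      ohf <- opposite_halves_fraction(ori)
      ad <- arm_distance(ft)
      cfgt <- classify_configuration(ori)
      f1 <- file.path(out_dir, "organization_configurations.csv")
      fwrite(cfgt, f1)
      manifest$files$organization <- f1
      manifest$tallies$organization <- list(arm_distance_excluded = ad$n_excluded)
      summary$opposite_halves_fraction <- ohf$fraction
      summary$arm_distance_mean <- ad$mean
      summary$translational_fraction <-
        mean(cfgt[label != "UNDETERMINED"]$label == "TRANSLATIONAL")
    }
    if ("flipping" %in% stages) {
      tr <- orientation_trace(ft, ct)
      fpc <- flips_per_cycle(tr, forest, "pre_duplication")
      mdr <- mother_daughter_retention(forest, ft, tr)
      f1 <- file.path(out_dir, "flipping_events.csv")
      fwrite(tr$flips, f1)
      manifest$files$flipping <- f1
      manifest$tallies$flipping <- list(excluded_traces = tr$n_excluded,
                                        excluded_pairs = mdr$n_excluded)
      summary$flips_per_cycle <- fpc$mean
      summary$mother_daughter_retention <- mdr$fraction
    }
    if ("colocalization" %in% stages) {
      nd <- nearest_distances(ft, "DnaQ", "DnaN")
      f1 <- file.path(out_dir, "colocalization_pairs.csv")
      if (nrow(nd$pairs)) {
        fwrite(nd$pairs, f1)
        cf <- colocal_fraction(nd, 0.3)
        summary$colocal_fraction_300nm <- cf$fraction
      } else fwrite(data.table(), f1)
      manifest$files$colocalization <- f1
      manifest$tallies$colocalization <- list(censored = nd$n_censored)
    }
    if ("retention" %in% stages) {
      pc <- call_older_pole(ft)
      sr <- score_retention(ft, pc)
      f1 <- file.path(out_dir, "retention_calls.csv")
      fwrite(sr$calls, f1)
      manifest$files$retention <- f1
      manifest$tallies$retention <- list(undetermined = sr$n_undetermined)
      summary$retention_fraction <- sr$fraction
      if (!is.na(sr$fraction) && sr$n > 0) {
        k <- round(sr$fraction * sr$n)
        summary$retention_binomial_p <-
          binomial_two_tailed(k, sr$n)$p_value
      }
    }

    sfile <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, sfile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest$files$summary <- sfile
    manifest$finished <- format(Sys.time())
    allf <- setdiff(unlist(manifest$files), character())
    manifest$md5 <- as.list(tools::md5sum(allf[file.exists(allf)]))
    if (is.character(config) && file.exists(config))
      manifest$config_md5 <- unname(tools::md5sum(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}

#' Command-line entry point
#'
#' Dispatcher behind the `chromolin` CLI script
#' (`inst/cli/chromolin.R`): `simulate --preset <name> --mode <m> --layout
#' <l> --seed <int> --out <dir>`, `analyze --stage <s> --cells <csv> --foci
#' <csv> --frame-interval <min> --out <dir>`, and `run --config
#' <json>`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
chromolin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: chromolin <simulate|analyze|run> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1] + 1L] else default
  }
  switch(cmd,
    simulate = {
      pr <- preset(opt("--preset", "WT"),
                   mode = opt("--mode", "phenomenological"))
      sim <- simulate_experiment(
        pr, layout = opt("--layout", "mother_machine"),
        n_lineages = as.integer(opt("--lineages", "10")),
        duration = as.numeric(opt("--duration",
                                  4 * pr$generation_time_mean)),
        frame_interval = as.numeric(opt("--frame-interval",
                                        if (opt("--layout", "mother_machine") ==
                                            "pad") 10 else 5)),
        seed = as.integer(opt("--seed", "1")))
      write_sim_output(sim, opt("--out", stop("--out required")))
    },
    analyze = {
      stage <- opt("--stage", stop("--stage required"))
      cfg <- list(cell_table = opt("--cells"), focus_table = opt("--foci"),
                  frame_interval = as.numeric(opt("--frame-interval", "5")),
                  stages = stage)
      run_pipeline(cfg, out_dir = opt("--out", stop("--out required")))
    },
    run = run_pipeline(opt("--config", stop("--config required")),
                       out_dir = opt("--out")),
    report = {
      # run every stage, then print the headline-statistics JSON to stdout
      out <- opt("--out", tempfile())
      run_pipeline(opt("--config", stop("--config required")), out_dir = out)
      cat(readLines(file.path(out, "summary.json")), sep = "\n")
    },
    stop("unknown command '", cmd, "'")
  )
  invisible(0L)
}
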