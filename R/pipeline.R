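# End-to-end orchestration of the four-system analysis: RMSD rigidity,
# hydrogen-bond statistics, and the LIE thermodynamic cycle, from either a
# named synthetic preset or an on-disk dataset directory.

SYSTEM_NAMES <- c("dna_AT", "dna_GC", "complex_AT", "complex_GC")

#' Pipeline configuration
#'
#' Exactly one of `preset` and `input_dir` must be given.  All defaults
#' equal the canonical analysis profile: heavy-atom selection, 3.0 A / 20
#' degree hydrogen-bond criteria, 10 A bridge radius, alpha 0.18 / beta
#' 0.43, 10 blocks, 0.1 A histogram bins.
#'
#' @param preset synthetic preset name (see [synthetic_preset()]), or
#'   `NULL`.
#' @param input_dir dataset directory written by [write_dataset()], or
#'   `NULL`.
#' @param selection atom selection for RMSD.
#' @param criteria an [hbond_criteria].
#' @param params a [lie_params].
#' @param block_count blocks for energy standard errors.
#' @param bin_width RMSD histogram bin width, Angstrom.
#' @param bridge_radius water-bridge search radius, Angstrom.
#' @param seed master seed for synthetic generation.
#' @param output_dir optional directory for per-stage CSV output.
#' @return object of class `snp_config`.
#' @export
snp_config <- function(preset = "paper_default", input_dir = NULL,
                       selection = "heavy", criteria = hbond_criteria(),
                       params = lie_params(), block_count = 10L,
                       bin_width = 0.1, bridge_radius = 10.0, seed = 42L,
                       output_dir = NULL) {
  if (is.null(preset) == is.null(input_dir))
    stop("exactly one of 'preset' and 'input_dir' must be set")
  stopifnot(inherits(criteria, "hbond_criteria"),
            inherits(params, "lie_params"))
  structure(list(preset = preset, input_dir = input_dir,
                 selection = selection, criteria = criteria,
                 params = params, block_count = as.integer(block_count),
                 bin_width = bin_width, bridge_radius = bridge_radius,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "snp_config")
}

#' Write a four-system dataset to disk
#'
#' Layout: `structures/<system>.pdb`,
#' `trajectories/<system>_run<NN>.pdb` (multi-model),
#' `energies/<system>_run<NN>.csv`, with `<system>` one of `dna_AT`,
#' `dna_GC`, `complex_AT`, `complex_GC`.
#'
#' @param dataset a [synthetic_preset()] result (or the same shape).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  for (sub in c("structures", "trajectories", "energies"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (sys in names(dataset$structures))
    write_pdb(dataset$structures[[sys]],
              file.path(dir, "structures", paste0(sys, ".pdb")))
  for (sys in names(dataset$trajectories)) {
    trajs <- dataset$trajectories[[sys]]
    for (r in seq_along(trajs))
      write_trajectory(trajs[[r]], file.path(
        dir, "trajectories", sprintf("%s_run%02d.pdb", sys, r)))
  }
  for (r in seq_along(dataset$energies)) {
    for (cell in names(dataset$energies[[r]])) {
      es <- dataset$energies[[r]][[cell]]
      sys <- sprintf("%s_%s", if (es$environment == "Complex") "complex"
                     else "dna", es$variant)
      write_energy_table(es, file.path(
        dir, "energies", sprintf("%s_run%02d.csv", sys, r)))
    }
  }
  invisible(dir)
}

#' Read a four-system dataset directory
#'
#' Inverse of [write_dataset()].  Fails with an explicit list of missing
#' (variant, environment) cells when the four-system design is incomplete,
#' and with a pairing error when run counts differ between systems.
#'
#' @param dir dataset directory.
#' @return list with `structures`, `trajectories`, `energies` as in
#'   [synthetic_preset()].
#' @export
read_dataset <- function(dir) {
  efiles <- list.files(file.path(dir, "energies"), pattern = "\\.csv$",
                       full.names = TRUE)
  sysof <- function(f) sub("_run[0-9]+\\.(csv|pdb)$", "", basename(f))
  have <- unique(sysof(efiles))
  missing_sys <- setdiff(SYSTEM_NAMES, have)
  if (length(missing_sys))
    stop("incomplete four-system design: missing ",
         paste(missing_sys, collapse = ", "))
  runs_per <- table(sysof(efiles))
  if (length(unique(as.integer(runs_per))) != 1L)
    stop("mismatched run counts across systems: ",
         paste(sprintf("%s=%d", names(runs_per), runs_per), collapse = ", "))
  n_runs <- as.integer(runs_per[1])
  energies <- lapply(seq_len(n_runs), function(r) {
    runset <- lapply(SYSTEM_NAMES, function(sys)
      read_energy_table(file.path(dir, "energies",
                                  sprintf("%s_run%02d.csv", sys, r))))
    names(runset) <- SYSTEM_NAMES
    runset
  })
  structures <- NULL
  sdir <- file.path(dir, "structures")
  if (dir.exists(sdir)) {
    structures <- lapply(SYSTEM_NAMES, function(sys) {
      f <- file.path(sdir, paste0(sys, ".pdb"))
      if (file.exists(f)) read_pdb(f) else NULL
    })
    names(structures) <- SYSTEM_NAMES
  }
  trajectories <- NULL
  tdir <- file.path(dir, "trajectories")
  if (dir.exists(tdir) && length(list.files(tdir))) {
    trajectories <- lapply(SYSTEM_NAMES, function(sys) {
      fs <- sort(list.files(tdir, pattern = paste0("^", sys, "_run"),
                            full.names = TRUE))
      lapply(fs, function(f)
        read_trajectory(f, topology = structures[[sys]]))
    })
    names(trajectories) <- SYSTEM_NAMES
  }
  list(structures = structures, trajectories = trajectories,
       energies = energies)
}

#' Run the four-system analysis pipeline
#'
#' Executes the RMSD, hydrogen-bond and LIE stages on a synthetic preset
#' or an input directory and assembles a report mirroring the result
#' structure of the study design: per-system RMSD histograms with a
#' rigidity verdict per environment, per-system hydrogen-bond statistics
#' with the wild-type vs mutant comparison for the complexes, and the
#' per-run plus pooled relative binding free energy.
#'
#' @param config a [snp_config].
#' @return object of class `bindshift_report`.
#' @export
run_pipeline <- function(config = snp_config()) {
  stopifnot(inherits(config, "snp_config"))
  message("stage 0/3: assembling inputs")
  data <- if (!is.null(config$preset))
    synthetic_preset(config$preset, seed = config$seed)
  else read_dataset(config$input_dir)
  validate_four_systems(data)

  message("stage 1/3: RMSD")
  rmsd_stage <- NULL
  if (!is.null(data$trajectories)) {
    series <- lapply(data$trajectories, function(trajs)
      lapply(seq_along(trajs), function(r)
        rmsd_series(trajs[[r]], selection = config$selection, fit = TRUE,
                    run_id = r)))
    hist_list <- lapply(series, rmsd_histogram, bin_width = config$bin_width)
    rmsd_stage <- list(
      histograms = hist_list,
      rigidity = list(
        dna = rigidity_summary(series$dna_AT, series$dna_GC),
        complex = rigidity_summary(series$complex_AT, series$complex_GC)),
      series = series)
  }

  message("stage 2/3: hydrogen bonds")
  hbond_stage <- NULL
  if (!is.null(data$trajectories) && !is.null(data$structures)) {
    hb <- lapply(SYSTEM_NAMES, function(sys) {
      trajs <- data$trajectories[[sys]]
      per_run <- lapply(trajs, function(tr) {
        ev <- hbond_trajectory(tr, config$criteria)
        hbond_statistics(ev, n_frames = n_frames(tr), dt_ps = tr$dt_ps)
      })
      list(per_run = per_run,
           mean_count = mean(unlist(lapply(per_run, `[[`, "counts"))))
    })
    names(hb) <- SYSTEM_NAMES
    hbond_stage <- list(
      systems = hb,
      complex_comparison = list(
        wt_mean_count = hb$complex_AT$mean_count,
        mut_mean_count = hb$complex_GC$mean_count,
        mut_minus_wt = hb$complex_GC$mean_count - hb$complex_AT$mean_count))
  }

  message("stage 3/3: LIE thermodynamic cycle")
  lie_stage <- lie_ddg(data$energies, params = config$params,
                       block_count = config$block_count)

  report <- structure(list(
    rmsd = rmsd_stage, hbond = hbond_stage, lie = lie_stage,
    provenance = list(config = config, seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("bindshift")),
                      timestamp = format(Sys.time(), usetz = TRUE))),
    class = "bindshift_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

validate_four_systems <- function(data) {
  if (is.null(data$energies) || !length(data$energies))
    stop("dataset contains no energy series")
  for (r in seq_along(data$energies)) {
    run <- data$energies[[r]]
    cells <- vapply(run, function(e)
      paste(e$variant, e$environment, sep = "."), "")
    need <- c("AT.Complex", "AT.DNA", "GC.Complex", "GC.DNA")
    absent <- setdiff(need, cells)
    if (length(absent))
      stop("incomplete four-system design in run ", r, ": missing cell(s) ",
           paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a report's tables to CSV files
#'
#' Emits `rmsd_histogram_<system>.csv` (bin_start, bin_end, count),
#' `hbond_summary_<system>.csv`, `ddg_per_run.csv` (with a pooled row) and
#' a machine-readable `report.json`.
#'
#' @param report a `bindshift_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$rmsd)) {
    for (sys in names(report$rmsd$histograms)) {
      h <- report$rmsd$histograms[[sys]]
      utils::write.csv(data.frame(
        bin_start = h$bin_edges[-length(h$bin_edges)],
        bin_end = h$bin_edges[-1], count = h$counts),
        file.path(dir, sprintf("rmsd_histogram_%s.csv", sys)),
        row.names = FALSE)
    }
  }
  if (!is.null(report$hbond)) {
    for (sys in names(report$hbond$systems)) {
      per_run <- report$hbond$systems[[sys]]$per_run
      tab <- do.call(rbind, lapply(seq_along(per_run), function(r) {
        s <- per_run[[r]]$summary
        if (nrow(s)) cbind(run = r, s) else NULL
      }))
      if (!is.null(tab))
        utils::write.csv(tab, file.path(
          dir, sprintf("hbond_summary_%s.csv", sys)), row.names = FALSE)
    }
  }
  lie <- report$lie
  tab <- if (!is.null(lie$per_run)) lie$per_run
  else data.frame(run = 1L, ddg = lie$ddg,
                  el_component = lie$ddg_el_component,
                  vdw_component = lie$ddg_vdw_component,
                  dg_bind_at = lie$dg_bind_at, dg_bind_gc = lie$dg_bind_gc,
                  se_ddg = lie$se_ddg)
  pooled <- data.frame(run = NA_integer_, ddg = lie$ddg,
                       el_component = lie$ddg_el_component,
                       vdw_component = lie$ddg_vdw_component,
                       dg_bind_at = lie$dg_bind_at,
                       dg_bind_gc = lie$dg_bind_gc, se_ddg = lie$se_ddg)
  utils::write.csv(rbind(tab, pooled), file.path(dir, "ddg_per_run.csv"),
                   row.names = FALSE)
  json <- list(
    ddg = lie$ddg, se_ddg = lie$se_ddg,
    ddg_el_component = lie$ddg_el_component,
    ddg_vdw_component = lie$ddg_vdw_component, n_runs = lie$n_runs,
    rigidity = if (!is.null(report$rmsd))
      lapply(report$rmsd$rigidity, function(rg)
        list(verdict = rg$verdict, wt_mean = rg$wt$mean,
             mut_mean = rg$mut$mean, wt_sd = rg$wt$sd, mut_sd = rg$mut$sd)),
    hbond_complex_comparison = report$hbond$complex_comparison,
    provenance = list(
      seed = report$provenance$seed,
      package_version = report$provenance$package_version,
      timestamp = report$provenance$timestamp))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @export
print.bindshift_report <- function(x, ...) {
  cat("==== rSNP binding-shift analysis report ====\n\n")
  if (!is.null(x$rmsd)) {
    cat("-- RMSD rigidity --\n")
    cat("DNA systems:\n"); print(x$rmsd$rigidity$dna)
    cat("Complex systems:\n"); print(x$rmsd$rigidity$complex)
    cat("\n")
  }
  if (!is.null(x$hbond)) {
    cc <- x$hbond$complex_comparison
    cat("-- Hydrogen bonds (complexes) --\n")
    cat(sprintf(
      "  mean bonds/frame: wild-type %.2f, mutant %.2f (diff %+.2f)\n\n",
      cc$wt_mean_count, cc$mut_mean_count, cc$mut_minus_wt))
  }
  cat("-- LIE thermodynamic cycle --\n")
  print(x$lie)
  cat(sprintf("\n(seed %d, bindshift %s, %s)\n", x$provenance$seed,
              x$provenance$package_version, x$provenance$timestamp))
  invisible(x)
}
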