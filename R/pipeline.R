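# Config-driven orchestration of the four analyses (RMSD, Rg, patch
# exposure, residue-ligand contacts) with a reproducible report.

CONFIG_DEFAULTS <- list(
  trajectory = NULL,          # required, path
  format = "auto",            # auto | pdb | xyz
  topology = NULL,            # path, required for xyz
  reference = NULL,           # path; default = frame 1 of the trajectory
  units = "angstrom",         # angstrom | nm
  patch_resids = 333:335,
  patch_chain = NA_character_,
  patch_label = "GGG",
  ligand = NULL,              # selection string; contacts skipped if NULL
  threshold = 100,            # A^2
  probe_radius = 1.4,         # A
  n_sphere_points = 960L,
  contact_cutoff = 4.5,       # A
  atom_class = "heavy",       # heavy | all
  gain_threshold = 0.25,
  loss_threshold = 0.25,
  segmentation = "halves",
  rmsd_selection = "calpha",
  rg_selection = "calpha",
  weights = "uniform",        # uniform | mass
  exclude_ligand_occlusion = FALSE,
  log_level = "info",         # info | quiet
  seed = 1L                   # echoed; analyses themselves are deterministic
)

config_check <- function(cfg, errors) {
  chk <- function(cond, msg) if (!cond) c(errors, msg) else errors
  errors <- chk(!is.null(cfg$trajectory) && is.character(cfg$trajectory),
                "'trajectory' is required (path to a trajectory file)")
  if (!is.null(cfg$trajectory) && is.character(cfg$trajectory)) {
    errors <- chk(file.exists(cfg$trajectory),
                  paste0("trajectory file not found: ", cfg$trajectory))
  }
  for (p in c("topology", "reference")) {
    if (!is.null(cfg[[p]])) {
      errors <- chk(file.exists(cfg[[p]]),
                    paste0(p, " file not found: ", cfg[[p]]))
    }
  }
  errors <- chk(cfg$format %in% c("auto", "pdb", "xyz"),
                "'format' must be auto, pdb or xyz")
  errors <- chk(cfg$units %in% c("angstrom", "nm"),
                "'units' must be angstrom or nm")
  errors <- chk(cfg$atom_class %in% c("heavy", "all"),
                "'atom_class' must be heavy or all")
  errors <- chk(cfg$weights %in% c("uniform", "mass"),
                "'weights' must be uniform or mass")
  errors <- chk(cfg$log_level %in% c("info", "quiet"),
                "'log_level' must be info or quiet")
  for (p in c("threshold", "probe_radius", "n_sphere_points",
              "contact_cutoff", "gain_threshold", "loss_threshold")) {
    v <- cfg[[p]]
    errors <- chk(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
                  paste0("'", p, "' must be a positive number"))
  }
  if (is.numeric(cfg$n_sphere_points)) {
    errors <- chk(cfg$n_sphere_points >= 92,
                  "'n_sphere_points' must be >= 92")
  }
  errors <- chk(length(cfg$patch_resids) >= 1 &&
                  all(is.finite(cfg$patch_resids)),
                "'patch_resids' must be a non-empty integer vector")
  if (!identical(cfg$segmentation, "halves") && !is.list(cfg$segmentation)) {
    errors <- c(errors,
                "'segmentation' must be \"halves\" or a list of frame vectors")
  }
  errors
}

#' Validate an analysis configuration
#'
#' Accepts a YAML file path or a named list, fills every documented
#' default, rejects unknown keys (suggesting the nearest known key), and
#' reports all validation problems in a single error.
#'
#' @param config path to a YAML config file, or a named list.
#' @return object of class `analysis_config`: the fully resolved
#'   configuration.
#' @export
validate_config <- function(config) {
  raw <- if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else stop("config must be a file path or a named list")
  if (is.null(raw)) raw <- list()
  raw <- raw[!vapply(raw, is.null, TRUE)]

  errors <- character(0)
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  for (k in unknown) {
    d <- utils::adist(k, names(CONFIG_DEFAULTS))
    hint <- if (min(d) <= 3) {
      paste0(" (did you mean '", names(CONFIG_DEFAULTS)[which.min(d)], "'?)")
    } else ""
    errors <- c(errors, paste0("unknown config key '", k, "'", hint))
  }
  cfg <- CONFIG_DEFAULTS
  for (k in intersect(names(raw), names(CONFIG_DEFAULTS))) {
    cfg[[k]] <- raw[[k]]
  }
  # resid lists may arrive as "333-335" strings from YAML
  if (is.character(cfg$patch_resids)) {
    cfg$patch_resids <- tryCatch(
      parse_id_list(cfg$patch_resids, "patch_resids"),
      error = function(e) {
        errors <<- c(errors, conditionMessage(e)); integer(0)
      })
  }
  errors <- config_check(cfg, errors)
  if (length(errors)) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  cfg$patch_resids <- as.integer(cfg$patch_resids)
  cfg$n_sphere_points <- as.integer(cfg$n_sphere_points)
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k,
                if (is.null(v)) "(unset)" else
                  paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Run the full trajectory analysis
#'
#' Executes the RMSD, radius-of-gyration, patch-exposure and (when a
#' ligand selection is configured) contact analyses on one trajectory,
#' writing TSV series, JSON statistics and a JSON report into `out_dir`.
#' Outputs are staged in a temporary directory and moved into place only
#' on success, so a failing run leaves no partial outputs.  Two runs on
#' identical inputs produce byte-identical series files; the report's
#' config echo, fed back to [validate_config()], reproduces the run.
#'
#' @param config an [validate_config()] result, a config file path, or a
#'   named list.
#' @param out_dir output directory (created if missing).
#' @return the report, an object of class `analysis_report`, invisibly.
#' @export
run_analysis <- function(config, out_dir) {
  cfg <- if (inherits(config, "analysis_config")) config else
    validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  warn_log <- character(0)
  note <- function(...) {
    if (cfg$log_level != "quiet") message("[taupatch] ", ...)
  }
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  note("reading trajectory ", cfg$trajectory)
  topology <- if (!is.null(cfg$topology)) read_pdb(cfg$topology) else NULL
  traj <- read_trajectory(cfg$trajectory, cfg$format, topology, cfg$units)
  traj$topology <- collect(assign_radii(traj$topology))
  reference <- if (!is.null(cfg$reference)) {
    collect(assign_radii(read_pdb(cfg$reference)))
  } else NULL

  stage <- tempfile("taupatch_run_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  blocks <- list()

  note("RMSD series (", cfg$rmsd_selection, ")")
  rmsd <- collect(rmsd_series(traj, reference, cfg$rmsd_selection,
                              cfg$weights))
  write_timeseries_tsv(rmsd, file.path(stage, "rmsd.tsv"))
  rmsd_dens <- collect(probability_density(rmsd))
  write_density_tsv(rmsd_dens, file.path(stage, "rmsd_density.tsv"), "A")
  blocks$rmsd <- list(series = "rmsd.tsv", density = "rmsd_density.tsv",
                      mean = mean(rmsd$values), sd = stats::sd(rmsd$values))

  note("radius-of-gyration series (", cfg$rg_selection, ")")
  rg <- collect(rg_series(traj, cfg$rg_selection, cfg$weights))
  write_timeseries_tsv(rg, file.path(stage, "rg.tsv"))
  rg_dens <- collect(probability_density(rg))
  write_density_tsv(rg_dens, file.path(stage, "rg_density.tsv"), "A")
  seg_rg <- segment_frames(length(rg$values), cfg$segmentation)
  blocks$rg <- list(series = "rg.tsv", density = "rg_density.tsv",
                    mean = mean(rg$values), sd = stats::sd(rg$values),
                    segment_means = lapply(seg_rg, function(fr)
                      mean(rg$values[fr])))

  note("patch exposure (", cfg$patch_label, ": ",
       paste(range(cfg$patch_resids), collapse = "-"), ")")
  patch <- patch_definition(cfg$patch_resids, cfg$patch_chain,
                            cfg$patch_label)
  exclude <- if (isTRUE(cfg$exclude_ligand_occlusion) &&
                 !is.null(cfg$ligand)) cfg$ligand else NULL
  expo <- collect(exposure_series(traj, patch, cfg$threshold,
                                  cfg$probe_radius, cfg$n_sphere_points,
                                  exclude = exclude))
  write_exposure_tsv(expo, file.path(stage, "exposure.tsv"))
  stats_df <- segment_stats(expo, cfg$segmentation)
  write.table(format(stats_df, digits = 10), file.path(stage,
              "exposure_segments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(stats_df, file.path(stage, "exposure_segments.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  blocks$exposure <- list(series = "exposure.tsv",
                          segments_tsv = "exposure_segments.tsv",
                          segments_json = "exposure_segments.json",
                          threshold = cfg$threshold,
                          segments = stats_df)

  if (!is.null(cfg$ligand)) {
    note("residue-ligand contacts (", cfg$ligand, ")")
    cm <- collect(contact_matrix(traj, cfg$ligand, cfg$contact_cutoff,
                                 cfg$atom_class))
    profiles <- contact_frequency(cm, cfg$segmentation)
    for (pr in profiles) {
      write.table(
        data.frame(residue = pr$residues$label, resid = pr$residues$resid,
                   frequency = sprintf("%.6f", pr$frequency)),
        file.path(stage, paste0("contacts_", pr$segment, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    diff_block <- NULL
    if (length(profiles) >= 2) {
      dc <- differential_contacts(profiles[[1]],
                                  profiles[[length(profiles)]],
                                  cfg$gain_threshold, cfg$loss_threshold)
      jsonlite::write_json(
        list(gained = dc$gained, lost = dc$lost,
             gained_resid = dc$gained_resid, lost_resid = dc$lost_resid,
             gain_threshold = dc$gain_threshold,
             loss_threshold = dc$loss_threshold, table = dc$table),
        file.path(stage, "contacts_differential.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA,
        dataframe = "rows")
      diff_block <- list(file = "contacts_differential.json",
                         gained = dc$gained, lost = dc$lost)
    }
    blocks$contacts <- list(
      profiles = paste0("contacts_", vapply(profiles, `[[`, "", "segment"),
                        ".tsv"),
      cutoff = cfg$contact_cutoff, atom_class = cfg$atom_class,
      differential = diff_block)
  } else {
    warn_log <- c(warn_log,
                  "no ligand selection configured; contact analysis skipped")
    note("no ligand selection; skipping contacts")
  }

  report <- structure(list(
    package = "taupatch",
    version = as.character(utils::packageVersion("taupatch")),
    config = unclass(cfg),
    n_frames = n_frames(traj),
    n_atoms = dim(traj$coords)[1],
    blocks = blocks,
    warnings = warn_log,
    wall_clock_s = round(proc.time()[["elapsed"]] - t0, 3)),
    class = "analysis_report")
  report_for_json <- report
  report_for_json$blocks$exposure$segments <-
    as.data.frame(report_for_json$blocks$exposure$segments)
  jsonlite::write_json(unclass(report_for_json),
                       file.path(stage, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null")

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(stage)) {
    file.copy(file.path(stage, f), file.path(out_dir, f), overwrite = TRUE)
  }
  note("wrote ", length(list.files(stage)), " files to ", out_dir)
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report (taupatch %s): %d frames x %d atoms\n",
              x$version, x$n_frames, x$n_atoms))
  cat("  blocks:", paste(names(x$blocks), collapse = ", "), "\n")
  if (!is.null(x$blocks$exposure)) {
    print(x$blocks$exposure$segments)
  }
  if (!is.null(x$blocks$contacts$differential)) {
    cat("  gained:", paste(x$blocks$contacts$differential$gained,
                           collapse = ", "), "\n")
    cat("  lost:  ", paste(x$blocks$contacts$differential$lost,
                           collapse = ", "), "\n")
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
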