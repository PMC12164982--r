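# Pipeline orchestration: validated configuration, staged execution, and a
# run manifest for reproducibility.

pipeline_defaults <- function() {
  list(
    stages = c("simulate", "handshake", "blades", "lipids", "surface",
               "pore", "fit"),
    seed = 1L,
    out_dir = "piezotraj-run",
    # inputs: either simulation parameters or trajectory files
    traj = NULL, topology = NULL,
    n_frames = 500L, n_lipids = 600L,
    # analysis cutoffs/bins (defaults are the published values where stated)
    handshake_cutoff = 1.5,
    pool_cutoff = 2.5,
    contact_cutoff = 0.6,
    cavity_spacing_A = 1.4,
    cavity_dim = 3L,
    hist_bin_nm = 0.1,
    conf_bin_d = 0.25,
    conf_bin_theta = 2,
    height_bin_nm = 0.5,
    density_bin_nm = 0.5,
    density_species = "PIP2",
    bind_cutoff = 1.5, unbind_cutoff = 2.0,
    stable_min_dwell = 200L, unstable_min_transitions = 3L,
    unstable_window = 500L, release_min_unbound = 500L,
    pressure_file = NULL, dose_file = NULL
  )
}

config_types <- function() {
  num <- c("handshake_cutoff", "pool_cutoff", "contact_cutoff",
           "cavity_spacing_A", "hist_bin_nm", "conf_bin_d",
           "conf_bin_theta", "height_bin_nm", "density_bin_nm",
           "bind_cutoff", "unbind_cutoff")
  int <- c("seed", "n_frames", "n_lipids", "cavity_dim",
           "stable_min_dwell", "unstable_min_transitions",
           "unstable_window", "release_min_unbound")
  chr <- c("out_dir", "traj", "topology", "density_species",
           "pressure_file", "dose_file")
  list(num = num, int = int, chr = chr)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML string, a file path, or a named list; fills defaults
#' (published parameter values where one exists: handshake cutoff 1.5 nm,
#' PIP2 pool cutoff 2.5 nm, contact cutoff 0.6 nm, cavity spacing 1.4 A,
#' buriedness 3), checks types and ranges, and reports every unknown key.
#' Deviations from the defaults are reported as messages.
#'
#' @param config YAML text, a path to a YAML file, or a named list. `NULL`
#'   or empty input yields the full default configuration.
#' @return A validated `run_config` list. Accumulated problems raise a
#'   single config error listing all of them.
#' @export
validate_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  if (is.null(config)) {
    user <- list()
  } else if (is.character(config) && length(config) == 1L) {
    user <- if (file.exists(config)) yaml::read_yaml(config)
            else yaml::yaml.load(config)
    if (is.null(user)) user <- list()
  } else if (is.list(config)) {
    user <- config
  } else {
    abort_config("config must be YAML text, a file path, or a list")
  }
  errors <- character(0)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  ty <- config_types()
  cfg <- defaults
  for (key in intersect(names(user), names(defaults))) {
    val <- user[[key]]
    if (key %in% ty$num || key %in% ty$int) {
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
        errors <- c(errors, sprintf("'%s' must be a finite number", key))
        next
      }
      if (val <= 0 && key != "seed") {
        errors <- c(errors, sprintf("'%s' must be > 0", key))
        next
      }
      cfg[[key]] <- if (key %in% ty$int) as.integer(val) else as.numeric(val)
    } else if (key %in% ty$chr) {
      if (!is.character(val) || length(val) != 1L) {
        errors <- c(errors, sprintf("'%s' must be a single string", key))
        next
      }
      cfg[[key]] <- val
    } else if (key == "stages") {
      known <- pipeline_defaults()$stages
      bad <- setdiff(val, known)
      if (length(bad)) {
        errors <- c(errors, sprintf("unknown stage(s): %s",
                                    paste(bad, collapse = ", ")))
      } else {
        cfg$stages <- val
      }
    }
  }
  if (!length(errors) && cfg$unbind_cutoff < cfg$bind_cutoff) {
    errors <- c(errors, "unbind_cutoff must be >= bind_cutoff")
  }
  if (length(errors)) {
    abort_config(paste0("invalid configuration:\n  - ",
                        paste(errors, collapse = "\n  - ")))
  }
  for (key in c("handshake_cutoff", "pool_cutoff", "contact_cutoff",
                "cavity_spacing_A", "cavity_dim")) {
    if (!identical(cfg[[key]], defaults[[key]]) &&
        !isTRUE(all.equal(cfg[[key]], defaults[[key]]))) {
      message(sprintf("config: '%s' deviates from the default (%s -> %s)",
                      key, format(defaults[[key]]), format(cfg[[key]])))
    }
  }
  structure(cfg, class = "run_config")
}

write_matrix_csv <- function(m, path, value_name = "value") {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (synthetic
#' trajectory + ground truth), `handshake` (tip distances, states,
#' frequencies, histogram, mode episodes), `blades` (distance/angle/height,
#' projected area), `lipids` (PIP2 pool series, density map), `surface`
#' (leaflet height maps, dome depth), `pore` (triangle metrics, cavity
#' volume of the first frame), `fit` (response-curve fits on provided or
#' simulated tables). All outputs are CSV/JSON under `out_dir`; the
#' manifest records the configuration, output checksums and package
#' version.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return The run manifest, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  traj <- NULL; gt <- NULL
  if ("simulate" %in% cfg$stages) {
    stage("simulate", {
      sim <- simulate_channel(
        channel_sim_params(n_frames = cfg$n_frames),
        membrane_spec(n_lipids = cfg$n_lipids), seed = cfg$seed)
      traj <- sim$trajectory; gt <- sim$ground_truth
      write_gro(traj, emit(file.path(cfg$out_dir, "trajectory.gro")))
      write_topology_csv(traj$topology,
                         emit(file.path(cfg$out_dir, "topology.csv")))
      gt_df <- data.frame(frame = seq_len(nrow(gt$bound)),
                          bound1 = gt$bound[, 1], bound2 = gt$bound[, 2],
                          bound3 = gt$bound[, 3],
                          pool1 = gt$pool[, 1], pool2 = gt$pool[, 2],
                          pool3 = gt$pool[, 3])
      utils::write.csv(gt_df, emit(file.path(cfg$out_dir, "ground_truth.csv")),
                       row.names = FALSE, quote = FALSE)
    })
  } else if (!is.null(cfg$traj)) {
    stage("load", {
      traj <- read_gro(cfg$traj, topology = cfg$topology)
    })
  }
  needs_traj <- intersect(cfg$stages,
                          c("handshake", "blades", "lipids", "surface", "pore"))
  if (length(needs_traj) && is.null(traj)) {
    abort_config("analysis stages need either 'simulate' or a 'traj' input")
  }
  series <- NULL
  if ("handshake" %in% cfg$stages) {
    stage("handshake", {
      d <- tip_distance_series(traj)
      series <- classify_handshakes(d, cutoff = cfg$handshake_cutoff)
      per_frame <- data.frame(frame = seq_len(nrow(d)), d,
                              count = series$count)
      utils::write.csv(per_frame,
                       emit(file.path(cfg$out_dir, "handshake_series.csv")),
                       row.names = FALSE, quote = FALSE)
      freq <- handshake_frequencies(series)
      utils::write.csv(data.frame(count = 0:3, frequency = freq),
                       emit(file.path(cfg$out_dir, "handshake_frequencies.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(distance_histogram(series, cfg$hist_bin_nm),
                       emit(file.path(cfg$out_dir, "distance_histogram.csv")),
                       row.names = FALSE, quote = FALSE)
      pool <- pip2_pool_series(traj, cutoff = cfg$pool_cutoff)
      eps <- classify_modes(d, pool, mode_params(
        cfg$bind_cutoff, cfg$unbind_cutoff, cfg$stable_min_dwell,
        cfg$unstable_min_transitions, cfg$unstable_window,
        cfg$release_min_unbound))
      utils::write.csv(eps, emit(file.path(cfg$out_dir, "mode_episodes.csv")),
                       row.names = FALSE, quote = FALSE)
    })
  }
  if ("blades" %in% cfg$stages) {
    stage("blades", {
      bd <- blade_distance(traj); ba <- blade_angle(traj)
      bh <- blade_height(traj)
      utils::write.csv(data.frame(frame = seq_len(nrow(bd)),
                                  distance = bd, angle = ba, height = bh),
                       emit(file.path(cfg$out_dir, "blade_metrics.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(projected_area(traj),
                       emit(file.path(cfg$out_dir, "projected_area.csv")),
                       row.names = FALSE, quote = FALSE)
    })
  }
  if ("lipids" %in% cfg$stages) {
    stage("lipids", {
      pool <- pip2_pool_series(traj, cutoff = cfg$pool_cutoff)
      utils::write.csv(data.frame(frame = seq_len(nrow(pool)), pool),
                       emit(file.path(cfg$out_dir, "pip2_pool.csv")),
                       row.names = FALSE, quote = FALSE)
      dm <- lipid_density_map(traj, cfg$density_species,
                              bin = cfg$density_bin_nm)
      write_matrix_csv(dm$values,
                       emit(file.path(cfg$out_dir, "density_map.csv")))
      jsonlite::write_json(list(bin = dm$bin, origin = dm$origin,
                                kind = dm$kind),
                           emit(file.path(cfg$out_dir, "density_map.json")),
                           auto_unbox = TRUE)
    })
  }
  if ("surface" %in% cfg$stages) {
    stage("surface", {
      hm <- leaflet_height_map(traj, "lower", bin = cfg$height_bin_nm)
      write_matrix_csv(hm$values,
                       emit(file.path(cfg$out_dir, "height_map_lower.csv")))
      jsonlite::write_json(list(bin = hm$bin, origin = hm$origin,
                                kind = hm$kind,
                                dome_depth_nm = dome_depth(hm)),
                           emit(file.path(cfg$out_dir, "height_map_lower.json")),
                           auto_unbox = TRUE)
    })
  }
  if ("pore" %in% cfg$stages) {
    stage("pore", {
      tri <- do.call(rbind, lapply(c("top", "middle", "bottom"), function(l) {
        pore_triangle(traj, l)
      }))
      utils::write.csv(tri, emit(file.path(cfg$out_dir, "pore_triangles.csv")),
                       row.names = FALSE, quote = FALSE)
      cav <- cavity_volume(traj$frames[[1]], traj$topology,
                           spacing = cfg$cavity_spacing_A,
                           dim_threshold = cfg$cavity_dim)
      jsonlite::write_json(list(volume_A3 = cav$volume_A3,
                                volume_nm3 = cav$volume_nm3,
                                n_voxels = nrow(cav$voxels),
                                spacing_A = cav$spacing,
                                dim = cav$dim_threshold),
                           emit(file.path(cfg$out_dir, "cavity.json")),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  if ("fit" %in% cfg$stages) {
    stage("fit", {
      pr <- if (!is.null(cfg$pressure_file)) {
        utils::read.csv(cfg$pressure_file)
      } else {
        simulate_pressure_response(noise_sd = 10, seed = cfg$seed)
      }
      bf <- fit_boltzmann(pr$pressure_mmHg, pr$response)
      dr <- if (!is.null(cfg$dose_file)) {
        utils::read.csv(cfg$dose_file)
      } else {
        simulate_dose_response(noise_sd = 0.02, seed = cfg$seed + 1L)
      }
      hf <- fit_hill(dr$dose_uM, dr$response)
      jsonlite::write_json(
        list(boltzmann = list(coefficients = as.list(bf$coefficients),
                              se = as.list(bf$se), converged = bf$converged,
                              rss = bf$rss),
             hill = list(coefficients = as.list(hf$coefficients),
                         se = as.list(hf$se), converged = hf$converged,
                         rss = hf$rss)),
        emit(file.path(cfg$out_dir, "fits.json")),
        auto_unbox = TRUE, digits = NA)
    })
  }
  manifest <- list(
    config = unclass(cfg),
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(outputs)),
    package_version = as.character(utils::packageVersion("piezotraj")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
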