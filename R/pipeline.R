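# ---------------------------------------------------------------------------
# One-config orchestration of the full per-system analysis: occupancy
# maps, SASA series, chi1/rotamer/side-chain-RMSD tables, protonation
# states, helix segmentation of the final frame, and (given >= 2 final
# structures) the RMSD matrix + MDS embedding.
# ---------------------------------------------------------------------------

#' Load and validate an analysis configuration
#'
#' YAML with keys: `topology`, `trajectory` (paths); `portal_selections`
#' (named list of selection expressions, e.g. alpha1/alpha2 flanks);
#' `tracked_residues` (list of `chain`/`resno`); `grid` (`spacing`,
#' `padding`, `thresholds`); `smoothing` (`window`, `degree`);
#' `ph` (numeric vector); `pka_tables` (paths); `helix_regions` (named
#' list of 2-vectors); `time_per_frame`; `seed`.  Defaults mirror the
#' standard analysis parameters: spacing 0.5 A, thresholds 0.5/0.9,
#' window 51, degree 3, pH 7 and 4.5, 0.04 ns/frame.
#'
#' @param path YAML config path.
#' @return Object of class `"analysis_config"` (validated list).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    grid = list(spacing = 0.5, padding = 2, thresholds = c(0.5, 0.9)),
    smoothing = list(window = 51, degree = 3),
    ph = c(7, 4.5),
    time_per_frame = 0.04,
    seed = 1L,
    dwell = 50
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (k2 in names(defaults[[k]])) {
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- defaults[[k]][[k2]]
      }
    }
  }
  for (key in c("topology", "trajectory")) {
    if (is.null(cfg[[key]])) stop("config lacks required key: ", key)
    if (!file.exists(cfg[[key]])) {
      stop(sprintf("config %s path does not exist: %s", key, cfg[[key]]))
    }
  }
  th <- unlist(cfg$grid$thresholds)
  if (any(th <= 0 | th > 1)) stop("occupancy thresholds must be in (0, 1]")
  for (p in cfg$pka_tables) {
    if (!file.exists(p)) stop("pKa table not found: ", p)
  }
  structure(cfg, class = "analysis_config", path = path)
}

log_stage <- function(...) message(sprintf("[portaldyn] %s", sprintf(...)))

#' Run the full analysis described by a configuration
#'
#' Produces, under `out_dir`: `occupancy_<sel>_<thr>.dx` maps and a map
#' per portal selection, `sasa_<sel>.csv` (raw + smoothed),
#' `residue_<chain><resno>.csv` (chi1, rotamer label, side-chain RMSD per
#' frame), `rotamer_summary.json`, `protonation_ph<ph>.json` + PQR (when
#' pKa tables are given), `helix_segments.json` (final frame), and --
#' when >= 2 `final_structures` paths are configured -- `rmsd_matrix.csv`
#' and `embedding.csv`.  A `run_manifest.json` records package version,
#' config hash, seed and every parameter actually used.  Any stage
#' failure aborts with the stage name.
#'
#' @param config An [read_analysis_config()] object (or a path to one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  stage <- function(name, expr) {
    log_stage("stage: %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  top <- stage("read_topology", read_topology(config$topology))
  traj <- stage("read_trajectory",
                read_trajectory(top, config$trajectory,
                                time_per_frame = config$time_per_frame))

  sels <- config$portal_selections
  if (length(sels)) {
    for (nm in names(sels)) {
      stage(paste0("occupancy_", nm), {
        map <- fractional_occupancy(traj, sels[[nm]],
                                    spacing = config$grid$spacing,
                                    padding = config$grid$padding)
        for (th in unlist(config$grid$thresholds)) {
          f <- file.path(out_dir, sprintf("occupancy_%s_%0.2f.dx", nm, th))
          vol <- occupied_volume(map, th)
          map_th <- map
          map_th$values <- as.numeric(map$values >= th - 1e-12)
          write_dx(map_th, f)
          written[[basename(f)]] <- f
        }
        f <- file.path(out_dir, sprintf("occupancy_%s.dx", nm))
        write_dx(map, f)
        written[[basename(f)]] <- f
      })
      stage(paste0("sasa_", nm), {
        raw <- sasa_series(traj, sels[[nm]])
        sm <- savgol_smooth(raw, window = min(config$smoothing$window,
                                              n_frames(traj) -
                                                (1 - n_frames(traj) %% 2)),
                            degree = config$smoothing$degree)
        f <- file.path(out_dir, sprintf("sasa_%s.csv", nm))
        write_series_csv(raw, f, smoothed = sm)
        written[[basename(f)]] <- f
      })
    }
  }

  summaries <- list()
  for (tr in config$tracked_residues) {
    key <- sprintf("%s%s", tr$chain, tr$resno)
    stage(paste0("residue_", key), {
      trace <- chi1_series(traj, tr$chain, tr$resno)
      summ <- rotamer_summary(trace, dwell = config$dwell)
      rmsd <- tryCatch(
        sidechain_rmsd_series(traj, tr$chain, tr$resno),
        error = function(e) NULL)
      df <- data.frame(frame = seq_along(trace$chi1),
                       time_ns = (seq_along(trace$chi1) - 1) *
                         trace$time_per_frame,
                       chi1_deg = trace$chi1,
                       label = summ$labels)
      if (!is.null(rmsd)) df$rmsd_A <- rmsd$values
      f <- file.path(out_dir, sprintf("residue_%s.csv", key))
      utils::write.csv(df, f, row.names = FALSE)
      written[[basename(f)]] <- f
      summaries[[key]] <- list(
        chain = tr$chain, residue_number = tr$resno,
        circular_mean_deg = round(summ$circular_mean, 4),
        circular_sd_deg = round(summ$circular_sd, 4),
        dominant_rotamer = summ$dominant_label,
        rotamer_change = summ$change_flag,
        change_frames = summ$change_frames,
        statistics = "circular", superposition = "CA-fit vs frame 1"
      )
    })
  }
  if (length(summaries)) {
    f <- file.path(out_dir, "rotamer_summary.json")
    jsonlite::write_json(summaries, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written[["rotamer_summary.json"]] <- f
  }

  if (length(config$pka_tables)) {
    preds <- stage("read_pka_tables", read_pka_tables(config$pka_tables))
    cons <- stage("consensus_pka", consensus_pka(preds))
    for (ph in unlist(config$ph)) {
      stage(sprintf("protonation_ph%g", ph), {
        asg <- assign_protonation(cons, ph)
        f <- file.path(out_dir, sprintf("protonation_ph%g.json", ph))
        jsonlite::write_json(list(
          pH = ph, net_charge = net_charge(asg),
          unresolved = cons$residue_number[cons$status == "unresolved"],
          residues = asg
        ), f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
        written[[basename(f)]] <- f
        fq <- file.path(out_dir, sprintf("charges_ph%g.pqr", ph))
        write_pqr_charges(top, asg, fq,
                          frame = get_frame(traj, n_frames(traj)))
        written[[basename(fq)]] <- fq
      })
    }
  }

  if (length(config$helix_regions)) {
    stage("helix_segmentation", {
      final <- get_frame(traj, n_frames(traj))
      flags <- assign_helix(top, final)
      segs <- lapply(names(config$helix_regions), function(nm) {
        sg <- segment_helices(flags, top, unlist(config$helix_regions[[nm]]))
        list(region = nm, segments = sg$text, hinges = sg$hinges)
      })
      f <- file.path(out_dir, "helix_segments.json")
      jsonlite::write_json(segs, f, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      written[["helix_segments.json"]] <- f
    })
  }

  if (length(config$final_structures) >= 2) {
    stage("structure_comparison", {
      structs <- lapply(config$final_structures, function(p) {
        tp <- read_topology(p)
        list(topology = tp, frame = get_frame(read_trajectory(tp, p), 1))
      })
      names(structs) <- vapply(config$final_structures, function(p)
        tools::file_path_sans_ext(basename(p)), character(1))
      m <- rmsd_matrix(structs, atom_names = c("N", "CA", "C", "O"))
      f <- file.path(out_dir, "rmsd_matrix.csv")
      utils::write.csv(as.data.frame(unclass(m)), f)
      written[["rmsd_matrix.csv"]] <- f
      emb <- mds_embed(m)
      f2 <- file.path(out_dir, "embedding.csv")
      utils::write.csv(data.frame(label = rownames(emb),
                                  x = emb[, 1], y = emb[, 2],
                                  row.names = NULL), f2, row.names = FALSE)
      written[["embedding.csv"]] <- f2
    })
  }

  manifest <- list(
    package = "portaldyn",
    version = as.character(utils::packageVersion("portaldyn")),
    config_hash = unname(tools::md5sum(attr(config, "path") %||%
                                         tempfile_config(config))),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("class"))],
    outputs = names(written)
  )
  f <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  written[["run_manifest.json"]] <- f
  log_stage("done: %d artifact(s) in %s", length(written), out_dir)
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hash surrogate when the config came in as an in-memory object: serialise
# it to a temp file so the manifest still records a content hash.
tempfile_config <- function(config) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), f)
  f
}
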