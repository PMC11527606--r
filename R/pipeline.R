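#' @section Pipeline:
#' One JSON config drives an end-to-end multi-system comparison: read
#' each system, run the per-system analyses (gating, permeation,
#' occupancy/dwell, contact fractions, correlations, torsions,
#' RMSD/RMSF), then the configured apo-vs-holo comparisons (difference
#' tables, correlation differences, combined PCA). Each analysis is
#' isolated: one failing table is logged and skipped without aborting
#' the bundle. Identical config + seed give identical outputs.
#' @name poregate-pipeline
NULL

parse_res_string <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("residue reference must be 'CHAIN:RESID': ", s)
  res_ref(parts[1L], as.integer(parts[2L]))
}

# FNV-style hash of a string, for the run log's config fingerprint.
config_hash <- function(txt) {
  h <- 2166136261 %% 2^31
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Validate an analysis config
#'
#' @param config parsed config list.
#' @param check_files also require input files to exist.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config, check_files = TRUE) {
  probs <- character()
  add <- function(p) probs <<- c(probs, p)
  if (is.null(config$systems) || !length(config$systems))
    add("config needs a non-empty 'systems' list")
  labels <- vapply(config$systems, function(s)
    if (is.null(s$label)) NA_character_ else s$label, "")
  if (anyNA(labels)) add("every system needs a 'label'")
  if (anyDuplicated(stats::na.omit(labels))) add("system labels must be unique")
  for (s in config$systems) {
    for (f in c("topology", "trajectory")) {
      if (is.null(s[[f]])) add(sprintf("system '%s' missing '%s'", s$label, f))
      else if (check_files && !file.exists(s[[f]]))
        add(sprintf("system '%s': file not found: %s", s$label, s[[f]]))
    }
  }
  if (!is.null(config$comparisons)) {
    for (cmp in config$comparisons) {
      for (side in c("apo", "holo"))
        if (is.null(cmp[[side]]) || !(cmp[[side]] %in% labels))
          add(sprintf("comparison references undefined label '%s'",
                      if (is.null(cmp[[side]])) "(missing)" else cmp[[side]]))
    }
  }
  if (is.null(config$selections$ions)) add("selections need an 'ions' expression")
  for (k in c("sf", "hbc", "gloop"))
    if (is.null(config$selections[[k]]))
      add(sprintf("selections need a '%s' boundary expression", k))
  probs
}

#' Read and validate an analysis config from JSON
#' @param path JSON file path.
#' @param check_files require referenced files to exist.
#' @return the config list, with `._json` carrying the raw text.
#' @export
read_analysis_config <- function(path, check_files = TRUE) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  config <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  probs <- validate_config(config, check_files = check_files)
  if (length(probs))
    stop("invalid config:\n  - ", paste(probs, collapse = "\n  - "))
  config$`._json` <- txt
  config
}

cfg_cut <- function(config, name, default) {
  v <- config$cutoffs[[name]]
  if (is.null(v)) default else v
}

cfg_window <- function(sysdef) {
  w <- sysdef$window
  if (is.null(w)) return(NULL)
  frame_window(start = if (is.null(w$start)) 0L else w$start,
               end = w$end, stride = if (is.null(w$stride)) 1L else w$stride)
}

#' Run the full analysis pipeline
#'
#' @param config parsed (validated) config list, see
#'   [read_analysis_config()].
#' @param output_dir overrides `config$output_dir`.
#' @return a `pg_report_bundle`: `tables` (per system/analysis),
#'   `comparisons`, `errors` (named list of failure messages), `log`
#'   (data frame), `summary`, `output_dir`.
#' @export
run_analysis <- function(config, output_dir = NULL) {
  out <- output_dir %||% config$output_dir %||% stop("no output_dir configured")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  logs <- list(); errors <- list(); tables <- list(); summaries <- list()
  note <- function(system, analysis, status, rows, secs) {
    logs[[length(logs) + 1L]] <<- data.frame(
      system = system, analysis = analysis, status = status,
      rows = rows, seconds = round(secs, 3), stringsAsFactors = FALSE)
  }
  step <- function(system, analysis, fun) {
    t0 <- proc.time()[3L]
    res <- tryCatch(fun(), error = function(e) e)
    secs <- proc.time()[3L] - t0
    if (inherits(res, "error")) {
      errors[[paste(system, analysis, sep = "/")]] <<- conditionMessage(res)
      note(system, analysis, "error", 0L, secs)
      NULL
    } else {
      nr <- if (is.data.frame(res)) nrow(res) else NA_integer_
      note(system, analysis, "ok", nr, secs)
      res
    }
  }

  sel <- config$selections
  gate_cut <- cfg_cut(config, "gate_open", 5.69)
  systems <- list()

  for (sysdef in config$systems) {
    lab <- sysdef$label
    sysres <- step(lab, "read", function() {
      topo <- read_topology(sysdef$topology)
      traj <- read_trajectory(topo, sysdef$trajectory)
      list(topology = topo, trajectory = traj, window = cfg_window(sysdef))
    })
    if (is.null(sysres)) next
    systems[[lab]] <- sysres
    traj <- sysres$trajectory
    win <- sysres$window
    pre <- function(f) file.path(out, paste0(lab, "_", f))

    ## gating
    for (g in config$gates %||% list()) {
      gd <- gate_definition(g$name, g$resid,
                            atom_scope = g$atom_scope %||% "sidechain_heavy")
      tr <- step(lab, paste0("gate_", g$name), function() {
        trace <- gate_distance_trace(traj, gd, win)
        write_gate_trace(trace, pre(paste0("gate_", g$name, ".tsv")), gate_cut)
        stats <- open_fraction(trace, cutoff = gate_cut)
        write_gate_stats(stats, pre(paste0("gate_", g$name, ".json")))
        list(trace = trace, stats = stats)
      })
      if (!is.null(tr))
        tables[[lab]][[paste0("gate_", g$name)]] <- tr
    }

    ## permeation + occupancy + dwell
    perm <- step(lab, "permeation", function() {
      ions <- select_atoms(traj$topology, sel$ions)
      model <- build_compartments(
        traj,
        select_atoms(traj$topology, sel$sf, granularity = "residue"),
        select_atoms(traj$topology, sel$hbc, granularity = "residue"),
        select_atoms(traj$topology, sel$gloop, granularity = "residue"),
        radial_cutoff = cfg_cut(config, "radial", 10),
        hysteresis = cfg_cut(config, "hysteresis", 2))
      ev <- detect_permeation_events(traj, ions, model, "ext_to_int", win)
      write_events(ev, pre("events.tsv"))
      occ <- lapply(c("sf", "cavity", "gloop"), function(r)
        occupancy_distribution(traj, ions, model, r, win))
      for (o in occ)
        write_occupancy(o, pre(paste0("occupancy_", attr(o, "region"), ".tsv")))
      residues <- select_atoms(traj$topology, sel$dwell_residues %||% "protein",
                               granularity = "residue")
      dw <- dwell_profile(traj, ions, model, residues, window = win)
      write_dwell(dw, pre("dwell.tsv"))
      list(events = ev, model = model, occupancy = occ, dwell = dw)
    })
    if (!is.null(perm)) tables[[lab]]$permeation <- perm

    ## contact fractions
    for (ct in c("salt_bridge", "hbond", "hydrophobic")) {
      ft <- step(lab, paste0("fractions_", ct), function() {
        crit <- contact_criteria(ct,
                                 distance_cutoff = cfg_cut(config, ct, NULL),
                                 angle_cutoff = cfg_cut(config, "hbond_angle", 135))
        tab <- pair_fractions(traj, crit, win, system_label = lab)
        write_pair_fractions(tab, pre(paste0("fractions_", ct, ".tsv")))
        tab
      })
      if (!is.null(ft)) tables[[lab]][[paste0("fractions_", ct)]] <- ft
    }

    ## collective dynamics
    cc <- step(lab, "correlation", function() {
      cm <- correlation_matrix(traj,
                               select_atoms(traj$topology, sel$correlation %||% "name CA"),
                               win)
      utils::write.table(cm$matrix, pre("correlation.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
      cm
    })
    if (!is.null(cc)) tables[[lab]]$correlation <- cc

    tor <- step(lab, "torsions", function() {
      ts <- torsion_summary(traj, win)
      write_torsions(ts, pre("torsions.tsv"))
      ts
    })
    if (!is.null(tor)) tables[[lab]]$torsions <- tor

    rms <- step(lab, "rmsd_rmsf", function() {
      ca <- select_atoms(traj$topology, sel$correlation %||% "name CA")
      rt <- rmsd_trace(traj, ca, window = win)
      write_tsv(rt, pre("rmsd.tsv"))
      rf <- rmsf_profile(traj, ca, win)
      write_tsv(rf, pre("rmsf.tsv"))
      list(rmsd = rt, rmsf = rf)
    })
    if (!is.null(rms)) tables[[lab]]$rmsd_rmsf <- rms

    ## ligand contacts (only if a ligand selection is configured and hits)
    if (!is.null(sel$ligand)) {
      lc <- step(lab, "ligand_contacts", function() {
        lig <- suppressWarnings(select_atoms(traj$topology, sel$ligand))
        if (!length(lig$atom_indices)) return(NULL)
        prof <- ligand_contact_profile(
          traj, lig,
          select_atoms(traj$topology, sel$dwell_residues %||% "protein",
                       granularity = "residue"),
          cutoff = cfg_cut(config, "ligand_contact", 4.0), window = win)
        write_tsv(prof, pre("ligand_contacts.tsv"))
        prof
      })
      if (!is.null(lc)) tables[[lab]]$ligand_contacts <- lc
    }

    summaries[[lab]] <- list(
      n_frames = traj$n_frames,
      permeation_events_ext_to_int =
        if (!is.null(perm)) nrow(perm$events) else NA,
      gate_open_fractions = {
        gf <- list()
        for (g in config$gates %||% list()) {
          st <- tables[[lab]][[paste0("gate_", g$name)]]$stats
          if (!is.null(st)) gf[[g$name]] <- st$open_fraction
        }
        gf
      })
  }

  ## comparisons
  comparisons <- list()
  for (cmp in config$comparisons %||% list()) {
    key <- paste0(cmp$apo, "_vs_", cmp$holo)
    if (is.null(systems[[cmp$apo]]) || is.null(systems[[cmp$holo]])) {
      errors[[paste0(key, "/inputs")]] <- "one or both systems failed to load"
      next
    }
    for (ct in c("salt_bridge", "hbond", "hydrophobic")) {
      dt <- step(key, paste0("diff_", ct), function() {
        ta <- tables[[cmp$apo]][[paste0("fractions_", ct)]]
        th <- tables[[cmp$holo]][[paste0("fractions_", ct)]]
        if (is.null(ta) || is.null(th)) stop("fraction tables unavailable")
        d <- difference_table(ta, th)
        write_difference_table(d, file.path(out, paste0(key, "_diff_", ct, ".tsv")),
                               file.path(out, paste0(key, "_diff_", ct, "_matrix.tsv")))
        d
      })
      if (!is.null(dt)) comparisons[[key]][[paste0("diff_", ct)]] <- dt
    }
    cd <- step(key, "correlation_difference", function() {
      ca <- tables[[cmp$apo]]$correlation
      ch <- tables[[cmp$holo]]$correlation
      if (is.null(ca) || is.null(ch)) stop("correlation matrices unavailable")
      d <- correlation_difference(ca, ch)
      write_tsv(d, file.path(out, paste0(key, "_correlation_diff.tsv")))
      d
    })
    if (!is.null(cd)) comparisons[[key]]$correlation_difference <- cd
    pc <- step(key, "combined_pca", function() {
      ta <- systems[[cmp$apo]]$trajectory
      th <- systems[[cmp$holo]]$trajectory
      sa <- select_atoms(ta$topology, sel$correlation %||% "name CA")
      sb <- select_atoms(th$topology, sel$correlation %||% "name CA")
      pca <- combined_pca(ta, th, sa, sb,
                          systems[[cmp$apo]]$window, systems[[cmp$holo]]$window,
                          labels = c(cmp$apo, cmp$holo))
      write_tsv(data.frame(ev = seq_along(pca$eigenvalues),
                           eigenvalue = pca$eigenvalues),
                file.path(out, paste0(key, "_eigenvalues.tsv")))
      write_tsv(pca$projections, file.path(out, paste0(key, "_projections.tsv")))
      write_pca_morph(pca, ta$topology,
                      file.path(out, paste0(key, "_ev1_morph.pdb")), ev = 1L)
      pca
    })
    if (!is.null(pc)) comparisons[[key]]$pca <- pc
  }

  log_df <- do.call(rbind, logs)
  summary <- list(seed = seed,
                  config_hash = config_hash(config$`._json` %||% ""),
                  systems = summaries,
                  n_errors = length(errors),
                  errors = errors)
  write_json_summary(summary, file.path(out, "summary.json"))
  write_tsv(log_df, file.path(out, "run_log.tsv"))
  structure(list(tables = tables, comparisons = comparisons,
                 errors = errors, log = log_df, summary = summary,
                 output_dir = out),
            class = "pg_report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a synthetic-channel simulation from a JSON config
#'
#' Writes `topology.pdb`, `traj.dcd` and `manifest.json` into `out_dir`.
#' The config mirrors the generator API: a `spec` block, `n_frames`,
#' and optional `schedules`, `ions` (either counts
#' `{"complete": n, "abort": n, "retrograde": n}` or explicit scripts),
#' `contacts`, `correlations`, `torsions` blocks; residues are written
#' `"CHAIN:RESID"`.
#'
#' @param config parsed simulation config list (or a JSON file path).
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  if (is.character(config))
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- config$spec %||% list()
  spec_args <- sp[intersect(names(sp),
                            names(formals(channel_spec)))]
  spec <- do.call(channel_spec, spec_args)
  n_frames <- config$n_frames %||% 100L
  schedules <- lapply(config$schedules %||% list(), function(s)
    do.call(gate_schedule, s))
  ions <- if (!is.null(config$ions$complete) || !is.null(config$ions$abort) ||
                !is.null(config$ions$retrograde)) {
    make_ion_scripts(spec, n_frames,
                     n_complete = config$ions$complete %||% 0L,
                     n_abort = config$ions$abort %||% 0L,
                     n_retrograde = config$ions$retrograde %||% 0L)
  } else {
    lapply(config$ions %||% list(), function(s)
      ion_script(s$ion, do.call(rbind, lapply(s$waypoints, as.data.frame)),
                 s$lateral_noise_sd %||% 0.5, s$outcome %||% "park"))
  }
  n_scripted <- length(ions)
  if (n_scripted > spec$n_ions) {
    spec_args$n_ions <- n_scripted
    spec <- do.call(channel_spec, spec_args)
  }
  contacts <- lapply(config$contacts %||% list(), function(p)
    contact_plan(parse_res_string(p$res_a), parse_res_string(p$res_b),
                 p$type, p$fraction))
  correlations <- lapply(config$correlations %||% list(), function(p)
    correlation_plan(parse_res_string(p$res_a), parse_res_string(p$res_b),
                     p$rho))
  torsions <- lapply(config$torsions %||% list(), function(p)
    torsion_plan(parse_res_string(p$res), p$phi, p$psi, p$jitter_sd %||% 0))
  gen <- generate_trajectory(spec, n_frames, schedules = schedules,
                             ions = ions, contacts = contacts,
                             correlations = correlations, torsions = torsions)
  write_multimodel_pdb(gen$trajectory, file.path(out_dir, "topology.pdb"),
                       frames = 0L)
  write_dcd(gen$trajectory, file.path(out_dir, "traj.dcd"))
  write_json_summary(gen$manifest, file.path(out_dir, "manifest.json"))
  invisible(gen$manifest)
}
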