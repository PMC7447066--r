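## End-to-end pipeline per condition code: generates (or loads) replicate
## trajectories, runs every analysis stage, and emits the table/figure data
## as CSV plus a JSON manifest.

#' Default analysis configuration
#'
#' All cutoffs, spans and options the pipeline consults, overridable via a
#' YAML config file ([read_config()]) or per-call arguments.
#'
#' @return Named list of defaults.
#' @export
psi_config <- function() {
  list(window_fraction = 0.10,   # tail fraction analysed
       bin_width = 0.01,         # nm, S-gamma histograms
       reform_cutoff = 0.40,     # nm, disulfide reformability
       reform_verdict_threshold = 0.5,
       hb_dist = 0.35,           # nm
       hb_angle = 30,            # degrees
       contact_cutoff = 0.45,    # nm, hydrophobic + salt bridge
       cation_pi_cutoff = 0.60,  # nm
       loop_span = c(40L, 63L),
       hydrophobic_set = HYDROPHOBIC_DEFAULT,
       protonation_overrides = NULL,
       ss_window_fraction = 1.0) # SS series is already the analysis window
}

#' Read a key-value (YAML) analysis config
#'
#' Unknown keys are rejected; given keys override [psi_config()] defaults.
#'
#' @param path YAML file.
#' @return Full config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- psi_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    abort("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, user)
}

#' Run the full analysis pipeline for one condition
#'
#' For a condition (pH, disulfide code), generates `n_replicates` synthetic
#' replicate trajectories and secondary-structure series under the
#' condition's S-gamma distance laws (or loads ensembles from
#' `manifest$inputs`), runs every analysis stage over the tail window, and
#' writes the report bundle to `manifest$outdir`:
#' `sg-histograms.csv`, `rmsf.csv`, `structure-summary.csv`,
#' `variation.csv`, `mode.csv`, `contacts.csv`, `loop-contacts.csv`,
#' `com-separations.csv`, plus `sg-verdicts.json` and `manifest.json`
#' (condition, seed, config and version echo).
#'
#' @param manifest List with elements `ph`, `code`, `n_replicates`
#'   (default 3), `outdir`, `seed`, and optionally `inputs` (list of paths
#'   per replicate, each readable by [read_ensemble()]), `spec` (a
#'   `psi_synthetic_spec` template) and `config` (overrides of
#'   [psi_config()]).
#' @return Invisibly, a list with every stage's results.
#' @export
run_pipeline <- function(manifest) {
  ph <- manifest$ph %||% abort("manifest needs a pH")
  code <- manifest$code %||% abort("manifest needs a condition code")
  resolve_condition(code)  # validates
  n_rep <- manifest$n_replicates %||% 3L
  if (n_rep < 1L) abort("manifest needs at least one replicate")
  cfg <- utils::modifyList(psi_config(), manifest$config %||% list())
  outdir <- manifest$outdir %||% abort("manifest needs an output directory")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- manifest$seed %||% 1L

  ## --- assemble replicates -----------------------------------------------
  trajs <- list(); sss <- list()
  if (!is.null(manifest$inputs)) {
    for (r in seq_along(manifest$inputs))
      trajs[[r]] <- read_ensemble(manifest$inputs[[r]])
    n_rep <- length(trajs)
  } else {
    template <- manifest$spec %||% synthetic_spec()
    for (r in seq_len(n_rep)) {
      sp <- template
      sp$seed <- as.integer(seed + 1009L * r)
      sp$sg_laws <- condition_sg_laws(code, ph)
      trajs[[r]] <- make_trajectory(sp)
      sss[[r]] <- make_ss_series(sp)
    }
  }
  top <- trajs[[1]]$topology
  prot <- assign_protonation(top, ph, cfg$protonation_overrides)

  ## --- S-gamma distances --------------------------------------------------
  dist_native <- do.call(rbind, lapply(seq_len(n_rep), function(r)
    sg_distances(trajs[[r]], window = cfg$window_fraction, replicate = r)))
  dist_nonnat <- do.call(rbind, lapply(seq_len(n_rep), function(r)
    interchange_distances(trajs[[r]], window = cfg$window_fraction,
                          replicate = r)))
  hist_all <- pooled_histogram(rbind(dist_native, dist_nonnat),
                               bin_width = cfg$bin_width)
  verdicts <- reformability(rbind(dist_native, dist_nonnat),
                            cutoff = cfg$reform_cutoff,
                            verdict_threshold = cfg$reform_verdict_threshold)
  utils::write.csv(hist_all, file.path(outdir, "sg-histograms.csv"),
                   row.names = FALSE)
  jsonlite::write_json(verdicts, file.path(outdir, "sg-verdicts.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  ## --- structure metrics ---------------------------------------------------
  wtrajs <- lapply(trajs, select_window, fraction = cfg$window_fraction)
  rmsd_wl <- lapply(wtrajs, rmsd_series, measure = "backbone")
  rmsd_nl <- lapply(wtrajs, rmsd_series, measure = "backbone_noloop")
  rg_wl <- lapply(wtrajs, radius_of_gyration, selection = "all")
  rg_nl <- lapply(wtrajs, radius_of_gyration, selection = "all_noloop")
  summ <- function(lst, metric, variant) {
    s <- summarize_replicates(lst)
    data.frame(metric = metric, variant = variant, mean = s$mean,
               sem = s$sem, n = s$n, stringsAsFactors = FALSE)
  }
  structure_summary <- rbind(
    summ(rmsd_wl, "rmsd", "with-loop"), summ(rmsd_nl, "rmsd", "no-loop"),
    summ(rg_wl, "rg", "with-loop"), summ(rg_nl, "rg", "no-loop"))
  utils::write.csv(structure_summary,
                   file.path(outdir, "structure-summary.csv"),
                   row.names = FALSE)

  rmsf_raw <- lapply(wtrajs, rmsf_profile, mode = "raw")
  rmsf_pc1 <- lapply(wtrajs, rmsf_profile, mode = "pc1")
  rmsf_tab <- rbind(cbind(mode = "raw", pool_residue_profiles(rmsf_raw)),
                    cbind(mode = "pc1", pool_residue_profiles(rmsf_pc1)))
  utils::write.csv(rmsf_tab, file.path(outdir, "rmsf.csv"), row.names = FALSE)

  com_rows <- list()
  for (variant in c("with-loop", "no-loop")) {
    excl <- variant == "no-loop"
    per_rep <- lapply(wtrajs, function(tr) {
      com_separation(tr,
                     atom_indices(tr$topology, chain = "A", exclude_loop = excl),
                     atom_indices(tr$topology, chain = "B", exclude_loop = excl))
    })
    com_rows[[variant]] <- summ(per_rep, "com_monomer", variant)
  }
  for (h in names(top$helix_spans)) {
    span <- seq.int(top$helix_spans[[h]][1], top$helix_spans[[h]][2])
    per_rep <- lapply(wtrajs, function(tr) {
      com_separation(tr,
                     atom_indices(tr$topology, chain = "A", residues = span),
                     atom_indices(tr$topology, chain = "B", residues = span))
    })
    com_rows[[h]] <- summ(per_rep, paste0("com_", h), "inter-monomer")
  }
  utils::write.csv(do.call(rbind, com_rows),
                   file.path(outdir, "com-separations.csv"), row.names = FALSE)

  ## --- secondary-structure variation ---------------------------------------
  variation <- mode_tab <- net_var <- NULL
  if (length(sss)) {
    variation <- variation_index(sss, window = cfg$ss_window_fraction)
    utils::write.csv(variation$summary, file.path(outdir, "variation.csv"),
                     row.names = FALSE)
    mode_tab <- ss_mode(sss, window = cfg$ss_window_fraction)
    utils::write.csv(mode_tab, file.path(outdir, "mode.csv"),
                     row.names = FALSE)
    net_var <- dimer_net_variation(variation)
  }

  ## --- contacts -------------------------------------------------------------
  censuses <- lapply(seq_len(n_rep), function(r)
    contact_census(trajs[[r]], prot, window = cfg$window_fraction,
                   hb_dist = cfg$hb_dist, hb_angle = cfg$hb_angle,
                   contact_cutoff = cfg$contact_cutoff, replicate = r))
  contact_summary <- summarize_contacts(censuses)
  main <- contact_summary[contact_summary$category %in% c("intra", "inter"), ]
  loops <- contact_summary[contact_summary$category %in%
                             c("intra_loop", "loop_nonloop"), ]
  utils::write.csv(main, file.path(outdir, "contacts.csv"), row.names = FALSE)
  utils::write.csv(loops, file.path(outdir, "loop-contacts.csv"),
                   row.names = FALSE)
  catpi <- cation_pi_screen(frame_xyz(wtrajs[[1]], n_frames(wtrajs[[1]])),
                            top, prot, cutoff = cfg$cation_pi_cutoff)

  manifest_out <- list(
    condition = list(ph = ph, code = code),
    n_replicates = n_rep, seed = seed,
    window_fraction = cfg$window_fraction,
    config = cfg[setdiff(names(cfg), "hydrophobic_set")],
    reform_verdicts = verdicts,
    net_variation = net_var,
    cation_pi_candidates = nrow(catpi),
    package_version = as.character(utils::packageVersion("psitraj")))
  jsonlite::write_json(manifest_out, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")

  invisible(list(trajectories = trajs, ss_series = sss,
                 sg_histograms = hist_all, sg_verdicts = verdicts,
                 structure_summary = structure_summary, rmsf = rmsf_tab,
                 com = do.call(rbind, com_rows),
                 variation = variation, mode = mode_tab,
                 net_variation = net_var,
                 contacts = contact_summary, censuses = censuses,
                 cation_pi = catpi, protonation = prot,
                 manifest = manifest_out))
}
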