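# End-to-end pipeline driver: one entry point with subcommands
# {simulate, coevolve, modes, localflucts, pull, pocket}, YAML configs
# validated fail-fast (unknown keys abort before any computation),
# versioned outputs and a JSON run manifest listing every output file
# with an md5 checksum.  Rerunning a subcommand with the same config and
# seed produces byte-identical numeric outputs.

validate_keys <- function(cfg, allowed, where) {
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown key(s) in %s config: %s", where,
                  paste(unknown, collapse = ", ")))
  }
  invisible(cfg)
}

positive_or_abort <- function(cfg, keys, where) {
  for (k in intersect(keys, names(cfg))) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      abort(sprintf("`%s` in %s config must be a positive number.", k, where))
    }
  }
  invisible(cfg)
}

#' Run one pipeline subcommand end-to-end
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Top-level keys: `subcommand` (one of `simulate`, `coevolve`,
#'   `modes`, `localflucts`, `pull`, `pocket`), `seed`, `out_dir`, and a
#'   block named after the subcommand holding its parameters.  Unknown
#'   keys abort before any computation.
#' @param seed overrides the config seed.
#' @param out_dir overrides the config output directory.
#' @return invisibly, the manifest list (also written as
#'   `run_manifest.json` in `out_dir`); output files are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_keys(config,
                c("subcommand", "seed", "out_dir", "simulate", "coevolve",
                  "modes", "localflucts", "pull", "pocket"),
                "top-level")
  sub <- config$subcommand %||% abort("Config needs a `subcommand` key.")
  if (!sub %in% c("simulate", "coevolve", "modes", "localflucts", "pull",
                  "pocket")) {
    abort(sprintf("Unknown subcommand '%s'.", sub))
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% abort("Config needs `out_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config[[sub]] %||% list()
  outputs <- switch(sub,
    simulate = pipeline_simulate(cfg, seed, out_dir),
    coevolve = pipeline_coevolve(cfg, seed, out_dir),
    modes = pipeline_modes(cfg, seed, out_dir),
    localflucts = pipeline_localflucts(cfg, seed, out_dir),
    pull = pipeline_pull(cfg, seed, out_dir),
    pocket = pipeline_pocket(cfg, seed, out_dir))
  manifest <- list(
    subcommand = sub, seed = seed,
    parameters = cfg,
    inputs = outputs$inputs %||% list(),
    outputs = purrr::map(outputs$files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- paste0("c", seq_len(ncol(df)))
  readr::write_csv(df, path)
  path
}

pipeline_simulate <- function(cfg, seed, out_dir) {
  validate_keys(cfg, c("msa", "ensemble", "pull"), "simulate")
  files <- character()
  if (!is.null(cfg$msa)) {
    m <- cfg$msa
    validate_keys(m, c("n_sequences", "length", "gap_fraction"),
                  "simulate.msa")
    positive_or_abort(m, c("n_sequences", "length"), "simulate.msa")
    msa <- generate_msa(msa_spec(n_sequences = m$n_sequences %||% 200,
                                 length = m$length %||% 30,
                                 gap_fraction = m$gap_fraction %||% 0,
                                 seed = seed))
    files <- c(files, write_msa(msa, file.path(out_dir, "msa.fasta")))
  }
  if (!is.null(cfg$ensemble)) {
    e <- cfg$ensemble
    validate_keys(e, c("n_frames", "n_atoms", "variances", "isotropic_noise"),
                  "simulate.ensemble")
    positive_or_abort(e, c("n_frames", "n_atoms", "isotropic_noise"),
                      "simulate.ensemble")
    n_atoms <- e$n_atoms %||% 20
    variances <- as.numeric(e$variances %||% c(9, 4, 1))
    mean_c <- helix_mean_coords(n_atoms)
    dirs <- with_seed(seed + 1L,
                      orthonormal_modes(mean_c, length(variances)))
    ens <- generate_ensemble(ensemble_spec(
      n_frames = e$n_frames %||% 1000, n_atoms = n_atoms,
      mean_coords = mean_c,
      planted_modes = list(directions = dirs, variances = variances),
      isotropic_noise = e$isotropic_noise %||% 0.1, seed = seed))
    files <- c(files,
               write_coord_table(ens, file.path(out_dir, "ensemble.csv")),
               write_pdb_ensemble(ens, file.path(out_dir, "ensemble.pdb")))
  }
  if (!is.null(cfg$pull)) {
    p <- cfg$pull
    validate_keys(p, c("k_well", "x0", "spring_k", "velocity", "temperature",
                       "friction", "dt", "start_anchor", "end_anchor",
                       "n_replicas", "stride"), "simulate.pull")
    positive_or_abort(p, c("k_well", "spring_k", "velocity", "temperature",
                           "friction", "dt", "n_replicas", "stride"),
                      "simulate.pull")
    spec <- pull_spec(
      potential = pull_potential("harmonic", k_well = p$k_well %||% 2,
                                 x0 = p$x0 %||% 0),
      spring_k = p$spring_k %||% 10, velocity = p$velocity %||% 0.05,
      temperature = p$temperature %||% 300, friction = p$friction %||% 1,
      dt = p$dt %||% 0.005, start_anchor = p$start_anchor %||% 0,
      end_anchor = p$end_anchor %||% 5,
      n_replicas = p$n_replicas %||% 20, stride = p$stride %||% 10,
      seed = seed)
    pe <- simulate_pull(spec)
    files <- c(files, write_pulling_csv(pe, file.path(out_dir, "pulling.csv")))
  }
  if (length(files) == 0L) {
    abort("simulate config must request at least one of msa/ensemble/pull.")
  }
  list(files = files)
}

pipeline_coevolve <- function(cfg, seed, out_dir) {
  validate_keys(cfg, c("msa", "structure", "n_permutations", "pseudocount",
                       "z_threshold", "contact_cutoff"), "coevolve")
  positive_or_abort(cfg, c("n_permutations", "z_threshold", "contact_cutoff"),
                    "coevolve")
  msa <- read_msa(cfg$msa %||% abort("coevolve config needs `msa`."))
  zt <- cfg$z_threshold %||% 6.5
  pc <- cfg$pseudocount %||% 0.5
  freqs <- column_frequencies(msa, pseudocount = pc)
  kl <- kl_conservation(freqs)
  mi <- mi_zscores(msa, n_permutations = cfg$n_permutations %||% 100,
                   seed = seed, pseudocount = pc)
  cmi <- cumulative_mi(mi, z_threshold = zt)
  readr::write_csv(kl, file.path(out_dir, "kl.csv"))
  readr::write_csv(cmi, file.path(out_dir, "cmi.csv"))
  readr::write_csv(coevolution_network(mi, z_threshold = zt),
                   file.path(out_dir, "edges.csv"))
  files <- c(
    file.path(out_dir, c("kl.csv", "cmi.csv", "edges.csv")),
    write_matrix_csv(mi$raw_mi, file.path(out_dir, "raw_mi.csv")),
    write_matrix_csv(mi$apc_mi, file.path(out_dir, "apc_mi.csv")),
    write_matrix_csv(mi$z, file.path(out_dir, "z.csv")))
  if (!is.null(cfg$structure)) {
    st <- read_structure(cfg$structure)
    dm <- residue_distance_map(st)
    L <- msa_length(msa)
    if (nrow(dm) < L) {
      dm2 <- matrix(NA_real_, L, L)
      dm2[seq_len(nrow(dm)), seq_len(ncol(dm))] <- dm
      dm <- dm2
    } else if (nrow(dm) > L) {
      dm <- dm[seq_len(L), seq_len(L)]
    }
    pmi <- proximity_mi(cmi, dm, cutoff = cfg$contact_cutoff %||% 5.0)
    readr::write_csv(pmi, file.path(out_dir, "pmi.csv"))
    files <- c(files, file.path(out_dir, "pmi.csv"))
  }
  list(files = files, inputs = cfg[intersect(c("msa", "structure"),
                                             names(cfg))])
}

read_any_ensemble <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    as_coord_ensemble(read_structure(path))
  } else {
    read_coord_table(path)
  }
}

pipeline_modes <- function(cfg, seed, out_dir) {
  validate_keys(cfg, c("ensemble", "ensemble_b", "n_modes", "k"), "modes")
  positive_or_abort(cfg, c("n_modes", "k"), "modes")
  ens <- read_any_ensemble(cfg$ensemble %||% abort("modes config needs `ensemble`."))
  ens <- superpose(ens, backbone_selection(ens))
  modes <- covariance_modes(ens, n_modes = cfg$n_modes %||% 10)
  readr::write_csv(tidy(modes), file.path(out_dir, "modes.csv"))
  fl <- mode_fluctuations(modes, 1)
  readr::write_csv(fl, file.path(out_dir, "pc1_fluctuations.csv"))
  files <- file.path(out_dir, c("modes.csv", "pc1_fluctuations.csv"))
  if (!is.null(cfg$ensemble_b)) {
    ensb <- read_any_ensemble(cfg$ensemble_b)
    ensb <- superpose(ensb, backbone_selection(ensb))
    modes_b <- covariance_modes(ensb, n_modes = cfg$n_modes %||% 10)
    ov <- mode_overlap(modes, modes_b, k = cfg$k %||% 10)
    jsonlite::write_json(
      list(k = ov$k, rmsip = ov$rmsip,
           covariance_overlap = ov$covariance_overlap,
           variance_capture = ov$variance_capture),
      file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "overlap.json"))
  }
  list(files = files,
       inputs = cfg[intersect(c("ensemble", "ensemble_b"), names(cfg))])
}

pipeline_localflucts <- function(cfg, seed, out_dir) {
  validate_keys(cfg, c("ensemble", "windows"), "localflucts")
  ens <- read_any_ensemble(cfg$ensemble %||%
                             abort("localflucts config needs `ensemble`."))
  wins <- cfg$windows %||% abort("localflucts config needs `windows`.")
  prof <- purrr::imap(wins, function(w, nm) {
    if (length(w) != 2L) abort("Each window must be [first_resno, last_resno].")
    dplyr::mutate(local_fluctuations(ens, seq(w[[1]], w[[2]])),
                  window = nm, .before = 1)
  }) |> purrr::list_rbind()
  readr::write_csv(prof, file.path(out_dir, "localflucts.csv"))
  list(files = file.path(out_dir, "localflucts.csv"),
       inputs = cfg["ensemble"])
}

pipeline_pull <- function(cfg, seed, out_dir) {
  validate_keys(cfg, c("pulling", "temperature", "smooth_window",
                       "n_rupture"), "pull")
  positive_or_abort(cfg, c("temperature", "smooth_window", "n_rupture"),
                    "pull")
  ens <- read_pulling_csv(cfg$pulling %||% abort("pull config needs `pulling`."),
                          temperature = cfg$temperature %||% 300)
  if (!"work" %in% names(ens)) {
    ens <- new_pulling_ensemble(accumulate_work(ens), attr(ens, "temperature"))
  }
  pmf <- jarzynski_pmf(ens)
  readr::write_csv(as_tibble(pmf), file.path(out_dir, "work_pmf.csv"))
  rp <- detect_rupture(ens, n_points = cfg$n_rupture %||% 2,
                       smooth_window = cfg$smooth_window %||% 5)
  jsonlite::write_json(rp, file.path(out_dir, "rupture.json"),
                       dataframe = "rows", digits = NA)
  list(files = file.path(out_dir, c("work_pmf.csv", "rupture.json")),
       inputs = cfg["pulling"])
}

pipeline_pocket <- function(cfg, seed, out_dir) {
  validate_keys(cfg, c("structure", "ensemble", "ligand_resid", "inclusion",
                       "grid_spacing", "padding"), "pocket")
  positive_or_abort(cfg, c("grid_spacing", "padding"), "pocket")
  gs <- cfg$grid_spacing %||% 1.0
  if (!is.null(cfg$structure) && !is.null(cfg$ligand_resid)) {
    scene <- pocket_from_structure(read_structure(cfg$structure),
                                   ligand_resid = cfg$ligand_resid,
                                   grid_spacing = gs)
  } else if (!is.null(cfg$inclusion)) {
    inc <- purrr::map_dfr(cfg$inclusion, function(s) {
      tibble(x = s[[1]], y = s[[2]], z = s[[3]], radius = s[[4]])
    })
    atoms <- NULL
    if (!is.null(cfg$structure)) {
      st <- read_structure(cfg$structure)
      atoms <- st$atoms[, c("x", "y", "z", "element")]
    }
    scene <- pocket_scene(atoms = atoms, inclusion = inc, grid_spacing = gs,
                          padding = cfg$padding %||% 0)
  } else {
    abort("pocket config needs `inclusion` or `structure` + `ligand_resid`.")
  }
  if (!is.null(cfg$ensemble)) {
    ens <- read_any_ensemble(cfg$ensemble)
    vr <- volume_series(scene, ens)
    readr::write_csv(vr$series, file.path(out_dir, "volumes.csv"))
    jsonlite::write_json(vr$summary, file.path(out_dir, "volume_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- file.path(out_dir, c("volumes.csv", "volume_summary.json"))
  } else {
    vr <- measure_volume(scene)
    jsonlite::write_json(
      list(volume = vr$volume, n_points_kept = vr$n_points_kept,
           n_points_total = vr$n_points_total, grid_spacing = gs),
      file.path(out_dir, "volume_summary.json"), auto_unbox = TRUE,
      digits = NA)
    files <- file.path(out_dir, "volume_summary.json")
  }
  list(files = files,
       inputs = cfg[intersect(c("structure", "ensemble"), names(cfg))])
}
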