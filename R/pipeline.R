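# One configured entry point running the stage sequence
# maps -> restraints -> bd -> cluster -> score -> rescore, with a manifest
# sufficient to reproduce any stage bit-identically.

CONFIG_SCHEMA <- list(
  seed = "integer RNG seed; every stage derives its stream from it",
  output_dir = "optional directory for stage artifacts",
  stages = "subset of maps, restraints, bd, cluster, score, rescore",
  stationary = list(
    kind = "toy_barrel or pqr",
    path = "PQR path when kind = pqr", params = "sidecar parameter table path",
    radius = "barrel radius (A)", height = "barrel height (A)",
    rim_frac = "height fraction of the charged rim ring",
    n_per_ring = "atoms per ring", ring_spacing = "ring spacing (A)",
    rim_charge = "per-atom rim charge (e)", site_charge = "per-atom site charge (e)",
    site_angle_deg = "azimuth of the site arc", site_halfwidth_deg = "site arc half-width",
    site_resid = "residue id of the mutable site"),
  mobile = list(
    kind = "anchor_probe or pqr",
    path = "PQR path when kind = pqr", params = "sidecar parameter table path",
    n_atoms = "probe length", pitch = "axial rise per atom (A)",
    helix_radius = "helix radius (A)", head_charge = "head charge (e)"),
  maps = list(
    spacing = "grid spacing, 1 A",
    cutoff = "force cutoff, 34 A",
    cap = "LJ/electrostatic clamp, kcal/mol",
    solvent_dielectric = "solvent dielectric, 78",
    ionic_strength = "molar ionic strength for Debye screening",
    lj_scale = "LJ well-depth scale, 0.3",
    elec_dx = "optional imported DX electrostatic map"),
  restraints = list(
    temperature = "K, 310", k = "anchor well curvature kcal/mol/A^2",
    n_samples = "z samples per anchor", bin_width = "histogram bin, 0.5 A",
    wall_radius = "confinement wall radius, 150 A",
    wall_stiffness = "wall force constant kcal/mol/A^2"),
  bd = list(
    timestep_fs = "200 fs", duration_ns = "per-replica length",
    output_stride_ns = "0.2 ns", n_replicas = "independent replicas",
    start_radius = "initial lateral distance (A)", temperature = "K, 310",
    d_trans = "A^2/ns", d_rot = "rad^2/ns",
    stokes_radius = "A; used with viscosity when d_trans absent",
    viscosity = "mPa s"),
  analysis = list(
    contact_cutoff = "3 A", rmsd_cutoff = "10 A",
    energy_cutoff = "12 A", eps_r = "scoring dielectric"),
  rescore = list(
    site_resid = "stationary residue to perturb",
    modified_charges = "replacement charges for the site atoms"))

check_keys <- function(cfg, schema, path = "") {
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad) > 0)
    abort(paste0("unknown config key", if (length(bad) > 1) "s", ": ",
                 paste0(path, bad, collapse = ", ")))
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && is.list(cfg[[k]]))
      check_keys(cfg[[k]], schema[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' Checks every key against the published schema (see
#' [pipeline_config_schema()]); unknown keys raise an error.
#'
#' @param config Named list, or path to a YAML file.
#' @return The config as a list, invisibly extended with defaults.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, CONFIG_SCHEMA)
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||%
    c("maps", "restraints", "bd", "cluster", "score", "rescore")
  config
}

#' The pipeline configuration schema
#'
#' @return Nested named list whose leaves describe each key, its unit and
#'   default.
#' @export
pipeline_config_schema <- function() CONFIG_SCHEMA

build_body <- function(spec, default_kind) {
  kind <- spec$kind %||% default_kind
  if (kind == "pqr") {
    params <- if (!is.null(spec$params)) read_param_table(spec$params)
    return(read_pqr(spec$path, params))
  }
  spec$kind <- NULL; spec$path <- NULL; spec$params <- NULL
  if (kind == "toy_barrel") do.call(make_toy_barrel, spec)
  else if (kind == "anchor_probe") do.call(make_anchor_probe, spec)
  else abort(paste0("unknown body kind '", kind, "'"))
}

#' Run the configured association pipeline
#'
#' Executes the requested stages in order (maps, restraints, bd, cluster,
#' score, rescore), each seeded deterministically from the config seed;
#' reruns with the same config give identical artifacts. A stage that needs
#' a missing upstream artifact names the stage to run first.
#'
#' @param config Named list or YAML path; see [pipeline_config_schema()].
#' @return A list with the stage artifacts (`stationary`, `mobile`, `maps`,
#'   `density`, `restraints`, `trajectory`, `contacts`, `clusters`,
#'   `energies`, `hotspot`, `rescoring`) and a `manifest` tibble with
#'   per-stage timing and content hashes.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  art <- list(config = cfg)
  manifest <- tibble(stage = character(), elapsed_s = numeric(),
                     hash = character())
  note <- function(stage, t0, obj) {
    manifest <<- bind_rows(manifest, tibble(
      stage = stage, elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
      hash = rlang::hash(obj)))
  }
  need <- function(what, stage) {
    if (is.null(art[[what]]))
      abort(paste0("missing upstream artifact '", what,
                   "': run stage '", stage, "' first"))
    art[[what]]
  }

  art$stationary <- build_body(cfg$stationary %||% list(), "toy_barrel")
  art$mobile <- build_body(cfg$mobile %||% list(), "anchor_probe")
  anchors_tbl <- attr(art$mobile, "anchors")

  for (stage in cfg$stages) {
    t0 <- as.numeric(Sys.time())
    if (stage == "maps") {
      m <- cfg$maps %||% list()
      elec <- if (!is.null(m$elec_dx)) read_dx(m$elec_dx)
      frame <- grid_frame(art$stationary, margin = (m$cutoff %||% 34) / 2,
                          spacing = m$spacing %||% 1)
      art$maps <- build_map_set(
        art$stationary, frame = frame, elec_map = elec,
        cutoff = m$cutoff %||% 34, cap = m$cap %||% 30,
        solvent_dielectric = m$solvent_dielectric %||% 78,
        ionic_strength = m$ionic_strength %||% 0,
        lj_scale = m$lj_scale %||% 0.3)
      art$density <- build_density_set(art$mobile, spacing = m$spacing %||% 1)
      note(stage, t0, art$maps$elec$values)
    } else if (stage == "restraints") {
      r <- cfg$restraints %||% list()
      set.seed(cfg$seed + 1L)
      C <- coords_matrix(art$mobile)
      pots <- lapply(seq_len(nrow(anchors_tbl)), function(i) {
        z0 <- mean(C[art$mobile$resid == anchors_tbl$resid[i], 3])
        z <- sample_anchored_z(r$k %||% 0.616, z0, r$n_samples %||% 2e4,
                               r$temperature %||% 310,
                               seed = cfg$seed + 100L + i)
        boltzmann_invert(z, r$temperature %||% 310,
                         bin_width = r$bin_width %||% 0.5,
                         label = anchors_tbl$label[i])
      })
      names(pots) <- anchors_tbl$label
      art$restraints <- restraint_set(
        pots, wall_radius = r$wall_radius %||% 150,
        wall_stiffness = r$wall_stiffness %||% 10)
      note(stage, t0, lapply(pots, function(p) p$U))
    } else if (stage == "bd") {
      b <- cfg$bd %||% list()
      maps <- need("maps", "maps"); density <- need("density", "maps")
      model <- if (!is.null(b$d_trans)) {
        diffusion_model(b$d_trans, b$d_rot, b$temperature %||% 310)
      } else {
        stokes_diffusion(b$stokes_radius %||% 15, b$viscosity %||% 0.6913,
                         b$temperature %||% 310)
      }
      params <- bd_params(
        timestep_fs = b$timestep_fs %||% 200,
        duration_ns = b$duration_ns %||% 10,
        output_stride_ns = b$output_stride_ns %||% 0.2,
        temperature = b$temperature %||% 310, seed = cfg$seed + 2L)
      nrep <- b$n_replicas %||% 5
      r0 <- b$start_radius %||% 40
      theta <- 2 * pi * (seq_len(nrep) - 1) / nrep
      com <- density$com
      init <- cbind(r0 * cos(theta), r0 * sin(theta), com[3],
                    1, 0, 0, 0)
      anch <- NULL
      if (!is.null(art$restraints)) {
        C <- coords_matrix(art$mobile)
        anch <- bind_rows(lapply(seq_len(nrow(anchors_tbl)), function(i) {
          p <- colMeans(C[art$mobile$resid == anchors_tbl$resid[i], ,
                          drop = FALSE])
          tibble(label = anchors_tbl$label[i], x = p[1], y = p[2], z = p[3])
        }))
      }
      art$trajectory <- run_bd(density, maps, model, params, init,
                               restraints = art$restraints, anchors = anch)
      note(stage, t0, poses_matrix(art$trajectory))
    } else if (stage == "cluster") {
      a <- cfg$analysis %||% list()
      traj <- need("trajectory", "bd")
      art$contacts <- contact_frames(traj, art$mobile, art$stationary,
                                     cutoff = a$contact_cutoff %||% 3)
      art$energies <- trajectory_energies(
        traj, art$mobile, art$stationary, art$contacts,
        eps_r = a$eps_r %||% 1, cutoff = a$energy_cutoff %||% 12)
      art$clusters <- cluster_poses(
        traj, art$mobile, rmsd_cutoff = a$rmsd_cutoff %||% 10,
        frames = art$contacts, energies = art$energies)
      note(stage, t0, tidy(art$clusters))
    } else if (stage == "score") {
      traj <- need("trajectory", "bd")
      sel <- which(art$mobile$resid %in% anchors_tbl$resid)
      art$hotspot <- hotspot_density(traj, art$mobile, sel)
      note(stage, t0, art$hotspot$density)
    } else if (stage == "rescore") {
      rs <- cfg$rescore
      if (!is.null(rs)) {
        clusters <- need("clusters", "cluster")
        a <- cfg$analysis %||% list()
        art$rescoring <- phospho_rescore(
          need("trajectory", "bd"), art$mobile, art$stationary, clusters,
          site_resid = rs$site_resid %||% attr(art$stationary, "site_resid"),
          modified_charges = rs$modified_charges,
          eps_r = a$eps_r %||% 1, cutoff = a$energy_cutoff %||% 12)
        note(stage, t0, art$rescoring)
      }
    } else {
      abort(paste0("unknown stage '", stage, "'"))
    }
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(art$trajectory))
      write_trajectory(art$trajectory, file.path(cfg$output_dir, "trajectory.txt"))
    if (!is.null(art$maps))
      write_dx(art$maps$elec, file.path(cfg$output_dir, "elec.dx"))
    if (!is.null(art$restraints))
      for (lab in names(art$restraints$potentials))
        write_z_potential(art$restraints$potentials[[lab]],
                          file.path(cfg$output_dir, paste0("restraint_", lab, ".txt")))
    yaml::write_yaml(list(config = cfg,
                          manifest = lapply(seq_len(nrow(manifest)), function(i)
                            as.list(manifest[i, ]))),
                     file.path(cfg$output_dir, "manifest.yaml"))
  }
  art$manifest <- manifest
  art
}
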