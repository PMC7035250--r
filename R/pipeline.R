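## End-to-end orchestration: a single run configuration whose defaults
## are the study parameters (hill height 2.48 kJ/mol, pace 1 ps, bias
## factor 20, Gaussian widths 0.2/0.5, lower walls at Hb_core = 5 and
## pipi_core = 8, kT = 2.494), plus the generate / simulate / reweight
## / classify / analyze entry points.  Every command writes a manifest
## (config hash + seed) so reruns are reproducible.

#' Run configuration
#'
#' @param seed master RNG seed.
#' @param w0,pace,gamma,sigma,kT well-tempered metadynamics parameters.
#' @param wall_hb,wall_pipi lower-wall thresholds on the two biased
#'   CVs.
#' @param t_high,t_slip,t_low,t_margin classification flow thresholds.
#' @param n_blocks block count for basin uncertainties.
#' @param n_steps,dt,friction,out_stride Langevin engine settings.
#' @param noise_sd transition-trajectory coordinate noise, Angstrom.
#' @param frames_per_segment frames per transition leg.
#' @return list of class \code{g4RunConfig}.
#' @export
g4RunConfig <- function(seed = 1, w0 = 2.48, pace = 1, gamma = 20,
                        sigma = c(0.2, 0.5), kT = 2.494,
                        wall_hb = 5, wall_pipi = 8,
                        t_high = 0.80, t_slip = 0.70, t_low = 0.40, t_margin = 0.05,
                        n_blocks = 5, n_steps = 2e6, dt = 0.002,
                        friction = 1, out_stride = 10, noise_sd = 0.3,
                        frames_per_segment = 100) {
  structure(as.list(environment()), class = "g4RunConfig")
}

## tiny FNV-1a over the serialised config; enough to detect manifest
## drift between reruns
.config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_manifest <- function(config, outdir, command, extra = list()) {
  man <- c(list(command = command, config_hash = .config_hash(config),
                seed = config$seed,
                config = unclass(config)), extra)
  path <- file.path(outdir, paste0(command, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate the synthetic fixture set
#'
#' Writes the ideal native structure, every enumerated slipped
#' topology (open-triad variants with cations; the closed-triad
#' variant for the 2d code), a noisy native-to-4d transition
#' trajectory, and a manifest.  Deterministic for a given seed.
#'
#' @param config a [g4RunConfig()] list.
#' @param outdir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
runGenerate <- function(config = g4RunConfig(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory ", outdir, call. = FALSE)
  paths <- list()
  native <- buildIdealG4("native")
  paths$native <- file.path(outdir, "native.pdb")
  writeStructure(native, paths$native)
  codes <- c("2d", "3d", "3u", "4d", "24d", "34d")
  for (cd in codes) {
    form <- if (cd == "2d") "closed" else "open"
    s <- buildIdealG4(cd, triad_form = form, waters = (cd == "4d"))
    paths[[cd]] <- file.path(outdir, paste0(cd, ".pdb"))
    writeStructure(s, paths[[cd]])
  }
  traj <- transitionTrajectory(list("native", "4d"),
                               frames_per_segment = config$frames_per_segment,
                               noise_sd = config$noise_sd,
                               seed = config$seed)
  paths$transition <- file.path(outdir, "transition_native_4d.pdb")
  writeTrajectory(traj, paths$transition)
  .write_manifest(config, outdir, "generate",
                  list(files = vapply(paths, basename, "")))
  invisible(paths)
}

#' Run the well-tempered metadynamics sampler on a model potential
#'
#' Writes COLVAR and HILLS files in the documented dialects plus a
#' manifest.  Wall restraints are applied only when thresholds fall
#' inside the sampling grid of the chosen potential (the G4 walls at
#' 5/8 live on the molecular CV scale, not on the model-potential
#' coordinates).
#'
#' @param config a [g4RunConfig()] list.
#' @param outdir output directory.
#' @param potential id accepted by [makeModelPotential()] or a
#'   [ModelPotential-class].
#' @param grid sampling grid per CV, list of c(min, max, n).
#' @param s0 start point.
#' @param walls list of [WallRestraint-class] (default none).
#' @return list with \code{colvar}, \code{bias}, and the written
#'   paths, invisibly.
#' @export
runSimulate <- function(config = g4RunConfig(), outdir,
                        potential = "double_well_1d", grid = NULL,
                        s0 = NULL, walls = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(potential)) potential <- makeModelPotential(potential)
  d <- potential@d
  p <- wtMetaDParams(w0 = config$w0, pace = config$pace,
                     gamma = config$gamma,
                     sigma = rep_len(config$sigma, d)[seq_len(d)],
                     kT = config$kT)
  if (is.null(grid))
    grid <- if (d == 1) list(c(-2.5, 2.5, 501))
            else rep(list(c(-4.5, 4.5, 181)), 2)
  if (d == 1 && identical(potential@id, "double_well_1d"))
    p@sigma <- rep(0.1, 1)
  res <- runLangevinWTMetaD(potential, p, walls = walls,
                            n_steps = config$n_steps, dt = config$dt,
                            friction = config$friction, s0 = s0,
                            grid = grid, seed = config$seed,
                            out_stride = config$out_stride)
  cpath <- file.path(outdir, "COLVAR")
  hpath <- file.path(outdir, "HILLS")
  writeColvar(res$colvar, cpath)
  writeHills(res$bias, hpath, gamma = config$gamma)
  .write_manifest(config, outdir, "simulate",
                  list(potential = potential@id,
                       n_hills = nHills(res$bias)))
  invisible(c(res, list(colvar_path = cpath, hills_path = hpath,
                        potential = potential)))
}

#' Reweight a biased run onto its CVs and report basin free energies
#'
#' Reads COLVAR/HILLS, computes the time-dependent offset c(t) and
#' frame weights, reconstructs the free-energy surface on the sampled
#' CVs, and - when basins are given - writes a basin report with
#' block-derived uncertainties.
#'
#' @param config a [g4RunConfig()] list.
#' @param colvar_path,hills_path files from [runSimulate()].
#' @param outdir output directory.
#' @param breaks list of bin-edge vectors per CV (default: 120 bins
#'   over the sampled range).
#' @param basins optional named rectangle list for [assignBasins()].
#' @param burnin fraction of early frames discarded (default 0.25).
#' @return list with \code{fes} ([FESGrid-class]), \code{weights},
#'   \code{basins} (data.frame or NULL), invisibly.
#' @export
runReweight <- function(config = g4RunConfig(), colvar_path, hills_path,
                        outdir, breaks = NULL, basins = NULL,
                        burnin = 0.25) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  colvar <- readColvar(colvar_path)
  hl <- readHills(hills_path)
  d <- hl$state@d
  p <- wtMetaDParams(w0 = config$w0, pace = config$pace,
                     gamma = config$gamma,
                     sigma = rep_len(config$sigma, d), kT = config$kT)
  cvcols <- setdiff(names(colvar), c("time", "bias"))[seq_len(d)]
  vals <- as.matrix(colvar[, cvcols, drop = FALSE])
  mids <- lapply(seq_len(d), function(i)
    seq(min(vals[, i]), max(vals[, i]), length.out = if (d == 1) 201 else 81))
  ct <- computeCt(hl$state, mids, p)
  keep <- seq(floor(burnin * nrow(colvar)) + 1, nrow(colvar))
  w <- frameWeights(colvar[keep, ], ct, p@kT)
  if (is.null(breaks))
    breaks <- lapply(seq_len(d), function(i)
      seq(min(vals[, i]), max(vals[, i]), length.out = 121))
  fes <- fesFromWeights(vals[keep, , drop = FALSE], w, breaks, p@kT,
                        cv_names = cvcols)
  ## TSV grid output
  grid_df <- do.call(expand.grid, fes@mids)
  names(grid_df) <- paste0(cvcols, "_center")
  grid_df$F_kJ_mol <- as.numeric(fes@F)
  grid_df$visited <- as.integer(fes@visited)
  write.table(grid_df, file.path(outdir, "fes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  basin_df <- NULL
  if (!is.null(basins)) {
    labels <- assignBasins(vals[keep, , drop = FALSE], basins)
    basin_df <- basinFreeEnergy(labels, w, n_blocks = config$n_blocks,
                                kT = p@kT)
    jsonlite::write_json(basin_df, file.path(outdir, "basins.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  .write_manifest(config, outdir, "reweight", list())
  invisible(list(fes = fes, weights = w, basins = basin_df, ct = ct))
}

#' Classify a trajectory into slipped topologies
#'
#' Writes a per-frame TSV report (time, label, per-topology Hoogsteen
#' fractions) and a JSON summary of label populations.
#'
#' @param config a [g4RunConfig()] list.
#' @param traj a [G4Trajectory-class] or path to a multi-model PDB.
#' @param outdir output directory.
#' @return the classification data.frame, invisibly.
#' @export
runClassify <- function(config = g4RunConfig(), traj, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(traj)) traj <- readTrajectory(traj)
  ref <- buildIdealG4("native", cations = FALSE)
  specs <- topologyCVSpecs(ref)
  ## specs are index-based: map onto the trajectory topology by
  ## (resid, name) identity
  specs <- lapply(specs, function(sp) {
    map <- function(i) {
      a <- ref@atoms[i, ]
      .atom_index(traj@topology, a$resid, a$name)
    }
    sp@pairs <- matrix(vapply(as.integer(sp@pairs), map, 0L),
                       ncol = 2)
    sp
  })
  rep <- classifyTrajectory(traj, specs, t_high = config$t_high,
                            t_slip = config$t_slip,
                            t_low = config$t_low,
                            t_margin = config$t_margin)
  write.table(rep, file.path(outdir, "classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pop <- table(rep$label)
  summary <- list(n_frames = nrow(rep),
                  populations = as.list(as.integer(pop)),
                  percentages = as.list(100 * as.numeric(pop) / nrow(rep)))
  names(summary$populations) <- names(pop)
  names(summary$percentages) <- names(pop)
  jsonlite::write_json(summary, file.path(outdir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(config, outdir, "classify", list())
  invisible(rep)
}

#' Geometric stability analyses of a trajectory
#'
#' Writes the G-core RMSD series against a reference, per-residue
#' RMSF, glycosidic chi / syn-anti labels of purine residues, and the
#' K+ to guanine-O6 contact-count series.
#'
#' @param config a [g4RunConfig()] list.
#' @param traj a [G4Trajectory-class] or multi-model PDB path.
#' @param reference a [G4Structure-class] or PDB path.
#' @param outdir output directory.
#' @param core_selection selection of the G-core atoms used for RMSD.
#' @return list of the four tables, invisibly.
#' @export
runAnalyze <- function(config = g4RunConfig(), traj, reference, outdir,
                       core_selection = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(traj)) traj <- readTrajectory(traj)
  if (is.character(reference)) reference <- readStructure(reference)
  if (is.null(core_selection)) {
    res <- sort(unlist(defaultStrandLayout()))
    core_selection <- paste("resname DG and resnum",
                            paste(res, collapse = ","),
                            "and name N9,C8,N7,C5,C6,O6,N1,C2,N2,N3,C4")
  }
  rms <- rmsdSeries(traj, reference, core_selection)
  write.table(rms, file.path(outdir, "rmsd_gcore.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  flu <- rmsf(traj, core_selection)
  write.table(flu, file.path(outdir, "rmsf.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  a <- traj@topology@atoms
  pur <- sort(unique(a$resid[a$resname %in% c("DG", "DA")]))
  s1 <- frameStructure(traj, 1)
  chi <- do.call(rbind, lapply(pur, function(r) {
    out <- tryCatch(glycosidicChi(s1, r), error = function(e) NULL)
    if (is.null(out)) return(NULL)
    data.frame(resid = r, chi = out$chi, label = out$label)
  }))
  if (!is.null(chi))
    write.table(chi, file.path(outdir, "chi.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  kidx <- which(a$resname == "K")
  o6 <- which(a$name == "O6" & a$resname == "DG")
  if (length(kidx) && length(o6)) {
    cc <- contactSeries(traj, kidx, o6, cutoff = 3.5)
    write.table(cc, file.path(outdir, "k_o6_contacts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else cc <- NULL
  .write_manifest(config, outdir, "analyze", list())
  invisible(list(rmsd = rms, rmsf = flu, chi = chi, contacts = cc))
}
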