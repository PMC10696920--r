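#' Parse and validate a run configuration
#'
#' YAML configuration for the end-to-end build. Required keys: `genome`
#' (FASTA path), `matrix` and `bed` (triplet contact matrix paths, one per
#' resolution), `resolution` (bp, scalar or list parallel to `matrix`).
#' Optional keys with defaults: `alpha` (-3), `tau` (5),
#' `outlier_threshold` (10, multiple of the median adjacent distance),
#' `seed` (42), `output_dir` ("hicbeads_out"), `tracks` (list of
#' `{path, mode, cutoff}`), `noise` (`{lambda_grid, replicates}`),
#' `log_level` ("info"). Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  cfg <- yaml::read_yaml(path)
  known <- c("genome", "matrix", "bed", "resolution", "alpha", "tau",
             "outlier_threshold", "seed", "output_dir", "tracks", "noise",
             "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown config key: ", unknown[1]))
  }
  for (key in c("genome", "matrix", "bed", "resolution")) {
    if (is.null(cfg[[key]])) abort(paste0("missing required key: ", key))
  }
  cfg$resolution <- as.numeric(unlist(cfg$resolution))
  if (any(is.na(cfg$resolution)) || any(cfg$resolution < 1)) {
    abort("resolution must be a positive number of base pairs")
  }
  cfg$matrix <- unlist(cfg$matrix)
  cfg$bed <- unlist(cfg$bed)
  if (length(cfg$matrix) != length(cfg$resolution) ||
      length(cfg$bed) != length(cfg$resolution)) {
    abort("matrix, bed and resolution must have the same length")
  }
  defaults <- list(alpha = -3, tau = 5, outlier_threshold = 10, seed = 42,
                   output_dir = "hicbeads_out", tracks = list(),
                   noise = NULL, log_level = "info")
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  }
  if (cfg$alpha >= 0) abort("alpha must be < 0")
  if (cfg$tau <= 1) abort("tau must be > 1")
  for (f in c(cfg$genome, cfg$matrix, cfg$bed,
              vapply(cfg$tracks, function(t) t$path %||% "", character(1)))) {
    if (nzchar(f) && !file.exists(f)) abort(paste0("dangling path: ", f))
  }
  for (t in cfg$tracks) {
    if (is.null(t$path)) abort("track entry needs a path")
    if (!is.null(t$mode) && !t$mode %in% c("binarize", "floor", "none")) {
      abort(paste0("unknown track mode: ", t$mode))
    }
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the end-to-end model build
#'
#' For each configured resolution: reads the contact matrix, fits the 3D
#' structure, refines and annotates it, screens for assembly inversions,
#' optionally paints omics tracks, and writes the outputs: annotated PDB
#' and G3D models, a dense matrix TSV for external heatmap rendering, the
#' inversion report (TSV), painted-track PDBs, and a JSON run manifest
#' (versions, seeds, parameters, log-likelihood) for reproducibility. Any
#' stage failure aborts with a stage-named error. Deterministic: the same
#' config and seed give byte-identical outputs.
#'
#' @param config A [parse_config()] result (or an equivalent list).
#' @return The output directory path, invisibly.
#' @export
run_build <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- build_stage("genome", load_genome(config$genome))
  manifest <- list(
    package = "hicbeads",
    version = as.character(utils::packageVersion("hicbeads")),
    seed = config$seed,
    alpha = config$alpha,
    tau = config$tau,
    outlier_threshold = config$outlier_threshold,
    resolutions = config$resolution,
    models = list()
  )
  for (k in seq_along(config$resolution)) {
    res <- config$resolution[k]
    tag <- sprintf("res_%d", as.integer(res))
    layout <- build_stage("layout", make_layout(genome, res))
    mat <- build_stage("contacts",
                       read_triplet(config$matrix[k], config$bed[k], layout))
    fitc <- fit_config(alpha = config$alpha, seed = config$seed)
    model <- build_stage("inference", fit_structure(mat, fitc))
    model <- build_stage("refinement",
                         refine_model(model, config$outlier_threshold))
    rep_ <- build_stage("assembly_qc", detect_inversions(model, config$tau))
    pdb <- file.path(config$output_dir, paste0(tag, "_model.pdb"))
    g3d <- file.path(config$output_dir, paste0(tag, "_model.g3d"))
    dense <- file.path(config$output_dir, paste0(tag, "_matrix.tsv"))
    invr <- file.path(config$output_dir, paste0(tag, "_inversions.tsv"))
    build_stage("export", {
      write_pdb(model, pdb)
      write_g3d(model, g3d)
      utils::write.table(as_dense(mat), dense, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      readr::write_tsv(rep_, invr, progress = FALSE)
    })
    painted <- character(0)
    for (t in config$tracks) {
      track <- build_stage("omics_tracks", {
        tr <- read_bedgraph(t$path, layout)
        if (!is.null(t$mode) && t$mode != "none") {
          tr <- threshold_track(tr, t$mode, t$cutoff)
        }
        tr
      })
      out <- file.path(config$output_dir,
                       paste0(tag, "_",
                              tools::file_path_sans_ext(basename(t$path)),
                              ".pdb"))
      build_stage("omics_tracks",
                  write_pdb(paint_model(model, track), out))
      painted <- c(painted, out)
    }
    manifest$models[[tag]] <- list(
      resolution = res,
      n_beads = nrow(model$beads),
      n_placed = sum(placed(model)),
      loglik = model$loglik,
      iterations = model$iterations,
      beta = model$params$beta,
      dispersion = model$params$r,
      inversions_accepted = sum(rep_$accepted),
      outputs = c(pdb, g3d, dense, invr, painted)
    )
  }
  if (!is.null(config$noise)) {
    nc <- noise_config(
      lambda_grid = as.numeric(unlist(config$noise$lambda_grid %||%
                                        c(0.1, seq(5, 110, by = 5)))),
      replicates = config$noise$replicates %||% 50,
      base_seed = config$seed,
      fit = fit_config(alpha = config$alpha, seed = config$seed),
      outlier_threshold = config$outlier_threshold
    )
    records <- build_stage("stability", run_noise_experiment(mat, nc))
    summarize_rmsd(records,
                   file.path(config$output_dir, "rmsd_summary.tsv"))
    readr::write_tsv(records,
                     file.path(config$output_dir, "rmsd_records.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$output_dir)
}
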