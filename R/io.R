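# On-disk contracts: plain CSV with header, UTF-8, '.' decimal point,
# angles in degrees everywhere.  A dataset directory holds one CSV per
# run (columns Fx,Fy,Fz,Mx,My,Mz), a manifest.csv with the run
# metadata, and a config.dcf with dataset-level settings.

run_meta_cols <- function() {
  c("run_id", "file", "posture", "feathers", "appendage",
    "deflection_deg", "roll_deg", "pitch_deg", "yaw_deg",
    "U_ms", "rho", "nu", "replicate")
}

#' Write a simulated study to disk
#'
#' Writes each run's time series as `runNNNNN.csv`, the run manifest
#' (including the generator's truth coefficients) as `manifest.csv`,
#' and the dataset configuration as `config.dcf`.
#'
#' @param study a `"synthetic_study"` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(study$runs)) {
    run <- study$runs[[i]]
    utils::write.csv(run$samples,
                     file.path(dir, study$manifest$file[i]),
                     row.names = FALSE)
  }
  utils::write.csv(study$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  g <- study$geometry; cc <- study$conditions
  dcf <- matrix(c(S = g$S, lambda = g$lambda, scale = g$scale,
                  rho = cc$rho, nu = cc$nu, U = cc$U,
                  rate = study$runs[[1]]$rate), nrow = 1)
  colnames(dcf) <- c("S", "lambda", "scale", "rho", "nu", "U", "rate")
  write.dcf(dcf, file.path(dir, "config.dcf"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a wind-tunnel dataset from a manifest
#'
#' Validates the manifest schema (required columns, numeric fields,
#' unique run ids, resolvable file paths) and returns the manifest, the
#' dataset configuration, and a lazy per-run reader.  Schema violations
#' are reported with the offending row numbers and run ids.
#'
#' @param manifest_path path to `manifest.csv` (the directory holding
#'   it is the dataset root).
#' @return object of class `"run_dataset"`: list with `manifest`,
#'   `config` (named numeric), `conditions`, `geometry`, `read_run(i)`
#'   (returns a `"raw_run"`), and `n`.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_invalid("manifest not found: %s", manifest_path)
  root <- dirname(manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- run_meta_cols()
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop_invalid("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(man) == 0L) {
    warning("manifest is empty", call. = FALSE)
  }
  num_cols <- c("deflection_deg", "roll_deg", "pitch_deg", "yaw_deg",
                "U_ms", "rho", "nu")
  for (nm in num_cols) {
    vals <- suppressWarnings(as.numeric(man[[nm]]))
    bad <- which(is.na(vals) & !is.na(man[[nm]]))
    if (length(bad))
      stop_invalid("manifest column '%s' non-numeric at rows %s (run ids %s)",
                   nm, paste(bad, collapse = ", "),
                   paste(man$run_id[bad], collapse = ", "))
    man[[nm]] <- vals
  }
  if (anyDuplicated(man$run_id))
    stop_invalid("duplicate run ids: %s",
                 paste(unique(man$run_id[duplicated(man$run_id)]),
                       collapse = ", "))
  missing_files <- !file.exists(file.path(root, man$file))
  if (any(missing_files))
    stop_invalid("missing run files for run ids %s",
                 paste(man$run_id[missing_files], collapse = ", "))
  cfg_path <- file.path(root, "config.dcf")
  config <- if (file.exists(cfg_path)) {
    d <- read.dcf(cfg_path)
    stats::setNames(as.numeric(d[1, ]), colnames(d))
  } else c(S = 0.012, lambda = 0.08, scale = 0.2, rho = 1.204,
           nu = 1.5e-5, U = 6, rate = 1000)
  rate <- unname(config["rate"])
  read_run <- function(i) {
    samples <- utils::read.csv(file.path(root, man$file[i]))
    structure(list(samples = samples, rate = rate,
                   meta = as.list(man[i, setdiff(need, "file")])),
              class = "raw_run")
  }
  structure(list(manifest = man, config = config,
                 conditions = tunnel_conditions(
                   U = unname(config["U"]), rho = unname(config["rho"]),
                   nu = unname(config["nu"])),
                 geometry = model_geometry(
                   S = unname(config["S"]), lambda = unname(config["lambda"]),
                   scale = unname(config["scale"])),
                 read_run = read_run, n = nrow(man), root = root),
            class = "run_dataset")
}

#' @export
print.run_dataset <- function(x, ...) {
  cat(sprintf("run dataset at %s: %d runs\n", x$root, x$n))
  invisible(x)
}

#' Reduce raw runs to a tidy coefficient table
#'
#' The core data-reduction step: each run's time series is averaged,
#' the mean wrench is rotated from the sensor frame to the tunnel
#' frame using the run's nominal mounting orientation, and the result
#' is nondimensionalized at the run's tunnel conditions and the
#' reference geometry.  Averaging commutes with the (linear) rotation,
#' so the mean is rotated once.  Output is one row per run with the
#' six coefficients plus metadata, the interchange format of all
#' downstream analyses.
#'
#' @param runs a list of `"raw_run"` objects, a `"synthetic_study"`, or
#'   a `"run_dataset"` from [read_dataset()].
#' @param geometry a [model_geometry()]; defaulted from the dataset
#'   config when `runs` is a `"run_dataset"` or study.
#' @param posture_areas optional named per-posture area vector; when
#'   given, the reference area per row follows
#'   [reference_area_policy()].
#' @param reference_posture,per_posture passed to
#'   [reference_area_policy()].
#' @return data frame with metadata columns, `Re`, the six coefficient
#'   columns `CL, CD, CY, Cl, Cm, Cn`, and per-channel mean standard
#'   errors `se_F`, `se_M`.
#' @export
reduce_runs <- function(runs, geometry = NULL, posture_areas = NULL,
                        reference_posture = "sprawled",
                        per_posture = FALSE) {
  if (inherits(runs, "synthetic_study")) {
    geometry <- geometry %||% runs$geometry
    runs <- runs$runs
  } else if (inherits(runs, "run_dataset")) {
    geometry <- geometry %||% runs$geometry
    ds <- runs
    runs <- lapply(seq_len(ds$n), ds$read_run)
  }
  geometry <- geometry %||% model_geometry()
  areas <- if (!is.null(posture_areas))
    reference_area_policy(posture_areas, baseline = reference_posture,
                          per_posture = per_posture) else NULL
  rows <- lapply(runs, function(run) {
    rec <- recording(run$samples, rate = run$rate)
    avg <- average_recording(rec)
    o <- orientation(roll = run$meta$roll_deg, pitch = run$meta$pitch_deg,
                     yaw = run$meta$yaw_deg)
    w <- to_tunnel_frame(avg$mean, o)
    cond <- tunnel_conditions(U = run$meta$U_ms, rho = run$meta$rho,
                              nu = run$meta$nu)
    geo <- geometry
    if (!is.null(areas)) {
      if (!run$meta$posture %in% names(areas))
        stop_invalid("no reference area for posture '%s'", run$meta$posture)
      geo <- model_geometry(S = areas[[run$meta$posture]],
                            lambda = geometry$lambda,
                            scale = geometry$scale)
    }
    a <- suppressWarnings(nondimensionalize(w, cond, geo))
    n <- nrow(run$samples)
    data.frame(run_id = run$meta$run_id %||% NA_character_,
               posture = run$meta$posture,
               feathers = run$meta$feathers %||% TRUE,
               appendage = run$meta$appendage %||% "none",
               deflection_deg = run$meta$deflection_deg %||% 0,
               roll_deg = run$meta$roll_deg, pitch_deg = run$meta$pitch_deg,
               yaw_deg = run$meta$yaw_deg,
               replicate = run$meta$replicate %||% 1L,
               U_ms = cond$U, Re = reynolds_number(cond, geo$lambda),
               CL = a$CL, CD = a$CD, CY = a$CY,
               Cl = a$Cl, Cm = a$Cm, Cn = a$Cn,
               se_F = mean(avg$sd[1:3]) / sqrt(n),
               se_M = mean(avg$sd[4:6]) / sqrt(n))
  })
  do.call(rbind, rows)
}

#' Read a coefficient table, translating foreign column names
#'
#' Reads a tidy coefficient CSV.  Externally produced tables (e.g. a
#' deposited dataset with its own header conventions) can be adapted by
#' `mapping`, a named character vector `c(canonical = "external")`
#' translating external headers onto the canonical schema used by
#' [assemble_sweep()] and friends.
#'
#' @param path CSV path.
#' @param mapping optional named character vector mapping canonical
#'   names to the file's column names.
#' @return data frame in the canonical schema.
#' @export
read_coefficient_table <- function(path, mapping = NULL) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      ext <- mapping[[canon]]
      if (!ext %in% names(tbl))
        stop_invalid("mapped column '%s' absent from %s", ext, path)
      names(tbl)[names(tbl) == ext] <- canon
    }
  }
  tbl
}

#' @rdname read_coefficient_table
#' @param tbl coefficient table to write.
#' @export
write_coefficient_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
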