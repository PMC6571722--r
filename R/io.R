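# Artifact I/O: TSV tables with JSON metadata sidecars, extended-XYZ
# snapshots, run configuration documents, and checkpoint/restore of the
# sampler state.  All floating-point values are written with 17 significant
# digits so round-trips are bit-faithful.

meta_path <- function(path) paste0(path, ".meta.json")

write_tsv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a density of states table
#'
#' The table is anchored (`max(log_g) = 0`) and written as TSV with columns
#' `Env_raw`, `nst`, `log_g`, `visits`; a JSON sidecar
#' (`<path>.meta.json`) carries the model fingerprint, model summary,
#' accumulated MCS, schedule, seed and package version.
#'
#' @param dos an `sf_dos`.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_dos <- function(dos, path) {
  dos <- anchor_dos(dos)
  keep <- intersect(c("Env_raw", "nst", "log_g", "visits", "n_runs",
                      "log_g_sd"), names(dos$table))
  write_tsv17(dos$table[keep], path)
  meta <- list(kind = "dos", fingerprint = dos$fingerprint,
               model_info = dos$model_info, n_mcs = dos$n_mcs,
               schedule = if (!is.null(dos$schedule)) unclass(dos$schedule),
               seed = dos$seed,
               package_version = as.character(packageVersion("sfcopoly")))
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

read_meta <- function(path, kind) {
  mp <- meta_path(path)
  if (!file.exists(mp)) stop("metadata sidecar missing: ", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(meta$kind, kind))
    stop(sprintf("expected a %s artifact, found %s", kind, meta$kind))
  meta
}

#' @rdname write_dos
#' @param expect_fingerprint optional model fingerprint that the artifact
#'   must match (hard error otherwise).
#' @export
read_dos <- function(path, expect_fingerprint = NULL) {
  meta <- read_meta(path, "dos")
  if (!is.null(expect_fingerprint) &&
      !identical(meta$fingerprint, expect_fingerprint))
    stop("stale artifact: DoS fingerprint does not match the model")
  tab <- read.table(path, header = TRUE, sep = "\t")
  mi <- meta$model_info
  mi$eps_raw <- as.integer(mi$eps_raw)
  structure(list(table = tab, fingerprint = meta$fingerprint,
                 model_info = mi, n_mcs = meta$n_mcs,
                 schedule = meta$schedule, seed = meta$seed),
            class = "sf_dos")
}

#' Write / read a production observable table
#'
#' @param obs an `sf_obs` from [production_run()].
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(obs, path) {
  write_tsv17(obs$table, path)
  meta <- list(kind = "obs", fingerprint = obs$fingerprint,
               model_info = obs$model_info, n_mcs = obs$n_mcs,
               sample_every = obs$sample_every, seed = obs$seed,
               observables = obs$observables,
               package_version = as.character(packageVersion("sfcopoly")))
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_observables
#' @inheritParams read_dos
#' @export
read_observables <- function(path, expect_fingerprint = NULL) {
  meta <- read_meta(path, "obs")
  if (!is.null(expect_fingerprint) &&
      !identical(meta$fingerprint, expect_fingerprint))
    stop("stale artifact: observable-table fingerprint does not match")
  tab <- read.table(path, header = TRUE, sep = "\t")
  mi <- meta$model_info
  mi$eps_raw <- as.integer(mi$eps_raw)
  structure(list(table = tab, fingerprint = meta$fingerprint,
                 model_info = mi, n_mcs = meta$n_mcs,
                 sample_every = meta$sample_every, seed = meta$seed,
                 observables = meta$observables,
                 below_floor = tab[FALSE, c("Env_raw", "nst", "count")],
                 min_count = NA),
            class = "sf_obs")
}

#' Write / read a conformation as extended XYZ
#'
#' Element column encodes the bead type (S/F); the comment line carries
#' `key=value` metadata (`N`, `b`, `preset`, `eps_st`, `Env_raw`, `nst`,
#' optionally `seed`).
#'
#' @param coords `N x 3` coordinate matrix.
#' @param model the `sf_model`.
#' @param path output file.
#' @param seed optional seed recorded in the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(coords, model, path, seed = NULL) {
  coords <- check_coords(coords, model)
  ms <- macrostate(coords, model)
  com <- sprintf("N=%d b=%d preset=%s eps_st=%.17g Env_raw=%d nst=%d%s",
                 model$N, model$b, model$preset, model$eps_st,
                 ms$Env_raw, ms$nst,
                 if (is.null(seed)) "" else sprintf(" seed=%d", seed))
  lines <- c(sprintf("%d", model$N), com,
             sprintf("%s %.17g %.17g %.17g", model$pattern,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz`: list with `coords`, `pattern`, and the parsed
#'   comment `meta`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  kv <- strsplit(strsplit(trimws(lines[2]), "\\s+")[[1]], "=", fixed = FALSE)
  meta <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  pattern <- vapply(rows, `[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), c(0, 0, 0)))
  list(coords = coords, pattern = pattern, meta = meta)
}

#' Write / read a microcanonical or profile curve with metadata
#'
#' @param curve a data.frame (e.g. an `sf_micro_curve`).
#' @param path TSV file path.
#' @param meta named list of metadata stored in the sidecar (the curve's
#'   attributes `ensemble`, `eps_st`, `d`, `bin_width`, `smooth_bins` are
#'   included automatically when present).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, meta = list()) {
  auto <- attributes(curve)[intersect(
    c("ensemble", "eps_st", "d", "bin_width", "smooth_bins"),
    names(attributes(curve)))]
  write_tsv17(as.data.frame(curve), path)
  jsonlite::write_json(c(list(kind = "curve"), auto, meta), meta_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  meta <- read_meta(path, "curve")
  tab <- read.table(path, header = TRUE, sep = "\t")
  for (a in setdiff(names(meta), "kind")) attr(tab, a) <- meta[[a]]
  tab
}

#' Serialize a state diagram
#'
#' Writes the CV surface as a long-format TSV (`x`, `y`, `CV`), the maxima
#' loci and transition markers as companion TSVs, and a JSON metadata file.
#'
#' @param diagram an `sf_state_diagram`.
#' @param prefix path prefix; files `<prefix>_surface.tsv`,
#'   `<prefix>_maxima.tsv`, `<prefix>_transitions.tsv` (when present) and
#'   `<prefix>.json` are created.
#' @return `prefix`, invisibly.
#' @export
write_state_diagram <- function(diagram, prefix) {
  surf <- expand.grid(y = diagram$y_grid, x = diagram$x_grid)
  surf <- data.frame(x = surf$x, y = surf$y, CV = as.vector(diagram$CV))
  write_tsv17(surf, paste0(prefix, "_surface.tsv"))
  write_tsv17(diagram$maxima, paste0(prefix, "_maxima.tsv"))
  if (!is.null(diagram$transitions))
    write_tsv17(diagram$transitions, paste0(prefix, "_transitions.tsv"))
  jsonlite::write_json(list(kind = "state_diagram",
                            fingerprint = diagram$fingerprint,
                            model_info = diagram$model_info,
                            nx = length(diagram$x_grid),
                            ny = length(diagram$y_grid)),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a model and run settings from a configuration document
#'
#' JSON (or YAML when the `yaml` package is installed and the extension is
#' `.yml`/`.yaml`) with two sections: `model` (keys mirroring the
#' [sf_model()] arguments) and an optional `run` section (free-form,
#' returned as-is).  Unknown `model` keys are rejected with a field-level
#' message.
#'
#' @param path configuration file.
#' @return list with `model` (an `sf_model`) and `run` (list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$model)) stop("config must have a 'model' section")
  allowed <- setdiff(names(formals(sf_model)), "")
  unknown <- setdiff(names(cfg$model), allowed)
  if (length(unknown))
    stop("unknown model field(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model[["N"]])) stop("model field 'N' is required")
  if (!is.null(cfg$model[["eps"]]))
    cfg$model$eps <- unlist(cfg$model[["eps"]])
  model <- do.call(sf_model, cfg$model)
  list(model = model, run = cfg$run %||% list())
}

#' Checkpoint / restore a SAMC run
#'
#' `checkpoint_samc()` writes the DoS, the current conformation, the full
#' RNG state and the schedule position, so `restore_samc()` +
#' [run_samc()] continues bit-identically to an uninterrupted run with the
#' same seed stream.
#'
#' @param dos an `sf_dos` returned by [run_samc()] (carries `conf`,
#'   `rng_state`, `t_next`).
#' @param model the `sf_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
checkpoint_samc <- function(dos, model, dir) {
  if (is.null(dos$rng_state) || is.null(dos$t_next))
    stop("dos does not carry sampler state (not produced by run_samc?)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dos(dos, file.path(dir, "dos.tsv"))
  write_xyz(dos$conf, model, file.path(dir, "conf.xyz"))
  jsonlite::write_json(
    list(kind = "checkpoint", fingerprint = dos$fingerprint,
         t_next = dos$t_next, rng_state = dos$rng_state,
         schedule = if (!is.null(dos$schedule)) unclass(dos$schedule),
         package_version = as.character(packageVersion("sfcopoly"))),
    file.path(dir, "state.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname checkpoint_samc
#' @return `restore_samc`: list with `dos`, `conf`, `t_next`, `schedule`;
#'   the global RNG state is restored as a side effect.
#' @export
restore_samc <- function(model, dir) {
  sp <- file.path(dir, "state.json")
  if (!file.exists(sp)) stop("no checkpoint found in ", dir)
  st <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(st$kind, "checkpoint")) stop("not a checkpoint: ", dir)
  if (!identical(st$fingerprint, model_fingerprint(model)))
    stop("checkpoint belongs to a different model (fingerprint mismatch)")
  dos <- read_dos(file.path(dir, "dos.tsv"),
                  expect_fingerprint = model_fingerprint(model))
  conf <- read_xyz(file.path(dir, "conf.xyz"))$coords
  set_rng_state(as.integer(st$rng_state))
  sched <- if (!is.null(st$schedule))
    gain_schedule(st$schedule$gamma0, st$schedule$t0) else NULL
  list(dos = dos, conf = conf, t_next = st$t_next, schedule = sched)
}
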