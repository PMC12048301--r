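#' Validate and normalize a study configuration file
#'
#' Reads a YAML (or JSON) configuration, checks it against the known
#' schema (unknown keys are rejected, basic physical constraints are
#' enforced), fills defaults, and returns a normalized [study_config()].
#'
#' Recognized top-level keys: `grid` (n_rows, n_cols, dx_mm, D),
#' `baseline_apd_ms`, `lesion` ([lesion_spec()] arguments), `pacing`
#' ([pacing_protocol()] arguments), `ectopic` ([ectopic_spec()]
#' arguments), `acquisition` ([acquisition_model()] arguments), `ionic`
#' ([ionic_params()] arguments), `n_preparations`, `seed`.
#'
#' @param path configuration file path, or a named list
#' @return list with `config` (`vf_config`), `n_preparations`, `seed`
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    stopifnot(file.exists(path))
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  } else path
  if (is.null(raw)) raw <- list()
  schema <- list(
    grid = c("n_rows", "n_cols", "dx_mm", "D"),
    baseline_apd_ms = NULL, n_preparations = NULL, seed = NULL,
    lesion = names(formals(lesion_spec)),
    pacing = names(formals(pacing_protocol)),
    ectopic = names(formals(ectopic_spec)),
    acquisition = names(formals(acquisition_model)),
    ionic = names(formals(ionic_params)))
  errs <- character(0)
  bad_top <- setdiff(names(raw), names(schema))
  if (length(bad_top))
    errs <- c(errs, sprintf("unknown key(s): %s", paste(bad_top, collapse = ", ")))
  for (sec in intersect(names(raw), names(schema))) {
    if (is.null(schema[[sec]])) next
    bad <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(bad))
      errs <- c(errs, sprintf("unknown key(s) in '%s': %s", sec,
                              paste(bad, collapse = ", ")))
  }
  gr <- raw$grid
  if (!is.null(gr$dx_mm) && gr$dx_mm <= 0)
    errs <- c(errs, "grid.dx_mm must be > 0")
  if (!is.null(gr$D) && gr$D <= 0)
    errs <- c(errs, "grid.D must be > 0")
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  cfg <- study_config(
    n_rows = gr$n_rows %||% 128, n_cols = gr$n_cols %||% 128,
    dx_mm = gr$dx_mm %||% 0.39, D = gr$D %||% 0.1,
    baseline_apd_ms = raw$baseline_apd_ms %||% 240,
    lesion = do.call(lesion_spec, raw$lesion %||% list()),
    pacing = do.call(pacing_protocol, raw$pacing %||% list()),
    ectopic = do.call(ectopic_spec, raw$ectopic %||% list()),
    acquisition = do.call(acquisition_model, raw$acquisition %||% list()),
    ionic = do.call(ionic_params, raw$ionic %||% list()))
  list(config = cfg, n_preparations = raw$n_preparations %||% 1,
       seed = raw$seed %||% 1)
}

#' Run the full study pipeline
#'
#' For each seeded preparation: generate (simulate + acquire + pseudo-ECG),
#' extract pre-trigger maps, delineate the border and compute gradient
#' maps, detect beats/PVCs/VF episodes on the ECG, localize the trigger
#' origin and measure the site; then aggregate the event summary and the
#' trigger-versus-nontrigger gradient comparison into a Markdown report.
#' Deterministic for a fixed config + seed. A failing stage aborts with
#' the stage name and preparation id.
#'
#' @param config `vf_config` (or a path accepted by [validate_config()])
#' @param out_dir output directory
#' @param n_preparations number of preparations
#' @param seed master seed
#' @param write_movies also write the (large) per-episode movies
#' @param nontrigger_clearance_mm,nontrigger_edge_mm nontrigger-site
#'   sampling geometry (scale down for small test grids)
#' @return list with the aggregated tables; artifacts + `manifest.json`
#'   under `out_dir`
#' @export
run_study <- function(config = study_config(), out_dir,
                      n_preparations = 1, seed = 1, write_movies = FALSE,
                      nontrigger_clearance_mm = 10,
                      nontrigger_edge_mm = 4) {
  if (is.character(config)) {
    v <- validate_config(config)
    config <- v$config
    n_preparations <- v$n_preparations
    seed <- v$seed
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  ep_seeds <- sample.int(.Machine$integer.max %/% 2, n_preparations)
  stage <- function(name, prep, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for preparation %d: %s",
                   name, prep, conditionMessage(e)), call. = FALSE))
  }
  all_sites <- list(); all_nt <- list(); all_beats <- list(); all_eps <- list()
  for (k in seq_len(n_preparations)) {
    ep <- stage("generate", k, synth_preparation(config, seed = ep_seeds[k]))
    if (write_movies)
      stage("write", k, write_movie_tiff(
        ep$optical, file.path(out_dir, sprintf("prep%02d_movie.tif", k))))
    stage("write", k, write_ecg_csv(
      ep$ecg, file.path(out_dir, sprintf("prep%02d_ecg.csv", k))))
    ei <- ep$sim$truth$ectopic

    win <- stage("maps", k, pre_trigger_window(ep$sim))
    maps <- stage("maps", k, build_maps(
      ep$optical, data.frame(start_ms = win[1], end_ms = win[2]))[[1]])
    geo <- stage("gradients", k, delineate_border(maps$apd80))
    ga <- stage("gradients", k, local_gradient(maps$apd80))
    grt <- stage("gradients", k, local_gradient(maps$rt))
    stage("gradients", k, write_map(
      maps$apd80, file.path(out_dir, sprintf("prep%02d_apd80", k))))

    beats <- stage("events", k, classify_pvc(detect_beats(ep$ecg)))
    beats$prep <- k
    eps <- stage("events", k, detect_vf(ep$ecg, beats))
    if (nrow(eps)) eps$prep <- k
    all_beats[[k]] <- beats
    all_eps[[k]] <- eps

    if (!is.null(ei) && isTRUE(ei$captured[1])) {
      twin <- c(ei$realized_ms[1] - 40, ei$realized_ms[1] + 280)
      loc <- stage("localize", k, localize_trigger(ep$optical, twin))
      ts <- stage("localize", k, measure_trigger_site(
        loc$origin, geo, ga, grt, snap_mm = 1.5))
      ts$prep <- k
      all_sites[[k]] <- ts
      all_nt[[k]] <- within(stage("localize", k, sample_nontrigger_sites(
        geo, ga, grt, n = 3, seed = ep_seeds[k],
        clearance_mm = nontrigger_clearance_mm,
        edge_margin_mm = nontrigger_edge_mm)), prep <- k)
    }
  }
  beats <- do.call(rbind, all_beats)
  episodes <- do.call(rbind, all_eps)
  if (is.null(episodes)) episodes <- detect_vf(
    structure(list(time_ms = 0:10, amp = rep(0, 11), dt_ms = 1,
                   pacing = data.frame()), class = "vf_ecg"),
    beats[0, , drop = FALSE])
  es <- stage("report", 0, episode_summary(episodes, beats))
  sites <- do.call(rbind, all_sites)
  nts <- do.call(rbind, all_nt)
  gr <- if (!is.null(sites) && nrow(sites) >= 2 && !is.null(nts))
    gradient_comparison(sites, nts) else NULL
  stage("report", 0, render_report(
    list(episode_summary = es, gradients = gr,
         seeds = ep_seeds,
         config_echo = paste(utils::capture.output(utils::str(config)),
                             collapse = "\n")),
    file.path(out_dir, "report.md")))
  write.csv(beats, file.path(out_dir, "beats.csv"), row.names = FALSE)
  write.csv(episodes, file.path(out_dir, "episodes.csv"), row.names = FALSE)
  if (!is.null(sites))
    write.csv(sites, file.path(out_dir, "trigger_sites.csv"),
              row.names = FALSE)
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  jsonlite::write_json(
    list(seed = seed, episode_seeds = ep_seeds,
         files = data.frame(file = basename(files),
                            md5 = unname(tools::md5sum(files)))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(episode_summary = es, gradients = gr, beats = beats,
                 episodes = episodes, sites = sites, nontrigger = nts))
}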