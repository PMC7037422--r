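default_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    conditions = list(
      nm_types = "TiO2",
      doses = nm_dose_grid(),
      timepoints = 72,
      n_replicates = 3L),
    generator = list(
      synergy_coeff = 0,
      baseline_mortality = 0.05,
      n_events = 3000L),
    gating = list(
      target_low_ni = 0.70,
      target_low_ir = 0.60),
    fluor = list(
      method = "valley",
      dioc = NULL,
      pi = NULL),
    fit = list(n_starts = 5L),
    distance = list(scaling = "unit", log_ed50 = TRUE),
    growth = list(
      enabled = TRUE,
      nm_type = "TiO2",
      doses = c(0, 64),
      days = c(0, 3, 7),
      n_fields = 3L,
      plating_per_field = 30,
      field_size = 256L),
    pcr = list(
      enabled = TRUE,
      doses = c(0, 16, 32),
      n_replicates = 3L),
    counting = list(smooth_sigma = 2, min_area = 20))
}

#' Validate and default a pipeline configuration
#'
#' Reads a YAML or JSON config (or takes a list), checks it against the
#' schema — unknown keys are rejected, values type- and range-checked,
#' all violations reported together — and fills defaults. See
#' `default_config` in the package source for the full schema and
#' defaults.
#'
#' @param config a file path (`.yaml`/`.yml`/`.json`) or a named list.
#' @return a validated `run_config` list.
#' @export
#' @examples
#' cfg <- validate_config(list(seed = 42,
#'                             conditions = list(nm_types = "TiO2")))
#' cfg$seed
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a path to YAML/JSON")
  defs <- default_config()
  errors <- character()

  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0)
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  for (sec in intersect(names(config), names(defs))) {
    if (is.list(defs[[sec]]) && !is.null(config[[sec]])) {
      if (!is.list(config[[sec]])) {
        errors <- c(errors, paste0("'", sec, "' must be a list"))
        next
      }
      bad <- setdiff(names(config[[sec]]), names(defs[[sec]]))
      if (length(bad) > 0)
        errors <- c(errors, paste0("unknown key(s) in '", sec, "': ",
                                   paste(bad, collapse = ", ")))
    }
  }
  cfg <- utils::modifyList(defs, config[intersect(names(config), names(defs))])

  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
      "'seed' must be a single integer")
  chk(all(cfg$conditions$nm_types %in% setdiff(nm_types(), "none")),
      paste0("'conditions$nm_types' must be among: ",
             paste(setdiff(nm_types(), "none"), collapse = ", ")))
  chk(is.numeric(cfg$conditions$doses) && all(is.finite(cfg$conditions$doses)) &&
        all(cfg$conditions$doses >= 0),
      "'conditions$doses' must be finite doses >= 0")
  chk(0 %in% cfg$conditions$doses,
      "'conditions$doses' must include the dose-0 control")
  chk(all(cfg$conditions$timepoints >= 0),
      "'conditions$timepoints' must be >= 0")
  chk(cfg$conditions$n_replicates >= 1, "'conditions$n_replicates' must be >= 1")
  chk(cfg$generator$synergy_coeff >= 0, "'generator$synergy_coeff' must be >= 0")
  chk(cfg$generator$baseline_mortality >= 0 && cfg$generator$baseline_mortality <= 1,
      "'generator$baseline_mortality' must be a fraction")
  chk(cfg$generator$n_events >= 1, "'generator$n_events' must be >= 1")
  for (k in c("target_low_ni", "target_low_ir"))
    chk(cfg$gating[[k]] > 0 && cfg$gating[[k]] < 1,
        paste0("'gating$", k, "' must lie in (0, 1)"))
  chk(cfg$fluor$method %in% c("valley", "explicit"),
      "'fluor$method' must be \"valley\" or \"explicit\"")
  chk(cfg$fit$n_starts >= 1, "'fit$n_starts' must be >= 1")

  if (length(errors) > 0)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(cfg, class = c("run_config", "list"))
}

pipeline_manifest <- function(cfg) {
  grids <- lapply(cfg$conditions$timepoints, function(tp) {
    g <- expand.grid(
      dose_surface = cfg$conditions$doses,
      nm_type = cfg$conditions$nm_types,
      irradiated = c(FALSE, TRUE),
      replicate = seq_len(cfg$conditions$n_replicates),
      stringsAsFactors = FALSE)
    g$timepoint_h <- tp
    g
  })
  man <- do.call(rbind, grids)
  man$nm_type <- ifelse(man$dose_surface == 0, "none", man$nm_type)
  man <- unique(man)
  man <- man[order(man$timepoint_h, man$nm_type, man$dose_surface,
                   man$irradiated, man$replicate), , drop = FALSE]
  man$counter <- seq_len(nrow(man))
  man$seed <- derive_seed(cfg$seed, man$counter)
  man$sample_id <- sprintf(
    "%s_d%g_%s_t%g_r%d", man$nm_type, man$dose_surface,
    ifelse(man$irradiated, "IR", "NI"), man$timepoint_h, man$replicate)
  rownames(man) <- NULL
  man
}

stage_log <- function(outdir, stage, started, extra = list()) {
  rec <- c(list(stage = stage, started = started,
                finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  logf <- file.path(outdir, "pipeline.log.jsonl")
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = logf, append = TRUE, sep = "")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates generate, gate, classify, fit, synergy, growth, qPCR and
#' report stages. Stages communicate only through files under `outdir`
#' (CSV/JSON), every stochastic step uses a sub-seed derived from the
#' master seed, and the run is deterministic: two runs with the same
#' config and seed produce an identical provenance hash.
#'
#' @param config anything [validate_config()] accepts.
#' @param outdir output directory (created if needed); overrides
#'   `config$outdir`.
#' @param seed optional master-seed override.
#' @return a `run_report` list (also written to `report.json`): stage
#'   output paths with MD5 hashes, the synergy heat map, summary tables
#'   and the provenance hash.
#' @export
#' @examples
#' \donttest{
#' cfg <- list(conditions = list(doses = c(0, 16, 48, 64)),
#'             generator = list(n_events = 500),
#'             growth = list(enabled = FALSE), pcr = list(enabled = FALSE))
#' rep <- run_pipeline(cfg, outdir = tempfile(), seed = 1)
#' rep$heatmap
#' }
run_pipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) stop("an output directory is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$outdir, "events"), showWarnings = FALSE)
  outputs <- character()
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  gp <- default_generative_params(
    synergy_coeff = cfg$generator$synergy_coeff,
    baseline_mortality = cfg$generator$baseline_mortality)

  ## stage: simulate -------------------------------------------------------
  man <- pipeline_manifest(cfg)
  man$path <- file.path("events", paste0(man$sample_id, ".csv"))
  for (i in seq_len(nrow(man))) {
    cond <- sample_condition(man$nm_type[i], man$dose_surface[i],
                             man$irradiated[i], man$timepoint_h[i])
    ev <- simulate_events(cond, gp, cfg$generator$n_events, man$seed[i])
    ev$sample_id <- man$sample_id[i]
    write_event_csv(ev, file.path(cfg$outdir, man$path[i]))
  }
  man_path <- file.path(cfg$outdir, "samples.csv")
  write.csv(man, man_path, row.names = FALSE)
  outputs <- c(outputs, "samples.csv", man$path)
  stage_log(cfg$outdir, "simulate", t0,
            list(seed = cfg$seed, n_samples = nrow(man)))

  ## stage: gate -----------------------------------------------------------
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  events <- lapply(man$path, function(p) read_event_csv(file.path(cfg$outdir, p)))
  gate_rows <- list()
  for (tp in unique(man$timepoint_h)) {
    for (ir in c(FALSE, TRUE)) {
      sel_ctrl <- man$timepoint_h == tp & man$irradiated == ir &
        man$dose_surface == 0
      ctrl <- do.call(rbind, events[sel_ctrl])
      target <- if (ir) cfg$gating$target_low_ir else cfg$gating$target_low_ni
      thr <- compute_ssc_threshold(ctrl, target)
      sel <- which(man$timepoint_h == tp & man$irradiated == ir)
      for (i in sel) {
        g <- apply_ssc_gate(events[[i]], thr)
        gate_rows[[length(gate_rows) + 1L]] <- cbind(
          man[i, c("sample_id", "nm_type", "dose_surface", "irradiated",
                   "timepoint_h", "replicate")],
          data.frame(threshold = thr, frac_low = g$frac_low,
                     frac_high = g$frac_high))
      }
    }
  }
  gating <- do.call(rbind, gate_rows)
  write.csv(gating, file.path(cfg$outdir, "gating.csv"), row.names = FALSE)
  outputs <- c(outputs, "gating.csv")
  stage_log(cfg$outdir, "gate", t0, list())

  ## stage: death ----------------------------------------------------------
  thr_fluor <- if (cfg$fluor$method == "explicit") {
    derive_fluor_thresholds(rule = list(method = "explicit",
                                        dioc = cfg$fluor$dioc,
                                        pi = cfg$fluor$pi))
  } else {
    derive_fluor_thresholds(do.call(rbind, events),
                            rule = list(method = "valley"))
  }
  death <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    d <- classify_death(events[[i]], thr_fluor)
    cbind(man[i, c("sample_id", "nm_type", "dose_surface", "irradiated",
                   "timepoint_h", "replicate")],
          data.frame(live = d$live, apoptotic = d$apoptotic,
                     dead = d$dead, mortality = d$mortality))
  }))
  write.csv(death, file.path(cfg$outdir, "mortality.csv"), row.names = FALSE)
  comp <- comparison_suite(death)
  write.csv(comp, file.path(cfg$outdir, "comparisons.csv"), row.names = FALSE)
  outputs <- c(outputs, "mortality.csv", "comparisons.csv")
  stage_log(cfg$outdir, "death", t0,
            list(dioc_threshold = thr_fluor$dioc, pi_threshold = thr_fluor$pi))

  ## stage: fit + synergy --------------------------------------------------
  death <- read.csv(file.path(cfg$outdir, "mortality.csv"),
                    stringsAsFactors = FALSE)
  results <- list(); res_nm <- character(); res_tp <- numeric()
  fits <- list()
  for (tp in unique(death$timepoint_h)) {
    for (nm in cfg$conditions$nm_types) {
      sel <- death$timepoint_h == tp &
        (death$nm_type == nm | death$dose_surface == 0)
      ni <- death[sel & !death$irradiated, ]
      ir <- death[sel & death$irradiated, ]
      res <- synergy_call(
        dose_response_data(ir$dose_surface, ir$mortality, ir$replicate),
        dose_response_data(ni$dose_surface, ni$mortality, ni$replicate),
        scaling = cfg$distance$scaling, log_ed50 = cfg$distance$log_ed50,
        n_starts = cfg$fit$n_starts, seed = cfg$seed)
      key <- paste0(nm, "_t", tp)
      fits[[key]] <- list(
        observed = unclass(res$observed_fit),
        simulated = unclass(res$simulated_fit))
      results[[length(results) + 1L]] <- res
      res_nm <- c(res_nm, nm); res_tp <- c(res_tp, tp)
    }
  }
  jsonlite::write_json(fits, file.path(cfg$outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  hm <- synergy_heatmap(results, res_nm, res_tp)
  write.csv(data.frame(nm_type = rownames(hm), hm, check.names = FALSE),
            file.path(cfg$outdir, "heatmap.csv"), row.names = FALSE)
  syn_json <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    list(nm_type = res_nm[i], timepoint_h = res_tp[i], q_ir = r$q_ir,
         distance = r$distance, sign = r$sign,
         per_dose_delta = as.list(r$per_dose_delta))
  })
  jsonlite::write_json(syn_json, file.path(cfg$outdir, "synergy.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, "fits.json", "heatmap.csv", "synergy.json")
  stage_log(cfg$outdir, "synergy", t0, list())

  ## stage: growth ---------------------------------------------------------
  if (isTRUE(cfg$growth$enabled)) {
    g <- cfg$growth
    growth_rows <- list()
    ctr <- 100000L
    for (ir in c(FALSE, TRUE)) for (dose in g$doses) {
      nm <- if (dose == 0) "none" else g$nm_type
      cond <- sample_condition(nm, dose, ir, 0)
      by_day <- list()
      for (day in g$days) {
        ctr <- ctr + 1L
        by_day[[as.character(day)]] <- simulate_growth_images(
          cond, day, gp, n_fields = g$n_fields,
          seed = derive_seed(cfg$seed, ctr),
          plating_per_field = g$plating_per_field,
          field_size = g$field_size)
      }
      series <- build_growth_series(
        lapply(by_day, identity),
        smooth_sigma = cfg$counting$smooth_sigma,
        min_area = cfg$counting$min_area)
      series$nm_type <- nm; series$dose_surface <- dose
      series$irradiated <- ir
      growth_rows[[length(growth_rows) + 1L]] <- series
    }
    growth <- do.call(rbind, growth_rows)
    write.csv(growth, file.path(cfg$outdir, "growth.csv"), row.names = FALSE)
    outputs <- c(outputs, "growth.csv")
    stage_log(cfg$outdir, "growth", t0, list())
  }

  ## stage: pcr ------------------------------------------------------------
  if (isTRUE(cfg$pcr$enabled)) {
    ctr <- 200000L
    ct_rows <- list()
    for (tp in unique(cfg$conditions$timepoints))
      for (ir in c(FALSE, TRUE)) for (dose in cfg$pcr$doses)
        for (nm in if (dose == 0) "none" else cfg$conditions$nm_types) {
          ctr <- ctr + 1L
          ct_rows[[length(ct_rows) + 1L]] <- simulate_pcr(
            sample_condition(nm, dose, ir, tp), gp,
            seed = derive_seed(cfg$seed, ctr),
            n_replicates = cfg$pcr$n_replicates)
        }
    ct <- do.call(rbind, ct_rows)
    write.csv(ct, file.path(cfg$outdir, "ct.csv"), row.names = FALSE)
    fc <- fold_change_table(ct, reference_gene = gp$reference_gene)
    write.csv(fc, file.path(cfg$outdir, "fold_changes.csv"), row.names = FALSE)
    outputs <- c(outputs, "ct.csv", "fold_changes.csv")
    stage_log(cfg$outdir, "pcr", t0, list())
  }

  ## stage: report ---------------------------------------------------------
  hashes <- vapply(outputs, function(p)
    unname(tools::md5sum(file.path(cfg$outdir, p))), character(1))
  provenance <- unname(tools::md5sum(
    local({
      tf <- tempfile()
      writeLines(paste(sort(paste(outputs, hashes)), collapse = "\n"), tf)
      tf
    })))
  report <- list(
    config = unclass(cfg), outputs = as.list(hashes),
    heatmap = hm, provenance_hash = provenance)
  jsonlite::write_json(
    list(config = unclass(cfg)[setdiff(names(cfg), "outdir")],
         outputs = as.list(hashes),
         heatmap = list(nm_type = rownames(hm),
                        timepoint_h = colnames(hm),
                        score = unname(apply(hm, 1, as.list))),
         provenance_hash = provenance),
    file.path(cfg$outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  stage_log(cfg$outdir, "report", t0, list(provenance_hash = provenance))
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat("  outputs:", length(x$outputs), "files\n")
  cat("  provenance:", x$provenance_hash, "\n")
  cat("  signed synergy scores:\n")
  print(round(x$heatmap, 4))
  invisible(x)
}
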