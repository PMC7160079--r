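# Assembly of all metrics into a single machine-readable QA report.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  config$seed <- config$seed %||% 1L
  if (is.null(config$metrics) || !length(config$metrics))
    stop("config requests no metrics")
  config
}

# fetch the input volume for a metric: an explicit path, or the standard
# synthetic fixture when `simulate: true`
metric_volume <- function(sec, metric, seed, simulator) {
  if (isTRUE(sec$simulate)) return(simulator(seed))
  if (is.null(sec$input))
    stop("missing input for requested metric: ", metric)
  read_volume(sec$input)
}

#' Run a full QA report
#'
#' Executes the requested metrics and writes a JSON report plus per-metric
#' CSV curves under `out_dir`. Each metric section either names an `input`
#' volume (path base as for [read_volume()]) or sets `simulate: true` to run
#' on the standard synthetic fixture seeded from the config `seed`, which
#' makes the whole pipeline re-runnable byte-identically.
#'
#' Supported metric keys: `mtf_wire`, `mtf_edge`, `ssp`, `nps`,
#' `uniformity`, `hu`, `lowcontrast`, `dosematch`.
#'
#' @param config A list, or the path of a YAML file. Top level: `out_dir`,
#'   `seed` (default 1), `metrics` (named list of sections; each may carry
#'   metric-specific options).
#' @return The report (class `qa_report`), invisibly; side effect: files
#'   under `out_dir`.
#' @export
run_report <- function(config) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("ctiq")),
    seed = cfg$seed,
    metrics_requested = names(cfg$metrics),
    inputs = lapply(cfg$metrics, function(s) s$input %||% "simulated"),
    options = cfg$metrics
  ))
  m <- cfg$metrics
  seed <- cfg$seed
  csv <- function(df, name)
    utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
  mtf_summary <- function(curve) {
    pct <- function(p) tryCatch(mtf_percent_frequency(curve, p),
                                error = function(e) NA_real_)
    list(f90 = pct(90), f50 = pct(50), f10 = pct(10), f2 = pct(2))
  }

  if (!is.null(m$mtf_wire)) {
    sec <- m$mtf_wire
    vol <- metric_volume(sec, "mtf_wire", seed, function(s)
      simulate_wire_image(phantom_truth(rng_seed = s)))
    curve <- mtf_from_wire(vol, opts = sec$opts %||% list(crop = 128L,
                                                          pad = 512L,
                                                          annulus = c(48, 60)))
    csv(data.frame(frequency = curve$frequencies,
                   modulation = curve$modulation), "mtf_wire.csv")
    report$mtf_wire <- mtf_summary(curve)
  }
  if (!is.null(m$mtf_edge)) {
    sec <- m$mtf_edge
    vol <- metric_volume(sec, "mtf_edge", seed, function(s)
      simulate_rod_image(phantom_truth(rng_seed = s)))
    curve <- mtf_from_circular_edge(vol, opts = sec$opts %||% list())
    csv(data.frame(frequency = curve$frequencies,
                   modulation = curve$modulation), "mtf_edge.csv")
    report$mtf_edge <- mtf_summary(curve)
  }
  if (!is.null(m$ssp)) {
    sec <- m$ssp
    vol <- metric_volume(sec, "ssp", seed, function(s)
      simulate_foil_stack(phantom_truth(rng_seed = s), z_increment = 0.1,
                          z_extent = 4))
    curve <- ssp_from_foil(vol)
    csv(data.frame(z = curve$z, response = curve$response), "ssp.csv")
    report$ssp <- list(fwhm_mm = curve$fwhm)
  }
  if (!is.null(m$nps)) {
    sec <- m$nps
    vols <- if (isTRUE(sec$simulate)) {
      tr <- phantom_truth(rng_seed = seed, noise_kernel = dog_kernel())
      list(simulate_noise_volume(tr, n_slices = 2L),
           simulate_noise_volume(tr, n_slices = 2L, seed_offset = 1L))
    } else if (!is.null(sec$inputs)) {
      lapply(sec$inputs, read_volume)
    } else stop("missing input for requested metric: nps")
    roi_spec <- sec$roi %||% list(size = 64L)
    opts <- sec$opts %||% list(slice_gap = 1L, max_slices = 2L)
    un <- nps_2d(vols, roi_spec, opts, mode = "unsubtracted")
    csv(un$nps1d, "nps_unsubtracted.csv")
    report$nps <- list(noise_sd = un$noise_sd,
                       peak_frequency = un$peak_frequency,
                       n_rois = un$n_rois)
    if (length(vols) >= 2) {
      su <- nps_2d(vols, roi_spec, opts, mode = "subtracted")
      csv(su$nps1d, "nps_subtracted.csv")
      report$nps$peak_frequency_subtracted <- su$peak_frequency
    }
  }
  if (!is.null(m$uniformity)) {
    sec <- m$uniformity
    vol <- metric_volume(sec, "uniformity", seed, function(s)
      simulate_noise_volume(phantom_truth(rng_seed = s,
                                          noise_sigma_white = 5),
                            grid_size = 360L, pixel_pitch = 1))
    rep_u <- uniformity_test(vol,
                             phantom_diameter = sec$phantom_diameter %||% 320,
                             roi_diameter = sec$roi_diameter %||% 32,
                             limit = sec$limit %||% 5)
    report$uniformity <- list(centre_mean = rep_u$centre_mean,
                              diffs = as.list(rep_u$diffs),
                              limit = rep_u$limit, pass = rep_u$pass)
  }
  if (!is.null(m$hu)) {
    sec <- m$hu
    vol <- metric_volume(sec, "hu", seed, function(s)
      simulate_insert_module(phantom_truth(rng_seed = s), noise = TRUE))
    layout <- if (!is.null(sec$layout)) as.data.frame(sec$layout)
              else if (!is.null(vol$truth$insert_layout)) vol$truth$insert_layout
              else stop("missing input for requested metric: hu (no layout)")
    meas <- measure_insert_hu(vol, layout,
                              roi_diameter = sec$roi_diameter %||% 10)
    chk <- ct_number_check(meas)
    report$hu <- lapply(seq_len(nrow(chk)), function(i)
      list(material = chk$material[i], value = chk$value[i],
           lo = chk$lo[i], hi = chk$hi[i], pass = chk$pass[i]))
  }
  if (!is.null(m$lowcontrast)) {
    sec <- m$lowcontrast
    vol <- metric_volume(sec, "lowcontrast", seed, function(s)
      simulate_low_contrast_module(phantom_truth(rng_seed = s)))
    layout <- if (!is.null(sec$layout)) as.data.frame(sec$layout)
              else if (!is.null(vol$truth$lc_layout)) vol$truth$lc_layout
              else stop("missing input for requested metric: lowcontrast ",
                        "(no layout)")
    cnr <- measure_object_cnr(vol, layout)
    vis <- count_visible(cnr, rule_threshold = sec$rule_threshold %||% 4)
    report$lowcontrast <- list(counts = as.list(vis$counts),
                               score = visibility_score(vis),
                               rule_threshold = vis$rule_threshold)
  }
  if (!is.null(m$dosematch)) {
    sec <- m$dosematch
    need <- c("doses", "scores", "reference_score", "base_dose")
    if (!all(need %in% names(sec)))
      stop("missing input for requested metric: dosematch")
    dm <- dose_match(as.numeric(sec$doses), as.numeric(sec$scores),
                     sec$reference_score, sec$base_dose)
    report$dosematch <- list(matched_dose = dm$matched_dose,
                             percent_increase = dm$percent_increase,
                             reached = dm$reached)
  }

  class(report) <- "qa_report"
  jsonlite::write_json(unclass(report), file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

#' Validate a QA report against the shipped schema
#'
#' Structural validation (required keys and value types) driven by the JSON
#' schema at `inst/schema/qa-report-schema.json`.
#'
#' @param report A `qa_report` object, a list, or the path of a report.json.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  report <- unclass(report)
  schema <- jsonlite::read_json(system.file("schema",
                                            "qa-report-schema.json",
                                            package = "ctiq"),
                                simplifyVector = FALSE)
  check <- function(obj, sch, path) {
    type <- sch$type
    ok <- switch(type,
                 object = is.list(obj),
                 number = is.numeric(obj) || is.null(obj),
                 integer = is.numeric(obj),
                 string = is.character(obj),
                 boolean = is.logical(obj),
                 array = is.list(obj) || is.vector(obj),
                 TRUE)
    if (!ok) stop("report field ", path, " is not of type ", type)
    if (type == "object" && !is.null(sch$required))
      for (k in sch$required)
        if (is.null(obj[[k]]))
          stop("report is missing required field ", path, ".", k)
    if (type == "object" && !is.null(sch$properties))
      for (k in names(sch$properties))
        if (!is.null(obj[[k]]))
          check(obj[[k]], sch$properties[[k]], paste0(path, ".", k))
  }
  check(report, schema, "$")
  invisible(TRUE)
}
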