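#' Analysis configuration
#'
#' Flat configuration for a full report run: input data path, predictive
#' criteria, bootstrap settings, output directory and seed. Configurations
#' round-trip losslessly through a flat `key = value` text file
#' ([read_config()] / [write_config()]).
#'
#' @param input path to a score/label CSV or TSV (see [read_scores()]).
#' @param output_dir directory for the report bundle (created if absent).
#' @param prevalence,ppv_c,npv_c,sn_min,sp_min criteria fields as in
#'   [predictive_criteria()].
#' @param boot number of bootstrap replicates (0 disables the bootstrap).
#' @param level confidence level for the bootstrap band.
#' @param seed integer seed.
#' @param digits decimal places for the human-readable `display` block.
#' @return A list classed `"analysis_config"`.
#' @export
analysis_config <- function(input, output_dir = ".", prevalence,
                            ppv_c = NULL, npv_c = NULL,
                            sn_min = NULL, sp_min = NULL,
                            boot = 2000L, level = 0.95, seed = 1L,
                            digits = 3L) {
  cfg <- list(input = input, output_dir = output_dir, prevalence = prevalence,
              ppv_c = ppv_c, npv_c = npv_c, sn_min = sn_min, sp_min = sp_min,
              boot = as.integer(boot), level = level, seed = as.integer(seed),
              digits = as.integer(digits))
  # validate criteria eagerly
  invisible(predictive_criteria(prevalence, ppv_c, npv_c, sn_min, sp_min))
  structure(cfg, class = "analysis_config")
}

#' Read / write a flat key = value configuration file
#'
#' @param path file path.
#' @return [read_config()] returns an `analysis_config`.
#' @rdname config_io
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  num <- c("prevalence", "ppv_c", "npv_c", "sn_min", "sp_min",
           "boot", "level", "seed", "digits")
  args <- stats::setNames(as.list(vals), trimws(keys))
  for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
  do.call(analysis_config, args)
}

#' @param config an `analysis_config`.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  flat <- config[!vapply(config, is.null, logical(1))]
  writeLines(paste(names(flat), unlist(flat), sep = " = "), path)
  invisible(path)
}

json_number_block <- function(x, digits) {
  list(value = x, display = report_round(x, digits))
}

#' Run a full compliance report
#'
#' Ties all modules together: reads the scores, fits the ROC curve, builds
#' the isolines and success region, evaluates compliance (with and without
#' bootstrap uncertainty), selects rule-in and/or rule-out thresholds, and
#' writes a machine-readable bundle to the output directory:
#' `roc.csv` (operating points), `geometry.csv` (isoline segments and region
#' vertices), `geometry.json`, `compliance.json`, `thresholds.json`,
#' `band.csv` (when bootstrapped) and `summary.txt`. JSON payloads carry a
#' `schema_version` field, full-precision values and a rounded `display`
#' block; outputs are byte-identical across runs with the same configuration.
#'
#' @param config an [analysis_config()].
#' @return The report bundle, invisibly (a list with the fitted objects and
#'   output paths).
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  data <- read_scores(config$input)
  criteria <- predictive_criteria(config$prevalence, config$ppv_c,
                                  config$npv_c, config$sn_min, config$sp_min)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  curve <- roc_curve(data)
  write_roc(curve, out("roc.csv"))

  region <- success_region(criteria)
  geom <- list()
  if (!is.null(criteria$ppv_c)) {
    l <- suppressWarnings(equi_ppv_line(criteria$ppv_c, criteria$p))
    geom$equi_ppv <- l
  }
  if (!is.null(criteria$npv_c)) {
    l <- suppressWarnings(equi_npv_line(criteria$npv_c, criteria$p))
    geom$equi_npv <- l
  }
  geo_rows <- do.call(rbind, c(
    lapply(geom, function(l) {
      if (is.null(l$segment)) return(NULL)
      data.frame(kind = l$kind, x = l$segment[, 1], y = l$segment[, 2])
    }),
    list(if (!region$empty)
      data.frame(kind = "region-vertex",
                 x = region$vertices[, 1], y = region$vertices[, 2]))))
  utils::write.csv(geo_rows, out("geometry.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    schema_version = 1L,
    isolines = lapply(geom, function(l)
      list(kind = l$kind, slope = l$slope, intercept = l$intercept,
           p = l$p, cutoff = l$cutoff)),
    region_vertices = if (region$empty) list() else
      as.data.frame(region$vertices)),
    out("geometry.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- roc_meets_criteria(curve, criteria)
  comp <- list(schema_version = 1L, seed = config$seed,
               meets = report$meets,
               auroc = json_number_block(curve$auc, config$digits),
               best_ppv = json_number_block(report$best_ppv, config$digits),
               best_npv = json_number_block(report$best_npv, config$digits),
               each_criterion = report$each_criterion)
  if (config$boot > 0L) {
    ci <- compliance_with_ci(data, criteria, B = config$boot,
                             level = config$level, seed = config$seed)
    comp$bootstrap <- list(verdict = ci$verdict,
                           replicate_fraction =
                             json_number_block(ci$replicate_fraction,
                                               config$digits),
                           B = config$boot, level = config$level)
    utils::write.csv(ci$band$band, out("band.csv"), row.names = FALSE)
  } else ci <- NULL
  jsonlite::write_json(comp, out("compliance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  choices <- list()
  if (!is.null(criteria$ppv_c))
    choices$rule_in <- select_rule_in_threshold(curve, criteria)
  if (!is.null(criteria$npv_c))
    choices$rule_out <- select_rule_out_threshold(curve, criteria)
  choices$youden <- youden_threshold(curve, criteria$p)
  choices$closest_corner <- closest_corner_threshold(curve, criteria$p)
  jsonlite::write_json(list(
    schema_version = 1L,
    choices = lapply(choices, function(ch)
      list(rule = ch$rule, threshold = ch$threshold, feasible = ch$feasible,
           sn = json_number_block(ch$sn, config$digits),
           sp = json_number_block(ch$sp, config$digits),
           ppv = json_number_block(ch$ppv, config$digits),
           npv = json_number_block(ch$npv, config$digits)))),
    out("thresholds.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  con <- file(out("summary.txt"), "w")
  sink(con)
  print(curve); print(criteria); print(report)
  if (!is.null(ci)) print(ci)
  for (ch in choices) print(ch)
  sink(); close(con)

  invisible(list(curve = curve, criteria = criteria, compliance = report,
                 bootstrap = ci, thresholds = choices,
                 paths = vapply(c("roc.csv", "geometry.csv", "geometry.json",
                                  "compliance.json", "thresholds.json",
                                  "summary.txt"), out, "")))
}
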