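# End-to-end orchestration: config parsing, group summaries, association
# tables, QC flags and a reproducible plain-text run report.

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Recognised keys:
#' `seed`, `out_dir`, `cohort_csv` (omit to simulate), `n`, `n_clinic`,
#' `models` (comma-separated subset of `anthro`, `bmi-adj-nat`,
#' `three-comp`), `exclude_clinic` (true/false), `ff_threshold`, `rays`,
#' `phantom_demo`, `waveform_demo` (true/false stage toggles).
#'
#' @param path config file.
#' @return validated config list of class `run_config` (with `config_hash`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop_validation("malformed config line: ", lines[bad][1])
  cfg <- stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
    trimws(vapply(kv, `[[`, "", 1)))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of raw (character) config values.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(seed = "1", out_dir = tempfile("bodycomp3_run_"),
                   cohort_csv = "", n = "82", n_clinic = "3",
                   models = "anthro,bmi-adj-nat,three-comp",
                   exclude_clinic = "true", ff_threshold = "0.5", rays = "360",
                   phantom_demo = "false", waveform_demo = "false")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop_validation("unknown config key(s): ",
                                       paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  out <- list(
    seed = as.integer(cfg$seed), out_dir = cfg$out_dir,
    cohort_csv = cfg$cohort_csv, n = as.integer(cfg$n),
    n_clinic = as.integer(cfg$n_clinic),
    models = trimws(strsplit(cfg$models, ",")[[1]]),
    exclude_clinic = tolower(cfg$exclude_clinic) %in% c("true", "1", "yes"),
    ff_threshold = as.numeric(cfg$ff_threshold), rays = as.integer(cfg$rays),
    phantom_demo = tolower(cfg$phantom_demo) %in% c("true", "1", "yes"),
    waveform_demo = tolower(cfg$waveform_demo) %in% c("true", "1", "yes"))
  bad_models <- setdiff(out$models, c("anthro", "bmi-adj-nat", "three-comp"))
  if (length(bad_models)) stop_validation("unknown model name(s): ",
                                          paste(bad_models, collapse = ", "))
  if (nzchar(out$cohort_csv) && !file.exists(out$cohort_csv)) {
    stop_validation("cohort_csv does not exist: ", out$cohort_csv)
  }
  canon <- paste(sprintf("%s=%s", names(cfg)[order(names(cfg))],
                         unlist(cfg)[order(names(cfg))]), collapse = "\n")
  tf <- tempfile(); writeLines(canon, tf)
  out$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  structure(out, class = "run_config")
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

# display precision: one digit beyond a value's natural scale
digits_for <- function(x) {
  m <- stats::median(abs(x[is.finite(x) & x != 0]))
  if (!is.finite(m) || m >= 100) 1L else if (m >= 10) 1L else if (m >= 1) 2L else 3L
}

#' Group-comparison summary table (median and IQR by weight status)
#'
#' One row per variable: `median (IQR)` per group, preceded by count rows
#' formatted `n (percent)` with integer percentages. Empty groups are flagged
#' and their summaries omitted; single-subject groups are flagged as
#' degenerate IQRs.
#'
#' @param cohort cohort data.frame with a `weight_status` column.
#' @param variables variables to summarize (defaults to the standard
#'   anthropometric + cardiovascular set present in the cohort).
#' @param groups weight-status groups to compare.
#' @return data.frame of class `group_summary` with attribute `flags`.
#' @export
summarize_groups <- function(cohort, variables = NULL,
                             groups = c("normal", "overweight/obese")) {
  if (!"weight_status" %in% names(cohort)) {
    stop_validation("cohort needs a weight_status column")
  }
  variables <- variables %||% intersect(
    c("age", "height", "weight", "bsa", "bmi", "bmi_z", "waist", "waist_z",
      "waist_height_z", "nat", "sat", "vat", cardiovascular_outcomes()),
    names(cohort))
  flags <- character()
  total <- nrow(cohort)
  out <- data.frame(variable = c("n_pct", variables))
  for (g in groups) {
    rows <- cohort$weight_status == g
    ng <- sum(rows, na.rm = TRUE)
    col <- character(length(variables) + 1L)
    col[1] <- sprintf("%d (%d)", ng, round(100 * ng / total))
    if (ng == 0L) {
      flags <- c(flags, paste0("empty_group:", g))
      col[-1] <- NA_character_
    } else {
      if (ng == 1L) flags <- c(flags, paste0("degenerate_iqr:", g))
      for (i in seq_along(variables)) {
        v <- cohort[[variables[i]]][rows]
        dg <- digits_for(cohort[[variables[i]]])
        qs <- stats::quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7)
        col[i + 1L] <- sprintf("%s (%s to %s)", fmt_num(qs[1], dg),
                               fmt_num(qs[2], dg), fmt_num(qs[3], dg))
      }
    }
    out[[g]] <- col
  }
  class(out) <- c("group_summary", "data.frame")
  attr(out, "flags") <- flags
  out
}

#' Run the full pipeline from a configuration
#'
#' Simulates (or loads) a cohort, derives anthropometric columns if absent,
#' fits every requested association model (with the clinic-recruit
#' sensitivity re-run when configured), optionally demonstrates the
#' segmentation and PWV stages on seeded synthetic inputs, and writes all
#' tables plus a provenance run log to `out_dir`. Deterministic for a fixed
#' config + seed; report bodies carry no timestamps.
#'
#' @param config a `run_config` (from [read_run_config()] /
#'   [validate_run_config()]) or a path to a config file.
#' @return list of class `run_report`: `cohort`, `group_summary`,
#'   `associations` (one table per model), `sensitivity`, `qc_flags`,
#'   `provenance`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- character()

  cohort <- if (nzchar(config$cohort_csv)) {
    read_cohort(config$cohort_csv)
  } else {
    generate_cohort(cohort_spec(n = config$n, n_clinic = config$n_clinic,
                                seed = config$seed))
  }
  if (!"weight_status" %in% names(cohort)) cohort <- anthro_augment(cohort)
  excl <- cohort$weight_status == "underweight/out-of-range"
  if (any(excl)) {
    qc <- c(qc, sprintf("excluded_underweight:%s",
                        paste(cohort$id[excl], collapse = ",")))
  }

  gs <- summarize_groups(cohort)
  qc <- c(qc, attr(gs, "flags"))

  assoc <- lapply(stats::setNames(config$models, config$models), function(m) {
    association_grid(cohort, m)
  })
  sens <- if (config$exclude_clinic && "clinic_recruit" %in% names(cohort)) {
    sensitivity_exclude(cohort, "clinic_recruit",
                        model = config$models[length(config$models)])
  }

  demo <- list()
  if (config$phantom_demo) {
    ph <- generate_phantom(phantom_spec(
      slice_count = 2L, image_size = 96L, voxel_dims = c(4, 4, 10),
      outer_semiaxes = c(150, 110), sat_thickness = 28,
      vat_blobs = list(list(center = c(25, 0), radius = 22, fat_fraction = 0.8)),
      seed = config$seed))
    seg <- segment_stack(ph$stack, ff_threshold = config$ff_threshold,
                         n_rays = config$rays)
    demo$segmentation <- data.frame(
      compartment = c("sat", "vat", "nat"),
      truth_l = c(ph$truth$sat_volume_l, ph$truth$vat_volume_l, ph$truth$nat_volume_l),
      recovered_l = c(seg$sat_volume_l, seg$vat_volume_l, seg$nat_volume_l))
    qc <- c(qc, seg$flags)
  }
  if (config$waveform_demo) {
    wf <- generate_waveform(waveform_spec(seed = config$seed))
    demo$pwv <- data.frame(true_pwv = attr(wf, "true_pwv"),
                           estimated_pwv = as.numeric(pwv_qa(wf)))
  }

  prov <- c(sprintf("package=bodycomp3 %s",
                    as.character(utils::packageVersion("bodycomp3"))),
            sprintf("config_hash=%s", config$config_hash),
            sprintf("seed=%d", config$seed),
            sprintf("n=%d", nrow(cohort)),
            sprintf("models=%s", paste(config$models, collapse = ",")))

  paths <- c(cohort = file.path(config$out_dir, "cohort.csv"),
             group_summary = file.path(config$out_dir, "group_summary.csv"),
             run_log = file.path(config$out_dir, "run_log.txt"))
  write_cohort(cohort, paths["cohort"])
  utils::write.csv(as.data.frame(gs), paths["group_summary"], row.names = FALSE)
  for (m in names(assoc)) {
    p <- file.path(config$out_dir, sprintf("associations_%s.csv", m))
    utils::write.csv(as.data.frame(assoc[[m]]), p, row.names = FALSE)
    paths[paste0("associations_", m)] <- p
  }
  if (!is.null(sens)) {
    p <- file.path(config$out_dir, "sensitivity_comparison.csv")
    utils::write.csv(sens$comparison, p, row.names = FALSE)
    paths["sensitivity"] <- p
  }
  writeLines(c(prov, sprintf("qc_flag=%s", qc)), paths["run_log"])

  structure(class = "run_report", list(
    cohort = cohort, group_summary = gs, associations = assoc,
    sensitivity = sens, demo = demo, qc_flags = qc, provenance = prov,
    paths = paths, config = config))
}
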