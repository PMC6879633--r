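#' Run the per-variant analysis pipeline
#'
#' Reads a YAML or JSON configuration listing protein variants and the
#' data files available for each, runs every configured analysis stage
#' (shift classification, directional Arrhenius fits and behavior calls,
#' dimer Kd, chemical/thermal stability, rotamer transition counting),
#' and assembles one report row per variant. Stages whose inputs are not
#' configured are marked "not measured"; a stage that fails is recorded
#' as an error string for that variant and the remaining variants are
#' still processed. Referenced files are checked upfront and a missing
#' path is an error naming that path.
#'
#' Configuration keys: `seed`, `threshold_ppm`, `min_dwell`, and a
#' `variants` list whose entries have `name`, `mutations`, and optional
#' paths `shifts`, `rates`, `titration`, `chemical`, `thermal`,
#' `dihedrals`, plus `probe_residue` (default `"W43e"`) and
#' `reporter_residue` (default `"T17"`).
#'
#' @param config path to a YAML/JSON config file, or an equivalent list
#' @param out_dir optional output directory; when given, the report is
#'   written as both TSV and JSON together with a JSON-lines run log
#' @return a `variant_report_set`: list of per-variant report rows plus
#'   the settings used
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  } else {
    base <- config$base_dir %||% "."
  }
  if (is.null(config$variants) || length(config$variants) == 0)
    stop("config lists no variants")
  seed <- config$seed %||% 1L
  threshold <- config$threshold_ppm %||% 0.6
  min_dwell <- config$min_dwell %||% 1L

  resolve <- function(path) {
    if (is.null(path)) return(NULL)
    p <- if (file.exists(path)) path else file.path(base, path)
    if (!file.exists(p)) stop("referenced file not found: ", path)
    p
  }
  # upfront existence check for every referenced file
  for (v in config$variants)
    for (key in c("shifts", "rates", "titration", "chemical", "thermal",
                  "dihedrals"))
      resolve(v[[key]])

  reports <- lapply(config$variants, function(v) {
    acc <- new.env(parent = emptyenv())
    acc$variant <- v$name %||% "unnamed"
    acc$mutations <- v$mutations %||% ""
    probe <- v$probe_residue %||% "W43e"
    reporter <- v$reporter_residue %||% "T17"
    for (fld in c("delta_delta_ppm", "Ea_fwd", "Ea_fwd_se", "Ea_rev",
                  "Ea_rev_se", "Kd_M", "Kd_se_M", "Cm_M", "m_value",
                  "dG_U", "Tm_C", "n_transitions", "n_chi1_transitions",
                  "mean_rmsf_A"))
      assign(fld, NA_real_, envir = acc)   # "not measured" marker
    acc$exchange_mode <- NA_character_
    acc$behavior <- NA_character_
    acc$reporter_consistent <- NA
    acc$errors <- character(0)

    run_stage <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        acc$errors <- c(acc$errors, paste0(label, ": ", conditionMessage(e)))
        NULL
      })
    }

    if (!is.null(v$shifts)) run_stage("shifts", {
      pairs <- read_shifts_tsv(resolve(v$shifts))
      labs <- vapply(pairs, function(p) p$residue_label, character(1))
      pair <- pairs[[match(probe, labs)]]
      mode_call <- classify_mode(pair, threshold = threshold)
      acc$delta_delta_ppm <- mode_call$delta_delta
      acc$exchange_mode <- mode_call$mode
    })

    if (!is.null(v$rates)) run_stage("rates", {
      series <- read_rates_tsv(resolve(v$rates))
      pick <- function(res, dir) {
        key <- paste(res, dir)
        if (key %in% names(series)) series[[key]] else NULL
      }
      pf <- pick(probe, "1->2"); pr <- pick(probe, "2->1")
      if (is.null(pf) || is.null(pr))
        stop("probe residue ", probe, " needs both transition directions")
      ff <- fit_arrhenius(pf); fr <- fit_arrhenius(pr)
      rf <- pick(reporter, "1->2"); rr <- pick(reporter, "2->1")
      beh <- classify_behavior(ff, fr,
                               if (is.null(rf)) NULL else fit_arrhenius(rf),
                               if (is.null(rr)) NULL else fit_arrhenius(rr))
      acc$Ea_fwd <- ff$Ea_app; acc$Ea_fwd_se <- ff$Ea_stderr
      acc$Ea_rev <- fr$Ea_app; acc$Ea_rev_se <- fr$Ea_stderr
      acc$behavior <- beh$behavior
      acc$reporter_consistent <- beh$reporter_consistent
    })

    if (!is.null(v$titration)) run_stage("titration", {
      fit <- fit_kd(read_titration_tsv(resolve(v$titration)))
      if (fit$identifiable) {
        acc$Kd_M <- fit$Kd
        acc$Kd_se_M <- fit$Kd_stderr
      }
    })

    if (!is.null(v$chemical)) run_stage("chemical", {
      fit <- fit_chemical(read_denaturation_csv(resolve(v$chemical)))
      acc$Cm_M <- fit$midpoint
      acc$m_value <- fit$m_value
      acc$dG_U <- fit$dG_U
    })

    if (!is.null(v$thermal)) run_stage("thermal", {
      fit <- fit_thermal(read_denaturation_csv(resolve(v$thermal)))
      acc$Tm_C <- fit$midpoint
    })

    if (!is.null(v$dihedrals)) run_stage("dihedrals", {
      series <- read_dihedral_tsv(resolve(v$dihedrals))
      states <- assign_rotamer_states(series)
      acc$n_transitions <- count_transitions(states, min_dwell = min_dwell)
      acc$n_chi1_transitions <- count_transitions(states,
                                                  min_dwell = min_dwell,
                                                  dihedral = "chi1")
    })

    out <- as.list(acc)
    out[intersect(.report_columns, names(out))]
  })

  out <- structure(list(reports = reports,
                        settings = list(seed = seed,
                                        threshold_ppm = threshold,
                                        min_dwell = min_dwell)),
                   class = "variant_report_set")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(out, file.path(out_dir, "variant_report.tsv"), "tsv")
    write_report(out, file.path(out_dir, "variant_report.json"), "json")
    log_lines <- c(
      jsonlite::toJSON(list(event = "run", package = "confex",
                            version = as.character(utils::packageVersion("confex")),
                            seed = seed, n_variants = length(reports)),
                       auto_unbox = TRUE))
    writeLines(log_lines, file.path(out_dir, "run_log.jsonl"))
  }
  out
}

# fixed column order of the variant report
.report_columns <- c("variant", "mutations", "delta_delta_ppm",
                     "exchange_mode", "Ea_fwd", "Ea_fwd_se", "Ea_rev",
                     "Ea_rev_se", "behavior", "reporter_consistent",
                     "Kd_M", "Kd_se_M", "Cm_M", "m_value", "dG_U", "Tm_C",
                     "n_transitions", "n_chi1_transitions", "mean_rmsf_A",
                     "errors")

#' Write a variant report
#'
#' TSV output uses a stable column order with numeric fields formatted to
#' 4 significant digits and absent measurements written as
#' `not_measured`; JSON output round-trips losslessly.
#'
#' @param report_set a `variant_report_set` from [run_pipeline()]
#' @param file output path
#' @param format `"tsv"` or `"json"`
#' @return the output path, invisibly
#' @export
write_report <- function(report_set, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  reports <- if (inherits(report_set, "variant_report_set"))
    report_set$reports else report_set
  if (length(reports) == 0) stop("report collection is empty")
  if (format == "json") {
    jsonlite::write_json(reports, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    return(invisible(file))
  }
  fmt <- function(x) {
    if (length(x) == 0) return("")
    if (is.character(x)) return(paste(x, collapse = "; "))
    if (is.na(x)) return("not_measured")
    if (is.logical(x)) return(as.character(x))
    if (is.numeric(x)) return(format(signif(x, 4), trim = TRUE))
    as.character(x)
  }
  rows <- vapply(reports, function(r)
    paste(vapply(.report_columns, function(cn) fmt(r[[cn]]), character(1)),
          collapse = "\t"), character(1))
  writeLines(c(paste(.report_columns, collapse = "\t"), rows), file)
  invisible(file)
}

#' @export
print.variant_report_set <- function(x, ...) {
  cat(sprintf("Variant report: %d variants (seed %s, threshold %.2f ppm)\n",
              length(x$reports), x$settings$seed, x$settings$threshold_ppm))
  for (r in x$reports) {
    cat(sprintf("  %-16s mode=%s behavior=%s Kd=%s dG_U=%s\n",
                r$variant,
                r$exchange_mode %||% "?",
                if (is.na(r$behavior %||% NA)) "not_measured" else r$behavior,
                if (is.na(r$Kd_M)) "not_measured" else sprintf("%.3g M", r$Kd_M),
                if (is.na(r$dG_U)) "not_measured" else sprintf("%.3g", r$dG_U)))
    if (length(r$errors)) cat("    errors: ", paste(r$errors, collapse = "; "), "\n")
  }
  invisible(x)
}
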