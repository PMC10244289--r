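# Report generation: result-table export (CSV/JSON), run manifests, and a
# programmatic command dispatcher orchestrating the standard analyses.

#' Run manifest
#'
#' Captures everything needed to attribute an emitted report to one model
#' run: the full configuration, the provenance mix of each parameter table,
#' the seed, package version and a timestamp.
#'
#' @param params A `parameter_set`.
#' @param config A [model_config()].
#' @return A list ready for JSON serialisation.
#' @export
run_manifest <- function(params, config) {
  prov <- lapply(params[PARAM_TABLES], function(tb) {
    if ("provenance" %in% names(tb)) {
      as.list(table(tb$provenance))
    } else {
      list(unspecified = nrow(tb))
    }
  })
  list(
    package = "gdmcea",
    version = as.character(utils::packageVersion("gdmcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$rng_seed,
    config = unclass(config),
    provenance = prov
  )
}

comparison_table <- function(result) {
  stopifnot(inherits(result, "cea_comparison"))
  rows <- dplyr::select(result$arms, -"key")
  extra <- tibble(
    outcome = c("Incremental QALYs per woman", "Incremental cost per woman",
                "ICER", "ROI ratio"),
    usual_care = NA_real_,
    intervention = NA_real_,
    incremental = c(result$per_woman$delta_qaly, result$per_woman$delta_cost,
                    result$icer, result$roi)
  )
  out <- bind_rows(rows, extra)
  out$label <- NA_character_
  out$label[out$outcome == "ICER"] <- result$icer_label
  out
}

round_presentation <- function(tb) {
  num <- vapply(tb, is.numeric, logical(1))
  tb[num] <- lapply(tb[num], function(x) {
    ifelse(abs(x) >= 100, round(x), signif(x, 3))
  })
  tb
}

#' Export result tables
#'
#' Writes a result object as CSV and JSON with fixed column order and
#' deterministic bytes: a full-precision CSV, a rounded presentation variant
#' (`*_rounded.csv`), and a JSON document. Supported inputs: a
#' `cea_comparison` (outcome/cost-category rows with ICER and ROI, the shape
#' of a published results table), a `cea_psa` (per-iteration plane
#' coordinates as CSV; quadrant fractions and percentile CIs as JSON), a
#' `cea_tornado` or a `cea_sweep`.
#'
#' @param result A result object.
#' @param path Output path prefix (without extension); directories are
#'   created as needed.
#' @param formats Subset of `c("csv", "json")`.
#' @return Character vector of files written, invisibly.
#' @export
export_tables <- function(result, path, formats = c("csv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit_csv <- function(tb, suffix = "") {
    f <- paste0(path, suffix, ".csv")
    readr::write_csv(tb, f, progress = FALSE)
    files <<- c(files, f)
    fr <- paste0(path, suffix, "_rounded.csv")
    readr::write_csv(round_presentation(tb), fr, progress = FALSE)
    files <<- c(files, fr)
  }
  emit_json <- function(obj) {
    f <- paste0(path, ".json")
    jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <<- c(files, f)
  }
  if (inherits(result, "cea_comparison")) {
    tb <- comparison_table(result)
    if ("csv" %in% formats) emit_csv(tb)
    if ("json" %in% formats) {
      emit_json(list(
        table = tb, icer = result$icer, icer_label = result$icer_label,
        roi = result$roi, per_woman = result$per_woman,
        total_births = result$total_births
      ))
    }
  } else if (inherits(result, "cea_psa")) {
    if ("csv" %in% formats) emit_csv(result$iterations)
    if ("json" %in% formats) {
      emit_json(list(
        n_iterations = result$n_iterations, n_resampled = result$n_resampled,
        seed = result$seed, quadrants = result$quadrants, ci = result$ci
      ))
    }
  } else if (inherits(result, "cea_tornado")) {
    if ("csv" %in% formats) emit_csv(as_tibble(result))
    if ("json" %in% formats) emit_json(list(tornado = as_tibble(result)))
  } else if (inherits(result, "cea_sweep")) {
    if ("csv" %in% formats) emit_csv(result$curve)
    if ("json" %in% formats) {
      emit_json(list(curve = result$curve, roots = result$roots,
                     wtp = result$wtp))
    }
  } else {
    abort("Unsupported result type for export.")
  }
  invisible(files)
}

#' Programmatic analysis dispatcher
#'
#' Runs one of the standard analyses end to end and writes its artifacts
#' (result CSV/JSON plus a `manifest.json`) to an output directory. Commands:
#' `"synth"` (write a synthetic parameter bundle), `"run"` (two-arm
#' comparison), `"psa"`, `"dsa"`, `"sweep-rr"` (scenario-2 sweep) and
#' `"threshold-cost"`.
#'
#' @param command One of the commands above.
#' @param params A `parameter_set` (defaults to the packaged reference
#'   bundle; ignored by `"synth"`).
#' @param config A [model_config()].
#' @param out_dir Output directory.
#' @param ... Passed to the underlying analysis function
#'   ([generate_synthetic_bundle()], [run_psa()], etc.).
#' @return The result object, invisibly.
#' @export
run_analysis <- function(command = c("run", "synth", "psa", "dsa", "sweep-rr",
                                     "threshold-cost"),
                         params = NULL, config = model_config(),
                         out_dir, ...) {
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(params) && command != "synth") {
    params <- load_reference_fixture()
  }
  result <- switch(command,
    synth = {
      bundle <- generate_synthetic_bundle(
        synth_spec(rng_seed = config$rng_seed, ...)
      )
      write_parameter_bundle(bundle, file.path(out_dir, "bundle"))
      bundle
    },
    run = {
      res <- run_comparison(params, config)
      export_tables(res, file.path(out_dir, "comparison"))
      res
    },
    psa = {
      res <- run_psa(params, config, ...)
      export_tables(res, file.path(out_dir, "psa"))
      res
    },
    dsa = {
      res <- one_way_dsa(params, config, ...)
      export_tables(res, file.path(out_dir, "tornado"))
      res
    },
    `sweep-rr` = {
      res <- scenario2_sweep(params, config, ...)
      export_tables(res, file.path(out_dir, "scenario2_sweep"))
      res
    },
    `threshold-cost` = {
      res <- intervention_cost_threshold(params, config, ...)
      jsonlite::write_json(
        list(threshold_cost = as.numeric(res),
             converged = isTRUE(attr(res, "converged")),
             wtp = config$wtp_threshold),
        file.path(out_dir, "threshold_cost.json"),
        auto_unbox = TRUE, digits = NA
      )
      res
    }
  )
  manifest <- run_manifest(
    if (command == "synth") result else params, config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
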