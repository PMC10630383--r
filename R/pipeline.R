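# Pipeline orchestration: run every stage end to end on a sample CSV, write
# the CSV/JSON outputs and a run manifest that makes the run reproducible.

#' Default pipeline configuration
#'
#' @param seed Master seed funnelling all randomness in the run.
#' @param mode `"both"`, `"deterministic"` or `"probabilistic"`.
#' @param n_iterations Monte Carlo iterations.
#' @param concentration_mode `"fitted"` or `"empirical"` (see [mc_config()]).
#' @param gof_pvalues Compute bootstrap AD p-values in the concentration fit?
#' @return A nested list mirroring the YAML config schema.
#' @export
default_config <- function(seed = 42L, mode = "both", n_iterations = 10000L,
                           concentration_mode = "fitted", gof_pvalues = TRUE) {
  profiles <- default_exposure_profiles()
  list(
    seed = as.integer(seed),
    mode = mode,
    mc = list(n_iterations = as.integer(n_iterations),
              concentration = concentration_mode,
              gof_pvalues = gof_pvalues),
    exposure = lapply(profiles, function(p) {
      p[c("IR_w", "EF_r", "ED", "BW", "SA", "Kp", "ET", "CF")]
    }),
    rfd = list(NO3 = 1.6, F = 0.06)
  )
}

#' Read / write a pipeline configuration
#'
#' YAML round trip of the [default_config()] schema; missing blocks fall back
#' to defaults.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config()` returns the merged configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  utils::modifyList(cfg, user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.config_profiles <- function(config) {
  lapply(names(config$exposure), function(ag) {
    do.call(exposure_profile, c(list(age_group = ag), config$exposure[[ag]]))
  }) |> stats::setNames(names(config$exposure))
}

#' Run the full analysis pipeline
#'
#' Executes charge-balance QA, descriptive statistics, standards exceedance,
#' the built-in classification schemes, deterministic and probabilistic HHRA,
#' sensitivity and uncertainty analysis, Piper/Gibbs/ionic-ratio/saturation
#' hydrochemistry and the PCA/cluster chemometrics on one sample CSV, writing
#' every result as CSV/JSON/TXT under `out_dir` plus a `manifest.json`
#' recording inputs, config hash, seed, package version, per-stage status and
#' output paths. Stage failures are recorded in the manifest and independent
#' downstream stages still run. Outputs contain no timestamps, so a rerun
#' with identical inputs and seed is byte-identical.
#'
#' @param samples Path to the sample CSV ([read_samples()] format).
#' @param config Optional path to a YAML configuration ([default_config()]
#'   schema) or a configuration list; `NULL` uses the defaults.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly, as a list of class `"run_manifest"`.
#' @export
run_pipeline <- function(samples, config = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- read_config(config)
  } else if (is.null(config)) {
    config <- default_config()
  }
  seed <- as.integer(config$seed)
  manifest <- list(
    inputs = list(samples = samples, config = cfg_path %||% "(defaults)"),
    config_hash = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                  else NA_character_,
    seed = seed,
    package_version = as.character(utils::packageVersion("aquarisk")),
    mode = config$mode,
    stages = list(),
    outputs = character(0)
  )
  if (is.null(cfg_path)) {
    tmp <- file.path(out_dir, "config_used.yaml")
    write_config(config, tmp)
    manifest$config_hash <- unname(tools::md5sum(tmp))
    manifest$outputs <- c(manifest$outputs, tmp)
  }
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, p)
    p
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    elapsed <- round(proc.time()[["elapsed"]] - t0, 2)
    ok <- !inherits(res, "error")
    message(sprintf("[aquarisk] stage %-16s %s (%.2fs)", name,
                    if (ok) "ok" else paste("FAILED:", conditionMessage(res)),
                    elapsed))
    manifest$stages[[name]] <<- if (ok) "ok" else
      paste("failed:", conditionMessage(res))
    if (ok) res else NULL
  }

  tab <- stage("read", read_samples(samples))
  if (is.null(tab)) {
    manifest$stages$read <- paste(manifest$stages$read, "(pipeline aborted)")
    class(manifest) <- "run_manifest"
    .write_manifest(manifest, out_dir)
    stop("input validation failed: ", samples)
  }
  profiles <- .config_profiles(config)
  rfd <- rfd_registry(lapply(config$rfd, function(v) list(ingestion = v, dermal = v)))

  stage("qa", {
    emit_csv(charge_balance_error(tab), "cbe.csv")
    emit_csv(descriptive_stats(tab), "stats.csv")
    emit_csv(exceedance_summary(tab), "exceedance.csv")
  })
  stage("classification", {
    schemes <- list(sawyer_mccarty_th = tab$TH, freeze_cherry_tds = tab$TDS,
                    davis_dewiest_tds = tab$TDS, ec_salinity = tab$EC,
                    adimalla_no3 = tab$NO3, adimalla_f = tab[["F"]])
    for (s in names(schemes)) {
      cl <- suppressWarnings(classify(schemes[[s]], s, tab$sample_id))
      emit_csv(cl$summary, paste0("classes_", s, ".csv"))
    }
  })
  det <- NULL
  if (config$mode %in% c("both", "deterministic")) {
    det <- stage("hhra_deterministic", {
      d <- deterministic_risk_table(tab, profiles, rfd)
      emit_csv(d, "risk_deterministic.csv")
      d
    })
  } else manifest$stages$hhra_deterministic <- "skipped"
  if (config$mode %in% c("both", "probabilistic")) {
    stage("hhra_probabilistic", {
      mc <- mc_config(n_iterations = config$mc$n_iterations, seed = seed,
                      exposure = default_exposure_specs(profiles),
                      concentration_mode = config$mc$concentration)
      fit <- hhra(tab, profiles, rfd, approach = "probabilistic", mc = mc,
                  gof_pvalues = isTRUE(config$mc$gof_pvalues))
      emit_csv(fit$probabilistic$summary, "risk_probabilistic.csv")
      emit_csv(fit$sensitivity, "sensitivity.csv")
      if (!is.null(fit$gof)) {
        gof <- do.call(rbind, lapply(names(fit$gof), function(ch) {
          cbind(parameter = ch, fit$gof[[ch]]$report,
                selected = fit$gof[[ch]]$selected)
        }))
        emit_csv(gof, "gof.csv")
      }
      writeLines(uncertainty_report(mc, profiles),
                 file.path(out_dir, "uncertainty.txt"))
      manifest$outputs <- c(manifest$outputs, file.path(out_dir, "uncertainty.txt"))
    })
  } else manifest$stages$hhra_probabilistic <- "skipped"
  stage("hydrochem", {
    pi <- piper_classify(tab)
    emit_csv(pi$samples, "piper.csv")
    emit_csv(gibbs_classify(tab), "gibbs.csv")
    emit_csv(ionic_ratios(tab), "ratios.csv")
    keep <- c("sample_id", "mineral", "ionic_strength", "si", "defined")
    si <- rbind(as.data.frame(saturation_index(tab, "fluorite"))[, keep],
                as.data.frame(saturation_index(tab, "calcite"))[, keep])
    emit_csv(si, "si.csv")
  })
  stage("chemometrics", {
    z <- zscore(tab)
    pca <- pca_varimax(z)
    load_df <- data.frame(parameter = rownames(pca$rotated),
                          round(pca$rotated, 4),
                          communality = round(pca$communalities, 4))
    emit_csv(load_df, "pca_loadings.csv")
    wc <- ward_cluster(z)
    emit_csv(data.frame(sample_id = names(wc$assignments),
                        cluster = wc$assignments), "clusters.csv")
    prof <- cluster_profile(tab, wc$assignments)
    emit_csv(cbind(parameter = rownames(prof$means), prof$means),
             "cluster_means.csv")
    dend <- list(merge = wc$hclust$merge, height = wc$hclust$height,
                 quotient = wc$quotient, order = wc$hclust$order,
                 labels = wc$hclust$labels)
    p <- file.path(out_dir, "dendrogram.json")
    jsonlite::write_json(dend, p, digits = NA)
    manifest$outputs <- c(manifest$outputs, p)
  })
  class(manifest) <- "run_manifest"
  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  p <- file.path(out_dir, "manifest.json")
  m <- unclass(manifest)
  m$outputs <- basename(m$outputs)
  jsonlite::write_json(m, p, auto_unbox = TRUE, pretty = TRUE)
  invisible(p)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", mode ", x$mode, ")\n", sep = "")
  for (s in names(x$stages)) cat("  ", format(s, width = 20), x$stages[[s]], "\n")
  cat(length(x$outputs), "output file(s)\n")
  invisible(x)
}
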