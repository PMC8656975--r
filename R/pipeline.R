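#' Round half away from zero
#'
#' Display rounding for report percentages (base R's `round` rounds half to
#' even); raw values are kept at full precision elsewhere.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Record-retention summary
#'
#' Fraction of event-level records with a resolvable tract assignment
#' (records lost to geocoding failure lack one).
#'
#' @param records data.frame with a `tract_id` column; `NA` or empty ids
#'   mark unassigned records.
#' @return list `total`, `retained`, `excluded`, `retained_pct` (full
#'   precision) and `retained_pct_display` (2 decimals, half-up).
#' @export
retention_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty table", call. = FALSE)
  ok <- !is.na(records$tract_id) & nzchar(as.character(records$tract_id))
  pct <- 100 * sum(ok) / nrow(records)
  list(total = nrow(records), retained = sum(ok), excluded = sum(!ok),
       retained_pct = pct, retained_pct_display = round_half_up(pct, 2))
}

#' Percentage of tracts beyond a threshold
#'
#' @param values per-tract statistic; `NA` (undefined) values are dropped
#'   from both numerator and denominator.
#' @param threshold cut point; the comparison is strict.
#' @param direction `"above"` or `"below"`.
#' @return percentage (full precision).
#' @export
threshold_summary <- function(values, threshold, direction = c("above", "below")) {
  direction <- match.arg(direction)
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("no defined values", call. = FALSE)
  hit <- if (direction == "above") v > threshold else v < threshold
  100 * sum(hit) / length(v)
}

#' Pipeline configuration
#'
#' @param preset `"asturias-like"` (the default synthetic study: 558 tracts,
#'   mean population 1265, ~3218 events over 3 years) or `NULL` when
#'   supplying input files.
#' @param counts,population,adjacency optional paths to a counts CSV
#'   (`tract_id,sex,age_group,value`), population CSV (same layout) and GAL
#'   adjacency file; used when `preset` is `NULL`.
#' @param model spatial prior passed to [fit_car()].
#' @param mcmc list overriding [mcmc_control()] fields (e.g.
#'   `list(n_chains = 2, n_iter = 2000)`).
#' @param joint also fit the shared-component joint model.
#' @param cluster list overriding clustering settings `style`, `n_perm`,
#'   `alpha`, and `use_joint` (cluster on joint-model SRRs instead of the
#'   per-sex fits).
#' @param null_risk preset option: flat-risk (`theta == 1`) scenario.
#' @param seed global seed; stage seeds are derived as fixed offsets.
#' @param out_dir output directory (`NULL` = no files written).
#' @param geojson also write a GeoJSON FeatureCollection with SRR/PP/LISA
#'   properties (lattice presets only).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "asturias-like", counts = NULL,
                            population = NULL, adjacency = NULL,
                            model = "bym", mcmc = list(), joint = FALSE,
                            cluster = list(), null_risk = FALSE,
                            seed = 1, out_dir = NULL, geojson = FALSE) {
  mc <- utils::modifyList(list(n_chains = 2, n_iter = 3000, n_burnin = 1000,
                               thin = 2), mcmc)
  cl <- utils::modifyList(list(style = "row", n_perm = 999, alpha = 0.05,
                               use_joint = FALSE), cluster)
  if (is.null(preset)) {
    for (f in c(counts, population, adjacency))
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  structure(list(preset = preset, counts = counts, population = population,
                 adjacency = adjacency, model = model, mcmc = mc,
                 joint = joint, cluster = cl, null_risk = null_risk,
                 seed = as.integer(seed), out_dir = out_dir,
                 geojson = geojson),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any [pipeline_config()] argument; nested `mcmc:` and
#' `cluster:` blocks override the stage defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file (e.g. `seed`, `out_dir`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, list(...))
  do.call(pipeline_config, cfg)
}

.write_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Run the full disease-mapping pipeline
#'
#' simulate (or load) -> standardize -> smooth (per sex, optionally joint)
#' -> cluster on the smoothed relative risks, then summarize. Stage seeds
#' are fixed offsets of the global seed, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result`: the `$report` (a
#'   `summary_report` of per-sex tract percentages, Moran/LISA results and
#'   the cross-sex SAR correlation), per-stage results (`$sar`, `$fits`,
#'   `$joint`, `$moran`, `$lisa`), the inputs used, and a `$manifest`. When
#'   `config$out_dir` is set, all artifacts are written there as
#'   CSV/GAL/JSON (and optionally GeoJSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  t0 <- Sys.time()

  # --- stage 1: inputs ------------------------------------------------
  if (!is.null(config$preset)) {
    if (config$preset != "asturias-like")
      stop("unknown preset: ", config$preset, call. = FALSE)
    study <- simulate_study(seed = seed + 1000L, null_risk = config$null_risk)
    graph <- study$graph; pop <- study$pop; counts <- study$counts
    events <- study$events
  } else {
    graph <- read_gal(config$adjacency)
    pop <- utils::read.csv(config$population, stringsAsFactors = FALSE)
    counts <- utils::read.csv(config$counts, stringsAsFactors = FALSE)
    events <- NULL
    study <- NULL
  }

  # --- stage 2: standardization --------------------------------------
  sar_tab <- standardize(counts, pop)
  sar_by_sex <- split(sar_tab, sar_tab$sex)

  # --- stage 3: smoothing --------------------------------------------
  mc <- config$mcmc
  fits <- list(); srr <- list()
  for (i in seq_along(sexes)) {
    s <- sexes[i]
    tab <- sar_by_sex[[s]]
    tab <- tab[match(graph$tract_ids, tab$tract_id), ]
    fits[[s]] <- fit_car(tab$O, tab$E, graph, model = config$model,
                         mcmc = mcmc_control(n_chains = mc$n_chains,
                                             n_iter = mc$n_iter,
                                             n_burnin = mc$n_burnin,
                                             thin = mc$thin,
                                             seed = seed + 2000L + i))
    srr[[s]] <- stats::setNames(fits[[s]]$summary$SRR, graph$tract_ids)
  }

  joint <- NULL
  if (isTRUE(config$joint)) {
    tm <- sar_by_sex$male[match(graph$tract_ids, sar_by_sex$male$tract_id), ]
    tf <- sar_by_sex$female[match(graph$tract_ids, sar_by_sex$female$tract_id), ]
    joint <- fit_shared_component(tm$O, tm$E, tf$O, tf$E, graph,
                                  mcmc = mcmc_control(n_chains = mc$n_chains,
                                                      n_iter = mc$n_iter,
                                                      n_burnin = mc$n_burnin,
                                                      thin = mc$thin,
                                                      seed = seed + 3000L))
  }

  # --- stage 4: clustering on SRR ------------------------------------
  cl <- config$cluster
  W <- make_weights(graph, style = cl$style)
  moran <- list(); lisa_res <- list()
  for (i in seq_along(sexes)) {
    s <- sexes[i]
    x <- if (isTRUE(cl$use_joint) && !is.null(joint))
      stats::setNames(joint$summary[[s]]$SRR, graph$tract_ids) else srr[[s]]
    ok <- !is.na(x)
    xs <- x
    xs[!ok] <- mean(x, na.rm = TRUE)   # undefined tracts held at the mean
    moran[[s]] <- morans_i_test(xs, W, n_perm = cl$n_perm,
                                seed = seed + 4000L + i)
    lisa_res[[s]] <- lisa(xs, W, n_perm = cl$n_perm, alpha = cl$alpha,
                          seed = seed + 5000L + i)
    lisa_res[[s]]$class[!ok] <- "not-significant"
  }

  # --- stage 5: summary report ----------------------------------------
  per_sex <- lapply(sexes, function(s) {
    st <- sar_by_sex[[s]]
    fs <- fits[[s]]$summary
    cls <- table(factor(lisa_res[[s]]$class,
                        levels = c("high-high", "low-low", "high-low",
                                   "low-high", "not-significant")))
    list(n_tracts = nrow(fs),
         pct_sar_above_100 = threshold_summary(st$SAR, 100, "above"),
         pct_pp_ge_0.8 = 100 * mean(fs$PP >= 0.8, na.rm = TRUE),
         pct_pp_lt_0.2 = 100 * mean(fs$PP < 0.2, na.rm = TRUE),
         moran_I = moran[[s]]$I, moran_z = moran[[s]]$z,
         moran_p = moran[[s]]$p_value,
         lisa_classes = as.list(cls))
  })
  names(per_sex) <- sexes
  report <- structure(list(
    per_sex = per_sex,
    sar_cross_correlation = sar_cross_correlation(sar_by_sex$male,
                                                  sar_by_sex$female),
    retention = if (!is.null(events)) retention_summary(events) else NULL),
    class = "summary_report")

  manifest <- list(
    seed = seed, preset = config$preset, model = config$model,
    mcmc = mc, cluster = cl[c("style", "n_perm", "alpha")],
    joint = isTRUE(config$joint), null_risk = isTRUE(config$null_risk),
    n_tracts = graph$n, total_events = sum(counts$value),
    warnings = c(if (!all(vapply(fits, `[[`, logical(1), "converged")))
                   "non-convergence flagged",
                 if (any(!sar_tab$defined)) "undefined SAR tract(s)"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(list(report = report, sar = sar_tab, fits = fits,
                        joint = joint, moran = moran, lisa = lisa_res,
                        graph = graph, pop = pop, counts = counts,
                        events = events, study = study,
                        config = config, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Write all pipeline artifacts to a directory
#'
#' @param result a `pipeline_result`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  .write_csv(result$pop, p("population.csv"))
  .write_csv(result$counts, p("counts.csv"))
  write_gal(result$graph, p("adjacency.gal"))
  st <- result$sar
  st$SAR <- ifelse(st$defined, format(round_half_up(st$SAR, 2), trim = TRUE), "")
  .write_csv(st[c("tract_id", "sex", "O", "E", "SAR")], p("sar.csv"))
  for (s in names(result$fits)) {
    fs <- result$fits[[s]]$summary
    names(fs)[names(fs) == "exceeds"] <- "exceeds_0.8"
    .write_csv(fs, p(sprintf("srr_%s.csv", s)))
    jsonlite::write_json(
      list(model = result$fits[[s]]$model,
           hyper = as.data.frame(result$fits[[s]]$hyper),
           dic = result$fits[[s]]$dic, p_D = result$fits[[s]]$p_D,
           waic = result$fits[[s]]$waic, p_waic = result$fits[[s]]$p_waic,
           rhat = as.list(result$fits[[s]]$rhat),
           converged = result$fits[[s]]$converged),
      p(sprintf("fit_%s.json", s)), auto_unbox = TRUE, digits = NA)
    m <- result$moran[[s]]
    jsonlite::write_json(m[c("I", "expectation", "z", "p_value", "n_perm",
                             "method")],
                         p(sprintf("moran_%s.json", s)), auto_unbox = TRUE,
                         digits = NA)
    .write_csv(as.data.frame(result$lisa[[s]]), p(sprintf("lisa_%s.csv", s)))
  }
  if (!is.null(result$joint)) {
    for (s in names(result$joint$summary))
      .write_csv(result$joint$summary[[s]], p(sprintf("srr_joint_%s.csv", s)))
    jsonlite::write_json(list(kappa = as.list(result$joint$kappa),
                              cross_correlation =
                                as.list(result$joint$cross_correlation),
                              dic = result$joint$dic, waic = result$joint$waic),
                         p("joint.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(.report_as_list(result$report), p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(result$config$geojson) && !is.null(result$graph$coords)) {
    props <- list(SRR_male = result$fits$male$summary$SRR,
                  SRR_female = result$fits$female$summary$SRR,
                  PP_male = result$fits$male$summary$PP,
                  PP_female = result$fits$female$summary$PP,
                  lisa_male = result$lisa$male$class,
                  lisa_female = result$lisa$female$class)
    write_lattice_geojson(result$graph, p("tracts.geojson"), props)
  }
  invisible(out_dir)
}

.report_as_list <- function(report) {
  list(per_sex = report$per_sex,
       sar_cross_correlation = report$sar_cross_correlation,
       retention = report$retention)
}

#' @export
print.summary_report <- function(x, ...) {
  for (s in names(x$per_sex)) {
    p <- x$per_sex[[s]]
    cat(sprintf(
      "%s: %d tracts | SAR>100: %.2f%% | PP>=0.8: %.2f%% | PP<0.2: %.2f%% | Moran I = %.3f (z = %.1f)\n",
      s, p$n_tracts, round_half_up(p$pct_sar_above_100, 2),
      round_half_up(p$pct_pp_ge_0.8, 2), round_half_up(p$pct_pp_lt_0.2, 2),
      p$moran_I, p$moran_z))
  }
  cat(sprintf("cross-sex SAR Pearson correlation: %.4f\n",
              x$sar_cross_correlation))
  if (!is.null(x$retention))
    cat(sprintf("records retained: %d of %d (%.2f%%)\n",
                x$retention$retained, x$retention$total,
                x$retention$retained_pct_display))
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed", x$manifest$seed, ",", x$manifest$n_tracts,
      "tracts,", x$manifest$total_events, "events)\n")
  print(x$report)
  invisible(x)
}
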