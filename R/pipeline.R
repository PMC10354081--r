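#' Load a pipeline run configuration
#'
#' The configuration is a YAML (or already-parsed list) with blocks:
#' `clades` (per clade: `id`, `tree`, `ranges`, optional `regions` and
#' `habitat` coding files), `scheme` (`areas`, `focal`, optional
#' `max_range_size`, `slice_boundaries`, `multipliers`), optional
#' `scheme_regions` (same shape, for source-region assignment), `mde`
#' (`bin_width` 0.1, `window` 0.5, `n_boot` 1000, `mode` `"interval"`),
#' `changepoints` (`k` 1-4), `habitat` (`model` `"ER"`, `threshold` 0.8),
#' `seed`, and `output_dir`. Defaults fill any omitted option.
#'
#' @param x path to a YAML file, or a list.
#' @return a normalized config list of class `"run_config"`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(seed = 1, output_dir = "biomedyn-out",
                   mde = list(bin_width = 0.1, window = 0.5, n_boot = 1000,
                              mode = "interval", per_ma = FALSE),
                   changepoints = list(k = 1:4, n_starts = 5),
                   habitat = list(model = "ER", threshold = 0.8))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  if (is.null(cfg$clades) || !length(cfg$clades))
    .stopf("config needs at least one clade (tree + ranges)")
  if (is.null(cfg$scheme)) .stopf("config needs a 'scheme' block")
  class(cfg) <- "run_config"
  cfg
}

.scheme_from_config <- function(sc, default_max = NULL) {
  mult <- NULL
  if (!is.null(sc$multipliers))
    mult <- lapply(sc$multipliers, function(m)
      matrix(unlist(m), length(sc$areas), length(sc$areas), byrow = TRUE))
  area_scheme(unlist(sc$areas), sc$focal,
              max_range_size = sc$max_range_size %||% default_max %||%
                length(unlist(sc$areas)),
              slice_boundaries = unlist(sc$slice_boundaries) %||% numeric(0),
              multipliers = mult)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_hash <- function(cfg) {
  x <- unclass(cfg)
  x$output_dir <- NULL  # the analysis, not where it lands, identifies a run
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (v in s) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

.provenance <- function(cfg) {
  c(sprintf("biomedyn %s", as.character(packageVersion("biomedyn"))),
    sprintf("config %s seed %s", .cfg_hash(cfg), format(cfg$seed)))
}

#' Run the full biome-assembly pipeline
#'
#' Per clade: reads the dated tree and range coding, fits DEC rates,
#' estimates ancestral ranges, classifies dispersal-into-biome and in situ
#' diversification events, and (when a fine regionalization is configured)
#' assigns source regions. Events are pooled across clades; MDisE and MDivE
#' curves, origination/peak features with bootstrap CIs, BIC-selected
#' change points, per-source curves, and habitat pre-adaptation reports are
#' then computed and written to the output directory together with a
#' human-readable summary. Any stage failure aborts with the stage and
#' clade named; outputs already written are retained.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return invisibly, a list with `events`, `tallies`, `features`,
#'   `changepoints`, `habitat`, and `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(cfg)
  stage <- function(what, clade, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed for clade '%s': %s", what, clade,
             conditionMessage(e)))
  }
  all_events <- list()
  habitat_reports <- list()
  for (cl in cfg$clades) {
    id <- cl$id %||% basename(cl$tree)
    tree <- stage("read_tree", id, read_dated_tree(cl$tree, clade_id = id))
    ranges <- stage("read_coding", id, {
      sc <- cfg$scheme
      read_coding(cl$ranges, unlist(sc$areas), scheme_id = "ranges")
    })
    max_obs <- max(nchar(ranges$code))
    scheme <- .scheme_from_config(cfg$scheme, default_max = max_obs)
    fit <- stage("dec_fit", id, fit_dec(tree, ranges, scheme))
    anc <- stage("ancestral_ranges", id,
                 ancestral_ranges(tree, ranges, scheme, fit$params))
    write_ancestral_ranges(anc,
                           file.path(cfg$output_dir,
                                     sprintf("ancestral_%s.tsv", id)),
                           tree = tree,
                           tree_path = file.path(cfg$output_dir,
                                                 sprintf("map_%s.nwk", id)))
    ev <- stage("classify_events", id,
                classify_events(tree, anc, ranges, scheme))
    if (!is.null(cl$regions) && !is.null(cfg$scheme_regions)) {
      ev <- stage("assign_sources", id, {
        tips13 <- read_coding(cl$regions, unlist(cfg$scheme_regions$areas),
                              scheme_id = "regions")
        sch13 <- .scheme_from_config(cfg$scheme_regions,
                                     default_max = max(nchar(tips13$code)))
        fit13 <- fit_dec(tree, tips13, sch13)
        anc13 <- ancestral_ranges(tree, tips13, sch13, fit13$params)
        assign_sources(ev, tree, anc13, tips13, sch13)
      })
    }
    if (!is.null(cl$habitat)) {
      habitat_reports[[id]] <- stage("habitat", id, {
        hab <- read_coding(cl$habitat, c("o", "c", "b"), scheme_id = "habitat")
        anc_h <- ancestral_habitat(tree, hab, model = cfg$habitat$model)
        rep_h <- preadaptation_report(ev, tree, anc_h,
                                      threshold = cfg$habitat$threshold)
        write.table(rep_h$calls,
                    file.path(cfg$output_dir,
                              sprintf("habitat_calls_%s.tsv", id)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        rep_h
      })
    }
    all_events[[id]] <- ev
  }
  events <- event_table(do.call(rbind, all_events))
  events <- events[order(-events$point_age), , drop = FALSE]
  write_event_table(events, file.path(cfg$output_dir, "events.tsv"),
                    provenance = prov)
  tl <- tally(events)
  tally_df <- data.frame(
    measure = c("n_dispersal", "n_insitu", "n_total", "ratio",
                if (length(tl$source_counts))
                  paste0("source_", names(tl$source_counts))),
    value = c(tl$n_dispersal, tl$n_insitu, tl$n_total,
              if (tl$ratio_defined) round(tl$ratio, 4) else NA,
              as.integer(tl$source_counts)))
  write.table(tally_df, file.path(cfg$output_dir, "tally.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- list(events = events, tallies = tl, output_dir = cfg$output_dir)
  features <- list(); cps <- list()
  for (nm in c("MDisE", "MDivE")) {
    ty <- c(MDisE = "dispersal_in", MDivE = "in_situ")[[nm]]
    ev_t <- events[events$event_type == ty, , drop = FALSE]
    if (nrow(ev_t) == 0) next
    curve <- mde_curve(ev_t, bin_width = cfg$mde$bin_width,
                       window = cfg$mde$window, per_ma = cfg$mde$per_ma)
    write_mde_curve(curve, file.path(cfg$output_dir,
                                     sprintf("curve_%s.tsv", nm)), prov)
    feats <- bootstrap_features(ev_t, n_boot = cfg$mde$n_boot,
                                seed = cfg$seed, mode = cfg$mde$mode,
                                bin_width = cfg$mde$bin_width,
                                window = cfg$mde$window)
    features[[nm]] <- feats
    if (nrow(curve) >= 2 * max(cfg$changepoints$k) + 4) {
      cps[[nm]] <- select_changepoints(curve$mid, curve$smoothed,
                                       k_candidates = cfg$changepoints$k,
                                       n_starts = cfg$changepoints$n_starts,
                                       seed = cfg$seed)
    }
  }
  src_curves <- per_source_curves(events, bin_width = cfg$mde$bin_width,
                                  window = cfg$mde$window)
  for (r in names(src_curves))
    write_mde_curve(src_curves[[r]],
                    file.path(cfg$output_dir, sprintf("curve_source_%s.tsv", r)),
                    prov)
  out$features <- features
  out$changepoints <- cps
  out$habitat <- habitat_reports
  jsonlite::write_json(
    list(provenance = prov,
         tallies = tl[c("n_dispersal", "n_insitu", "n_total", "ratio")],
         features = lapply(features, function(f)
           list(origination = unname(f$origination), peak = unname(f$peak))),
         changepoints = lapply(cps, function(cp)
           list(k = cp$best$k, psi = cp$best$psi,
                psi_ci = cp$best$psi_ci, bic = cp$bic_table$bic))),
    file.path(cfg$output_dir, "features.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste0("# ", prov), .pipeline_summary(out)),
             file.path(cfg$output_dir, "summary.txt"))
  invisible(out)
}

.pipeline_summary <- function(out) {
  lines <- format_tally(out$tallies)
  if (out$tallies$n_total == 0)
    return(c(lines, "No focal-region events detected; nothing further to summarize."))
  for (nm in names(out$features)) {
    f <- out$features[[nm]]
    lines <- c(lines, sprintf(
      "%s: origination %.2f Ma (%.2f-%.2f), peak %.2f Ma (%.2f-%.2f)", nm,
      f$origination[1], f$origination[2], f$origination[3],
      f$peak[1], f$peak[2], f$peak[3]))
  }
  for (nm in names(out$changepoints)) {
    cp <- out$changepoints[[nm]]
    lines <- c(lines, sprintf(
      "%s change points (k = %d by BIC): %s", nm, cp$best$k,
      paste(sprintf("%.2f (%.2f-%.2f)", cp$best$psi,
                    cp$best$psi_ci[, 1], cp$best$psi_ci[, 2]),
            collapse = ", ")))
  }
  for (nm in names(out$habitat)) {
    s <- out$habitat[[nm]]$summary
    if (s$n_events > 0)
      lines <- c(lines, sprintf(
        "%s habitat ancestry: %d/%d unambiguous calls open (threshold %.2f)",
        nm, s$n_open, s$n_unambiguous, s$threshold))
  }
  lines
}
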