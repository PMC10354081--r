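#' Event-rate-through-time (MDE) curves
#'
#' Counts, in contiguous 0.1-Ma time slices laid from the oldest event bound
#' down to the present, the number of events whose age credibility interval
#' overlaps each slice ("maximal number of observed events" per slice:
#' MDisE for dispersals, MDivE for in situ diversification), then smooths
#' the series with a centered 0.5-Ma sliding-window mean (truncated at the
#' series ends).
#'
#' Slices are aligned to the `bin_width` grid ending at 0 Ma. Each slice
#' covers the age interval `(younger_edge, older_edge]`, with the youngest
#' slice additionally closed at 0, so a point age falls in exactly one
#' slice; event intervals are closed `[older, younger]`.
#'
#' @param events an [event_table].
#' @param type count only this event type (`"dispersal_in"`, `"in_situ"`,
#'   or `NULL` for all).
#' @param region count only dispersal events with this source region.
#' @param bin_width slice width in Ma (default 0.1).
#' @param window smoothing window in Ma (default 0.5).
#' @param per_ma scale counts to events per Ma (divide by `bin_width`);
#'   default off, i.e. counts per slice.
#' @return an object of class `"mde_curve"`: data frame with columns
#'   `bin_older`, `bin_younger`, `mid`, `raw`, `smoothed` (oldest slice
#'   first).
#' @export
mde_curve <- function(events, type = NULL, region = NULL,
                      bin_width = 0.1, window = 0.5, per_ma = FALSE) {
  ev <- events
  if (!is.null(type)) ev <- ev[ev$event_type == type, , drop = FALSE]
  if (!is.null(region))
    ev <- ev[ev$event_type == "dispersal_in" & ev$source_region == region, ,
             drop = FALSE]
  if (nrow(ev) == 0) .stopf("no events to bin")
  oldest <- max(ev$older)
  B <- max(1L, ceiling(oldest / bin_width - 1e-9))
  older_edges <- (B:1) * bin_width
  younger_edges <- older_edges - bin_width
  raw <- .bin_overlap_counts(ev$older, ev$younger, older_edges, younger_edges)
  if (per_ma) raw <- raw / bin_width
  half <- floor(round(window / bin_width) / 2)
  smoothed <- vapply(seq_len(B), function(i)
    mean(raw[max(1L, i - half):min(B, i + half)]), 0)
  out <- data.frame(bin_older = older_edges, bin_younger = younger_edges,
                    mid = (older_edges + younger_edges) / 2,
                    raw = raw, smoothed = smoothed)
  attr(out, "type") <- if (is.null(type)) "all" else type
  attr(out, "region") <- region
  attr(out, "bin_width") <- bin_width
  attr(out, "window") <- window
  attr(out, "per_ma") <- per_ma
  class(out) <- c("mde_curve", "data.frame")
  out
}

# Vectorized overlap counting: event i overlaps slice b iff
# older_i > younger_edge_b (or >= 0 for the last slice) and
# younger_i <= older_edge_b. Uses an increment/cumsum sweep over slices.
.bin_overlap_counts <- function(older, younger, older_edges, younger_edges) {
  B <- length(older_edges)
  bw <- older_edges[1] - younger_edges[1]
  # first (oldest) slice index whose younger edge is < older_i:
  i0 <- pmax(1L, B - ceiling(pmin(older, older_edges[1]) / bw - 1e-9) + 1L)
  # handle point ages at 0: they belong to the last slice
  i0 <- pmin(i0, B)
  # last (youngest) slice whose older edge is >= younger_i:
  i1 <- B - pmax(0L, ceiling(younger / bw - 1e-9) - 1L)
  keep <- i1 >= i0
  inc <- numeric(B + 1L)
  for (k in which(keep)) {
    inc[i0[k]] <- inc[i0[k]] + 1
    inc[i1[k] + 1L] <- inc[i1[k] + 1L] - 1
  }
  cumsum(inc[seq_len(B)])
}

#' Origination of an event series
#'
#' The point estimate is the oldest event point age in the series; the
#' "support onset" (older edge of the oldest slice with a nonzero raw
#' count, i.e. the oldest age any event interval reaches, rounded up to the
#' slice grid) is reported alongside.
#'
#' @param events an [event_table] (already filtered to one type if desired).
#' @param curve optionally, a matching [mde_curve()] for the support onset.
#' @return list with `origination` (Ma) and `support_onset` (Ma or `NA`).
#' @export
origination <- function(events, curve = NULL) {
  if (nrow(events) == 0) .stopf("no events")
  onset <- NA_real_
  if (!is.null(curve)) {
    nz <- which(curve$raw > 0)
    if (length(nz)) onset <- curve$bin_older[nz[1]]
  }
  list(origination = max(events$point_age), support_onset = onset)
}

#' Peak of an MDE curve
#'
#' The midpoint of the contiguous run of slices attaining the maximum
#' smoothed value (the oldest such run if several runs tie). A curve whose
#' maximum run spans the whole series is flagged `flat`; an all-zero curve
#' returns `NA` with `defined = FALSE`.
#'
#' @param curve an [mde_curve()].
#' @return list with `peak` (Ma), `defined`, `flat`, and the run's slice
#'   index range.
#' @export
peak <- function(curve) {
  s <- curve$smoothed
  if (all(s == 0))
    return(list(peak = NA_real_, defined = FALSE, flat = TRUE,
                run = c(NA_integer_, NA_integer_)))
  mx <- max(s)
  at <- abs(s - mx) < 1e-12
  # first (oldest) maximal run
  start <- which(at & !c(FALSE, at[-length(at)]))[1]
  end <- start
  while (end < length(s) && at[end + 1L]) end <- end + 1L
  list(peak = (curve$mid[start] + curve$mid[end]) / 2,
       defined = TRUE, flat = start == 1L && end == length(s),
       run = c(start, end))
}

#' Bootstrap confidence intervals for origination and peak
#'
#' Re-samples 1000 pseudoreplicates (by default) from the raw credibility
#' intervals and recomputes origination and peak for each, reporting
#' 2.5/97.5 percentile CIs. Two resampling modes are provided:
#'
#' * `"interval"` (default): draw one age uniformly within each event's
#'   interval; the replicate's curve is built from the drawn point ages.
#' * `"resample"`: resample events with replacement, keeping their
#'   intervals.
#'
#' @param events an [event_table], filtered to one event type.
#' @param n_boot number of pseudoreplicates (default 1000).
#' @param seed RNG seed; identical seeds give identical CIs.
#' @param mode `"interval"` or `"resample"`.
#' @param bin_width,window as in [mde_curve()].
#' @return an object of class `"curve_feature"`: list with `origination`
#'   and `peak`, each `c(estimate, ci_older, ci_younger)`, plus `n_boot`,
#'   `seed`, `mode`.
#' @export
bootstrap_features <- function(events, n_boot = 1000, seed = 1,
                               mode = c("interval", "resample"),
                               bin_width = 0.1, window = 0.5) {
  mode <- match.arg(mode)
  if (nrow(events) < 2)
    .warnf("fewer than 2 events; bootstrap CIs are degenerate")
  if (n_boot < 100) .warnf("n_boot < 100; CIs will be unstable")
  curve <- mde_curve(events, bin_width = bin_width, window = window)
  est_orig <- origination(events)$origination
  est_peak <- peak(curve)$peak
  n <- nrow(events)
  res <- .with_seed(seed, function() {
    orig <- numeric(n_boot); pk <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      if (mode == "interval") {
        ages <- runif(n, events$younger, events$older)
        o <- ages; y <- ages
      } else {
        idx <- sample.int(n, n, replace = TRUE)
        o <- events$older[idx]; y <- events$younger[idx]
        ages <- events$point_age[idx]
      }
      orig[b] <- max(ages)
      pk[b] <- .peak_from_bounds(o, y, bin_width, window)
    }
    list(orig = orig, pk = pk)
  })
  ci <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    unname(quantile(v, c(0.975, 0.025)))
  }
  structure(list(origination = c(estimate = est_orig, ci(res$orig)),
                 peak = c(estimate = est_peak, ci(res$pk)),
                 n_boot = n_boot, seed = seed, mode = mode),
            class = "curve_feature")
}

# fast peak for bootstrap replicates, given interval bounds
.peak_from_bounds <- function(older, younger, bin_width, window) {
  oldest <- max(older)
  B <- max(1L, ceiling(oldest / bin_width - 1e-9))
  oe <- (B:1) * bin_width
  raw <- .bin_overlap_counts(older, younger, oe, oe - bin_width)
  half <- floor(round(window / bin_width) / 2)
  cs <- cumsum(c(0, raw))
  lo <- pmax(0L, seq_len(B) - half - 1L)
  hi <- pmin(B, seq_len(B) + half)
  s <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  mx <- max(s)
  at <- abs(s - mx) < 1e-12
  start <- which(at & !c(FALSE, at[-length(at)]))[1]
  end <- start
  while (end < B && at[end + 1L]) end <- end + 1L
  mids <- oe - bin_width / 2
  (mids[start] + mids[end]) / 2
}

#' @export
print.curve_feature <- function(x, ...) {
  cat(sprintf("Origination: %.2f Ma (95%% CI %.2f-%.2f)\n",
              x$origination[1], x$origination[2], x$origination[3]))
  cat(sprintf("Peak:        %.2f Ma (95%% CI %.2f-%.2f)\n",
              x$peak[1], x$peak[2], x$peak[3]))
  cat(sprintf("(%d bootstrap pseudoreplicates, mode '%s', seed %s)\n",
              x$n_boot, x$mode, format(x$seed)))
  invisible(x)
}

#' Per-source-region dispersal curves
#'
#' One [mde_curve()] per non-empty source region, over source-assigned
#' dispersal events only.
#'
#' @param events an [event_table].
#' @param ... passed to [mde_curve()].
#' @return named list of curves (possibly empty).
#' @export
per_source_curves <- function(events, ...) {
  ev <- events[events$event_type == "dispersal_in" &
               nzchar(events$source_region), , drop = FALSE]
  regions <- sort(unique(ev$source_region))
  setNames(lapply(regions, function(r) mde_curve(ev, region = r, ...)),
           regions)
}

#' Write an MDE curve as delimited text
#'
#' @param curve an [mde_curve()].
#' @param path output path.
#' @param provenance optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_mde_curve <- function(curve, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
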