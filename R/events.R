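#' Classify species-level biogeographic events on a range-annotated tree
#'
#' Two event classes are recognized, following the standard two-state
#' (focal / non-focal) reading of a DEC reconstruction:
#'
#' * **dispersal into the focal region** (`dispersal_in`): an edge whose
#'   child MAP range contains the focal area while the parent MAP range does
#'   not. The event is anchored on the child node; its point age is the
#'   child-node age and its interval spans from the parent node's HPD older
#'   bound (or point age) to the child node's HPD younger bound (or point
#'   age) — the full window in which the range gain could have occurred.
#' * **in situ diversification** (`in_situ`): an internal node whose MAP
#'   range and both children's MAP ranges contain the focal area. Point age
#'   and interval are the node's age and HPD.
#'
#' A node can yield both one `in_situ` event and (on its stem edge) one
#' `dispersal_in` event; the two classes are tallied independently. Events
#' are returned sorted from oldest to youngest point age.
#'
#' @param tree a [dated_tree].
#' @param anc an [ancestral_ranges()] result for `tree` (MAP ranges for
#'   internal nodes).
#' @param tips a [coding_table] giving tip ranges.
#' @param scheme the [area_scheme] used for the reconstruction.
#' @return an [event_table].
#' @export
classify_events <- function(tree, anc, tips, scheme) {
  n <- length(tree$tip.label)
  map <- .node_map_ranges(tree, anc, tips)
  focal <- scheme$focal
  has_focal <- vapply(map, function(s) focal %in% s, logical(1))
  recs <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (has_focal[ch] && !has_focal[p]) {
      tm <- attach_timing(list(event_type = "dispersal_in", node_id = ch), tree)
      recs[[length(recs) + 1L]] <- data.frame(
        clade_id = tree$clade_id, event_type = "dispersal_in",
        node_id = ch, point_age = tm$point_age,
        older = tm$older, younger = tm$younger,
        source_region = "", stringsAsFactors = FALSE)
    }
  }
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = 1:(n + tree$Nnode)))
  for (v in (n + 1L):(n + tree$Nnode)) {
    ch <- children[[v]]
    if (has_focal[v] && all(has_focal[ch])) {
      tm <- attach_timing(list(event_type = "in_situ", node_id = v), tree)
      recs[[length(recs) + 1L]] <- data.frame(
        clade_id = tree$clade_id, event_type = "in_situ",
        node_id = v, point_age = tm$point_age,
        older = tm$older, younger = tm$younger,
        source_region = "", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else NULL
  out <- event_table(out)
  out[order(-out$point_age, out$event_type, out$node_id), , drop = FALSE]
}

# MAP range (as a character vector of area symbols) for every node:
# tips from the coding table, internal nodes from the ancestral table.
.node_map_ranges <- function(tree, anc, tips) {
  n <- length(tree$tip.label)
  out <- vector("list", n + tree$Nnode)
  idx <- match(tree$tip.label, tips$species)
  if (anyNA(idx)) .stopf("tip(s) missing range coding: %s",
                         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  for (i in seq_len(n)) out[[i]] <- .code_set(tips$code[idx[i]])
  for (v in (n + 1L):(n + tree$Nnode)) {
    lbl <- anc$map[as.character(v)]
    if (is.na(lbl)) .stopf("node %d has no MAP range", v)
    out[[v]] <- .code_set(lbl)
  }
  out
}

#' Timing of a single biogeographic event
#'
#' @param event list with `event_type` and `node_id` (the child node of the
#'   gaining edge for `dispersal_in`; the diversifying node for `in_situ`).
#' @param tree a [dated_tree].
#' @return list with `point_age`, `older`, `younger` (Ma).
#' @export
attach_timing <- function(event, tree) {
  v <- event$node_id
  if (event$event_type == "dispersal_in") {
    k <- match(v, tree$edge[, 2])
    if (is.na(k)) .stopf("dispersal event node %d has no parent edge", v)
    p <- tree$edge[k, 1]
    if (tree$age[p] < tree$age[v] - 1e-9)
      .stopf("parent younger than child on edge %d -> %d", p, v)
    older <- if (!is.na(tree$hpd[p, 1])) tree$hpd[p, 1] else tree$age[p]
    younger <- if (!is.na(tree$hpd[v, 2])) tree$hpd[v, 2] else tree$age[v]
    list(point_age = tree$age[v], older = unname(older),
         younger = max(unname(younger), 0))
  } else {
    older <- if (!is.na(tree$hpd[v, 1])) tree$hpd[v, 1] else tree$age[v]
    younger <- if (!is.na(tree$hpd[v, 2])) tree$hpd[v, 2] else tree$age[v]
    list(point_age = tree$age[v], older = unname(older),
         younger = max(unname(younger), 0))
  }
}

#' Assign source regions to dispersal events
#'
#' Uses an ancestral reconstruction under a finer regionalization (e.g. a
#' 13-region floristic scheme sharing the same focal symbol) on the same
#' tree. The source of a dispersal event is the single non-focal area in the
#' parent node's MAP range when that is unambiguous; events whose parent
#' range contains zero or several distinct non-focal areas get an empty
#' source and are excluded from per-source tallies.
#'
#' @param events an [event_table] from [classify_events()].
#' @param tree the same [dated_tree] used for classification.
#' @param anc_regions [ancestral_ranges()] result under the fine scheme.
#' @param tips_regions [coding_table] of tip ranges under the fine scheme.
#' @param scheme_regions the fine [area_scheme]; its focal symbol marks the
#'   focal biome.
#' @return `events` with `source_region` filled for unambiguous dispersals.
#' @export
assign_sources <- function(events, tree, anc_regions, tips_regions,
                           scheme_regions) {
  if (!scheme_regions$focal %in% scheme_regions$areas)
    .stopf("scheme lacks a focal area")
  map <- .node_map_ranges(tree, anc_regions, tips_regions)
  for (i in which(events$event_type == "dispersal_in" &
                  events$clade_id == tree$clade_id)) {
    v <- events$node_id[i]
    k <- match(v, tree$edge[, 2])
    if (is.na(k)) next
    src <- setdiff(map[[tree$edge[k, 1]]], scheme_regions$focal)
    events$source_region[i] <- if (length(src) == 1) src else ""
  }
  events
}

#' Tally classified events
#'
#' @param events an [event_table].
#' @return list with `n_dispersal`, `n_insitu`, `n_total`, `ratio`
#'   (dispersal / in situ; `Inf` with `ratio_defined = FALSE` when there are
#'   no in situ events), `source_counts` and `source_pct` (over
#'   source-assigned dispersal events only).
#' @export
tally <- function(events) {
  n_disp <- sum(events$event_type == "dispersal_in")
  n_ins <- sum(events$event_type == "in_situ")
  src <- events$source_region[events$event_type == "dispersal_in" &
                              nzchar(events$source_region)]
  counts <- if (length(src)) sort(table(src), decreasing = TRUE) else
    table(character())
  list(n_dispersal = n_disp, n_insitu = n_ins, n_total = n_disp + n_ins,
       ratio = if (n_ins > 0) n_disp / n_ins else Inf,
       ratio_defined = n_ins > 0,
       n_source_assigned = length(src),
       source_counts = counts,
       source_pct = if (length(src)) 100 * counts / length(src) else counts)
}

#' @rdname tally
#' @param x a tally result.
#' @param ... unused.
#' @export
format_tally <- function(x, ...) {
  lines <- c(
    sprintf("Biogeographic events: %d total (%d dispersal into the focal region, %d in situ diversification)",
            x$n_total, x$n_dispersal, x$n_insitu),
    if (x$ratio_defined)
      sprintf("Dispersal : in situ ratio = %.2f", x$ratio)
    else "Dispersal : in situ ratio undefined (no in situ events)")
  if (x$n_source_assigned > 0) {
    lines <- c(lines,
               sprintf("Source regions assigned for %d dispersal events:", x$n_source_assigned),
               sprintf("  %s: %d (%.1f%%)", names(x$source_counts),
                       as.integer(x$source_counts), as.numeric(x$source_pct)))
  }
  paste(lines, collapse = "\n")
}
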