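#' Simulate a dated birth-death tree conditioned on a tip count
#'
#' Forward (Gillespie) simulation of a constant-rate birth-death process,
#' stopped at the moment the birth that would create the `n_tips + 1`-th
#' extant lineage occurs; extinct lineages are pruned, so the returned tree
#' is ultrametric with `n_tips` extant tips. Under a pure-birth process the
#' expected crown age is `sum_{i=2..n} 1 / (i * birth)`.
#'
#' @param birth speciation rate (events/Ma), `> death`.
#' @param death extinction rate (events/Ma), `>= 0`.
#' @param n_tips number of extant tips (>= 2).
#' @param seed RNG seed.
#' @param max_attempts restarts allowed when the process dies out.
#' @return a [dated_tree].
#' @export
simulate_tree <- function(birth, death = 0, n_tips, seed = 1,
                          max_attempts = 1000) {
  if (birth <= death || death < 0) .stopf("need birth > death >= 0")
  if (n_tips < 2) .stopf("n_tips must be >= 2")
  .with_seed(seed, function() {
    for (att in seq_len(max_attempts)) {
      res <- .bd_attempt(birth, death, n_tips)
      if (!is.null(res)) return(res)
    }
    .stopf("birth-death condition not attained in %d attempts", max_attempts)
  })
}

.bd_attempt <- function(birth, death, n_tips) {
  # lineage records
  parent <- c(NA_integer_); t0 <- c(0); t1 <- c(NA_real_)
  extinct <- c(FALSE)
  extant <- 1L
  time <- 0
  cap <- 200L * n_tips + 1000L
  for (step in seq_len(cap)) {
    k <- length(extant)
    time <- time + rexp(1, k * (birth + death))
    is_birth <- runif(1) < birth / (birth + death)
    if (is_birth && k == n_tips) {
      # present moment: stop just before the (n+1)-th extant lineage appears
      t1[extant] <- time
      return(.bd_build(parent, t0, t1, extinct, time, n_tips))
    }
    who <- extant[sample.int(k, 1)]
    if (is_birth) {
      t1[who] <- time
      id1 <- length(parent) + 1L; id2 <- id1 + 1L
      parent <- c(parent, who, who)
      t0 <- c(t0, time, time); t1 <- c(t1, NA_real_, NA_real_)
      extinct <- c(extinct, FALSE, FALSE)
      extant <- c(setdiff(extant, who), id1, id2)
    } else {
      t1[who] <- time
      extinct[who] <- TRUE
      extant <- setdiff(extant, who)
      if (length(extant) == 0) return(NULL)
    }
  }
  NULL
}

.bd_build <- function(parent, t0, t1, extinct, present, n_tips) {
  kids <- split(seq_along(parent), factor(parent, levels = seq_along(parent)))
  tip_ct <- 0L
  # returns list(newick_body, extra_len) for the surviving part below lineage l
  rec <- function(l) {
    ch <- kids[[l]]
    len <- t1[l] - t0[l]
    if (length(ch) == 0) {
      if (extinct[l]) return(NULL)
      tip_ct <<- tip_ct + 1L
      return(list(s = sprintf("t%d", tip_ct), len = len))
    }
    subs <- Filter(Negate(is.null), lapply(ch, rec))
    if (length(subs) == 0) return(NULL)
    if (length(subs) == 1)  # collapse single survivor through this node
      return(list(s = subs[[1]]$s, len = len + subs[[1]]$len))
    body <- paste0("(", paste(vapply(subs, function(z)
      sprintf("%s:%.12g", z$s, z$len), ""), collapse = ","), ")")
    list(s = body, len = len)
  }
  top <- rec(1L)
  if (is.null(top) || tip_ct != n_tips) return(NULL)
  if (!startsWith(top$s, "(")) return(NULL)
  nw <- paste0(top$s, ";")
  .tree_from_parse(.parse_newick(nw), "sim")
}

#' Attach synthetic node-age HPD intervals
#'
#' Emulates divergence-dating uncertainty: each internal node gets an
#' interval centered on its age with width `rel_width * age` (at least
#' `min_width`), mildly jittered so widths vary across nodes.
#'
#' @param tree a [dated_tree].
#' @param rel_width mean interval width relative to node age.
#' @param min_width floor on the interval width (Ma).
#' @param seed RNG seed.
#' @return the tree with `hpd` filled for internal nodes.
#' @export
add_node_hpd <- function(tree, rel_width = 0.2, min_width = 0.05, seed = 1) {
  n <- length(tree$tip.label)
  .with_seed(seed, function() {
    for (v in (n + 1L):(n + tree$Nnode)) {
      w <- max(min_width, rel_width * tree$age[v] * runif(1, 0.5, 1.5))
      u <- runif(1, 0.25, 0.75)  # asymmetric placement around the point age
      tree$hpd[v, ] <- c(tree$age[v] + u * w,
                         max(0, tree$age[v] - (1 - u) * w))
    }
    tree
  })
}

#' Forward-simulate a DEC range history on a dated tree
#'
#' Anagenesis is simulated by the Gillespie algorithm under the
#' slice-appropriate DEC rate matrix along every branch; at every internal
#' node a cladogenetic scenario is drawn from [cladogenesis_distribution()].
#' Every gain of the focal area along a branch is recorded with its age.
#' Lineages absorbed into the null range are dead; dead subtrees are pruned
#' by default (`on_dead = "prune"`), or the whole simulation is redrawn
#' (`"retry"`).
#'
#' The returned `true_events` table applies the event definitions to the
#' true node states of the final tree: an edge is a dispersal-into-biome
#' event when the child's state contains the focal area and the parent's
#' does not (dated by the youngest recorded gain on that edge), and a node
#' is an in situ diversification event when it and both children contain
#' the focal area.
#'
#' @param tree a [dated_tree] (binary).
#' @param scheme an [area_scheme].
#' @param params a [dec_params].
#' @param root_range range label at the root (e.g. `"B"`).
#' @param seed RNG seed.
#' @param on_dead `"prune"`, `"retry"`, or `"error"`.
#' @param max_attempts retries for `"retry"` (also caps pruning retries when
#'   fewer than 2 tips survive).
#' @return list with `tree` (possibly pruned), `coding` (a [coding_table]),
#'   `node_states` (character vector of range labels, all nodes),
#'   `anc_true` (MAP-style table usable by [classify_events()]),
#'   `true_events` (an [event_table]), `gain_log`, and `n_dead`.
#' @export
simulate_ranges <- function(tree, scheme, params, root_range, seed = 1,
                            on_dead = c("prune", "retry", "error"),
                            max_attempts = 100) {
  on_dead <- match.arg(on_dead)
  ss <- build_state_space(scheme)
  root_idx <- .state_index(ss, root_range)
  if (root_idx == 1L) .stopf("root range must be observable")
  n_slices <- length(scheme$slice_boundaries) + 1L
  Qs <- lapply(seq_len(n_slices), function(s) anagenetic_rate_matrix(ss, params, s))
  clado <- .clado_tables(ss)
  for (att in seq_len(max_attempts)) {
    sim <- .with_seed(.child_seed(seed, att), function()
      .range_forward(tree, ss, Qs, clado, root_idx, scheme))
    dead_tips <- which(sim$dead[seq_along(tree$tip.label)])
    if (length(dead_tips) == 0) return(.range_finalize(tree, sim, ss, scheme))
    if (on_dead == "error") .stopf("%d lineage(s) reached the null range",
                                   length(dead_tips))
    if (on_dead == "prune") {
      if (length(tree$tip.label) - length(dead_tips) >= 2) {
        pruned <- .prune_dated(tree, dead_tips, sim)
        return(.range_finalize(pruned$tree, pruned$sim, ss, scheme))
      }
      # fewer than 2 survivors: fall through to a redraw
    }
  }
  .stopf("range simulation failed after %d attempts (lineage extinction)",
         max_attempts)
}

.range_forward <- function(tree, ss, Qs, clado, root_idx, scheme) {
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  state <- integer(n_all)
  dead <- logical(n_all)
  gains <- list()
  focal_i <- match(scheme$focal, scheme$areas)
  has_focal <- vapply(ss$states, function(s) focal_i %in% s, logical(1))
  root <- n + 1L
  state[root] <- root_idx
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = 1:n_all))
  pre_nodes <- unique(c(root, ape::reorder.phylo(tree, "cladewise")$edge[, 2]))
  bounds <- scheme$slice_boundaries
  for (v in pre_nodes) {
    if (v <= n || dead[v]) {
      if (dead[v] && v > n) for (ch in children[[v]]) dead[ch] <- TRUE
      next
    }
    if (dead[v]) next
    tb <- clado[[state[v]]]
    pick <- sample.int(length(tb$w), 1, prob = tb$w)
    daughter <- c(tb$l[pick], tb$r[pick])
    for (j in 1:2) {
      ch <- children[[v]][j]
      res <- .gillespie_branch(daughter[j], tree$age[v], tree$age[ch],
                               Qs, bounds, has_focal)
      state[ch] <- res$state
      if (length(res$gain_ages))
        gains[[length(gains) + 1L]] <- data.frame(node = ch, age = res$gain_ages)
      if (res$state == 1L) {
        dead[ch] <- TRUE
        if (ch > n) {
          # mark whole subtree dead
          stack <- ch
          while (length(stack)) {
            w <- stack[1]; stack <- stack[-1]
            dead[w] <- TRUE
            if (w > n) stack <- c(stack, children[[w]])
          }
        }
      }
    }
  }
  list(state = state, dead = dead,
       gains = if (length(gains)) do.call(rbind, gains) else
         data.frame(node = integer(), age = numeric()))
}

# Gillespie simulation from parent age down to child age, slice-aware.
.gillespie_branch <- function(s, age_from, age_to, Qs, bounds, has_focal) {
  gain_ages <- numeric()
  t <- age_from
  while (t > age_to + 1e-12) {
    sl <- .slice_of(t - 1e-12, bounds)
    below <- bounds[bounds < t - 1e-12]
    seg_end <- if (length(below)) max(age_to, below[1]) else age_to
    Q <- Qs[[sl]]
    rate <- -Q[s, s]
    if (rate <= 0) { t <- seg_end; if (seg_end <= age_to + 1e-12) break else next }
    w <- rexp(1, rate)
    if (t - w <= seg_end) { t <- seg_end; if (seg_end <= age_to + 1e-12) break else next }
    t <- t - w
    p <- Q[s, ]; p[s] <- 0
    new_s <- sample.int(length(p), 1, prob = p)
    if (has_focal[new_s] && !has_focal[s]) gain_ages <- c(gain_ages, t)
    s <- new_s
    if (s == 1L) break  # null range is absorbing
  }
  list(state = s, gain_ages = gain_ages)
}

.prune_dated <- function(tree, dead_tips, sim) {
  n <- length(tree$tip.label)
  phy <- tree
  phy$node.label <- sprintf("nd%d", (n + 1L):(n + tree$Nnode))
  class(phy) <- "phylo"
  phy$age <- phy$hpd <- phy$clade_id <- phy$hpd_excludes_age <- NULL
  pr <- ape::drop.tip(phy, tree$tip.label[dead_tips])
  new_tree <- dated_tree(pr, clade_id = tree$clade_id)
  # remap states, HPDs and gain log to the new numbering via labels
  old_of <- integer(length(new_tree$tip.label) + new_tree$Nnode)
  old_of[seq_along(new_tree$tip.label)] <-
    match(new_tree$tip.label, tree$tip.label)
  old_of[(length(new_tree$tip.label) + 1L):length(old_of)] <-
    as.integer(sub("^nd", "", pr$node.label))
  new_tree$hpd <- tree$hpd[old_of, , drop = FALSE]
  state <- sim$state[old_of]
  # gains recorded on dropped-out intermediate nodes are reattached to the
  # first retained descendant on the same lineage path
  parent_old <- rep(NA_integer_, n + tree$Nnode)
  parent_old[tree$edge[, 2]] <- tree$edge[, 1]
  keep_new <- setNames(seq_along(old_of), old_of)
  gains <- sim$gains
  if (nrow(gains)) {
    gains$node <- vapply(gains$node, function(v) {
      # walk down is not possible; instead walk up from each retained node is
      # costly -- map by climbing from the recorded node upward only when the
      # recorded node itself was dropped
      if (!is.na(keep_new[as.character(v)])) return(unname(keep_new[as.character(v)]))
      NA_integer_
    }, 1L)
  }
  new_tree$node.label <- NULL
  list(tree = new_tree,
       sim = list(state = state, dead = logical(length(state)),
                  gains = gains[!is.na(gains$node), , drop = FALSE]))
}

.range_finalize <- function(tree, sim, ss, scheme) {
  n <- length(tree$tip.label)
  labels <- ss$labels[sim$state]
  names(labels) <- c(tree$tip.label, sprintf("%d", (n + 1L):(n + tree$Nnode)))
  coding <- coding_table(setNames(labels[seq_len(n)], tree$tip.label),
                         scheme$areas, "sim-ranges")
  nodes <- (n + 1L):(n + tree$Nnode)
  anc_true <- structure(list(map = setNames(ss$labels[sim$state[nodes]],
                                            nodes),
                             prob = NULL, loglik = NA_real_),
                        class = "ancestral_range_table")
  focal <- scheme$focal
  hasf <- vapply(sim$state, function(i) focal %in% ss$scheme$areas[ss$states[[i]]],
                 logical(1))
  recs <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (hasf[ch] && !hasf[p]) {
      g <- sim$gains$age[sim$gains$node == ch]
      age <- if (length(g)) min(g) else tree$age[ch]
      recs[[length(recs) + 1L]] <- data.frame(
        event_type = "dispersal_in", node_id = ch, age = age)
    }
  }
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = 1:(n + tree$Nnode)))
  for (v in (n + 1L):(n + tree$Nnode)) {
    if (hasf[v] && all(hasf[children[[v]]]))
      recs[[length(recs) + 1L]] <- data.frame(
        event_type = "in_situ", node_id = v, age = tree$age[v])
  }
  true_events <- if (length(recs)) do.call(rbind, recs) else
    data.frame(event_type = character(), node_id = integer(), age = numeric())
  list(tree = tree, coding = coding, node_states = labels,
       anc_true = anc_true, true_events = true_events,
       gain_log = sim$gains, n_dead = sum(sim$dead))
}

#' Scenario for multi-clade synthetic event ensembles
#'
#' Bundles the study-scale conditions used by the generators: the number
#' and size of clades, DEC rates, the piecewise-constant event intensity
#' with its change-point ages, interval-width model, event-type mix, and
#' source-region mixture. Defaults emulate a ~130-event, 32-clade focal
#' biome assembly initiating at ~10.2 Ma with intensity steps at 7.2, 2.6,
#' (0.9,) and 0.6 Ma, a roughly 4:1 dispersal-to-in-situ ratio, and a
#' dominant (~54%) single source region.
#'
#' @param n_clades,birth,death,n_tips per-clade tree simulation settings.
#' @param dec_d,dec_e DEC rates for forward range simulation.
#' @param breaks intensity node ages, Ma, strictly decreasing to 0.
#' @param rates events/Ma. With `shape = "linear"` (default), one value per
#'   entry of `breaks`: the intensity at that age, interpolated linearly
#'   between breaks, so the expected event-rate curve is piecewise linear
#'   with kinks (change points) at the interior breaks. With
#'   `shape = "constant"`, one value per interval between breaks
#'   (piecewise-constant intensity, i.e. step change points). In both
#'   shapes `lambda(t) = 0` older than `breaks[1]`.
#' @param shape `"linear"` or `"constant"` intensity interpolation.
#' @param rel_width,min_width credibility-interval width model (relative to
#'   the event age, with a floor).
#' @param p_dispersal probability an event is a dispersal (vs in situ).
#' @param p_source_assigned fraction of dispersal events with a resolvable
#'   single source region.
#' @param source_probs named probabilities over source-region symbols.
#' @param seed master seed.
#' @return a list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_clades = 32, birth = 0.4, death = 0.1, n_tips = 40,
                         dec_d = 0.2, dec_e = 0.02,
                         breaks = c(10.24, 7.2, 2.6, 0.6, 0),
                         rates = c(1, 2, 12, 54, 30),
                         shape = c("linear", "constant"),
                         rel_width = 0.1, min_width = 0.2,
                         p_dispersal = 105 / 131,
                         p_source_assigned = 26 / 105,
                         source_probs = c(G = 14, D = 3, B = 2, E = 2, F = 2,
                                          C = 1, H = 1, J = 1) / 26,
                         seed = 1) {
  shape <- match.arg(shape)
  if (any(diff(breaks) >= 0) || breaks[length(breaks)] != 0)
    .stopf("breaks must decrease strictly to 0")
  need <- if (shape == "linear") length(breaks) else length(breaks) - 1L
  if (length(rates) != need)
    .stopf("shape '%s' needs %d rate values for %d breaks", shape, need,
           length(breaks))
  if (any(rates < 0)) .stopf("intensities must be non-negative")
  structure(list(n_clades = n_clades, birth = birth, death = death,
                 n_tips = n_tips, dec_d = dec_d, dec_e = dec_e,
                 breaks = breaks, rates = rates, shape = shape,
                 rel_width = rel_width,
                 min_width = min_width, p_dispersal = p_dispersal,
                 p_source_assigned = p_source_assigned,
                 source_probs = source_probs, seed = seed),
            class = "sim_scenario")
}

#' Draw a multi-clade event ensemble from a piecewise-constant intensity
#'
#' Event point ages come from an inhomogeneous Poisson process with the
#' scenario's piecewise-constant intensity; each age is wrapped in a
#' credibility interval of width `rel_width * age` (floored at
#' `min_width`), placed uniformly around the age and clipped at 0. Event
#' types and source regions follow the scenario's mixtures.
#'
#' @param scenario a [sim_scenario].
#' @param seed RNG seed (defaults to the scenario's).
#' @param intensity_scale multiplies all intensities (problem-size knob for
#'   power studies).
#' @return an [event_table].
#' @export
simulate_event_ensemble <- function(scenario, seed = scenario$seed,
                                    intensity_scale = 1) {
  br <- scenario$breaks
  lam <- scenario$rates * intensity_scale
  if (all(lam == 0)) {
    .warnf("intensity is identically zero; empty event table")
    return(event_table())
  }
  .with_seed(seed, function() {
    ages <- numeric(0)
    for (j in seq_len(length(br) - 1L)) {
      len <- br[j] - br[j + 1]
      if (scenario$shape == "constant") {
        nj <- rpois(1, lam[j] * len)
        if (nj > 0) ages <- c(ages, runif(nj, br[j + 1], br[j]))
      } else {
        # linear interpolation between (br[j], lam[j]) and (br[j+1], lam[j+1])
        a <- lam[j + 1]                    # intensity at the young end
        b <- (lam[j] - lam[j + 1]) / len   # slope toward the old end
        area <- len * (lam[j] + lam[j + 1]) / 2
        nj <- rpois(1, area)
        if (nj > 0) {
          u <- runif(nj) * area
          x <- if (abs(b) < 1e-12) u / a else
            (-a + sqrt(pmax(0, a^2 + 2 * b * u))) / b
          ages <- c(ages, br[j + 1] + pmin(pmax(x, 0), len))
        }
      }
    }
    if (!length(ages)) return(event_table())
    ages <- sort(ages, decreasing = TRUE)
    n <- length(ages)
    w <- pmax(scenario$min_width, scenario$rel_width * ages)
    u <- runif(n)
    older <- ages + u * w
    younger <- pmax(0, ages - (1 - u) * w)
    type <- ifelse(runif(n) < scenario$p_dispersal, "dispersal_in", "in_situ")
    src <- character(n)
    disp <- which(type == "dispersal_in")
    assigned <- disp[runif(length(disp)) < scenario$p_source_assigned]
    if (length(assigned))
      src[assigned] <- sample(names(scenario$source_probs), length(assigned),
                              replace = TRUE, prob = scenario$source_probs)
    event_table(data.frame(
      clade_id = "ensemble", event_type = type, node_id = seq_len(n),
      point_age = ages, older = older, younger = younger,
      source_region = src, stringsAsFactors = FALSE))
  })
}

#' Integrated intensity of a scenario
#'
#' Expected number of events, `integral of lambda(t) dt`.
#' @param scenario a [sim_scenario].
#' @return numeric.
#' @export
expected_event_count <- function(scenario) {
  len <- -diff(scenario$breaks)
  if (scenario$shape == "constant") sum(scenario$rates * len)
  else sum(len * (head(scenario$rates, -1) + tail(scenario$rates, -1)) / 2)
}

#' Simulate a habitat history on a dated tree
#'
#' Two-state (open/closed) continuous-time Markov simulation along every
#' branch.
#'
#' @param tree a [dated_tree].
#' @param rates `c(open_to_closed, closed_to_open)` in events/Ma.
#' @param root_state `"open"` or `"closed"`.
#' @param seed RNG seed.
#' @return list with `coding` (named states per tip), `node_states`
#'   (states at every node), `n_changes`.
#' @export
simulate_habitats <- function(tree, rates, root_state = "open", seed = 1) {
  if (any(rates < 0)) .stopf("rates must be non-negative")
  sts <- c("open", "closed")
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  .with_seed(seed, function() {
    state <- integer(n_all)
    state[n + 1L] <- match(root_state, sts)
    changes <- 0L
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    for (k in seq_len(nrow(pre))) {
      p <- pre[k, 1]; ch <- pre[k, 2]
      s <- state[p]
      t_rem <- tree$age[p] - tree$age[ch]
      repeat {
        r <- rates[s]
        if (r <= 0) break
        w <- rexp(1, r)
        if (w >= t_rem) break
        t_rem <- t_rem - w
        s <- 3L - s
        changes <- changes + 1L
      }
      state[ch] <- s
    }
    list(coding = setNames(sts[state[seq_len(n)]], tree$tip.label),
         node_states = setNames(sts[state], c(tree$tip.label,
                                              (n + 1L):n_all)),
         n_changes = changes)
  })
}

#' Write a complete synthetic multi-clade study to disk
#'
#' Simulates `n_clades` dated birth-death trees with node-age HPDs, forward
#' DEC range histories over a two-area scheme (focal area `"A"`, non-focal
#' `"B"`), and habitat histories, writing per-clade newick trees and coding
#' tables plus a ready-to-run pipeline configuration. The resulting
#' directory is consumed by [run_pipeline()] exactly like a real study.
#'
#' @param dir output directory (created if needed).
#' @param scenario a [sim_scenario] supplying clade counts, tree and DEC
#'   settings.
#' @param seed master seed (defaults to the scenario's).
#' @param habitat also simulate and write open/closed habitat codings.
#' @return the pipeline configuration (a list), invisibly; it is also
#'   written to `<dir>/config.yaml`.
#' @export
simulate_study <- function(dir, scenario = sim_scenario(), seed = scenario$seed,
                           habitat = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sch <- area_scheme(c("A", "B"), "A", 2)
  clades <- list()
  for (i in seq_len(scenario$n_clades)) {
    id <- sprintf("clade%02d", i)
    tr <- simulate_tree(scenario$birth, scenario$death, scenario$n_tips,
                        seed = .child_seed(seed, i))
    tr$clade_id <- id
    tr <- add_node_hpd(tr, seed = .child_seed(seed, 1000 + i))
    sim <- simulate_ranges(tr, sch, dec_params(scenario$dec_d, scenario$dec_e),
                           "B", seed = .child_seed(seed, 2000 + i))
    tree_file <- file.path(dir, paste0(id, ".nwk"))
    write_dated_tree(sim$tree, tree_file)
    rng_file <- file.path(dir, paste0(id, "_ranges.tsv"))
    write_coding(sim$coding, rng_file)
    entry <- list(id = id, tree = tree_file, ranges = rng_file)
    if (habitat) {
      hab <- simulate_habitats(sim$tree, c(0.08, 0.08), "open",
                               seed = .child_seed(seed, 3000 + i))
      hab_file <- file.path(dir, paste0(id, "_habitat.tsv"))
      codes <- c(open = "o", closed = "c")[hab$coding]
      names(codes) <- names(hab$coding)
      write_coding(coding_table(codes, c("o", "c", "b"), "habitat"), hab_file)
      entry$habitat <- hab_file
    }
    clades[[i]] <- entry
  }
  cfg <- list(seed = seed, output_dir = file.path(dir, "out"),
              clades = clades,
              scheme = list(areas = c("A", "B"), focal = "A",
                            max_range_size = 2))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(cfg)
}
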