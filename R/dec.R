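#' Define an area scheme for DEC analyses
#'
#' An area scheme fixes the ordered set of area symbols, the focal area (the
#' biome whose assembly is analyzed), the maximum number of areas allowed in
#' an ancestral range (usually the maximum observed among extant taxa), and
#' optional time-stratified dispersal multipliers: one pairwise multiplier
#' matrix per time slice, scaling the per-pair range-expansion rate.
#'
#' @param areas ordered vector of single-character area symbols.
#' @param focal the focal-area symbol (must be in `areas`).
#' @param max_range_size maximum number of areas in any range (default: all).
#' @param slice_boundaries ages (Ma) separating time slices, strictly
#'   decreasing toward the present; `k` boundaries define `k + 1` slices
#'   ordered oldest first.
#' @param multipliers list of square dispersal-multiplier matrices (values in
#'   `[0, 1]`, diagonal ignored), one per slice; default all-ones.
#' @return an object of class `"area_scheme"`.
#' @export
area_scheme <- function(areas, focal, max_range_size = length(areas),
                        slice_boundaries = numeric(0), multipliers = NULL) {
  areas <- as.character(areas)
  if (anyDuplicated(areas)) .stopf("duplicated area symbols")
  if (!focal %in% areas) .stopf("focal area '%s' not in areas", focal)
  if (max_range_size < 1 || max_range_size > length(areas))
    .stopf("max_range_size must be in 1..%d", length(areas))
  n_slice <- length(slice_boundaries) + 1L
  if (length(slice_boundaries) &&
      any(diff(slice_boundaries) >= 0))
    .stopf("slice boundaries must be strictly decreasing toward the present")
  if (is.null(multipliers))
    multipliers <- rep(list(matrix(1, length(areas), length(areas))), n_slice)
  if (length(multipliers) != n_slice)
    .stopf("need %d multiplier matrices for %d slice boundaries",
           n_slice, length(slice_boundaries))
  for (m in multipliers) {
    if (!is.matrix(m) || any(dim(m) != length(areas)))
      .stopf("multiplier matrices must be %d x %d", length(areas), length(areas))
    if (any(m < 0 | m > 1)) .stopf("multipliers must lie in [0, 1]")
  }
  structure(list(areas = areas, focal = focal,
                 max_range_size = as.integer(max_range_size),
                 slice_boundaries = as.numeric(slice_boundaries),
                 multipliers = multipliers),
            class = "area_scheme")
}

#' DEC rate parameters
#'
#' @param d range-expansion (dispersal) rate per area pair, events/Ma.
#' @param e per-area extirpation rate, events/Ma.
#' @return an object of class `"dec_params"`.
#' @export
dec_params <- function(d, e) {
  if (d < 0 || e < 0) .stopf("DEC rates must be non-negative")
  structure(list(d = d, e = e), class = "dec_params")
}

#' Enumerate the DEC state space
#'
#' All non-empty subsets of the areas with size up to `max_range_size`, in a
#' deterministic order (by size, then lexicographically in area order), plus
#' the null (empty) range as the first state. The null range is an internal
#' absorbing state of the anagenetic process (the lineage-extirpation
#' pathway); it is excluded from tip observations, cladogenesis, and the
#' root prior.
#'
#' @param scheme an [area_scheme].
#' @return an object of class `"dec_state_space"`: a list with `states`
#'   (list of integer area-index vectors; the null range first), `labels`
#'   (concatenated symbols, `""` for null), and `observable` (logical).
#' @export
build_state_space <- function(scheme) {
  A <- length(scheme$areas)
  states <- list(integer(0))
  for (sz in seq_len(scheme$max_range_size)) {
    cmb <- utils::combn(A, sz)
    for (j in seq_len(ncol(cmb))) states[[length(states) + 1L]] <- cmb[, j]
  }
  labels <- vapply(states, function(s) paste(scheme$areas[s], collapse = ""), "")
  structure(list(states = states, labels = labels,
                 observable = c(FALSE, rep(TRUE, length(states) - 1L)),
                 scheme = scheme),
            class = "dec_state_space")
}

.state_index <- function(ss, code) {
  set <- match(.code_set(code), ss$scheme$areas)
  if (anyNA(set)) .stopf("code '%s' uses symbols outside the scheme", code)
  set <- sort(set)
  lbl <- paste(ss$scheme$areas[set], collapse = "")
  i <- match(lbl, ss$labels)
  if (is.na(i)) .stopf("range '%s' exceeds max_range_size %d", code,
                       ss$scheme$max_range_size)
  i
}

#' Anagenetic DEC rate matrix for one time slice
#'
#' Range expansion `G -> G + {j}` has rate `d * sum_{i in G} m[i, j]` where
#' `m` is the slice's dispersal-multiplier matrix (only when `|G|` is below
#' the maximum range size); extirpation `G -> G - {i}` has rate `e` for each
#' occupied area, so singleton ranges decay to the absorbing null range.
#' Rows sum to zero.
#'
#' @param ss a [build_state_space()] result.
#' @param params a [dec_params].
#' @param slice 1-based time-slice index (oldest first).
#' @return square rate matrix over all states (null first), with state
#'   labels as dimnames.
#' @export
anagenetic_rate_matrix <- function(ss, params, slice = 1L) {
  if (params$d < 0 || params$e < 0) .stopf("DEC rates must be non-negative")
  m <- ss$scheme$multipliers[[slice]]
  S <- length(ss$states)
  Q <- matrix(0, S, S, dimnames = list(ss$labels, ss$labels))
  A <- length(ss$scheme$areas)
  idx <- function(set) match(paste(ss$scheme$areas[sort(set)], collapse = ""),
                             ss$labels)
  for (i in seq_len(S)) {
    G <- ss$states[[i]]
    if (length(G) == 0) next
    if (length(G) < ss$scheme$max_range_size) {
      for (j in setdiff(seq_len(A), G))
        Q[i, idx(c(G, j))] <- params$d * sum(m[G, j])
    }
    for (a in G) {
      k <- idx(setdiff(G, a))
      Q[i, k] <- Q[i, k] + params$e
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' DEC cladogenetic scenario distribution
#'
#' For a singleton parent range the only scenario is identical inheritance.
#' For a widespread parent range `G`, the allowed ordered daughter scenarios
#' are subset sympatry (one daughter a singleton subset of `G`, the other
#' `G` itself) and vicariance (one daughter a singleton, the other the
#' complement `G - s`), all with equal probability.
#'
#' @param parent parent range as a label (e.g. `"AB"`) or state index.
#' @param ss a [build_state_space()] result.
#' @return data frame with columns `left`, `right` (range labels) and `prob`
#'   (summing to 1).
#' @export
cladogenesis_distribution <- function(parent, ss) {
  i <- if (is.character(parent)) match(parent, ss$labels) else as.integer(parent)
  if (is.na(i) || i < 1 || i > length(ss$states)) .stopf("unknown parent range")
  G <- ss$states[[i]]
  if (length(G) == 0) .stopf("null range cannot speciate")
  lbl <- function(s) paste(ss$scheme$areas[sort(s)], collapse = "")
  if (length(G) == 1) {
    out <- data.frame(left = ss$labels[i], right = ss$labels[i], prob = 1)
  } else {
    L <- character(); R <- character()
    for (a in G) {
      s <- lbl(a); g <- ss$labels[i]; comp <- lbl(setdiff(G, a))
      L <- c(L, s, g); R <- c(R, g, s)          # subset sympatry, both orders
      L <- c(L, s, comp); R <- c(R, comp, s)    # vicariance, both orders
    }
    df <- unique(data.frame(left = L, right = R, stringsAsFactors = FALSE))
    out <- data.frame(df, prob = 1 / nrow(df))
  }
  if (anyNA(match(out$left, ss$labels)) || anyNA(match(out$right, ss$labels)))
    .stopf("cladogenetic daughter outside the state space")
  out
}

# Precompute cladogenesis scenarios for every observable state: list of
# (l, r, w) integer/numeric vectors per parent state index. The likelihood
# weight `w` is the probability of the *unordered* daughter-range outcome
# (both assignments of a left/right pair carry the pair's total mass), so a
# cherry with tips {A} and {B} below a widespread {A,B} parent scores the
# full vicariance probability 1/3 rather than a single ordered term 1/6.
.clado_tables <- function(ss) {
  lapply(seq_along(ss$states), function(i) {
    if (length(ss$states[[i]]) == 0) return(NULL)
    d <- cladogenesis_distribution(i, ss)
    list(l = match(d$left, ss$labels), r = match(d$right, ss$labels),
         w = d$prob * ifelse(d$left == d$right, 1, 2))
  })
}

# ---------------------------------------------------------------------------
# Likelihood machinery

# Split a branch [child_age, parent_age] at slice boundaries; return segments
# as (duration, slice_index) ordered youngest -> oldest.
.branch_segments <- function(child_age, parent_age, boundaries) {
  cuts <- boundaries[boundaries > child_age + 1e-12 & boundaries < parent_age - 1e-12]
  pts <- sort(unique(c(child_age, cuts, parent_age)))
  n_seg <- length(pts) - 1L
  out <- matrix(0, n_seg, 2)
  for (k in seq_len(n_seg)) {
    mid <- (pts[k] + pts[k + 1]) / 2
    slice <- sum(boundaries > mid) + 1L  # boundaries decreasing: count older cuts
    out[k, ] <- c(pts[k + 1] - pts[k], slice)
  }
  out
}

# slice index for an age given decreasing boundaries: slice 1 = oldest
.slice_of <- function(age, boundaries) {
  if (length(boundaries) == 0) return(1L)
  sum(boundaries > age) + 1L
}

.dec_engine <- function(tree, ranges, ss, params, need_up = FALSE) {
  scheme <- ss$scheme
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  S <- length(ss$states)
  miss <- setdiff(tree$tip.label, ranges$species)
  if (length(miss)) .stopf("tip(s) missing range coding: %s",
                           paste(miss, collapse = ", "))
  tip_state <- vapply(tree$tip.label, function(sp)
    .state_index(ss, ranges$code[match(sp, ranges$species)]), 1L)
  n_slices <- length(scheme$slice_boundaries) + 1L
  Qs <- lapply(seq_len(n_slices), function(s) anagenetic_rate_matrix(ss, params, s))
  decs <- lapply(Qs, .eigen_decompose)
  Pfun <- function(slice, t) .expm_safe(Qs[[slice]], t, decs[[slice]])
  clado <- .clado_tables(ss)

  children <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge)))
    children[[tree$edge[k, 1]]] <- c(children[[tree$edge[k, 1]]], tree$edge[k, 2])
  root <- n + 1L

  D <- matrix(0, S, n_all)        # at-node down partials (scaled)
  Dtop <- matrix(0, S, n_all)     # partials at top of each node's stem branch
  Pbr <- vector("list", n_all)    # branch transition matrix per child node
  logscale <- 0

  branch_P <- function(v, parent) {
    seg <- .branch_segments(tree$age[v], tree$age[parent], scheme$slice_boundaries)
    P <- NULL
    # product ordered oldest segment first: P_branch = P_old %*% ... %*% P_young
    for (k in rev(seq_len(nrow(seg)))) {
      Pk <- Pfun(seg[k, 2], seg[k, 1])
      P <- if (is.null(P)) Pk else P %*% Pk
    }
    if (is.null(P)) diag(S) else P
  }

  postorder <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  postorder <- c(postorder[!duplicated(postorder)], root)
  postorder <- unique(postorder)
  for (v in postorder) {
    if (v <= n) {
      D[tip_state[v], v] <- 1
    } else {
      ch <- children[[v]]
      if (length(ch) != 2)
        .stopf("DEC cladogenesis requires a binary tree (node %d has %d children)",
               v, length(ch))
      for (c0 in ch) {
        Pbr[[c0]] <- branch_P(c0, v)
        Dtop[, c0] <- as.numeric(Pbr[[c0]] %*% D[, c0])
      }
      Lv <- numeric(S)
      for (g in seq_len(S)) {
        tb <- clado[[g]]
        if (is.null(tb)) next
        Lv[g] <- sum(tb$w * Dtop[tb$l, ch[1]] * Dtop[tb$r, ch[2]])
      }
      mx <- max(Lv)
      if (mx <= 0 || !is.finite(mx))
        return(list(loglik = -Inf, D = D, ok = FALSE))
      D[, v] <- Lv / mx
      logscale <- logscale + log(mx)
    }
  }
  prior <- ifelse(ss$observable, 1 / sum(ss$observable), 0)
  lik_root <- sum(prior * D[, root])
  loglik <- log(lik_root) + logscale
  root_loglik <- log(D[, root]) + logscale  # per-root-state conditional logliks
  out <- list(loglik = loglik, root_loglik = root_loglik, ok = is.finite(loglik))

  if (need_up && is.finite(loglik)) {
    U <- matrix(0, S, n_all)
    U[, root] <- prior
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    for (k in seq_len(nrow(pre))) {
      p <- pre[k, 1]; c1 <- pre[k, 2]
      if (c1 <= n) next
      sib <- setdiff(children[[p]], c1)
      first <- children[[p]][1] == c1
      Sc <- numeric(S)
      for (g in seq_len(S)) {
        tb <- clado[[g]]
        if (is.null(tb) || U[g, p] == 0) next
        mine <- if (first) tb$l else tb$r
        other <- if (first) tb$r else tb$l
        contrib <- tb$w * Dtop[other, sib] * U[g, p]
        for (ii in seq_along(mine))
          Sc[mine[ii]] <- Sc[mine[ii]] + contrib[ii]
      }
      Uv <- as.numeric(crossprod(Pbr[[c1]], Sc))
      mx <- max(Uv)
      U[, c1] <- if (mx > 0) Uv / mx else Uv
    }
    out$U <- U
  }
  out$D <- D
  out
}

#' DEC log-likelihood of tip ranges on a dated tree
#'
#' Felsenstein pruning with DEC cladogenesis at internal nodes: branch
#' propagation uses the matrix exponential of the slice-appropriate
#' anagenetic rate matrix (branches crossing a slice boundary are integrated
#' piecewise), node combination uses [cladogenesis_distribution()], and the
#' root is averaged under a flat prior over observable ranges. Partial
#' likelihoods are rescaled at every node to guard against underflow.
#'
#' @param tree a [dated_tree] (binary).
#' @param ranges a [coding_table] over the scheme's areas.
#' @param scheme an [area_scheme].
#' @param params a [dec_params].
#' @return list with `loglik` (flat-root-prior average) and `root_loglik`
#'   (per-root-state conditional log-likelihoods, null state first).
#' @export
dec_loglik <- function(tree, ranges, scheme, params) {
  ss <- build_state_space(scheme)
  res <- .dec_engine(tree, ranges, ss, params)
  list(loglik = res$loglik, root_loglik = res$root_loglik)
}

#' Fit DEC rates by maximum likelihood
#'
#' Bounded quasi-Newton (`L-BFGS-B`) optimization of [dec_loglik()] over
#' `(d, e)` on the log scale, from a fixed deterministic start, so repeated
#' fits are identical.
#'
#' @inheritParams dec_loglik
#' @param init starting values `c(d, e)`.
#' @param lower,upper box bounds on the rates (events/Ma).
#' @return list with `params` (a [dec_params]), `loglik`, `convergence`
#'   (0 = converged), and `counts` from [stats::optim()].
#' @export
fit_dec <- function(tree, ranges, scheme, init = c(0.1, 0.05),
                    lower = 1e-7, upper = 100) {
  ss <- build_state_space(scheme)
  nll <- function(lp) {
    p <- dec_params(exp(lp[1]), exp(lp[2]))
    ll <- .dec_engine(tree, ranges, ss, p)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (nll(log(init)) >= 1e10)
    .stopf("non-finite DEC likelihood at starting values; consider rescaling ages")
  opt <- optim(log(init), nll, method = "L-BFGS-B",
               lower = log(c(lower, lower)), upper = log(c(upper, upper)),
               control = list(factr = 1e8))
  list(params = dec_params(exp(opt$par[1]), exp(opt$par[2])),
       loglik = -opt$value, convergence = opt$convergence,
       counts = opt$counts)
}

#' Marginal ancestral range estimation
#'
#' Combines down-pass (subtree) and up-pass (rest-of-tree) partial
#' likelihoods to obtain, for every internal node, the marginal posterior
#' probability of each observable range, plus the MAP range (ties broken
#' deterministically by state order).
#'
#' @inheritParams dec_loglik
#' @return an object of class `"ancestral_range_table"`: list with `prob`
#'   (internal nodes x observable ranges matrix, rows summing to 1), `map`
#'   (named character vector of MAP range labels), and `loglik`.
#' @export
ancestral_ranges <- function(tree, ranges, scheme, params) {
  ss <- build_state_space(scheme)
  res <- .dec_engine(tree, ranges, ss, params, need_up = TRUE)
  if (!is.finite(res$loglik)) .stopf("DEC likelihood is zero; check coding/params")
  n <- length(tree$tip.label)
  nodes <- (n + 1L):(n + tree$Nnode)
  obs <- which(ss$observable)
  prob <- matrix(0, length(nodes), length(obs),
                 dimnames = list(nodes, ss$labels[obs]))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    m <- res$U[obs, v] * res$D[obs, v]
    prob[i, ] <- m / sum(m)
  }
  map <- colnames(prob)[apply(prob, 1, which.max)]
  names(map) <- rownames(prob)
  structure(list(prob = prob, map = map, loglik = res$loglik,
                 state_labels = ss$labels[obs]),
            class = "ancestral_range_table")
}

#' @export
print.ancestral_range_table <- function(x, ...) {
  cat(sprintf("Ancestral ranges for %d internal nodes over %d observable ranges (loglik %.4f)\n",
              nrow(x$prob), ncol(x$prob), x$loglik))
  invisible(x)
}

#' Write ancestral-range outputs
#'
#' Writes the per-node marginal probability table as tab-delimited text
#' and, optionally, the tree in newick with MAP-range node labels.
#'
#' @param anc an [ancestral_ranges()] result.
#' @param path output path for the marginal table.
#' @param tree optionally, the matching [dated_tree].
#' @param tree_path where to write the MAP-annotated newick.
#' @return `path`, invisibly.
#' @export
write_ancestral_ranges <- function(anc, path, tree = NULL, tree_path = NULL) {
  df <- data.frame(node = rownames(anc$prob), map = unname(anc$map),
                   as.data.frame(anc$prob, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tree) && !is.null(tree_path)) {
    tr <- tree
    tr$node.label <- unname(anc$map[as.character(
      (length(tr$tip.label) + 1L):(length(tr$tip.label) + tr$Nnode))])
    phy <- tr
    phy$age <- phy$hpd <- phy$clade_id <- phy$hpd_excludes_age <- NULL
    class(phy) <- "phylo"
    ape::write.tree(phy, tree_path)
  }
  invisible(path)
}
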