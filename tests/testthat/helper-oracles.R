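# Independent brute-force oracles used to validate the fast implementations,
# plus small fixture builders. Everything here is written from first
# principles and deliberately avoids the package's internal code paths.

tree_from_newick <- function(nw, clade_id = "test") {
  f <- tempfile(fileext = ".nwk")
  writeLines(nw, f)
  on.exit(unlink(f))
  read_dated_tree(f, clade_id = clade_id)
}

# --- DEC brute force -------------------------------------------------------

# Enumerate all subsets of areas up to max size; null first, then by size
# and lexicographic order (mirrors the declared state order, re-derived).
oracle_states <- function(areas, max_size) {
  out <- list(integer(0))
  for (sz in seq_len(max_size))
    out <- c(out, lapply(seq_len(ncol(combn(length(areas), sz))),
                         function(j) combn(length(areas), sz)[, j]))
  out
}

oracle_Q <- function(states, m, d, e, max_size) {
  S <- length(states)
  eq <- function(a, b) length(a) == length(b) && all(a == b)
  Q <- matrix(0, S, S)
  for (i in seq_len(S)) {
    G <- states[[i]]
    if (!length(G)) next
    for (j in seq_len(S)) {
      H <- states[[j]]
      if (length(H) == length(G) + 1 && all(G %in% H) && length(G) < max_size) {
        new <- setdiff(H, G)
        Q[i, j] <- d * sum(m[G, new])
      } else if (length(H) == length(G) - 1 && all(H %in% G)) {
        Q[i, j] <- e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# unordered-outcome cladogenesis weight used in the likelihood: the pair
# {l, r} gets its total probability on either ordered assignment
oracle_clado_w <- function(states, g, l, r) {
  G <- states[[g]]; L <- states[[l]]; R <- states[[r]]
  if (!length(G)) return(0)
  eq <- function(a, b) length(a) == length(b) && all(sort(a) == sort(b))
  if (length(G) == 1) return(as.numeric(eq(L, G) && eq(R, G)))
  key <- function(s) paste(sort(s), collapse = "-")
  scen <- character()
  for (a in G) {
    scen <- c(scen,
              paste(key(a), key(G), sep = "|"), paste(key(G), key(a), sep = "|"),
              paste(key(a), key(setdiff(G, a)), sep = "|"),
              paste(key(setdiff(G, a)), key(a), sep = "|"))
  }
  scen <- unique(scen)
  hit <- paste(key(L), key(R), sep = "|") %in% scen
  # both ordered assignments of a pair carry the pair's total mass
  if (hit) 2 / length(scen) else 0
}

# Full joint enumeration of internal-node states. Returns loglik and the
# marginal probabilities over observable states for each internal node.
oracle_dec <- function(tree, codes, areas, focal, max_size, d, e,
                       boundaries = numeric(0), multipliers = NULL) {
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  states <- oracle_states(areas, max_size)
  S <- length(states)
  lbl <- vapply(states, function(s) paste(areas[s], collapse = ""), "")
  if (is.null(multipliers))
    multipliers <- rep(list(matrix(1, length(areas), length(areas))),
                       length(boundaries) + 1)
  Qs <- lapply(multipliers, function(m) oracle_Q(states, m, d, e, max_size))
  # branch transition matrix with piecewise slices (oldest segment first)
  Pbranch <- function(young, old) {
    cuts <- boundaries[boundaries > young + 1e-12 & boundaries < old - 1e-12]
    pts <- sort(unique(c(young, cuts, old)))
    P <- diag(S)
    for (k in rev(seq_len(length(pts) - 1))) {
      mid <- (pts[k] + pts[k + 1]) / 2
      sl <- sum(boundaries > mid) + 1
      P <- P %*% as.matrix(Matrix::expm(Qs[[sl]] * (pts[k + 1] - pts[k])))
    }
    P
  }
  Pe <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    Pe[[ch]] <- Pbranch(tree$age[ch], tree$age[p])
  }
  tip_state <- vapply(tree$tip.label, function(sp) {
    set <- sort(match(strsplit(codes[[sp]], "")[[1]], areas))
    which(lbl == paste(areas[set], collapse = ""))
  }, 1L)
  children <- split(tree$edge[, 2],
                    factor(tree$edge[, 1], levels = 1:n_all))
  internals <- (n + 1L):n_all
  obs <- which(lengths(states) > 0)
  combos <- expand.grid(rep(list(obs), length(internals)))
  lik_total <- 0
  marg <- matrix(0, length(internals), S)
  W <- array(NA_real_, c(S, S, S))
  for (ii in seq_len(nrow(combos))) {
    assign <- integer(n_all)
    assign[seq_len(n)] <- tip_state
    assign[internals] <- as.integer(combos[ii, ])
    lik <- 1 / length(obs)  # flat root prior
    for (v in internals) {
      ch <- children[[v]]
      term <- 0
      for (l in seq_len(S)) for (r in seq_len(S)) {
        if (is.na(W[assign[v], l, r]))
          W[assign[v], l, r] <- oracle_clado_w(states, assign[v], l, r)
        w <- W[assign[v], l, r]
        if (w > 0)
          term <- term + w * Pe[[ch[1]]][l, assign[ch[1]]] *
            Pe[[ch[2]]][r, assign[ch[2]]]
      }
      lik <- lik * term
    }
    lik_total <- lik_total + lik
    for (j in seq_along(internals))
      marg[j, assign[internals[j]]] <- marg[j, assign[internals[j]]] + lik
  }
  list(loglik = log(lik_total),
       marg = marg[, obs, drop = FALSE] / lik_total,
       labels = lbl[obs])
}

# --- MDE brute force -------------------------------------------------------

oracle_bin_counts <- function(older, younger, older_edges, younger_edges) {
  B <- length(older_edges)
  raw <- integer(B)
  for (b in seq_len(B)) {
    for (i in seq_along(older)) {
      # 1e-9 tolerance resolves float ties at grid edges the same way the
      # closed-interval rule does for exact arithmetic
      lower_ok <- if (b == B) older[i] >= younger_edges[b] else
        older[i] > younger_edges[b] + 1e-9
      if (lower_ok && younger[i] <= older_edges[b] + 1e-9)
        raw[b] <- raw[b] + 1L
    }
  }
  raw
}

# --- segmented grid-search oracle (k <= 2) --------------------------------

oracle_segmented_rss <- function(x, y, k, grid = NULL) {
  o <- order(x); x <- x[o]; y <- y[o]
  if (is.null(grid)) grid <- x[3:(length(x) - 3)]
  rss <- function(psi) {
    X <- cbind(1, x, vapply(psi, function(p) pmax(x - p, 0), numeric(length(x))))
    sum(qr.resid(qr(X), y)^2)
  }
  best <- Inf; best_psi <- NULL
  if (k == 1) {
    for (p in grid) if (rss(p) < best) { best <- rss(p); best_psi <- p }
  } else if (k == 2) {
    for (i in seq_along(grid)) for (j in seq_along(grid)) {
      if (grid[j] <= grid[i]) next
      v <- rss(c(grid[i], grid[j]))
      if (v < best) { best <- v; best_psi <- c(grid[i], grid[j]) }
    }
  }
  list(rss = best, psi = best_psi)
}

# --- 2-state Mk brute force ------------------------------------------------

oracle_mk2 <- function(tree, tip_states, rates) {
  n <- length(tree$tip.label)
  n_all <- n + tree$Nnode
  Q <- matrix(c(-rates[1], rates[1], rates[2], -rates[2]), 2, 2, byrow = TRUE)
  Pe <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    Pe[[ch]] <- as.matrix(Matrix::expm(Q * (tree$age[p] - tree$age[ch])))
  }
  tipL <- matrix(0, 2, n)
  for (i in seq_len(n)) {
    s <- tip_states[[tree$tip.label[i]]]
    tipL[, i] <- switch(s, open = c(1, 0), closed = c(0, 1), both = c(1, 1))
  }
  internals <- (n + 1L):n_all
  combos <- expand.grid(rep(list(1:2), length(internals)))
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = 1:n_all))
  parent <- integer(n_all); parent[tree$edge[, 2]] <- tree$edge[, 1]
  lik_total <- 0
  marg <- matrix(0, length(internals), 2)
  for (ii in seq_len(nrow(combos))) {
    assign <- integer(n_all)
    assign[internals] <- as.integer(combos[ii, ])
    lik <- 0.5
    for (v in internals) for (ch in children[[v]]) {
      if (ch <= n) {
        lik <- lik * sum(Pe[[ch]][assign[v], ] * tipL[, ch])
      } else {
        lik <- lik * Pe[[ch]][assign[v], assign[ch]]
      }
    }
    lik_total <- lik_total + lik
    for (j in seq_along(internals))
      marg[j, assign[internals[j]]] <- marg[j, assign[internals[j]]] + lik
  }
  list(loglik = log(lik_total), marg = marg / lik_total)
}

# evaluate fn under a temporary RNG seed, restoring the caller's stream
.with_seed_test <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}
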