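#' Ancestral habitat-state reconstruction (open vs closed)
#'
#' Marginal ancestral-state estimation for a two-state habitat character
#' (open: no canopy of other plants, e.g. tundra, grassland, alpine; closed:
#' forest understory) under a continuous-time Markov (Mk) model, with
#' transition rates fitted by maximum likelihood. Tips scored as occurring
#' in `"both"` habitats are treated as ambiguous observations (partial
#' likelihood 1 for either state) rather than as a third state.
#'
#' @param tree a [dated_tree].
#' @param coding a [coding_table] over the alphabet `c("open", "closed")`
#'   built with single-letter symbols `o`, `c` and `b` (both), or a named
#'   character vector of states `"open"`, `"closed"`, `"both"` per species.
#' @param model `"ER"` (equal rates) or `"ARD"` (all rates different).
#' @return an object of class `"habitat_anc"`: list with `prob` (internal
#'   nodes x 2 matrix of marginal probabilities, columns `open`, `closed`),
#'   `map`, `rates` (`c(open_to_closed, closed_to_open)`), and `loglik`.
#' @export
ancestral_habitat <- function(tree, coding, model = c("ER", "ARD")) {
  model <- match.arg(model)
  states <- .habitat_states(tree, coding)
  n <- length(tree$tip.label)
  # tip partials: open = (1,0), closed = (0,1), both = (1,1)
  tipL <- matrix(0, 2, n)
  tipL[1, states %in% c("open", "both")] <- 1
  tipL[2, states %in% c("closed", "both")] <- 1
  blen <- numeric(n + tree$Nnode)
  blen[tree$edge[, 2]] <- tree$age[tree$edge[, 1]] - tree$age[tree$edge[, 2]]
  nll <- function(lr) {
    r <- exp(lr)
    rates <- if (model == "ER") c(r[1], r[1]) else r
    -.mk2_engine(tree, tipL, blen, rates)$loglik
  }
  if (model == "ER") {
    opt <- optimize(function(l) nll(l), c(log(1e-6), log(100)))
    r <- exp(opt$minimum); rates <- c(r, r); ll <- -opt$objective
  } else {
    opt <- optim(log(c(0.1, 0.1)), nll, method = "L-BFGS-B",
                 lower = log(1e-6), upper = log(100))
    rates <- exp(opt$par); ll <- -opt$value
  }
  res <- .mk2_engine(tree, tipL, blen, rates, need_up = TRUE)
  nodes <- (n + 1L):(n + tree$Nnode)
  prob <- t(res$marg[, nodes, drop = FALSE])
  dimnames(prob) <- list(nodes, c("open", "closed"))
  map <- colnames(prob)[apply(prob, 1, which.max)]
  names(map) <- rownames(prob)
  structure(list(prob = prob, map = map,
                 rates = setNames(rates, c("open_to_closed", "closed_to_open")),
                 model = model, loglik = res$loglik),
            class = "habitat_anc")
}

.habitat_states <- function(tree, coding) {
  if (inherits(coding, "coding_table") || is.data.frame(coding)) {
    v <- c(o = "open", c = "closed", b = "both",
           open = "open", closed = "closed", both = "both")[coding$code]
    names(v) <- coding$species
  } else {
    v <- coding
  }
  out <- unname(v[tree$tip.label])
  bad <- is.na(out) | !out %in% c("open", "closed", "both")
  if (any(bad)) .stopf("tip(s) without a valid habitat state: %s",
                       paste(tree$tip.label[bad], collapse = ", "))
  out
}

# 2-state CTMC pruning with closed-form transition probabilities.
# rates = c(a, b): a = rate 1->2 (open->closed), b = rate 2->1.
.mk2_p <- function(rates, t) {
  a <- rates[1]; b <- rates[2]; r <- a + b
  if (r == 0) return(diag(2))
  e <- exp(-r * t)
  matrix(c(b / r + a / r * e, a / r - a / r * e,
           b / r - b / r * e, a / r + b / r * e),
         2, 2, byrow = TRUE)
}

.mk2_engine <- function(tree, tipL, blen, rates, need_up = FALSE) {
  n <- ncol(tipL)
  n_all <- n + tree$Nnode
  D <- matrix(0, 2, n_all)
  D[, seq_len(n)] <- tipL
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = 1:n_all))
  P <- vector("list", n_all)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  logscale <- 0
  for (v in c(rev(unique(pre[, 2])), n + 1L)) {
    if (v <= n) next
    Lv <- rep(1, 2)
    for (ch in children[[v]]) {
      P[[ch]] <- .mk2_p(rates, blen[ch])
      Lv <- Lv * as.numeric(P[[ch]] %*% D[, ch])
    }
    mx <- max(Lv)
    if (mx <= 0) return(list(loglik = -Inf))
    D[, v] <- Lv / mx
    logscale <- logscale + log(mx)
  }
  root <- n + 1L
  loglik <- log(sum(0.5 * D[, root])) + logscale
  out <- list(loglik = loglik)
  if (need_up) {
    U <- matrix(0, 2, n_all)
    U[, root] <- 0.5
    for (k in seq_len(nrow(pre))) {
      p <- pre[k, 1]; ch <- pre[k, 2]
      sibs <- setdiff(children[[p]], ch)
      m <- U[, p]
      for (s in sibs) m <- m * as.numeric(P[[s]] %*% D[, s])
      Uv <- as.numeric(crossprod(P[[ch]], m))
      mx <- max(Uv)
      U[, ch] <- if (mx > 0) Uv / mx else Uv
    }
    marg <- U * D
    out$marg <- sweep(marg, 2, pmax(colSums(marg), .Machine$double.xmin), "/")
  }
  out
}

#' Ancestral habitat of dispersal-event ancestors (pre-adaptation report)
#'
#' For every dispersal-into-biome event, reports the MAP habitat state and
#' its marginal probability at the parent node of the gaining edge (the
#' immigrant's immediate ancestor). Calls are `"open"` or `"closed"` when
#' the MAP probability reaches `threshold`, otherwise `"ambiguous"`. The
#' summary gives the fraction of unambiguous calls that are open — the
#' pre-adaptation signal.
#'
#' @param events an [event_table] classified on `tree`.
#' @param tree the [dated_tree] the events and reconstruction refer to.
#' @param anc a [ancestral_habitat()] result for the same tree.
#' @param threshold minimum MAP probability for an unambiguous call
#'   (default 0.8).
#' @return list with `calls` (data frame: node_id, ancestor_node, map,
#'   prob, call) and `summary` (n_events, n_unambiguous, n_open,
#'   frac_open_of_unambiguous).
#' @export
preadaptation_report <- function(events, tree, anc, threshold = 0.8) {
  ev <- events[events$event_type == "dispersal_in" &
               events$clade_id == tree$clade_id, , drop = FALSE]
  if (nrow(ev) && !all(as.character(unique(
        tree$edge[match(ev$node_id, tree$edge[, 2]), 1])) %in% rownames(anc$prob)))
    .stopf("events and habitat reconstruction refer to different trees")
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    v <- ev$node_id[i]
    p <- tree$edge[match(v, tree$edge[, 2]), 1]
    pr <- anc$prob[as.character(p), ]
    mp <- names(pr)[which.max(pr)]
    data.frame(node_id = v, ancestor_node = p, map = mp,
               prob = unname(max(pr)),
               call = if (max(pr) >= threshold) mp else "ambiguous",
               stringsAsFactors = FALSE)
  })
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_id = integer(), ancestor_node = integer(),
               map = character(), prob = numeric(), call = character())
  n_un <- sum(calls$call != "ambiguous")
  n_open <- sum(calls$call == "open")
  list(calls = calls,
       summary = list(n_events = nrow(calls), n_unambiguous = n_un,
                      n_open = n_open,
                      frac_open_of_unambiguous =
                        if (n_un > 0) n_open / n_un else NA_real_,
                      threshold = threshold))
}
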