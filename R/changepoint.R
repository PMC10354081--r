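#' Segmented (piecewise-linear) regression with k breakpoints
#'
#' Iterative-linearization fit (Muggeo-style): given current breakpoints
#' `psi`, the response is regressed on the basis `{1, x, (x - psi_j)_+,
#' I(x > psi_j)}`; each breakpoint is then updated by the ratio of the gap
#' coefficient to the slope-difference coefficient, `psi_j <- psi_j +
#' gamma_j / beta_j`, until the largest update falls below `tol` (or
#' `max_iter` is reached, in which case the last iterate is returned with
#' `converged = FALSE`). Breakpoint 95% CIs use the delta-method standard
#' error of `gamma_j / beta_j`. With `k = 0` the fit reduces to ordinary
#' least squares.
#'
#' @param x predictor (e.g. slice midpoints in Ma); must be strictly
#'   monotone. Internally sorted ascending.
#' @param y response (e.g. smoothed MDE values).
#' @param k number of breakpoints (>= 0).
#' @param psi optional initial breakpoints; default `k` equally spaced
#'   quantiles of `x`.
#' @param max_iter,tol iteration controls.
#' @return an object of class `"segmented_fit"`: list with `k`, `psi`,
#'   `psi_ci` (k x 2), `intercept`, `slopes` (one per segment, left to
#'   right in `x`), `rss`, `n`, `converged`, `iterations`.
#' @export
fit_segmented <- function(x, y, k, psi = NULL, max_iter = 100, tol = 1e-6) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  dx <- diff(x)
  if (!(all(dx > 0) || all(dx < 0))) .stopf("x must be strictly monotone")
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  if (k == 0) {
    X <- cbind(1, x)
    cf <- qr.coef(qr(X), y)
    r <- y - X %*% cf
    return(structure(list(k = 0L, psi = numeric(0),
                          psi_ci = matrix(numeric(0), 0, 2),
                          intercept = cf[1], slopes = cf[2],
                          rss = sum(r^2), n = n, converged = TRUE,
                          iterations = 0L),
                     class = "segmented_fit"))
  }
  if (n < 2 * k + 4) .stopf("need at least %d points for k = %d", 2 * k + 4, k)
  rng <- range(x)
  gap <- 3 * diff(rng) / (n - 1)      # keep >= 3 x-steps between breakpoints
  eps <- gap                          # and away from the boundary
  project <- function(p) {
    p <- sort(pmin(pmax(p, rng[1] + eps), rng[2] - eps))
    if (length(p) > 1)
      for (j in 2:length(p)) p[j] <- max(p[j], p[j - 1] + gap)
    pmin(p, rng[2] - eps)
  }
  broken_rss <- function(p) {
    X0 <- cbind(1, x, vapply(p, function(q) pmax(x - q, 0), numeric(n)))
    sum(stats::.lm.fit(X0, y)$residuals^2)
  }
  if (is.null(psi)) psi <- quantile(x, (1:k) / (k + 1), names = FALSE)
  psi <- project(psi)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
    V <- vapply(psi, function(p) as.numeric(x > p), numeric(n))
    X <- cbind(1, x, U, V)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) .stopf("collinear design at psi = %s",
                                   paste(signif(psi, 6), collapse = ", "))
    cf <- qr.coef(qrX, y)
    beta <- cf[2 + (1:k)]
    gam <- cf[2 + k + (1:k)]
    if (any(abs(beta) < 1e-12)) break  # flat slope change: psi unidentifiable
    # since d/dpsi (x - psi)_+ = -I(x > psi), the gap coefficient estimates
    # gamma = -beta * (psi_true - psi), hence the update psi - gamma/beta
    step <- -gam / beta
    # damped update: halve the step until the broken-line RSS does not worsen
    cur <- broken_rss(psi)
    h <- 1
    repeat {
      cand <- project(psi + h * step)
      if (broken_rss(cand) <= cur + 1e-12 || h < 1e-3) break
      h <- h / 2
    }
    delta <- max(abs(cand - psi))
    psi <- cand
    if (delta < tol) { converged <- TRUE; break }
  }
  # delta-method SE of psi_hat = psi + gamma/beta at the final design
  U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
  V <- vapply(psi, function(p) as.numeric(x > p), numeric(n))
  X <- cbind(1, x, U, V)
  qrX <- qr(X)
  cf <- qr.coef(qrX, y)
  resid <- y - X %*% cf
  dfree <- max(1L, n - ncol(X))
  s2 <- sum(resid^2) / dfree
  XtXi <- chol2inv(qr.R(qrX))
  beta <- cf[2 + (1:k)]; gam <- cf[2 + k + (1:k)]
  psi_ci <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("lower", "upper")))
  for (j in seq_len(k)) {
    ib <- 2 + j; ig <- 2 + k + j
    vb <- s2 * XtXi[ib, ib]; vg <- s2 * XtXi[ig, ig]
    cv <- s2 * XtXi[ib, ig]
    if (abs(beta[j]) > 1e-12) {
      r <- -gam[j] / beta[j]
      se <- sqrt(max(0, (vg + r^2 * vb - 2 * r * cv))) / abs(beta[j])
      psi_ci[j, ] <- psi[j] + r + c(-1, 1) * qnorm(0.975) * se
    }
  }
  # final parameters from the pure broken-line model at psi (no gap terms)
  X0 <- cbind(1, x, U)
  cf0 <- qr.coef(qr(X0), y)
  r0 <- y - X0 %*% cf0
  slopes <- cumsum(c(cf0[2], cf0[2 + (1:k)]))
  structure(list(k = as.integer(k), psi = unname(psi), psi_ci = psi_ci,
                 intercept = unname(cf0[1]), slopes = unname(slopes),
                 rss = sum(r0^2), n = n, converged = converged,
                 iterations = it),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented fit: k = %d, RSS = %.6g, %s after %d iteration(s)\n",
              x$k, x$rss, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (x$k > 0)
    for (j in seq_len(x$k))
      cat(sprintf("  psi_%d = %.4f  (95%% CI %.4f-%.4f)\n", j, x$psi[j],
                  x$psi_ci[j, 1], x$psi_ci[j, 2]))
  cat("  slopes:", paste(signif(x$slopes, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of change points by BIC
#'
#' Fits segmented regressions with each candidate number of breakpoints
#' (default 1-4), using multiple deterministic starts per candidate (the
#' quantile initialization plus `n_starts` seeded random initializations;
#' the best-RSS converged fit is kept), and selects the fit minimizing
#' `BIC = n log(RSS / n) + p log(n)` with `p = 2 + 2k` parameters
#' (intercept, base slope, k slope changes, k breakpoints). A fit with
#' `RSS = 0` (perfect interpolation) is flagged and the smallest such `k`
#' is selected.
#'
#' @inheritParams fit_segmented
#' @param k_candidates integer vector of breakpoint counts to try.
#' @param n_starts number of random initializations per candidate.
#' @param seed seed for the random initializations.
#' @return list with `best` (a [fit_segmented()] result), `bic_table`
#'   (data frame `k`, `rss`, `bic`, `converged`), and `zero_rss` flag.
#' @export
select_changepoints <- function(x, y, k_candidates = 1:4, n_starts = 5,
                                seed = 1) {
  n <- length(x)
  fits <- list()
  rows <- list()
  prev_psi <- NULL
  for (k in sort(unique(k_candidates))) {
    cand <- list(NULL)  # quantile init
    if (k > 0 && n_starts > 0) {
      rnd <- .with_seed(.child_seed(seed, k), function()
        lapply(seq_len(n_starts), function(s)
          sort(runif(k, min(x), max(x)))))
      cand <- c(cand, rnd)
    }
    # warm start from the previous k's best fit: adding one breakpoint can
    # never worsen the broken-line RSS, which keeps RSS monotone in k
    if (!is.null(prev_psi) && length(prev_psi) == k - 1)
      cand <- c(cand, list(sort(c(prev_psi, median(x)))))
    best <- NULL
    for (ini in cand) {
      f <- tryCatch(fit_segmented(x, y, k, psi = ini),
                    error = function(e) NULL)
      if (is.null(f)) next
      if (is.null(best) || f$rss < best$rss - 1e-12 ||
          (abs(f$rss - best$rss) <= 1e-12 && f$converged && !best$converged))
        best <- f
    }
    if (is.null(best)) next
    prev_psi <- best$psi
    p <- 2 + 2 * k
    bic <- if (best$rss <= 1e-12) -Inf else n * log(best$rss / n) + p * log(n)
    fits[[as.character(k)]] <- best
    rows[[as.character(k)]] <- data.frame(k = k, rss = best$rss, bic = bic,
                                          converged = best$converged)
  }
  if (!length(fits)) .stopf("no candidate model could be fitted")
  tab <- do.call(rbind, rows)
  zero <- !is.finite(tab$bic)
  pick <- if (any(zero)) which(zero)[1] else which.min(tab$bic)
  list(best = fits[[pick]], bic_table = tab, zero_rss = any(zero))
}
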