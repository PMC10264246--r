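#' Per-cell quality control: unique fragments and FrIP
#'
#' For each cell (per modality): `n_unique` = number of deduplicated
#' fragments, `frip` = fraction overlapping (>= 1 bp) any peak. Cells with
#' zero fragments do not appear. Interval intersection is done by sorted
#' overlap on GRanges.
#'
#' @param fragments deduplicated fragment data.frame.
#' @param peaks `GRanges` peak set.
#' @return `CellQCRecord` data.frame: cell, modality, n_unique, frip,
#'   log10_n.
#' @export
compute_cell_qc <- function(fragments, peaks) {
  if (!nrow(fragments)) {
    return(data.frame(cell = character(), modality = character(),
                      n_unique = integer(), frip = numeric(), log10_n = numeric()))
  }
  hit <- if (length(peaks)) IRanges::overlapsAny(df_to_granges(fragments), peaks)
         else rep(FALSE, nrow(fragments))
  key <- interaction(fragments$cell, fragments$modality, drop = TRUE)
  n <- tapply(hit, key, length)
  fr <- tapply(hit, key, mean)
  ids <- strsplit(names(n), ".", fixed = TRUE)
  # interaction() joins with "."; cell barcodes are ACGT so "." is safe
  out <- data.frame(
    cell = vapply(ids, `[`, character(1), 1),
    modality = vapply(ids, function(x) paste(x[-1], collapse = "."), character(1)),
    n_unique = as.integer(n),
    frip = as.numeric(fr), stringsAsFactors = FALSE)
  out$log10_n <- log10(out$n_unique)
  rownames(out) <- NULL
  out
}

# log density of a 2-D Gaussian with covariance S (regularized upstream)
dmvnorm2_log <- function(x, mu, S) {
  ch <- chol(S)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Two-component Gaussian mixture fit by EM
#'
#' Fits a full-covariance two-component mixture to (log10 unique fragments,
#' FrIP) points, the standard cell-vs-droplet separation for tagmentation
#' data. Initialization is deterministic: points are split at the median of
#' the first coordinate and component moments are taken from the halves, so
#' fits are reproducible without a seed. EM stops when the log-likelihood
#' gain drops below `tol` or after `max_iter` iterations; covariances are
#' regularized by `reg` on the diagonal.
#'
#' @param points numeric matrix/data.frame with two columns (log10_n, frip).
#' @param tol,max_iter,reg convergence tolerance, iteration cap, covariance
#'   ridge.
#' @return a `GMMFit`: means (2 x 2), covariances, weights, responsibilities,
#'   log-likelihood trace, `converged`.
#' @export
fit_gmm2 <- function(points, tol = 1e-6, max_iter = 500, reg = 1e-6) {
  x <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(x) <- "double"
  if (nrow(x) < 20) stopf("need >= 20 points to fit the mixture")
  if (anyNA(x) || any(!is.finite(x))) stopf("points must be finite")
  if (all(apply(x, 2, function(v) diff(range(v))) == 0))
    stopf("degenerate input: all points identical")
  n <- nrow(x)
  grp <- x[, 1] <= median(x[, 1])
  if (sum(grp) < 2 || sum(!grp) < 2) grp <- seq_len(n) <= n / 2
  comp_moments <- function(idx) {
    list(mu = colMeans(x[idx, , drop = FALSE]),
         S = stats::cov(x[idx, , drop = FALSE]) + diag(reg, 2))
  }
  m1 <- comp_moments(grp); m2 <- comp_moments(!grp)
  mu <- rbind(m1$mu, m2$mu)
  S <- list(m1$S, m2$S)
  w <- c(mean(grp), mean(!grp))
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- cbind(log(w[1]) + dmvnorm2_log(x, mu[1, ], S[[1]]),
                  log(w[2]) + dmvnorm2_log(x, mu[2, ], S[[2]]))
    mx <- pmax(logd[, 1], logd[, 2])
    lse <- mx + log(exp(logd[, 1] - mx) + exp(logd[, 2] - mx))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    r <- exp(logd - lse)
    if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
    for (kk in 1:2) {
      rk <- r[, kk]
      nk <- sum(rk)
      mu[kk, ] <- colSums(x * rk) / nk
      xc <- sweep(x, 2, mu[kk, ])
      S[[kk]] <- crossprod(xc, xc * rk) / nk + diag(reg, 2)
      w[kk] <- nk / n
    }
  }
  structure(list(means = mu, covariances = S, weights = w,
                 responsibilities = r, loglik_trace = ll_trace,
                 converged = converged), class = "GMMFit")
}

#' Select passing cells from a GMM fit
#'
#' The cell component is the one with the larger mean on both axes (more
#' fragments and higher FrIP); if neither dominates both, the component with
#' the larger FrIP mean is used with a warning. A cell passes when its
#' posterior responsibility for the cell component exceeds 0.5 (strictly).
#'
#' @param qc `CellQCRecord` table (rows aligned with the fit's points).
#' @param fit a [fit_gmm2()] result.
#' @return `qc` with logical `pass` and numeric `posterior` columns; the cell
#'   component index in `attr(, "cells_component")`.
#' @export
select_cells <- function(qc, fit) {
  stopifnot(inherits(fit, "GMMFit"), nrow(qc) == nrow(fit$responsibilities))
  dom <- (fit$means[1, 1] - fit$means[2, 1]) * (fit$means[1, 2] - fit$means[2, 2])
  if (dom > 0) {
    comp <- if (fit$means[1, 1] > fit$means[2, 1]) 1L else 2L
  } else {
    warnf("no component dominates both axes; using the larger FrIP mean")
    comp <- if (fit$means[1, 2] >= fit$means[2, 2]) 1L else 2L
  }
  qc$posterior <- fit$responsibilities[, comp]
  qc$pass <- qc$posterior > 0.5
  attr(qc, "cells_component") <- comp
  qc
}

#' Intersect passing-cell sets across modalities
#'
#' @param pass_sets named list (>= 2) of passing barcode vectors, one per
#'   modality.
#' @return list with `joint` (barcodes passing all modalities) and
#'   `fraction` = |joint| / |union of cells identified in any modality|.
#' @export
intersect_modalities <- function(pass_sets) {
  if (length(pass_sets) < 2) stopf("need at least two modalities")
  joint <- Reduce(intersect, pass_sets)
  all_ids <- Reduce(union, pass_sets)
  list(joint = joint,
       fraction = if (length(all_ids)) length(joint) / length(all_ids) else NA_real_)
}
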