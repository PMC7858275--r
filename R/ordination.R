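# Non-metric multidimensional scaling -----------------------------------------

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style NMDS: configuration distances are fitted to the
#' dissimilarities by monotone (isotonic) regression on their ranks
#' (pool-adjacent-violators via [stats::isoreg()]), and the configuration is
#' updated by iterative majorization (a Guttman transform towards the
#' disparities). Stress is Kruskal's stress-1,
#' `sqrt(sum((dhat - d)^2) / sum(d^2))` over all pairs. An update that would
#' increase stress is step-halved towards the previous configuration, so
#' accepted iterations never increase stress. The first start is the
#' classical (metric) scaling solution; remaining starts are random. The
#' best start by final stress is returned with centered coordinates.
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`).
#' @param k Number of ordination dimensions.
#' @param n_starts Number of starts (first is metric-scaling).
#' @param max_iter Maximum majorization iterations per start.
#' @param tol Relative stress-change convergence tolerance.
#' @param seed Integer seed for the random starts.
#' @return List of class `nmds_result`: `points` (n x k), `stress`,
#'   `n_iterations`, `converged`, `best_start`, `stress_per_start`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, max_iter = 300L, tol = 1e-6,
                 seed = 1L) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < k + 2L) stop("need at least k + 2 samples")
  low <- lower.tri(d)
  delta <- d[low]
  ord <- order(delta)

  run_start <- function(X0) {
    X <- X0
    D <- as.matrix(dist(X))
    stress_of <- function(Dm) {
      dv <- Dm[low]
      dhat <- numeric(length(dv))
      dhat[ord] <- isoreg(dv[ord])$yf
      list(stress = sqrt(sum((dhat - dv)^2) / sum(dv^2)), dhat = dhat)
    }
    st <- stress_of(D)
    iters <- 0L; converged <- FALSE
    for (it in seq_len(max_iter)) {
      iters <- it
      # Guttman transform towards the disparities
      dhat_m <- matrix(0, n, n)
      dhat_m[low] <- st$dhat
      dhat_m <- dhat_m + t(dhat_m)
      Dpos <- D; Dpos[Dpos < 1e-12] <- 1e-12
      Bmat <- -dhat_m / Dpos
      diag(Bmat) <- 0
      diag(Bmat) <- -rowSums(Bmat)
      Xn <- Bmat %*% X / n
      Dn <- as.matrix(dist(Xn))
      stn <- stress_of(Dn)
      step <- 1
      while (stn$stress > st$stress && step > 1e-4) {
        step <- step / 2
        Xn <- X + step * (Bmat %*% X / n - X)
        Dn <- as.matrix(dist(Xn))
        stn <- stress_of(Dn)
      }
      if (stn$stress > st$stress) { converged <- TRUE; break }
      improved <- (st$stress - stn$stress) / max(st$stress, 1e-12)
      X <- Xn; D <- Dn; st <- stn
      if (improved < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = st$stress, iters = iters, converged = converged)
  }

  starts <- vector("list", n_starts)
  starts[[1L]] <- tryCatch(cmdscale(d, k = k), error = function(e) NULL)
  if (is.null(starts[[1L]]) || ncol(starts[[1L]]) < k)
    starts[[1L]] <- with_stream_seed(seed, "nmds/0",
                                     matrix(rnorm(n * k), n, k))
  if (n_starts > 1L)
    for (s in 2:n_starts)
      starts[[s]] <- with_stream_seed(seed, paste0("nmds/", s - 1L),
                                      matrix(runif(n * k, -1, 1) *
                                               max(delta), n, k))
  fits <- lapply(starts, run_start)
  stresses <- vapply(fits, `[[`, 0, "stress")
  best <- which.min(stresses)
  X <- scale(fits[[best]]$X, center = TRUE, scale = FALSE)
  dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(points = X, stress = fits[[best]]$stress,
                 n_iterations = fits[[best]]$iters,
                 converged = fits[[best]]$converged,
                 best_start = best, stress_per_start = stresses),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points, %d dims, stress = %.4f (%s, start %d/%d)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged",
              x$best_start, length(x$stress_per_start)))
  invisible(x)
}
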