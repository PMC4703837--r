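#' Fit motif activities by ridge regression
#'
#' Linear response model relating binding-site counts to per-stage
#' signal: `E[p, s] = c_s + c_p + sum_m N[p, m] * A[m, s]`. The peak and
#' stage offsets are removed in closed form by double-centering E; the
#' motif-count columns are mean-centered so the offsets cannot leak into
#' the activities, and the ridge estimate is
#' `A = (Nc' Nc + lambda I)^-1 Nc' Ec`. Activities are identifiable up
#' to a per-motif constant across stages (rows of A are centered).
#' z-scores are activity over the posterior standard deviation
#' `sqrt(sigma^2 diag((Nc' Nc + lambda I)^-1))` with plug-in residual
#' variance.
#'
#' @param N peaks x motifs non-negative count matrix.
#' @param E peaks x stages signal matrix (same row order as `N`).
#' @param lambda Ridge penalty (>= 0); `lambda = 0` requires full
#'   column rank.
#' @return A `madzyd_activity` list: `A` (motifs x stages), `z`,
#'   `posterior_sd`, `sigma2`, `lambda`, `peak_offsets`,
#'   `stage_offsets`.
#' @export
fit_activities <- function(N, E, lambda) {
  N <- as.matrix(N); E <- as.matrix(E)
  if (nrow(N) != nrow(E)) stop("N and E must have matching peak rows")
  if (any(N < 0)) stop("motif counts must be non-negative")
  if (lambda < 0) stop("lambda must be non-negative")
  P <- nrow(N); M <- ncol(N); S <- ncol(E)
  peak_off <- rowMeans(E)
  stage_off <- colMeans(E) - mean(E)
  Ec <- E - peak_off %o% rep(1, S) - rep(1, P) %o% stage_off
  Nc <- scale(N, center = TRUE, scale = FALSE)
  G <- crossprod(Nc) + diag(lambda, M)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) {
    stop("normal matrix is rank-deficient; use lambda > 0")
  }
  A <- backsolve(ch, forwardsolve(t(ch), crossprod(Nc, Ec)))
  dimnames(A) <- list(colnames(N), colnames(E))
  resid <- Ec - Nc %*% A
  df <- max(1, P * S - M * S - P - S + 1)
  sigma2 <- sum(resid^2) / df
  Ginv_diag <- diag(chol2inv(ch))
  sd_m <- sqrt(sigma2 * Ginv_diag)
  z <- A / sd_m
  structure(list(A = A, z = z, posterior_sd = sd_m, sigma2 = sigma2,
                 lambda = lambda, peak_offsets = peak_off,
                 stage_offsets = stage_off),
            class = "madzyd_activity")
}

#' Choose the ridge penalty by cross-validation
#'
#' K-fold cross-validation over peaks on a log-spaced grid: for each
#' fold the model is fitted on the training peaks and the held-out
#' centered signal is predicted from the held-out motif counts; the
#' lambda minimizing mean squared prediction error wins. Fold
#' assignment is seeded, so the choice is deterministic.
#'
#' @param N,E As in [fit_activities()].
#' @param folds Number of folds (>= 2).
#' @param grid Candidate lambdas (default `10^seq(-3, 4, length 15)`).
#' @param seed Integer seed for fold assignment.
#' @return List with `lambda` (selected), `cv_error` (named per-grid
#'   mean squared errors).
#' @export
select_lambda <- function(N, E, folds = 5L,
                          grid = 10^seq(-3, 4, length.out = 15),
                          seed = 1L) {
  N <- as.matrix(N); E <- as.matrix(E)
  P <- nrow(N)
  if (folds < 2) stop("need at least 2 folds")
  if (P < 2 * folds) stop("too few peaks for ", folds, "-fold cross-validation")
  fold <- with_seed(seed + 808L, sample(rep(seq_len(folds), length.out = P)))
  err <- sapply(grid, function(lam) {
    se <- 0; nn <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- fit_activities(N[tr, , drop = FALSE], E[tr, , drop = FALSE], lam)
      n_mean <- colMeans(N[tr, , drop = FALSE])
      Nc_te <- sweep(N[te, , drop = FALSE], 2, n_mean)
      S <- ncol(E)
      Ec_te <- E[te, , drop = FALSE] -
        rowMeans(E[te, , drop = FALSE]) %o% rep(1, S) -
        rep(1, sum(te)) %o% fit$stage_offsets
      r <- Ec_te - Nc_te %*% fit$A
      se <- se + sum(r^2); nn <- nn + length(r)
    }
    se / nn
  })
  names(err) <- signif(grid, 4)
  list(lambda = grid[which.min(err)], cv_error = err)
}

#' Motifs with significant activity
#'
#' Motifs whose maximum absolute z-score across stages exceeds the
#' threshold (default 13), ordered by decreasing maximum |z|.
#'
#' @param model A [fit_activities()] result.
#' @param z_threshold Selection threshold (strict >).
#' @return data.frame (motif, max_abs_z), possibly empty.
#' @export
significant_motifs <- function(model, z_threshold = 13) {
  mz <- apply(abs(model$z), 1, max)
  sel <- mz > z_threshold
  out <- data.frame(motif = names(mz)[sel], max_abs_z = unname(mz[sel]),
                    stringsAsFactors = FALSE)
  out[order(-out$max_abs_z), , drop = FALSE]
}
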