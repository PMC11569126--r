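#' @title Mechanism-integrated group-wise pre-imputation and peer imputers
#' @description Implements MGpI — a per-gene, per-group blend of a
#'   lower-limit-of-detection (LLOD) floor fill and the group mean, weighted
#'   by the estimated probability that the missing value was censored below
#'   the detection floor — together with the classical comparator methods:
#'   half-minimum, per-gene mean, sample-wise k-nearest neighbours, and four
#'   low-rank matrix completions (probabilistic PCA, NIPALS, EM-SVD,
#'   singular value thresholding).
#' @name imputation
NULL

imputation_result <- function(matrix, method, params = list()) {
  structure(list(matrix = matrix, method = method, params = params),
            class = "imputation_result")
}

#' @method print imputation_result
#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result: method=%s, %d x %d\n", x$method,
              nrow(x$matrix$values), ncol(x$matrix$values)))
  invisible(x)
}

# rebuild an all-observed omics_matrix in the input's space, restoring the
# originally observed cells bit-identically from the input
finish_imputation <- function(orig, filled_log_or_same, work_space, pseudo) {
  v <- filled_log_or_same
  if (orig$space != work_space) {
    v <- if (orig$space == "linear") pmax(2^v - pseudo, 0) else log2(v + pseudo)
  }
  v[!orig$mask] <- orig$values[!orig$mask]
  mask <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(orig$values))
  omics_matrix(v, mask = mask, space = orig$space)
}

#' Median-match samples on the genes with no missing values
#'
#' Initial normalization step for MGpI: using only the genes observed in
#' every sample, each sample receives an additive log-space offset so that
#' its median over those complete genes equals the grand median of all
#' complete-gene values. Masked cells are untouched.
#'
#' @param m an `omics_matrix` in log2 space.
#' @return The normalized `omics_matrix`, with the per-sample offsets
#'   attached as `attr(, "offsets")` (named numeric vector).
#' @export
normalize_complete_genes <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$space != "log2") stop("normalization operates in log2 space")
  complete <- rowSums(m$mask) == 0
  if (!any(complete))
    stop("no gene is observed in every sample; pre-normalize the matrix ",
         "before imputation")
  sub <- m$values[complete, , drop = FALSE]
  grand <- stats::median(sub)
  offsets <- grand - apply(sub, 2, stats::median)
  v <- m$values
  v[m$mask] <- NA_real_
  v <- sweep(v, 2, offsets, "+")
  out <- omics_matrix(v, mask = m$mask, space = "log2")
  attr(out, "offsets") <- offsets
  out
}

#' Global LLOD floor: minimum observed log-space intensity
#'
#' @param m an `omics_matrix` in log2 space.
#' @return The minimum over all observed entries (scalar).
#' @export
estimate_epsilon <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$space != "log2") stop("epsilon is defined on the log2 matrix")
  obs <- m$values[!m$mask]
  if (length(obs) == 0) stop("matrix has no observed values")
  min(obs)
}

# per-group observed count, mean and sd for every gene; vectorized
group_stats <- function(v_obs, grp, groups) {
  K <- length(groups)
  n <- mu <- sd <- matrix(NA_real_, nrow(v_obs), K,
                          dimnames = list(rownames(v_obs), groups))
  for (k in seq_len(K)) {
    sub <- v_obs[, grp == groups[k], drop = FALSE]
    nk <- rowSums(!is.na(sub))
    s1 <- rowSums(sub, na.rm = TRUE)
    s2 <- rowSums(sub^2, na.rm = TRUE)
    mk <- ifelse(nk > 0, s1 / nk, NA_real_)
    vk <- ifelse(nk > 1, pmax(s2 - nk * mk^2, 0) / (nk - 1), NA_real_)
    n[, k] <- nk
    mu[, k] <- mk
    sd[, k] <- sqrt(vk)
  }
  list(n = n, mean = mu, sd = sd)
}

#' Fit the MGpI group model
#'
#' For every gene i and group k, computes the observed-data mean
#' \eqn{\bar x_k(i)} and standard deviation \eqn{\sigma_k(i)} (missing cells
#' never enter the estimates) and the LLOD probability
#' \eqn{\alpha_k(i) = \Phi((\epsilon - \bar x_k(i)) / \sigma_k(i))}, the
#' lower-tail normal mass below the global detection floor \eqn{\epsilon}.
#'
#' Degenerate cells follow the continuous limits of the fill rule: a group
#' with no observed value gets \eqn{\alpha = 1}; with a single observed
#' value, that value is the mean and the gene's pooled across-group SD
#' stands in for \eqn{\sigma}; a zero (or undefined) \eqn{\sigma} gives
#' \eqn{\alpha = 1} when \eqn{\bar x \le \epsilon} and 0 otherwise.
#'
#' @param m an `omics_matrix` in log2 space.
#' @param g a [group_labels()] object covering all samples.
#' @param epsilon LLOD floor; defaults to [estimate_epsilon()] of `m`.
#' @return A `group_model` list: `epsilon`, and gene x group matrices
#'   `group_mean`, `group_sd`, `llod_prob`, `n_observed`; plus `groups`.
#' @export
fit_group_model <- function(m, g, epsilon = NULL) {
  stopifnot(inherits(m, "omics_matrix"), inherits(g, "group_labels"))
  if (m$space != "log2") stop("group model is fitted in log2 space")
  grp <- match_labels(m, g)
  if (is.null(epsilon)) epsilon <- estimate_epsilon(m)
  v <- observed_values(m)
  st <- group_stats(v, grp, g$groups)
  pooled <- apply(v, 1, stats::sd, na.rm = TRUE)   # across-group fallback
  sigma <- st$sd
  single <- st$n == 1
  if (any(single))
    sigma[single] <- pooled[row(sigma)[single]]
  alpha <- matrix(NA_real_, nrow(v), ncol(st$mean), dimnames = dimnames(st$mean))
  ok <- !is.na(st$mean) & !is.na(sigma) & sigma > 0
  alpha[ok] <- stats::pnorm((epsilon - st$mean[ok]) / sigma[ok])
  deg <- !is.na(st$mean) & !ok                      # sigma zero or undefined
  alpha[deg] <- ifelse(st$mean[deg] <= epsilon, 1, 0)
  alpha[is.na(st$mean)] <- 1                        # fully missing group cell
  structure(list(epsilon = epsilon, group_mean = st$mean, group_sd = st$sd,
                 llod_prob = alpha, n_observed = st$n, groups = g$groups),
            class = "group_model")
}

#' MGpI: mechanism-integrated group-wise pre-imputation
#'
#' Every missing cell of gene i in group k is filled (in log2 space) with
#' \deqn{\tilde x_k(i) = \alpha_k(i)\,\epsilon/2 + [1 - \alpha_k(i)]\,\bar x_k(i),}
#' a blend of the LLOD floor fill \eqn{\epsilon/2} (half-minimum reading)
#' and the group mean, weighted by the censoring probability
#' \eqn{\alpha_k(i)} from [fit_group_model()]. All missing cells of the same
#' gene/group receive the same value; observed cells are returned exactly.
#'
#' @param m an `omics_matrix` (linear input is converted to log2 with
#'   `pseudo` and converted back on return).
#' @param g a [group_labels()] object.
#' @param llod_fill `"half_log_min"` applies \eqn{\epsilon/2} literally in
#'   log space; `"log_of_half_linear_min"` uses \eqn{\epsilon - 1} (log2 of
#'   half the linear minimum).
#' @param normalize `"auto"` median-matches samples on complete genes when
#'   at least one exists (skipped otherwise); `"always"` errors when no
#'   complete gene exists; `"never"` skips. Fills are mapped back to each
#'   sample's original scale, so observed values are never altered.
#' @param pseudo pseudo-count for linear inputs.
#' @return An `imputation_result` whose `matrix` has no missing cells.
#' @export
mgpi_impute <- function(m, g, llod_fill = c("half_log_min",
                                            "log_of_half_linear_min"),
                        normalize = c("auto", "always", "never"),
                        pseudo = 0) {
  llod_fill <- match.arg(llod_fill)
  normalize <- match.arg(normalize)
  stopifnot(inherits(m, "omics_matrix"))
  work <- ensure_space(m, "log2", pseudo)
  offsets <- stats::setNames(rep(0, ncol(work$values)), sample_ids(work))
  has_complete <- any(rowSums(work$mask) == 0)
  if (normalize == "always" || (normalize == "auto" && has_complete)) {
    work <- normalize_complete_genes(work)
    offsets <- attr(work, "offsets")
  }
  grp <- match_labels(work, g)
  model <- fit_group_model(work, g)
  floor_fill <- if (llod_fill == "half_log_min") model$epsilon / 2
                else model$epsilon - 1
  mu <- model$group_mean
  mu[is.na(mu)] <- 0                      # weight (1 - alpha) is 0 there
  fill <- model$llod_prob * floor_fill + (1 - model$llod_prob) * mu
  v <- observed_values(work)
  kidx <- match(grp, model$groups)
  miss <- which(work$mask, arr.ind = TRUE)
  if (nrow(miss)) {
    # undo the per-sample normalization offset so fills sit on the input scale
    v[miss] <- fill[cbind(miss[, 1], kidx[miss[, 2]])] - offsets[miss[, 2]]
  }
  out <- finish_imputation(m, v, "log2", pseudo)
  imputation_result(out, "mgpi",
                    list(epsilon = model$epsilon, llod_fill = llod_fill,
                         normalize = normalize, model = model))
}

#' Half-minimum imputation (linear space)
#'
#' Per gene, missing values are filled with half the minimum observed
#' linear intensity of that gene across all samples — the classical LLOD
#' fill. Log2 input is converted, filled and converted back.
#'
#' @inheritParams mgpi_impute
#' @return An `imputation_result`.
#' @export
halfmin_impute <- function(m, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"))
  work <- ensure_space(m, "linear", pseudo)
  v <- observed_values(work)
  nobs <- rowSums(!work$mask)
  if (any(nobs == 0 & rowSums(work$mask) > 0))
    stop("gene(s) with no observed value: ",
         paste(utils::head(rownames(v)[nobs == 0], 5), collapse = ", "))
  fills <- apply(v, 1, min, na.rm = TRUE) / 2
  miss <- which(work$mask, arr.ind = TRUE)
  if (nrow(miss)) v[miss] <- fills[miss[, 1]]
  out <- finish_imputation(m, v, "linear", pseudo)
  imputation_result(out, "min2", list())
}

#' Per-gene mean imputation (log2 space)
#'
#' Missing values are filled with the mean of the gene's observed log2
#' intensities across all samples — the classical MAR/MCAR fill.
#'
#' @inheritParams mgpi_impute
#' @return An `imputation_result`.
#' @export
mean_impute <- function(m, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"))
  work <- ensure_space(m, "log2", pseudo)
  v <- observed_values(work)
  nobs <- rowSums(!work$mask)
  if (any(nobs == 0))
    stop("gene(s) with no observed value: ",
         paste(utils::head(rownames(v)[nobs == 0], 5), collapse = ", "))
  fills <- rowMeans(v, na.rm = TRUE)
  miss <- which(work$mask, arr.ind = TRUE)
  if (nrow(miss)) v[miss] <- fills[miss[, 1]]
  out <- finish_imputation(m, v, "log2", pseudo)
  imputation_result(out, "mean", list())
}

#' Sample-wise k-nearest-neighbour imputation (log2 space)
#'
#' A missing cell (gene i, sample s) is filled with the weighted mean of
#' gene i in the k samples closest to s. Distance between two samples is
#' the Euclidean distance over the features observed in both; the weight of
#' a neighbour at distance d is 1 / (d + delta). When gene i is observed in
#' no other sample, the fill falls back to the gene's observed mean (a
#' message is emitted).
#'
#' @inheritParams mgpi_impute
#' @param k number of neighbours, must be < number of samples.
#' @param delta weight regularizer (default 1e-6), so that an exact
#'   duplicate sample (distance 0) dominates the average.
#' @return An `imputation_result`.
#' @export
swknn_impute <- function(m, k = 10, delta = 1e-6, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"), k >= 1)
  if (k >= ncol(m$values)) stop("k must be smaller than the number of samples")
  work <- ensure_space(m, "log2", pseudo)
  v <- observed_values(work)
  nobs <- rowSums(!work$mask)
  if (any(nobs == 0))
    stop("gene(s) with no observed value: ",
         paste(utils::head(rownames(v)[nobs == 0], 5), collapse = ", "))
  S <- ncol(v)
  # pairwise distances over co-observed features
  D <- matrix(Inf, S, S)
  for (s in seq_len(S - 1)) for (t in (s + 1):S) {
    co <- !is.na(v[, s]) & !is.na(v[, t])
    if (any(co)) D[s, t] <- D[t, s] <- sqrt(sum((v[co, s] - v[co, t])^2))
  }
  gene_means <- rowMeans(v, na.rm = TRUE)
  fallback <- 0L
  miss <- which(work$mask, arr.ind = TRUE)
  filled <- v
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; s <- miss[r, 2]
    cand <- which(!is.na(v[i, ]) & seq_len(S) != s & is.finite(D[s, ]))
    if (length(cand) == 0) {
      filled[i, s] <- gene_means[i]
      fallback <- fallback + 1L
      next
    }
    ord <- cand[order(D[s, cand], cand)]         # ties break by sample index
    nb <- ord[seq_len(min(k, length(ord)))]
    w <- 1 / (D[s, nb] + delta)
    filled[i, s] <- sum(w * v[i, nb]) / sum(w)
  }
  if (fallback > 0)
    message("swknn: ", fallback, " cell(s) fell back to the gene mean")
  out <- finish_imputation(m, filled, "log2", pseudo)
  imputation_result(out, "swknn",
                    list(k = k, delta = delta, n_fallback = fallback))
}

frob_delta <- function(a, b, idx) sqrt(sum((a[idx] - b[idx])^2))

# default rank: 90% cumulative variance (squared singular values) of the
# mean-filled matrix
default_rank <- function(xc) {
  d2 <- svd(xc, nu = 0, nv = 0)$d^2
  r <- which(cumsum(d2) / sum(d2) >= 0.9)[1]
  max(1L, min(r, min(dim(xc)) - 1L))
}

#' Low-rank matrix-completion imputation (PPCA, NIPALS, EM-SVD, SVT)
#'
#' Four classical matrix-factorization imputers operating in log2 space:
#' \describe{
#'   \item{ppca}{probabilistic PCA fitted by expectation-maximization; the
#'     posterior-mean reconstruction refills the missing cells each
#'     iteration. Random initialization — `seed` is mandatory.}
#'   \item{nipals}{missing-data-tolerant NIPALS PCA: components estimated
#'     by iterative regressions that skip missing cells.}
#'   \item{svd}{EM-SVD: alternate a truncated SVD of the current completed
#'     matrix with refilling the missing cells from the reconstruction.}
#'   \item{svt}{singular value thresholding for nuclear-norm minimization:
#'     soft-threshold the singular values, then re-project onto the
#'     observed entries with step size `svt_step`.}
#' }
#' Convergence is declared when the Frobenius change of the imputed cells
#' between successive iterates drops below `tol`; otherwise the best
#' iterate is returned with a warning and `params$converged = FALSE`.
#'
#' @inheritParams mgpi_impute
#' @param method one of `"ppca"`, `"nipals"`, `"svd"`, `"svt"`.
#' @param rank target rank; default: smallest rank capturing 90% of the
#'   squared-singular-value mass of the mean-filled matrix.
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param seed RNG seed, required for `ppca`.
#' @param svt_tau SVT shrinkage threshold; default 0.1 x largest singular
#'   value of the mean-filled matrix.
#' @param svt_step SVT step size (default 1).
#' @return An `imputation_result`.
#' @export
lowrank_impute <- function(m, method = c("ppca", "nipals", "svd", "svt"),
                           rank = NULL, tol = 1e-6, max_iter = 500,
                           seed = NULL, svt_tau = NULL, svt_step = 1,
                           pseudo = 0) {
  method <- match.arg(method)
  stopifnot(inherits(m, "omics_matrix"))
  work <- ensure_space(m, "log2", pseudo)
  v <- observed_values(work)
  missing <- work$mask
  if (!any(missing)) {
    return(imputation_result(finish_imputation(m, v, "log2", pseudo),
                             method, list(rank = rank, converged = TRUE,
                                          iterations = 0L)))
  }
  if (any(rowSums(!missing) == 0))
    stop("gene(s) with no observed value cannot be mean-initialized")
  mean_fill <- v
  gm <- rowMeans(v, na.rm = TRUE)
  mean_fill[missing] <- gm[row(v)[missing]]
  if (is.null(rank)) rank <- default_rank(mean_fill)
  if (rank >= min(dim(v))) stop("rank must be < min(genes, samples)")
  res <- switch(method,
    svd = fit_em_svd(v, missing, mean_fill, rank, tol, max_iter),
    ppca = fit_ppca(v, missing, mean_fill, rank, tol, max_iter, seed),
    nipals = fit_nipals(v, missing, rank, tol, max_iter),
    svt = fit_svt(v, missing, mean_fill, rank, tol, max_iter,
                  svt_tau, svt_step))
  if (!res$converged)
    warning(method, " imputation did not converge in ", max_iter,
            " iterations; returning best iterate")
  out <- finish_imputation(m, res$filled, "log2", pseudo)
  imputation_result(out, method,
                    c(list(rank = rank, tol = tol), res[c("converged",
                                                          "iterations")]))
}

fit_em_svd <- function(v, missing, xc, rank, tol, max_iter) {
  for (it in seq_len(max_iter)) {
    s <- svd(xc, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    new <- xc
    new[missing] <- recon[missing]
    if (frob_delta(new, xc, missing) < tol)
      return(list(filled = new, converged = TRUE, iterations = it))
    xc <- new
  }
  list(filled = xc, converged = FALSE, iterations = max_iter)
}

fit_ppca <- function(v, missing, xc, rank, tol, max_iter, seed) {
  if (is.null(seed)) stop("ppca requires a `seed` for its random initialization")
  set.seed(seed)
  d <- nrow(xc); n <- ncol(xc)
  W <- matrix(stats::rnorm(d * rank), d, rank)
  sig2 <- 1
  for (it in seq_len(max_iter)) {
    mu <- rowMeans(xc)
    Xd <- xc - mu
    M <- crossprod(W) + sig2 * diag(rank)
    Minv <- solve(M)
    Z <- Minv %*% crossprod(W, Xd)                        # r x n latent means
    Szz <- n * sig2 * Minv + tcrossprod(Z)
    W_new <- (Xd %*% t(Z)) %*% solve(Szz)
    resid <- sum(Xd^2) - 2 * sum((crossprod(W_new, Xd)) * Z) +
      sum(Szz * crossprod(W_new))
    sig2 <- max(resid / (n * d), 1e-12)
    W <- W_new
    recon <- mu + W %*% (solve(crossprod(W) + sig2 * diag(rank)) %*%
                           crossprod(W, Xd))
    new <- xc
    new[missing] <- recon[missing]
    if (frob_delta(new, xc, missing) < tol)
      return(list(filled = new, converged = TRUE, iterations = it))
    xc <- new
  }
  list(filled = xc, converged = FALSE, iterations = max_iter)
}

fit_nipals <- function(v, missing, rank, tol, max_iter) {
  mu <- rowMeans(v, na.rm = TRUE)
  Xd <- v - mu
  recon <- matrix(0, nrow(v), ncol(v))
  obs <- !missing
  iterations <- 0L
  converged <- TRUE
  for (h in seq_len(rank)) {
    tvec <- ifelse(is.na(Xd[1, ]), 0, Xd[1, ])
    if (all(tvec == 0)) tvec <- stats::rnorm(ncol(v))
    comp_ok <- FALSE
    for (it in seq_len(max_iter)) {
      iterations <- iterations + 1L
      # loadings: per-gene regression on t over observed cells
      T2 <- matrix(rep(tvec^2, each = nrow(v)), nrow(v))
      num <- rowSums(sweep(ifelse(obs, Xd, 0), 2, tvec, "*"))
      den <- rowSums(ifelse(obs, T2, 0))
      p <- ifelse(den > 0, num / den, 0)
      p <- p / max(sqrt(sum(p^2)), 1e-12)
      # scores: per-sample regression on p over observed cells
      P2 <- matrix(rep(p^2, ncol(v)), nrow(v))
      numt <- colSums(ifelse(obs, Xd, 0) * p)
      dent <- colSums(ifelse(obs, P2, 0))
      t_new <- ifelse(dent > 0, numt / dent, 0)
      if (sqrt(sum((t_new - tvec)^2)) < tol * max(sqrt(sum(t_new^2)), 1)) {
        tvec <- t_new; comp_ok <- TRUE; break
      }
      tvec <- t_new
    }
    if (!comp_ok) converged <- FALSE
    comp <- tcrossprod(p, tvec)
    recon <- recon + comp
    Xd <- Xd - comp                 # NA cells stay NA; obs mask handles them
  }
  filled <- v
  filled[missing] <- (mu + recon)[missing]
  list(filled = filled, converged = converged, iterations = iterations)
}

fit_svt <- function(v, missing, xc, rank, tol, max_iter, tau, step) {
  obs <- !missing
  if (is.null(tau)) tau <- 0.1 * svd(xc, nu = 0, nv = 0)$d[1]
  M <- ifelse(obs, v, 0)
  Y <- M
  prev <- xc
  for (it in seq_len(max_iter)) {
    s <- svd(Y)
    dshr <- pmax(s$d - tau, 0)
    keep <- dshr > 0
    X <- if (any(keep)) {
      s$u[, keep, drop = FALSE] %*% (dshr[keep] * t(s$v[, keep, drop = FALSE]))
    } else matrix(0, nrow(v), ncol(v))
    Y <- Y + step * ifelse(obs, M - X, 0)
    if (frob_delta(X, prev, missing) < tol) {
      filled <- v; filled[missing] <- X[missing]
      return(list(filled = filled, converged = TRUE, iterations = it))
    }
    prev <- X
  }
  filled <- v
  filled[missing] <- prev[missing]
  list(filled = filled, converged = FALSE, iterations = max_iter)
}

#' Run any of the suite's imputation methods by name
#'
#' Dispatcher used by the benchmark harness and the command-line wrapper.
#'
#' @inheritParams mgpi_impute
#' @param method one of `"mgpi"`, `"min2"`, `"mean"`, `"swknn"`, `"ppca"`,
#'   `"nipals"`, `"svd"`, `"svt"`.
#' @param ... passed to the underlying method.
#' @return An `imputation_result`.
#' @export
impute_matrix <- function(m, method, g = NULL, ...) {
  switch(method,
         mgpi = {
           if (is.null(g)) stop("mgpi requires group labels")
           mgpi_impute(m, g, ...)
         },
         min2 = halfmin_impute(m, ...),
         mean = mean_impute(m, ...),
         swknn = swknn_impute(m, ...),
         ppca = ,
         nipals = ,
         svd = ,
         svt = lowrank_impute(m, method = method, ...),
         stop("unknown imputation method: ", method))
}
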