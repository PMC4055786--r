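# Seed handling: evaluate `expr` under `seed` without disturbing the caller's
# RNG state. All draws inside are made in subject-major order so that
# increasing the number of subjects appends draws rather than reshuffling
# earlier subjects.
with_master_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Independent sub-seeds (one per replicate / subject block) derived from a
# master seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  with_master_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Upper-triangular Cholesky factor of a covariance matrix
#'
#' Computes the factor `CH` with `t(CH) %*% CH = cov`, used to turn
#' independent standard-normal draws into correlated random effects. The
#' factor is computed programmatically at run time; transcribing it by hand
#' is fragile because it must be redone whenever the covariance changes.
#'
#' @param cov Symmetric positive-definite covariance matrix.
#' @return The upper-triangular matrix `CH` (class `matrix`).
#' @examples
#' COV <- matrix(c(1.1, 0.6, -0.1, 0.6, 8.3, -0.7, -0.1, -0.7, 4.0), 3, 3)
#' cholesky_upper(COV)
#' @export
cholesky_upper <- function(cov) {
  cov <- as.matrix(cov)
  if (!isSymmetric(unname(cov), tol = 1e-8))
    stop("`cov` must be symmetric.", call. = FALSE)
  ch <- tryCatch(chol(cov), error = function(e) {
    minors <- vapply(seq_len(nrow(cov)),
                     function(k) det(cov[1:k, 1:k, drop = FALSE]), numeric(1))
    bad <- which(minors <= 0)[1]
    stop(sprintf(
      "`cov` is not positive definite: leading minor of order %d is not positive.",
      bad), call. = FALSE)
  })
  ch
}

#' Sample correlated multivariate-normal random effects
#'
#' Draws `n` independent effect vectors `eta = r %*% CH`, where `r` holds
#' independent standard normals and `CH` is the Cholesky factor of `cov`, so
#' that `eta` has covariance `cov`. A zero matrix (no variability) yields all
#' zeros. Draws are subject-major: subject `i` consumes draws
#' `(i-1)*d + 1 .. i*d`, so extending `n` never changes earlier subjects.
#'
#' @param n Number of subjects (>= 1).
#' @param cov Covariance matrix (positive definite, or all-zero for the
#'   degenerate no-variability case).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A tibble of effects, one column per dimension (named after
#'   `cov`'s column names, else `eta1`, `eta2`, ...).
#' @examples
#' COV <- matrix(c(1, 0.5, 0.5, 2), 2, 2)
#' sample_mvn_effects(5, COV, seed = 1)
#' @export
sample_mvn_effects <- function(n, cov, seed = NULL) {
  stopifnot(n >= 1)
  cov <- as.matrix(cov)
  d <- ncol(cov)
  nms <- colnames(cov)
  if (is.null(nms)) nms <- paste0("eta", seq_len(d))
  if (all(cov == 0)) {
    eta <- matrix(0, n, d)
  } else {
    ch <- cholesky_upper(cov)
    r <- with_master_seed(seed, matrix(rnorm(n * d), ncol = d, byrow = TRUE))
    eta <- r %*% ch
  }
  colnames(eta) <- nms
  as_tibble(as.data.frame(eta))
}

#' Uncentered empirical covariance of sampled effects
#'
#' `Omega[j, k] = mean_i(eta[i, j] * eta[i, k])`: the uncentered moment
#' estimator (the effect means are structurally zero), symmetric by
#' construction. For a large sample this should be close to the covariance
#' matrix the effects were drawn from.
#'
#' @param etas Matrix or data frame of effect vectors, one row per subject.
#' @param center If `TRUE`, subtract column means first (not the default).
#' @return Symmetric covariance matrix.
#' @examples
#' empirical_covariance(sample_mvn_effects(1e4, diag(2), seed = 1))
#' @export
empirical_covariance <- function(etas, center = FALSE) {
  m <- as.matrix(etas)
  if (center) m <- sweep(m, 2, colMeans(m))
  om <- crossprod(m) / nrow(m)
  (om + t(om)) / 2
}

#' Sample individual subject parameters (lognormal variability)
#'
#' Frozen per-subject parameter values `p_i = p_pop * exp(eta_i * mc_switch)`,
#' with etas drawn once per subject (never re-drawn during a simulation).
#' Variability is specified either as independent per-parameter standard
#' deviations (`sds`) or as a full covariance matrix (`cov`) whose column
#' order matches `names(pop_values)`. With `mc_switch = 0` the etas still
#' consume random draws but every subject equals the population-typical
#' value, mirroring the usual Monte-Carlo on/off switch.
#'
#' @param pop_values Named numeric of population-typical values (> 0).
#' @param n Number of subjects.
#' @param sds Named numeric of lognormal standard deviations (univariate
#'   mode); missing names get sd 0.
#' @param cov Covariance matrix of the etas (correlated mode).
#' @param mc_switch 1 to apply variability, 0 to switch it off.
#' @param seed Optional integer seed.
#' @return A tibble with `subject`, one `eta_<name>` column per parameter,
#'   and one column per individual parameter value.
#' @examples
#' sample_subject_params(c(CL = 0.2, V2 = 3), n = 4,
#'                       sds = c(CL = 0.2, V2 = 0.3), seed = 1)
#' @export
sample_subject_params <- function(pop_values, n, sds = NULL, cov = NULL,
                                  mc_switch = 1, seed = NULL) {
  stopifnot(all(pop_values > 0), n >= 1, mc_switch %in% c(0, 1))
  nms <- names(pop_values)
  if (is.null(nms)) stop("`pop_values` must be named.", call. = FALSE)
  if (is.null(cov)) {
    s <- setNames(rep(0, length(nms)), nms)
    if (!is.null(sds)) s[names(sds)] <- sds
    if (any(s < 0)) stop("`sds` must be >= 0.", call. = FALSE)
    cov <- diag(s^2, nrow = length(nms))
    colnames(cov) <- rownames(cov) <- nms
  }
  etas <- sample_mvn_effects(n, cov, seed = seed)
  names(etas) <- paste0("eta_", nms)
  params <- purrr::map2_dfc(
    as.list(pop_values), as.list(etas),
    function(pop, eta) pop * exp(eta * mc_switch))
  names(params) <- nms
  dplyr::bind_cols(tibble(subject = seq_len(n)), etas, params)
}

#' Sample subject body weights
#'
#' Body weights from a normal or uniform distribution. With
#' `mc_switch = 0` all subjects take the central value (the mean for the
#' normal; `central` — conventionally 70 kg — for the uniform). Normal draws
#' at or below zero are resampled: negative weights are physically
#' meaningless, and at typical parameters the resampling probability is
#' negligible.
#'
#' @param n Number of subjects.
#' @param dist `"normal"` or `"uniform"`.
#' @param mean,sd Normal parameters (kg).
#' @param lo,hi Uniform bounds (kg), `lo < hi`.
#' @param central Value used when `mc_switch = 0` for the uniform
#'   distribution (default 70 kg).
#' @param mc_switch 1 to sample, 0 for identical subjects.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` weights.
#' @examples
#' sample_bodyweight(5, "uniform", lo = 10, hi = 80, seed = 1)
#' @export
sample_bodyweight <- function(n, dist = c("normal", "uniform"),
                              mean = 70, sd = 10, lo = 10, hi = 80,
                              central = 70, mc_switch = 1, seed = NULL) {
  dist <- match.arg(dist)
  stopifnot(n >= 1, mc_switch %in% c(0, 1))
  if (dist == "uniform" && lo >= hi)
    stop("`lo` must be smaller than `hi`.", call. = FALSE)
  if (mc_switch == 0)
    return(rep(if (dist == "normal") mean else central, n))
  with_master_seed(seed, {
    if (dist == "uniform") {
      runif(n, lo, hi)
    } else {
      w <- rnorm(n, mean, sd)
      while (any(w <= 0)) w[w <= 0] <- rnorm(sum(w <= 0), mean, sd)
      w
    }
  })
}
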