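#' Zero-inflated negative binomial log-likelihood
#'
#' The mixture model used for per-taxon counts: with probability `pi` an
#' observation comes from a point mass at zero; otherwise from a negative
#' binomial with mean `mu_i = exp(x_i' beta)` and dispersion `theta`. All
#' zero counts share the same zero-component probability (the zero
#' component is intercept-only):
#' `l = sum_i log[ pi 1{y_i = 0} + (1 - pi) NB(y_i; mu_i, theta) ]`.
#'
#' @param beta count-component coefficients (log link), length `ncol(X)`.
#' @param pi zero-inflation probability, in `[0, 1)`.
#' @param theta negative binomial dispersion (size), > 0.
#' @param y nonnegative integer response.
#' @param X design matrix (must include the intercept).
#' @return the log-likelihood (scalar).
#' @export
zinb_loglik <- function(beta, pi, theta, y, X) {
  if (theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (pi < 0 || pi >= 1) stop("`pi` must be in [0, 1)", call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) {
    stop("`y` must be nonnegative integers", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  lognb <- stats::dnbinom(y, size = theta, mu = exp(eta), log = TRUE)
  ll <- log1p(-pi) + lognb
  if (pi > 0) {
    z <- y == 0
    if (any(z)) {
      # log(pi + (1 - pi) nb0) computed stably via log-sum-exp
      a <- rep(log(pi), sum(z))
      b <- ll[z]
      m <- pmax(a, b)
      ll[z] <- m + log(exp(a - m) + exp(b - m))
    }
  }
  sum(ll)
}

#' Fit a zero-inflated negative binomial model
#'
#' Maximises [zinb_loglik()] by multi-start quasi-Newton (BFGS)
#' optimisation over `(beta, qlogis(pi), log(theta))`. Starting values:
#' `beta` from a Poisson GLM, `theta` from method of moments on the
#' positive counts, and `pi` in `{0.1, 0.5}` (plus any extra starts
#' given). The best converged start is returned.
#'
#' @param y nonnegative integer response.
#' @param X design matrix including an intercept column.
#' @param pi_starts starting zero-inflation probabilities.
#' @param start optional full warm start: list with `beta`, `pi`, `theta`
#'   (used in addition to the default starts).
#' @param reltol relative log-likelihood convergence tolerance.
#' @return object of class `zinb_fit`: `coefficients` (named `beta`), `pi`,
#'   `theta`, `logLik`, `converged`, `n`, `df` (number of free
#'   parameters).
#' @export
fit_zinb <- function(y, X, pi_starts = c(0.1, 0.5), start = NULL,
                     reltol = 1e-10) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 3) stop("need n >= p + 3 observations", call. = FALSE)

  beta0 <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::poisson())$coefficients),
    error = function(e) NULL
  )
  if (is.null(beta0) || anyNA(beta0)) {
    beta0 <- c(log(mean(y) + 0.1), rep(0, p - 1))
  }
  ypos <- y[y > 0]
  theta0 <- if (length(ypos) > 2) {
    m <- mean(ypos); v <- stats::var(ypos)
    if (v > m) min(100, max(0.1, m^2 / (v - m))) else 10
  } else 1
  negll <- function(par) {
    beta <- par[seq_len(p)]
    pi <- stats::plogis(par[p + 1])
    theta <- exp(par[p + 2])
    ll <- zinb_loglik(beta, pi, theta, y, X)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- lapply(pi_starts, function(pi0) {
    c(beta0, stats::qlogis(pi0), log(theta0))
  })
  if (!is.null(start)) {
    starts <- c(starts, list(c(start$beta, stats::qlogis(max(min(start$pi, 0.95), 1e-4)),
                               log(start$theta))))
  }
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    conv <- fit$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$converged <- conv
    }
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  beta <- best$par[seq_len(p)]
  names(beta) <- colnames(X) %||% paste0("b", seq_len(p) - 1)
  structure(
    list(
      coefficients = beta,
      pi = stats::plogis(best$par[p + 1]),
      theta = exp(best$par[p + 2]),
      logLik = -best$value,
      converged = best$converged && any_conv,
      n = n,
      df = p + 2L
    ),
    class = "zinb_fit"
  )
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat("Zero-inflated negative binomial fit\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  pi = %.4f, theta = %.4f, logLik = %.3f, converged = %s, n = %d\n",
              x$pi, x$theta, x$logLik, x$converged, x$n))
  invisible(x)
}

#' Race-by-BV interaction tests across taxa
#'
#' For every taxon with enough nonzero counts, fits the full ZINB model
#' `log mu = b0 + b_race + b_BV + b_race:BV` and the reduced model without
#' the interaction, and compares them by likelihood ratio: the deviance
#' `D = 2 (l_full - l_reduced)` is referred to a chi-squared distribution
#' with as many degrees of freedom as interaction columns. P-values are
#' Benjamini-Hochberg adjusted across taxa.
#'
#' The full model is warm-started from the reduced fit (interaction terms
#' at zero), so the nested-likelihood ordering `l_full >= l_reduced` holds
#' by construction.
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`).
#' @param meta sample metadata with `sample`, a race column and a logical
#'   BV column.
#' @param race_col,bv_col metadata column names (defaults `race`,
#'   `bv_nugent`).
#' @param min_nonzero minimum number of samples with a nonzero count for a
#'   taxon to be tested (default 10).
#' @return tibble of class `interaction_lrt`: `taxid`, `deviance`, `df`,
#'   `p`, `q`, `converged`, `skipped` (reason or `NA`), plus the
#'   interaction coefficient estimate `interaction_est` of the first
#'   interaction column.
#' @export
interaction_lrt <- function(counts, meta, race_col = "race",
                            bv_col = "bv_nugent", min_nonzero = 10) {
  stopifnot(race_col %in% names(meta), bv_col %in% names(meta))
  m <- meta[, c("sample", race_col, bv_col)]
  names(m) <- c("sample", "race", "bv")
  m$race <- factor(m$race)
  m$bv <- as.logical(m$bv)
  wide <- count_matrix(counts)
  m <- m[match(rownames(wide), m$sample), ]
  if (anyNA(m$sample)) stop("count samples missing from metadata", call. = FALSE)
  X_full <- stats::model.matrix(~ race * bv, data = m)
  X_red <- stats::model.matrix(~ race + bv, data = m)
  int_cols <- setdiff(colnames(X_full), colnames(X_red))
  df <- length(int_cols)

  res <- lapply(colnames(wide), function(t) {
    y <- wide[, t]
    base <- tibble::tibble(taxid = t, deviance = NA_real_, df = df,
                           p = NA_real_, q = NA_real_, converged = NA,
                           skipped = NA_character_, interaction_est = NA_real_)
    if (sum(y > 0) < min_nonzero) {
      base$skipped <- "too_few_nonzero"
      return(base)
    }
    cell_zero <- tapply(y, interaction(m$race, m$bv, drop = TRUE),
                        function(v) all(v == 0))
    if (any(cell_zero)) {
      base$skipped <- "all_zero_group"
      return(base)
    }
    red <- tryCatch(fit_zinb(y, X_red), error = function(e) NULL)
    if (is.null(red)) {
      base$skipped <- "reduced_fit_failed"
      return(base)
    }
    warm <- list(
      beta = c(red$coefficients, stats::setNames(rep(0, df), int_cols))[colnames(X_full)],
      pi = red$pi, theta = red$theta
    )
    full <- tryCatch(fit_zinb(y, X_full, start = warm), error = function(e) NULL)
    if (is.null(full)) {
      base$skipped <- "full_fit_failed"
      return(base)
    }
    if (!isTRUE(red$converged) || !isTRUE(full$converged)) {
      base$skipped <- "not_converged"
      base$converged <- FALSE
      return(base)
    }
    D <- max(0, 2 * (full$logLik - red$logLik))
    base$deviance <- D
    base$p <- stats::pchisq(D, df = df, lower.tail = FALSE)
    base$converged <- TRUE
    base$interaction_est <- unname(full$coefficients[int_cols[1]])
    base
  })
  out <- dplyr::bind_rows(res)
  tested <- is.na(out$skipped)
  out$q[tested] <- bh_adjust(out$p[tested])
  structure(out, class = c("interaction_lrt", class(out)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control:
#' `q_(i) = min over j >= i of m p_(j) / j`, capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
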