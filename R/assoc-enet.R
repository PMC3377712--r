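#' Elastic-net regression by cyclic coordinate descent
#'
#' Minimises
#' `(1/2n) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 + (1 - alpha)/2 ||b||_2^2)`
#' over a log-spaced `lambda` path with warm starts, selecting `lambda` by
#' k-fold cross-validation. Predictors are standardised internally
#' (population standard deviation, as is conventional for this objective)
#' and coefficients are reported on the original scale. Binary responses
#' are handled with the same squared-error objective (a linear probability
#' model); fold assignment is then stratified on the response.
#'
#' @param x numeric predictor matrix (samples by taxa), typically
#'   `log(count + 0.5)`.
#' @param y numeric response (a clinical sign: pH as a real value, binary
#'   signs as 0/1).
#' @param alpha elastic-net mixing parameter in `(0, 1]`; 1 is the lasso
#'   (default 0.5).
#' @param lambda optional decreasing penalty path; computed from the data
#'   when `NULL` (`n_lambda` values from `lambda_max` down by
#'   `lambda_min_ratio`).
#' @param n_lambda,lambda_min_ratio path size and range (defaults 50 and
#'   1e-3).
#' @param k_folds cross-validation folds (default 10; must not exceed
#'   `n`).
#' @param seed integer seed for fold assignment.
#' @param rule `"min"` picks the CV-minimising lambda; `"1se"` the largest
#'   lambda within one standard error of the minimum.
#' @param criterion label stored with the result (e.g. `"ph"`).
#' @param objective `"linear"` (default, squared error — also for binary
#'   signs, i.e. a linear probability model) or `"logistic"` (penalised
#'   logistic deviance, fitted by iteratively reweighted coordinate
#'   descent; binary responses only).
#' @param tol,max_sweeps coordinate-descent convergence controls.
#' @return object of class `sign_model`: `criterion`, `coefficients`
#'   (tibble `taxon`, `estimate` — nonzero terms only), `intercept`,
#'   `lambda`, `alpha`, `cv` (tibble `lambda`, `mean_error`, `se`),
#'   `path` (full coefficient matrix, taxa by lambda), `rule`.
#' @export
elasticnet_fit <- function(x, y, alpha = 0.5, lambda = NULL, n_lambda = 50,
                           lambda_min_ratio = 1e-3, k_folds = 10, seed = 1,
                           rule = c("min", "1se"), criterion = "response",
                           objective = c("linear", "logistic"),
                           tol = 1e-9, max_sweeps = 1000) {
  rule <- match.arg(rule)
  objective <- match.arg(objective)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k_folds > n) stop("`k_folds` exceeds the number of samples", call. = FALSE)
  if (k_folds < 2) stop("`k_folds` must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  binary <- all(y %in% c(0, 1))
  if (objective == "logistic" && !binary) {
    stop("`objective = \"logistic\"` needs a binary 0/1 response", call. = FALSE)
  }
  local_rng(seed)
  solver <- if (objective == "logistic") enet_logistic_path else enet_path

  if (is.null(lambda)) {
    st <- standardize_cols(x)
    lambda_max <- max(abs(crossprod(st$x, y - mean(y)))) / (n * alpha)
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = n_lambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)

  folds <- if (binary) {
    f <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
    f
  } else {
    sample(rep_len(seq_len(k_folds), n))
  }

  cv_err <- matrix(NA_real_, k_folds, length(lambda))
  for (k in seq_len(k_folds)) {
    train <- folds != k
    fit_k <- solver(x[train, , drop = FALSE], y[train], alpha, lambda,
                    tol = tol, max_sweeps = max_sweeps)
    pred <- cbind(1, x[!train, , drop = FALSE]) %*% rbind(fit_k$b0, fit_k$beta)
    cv_err[k, ] <- if (objective == "logistic") {
      # mean binomial deviance on the held-out fold
      p <- stats::plogis(pred)
      p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
      colMeans(-2 * (y[!train] * log(p) + (1 - y[!train]) * log(1 - p)))
    } else {
      colMeans((y[!train] - pred)^2)
    }
  }
  mean_err <- colMeans(cv_err)
  se_err <- apply(cv_err, 2, stats::sd) / sqrt(k_folds)
  i_min <- which.min(mean_err)
  i_sel <- if (rule == "min") {
    i_min
  } else {
    which(mean_err <= mean_err[i_min] + se_err[i_min])[1]
  }

  full <- solver(x, y, alpha, lambda, tol = tol, max_sweeps = max_sweeps)
  beta <- full$beta[, i_sel]
  nz <- which(abs(beta) > 0)
  taxa <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  structure(
    list(
      criterion = criterion,
      coefficients = tibble::tibble(taxon = taxa[nz], estimate = unname(beta[nz])),
      intercept = full$b0[i_sel],
      lambda = lambda[i_sel],
      alpha = alpha,
      cv = tibble::tibble(lambda = lambda, mean_error = mean_err, se = se_err),
      path = full$beta,
      lambda_path = lambda,
      rule = rule,
      objective = objective,
      n = n
    ),
    class = "sign_model"
  )
}

#' @export
print.sign_model <- function(x, ...) {
  cat(sprintf("Elastic-net sign model: %s (alpha = %.2f, lambda = %.4g, %s rule)\n",
              x$criterion, x$alpha, x$lambda, x$rule))
  if (nrow(x$coefficients) == 0) {
    cat("  no taxa selected\n")
  } else {
    print(dplyr::arrange(x$coefficients, dplyr::desc(abs(.data$estimate))))
  }
  invisible(x)
}

# Coordinate-descent solver over a decreasing lambda path with warm starts.
# Returns coefficients on the original x scale. The penalised objective is
# checked to be non-increasing across sweeps.
enet_path <- function(x, y, alpha, lambda, tol = 1e-9, max_sweeps = 1000) {
  n <- nrow(x)
  p <- ncol(x)
  st <- standardize_cols(x)
  xs <- st$x
  ybar <- mean(y)
  yc <- y - ybar
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

  objective <- function(b, lam) {
    r <- yc - xs %*% b
    sum(r^2) / (2 * n) + lam * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
  }
  beta_out <- matrix(0, p, length(lambda))
  b <- rep(0, p)
  xty <- crossprod(xs, yc) / n
  for (l in seq_along(lambda)) {
    lam <- lambda[l]
    r <- yc - xs %*% b
    obj_prev <- objective(b, lam)
    for (sweep in seq_len(max_sweeps)) {
      max_delta <- 0
      for (j in seq_len(p)) {
        if (st$scale[j] == 0) next
        bj_old <- b[j]
        rho <- sum(xs[, j] * r) / n + bj_old # columns have unit population sd
        bj_new <- soft(rho, lam * alpha) / (1 + lam * (1 - alpha))
        if (bj_new != bj_old) {
          r <- r - xs[, j] * (bj_new - bj_old)
          b[j] <- bj_new
          max_delta <- max(max_delta, abs(bj_new - bj_old))
        }
      }
      obj_new <- objective(b, lam)
      if (obj_new > obj_prev + 1e-10) {
        stop("coordinate descent objective increased; this is a bug", call. = FALSE)
      }
      obj_prev <- obj_new
      if (max_delta < tol) break
    }
    beta_out[, l] <- b
  }
  # back-transform to the original scale
  beta_orig <- beta_out / st$scale
  beta_orig[st$scale == 0, ] <- 0
  b0 <- ybar - drop(crossprod(st$center, beta_orig))
  list(beta = beta_orig, b0 = b0)
}

standardize_cols <- function(x) {
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scale <- sqrt(colMeans(xc^2))
  xs <- sweep(xc, 2, ifelse(scale == 0, 1, scale), "/")
  list(x = xs, center = center, scale = scale)
}

# Penalised logistic regression over a decreasing lambda path: iteratively
# reweighted least squares, each weighted subproblem solved by cyclic
# coordinate descent on standardised predictors. Returns coefficients on
# the original x scale.
enet_logistic_path <- function(x, y, alpha, lambda, tol = 1e-9,
                               max_sweeps = 1000, max_irls = 50) {
  n <- nrow(x)
  p <- ncol(x)
  st <- standardize_cols(x)
  xs <- st$x
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  beta_out <- matrix(0, p, length(lambda))
  b0_out <- numeric(length(lambda))
  b <- rep(0, p)
  b0 <- stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  for (l in seq_along(lambda)) {
    lam <- lambda[l]
    for (iter in seq_len(max_irls)) {
      eta <- b0 + drop(xs %*% b)
      prob <- stats::plogis(eta)
      w <- pmax(prob * (1 - prob), 1e-6)
      z <- eta + (y - prob) / w
      b_old_outer <- c(b0, b)
      # weighted elastic-net subproblem
      r <- z - b0 - drop(xs %*% b)
      for (sweep_i in seq_len(max_sweeps)) {
        max_delta <- 0
        for (j in seq_len(p)) {
          if (st$scale[j] == 0) next
          bj_old <- b[j]
          wxx <- sum(w * xs[, j]^2) / n
          rho <- sum(w * xs[, j] * r) / n + wxx * bj_old
          bj_new <- soft(rho, lam * alpha) / (wxx + lam * (1 - alpha))
          if (bj_new != bj_old) {
            r <- r - xs[, j] * (bj_new - bj_old)
            b[j] <- bj_new
            max_delta <- max(max_delta, abs(bj_new - bj_old))
          }
        }
        b0_new <- b0 + sum(w * r) / sum(w)
        r <- r - (b0_new - b0)
        max_delta <- max(max_delta, abs(b0_new - b0))
        b0 <- b0_new
        if (max_delta < tol * 10) break
      }
      if (max(abs(c(b0, b) - b_old_outer)) < 1e-8) break
    }
    beta_out[, l] <- b
    b0_out[l] <- b0
  }
  beta_orig <- beta_out / st$scale
  beta_orig[st$scale == 0, ] <- 0
  list(beta = beta_orig, b0 = b0_out - drop(crossprod(st$center, beta_orig)))
}

#' Elastic-net associations for all four Amsel signs
#'
#' Fits [elasticnet_fit()] for each clinical criterion — vaginal pH (raw),
#' whiff test, clue cells (any vs none), abnormal discharge — and for the
#' composite Amsel diagnosis, on `log(count + 0.5)`-transformed taxon
#' counts, and tabulates which taxa associate with how many criteria.
#'
#' @param counts long count tibble (`sample`, `taxid`, `count`).
#' @param meta sample metadata from [simulate_cohort()] (needs `ph`,
#'   `amsel_whiff`, `clue_cells`, `amsel_discharge`, `bv_amsel`).
#' @param alpha,k_folds,rule passed to [elasticnet_fit()].
#' @param seed integer seed (per-criterion seeds are derived from it).
#' @return list of class `sign_association`: `models` (named list of
#'   `sign_model`), `membership` (tibble: `taxon`, one logical column per
#'   criterion, `n_criteria` over the four signs).
#' @export
sign_association_table <- function(counts, meta, alpha = 0.5, k_folds = 10,
                                   rule = "min", seed = 1) {
  need <- c("ph", "amsel_whiff", "clue_cells", "amsel_discharge", "bv_amsel")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks sign columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wide <- count_matrix(counts)
  m <- meta[match(rownames(wide), meta$sample), ]
  x <- log(wide + 0.5)
  responses <- list(
    ph = m$ph,
    whiff = as.numeric(m$amsel_whiff),
    clue = as.numeric(m$clue_cells != "none"),
    discharge = as.numeric(m$amsel_discharge),
    amsel = as.numeric(m$bv_amsel)
  )
  models <- lapply(seq_along(responses), function(i) {
    elasticnet_fit(x, responses[[i]], alpha = alpha, k_folds = k_folds,
                   rule = rule, criterion = names(responses)[i],
                   seed = seed + i)
  })
  names(models) <- names(responses)
  taxa <- colnames(x)
  membership <- tibble::tibble(taxon = taxa)
  for (nm in names(models)) {
    membership[[nm]] <- taxa %in% models[[nm]]$coefficients$taxon
  }
  membership$n_criteria <- rowSums(
    as.matrix(membership[, c("ph", "whiff", "clue", "discharge")])
  )
  structure(list(models = models, membership = membership),
            class = "sign_association")
}
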