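#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1). Requires n > k + 1.
#' @param loglik model log-likelihood (ML)
#' @param k number of estimated parameters (fixed effects + intercept +
#'   variance components where applicable)
#' @param n number of observations
#' @return AICc value
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined for n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights and relative variable importance
#'
#' Weights: w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2) with
#' delta_i = AICc_i - min AICc. The relative variable importance (RVI) of a
#' variable is the summed weight of all candidate models containing it — the
#' probability that the variable is in the best model given the data and the
#' candidate set.
#'
#' @param aicc_values numeric vector of AICc, one per candidate model
#' @param membership logical matrix, models x variables: does model i contain
#'   variable v
#' @return list with \code{weights} (sums to 1) and \code{rvi} named vector
#' @export
weights_and_rvi <- function(aicc_values, membership) {
  ok <- is.finite(aicc_values)
  w <- numeric(length(aicc_values))
  d <- aicc_values[ok] - min(aicc_values[ok])
  w[ok] <- exp(-d / 2) / sum(exp(-d / 2))
  rvi <- as.numeric(t(w) %*% (membership * 1))
  names(rvi) <- colnames(membership)
  list(weights = w, rvi = rvi)
}

# ---- fitting backends -------------------------------------------------------
# Contract: fit(y, X, data?) -> list(loglik, k, coef, var, converged)
# X includes the intercept column. k counts every estimated parameter.

fit_backend_lm <- function(y, X, weights = NULL) {
  n <- length(y); p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sqrt(weights)
  q <- qr(X * sw)
  beta <- qr.coef(q, y * sw)
  res <- y - as.vector(X %*% beta)
  rss <- sum(weights * res^2)
  # ML log-likelihood of y_i ~ N(x_i' beta, sigma^2 / w_i)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1) + sum(log(weights)) / 2
  xtxinv <- chol2inv(qr.R(q))
  se2 <- diag(xtxinv) * rss / (n - p)
  list(loglik = loglik, k = p + 1L,
       coef = stats::setNames(as.numeric(beta), colnames(X)),
       var = stats::setNames(se2, colnames(X)), converged = TRUE)
}

fit_backend_glm_binomial <- function(y, X) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  p <- fit$rank
  loglik <- p - fit$aic / 2
  vc <- tryCatch({
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    R[lower.tri(R)] <- 0
    diag(chol2inv(R))
  }, error = function(e) rep(NA_real_, p))
  list(loglik = loglik, k = p,
       coef = stats::setNames(fit$coefficients, colnames(X)),
       var = stats::setNames(vc, colnames(X)),
       converged = fit$converged)
}

fit_backend_lmer <- function(y, X, data, random, weights = NULL) {
  df <- data.frame(.y = y, X[, -1, drop = FALSE], check.names = FALSE)
  df$.w <- if (is.null(weights)) rep(1, length(y)) else weights
  for (g in all.vars(stats::as.formula(paste("~", random))))
    df[[g]] <- data[[g]]
  fixed <- if (ncol(X) > 1)
    paste(sprintf("`%s`", colnames(X)[-1]), collapse = " + ") else "1"
  fml <- stats::as.formula(paste(".y ~", fixed, "+", random))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = df, REML = FALSE, weights = .w,
                 control = lme4::lmerControl(calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(loglik = NA_real_, k = NA_integer_, coef = NULL, var = NULL,
                converged = FALSE))
  ll <- stats::logLik(fit)
  b <- lme4::fixef(fit)
  names(b)[names(b) != "(Intercept)"] <-
    gsub("`", "", names(b)[names(b) != "(Intercept)"])
  v <- diag(as.matrix(stats::vcov(fit)))
  names(v) <- names(b)
  list(loglik = as.numeric(ll), k = attr(ll, "df"),
       coef = b, var = v, converged = TRUE)
}

#' Fit every subset of a variable pool
#'
#' Enumerates all 2^p predictor subsets (including the intercept-only model)
#' and fits each with the chosen backend: \code{"lm"} (Gaussian, identity
#' link, fixed effects), \code{"glm"} (binomial, logit link) or \code{"lmer"}
#' (Gaussian with nested random intercepts, maximum likelihood). Models with
#' n <= k + 1 or failed convergence are excluded from weighting but counted.
#'
#' @param data data.frame holding response, predictors and any grouping
#'   columns
#' @param response response column name
#' @param pool character vector of predictor column names (max 10)
#' @param backend one of "lm", "glm", "lmer"
#' @param random random-intercept specification for the lmer backend, e.g.
#'   \code{"(1 | aviary/female)"}
#' @param weights optional observation weights (Gaussian backends): inverse
#'   relative residual variances, e.g. clutch sizes for clutch-mean responses
#' @return object of class \code{candidate_set}: list with \code{models}
#'   (per-model loglik, k, aicc, coef, var), \code{membership} matrix,
#'   \code{aicc} vector, \code{n}, \code{excluded} count
#' @export
all_subsets_fit <- function(data, response, pool, backend = "lm",
                            random = NULL, weights = NULL) {
  if (length(pool) > 10)
    stop("variable pool larger than 10 (", length(pool), ")")
  y <- data[[response]]
  if (anyNA(y)) stop("missing values in response")
  Xfull <- cbind(`(Intercept)` = 1,
                 as.matrix(data[, pool, drop = FALSE]))
  n <- length(y)
  p <- length(pool)
  nmod <- 2L^p
  membership <- matrix(FALSE, nmod, p, dimnames = list(NULL, pool))
  models <- vector("list", nmod)
  aiccs <- rep(NA_real_, nmod)
  excluded <- 0L
  for (i in seq_len(nmod)) {
    sel <- as.logical(bitwAnd(i - 1L, 2L^(seq_len(p) - 1L)))
    if (p == 0) sel <- logical(0)
    membership[i, ] <- sel
    X <- Xfull[, c(TRUE, sel), drop = FALSE]
    fit <- switch(backend,
                  lm = fit_backend_lm(y, X, weights),
                  glm = fit_backend_glm_binomial(y, X),
                  lmer = fit_backend_lmer(y, X, data, random, weights),
                  stop("unknown backend: ", backend))
    if (!isTRUE(fit$converged) || !is.finite(fit$loglik) ||
        n <= fit$k + 1) {
      excluded <- excluded + 1L
    } else {
      aiccs[i] <- aicc(fit$loglik, fit$k, n)
    }
    models[[i]] <- fit
  }
  structure(list(models = models, membership = membership, aicc = aiccs,
                 n = n, pool = pool, response = response, backend = backend,
                 excluded = excluded),
            class = "candidate_set")
}

#' Full model averaging with adjusted standard errors
#'
#' Averaged estimate of each variable over all candidate models, substituting
#' zero where the variable is absent. The adjusted (unconditional) standard
#' error is \code{sqrt(sum_i w_i (var_i + (beta_i - betabar)^2))} (revised
#' estimator); \code{adjust = "original"} uses the older summation-of-roots
#' form. p-values from the two-sided normal z = estimate / SE.
#'
#' @param cs \code{candidate_set} from \code{\link{all_subsets_fit}}
#' @param weights Akaike weights (default recomputed from the stored AICc)
#' @param adjust "revised" (default) or "original"
#' @return data.frame with variable, estimate, adjusted_se, z, p, rvi
#' @export
model_average <- function(cs, weights = NULL,
                          adjust = c("revised", "original")) {
  adjust <- match.arg(adjust)
  wr <- weights_and_rvi(cs$aicc, cs$membership)
  if (is.null(weights)) weights <- wr$weights
  if (all(weights == 0)) stop("all model weights are zero")
  vars <- c("(Intercept)", cs$pool)
  est <- se <- numeric(length(vars))
  for (j in seq_along(vars)) {
    v <- vars[j]
    b <- vapply(cs$models, function(m)
      if (!is.null(m$coef) && v %in% names(m$coef)) m$coef[[v]] else 0,
      numeric(1))
    s2 <- vapply(cs$models, function(m)
      if (!is.null(m$var) && v %in% names(m$var)) m$var[[v]] else 0,
      numeric(1))
    bbar <- sum(weights * b)
    est[j] <- bbar
    se[j] <- if (adjust == "revised")
      sqrt(sum(weights * (s2 + (b - bbar)^2)))
    else
      sum(weights * sqrt(s2 + (b - bbar)^2))
  }
  z <- est / se
  rvi <- c(NA_real_, wr$rvi[cs$pool])
  data.frame(variable = vars, estimate = est, adjusted_se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), rvi = unname(rvi),
             stringsAsFactors = FALSE)
}

#' Iterative variable rotation by relative variable importance
#'
#' Handles more candidate variables than an all-subsets search can carry:
#' round 1 takes the first \code{pool_size} variables in the configured
#' order, fits all subsets, and keeps variables with RVI > \code{keep_rvi};
#' each next round refills the pool with kept variables plus the next unused
#' ones, until every variable has entered a pool (at most a few rounds). The
#' final pool is the kept set of the last round; a final all-subsets fit and
#' full model averaging over it produce the coefficient table. Variables with
#' RVI > \code{relevant_rvi} in the final averaging are flagged relevant.
#'
#' @param data data.frame
#' @param response response column name
#' @param variables ordered candidate variables
#' @param backend,random,weights see \code{\link{all_subsets_fit}}
#' @param pool_size maximum variables per round (default 10)
#' @param keep_rvi retention threshold (default 0.5)
#' @param relevant_rvi relevance threshold (default 0.7)
#' @return object of class \code{rvi_selection}
#' @export
iterative_rvi_selection <- function(data, response, variables,
                                    backend = "lm", random = NULL,
                                    weights = NULL,
                                    pool_size = 10L, keep_rvi = 0.5,
                                    relevant_rvi = 0.7) {
  unused <- variables
  kept <- character(0)
  rounds <- list()
  repeat {
    if (length(kept) >= pool_size && length(unused)) {
      # all slots held by kept variables: release the weakest to keep rotating
      last_rvi <- rounds[[length(rounds)]]$rvi
      kept <- kept[order(-last_rvi[kept])][seq_len(pool_size - 1L)]
    }
    take <- utils::head(unused, pool_size - length(kept))
    pool <- c(kept, take)
    unused <- setdiff(unused, take)
    cs <- all_subsets_fit(data, response, pool, backend, random, weights)
    wr <- weights_and_rvi(cs$aicc, cs$membership)
    kept <- pool[wr$rvi[pool] > keep_rvi]
    rounds[[length(rounds) + 1L]] <- list(pool = pool, rvi = wr$rvi,
                                          kept = kept)
    if (!length(unused)) break
  }
  final_cs <- all_subsets_fit(data, response, kept, backend, random, weights)
  tab <- model_average(final_cs)
  tab$relevant <- !is.na(tab$rvi) & tab$rvi > relevant_rvi
  structure(list(response = response, rounds = rounds, final_pool = kept,
                 table = tab, n = final_cs$n, backend = backend,
                 keep_rvi = keep_rvi, relevant_rvi = relevant_rvi),
            class = "rvi_selection")
}

signif_marker <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*",
                       ifelse(p < 0.1, ".", ""))))
}

#' @export
print.rvi_selection <- function(x, digits = 4, ...) {
  cat(sprintf("Iterative AICc/RVI selection — response: %s (n = %d, %d round%s)\n",
              x$response, x$n, length(x$rounds),
              if (length(x$rounds) == 1) "" else "s"))
  cat(sprintf("Final variables (RVI > %.2g): %s\n\n", x$keep_rvi,
              if (length(x$final_pool)) paste(x$final_pool, collapse = ", ")
              else "(none)"))
  print(summary(x, digits = digits))
  invisible(x)
}

#' @export
summary.rvi_selection <- function(object, digits = 4, ...) {
  t <- object$table
  out <- data.frame(Estimate = round(t$estimate, digits),
                    `Adjusted SE` = round(t$adjusted_se, digits),
                    `p value` = round(t$p, digits),
                    ` ` = signif_marker(t$p),
                    RVI = ifelse(is.na(t$rvi), "", round(t$rvi, 2)),
                    row.names = t$variable, check.names = FALSE)
  out
}

#' @export
coef.rvi_selection <- function(object, ...) {
  stats::setNames(object$table$estimate, object$table$variable)
}

#' Write selection results as TSV tables
#' @param results named list of \code{rvi_selection} objects (name = response)
#' @param dir output directory
#' @return invisibly, the written file paths
#' @export
report_tables <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    t <- results[[nm]]$table
    t$signif <- signif_marker(t$p)
    f <- file.path(dir, paste0("selection_", nm, ".tsv"))
    utils::write.table(t, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
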