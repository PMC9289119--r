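#' Phylogenetic generalized least squares
#'
#' Fits a linear model whose residual covariance is proportional to a
#' Brownian-motion phylogenetic matrix `V` ([brownian_vcv()]):
#' `y = X beta + e`, `e ~ N(0, sigma^2 V)`. Estimation whitens the data with
#' the Cholesky factor of `V` and solves the resulting ordinary least
#' squares problem, so with `V = I` the fit is exactly OLS. The Brownian
#' rate `sigma^2` is profiled out, which is why `V` may be supplied on any
#' scale (covariance or correlation).
#'
#' Under maximum likelihood (default), `sigma2 = RSS_V / n` and
#' `logLik = -(n*log(2*pi*sigma2) + log|V| + n) / 2`. Standard errors use
#' the degrees-of-freedom-corrected variance `RSS_V / (n - p)`, with
#' t-tests on `n - p` residual degrees of freedom. `AIC = -2 logLik + 2 k`
#' with `k = p + 1` (the residual variance counts as an estimated
#' parameter). REML is available for variance-component work, but model
#' comparison across fixed-effect structures (dredging) requires ML.
#'
#' @param formula Model formula; variables are looked up in `data`.
#' @param data data.frame, one row per species. If it has a `species` column
#'   (or rownames) matching `V`'s dimnames, `V` is aligned to the data
#'   automatically; otherwise rows are assumed to be in `V`'s order.
#' @param V Species x species phylogenetic covariance matrix.
#' @param method `"ML"` (default) or `"REML"`.
#' @return Object of class `pgls_fit` with coefficients, standard errors,
#'   t- and p-values, `sigma2` (ML scale), `logLik`, `AIC`, `n`, `k` and the
#'   coefficient table in `$coefficients_table`.
#' @export
fit_pgls <- function(formula, data, V, method = c("ML", "REML")) {
  method <- match.arg(method)
  V <- .align_vcv(V, data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (nrow(X) != nrow(V))
    stop("data rows (", nrow(X), ") do not match V (", nrow(V), ")")
  R <- .chol_psd(V)
  w <- .whiten(R, X, y)
  fit <- .gls_core(w$Xw, w$yw, w$logdetV, method)
  fit$formula <- formula
  fit$terms <- attr(stats::terms(formula, data = data), "term.labels")
  fit$method <- method
  fit$call <- match.call()
  fit
}

# align V's rows/columns to the data's species order when names are available
.align_vcv <- function(V, data) {
  sp <- if ("species" %in% names(data)) as.character(data$species)
        else rownames(data)
  if (!is.null(sp) && !is.null(rownames(V)) &&
      !identical(sp, as.character(seq_len(nrow(data)))) &&
      all(sp %in% rownames(V))) {
    V <- V[sp, sp, drop = FALSE]
  }
  V
}

# Cholesky with a tiny diagonal jitter fallback for semi-definite V
.chol_psd <- function(V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    eps <- 1e-10 * mean(diag(V))
    R <- tryCatch(chol(V + diag(eps, nrow(V))), error = function(e) NULL)
    if (is.null(R)) stop("V is not positive (semi-)definite")
  }
  R
}

.whiten <- function(R, X, y) {
  Xw <- backsolve(R, X, transpose = TRUE)
  dimnames(Xw) <- dimnames(X)
  list(Xw = Xw,
       yw = backsolve(R, y, transpose = TRUE),
       logdetV = 2 * sum(log(diag(R))))
}

# whitened-scale GLS fit; the shared workhorse of fit_pgls and dredge_pgls
.gls_core <- function(Xw, yw, logdetV, method) {
  n <- nrow(Xw)
  p <- ncol(Xw)
  qx <- qr(Xw)
  if (qx$rank < p) {
    bad <- colnames(Xw)[qx$pivot[(qx$rank + 1):p]]
    stop("singular model matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (n <= p) stop("need more species than coefficients (n > p)")
  beta <- qr.coef(qx, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  XtX_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  s2_t <- rss / (n - p)
  se <- stats::setNames(sqrt(s2_t * diag(XtX_inv)), names(beta))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  ll <- if (method == "REML") {
    s2_r <- rss / (n - p)
    Rq <- qr.R(qx)
    -0.5 * ((n - p) * log(2 * pi * s2_r) + logdetV +
              2 * sum(log(abs(diag(Rq)))) + (n - p))
  } else {
    -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  }
  k <- p + 1
  structure(list(
    coefficients = beta,
    se = se,
    tval = tval,
    pval = pval,
    sigma2 = sigma2_ml,
    logLik = ll,
    AIC = -2 * ll + 2 * k,
    n = n,
    k = k,
    df.residual = n - p,
    coefficients_table = data.frame(
      Estimate = beta, SE = se, t_value = tval, p_value = pval,
      row.names = names(beta))
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (", x$method, ")\n", sep = "")
  if (!is.null(x$formula)) cat(deparse(x$formula), "\n")
  print(round(x$coefficients_table, 4))
  cat(sprintf("n = %d, logLik = %.3f, AIC = %.3f\n", x$n, x$logLik, x$AIC))
  invisible(x)
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' Single-predictor PGLS suite
#'
#' Fits one PGLS per response/predictor pair (by default: body mass, habitat
#' SSI and diet SSI against geographical and ecological density), each with
#' intercept and one slope, and returns a long coefficient table.
#'
#' @param data Predictor/response data.frame (one row per species).
#' @param V Phylogenetic covariance matrix.
#' @param responses,predictors Column names to cross.
#' @inheritParams fit_pgls
#' @return data.frame with `response`, `predictor`, `term`, `estimate`,
#'   `se`, `t_value`, `p_value`.
#' @export
single_predictor_suite <- function(data, V,
                                   responses = c("geo_density", "eco_density"),
                                   predictors = c("log_body_mass",
                                                  "ssi_habitat", "ssi_diet"),
                                   method = "ML") {
  out <- list()
  for (resp in responses) {
    for (pred in predictors) {
      f <- stats::reformulate(pred, response = resp)
      fit <- fit_pgls(f, data, V, method = method)
      out[[length(out) + 1]] <- data.frame(
        response = resp, predictor = pred,
        term = names(fit$coefficients),
        estimate = unname(fit$coefficients),
        se = unname(fit$se),
        t_value = unname(fit$tval),
        p_value = unname(fit$pval),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' All-subsets PGLS model dredging
#'
#' Fits every subset of the full model's terms (the intercept is always
#' included; a factor enters or leaves as a whole block) and ranks the
#' `2^m` models by AIC. ML estimation is enforced conceptually: AICs from
#' REML fits with different fixed effects are not comparable. Ties in AIC
#' are broken by fewer parameters, then by the lexicographic term string,
#' so the ranking is deterministic.
#'
#' @param full_formula Formula of the full model.
#' @inheritParams fit_pgls
#' @param max_terms Refuse to dredge more than this many terms (default 20).
#' @return Object of class `pgls_dredge`: list with `fits` (in ranked
#'   order), `table` (model, terms, k, logLik, AIC, delta) and
#'   `full_coefficients` (coefficient order of the full model).
#' @export
dredge_pgls <- function(full_formula, data, V, method = "ML",
                        max_terms = 20) {
  V <- .align_vcv(V, data)
  mf <- stats::model.frame(full_formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(full_formula, mf)
  trms <- attr(stats::terms(full_formula, data = data), "term.labels")
  m <- length(trms)
  if (m > max_terms)
    stop("refusing to dredge ", m, " terms (2^", m, " models); ",
         "raise max_terms explicitly if intended")
  assign <- attr(X, "assign")
  R <- .chol_psd(V)
  w <- .whiten(R, X, y)
  resp <- deparse(full_formula[[2]])
  fits <- vector("list", 2^m)
  for (i in seq_len(2^m)) {
    sel <- which(bitwAnd(i - 1, 2^(seq_len(m) - 1)) > 0)
    cols <- assign %in% c(0L, sel)
    fit <- .gls_core(w$Xw[, cols, drop = FALSE], w$yw, w$logdetV, method)
    fit$terms <- trms[sel]
    fit$formula <- stats::reformulate(if (length(sel)) trms[sel] else "1",
                                      response = resp)
    fit$method <- method
    fits[[i]] <- fit
  }
  aics <- vapply(fits, function(f) f$AIC, 0)
  ks <- vapply(fits, function(f) f$k, 0)
  lab <- vapply(fits, function(f)
    if (length(f$terms)) paste(sort(f$terms), collapse = "+") else "1", "")
  ord <- order(aics, ks, lab)
  fits <- fits[ord]
  tab <- data.frame(
    model = lab[ord],
    k = ks[ord],
    logLik = vapply(fits, function(f) f$logLik, 0),
    AIC = aics[ord],
    delta = aics[ord] - min(aics),
    stringsAsFactors = FALSE)
  structure(list(fits = fits, table = tab,
                 full_coefficients = colnames(X), response = resp),
            class = "pgls_dredge")
}

#' @export
print.pgls_dredge <- function(x, ...) {
  cat(length(x$fits), "models for response", x$response, "\n")
  print(utils::head(x$table, 10), digits = 4)
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}

#' Delta-AIC model selection and full model averaging
#'
#' Retains all models within `delta_cut` AIC units of the best model and
#' averages their coefficients with Akaike weights
#' `w_i = exp(-delta_i/2) / sum(exp(-delta_j/2))` (renormalized over the
#' retained set). Full averaging substitutes 0 for a coefficient in models
#' that do not contain its term, shrinking weakly supported effects toward
#' zero; `conditional = TRUE` instead averages only over the models that
#' contain the term. The unconditional standard error is
#' `sum_i w_i * sqrt(se_i^2 + (b_i - bbar)^2)`; the adjusted SE replaces
#' each `se_i` by `se_i * t(df_i, 0.975) / z(0.975)` to account for
#' small-sample t-distributed coefficient errors. Averaged coefficients are
#' tested with standard-normal z-statistics.
#'
#' @param fits A `pgls_dredge` object or list of `pgls_fit`s.
#' @param delta_cut AIC window for retention (default 2; the best model is
#'   always retained).
#' @param conditional Use conditional instead of full averaging.
#' @return Object of class `averaged_model`: `coefficients` data.frame
#'   (term, estimate, se, adj_se, z_value, p_value), `models` data.frame
#'   with AIC, delta and weights of the retained set, and `n_retained`.
#' @export
select_and_average <- function(fits, delta_cut = 2, conditional = FALSE) {
  co_order <- NULL
  if (inherits(fits, "pgls_dredge")) {
    co_order <- fits$full_coefficients
    fits <- fits$fits
  }
  if (length(fits) == 0) stop("no fitted models supplied")
  aics <- vapply(fits, function(f) f$AIC, 0)
  delta <- aics - min(aics)
  keep <- which(delta < delta_cut)
  fits <- fits[keep]
  delta <- delta[keep]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  if (is.null(co_order))
    co_order <- unique(unlist(lapply(fits, function(f)
      names(f$coefficients))))
  coefs <- lapply(co_order, function(j) {
    b <- vapply(fits, function(f)
      if (j %in% names(f$coefficients)) f$coefficients[[j]] else 0, 0)
    s <- vapply(fits, function(f)
      if (j %in% names(f$coefficients)) f$se[[j]] else 0, 0)
    df <- vapply(fits, function(f) f$df.residual, 0)
    present <- vapply(fits, function(f) j %in% names(f$coefficients), TRUE)
    wj <- w
    if (conditional) {
      if (!any(present)) return(NULL)
      wj <- w[present] / sum(w[present])
      b <- b[present]; s <- s[present]; df <- df[present]
    }
    bbar <- sum(wj * b)
    se <- sum(wj * sqrt(s^2 + (b - bbar)^2))
    s_adj <- s * stats::qt(0.975, df) / stats::qnorm(0.975)
    adj_se <- sum(wj * sqrt(s_adj^2 + (b - bbar)^2))
    z <- abs(bbar) / adj_se
    data.frame(term = j, estimate = bbar, se = se, adj_se = adj_se,
               z_value = z, p_value = 2 * stats::pnorm(-z),
               stringsAsFactors = FALSE)
  })
  coefs <- do.call(rbind, coefs)
  rownames(coefs) <- NULL
  models <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$terms)) paste(sort(f$terms), collapse = "+") else "1", ""),
    k = vapply(fits, function(f) f$k, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    delta = delta,
    weight = w,
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, models = models,
                 n_retained = length(fits),
                 delta_cut = delta_cut, conditional = conditional),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(if (x$conditional) "Conditional" else "Full",
      "model average over", x$n_retained,
      "model(s) with delta AIC <", x$delta_cut, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Robustness of the averaged model over a tree sample
#'
#' Repeats dredging and model averaging with the covariance matrix of each
#' tree in a sample, and summarizes the distribution of every averaged
#' coefficient together with its sign agreement with the consensus-tree
#' result. Used to check that conclusions do not hinge on any single
#' phylogenetic hypothesis.
#'
#' @inheritParams dredge_pgls
#' @param trees List of trees over the model species.
#' @param delta_cut AIC retention window per tree.
#' @param consensus Optional consensus tree (default:
#'   [consensus_tree()] of `trees`).
#' @return data.frame, one row per coefficient of the full model: mean, sd,
#'   min, max of the averaged estimate over trees, the consensus estimate,
#'   and `sign_agreement` (fraction of trees whose averaged estimate has the
#'   consensus sign).
#' @export
dredge_over_trees <- function(full_formula, data, trees, method = "ML",
                              delta_cut = 2, consensus = NULL) {
  if (is.null(consensus)) consensus <- consensus_tree(trees)
  sp <- if ("species" %in% names(data)) as.character(data$species)
        else rownames(data)
  avg_for <- function(tree) {
    V <- brownian_vcv(tree, species_order = sp)
    a <- select_and_average(dredge_pgls(full_formula, data, V,
                                        method = method),
                            delta_cut = delta_cut)
    stats::setNames(a$coefficients$estimate, a$coefficients$term)
  }
  cons_est <- avg_for(consensus)
  ests <- vapply(trees, avg_for, cons_est)
  if (is.null(dim(ests))) ests <- matrix(ests, nrow = 1,
                                         dimnames = list(names(cons_est), NULL))
  out <- data.frame(
    term = rownames(ests),
    mean = rowMeans(ests),
    sd = apply(ests, 1, stats::sd),
    min = apply(ests, 1, min),
    max = apply(ests, 1, max),
    consensus = unname(cons_est[rownames(ests)]),
    sign_agreement = vapply(seq_len(nrow(ests)), function(i)
      mean(sign(ests[i, ]) == sign(cons_est[rownames(ests)[i]])), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
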