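#' Build a conditional-logit design from a long stratum table
#'
#' Turns the long stratum representation (one row per person-day, columns
#' `stratum_id` and `case` plus raw exposures) into the numeric design the
#' fitter consumes. `terms` is a named list mapping column names to
#' [basis_spec()] objects, or a single [crossbasis_spec()] paired with
#' `cols = c(x1, x2)`. Rows with any missing required value are dropped and
#' strata left without their case day or without any control are excluded.
#'
#' @param strata long data.frame with columns `stratum_id`, `case` (0/1) and
#'   the exposure columns referenced by `terms`/`cols`.
#' @param terms named list of `basis_spec`s (names = exposure columns), or a
#'   single `crossbasis_spec`.
#' @param cols for a crossbasis, the two exposure column names, in spec
#'   order.
#' @return list of class `clogit_design` with elements `X` (matrix),
#'   `stratum` (integer vector), `case` (0/1 vector), `n_strata`.
#' @export
build_design <- function(strata, terms, cols = NULL) {
  stopifnot(all(c("stratum_id", "case") %in% names(strata)))
  if (inherits(terms, "crossbasis_spec")) {
    stopifnot(length(cols) == 2L, all(cols %in% names(strata)))
    keep <- is.finite(strata[[cols[1]]]) & is.finite(strata[[cols[2]]])
    strata <- strata[keep, , drop = FALSE]
    X <- crossbasis_matrix(strata[[cols[1]]], strata[[cols[2]]], terms)
  } else {
    stopifnot(is.list(terms), length(terms) >= 1L,
              all(names(terms) %in% names(strata)))
    keep <- Reduce(`&`, lapply(names(terms), function(cl) is.finite(strata[[cl]])))
    strata <- strata[keep, , drop = FALSE]
    X <- do.call(cbind, lapply(names(terms), function(cl)
      basis_matrix(strata[[cl]], terms[[cl]])))
  }
  sid <- as.integer(factor(strata$stratum_id))
  case <- as.numeric(strata$case)
  # keep only strata with exactly one case and >= 1 control
  ncase <- tapply(case, sid, sum)
  nday <- tabulate(sid)
  ok <- which(ncase == 1 & nday >= 2)
  keep <- sid %in% ok
  X <- X[keep, , drop = FALSE]
  sid <- as.integer(factor(sid[keep]))
  structure(list(X = X, stratum = sid, case = case[keep],
                 n_strata = max(sid, 0L)),
            class = "clogit_design")
}

#' Conditional logistic negative log-likelihood
#'
#' For strata \eqn{s} with one case day and design rows \eqn{x_d},
#' \deqn{-\ell(\beta) = -\sum_s [ x_{case}\beta - \log\sum_{d\in s} e^{x_d\beta} ],}
#' evaluated with log-sum-exp stabilization; this is the partial likelihood
#' that eliminates the stratum-level nuisance intercepts. The analytic
#' gradient is returned as attribute `"gradient"`.
#'
#' @param beta numeric coefficient vector.
#' @param design a [build_design()] result (or a list with `X`, `stratum`,
#'   `case`).
#' @return negative log-likelihood with attribute `gradient`.
#' @export
clogit_negloglik <- function(beta, design) {
  X <- design$X; sid <- design$stratum; case <- design$case
  if (any(!is.finite(X))) stop("non-finite design entries")
  eta <- drop(X %*% beta)
  mx <- as.numeric(tapply(eta, sid, max))
  w <- exp(eta - mx[sid])
  sumw <- drop(rowsum(w, sid))
  lse <- log(sumw) + mx                       # per-stratum log-sum-exp
  ll <- sum(eta[case == 1]) - sum(lse)
  p <- w / sumw[sid]                          # within-stratum softmax
  grad <- -(colSums(X[case == 1, , drop = FALSE]) - colSums(X * p))
  structure(-ll, gradient = grad)
}

# per-stratum softmax probabilities, shared by fitter internals
.clogit_prob <- function(beta, design) {
  eta <- drop(design$X %*% beta)
  mx <- as.numeric(tapply(eta, design$stratum, max))
  w <- exp(eta - mx[design$stratum])
  as.numeric(w / drop(rowsum(w, design$stratum))[design$stratum])
}

#' Fit the conditional logistic model
#'
#' Newton-Raphson with step-halving line search on the exact conditional
#' likelihood; the Hessian is the observed information
#' \eqn{\sum_s (E_s[xx'] - E_s[x]E_s[x]')} under the within-stratum softmax,
#' and is ridge-stabilized if numerically non-positive-definite.
#' Convergence requires both a relative log-likelihood change below `tol`
#' and a maximum absolute gradient below `grad_tol`. Coefficient escape
#' (any |beta| above 15) combined with fitted case-day probabilities near 1
#' raises a complete-separation diagnostic instead of returning a silently
#' huge estimate; a large coefficient with diffuse fitted probabilities is
#' left alone, since it reflects a weakly identified column (huge standard
#' error), not an unbounded likelihood.
#'
#' @param design a [build_design()] result.
#' @param init starting coefficients (default 0).
#' @param tol relative log-likelihood convergence tolerance.
#' @param grad_tol gradient sup-norm tolerance.
#' @param max_iter iteration cap.
#' @return object of class `clogit_fit`: list with `beta`, `vcov`, `loglik`,
#'   `n_strata`, `converged`, `iterations`, `separation`.
#' @export
clogit_fit <- function(design, init = NULL, tol = 1e-10, grad_tol = 1e-6,
                       max_iter = 100L) {
  X <- design$X
  p <- ncol(X)
  if (design$n_strata < 1L) stop("no informative strata")
  # informative = some within-stratum variation in at least one column
  v <- rowsum(X^2, design$stratum) / tabulate(design$stratum) -
    (rowsum(X, design$stratum) / tabulate(design$stratum))^2
  if (all(v < 1e-300)) stop("no informative strata (no within-stratum variation)")
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  stopifnot(length(beta) == p)
  nll <- clogit_negloglik(beta, design)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    g <- attr(nll, "gradient")
    pr <- .clogit_prob(beta, design)
    M <- rowsum(X * pr, design$stratum)          # per-stratum E[x]
    H <- crossprod(X, X * pr) - crossprod(M)     # observed information
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      # ridge fallback for non-PD information
      H <- H + diag(max(1e-8, 1e-8 * max(diag(H))), p)
      step <- solve(H, -g)
    }
    # step-halving line search
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      nll_new <- tryCatch(clogit_negloglik(cand, design), error = function(e) Inf)
      if (is.finite(nll_new) && nll_new <= nll + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { cand <- beta; nll_new <- nll; break }
    }
    rel <- abs(nll - nll_new) / (abs(nll) + 1e-12)
    beta <- cand
    nll <- nll_new
    g <- attr(nll, "gradient")
    if (rel < tol && max(abs(g)) < grad_tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # under complete separation the likelihood is unbounded: coefficients
  # drift off while the fitted case-day probabilities approach 1 (the
  # gradient decays to numerical zero, so it carries no signal). A large
  # coefficient alone can also reflect a weakly identified basis column;
  # requiring near-degenerate fitted probabilities separates the two.
  pr_fit <- .clogit_prob(beta, design)
  separation <- any(abs(beta) > 15) && mean(pr_fit[design$case == 1]) > 0.99
  if (separation)
    warning("possible complete separation: diverging coefficient with fitted case probabilities near 1")
  pr <- .clogit_prob(beta, design)
  M <- rowsum(X * pr, design$stratum)
  H <- crossprod(X, X * pr) - crossprod(M)
  H <- (H + t(H)) / 2
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  vc <- (vc + t(vc)) / 2
  structure(list(beta = beta, vcov = vc, loglik = -as.numeric(nll),
                 n_strata = design$n_strata, converged = converged,
                 iterations = iter, separation = separation),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic fit: %d strata, logLik %.3f, %s in %d iterations\n",
              x$n_strata, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  se <- sqrt(diag(x$vcov))
  print(data.frame(beta = x$beta, se = se, z = x$beta / se))
  invisible(x)
}

#' Akaike information criterion of a conditional-logit fit
#'
#' `2k - 2 logLik` with `k = length(beta)`; the stratum intercepts are
#' conditioned out and do not count as parameters.
#'
#' @param fit a converged [clogit_fit()] result.
#' @export
clogit_aic <- function(fit) {
  stopifnot(inherits(fit, "clogit_fit"))
  if (!fit$converged) stop("AIC requires a converged fit")
  2 * length(fit$beta) - 2 * fit$loglik
}

#' Choose exposure df by AIC
#'
#' Fits one conditional-logit model per candidate basis dimension for a
#' single exposure column (df 1 meaning the linear term) and returns the
#' AIC-minimizing choice, ties broken toward the smaller df.
#'
#' @param strata long stratum table (see [build_design()]).
#' @param col exposure column name.
#' @param candidate_dfs integer vector of candidate df values.
#' @param ... passed to [clogit_fit()].
#' @return list with `chosen_df`, `aic_table` (data.frame df/aic/converged),
#'   and `fits` (named list of `clogit_fit`s).
#' @export
select_df <- function(strata, col, candidate_dfs, ...) {
  stopifnot(length(candidate_dfs) >= 1L)
  xs <- strata[[col]][is.finite(strata[[col]])]
  fits <- list()
  rows <- lapply(candidate_dfs, function(df) {
    spec <- if (df <= 1L) basis_spec("linear", x = xs)
            else basis_spec("bspline", df = df, x = xs)
    f <- tryCatch({
      tl <- stats::setNames(list(spec), col)
      clogit_fit(build_design(strata, tl), ...)
    }, error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      warning("candidate df ", df, " failed to fit; excluded")
      return(data.frame(df = df, aic = NA_real_, converged = FALSE))
    }
    fits[[as.character(df)]] <<- f
    data.frame(df = df, aic = clogit_aic(f), converged = TRUE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab[tab$converged, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no candidate df produced a converged fit")
  ok <- ok[order(ok$aic, ok$df), , drop = FALSE]
  list(chosen_df = ok$df[1], aic_table = tab, fits = fits)
}
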