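#' Fit a two-Gaussian mixture to log expression by EM
#'
#' Models the bimodal distribution of log10 expression as a mixture of a
#' repressed and an active Gaussian component with free weights, means and
#' sds. Components are ordered so `mu_repressed < mu_active`. EM is
#' initialized from a median split (deterministic); if a component collapses
#' (sd below `sd_floor`) the fit restarts with jittered responsibilities,
#' failing after `max_restarts` attempts.
#'
#' @param log_expr Numeric vector of log-transformed expression values; at
#'   least 20 finite values with nonzero variance.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param max_restarts Restarts allowed on degenerate collapse.
#' @param sd_floor Smallest admissible component sd.
#' @param seed Integer seed (used only for restart jitter).
#' @return A `mixture_fit` list: `mu_repressed`, `sd_repressed`,
#'   `w_repressed`, `mu_active`, `sd_active`, `w_active`, `threshold`
#'   (density intersection between the means), `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`.
#' @export
fit_two_gaussians <- function(log_expr, tol = 1e-8, max_iter = 500L,
                              max_restarts = 5L, sd_floor = 1e-4,
                              seed = 1L) {
  x <- log_expr[is.finite(log_expr)]
  if (length(x) < 20L) stop("need at least 20 finite values")
  if (stats::sd(x) == 0) stop("zero variance: all values identical")
  n <- length(x)
  with_seed(seed, {
    run_em <- function(resp_init) {
      resp <- resp_init
      ll_trace <- numeric(0)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        # M step
        w <- colMeans(resp)
        mu <- colSums(resp * x) / colSums(resp)
        s2 <- colSums(resp * (outer(x, mu, "-")^2)) / colSums(resp)
        sdv <- sqrt(s2)
        if (any(!is.finite(sdv)) || any(sdv < sd_floor) || any(w < 1e-12)) {
          return(list(ok = FALSE))
        }
        # E step
        d1 <- w[1] * stats::dnorm(x, mu[1], sdv[1])
        d2 <- w[2] * stats::dnorm(x, mu[2], sdv[2])
        tot <- d1 + d2
        ll <- sum(log(tot))
        ll_trace <- c(ll_trace, ll)
        resp <- cbind(d1 / tot, d2 / tot)
        if (is.finite(ll_old) && ll - ll_old < tol) {
          return(list(ok = TRUE, w = w, mu = mu, sd = sdv, ll = ll,
                      trace = ll_trace, n_iter = it, converged = TRUE))
        }
        ll_old <- ll
      }
      list(ok = TRUE, w = w, mu = mu, sd = sdv, ll = ll_old,
           trace = ll_trace, n_iter = max_iter, converged = FALSE)
    }
    # deterministic initial responsibilities: hard median split
    med <- stats::median(x)
    resp0 <- cbind(as.numeric(x <= med), as.numeric(x > med))
    resp0 <- pmin(pmax(resp0, 0.05), 0.95)
    resp0 <- resp0 / rowSums(resp0)
    fit <- run_em(resp0)
    restarts <- 0L
    while (!fit$ok && restarts < max_restarts) {
      restarts <- restarts + 1L
      jitter <- matrix(stats::runif(2 * n, 0.05, 0.95), ncol = 2)
      fit <- run_em(jitter / rowSums(jitter))
    }
    if (!fit$ok) stop("EM collapsed after ", max_restarts, " restarts")
    ord <- order(fit$mu)  # repressed = lower mean
    out <- list(
      mu_repressed = fit$mu[ord[1]], sd_repressed = fit$sd[ord[1]],
      w_repressed = fit$w[ord[1]],
      mu_active = fit$mu[ord[2]], sd_active = fit$sd[ord[2]],
      w_active = fit$w[ord[2]],
      loglik = fit$ll, loglik_trace = fit$trace,
      n_iter = fit$n_iter, converged = fit$converged)
    out$threshold <- tryCatch(intersection_threshold(out),
                              error = function(e) NA_real_)
    class(out) <- c("mixture_fit", "list")
    out
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    paste0("two-Gaussian mixture fit (%d EM iterations, loglik %.2f)\n",
           "  repressed: mu = %.3f, sd = %.3f, w = %.3f\n",
           "  active:    mu = %.3f, sd = %.3f, w = %.3f\n",
           "  active/repressed threshold: %.4f (log10 units)\n"),
    x$n_iter, x$loglik, x$mu_repressed, x$sd_repressed, x$w_repressed,
    x$mu_active, x$sd_active, x$w_active, x$threshold))
  invisible(x)
}

#' Density intersection of the two mixture components
#'
#' Solves `w_r N(x | mu_r, sd_r) = w_a N(x | mu_a, sd_a)` for the root
#' between the two means — the expression threshold separating repressed
#' from active genes. The log-density equation is quadratic in `x` for
#' unequal sds and linear for equal sds; the between-means root is selected.
#'
#' @param fit A `mixture_fit` (or any list with the six parameter fields).
#' @return The threshold in the units of the fitted data (log10 TPM).
#' @export
intersection_threshold <- function(fit) {
  mu1 <- fit$mu_repressed; s1 <- fit$sd_repressed; w1 <- fit$w_repressed
  mu2 <- fit$mu_active; s2 <- fit$sd_active; w2 <- fit$w_active
  if (isTRUE(all.equal(mu1, mu2)) && isTRUE(all.equal(s1, s2))) {
    stop("identical components: no unique intersection")
  }
  # log w1 - log s1 - (x-mu1)^2/(2 s1^2) = log w2 - log s2 - (x-mu2)^2/(2 s2^2)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- mu1 / s1^2 - mu2 / s2^2
  cc <- mu2^2 / (2 * s2^2) - mu1^2 / (2 * s1^2) +
    log(w1 / s1) - log(w2 / s2)
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) stop("identical components: no unique intersection")
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("components do not intersect on the real line")
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  }
  between <- roots[roots >= lo & roots <= hi]
  if (length(between) == 0L) {
    # fall back to the root closest to the between-means midpoint
    return(roots[which.min(abs(roots - (lo + hi) / 2))])
  }
  between[which.min(abs(between - (lo + hi) / 2))]
}

#' Classify genes as active or repressed at a threshold
#'
#' A gene is active iff its log10 expression (with pseudocount) is greater
#' than or equal to the threshold; the boundary value itself is classified
#' active.
#'
#' @param expr_table `data.frame` with a `gene` column and one TPM column
#'   per condition, or a named numeric vector of TPM.
#' @param threshold Threshold in log10 units (from
#'   [intersection_threshold()]).
#' @param condition Which condition column to classify (default: first).
#' @param pseudocount Added to TPM before log10 (default 0.01).
#' @return `data.frame` with `gene`, `log_expr`, `class`
#'   (`active`/`repressed`), plus class counts in the `"counts"` attribute.
#' @export
classify_genes <- function(expr_table, threshold, condition = NULL,
                           pseudocount = 0.01) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (is.numeric(expr_table)) {
    genes <- names(expr_table)
    tpm <- unname(expr_table)
  } else {
    genes <- expr_table$gene
    cond_cols <- setdiff(names(expr_table), "gene")
    if (is.null(condition)) condition <- cond_cols[1]
    tpm <- expr_table[[condition]]
  }
  lg <- log10(tpm + pseudocount)
  cls <- ifelse(lg >= threshold, "active", "repressed")
  out <- data.frame(gene = genes, log_expr = lg, class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(active = sum(cls == "active"),
                           repressed = sum(cls == "repressed"))
  out
}
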