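# Approximate leave-one-out model comparison by truncated importance
# sampling over the pointwise posterior log-likelihood.

# elpd_loo per observation from a draws x obs log-likelihood matrix,
# with importance weights truncated at mean(w) * S^(3/4)
loo_pointwise <- function(ll) {
  S <- nrow(ll)
  apply(ll, 2, function(l) {
    lw <- -l                    # log raw importance weights
    lw <- lw - max(lw)
    cap <- log(mean(exp(lw))) + 0.75 * log(S)
    lw <- pmin(lw, cap)
    # elpd_i = log( sum(w * p) / sum(w) ) with p = exp(l)
    num <- logsumexp(lw + l)
    den <- logsumexp(lw)
    num - den
  })
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Compare fitted surplus-production families by approximate LOO
#'
#' Computes, for each fit, the approximate leave-one-out expected log
#' predictive density (elpd) by truncated importance sampling on the
#' pointwise log-likelihood, and reports differences to the best model
#' with standard errors. All fits must cover the same observations.
#'
#' @param ... Named [fit_reef_model()] objects (or a single named list).
#' @return A tibble sorted by decreasing elpd with columns `model`,
#'   `elpd`, `se_elpd`, `elpd_diff`, `se_diff`.
#' @export
model_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "reef_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1),
                                           "reef_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model$family, character(1))
  }
  lls <- lapply(fits, pointwise_loglik)
  ids <- lapply(lls, colnames)
  if (length(unique(vapply(ids, paste, character(1), collapse = "|"))) != 1L) {
    stop("fits cover different observation sets and cannot be compared")
  }
  pw <- lapply(lls, loo_pointwise)
  elpd <- vapply(pw, sum, numeric(1))
  se <- vapply(pw, function(p) sqrt(length(p) * stats::var(p)), numeric(1))
  best <- which.max(elpd)
  diff <- vapply(seq_along(pw), function(k) sum(pw[[k]] - pw[[best]]),
                 numeric(1))
  se_diff <- vapply(seq_along(pw), function(k) {
    d <- pw[[k]] - pw[[best]]
    sqrt(length(d) * stats::var(d))
  }, numeric(1))
  out <- tibble::tibble(model = names(fits), elpd = elpd, se_elpd = se,
                        elpd_diff = diff, se_diff = se_diff)
  out[order(-out$elpd), ]
}
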