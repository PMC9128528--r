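# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded operations (bootstraps, simulation-based tests) are reproducible
#' without disturbing the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Assemble a causal-effect estimate row
#'
#' All estimators return their result in this common one-row `data.frame`
#' layout: the effect on the log odds ratio scale (per SD of exposure), a
#' normal-theory 95% confidence interval, and the exponentiated (odds ratio)
#' counterparts.
#'
#' @param method character label for the estimator.
#' @param beta point estimate, log-OR per SD of exposure.
#' @param se standard error of `beta` (must be > 0).
#' @param n_snp number of instruments used.
#' @param pvalue optional; defaults to the two-sided normal p-value of
#'   `beta / se`.
#' @return a one-row `data.frame` with columns `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `or`, `or_ci_low`, `or_ci_high`, `pvalue`, `n_snp`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, pvalue = NULL) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  z <- stats::qnorm(0.975)
  if (is.null(pvalue)) pvalue <- 2 * stats::pnorm(-abs(beta / se))
  pvalue <- min(max(pvalue, .Machine$double.xmin), 1)
  data.frame(
    method = method, beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    or = exp(beta), or_ci_low = exp(beta - z * se), or_ci_high = exp(beta + z * se),
    pvalue = pvalue, n_snp = as.integer(n_snp),
    stringsAsFactors = FALSE
  )
}

# flags are stored as a comma-separated string ("" when none)
add_flag <- function(flags, flag) {
  out <- character(length(flags))
  for (i in seq_along(flags)) {
    cur <- flags[i]
    parts <- if (!nzchar(cur)) character(0) else strsplit(cur, ",", fixed = TRUE)[[1]]
    if (!flag %in% parts) parts <- c(parts, flag)
    out[i] <- paste(parts, collapse = ",")
  }
  out
}

has_flag <- function(flags, flag) {
  vapply(strsplit(ifelse(nzchar(flags), flags, ""), ",", fixed = TRUE),
         function(p) flag %in% p, logical(1))
}

stop_insufficient <- function(need, have, hint = NULL) {
  msg <- sprintf("insufficient instruments: need at least %d, have %d", need, have)
  if (!is.null(hint)) msg <- paste0(msg, "; ", hint)
  stop(msg, call. = FALSE)
}
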