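# internal helpers shared across modules

# error constructors: every user-facing failure carries a subclass so callers
# (and the pipeline) can branch on the kind of failure
ht_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "hydrotraits_error"), ...)
}

ht_schema_error <- function(msg, ...) ht_abort(msg, "ht_schema_error", ...)
ht_fit_error    <- function(msg, ...) ht_abort(msg, "ht_fit_error", ...)
ht_param_error  <- function(msg, ...) ht_abort(msg, "ht_param_error", ...)

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (!is.numeric(x)) {
    ht_param_error(sprintf("`%s` must be numeric.", name))
  }
  bad <- !is.na(x) & (x < lower | x > upper)
  if (any(bad)) {
    ht_param_error(sprintf(
      "`%s` must lie in [%s, %s] (offending values: %s).",
      name, format(lower), format(upper),
      paste(utils::head(format(x[bad]), 5), collapse = ", ")
    ))
  }
  if (!allow_na && anyNA(x)) {
    ht_param_error(sprintf("`%s` contains missing values.", name))
  }
  invisible(x)
}

# One user seed fans out to independent per-channel substreams, so that
# adding noise to one channel never shifts the draws of another.
fan_out_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# least-squares on a fixed design, returning coefficients and RSS
lsq <- function(X, y) {
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss, residuals = fit$residuals,
       rank = fit$rank)
}

first_non_null <- function(...) {
  for (x in list(...)) if (!is.null(x)) return(x)
  NULL
}
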