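# Internal helpers shared across modules.

# Deterministic child seed derived from a master seed and arbitrary keys
# (region names, fold indices, ...). Kept strictly below 2^31 - 1 so it is
# always a valid R/xgboost integer seed.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483587L
  as.integer((h + as.integer(seed) %% 2147483587L) %% 2147483587L + 1L)
}

# Per-column (gene) population variance, ddof = 0.
col_vars <- function(m, ddof = 0) {
  n <- nrow(m)
  mu <- colMeans(m)
  ss <- colSums(m^2) - n * mu^2
  denom <- n - ddof
  pmax(ss, 0) / denom
}

col_sds <- function(m, ddof = 0) sqrt(col_vars(m, ddof = ddof))

assert_expression_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric samples x genes matrix.", arg))
  }
  if (is.null(colnames(m))) {
    abort(sprintf("`%s` must carry gene IDs as column names.", arg))
  }
  invisible(m)
}

region_of <- function(m) {
  r <- attr(m, "region", exact = TRUE)
  if (is.null(r)) NA_character_ else r
}

`region_of<-` <- function(m, value) {
  if (is.null(value) || all(is.na(value))) {
    attr(m, "region") <- NULL
  } else {
    attr(m, "region") <- value
  }
  m
}
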