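# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a fixed RNG seed when one is given; otherwise use the
# current RNG stream. Keeps every exported stochastic operation reproducible
# from a single integer without disturbing the caller's RNG state.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_fosnet <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_fosnet(msg)
}

# Canonical group labelling: "sex.condition", e.g. "male.trained".
group_label <- function(sex, condition) paste(sex, condition, sep = ".")

SEXES <- c("male", "female")
CONDITIONS <- c("naive", "trained")

group_levels <- function() {
  as.vector(outer(SEXES, CONDITIONS, group_label))
}

# Descending rank with ties sharing the best (smallest) rank.
rank_desc <- function(x) {
  rank(-x, ties.method = "min", na.last = "keep")
}
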