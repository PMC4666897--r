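# internal validation helpers

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    .stopf("`%s` must be a single number, not NULL", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    .stopf("`%s` must be in [%s, %s], got %s", name,
           format(lower), format(upper), format(x))
  invisible(x)
}

.check_count <- function(x, name, lower = 1L) {
  .check_number(x, name, lower = lower)
  if (x != round(x)) .stopf("`%s` must be a whole number", name)
  invisible(as.integer(x))
}

.check_biomass_vector <- function(x, name = "biomass",
                                  require_nonneg = TRUE) {
  if (is.null(x) || !is.numeric(x) || length(x) < 1L)
    .stopf("`%s` must be a non-empty numeric vector", name)
  if (anyNA(x) || any(!is.finite(x)))
    .stopf("`%s` must be finite throughout", name)
  if (require_nonneg && any(x < 0))
    .stopf("`%s` must be non-negative (min found: %s)", name,
           format(min(x)))
  invisible(x)
}

# Seed the global RNG from `seed` when non-NULL; no-op otherwise.
.maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    .check_number(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Derive deterministic child seeds below 2^31 from a parent seed.
.child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max, n))
}
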