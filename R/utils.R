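# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("`%s` must lie in [0, 1]", name)
  invisible(x)
}

# run expr with a locally seeded RNG; outer RNG state is untouched so
# simulation components compose deterministically without interference
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a reproducible child seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647L)
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# fraction vocabularies (closed, case-sensitive)
FRACTION_LEVELS <- c("Whole", "HNA", "LNA", "BONCATpos", "BONCATneg", "PIpos", "Sheath")
SORTED_FRACTIONS <- c("HNA", "LNA", "BONCATpos", "BONCATneg", "PIpos")
GATE_FRACTIONS <- c("HNA", "BONCATpos", "PIpos")
TREATMENT_LEVELS <- c("Control", "Digoxin", "Nizatidine", "Glucose")
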