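# internal helpers shared across modules

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic child seed for a named generator stream. Each generator in
# the simulator consumes its own stream derived from the one top-level seed,
# so adding a generator does not perturb the draws of the others. Result is
# kept inside the 32-bit signed-integer range R requires for set.seed().
#' @noRd
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(seed) * 48271 + h * 69621 + 7) %% 2147483629)
}

# Run code under a seed (when given) without disturbing the caller's RNG
# state; seed = NULL uses the current stream.
#' @noRd
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# round-half-up to integers (base round() is round-half-even)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x >= 0) && !is.null(colnames(x))
}

#' @noRd
check_condition <- function(condition, n_samples) {
  condition <- as.factor(condition)
  if (length(condition) != n_samples)
    stopf("condition has %d labels for %d samples", length(condition), n_samples)
  if (nlevels(condition) != 2L)
    stopf("condition must have exactly 2 levels, got %d", nlevels(condition))
  if (any(table(condition) < 2L))
    stopf("each condition needs >= 2 samples")
  condition
}
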