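#' @importFrom stats rnorm runif predict
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "qfuse_validation_error")
}

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_bad_arg(sprintf("`%s` must be a single number.", name))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_bad_arg(sprintf("`%s` must be an integer.", name))
  }
  if (x < min || x > max) {
    abort_bad_arg(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

#' Spawn a child seed from a parent seed
#'
#' One global integer seed deterministically spawns per-stage seeds so that
#' changing one pipeline stage's stream never perturbs another's. The child
#' seed is a fixed arithmetic hash of the parent seed and a stage label,
#' reduced modulo 2^31 - 1.
#'
#' @param seed Parent integer seed.
#' @param label Character stage label (e.g. `"images"`, `"fusion"`).
#' @return A single integer seed.
#' @export
#' @examples
#' spawn_seed(1, "images")
spawn_seed <- function(seed, label) {
  check_number(seed, "seed", integerish = TRUE)
  h <- sum(utf8ToInt(as.character(label)) * (31^(seq_along(utf8ToInt(as.character(label))) %% 7)))
  as.integer((abs(seed) * 69069 + h * 2654435761) %% (2^31 - 1)) + 1L
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

#' Variance-scaled uniform initialisation
#'
#' Draws entries of an `n_out` x `n_in` matrix uniformly on
#' `[-a, a]` with `a = sqrt(6 / (n_in + n_out))` (Glorot-style scaling), the
#' package's default for all learnable projection matrices; biases start at
#' zero.
#'
#' @param n_out,n_in Output/input dimensions.
#' @return An `n_out` x `n_in` numeric matrix.
#' @keywords internal
init_matrix <- function(n_out, n_in) {
  a <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -a, a), n_out, n_in)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

as_label_int <- function(labels, n_classes = NULL, name = "labels") {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (!is.numeric(labels) || anyNA(labels)) {
    abort_bad_arg(sprintf("`%s` must be non-missing class indices.", name))
  }
  labels <- as.integer(round(labels))
  if (any(labels < 0L)) abort_bad_arg(sprintf("`%s` must be >= 0 (0-based class indices).", name))
  if (!is.null(n_classes) && any(labels >= n_classes)) {
    abort_bad_arg(sprintf("`%s` contains indices >= n_classes = %d.", name, n_classes))
  }
  labels
}
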