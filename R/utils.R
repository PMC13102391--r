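# Run `code` with a temporary RNG state seeded at `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Percentage of double-labelled cells in a dual retrograde tracing count
#'
#' Summarises the overlap between two retrogradely labelled neuron
#' populations as the percentage of double-labelled somata among all
#' labelled somata (single green + single red + double).
#'
#' @param n_double Count of double-labelled cells.
#' @param n_a,n_b Counts of cells labelled by each single tracer only.
#' @return Percentage of all labelled cells that are double-labelled.
#' @examples
#' double_label_pct(30, 305, 549)
#' @export
double_label_pct <- function(n_double, n_a, n_b) {
  counts <- c(n_double, n_a, n_b)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  total <- n_double + n_a + n_b
  if (total == 0) stop("no labelled cells", call. = FALSE)
  100 * n_double / total
}
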