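# Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a master seed
#'
#' A single master seed drives every stochastic stage of the pipeline
#' (simulation, splitting, cross-validation folding, bootstrap). Each stage
#' receives its own stream, derived deterministically from the master seed and
#' the stage name, so that changing one stage's behaviour never perturbs the
#' randomness of another.
#'
#' @param master Integer master seed.
#' @param stage Character stage label, e.g. `"simulate"`, `"split"`.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "simulate")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- abs(as.numeric(master)) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Scalar checks used by config validators.
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single strictly positive number.", name))
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name))
  }
  as.numeric(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must lie strictly between 0 and 1.", name))
  }
  as.numeric(x)
}

# Largest-remainder allocation of `total` units across groups with target
# shares `weights` (non-negative, not necessarily normalised). Returns integer
# counts summing exactly to `total`, each bounded by `cap` when given.
largest_remainder <- function(weights, total, cap = NULL) {
  stopifnot(all(weights >= 0), total >= 0)
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  if (!is.null(cap)) base <- pmin(base, cap)
  short <- total - sum(base)
  rem <- quota - floor(quota)
  # Deterministic order: largest fractional remainder first, ties to the
  # larger quota, then to the earlier group.
  ord <- order(-rem, -quota, seq_along(quota))
  i <- 1L
  while (short > 0L && i <= length(ord)) {
    g <- ord[i]
    room <- if (is.null(cap)) Inf else cap[g] - base[g]
    add <- min(short, room, 1)
    base[g] <- base[g] + add
    short <- short - add
    i <- i + 1L
  }
  if (short > 0L) abort("largest_remainder: infeasible allocation under caps.")
  as.integer(base)
}
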