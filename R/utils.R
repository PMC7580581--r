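# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All stochastic entry points funnel through this, so a seed given
# to one of them fully determines its output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Per-stage seeds derived from a master seed by fixed offsets, kept inside
# the 32-bit integer range. Adding a stage never perturbs earlier streams.
derive_seed <- function(master, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, distance = 37L, nmds = 53L,
               permanova = 71L, dispersion = 89L, pairwise = 107L,
               bootstrap = 131L, generic = 151L)
  off <- offsets[[stage]]
  as.integer((as.numeric(master) * 1009 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_whole <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && abs(x - round(x)) < 1e-8
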