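# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input("`%s` must be a single non-missing number", name)
  }
  if (x < lower || x > upper) {
    stop_input("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_input("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

# deterministic child seed derivation, kept within 32-bit integer range
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + 97 * as.numeric(k)) %% 2147483647
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# mean-one lognormal deviates with coefficient of variation `cv`
rlnorm_mean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

FITNESS_LEVELS <- c("low", "intermediate", "high")
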