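# internal helpers shared across modules

# error with a package condition class so callers can catch by failure kind:
# "usage" (bad arguments), "data" (unusable input), "compute" (no result)
pf_stop <- function(msg, type = "usage", call. = FALSE) {
  stop(errorCondition(msg,
                      class = c(paste0("pialflow_", type, "_error"),
                                "pialflow_error", "error", "condition")))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# circular shift of a vector by k positions (positive k moves content right)
circshift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FWHM of a Gaussian with standard deviation 1
FWHM_PER_SD <- 2 * sqrt(2 * log(2))
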