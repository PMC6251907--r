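# Internal helpers.

# A private uniform(0,1) stream seeded independently of the caller's RNG:
# swaps .Random.seed in and out around each draw so that generators are
# deterministic for a fixed seed without clobbering the session RNG state.
.seeded_rng <- function(seed) {
  genv <- globalenv()
  grab <- function() if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  put <- function(s) {
    if (is.null(s)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", s, envir = genv)
  }
  outer <- grab()
  set.seed(seed)
  state <- grab()
  put(outer)
  function(n = 1) {
    outer <- grab()
    put(state)
    u <- stats::runif(n)
    state <<- grab()
    put(outer)
    u
  }
}

# trapezoidal integral of y over x (thin wrapper, kept in one place)
.trapz <- function(x, y) pracma::trapz(x, y)
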