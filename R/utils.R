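# Internal helpers shared across modules.

BAND_NAMES <- c("Red", "RedEdge", "Nir", "Green", "Blue")
STAGES <- c("HS", "FL", "GF")
TREATMENTS <- c("W", "D")
ENVS <- c("E1", "E2")

# Wheat chromosome labels 1A..7D, ordered by (number, letter).
wheatChromosomes <- function(n = 21) {
  all <- paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
  all[seq_len(n)]
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Reflectance (fraction) column names used throughout for plot tables.
REFL_COLS <- c(Red = "r_red", RedEdge = "r_rededge", Nir = "r_nir",
               Green = "r_green", Blue = "r_blue")
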