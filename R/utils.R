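#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generator functions never leak random state into the
#' session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent child
#' seeds (all below 2^31), so that per-participant generators can be called
#' with explicit seeds while the whole run stays reproducible from a single
#' integer.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw from a truncated normal by inverse-CDF
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

# Polynomial rolling hash (mod 2^31 - 1) over a character scalar; used only
# for provenance manifests, not for security.
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.activity_classes <- c("sitting", "standing", "stepping", "time_in_bed")
.waking_classes <- c("sitting", "standing", "stepping")
.track_names <- c("Hairdresser", "Admin", "Sports", "Nursing")

# Consonant alphabet for the letter-memory test: 26 letters minus the five
# vowels and Y.
.lmt_consonants <- setdiff(LETTERS, c("A", "E", "I", "O", "U", "Y"))
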