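#' @useDynLib restcouple, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor cor.test fft lm mad median nextn pchisq pf pt
#'   prcomp pnorm qnorm quantile rbinom rnorm runif rpois sd var setNames
#' @importFrom utils head read.delim tail write.table
NULL

# Classed conditions: every user-facing failure mode carries a condition class
# "rc_error_<kind>" so callers and tests can branch on the kind, not the text.
rc_abort <- function(message, class, call. = FALSE, ...) {
  stop(structure(
    class = c(paste0("rc_error_", class), "rc_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  ))
}

rc_assert <- function(cond, message, class = "validation") {
  if (!isTRUE(cond)) rc_abort(message, class)
  invisible(TRUE)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched so generators are pure functions of (args, seed).
with_rc_seed <- function(seed, expr) {
  rc_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic child seed
#'
#' Folds a master seed and one or more stream labels into a 31-bit integer
#' (R integers are 32-bit signed), so each simulation stage gets its own
#' reproducible stream.
#'
#' @param master master seed.
#' @param ... stream labels (coerced to character).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  lab <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Frequency band definition
#'
#' A named frequency interval in Hz. The default analysis set spans the
#' common EEG rhythms: delta 0-4, theta 4-8, alpha 8-12, beta1 12-20,
#' beta2 21-29 and gamma 32-48 Hz.
#'
#' @param name band label, e.g. `"theta"`.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`.
#' @return A `band_spec` object.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  rc_assert(is.character(name) && length(name) == 1, "band name must be a string")
  rc_assert(is.numeric(f_lo) && is.numeric(f_hi) && f_lo >= 0 && f_lo < f_hi,
            "band edges must satisfy 0 <= f_lo < f_hi")
  structure(list(name = name, f_lo = as.numeric(f_lo), f_hi = as.numeric(f_hi)),
            class = "band_spec")
}

#' Default EEG frequency bands
#'
#' @return Named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  b <- list(
    band_spec("delta", 0, 4),
    band_spec("theta", 4, 8),
    band_spec("alpha", 8, 12),
    band_spec("beta1", 12, 20),
    band_spec("beta2", 21, 29),
    band_spec("gamma", 32, 48)
  )
  names(b) <- vapply(b, `[[`, "", "name")
  b
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1) {
    bands <- default_bands()
    rc_assert(band %in% names(bands),
              paste0("unknown band '", band, "'"), "validation")
    return(bands[[band]])
  }
  rc_abort("band must be a band_spec or a default band name", "validation")
}

#' Per-vertex scalar map over a source space
#'
#' Container for one value per vertex (power, node strength, t, Cohen's d,
#' -log10 p, or a seed-FC value), tagged with what it is and where it came
#' from.
#'
#' @param values numeric vector, one finite value per vertex.
#' @param kind one of `"power"`, `"node_strength"`, `"t"`, `"d"`,
#'   `"neglog10p"`, `"seed_fc"`.
#' @param band optional band name.
#' @param condition optional condition tag (`"inside"`/`"outside"`).
#' @param space_id optional identifier of the aligned source space.
#' @param meta optional list of extra metadata.
#' @return A `vertex_map` object.
#' @export
vertex_map <- function(values, kind = c("power", "node_strength", "t", "d",
                                        "neglog10p", "seed_fc"),
                       band = NULL, condition = NULL, space_id = NULL,
                       meta = list()) {
  kind <- match.arg(kind)
  rc_assert(is.numeric(values) && all(is.finite(values)),
            "vertex map values must be finite numerics")
  structure(list(values = as.numeric(values), kind = kind, band = band,
                 condition = condition, space_id = space_id, meta = meta),
            class = "vertex_map")
}

map_values <- function(m) if (inherits(m, "vertex_map")) m$values else as.numeric(m)

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %.3g-%.3g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("<vertex_map> kind=%s band=%s n=%d range=[%.4g, %.4g]\n",
              x$kind, x$band %||% "-", length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
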