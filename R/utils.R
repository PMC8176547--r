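#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so package internals never
#' perturb the caller's RNG stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed; kept well inside 32-bit integer range.
deriveSeed <- function(seed, salt) {
  as.integer((as.double(seed) %% 65011 * 32749 + as.double(salt) * 7919 + 1) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopStage <- function(stage, sample, msg) {
  stop(sprintf("stage '%s' failed at sample '%s': %s", stage, sample, msg),
       call. = FALSE)
}

assertRgb <- function(pixels, what = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop(sprintf("%s must be an H x W x 3 array", what), call. = FALSE)
  if (dim(pixels)[3] != 3L)
    stop(sprintf("%s must have exactly 3 channels, got %d", what,
                 dim(pixels)[3]), call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop(sprintf("%s values must lie in [0, 1]", what), call. = FALSE)
  invisible(pixels)
}

assertMask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop(sprintf("%s must be a {0,1} matrix", what), call. = FALSE)
  invisible(mask)
}
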