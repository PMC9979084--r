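# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are
#' reproducible without disturbing the caller's RNG stream.
#' @noRd
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# stopifnot with a readable message
abort_if <- function(cond, msg, class = "enamelmat_error") {
  if (isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(NULL)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  abort_if(!is_scalar_number(x) || x <= 0,
           sprintf("`%s` must be a single positive finite number", name),
           class = "enamelmat_validation_error")
}

# Linear interpolation that errors instead of extrapolating silently.
interp_linear <- function(x, y, xout, rule = 2L) {
  stats::approx(x, y, xout = xout, method = "linear", rule = rule,
                ties = "ordered")$y
}

# md5 of an in-memory object via its serialized bytes (used for provenance)
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

pkg_version_string <- function() {
  as.character(utils::packageVersion("enamelmat"))
}
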