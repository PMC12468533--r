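# Internal helpers shared across modules.

#' @keywords internal
gs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gaitsense_error")))
}

#' @keywords internal
gs_assert <- function(ok, msg, class = "gaitsense_invalid_input") {
  if (!isTRUE(ok)) gs_error(msg, class)
}

# Set the RNG locally when a seed is supplied; NULL leaves the caller's
# RNG stream untouched (so protocol runners can drive sub-generators
# from a single stream).
#' @keywords internal
gs_seed <- function(seed) {
  if (!is.null(seed)) {
    gs_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# FNV-1a hash over a deparsed R object; used for config provenance so a
# report can state which configuration produced it without a digest
# dependency.
#' @keywords internal
gs_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @keywords internal
is_uniform_time <- function(t, tol = 1e-6) {
  if (length(t) < 2) return(FALSE)
  dt <- diff(t)
  all(dt > 0) && (max(dt) - min(dt)) <= tol * mean(dt) + 1e-12
}
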