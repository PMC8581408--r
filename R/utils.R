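#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fustx <- function(..., call. = FALSE) stop(..., call. = call.)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_fustx(sprintf("'%s' must be a single non-missing number", name))
  }
  if (x < lower || x > upper) {
    stop_fustx(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_fustx(sprintf("'%s' must be an integer count", name))
  invisible(as.integer(x))
}

#' FNV-1a content fingerprint
#'
#' 32-bit Fowler-Noll-Vo (FNV-1a) hash of the deparsed representation of an
#' R object. Used to stamp run manifests and output headers with a
#' configuration fingerprint so that reruns can be matched to their config.
#' Not cryptographic.
#'
#' @param x any R object; deparsed to character before hashing.
#' @return an 8-character lowercase hex string.
#' @examples
#' fnv1a_hash(list(alpha = 0.05, seed = 1L))
#' @export
fnv1a_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261 # FNV offset basis; kept as double, reduced mod 2^32
  p <- 16777619 # FNV prime
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves to stay inside
    # double precision (h * p would exceed 2^53)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
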