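#' Generate DICOM-conformant unique identifiers
#'
#' Returns a closure that produces fresh UIDs under a dotted-decimal root.
#' The default root `"2.25."` carries a random 128-bit integer rendered in
#' decimal — the UUID-derived scheme the DICOM standard reserves for
#' unregistered applications — so every value fits the 64-character limit
#' of the UI value representation without an organisation root.  Sites
#' that own a registered root can supply it instead.
#'
#' With `seed` the generator draws from a private RNG stream, so the full
#' sequence of UIDs is reproducible and independent of the caller's RNG
#' state.  Without a seed the ambient R RNG is used.
#'
#' @param root UID prefix ending in `"."`, or `""`/`NULL` for the default
#'   `"2.25."`.  Each dot-separated component must be numeric with no
#'   leading zeros, and the root must leave room for at least a 64-bit
#'   random suffix.
#' @param seed optional integer; fixes the generated sequence.
#' @return A function of no arguments returning one new UID per call.
#'   Successive values are guaranteed pairwise distinct.
#' @examples
#' gen <- uid_generator(seed = 1)
#' gen()  # always the same first value for seed 1
#' @seealso [validate_uid()], [generate_uid()]
#' @export
uid_generator <- function(root = NULL, seed = NULL) {
  root <- normalize_uid_root(root)
  # bytes of entropy that still fit 64 chars: each byte adds < 2.41 digits
  max_digits <- 64L - nchar(root)
  n_bytes <- min(16L, floor(max_digits / 2.40824))
  if (n_bytes < 8L) {
    stop("uid root '", root, "' is too long to leave room for a random suffix",
         call. = FALSE)
  }

  rng_state <- NULL
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    set.seed(seed, kind = "Mersenne-Twister")
    rng_state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  seen <- new.env(parent = emptyenv())

  function() {
    draw <- function() sample.int(256L, n_bytes, replace = TRUE) - 1L
    if (!is.null(rng_state)) {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      assign(".Random.seed", rng_state, envir = globalenv())
      bytes <- draw()
      rng_state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    } else {
      bytes <- draw()
    }
    uid <- paste0(root, bytes_to_decimal(bytes))
    # 2^64+ random bits never collide in practice; the retry keeps the
    # pairwise-distinct contract absolute regardless
    while (!is.null(seen[[uid]])) {
      uid <- paste0(root, bytes_to_decimal(sample.int(256L, n_bytes,
                                                      replace = TRUE) - 1L))
    }
    seen[[uid]] <- TRUE
    uid
  }
}

#' Generate one or more fresh UIDs
#'
#' Convenience wrapper around [uid_generator()] for one-off use.
#'
#' @inheritParams uid_generator
#' @param n number of UIDs to generate.
#' @return Character vector of `n` distinct valid UIDs.
#' @export
generate_uid <- function(n = 1L, root = NULL, seed = NULL) {
  gen <- uid_generator(root = root, seed = seed)
  vapply(seq_len(n), function(i) gen(), character(1))
}

normalize_uid_root <- function(root) {
  if (is.null(root) || !nzchar(root)) return("2.25.")
  if (!grepl("\\.$", root)) {
    stop("uid root must end with '.': got '", root, "'", call. = FALSE)
  }
  body <- sub("\\.$", "", root)
  if (!isTRUE(validate_uid(body))) {
    stop("uid root '", root, "' is not a valid UID prefix: ",
         uid_invalid_reason(body), call. = FALSE)
  }
  root
}

# 16 random bytes -> decimal string of the 128-bit big-endian integer.
# Base-256 to base-10 conversion over base-1e7 limbs (doubles stay exact:
# limb * 65536 + carry < 2^53).
bytes_to_decimal <- function(bytes) {
  limbs <- 0          # little-endian, base 1e7
  n <- length(bytes)
  i <- 1L
  while (i <= n) {
    if (i + 1L <= n) {
      chunk <- bytes[i] * 256 + bytes[i + 1L]
      base <- 65536
      i <- i + 2L
    } else {
      chunk <- bytes[i]
      base <- 256
      i <- i + 1L
    }
    carry <- chunk
    for (j in seq_along(limbs)) {
      v <- limbs[j] * base + carry
      limbs[j] <- v %% 1e7
      carry <- v %/% 1e7
    }
    while (carry > 0) {
      limbs <- c(limbs, carry %% 1e7)
      carry <- carry %/% 1e7
    }
  }
  k <- length(limbs)
  out <- sprintf("%.0f", limbs[k])
  if (k > 1L) {
    out <- paste0(out, paste(sprintf("%07.0f", rev(limbs[-k])), collapse = ""))
  }
  out
}

#' Validate a DICOM UID
#'
#' Checks the UI value-representation rules: non-empty, at most 64
#' characters, dotted numeric components, no leading zeros (a component
#' that is exactly `"0"` is allowed), no leading/trailing/empty dot.
#'
#' @param x character vector of candidate UIDs.
#' @return Logical vector, `TRUE` where valid.  Use
#'   [uid_invalid_reason()] for the violated rule.
#' @examples
#' validate_uid("1.2.840.10008.1.2")  # TRUE
#' validate_uid("1.02.3")             # FALSE: leading zero
#' @export
validate_uid <- function(x) {
  is.na(uid_invalid_reason(x))
}

#' Explain why a UID is invalid
#'
#' @param x character vector of candidate UIDs.
#' @return Character vector: `NA` for valid values, otherwise the first
#'   violated rule.
#' @export
uid_invalid_reason <- function(x) {
  vapply(as.character(x), function(u) {
    if (is.na(u) || !nzchar(u)) return("empty")
    if (nchar(u) > 64L) return("longer than 64 characters")
    if (grepl("^\\.|\\.$", u)) return("starts or ends with '.'")
    comps <- strsplit(u, ".", fixed = TRUE)[[1]]
    if (any(!nzchar(comps))) return("empty component")
    if (any(!grepl("^[0-9]+$", comps))) return("non-numeric component")
    if (any(nchar(comps) > 1L & startsWith(comps, "0"))) {
      return("leading-zero component")
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
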