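# Rotation-orbit structure of P-bit circular binary patterns.
#
# A local binary pattern code is a P-bit word; bit p corresponds to the
# neighbour sampled at angle 2*pi*p/P (neighbour 0 east, angles
# counter-clockwise) and carries weight 2^p. Cyclic bit rotation of a code
# corresponds to rotating the underlying image patch by one angular step,
# so the equivalence classes under rotation ("orbits", binary necklaces)
# are the natural support for rotation-invariant histogram features.

MAX_P <- 24L

check_P <- function(P) {
  if (length(P) != 1L || is.na(P) || P != as.integer(P) || P < 1L || P > MAX_P)
    stop("P must be a single integer in [1, ", MAX_P, "]", call. = FALSE)
  as.integer(P)
}

check_code <- function(code, P) {
  if (any(is.na(code)) || any(code < 0) || any(code >= 2^P) ||
      any(code != floor(code)))
    stop("code must be an integer in [0, 2^P)", call. = FALSE)
  code
}

#' Cyclically rotate a binary pattern code
#'
#' Rotates the P-bit word `code` left by `k` bit positions (neighbour p
#' becomes neighbour p + k mod P). Rotation by P is the identity.
#' Arithmetic is done in doubles so all P up to 24 are exact.
#'
#' @param code integer code in `[0, 2^P)`; vectorized.
#' @param k number of positions to rotate (any integer; reduced mod P).
#' @param P number of bits (neighbourhood size).
#' @return the rotated code(s).
#' @examples
#' rotate_code(1, 1, 8)   # 2
#' rotate_code(255, 3, 8) # 255, all-ones is a fixed point
#' @export
rotate_code <- function(code, k, P) {
  P <- check_P(P)
  check_code(code, P)
  k <- ((k %% P) + P) %% P
  if (k == 0) return(code)
  (code * 2^k) %% 2^P + code %/% 2^(P - k)
}

popcount <- function(x, P) {
  n <- numeric(length(x))
  for (p in seq_len(P) - 1L) n <- n + (x %/% 2^p) %% 2
  n
}

#' Circular transition count and uniformity of a pattern
#'
#' A pattern is "uniform" when its circular sequence of bits has at most
#' two 0-1 transitions.
#'
#' @inheritParams rotate_code
#' @return list with `transition_count` (even integer) and `is_uniform`.
#' @export
classify_uniformity <- function(code, P) {
  P <- check_P(P)
  check_code(code, P)
  tc <- popcount(bit_xor(code, rotate_code(code, 1, P), P), P)
  list(transition_count = tc, is_uniform = tc <= 2)
}

# bitwXor works on 32-bit signed ints; stay in doubles for generality
bit_xor <- function(a, b, P) {
  r <- numeric(max(length(a), length(b)))
  a <- rep_len(a, length(r)); b <- rep_len(b, length(r))
  for (p in seq_len(P) - 1L) {
    r <- r + 2^p * as.numeric((a %/% 2^p) %% 2 != (b %/% 2^p) %% 2)
  }
  r
}

#' Rotation period of a pattern
#'
#' Smallest d > 0 with `rotate_code(code, d, P) == code`; always divides P
#' and equals the size of the code's rotation orbit.
#'
#' @inheritParams rotate_code
#' @export
code_period <- function(code, P) {
  P <- check_P(P)
  check_code(code, P)
  divs <- which(P %% seq_len(P) == 0)
  for (d in divs) if (rotate_code(code, d, P) == code) return(as.integer(d))
  P
}

#' Enumerate the rotation orbits of all P-bit patterns
#'
#' Partitions all 2^P codes into equivalence classes under cyclic bit
#' rotation. The canonical representative of an orbit is its minimum code;
#' orbits are numbered in ascending canonical order and each code records
#' its rotation index r (code == rotate_code(canonical, r), r in [0, d)
#' where d is the orbit period). The orbit count matches the binary
#' necklace count (1/P) * sum_{d | P} phi(d) 2^(P/d).
#'
#' @param P number of bits, 1 <= P <= 24.
#' @return an object of class `orbit_table`: list with `P`, `codes`
#'   (data.frame: code, orbit_id, rotation_index, period, ones,
#'   transitions, uniform) and `orbits` (data.frame: orbit_id, canonical,
#'   size, ones, uniform) plus `members`, a list giving for each orbit its
#'   member codes ordered by rotation index.
#' @examples
#' tab <- enumerate_orbits(8)
#' nrow(tab$orbits)  # 36
#' @export
enumerate_orbits <- function(P) {
  P <- check_P(P)
  codes <- as.numeric(0:(2^P - 1))
  canon <- codes
  rotk <- integer(length(codes))       # rotation taking canonical -> code
  rots <- codes
  for (k in seq_len(P - 1)) {
    rots <- (rots * 2) %% 2^P + rots %/% 2^(P - 1)  # rotate left by 1 more
    smaller <- rots < canon
    canon[smaller] <- rots[smaller]
    # code = rotate(canonical, r): canonical reached from code by k lefts
    # means code = rotate(canonical, -k) = rotate(canonical, P-k)
  }
  # period and rotation index per code
  period <- integer(length(codes))
  rotidx <- integer(length(codes))
  cur <- canon
  seen <- rep(FALSE, length(codes))
  r <- 0L
  repeat {
    hit <- !seen & (cur == codes)
    rotidx[hit] <- r
    seen <- seen | hit
    if (all(seen)) break
    cur <- (cur * 2) %% 2^P + cur %/% 2^(P - 1)
    r <- r + 1L
  }
  # period: smallest d>0 with rotate(code,d)==code, computed orbit-wise below
  ones <- popcount(codes, P)
  trans <- popcount(bit_xor(codes, (codes * 2) %% 2^P + codes %/% 2^(P - 1), P), P)
  uniform <- trans <= 2

  canon_sorted <- sort(unique(canon))
  orbit_id <- match(canon, canon_sorted)
  sizes <- tabulate(orbit_id, nbins = length(canon_sorted))
  period <- sizes[orbit_id]

  codes_df <- data.frame(
    code = codes, orbit_id = orbit_id, rotation_index = rotidx,
    period = period, ones = ones, transitions = trans, uniform = uniform)
  orbits_df <- data.frame(
    orbit_id = seq_along(canon_sorted), canonical = canon_sorted,
    size = sizes, ones = ones[match(canon_sorted, codes)],
    uniform = uniform[match(canon_sorted, codes)])
  members <- vector("list", length(canon_sorted))
  ord <- order(orbit_id, rotidx)
  members <- split(codes[ord], orbit_id[ord])
  names(members) <- NULL
  structure(list(P = P, codes = codes_df, orbits = orbits_df,
                 members = members),
            class = "orbit_table")
}

#' @export
print.orbit_table <- function(x, ...) {
  cat("orbit_table: P =", x$P, "-", nrow(x$orbits), "orbits,",
      nrow(x$codes), "codes\n")
  invisible(x)
}

#' Closed-form count of binary necklaces (rotation orbits)
#'
#' Burnside / Polya count: (1/P) * sum over divisors d of P of
#' phi(d) * 2^(P/d). Used as an analytic cross-check of
#' [enumerate_orbits()].
#'
#' @inheritParams enumerate_orbits
#' @export
necklace_count <- function(P) {
  P <- check_P(P)
  phi <- function(n) sum(gcd_vec(seq_len(n), n) == 1)
  divs <- which(P %% seq_len(P) == 0)
  sum(vapply(divs, function(d) phi(d) * 2^(P / d), numeric(1))) / P
}

gcd_vec <- function(a, b) {
  r <- mapply(function(x, y) {
    while (y != 0) { t <- y; y <- x %% y; x <- t }
    x
  }, a, b)
  as.numeric(r)
}

# cached orbit tables (P=8 is used throughout)
.orbit_cache <- new.env(parent = emptyenv())

orbit_table_cached <- function(P) {
  key <- as.character(P)
  if (is.null(.orbit_cache[[key]])) .orbit_cache[[key]] <- enumerate_orbits(P)
  .orbit_cache[[key]]
}

#' Export an orbit table as a per-code CSV
#'
#' @param table an `orbit_table`.
#' @param path output CSV path.
#' @export
write_orbit_csv <- function(table, path) {
  stopifnot(inherits(table, "orbit_table"))
  utils::write.csv(table$codes, path, row.names = FALSE)
  invisible(path)
}
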