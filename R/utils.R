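# Internal helpers: deterministic number formatting and a small
# self-contained pseudo-random generator (so fixture/hydrogen placement
# never touches R's global RNG state).

# Format a real deterministically: up to 9 decimals, trailing zeros
# trimmed but at least `min_dec` kept. Writing then re-parsing then
# re-writing is byte-stable because the printed value is the nearest
# double to its own 9-decimal representation.
fmt_num <- function(x, min_dec = 3) {
  vapply(x, function(v) {
    s <- sprintf("%.9f", v)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    dec <- sub("0+$", "", parts[2])
    if (nchar(dec) < min_dec) {
      dec <- paste0(dec, strrep("0", min_dec - nchar(dec)))
    }
    if (nchar(dec) == 0) parts[1] else paste0(parts[1], ".", dec)
  }, character(1))
}

# Linear congruential generator (mod 2^32, multiplier 69069): products stay
# below 2^53 so plain double arithmetic is exact.
lcg_new <- function(seed = 0) {
  env <- new.env(parent = emptyenv())
  env$state <- as.numeric(seed) %% 4294967296
  env
}

lcg_unif <- function(gen, n = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    gen$state <- (69069 * gen$state + 1) %% 4294967296
    out[i] <- gen$state / 4294967296
  }
  out
}

# Deterministic unit vector on the sphere (area-uniform).
lcg_unit_vector <- function(gen) {
  u <- lcg_unif(gen, 2)
  z <- 2 * u[1] - 1
  phi <- 2 * pi * u[2]
  r <- sqrt(max(0, 1 - z^2))
  c(r * cos(phi), r * sin(phi), z)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))

atom_xyz <- function(mol, i) {
  as.numeric(mol$atoms[i, c("x", "y", "z")])
}
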