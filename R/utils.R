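# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stream name.
# Keeps results of one stage invariant to enabling/disabling another.
.childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629) + 1L
}

# Run expr with a locally set RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Upper-triangle (i < j) values of a square matrix, column-major order.
.upperTri <- function(m) m[upper.tri(m)]

# Index pairs (i, j), i < j, matching .upperTri order.
.pairIndex <- function(n) {
  j <- rep(seq_len(n), each = n)[upper.tri(diag(n))]
  i <- rep(seq_len(n), times = n)[upper.tri(diag(n))]
  cbind(i = i, j = j)
}

# Permutation p-value, one-sided (>=), with the +1 correction.
.permP <- function(observed, perms, side = c("greater", "less", "two")) {
  side <- match.arg(side)
  B <- length(perms)
  pg <- (1 + sum(perms >= observed)) / (B + 1)
  pl <- (1 + sum(perms <= observed)) / (B + 1)
  switch(side,
         greater = pg,
         less = pl,
         two = min(1, 2 * min(pg, pl)))
}

# Project site coordinates onto the unit vector at a compass bearing
# (degrees clockwise from north). Uses local-plane km offsets so that a
# bearing has its geographic meaning at the sampled latitudes.
.bearingProjection <- function(lat, lon, bearingDeg) {
  th <- bearingDeg * pi / 180
  lat0 <- mean(lat)
  kmPerLat <- 111.32
  kmPerLon <- 111.32 * cos(lat0 * pi / 180)
  x <- (lon - mean(lon)) * kmPerLon   # east
  y <- (lat - lat0) * kmPerLat        # north
  x * sin(th) + y * cos(th)
}
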