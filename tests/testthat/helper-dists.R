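# Shared fixtures and independent oracles for the tests. Expected values
# for the gate examples are computed from closed forms here (binary/vector
# entropy), independently of the package's entropy code paths.

Hb <- function(p) {
  out <- numeric(length(p))
  ok <- p > 0 & p < 1
  out[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  out
}

Hvec <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# closed-form gate quantities used as frozen expectations
AND_MI1 <- Hb(1 / 4) - 0.5                # I(X1;Y) for the AND gate
AND3_MI1 <- Hb(1 / 8) - 0.5 * Hb(1 / 4)   # I(X1;Y) for the three-way AND
SUM3_MI1 <- Hvec(c(1, 3, 3, 1) / 8) - Hvec(c(1, 2, 1) / 4)
GH_AND <- Hb(1 / 4) - 0.75 * Hvec(c(1, 2) / 3)  # attained by Q = X1 OR X2

# garble one variable of a joint through a channel, producing a new joint
# with the variable replaced by the channel output
apply_channel <- function(dist, var, kappa, newname = "z") {
  tab <- as.data.frame(dist)
  rows <- list()
  for (r in seq_len(nrow(tab))) {
    x <- tab[[var]][r]
    for (zi in seq_len(nrow(kappa))) {
      nr <- tab[r, , drop = FALSE]
      nr[[var]] <- rownames(kappa)[zi] %||% as.character(zi)
      nr$p <- nr$p * kappa[zi, x]
      rows[[length(rows) + 1L]] <- nr
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == var] <- newname
  joint_dist(out[out$p > 0, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random rational coupling of two small variables (entries k/total), with
# optional structural zeros; used for the COPY-gate couplings
rand_rational_coupling <- function(seed, nx = 2, ny = 2, zero_frac = 0) {
  set.seed(seed)
  repeat {
    w <- sample(0:9, nx * ny, replace = TRUE)
    if (zero_frac > 0) w[runif(nx * ny) < zero_frac] <- 0
    if (sum(w) > 0) break
  }
  matrix(w / sum(w), nx, ny,
         dimnames = list(as.character(seq_len(nx) - 1),
                         as.character(seq_len(ny) - 1)))
}

# COPY-gate distribution from an explicit source coupling
copy_from_coupling <- function(pxx) {
  g <- expand.grid(x1 = rownames(pxx), x2 = colnames(pxx),
                   stringsAsFactors = FALSE)
  g$p <- pxx[cbind(g$x1, g$x2)]
  g$y <- paste0(g$x1, ",", g$x2)
  joint_dist(g[g$p > 0, c("x1", "x2", "y", "p")])
}
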