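# shared small-scale objects for the unit tests

small_arena <- function(res = 32L, L = 100) {
  arena_config(L, "periodic", grid_resolution = res)
}

small_dog_ensemble <- function(res = 32L, n_side = 16L, L = 100,
                               sigma1 = 3.75) {
  place_ensemble(small_arena(res, L), kind = "dog", sigma1 = sigma1,
                 n_side = n_side)
}

# brute-force Pearson autocorrelation at a single integer lag
ac_at_lag <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  a <- m[ri, rj]
  b <- m[ri - di, rj - dj]
  cor(as.numeric(a), as.numeric(b))
}
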