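# small deterministic fixtures used across test files

# 80 majority / 20 minority z-scored Gaussian table
imbalanced_table <- function(n_maj = 80L, n_min = 20L, d = 5L, seed = 42L) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n_maj + n_min) * d), ncol = d)
    labeled_table(X, rep(c(0L, 1L), c(n_maj, n_min)))
  })
}

# brute-force Tomek-link removal: enumerate all pairs, find mutual nearest
# neighbors with opposite labels, drop the majority member (label-0 on ties)
tomek_oracle <- function(table) {
  X <- table$features
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  nn <- integer(n)
  for (i in seq_len(n)) nn[i] <- which.min(D[i, ])
  maj <- if (sum(table$labels == 0L) >= sum(table$labels == 1L)) 0L else 1L
  drop <- logical(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a < b && nn[a] == b && nn[b] == a &&
        table$labels[a] != table$labels[b]) {
      drop[if (table$labels[a] == maj) a else b] <- TRUE
    }
  }
  which(!drop)
}

# is `point` a convex combination of the rows of `parents`? (1 or 2 parents)
on_segment <- function(point, parents, tol = 1e-8) {
  if (nrow(parents) == 1L) return(max(abs(point - parents[1, ])) <= tol)
  a <- parents[1, ]; b <- parents[2, ]
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else sum((point - a) * ab) / denom
  t >= -tol && t <= 1 + tol &&
    max(abs(point - (a + t * ab))) <= tol * (1 + sqrt(denom))
}

# check every synthetic row of `out` against its recorded parents
all_synthetic_on_segments <- function(out, tol = 1e-8) {
  syn <- which(out$provenance == "synthetic")
  all(vapply(syn, function(s) {
    par <- out$features[match(out$parent_ids[[s]], out$row_ids), ,
                        drop = FALSE]
    on_segment(out$features[s, ], par, tol)
  }, logical(1)))
}
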