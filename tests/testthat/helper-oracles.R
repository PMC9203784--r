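# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's matrix-algebra implementation: brute-force enumeration and
# textbook formulas only.

# Toy network: A->B:2, A->C:1, B->C:3, all other links 0.
toy_matrix <- function() {
  sc <- data.frame(
    source = c("A", "A", "B", "B", "C", "C"),
    target = c("B", "C", "A", "C", "A", "B"),
    score = c(2L, 1L, 0L, 3L, 0L, 0L)
  )
  build_matrix(c("A", "B", "C"), sc)
}

# Complete matrix over ids with every ordered pair scored by `f(i, j)`.
scores_from_fun <- function(ids, f) {
  grid <- expand.grid(source = ids, target = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid$score <- mapply(f, grid$source, grid$target)
  grid
}

constant_matrix <- function(ids, value) {
  build_matrix(ids, scores_from_fun(ids, function(i, j) value))
}

# Brute-force second-order influence: enumerate every directed length-2
# path from -> i -> to, i outside {from, to}, and sum the weight products.
brute_second_order <- function(M, from, to) {
  W <- M$weights
  ids <- rownames(W)
  acc <- 0
  for (i in setdiff(ids, c(from, to))) {
    w1 <- W[from, i]
    w2 <- W[i, to]
    if (!is.na(w1) && !is.na(w2)) acc <- acc + w1 * w2
  }
  acc
}

# Literal substitution of the total-influence formula:
# D_out(g) + sum_{j != g} w_gj * D_out(j), degrees summed by loop.
literal_total <- function(M, g) {
  W <- M$weights
  ids <- rownames(W)
  dout <- function(a) sum(W[a, setdiff(ids, a)])
  acc <- dout(g)
  for (j in setdiff(ids, g)) acc <- acc + W[g, j] * dout(j)
  acc
}

# Textbook Pearson correlation, written out with explicit sums.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Seeded random complete matrix over the full -3..3 scale.
random_small_matrix <- function(n, seed) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n)]
  build_matrix(ids, scores_from_fun(ids, function(i, j) sample(-3:3, 1)))
}
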