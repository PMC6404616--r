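# Shared fixtures, built in code at test time.

# 8 x 12 layout: wild type in the four corners, one EMPTY position, the rest
# numbered deletion strains.
make_test_layout <- function(n_rows = 8, n_cols = 12, n_wt_corners = 4,
                             plate_id = "P1") {
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  ids <- sprintf("s%03d", seq_len(nrow(grid)))
  corners <- rbind(c(1, 1), c(1, n_cols), c(n_rows, 1), c(n_rows, n_cols))
  for (i in seq_len(n_wt_corners)) {
    ids[grid$row == corners[i, 1] & grid$col == corners[i, 2]] <- "wt"
  }
  ids[grid$row == 2 & grid$col == 2] <- "EMPTY"
  plate_layout(plate_id, n_rows, n_cols,
               data.frame(row = grid$row, col = grid$col, strain_id = ids,
                          is_wt = ids == "wt"))
}

# Random density grid (zero at EMPTY positions) plus its rendered image.
make_rendered_plate <- function(layout = make_test_layout(), seed = 7,
                                params = render_params(seed = seed),
                                range = c(100, 6000)) {
  p <- layout$positions
  dmat <- matrix(0, layout$n_rows, layout$n_cols)
  vals <- withr::with_seed(seed,
                           stats::runif(nrow(p), range[1], range[2]))
  filled <- p$strain_id != "EMPTY"
  dmat[cbind(p$row[filled], p$col[filled])] <- vals[filled]
  list(layout = layout, densities = dmat,
       image = render_plate_image(dmat, layout, params), params = params)
}

# Direct-arithmetic hypergeometric upper tail (independent oracle: plain
# choose() products, no log space).
hyper_tail_direct <- function(k, n, K, N) {
  i <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exhaustive-draw oracle for tiny N: enumerate every size-n subset.
hyper_tail_enumerate <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)  # genes 1..K are the annotated ones
}
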