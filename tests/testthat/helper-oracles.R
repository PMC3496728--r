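# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Gotoh affine-gap global alignment score: a gap of length L costs
# open + extend * L (the same parameterisation global_align() documents).
gotoh_score <- function(a, b, mat, open = 10, extend = 0.5) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)  # ends in a match/mismatch
  X <- matrix(neg, n + 1, m + 1)  # ends in a gap in b (a consumed)
  Y <- matrix(neg, n + 1, m + 1)  # ends in a gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + extend * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[ra[i - 1], rb[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                     Y[i - 1, j] - open - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                     X[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# hand-worked sums-of-squares decomposition for an additive two-way layout,
# rows = colonies, cols = timepoints, one observation per cell
manual_two_way <- function(mat) {
  r <- nrow(mat); c <- ncol(mat)
  grand <- mean(mat)
  ss_col <- r * sum((colMeans(mat) - grand)^2)   # timepoint effect
  ss_row <- c * sum((rowMeans(mat) - grand)^2)   # colony effect
  ss_tot <- sum((mat - grand)^2)
  ss_res <- ss_tot - ss_col - ss_row
  df_col <- c - 1; df_row <- r - 1; df_res <- df_col * df_row
  f_time <- (ss_col / df_col) / (ss_res / df_res)
  f_colony <- (ss_row / df_row) / (ss_res / df_res)
  list(
    f_timepoint = f_time,
    p_timepoint = pf(f_time, df_col, df_res, lower.tail = FALSE),
    f_colony = f_colony,
    p_colony = pf(f_colony, df_row, df_res, lower.tail = FALSE)
  )
}

# small Ct fixture: one target, one reference, two colonies, given zt grid
make_ct_fixture <- function(target_ct, ref_ct = 18, zts = seq(2, 26, by = 4),
                            colonies = "A", reps = 3) {
  tidyr::expand_grid(colony = colonies, zt = zts, replicate = seq_len(reps)) |>
    dplyr::mutate(
      target = rep(target_ct, length.out = dplyr::n()),
      EF1a = ref_ct
    ) |>
    tidyr::pivot_longer(c("target", "EF1a"), names_to = "gene",
                        values_to = "ct") |>
    dplyr::select(gene, colony, zt, replicate, ct)
}
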