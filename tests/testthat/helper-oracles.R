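# Independent textbook-formula Pearson coefficient on pairwise-complete
# observations; deliberately not using stats::cor so it can serve as an
# oracle for correlation_matrix().
pearson_oracle <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Write a small CSV fixture into a per-test temporary file.
write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Best-permutation agreement between a planted labelling and cluster labels.
label_agreement <- function(truth, labels) {
  k <- max(truth, labels)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[labels] == truth))
  }
  best
}
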