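# Alignment fixtures shared by the MSA unit tests and acceptance suite.

ten_row_msa <- function(gap_col_gaps, width = 7L, gap_col = 4L) {
  rows <- vapply(1:10, function(i) {
    paste(rep(LETTERS[(i %% 5) + 1], width), collapse = "")
  }, character(1))
  for (i in seq_len(gap_col_gaps)) {
    substr(rows[i], gap_col, gap_col) <- "-"
  }
  setNames(rows, paste0("s", 1:10))
}

random_msa <- function(nrow = 8, ncol = 30, gap_prob = 0.15) {
  rows <- vapply(seq_len(nrow), function(i) {
    chars <- sample(AA_LETTERS, ncol, replace = TRUE)
    gaps <- runif(ncol) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  setNames(rows, sprintf("r%02d", seq_len(nrow)))
}
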