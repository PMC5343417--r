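# synthetic specimen records with controllable class structure
make_records <- function(n_per_cell = 10, side_sep = 0, gender_sep = 0,
                         noise = 1, seed = 1, n_features = 4) {
  set.seed(seed)
  cells <- expand.grid(gender = c("F", "M"), side = c("L", "R"),
                       i = seq_len(n_per_cell))
  n <- nrow(cells)
  x <- matrix(rnorm(n * n_features, sd = noise), n, n_features)
  x[, 1] <- x[, 1] + ifelse(cells$side == "L", side_sep, -side_sep)
  x[, 2] <- x[, 2] + ifelse(cells$gender == "F", gender_sep, -gender_sep)
  specimen_records(sprintf("s%03d", seq_len(n)), cells$gender, cells$side,
                   coefficients = x)
}
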