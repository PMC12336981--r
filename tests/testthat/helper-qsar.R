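# shared fixtures for the suite: the embedded study dataset is loaded once,
# toy datasets are built in code

study <- load_study_dataset()
study_train <- study$modeling[study$modeling$split == "train", ]
study_test <- study$modeling[study$modeling$split == "test", ]

# 4-point, 2-descriptor toy set with a known exact solution path
toy_two_descriptor <- function() {
  data.frame(
    compound_id = c("a", "b", "c", "d"),
    x1 = c(1, 2, 3, 5),
    x2 = c(2, 1, 4, 3),
    pIC50_obs = c(3.1, 4.0, 6.2, 8.4)
  )
}

# noiseless univariate line y = 2 + 3x
toy_line <- function(n = 6) {
  x <- seq_len(n)
  data.frame(compound_id = as.character(x), x1 = x, pIC50_obs = 2 + 3 * x)
}

# independent normal-equations solve: beta = (X'X)^-1 X'y via explicit inverse
normal_equations <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1) %*% t(X1) %*% y)
}
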