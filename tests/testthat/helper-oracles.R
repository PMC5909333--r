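# independent sum-of-squares oracle for the within-subject one-way ANOVA
rm_anova_ss_oracle <- function(m) {
  s <- nrow(m); t <- ncol(m)
  g <- mean(m)
  ss_time <- s * sum((colMeans(m) - g)^2)
  ss_subj <- t * sum((rowMeans(m) - g)^2)
  ss_err <- sum((m - g)^2) - ss_time - ss_subj
  f <- (ss_time / (t - 1)) / (ss_err / ((s - 1) * (t - 1)))
  list(F = f, df1 = t - 1, df2 = (s - 1) * (t - 1),
       p = stats::pf(f, t - 1, (s - 1) * (t - 1), lower.tail = FALSE))
}
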