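# Shared fixtures, all generated in code.

# Small study-shaped simulation used by several files.
tiny_sim <- function(seed = 11, n_case = 8, n_control = 7, n_features = 30,
                     effects = c(2, -2, 1.5)) {
  sim_counts(sim_design(n_case = n_case, n_control = n_control,
                        n_features = n_features,
                        informative_effects = effects, seed = seed))
}

# Independent pair-counting AUC oracle: (concordant + half ties) / (n1 n2).
auc_pairs <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  (sum(outer(s1, s0, ">")) + 0.5 * sum(outer(s1, s0, "=="))) /
    (length(s1) * length(s0))
}

# Independent Mann-Whitney enumeration oracle (pair counting, all splits).
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  splits <- combn(length(pooled), n1)
  us <- apply(splits, 2, function(i) u_of(pooled[i], pooled[-i]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# log2(RPM + 1) matrix + groups for a simulation.
sim_analysis_matrix <- function(sim) {
  rpm <- rpm_normalize(detection_filter(sim$counts))
  m <- log2_rpm(rpm)
  list(m = m,
       y = sim$subjects$group[match(colnames(m), sim$subjects$subject_id)])
}
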