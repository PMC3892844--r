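# shared fixtures built in code

# small clean walk: no noise, fixed seed
clean_params <- function(n_steps = 20, overlap_time = -0.04, ...) {
  gait_params(n_steps = n_steps, overlap_time = overlap_time,
              noise_sd = 0, seed = 42, ...)
}

# a mixed legal/illegal overlap vector away from decision boundaries
mixed_overlaps <- function(n, seed = 99, min_abs = 0.02) {
  set.seed(seed)
  s <- sample(c(-1, 1), n, replace = TRUE)
  s * runif(n, min_abs, 0.06)
}

# the per-step comparison table implied by printed confusion cells
cells_to_pairs <- function(illegal_agree, illegal_missed, legal_agree,
                           legal_flagged) {
  data.frame(
    step_index = seq_len(illegal_agree + illegal_missed + legal_agree +
                           legal_flagged),
    camera_label = c(rep("illegal", illegal_agree + illegal_missed),
                     rep("legal", legal_agree + legal_flagged)),
    sensor_verdict = c(rep("illegal", illegal_agree),
                       rep("legal", illegal_missed),
                       rep("legal", legal_agree),
                       rep("illegal", legal_flagged)))
}
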