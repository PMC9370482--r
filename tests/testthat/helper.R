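# shared fixtures, built in code

default_train <- function() build_train(protocol_config())

# saw-tooth calibration trajectory with the standard pattern
sim_sawtooth <- function(b_pn = 3.7, b_np = 3.1, noise = 0, seed = 1,
                         n_steps = 20, repeats = 3) {
  cfg <- stage_sim_config(true_backlash_pos_neg = b_pn,
                          true_backlash_neg_pos = b_np,
                          position_noise_sd_um = noise, seed = seed)
  gen_stage_trajectory(cfg, sawtooth_commands(n_steps, 1, repeats))
}

# hand-built trajectory from explicit deviation vectors (one repeat each)
traj_from_dev <- function(zplus, zminus, sigma_reps = NULL) {
  n <- length(zplus)
  rows <- list()
  reps <- if (is.null(sigma_reps)) 1 else length(sigma_reps)
  for (r in seq_len(reps)) {
    off <- if (is.null(sigma_reps)) 0 else sigma_reps[r]
    rows[[length(rows) + 1]] <- data.frame(
      repeat_idx = r, position_index = seq_len(n), direction = "+",
      target_um = seq_len(n), measured_um = seq_len(n) + zplus + off)
    rows[[length(rows) + 1]] <- data.frame(
      repeat_idx = r, position_index = seq_len(n), direction = "-",
      target_um = seq_len(n), measured_um = seq_len(n) + zminus + off)
  }
  d <- do.call(rbind, rows)
  stage_trajectory(d$repeat_idx, d$position_index, d$direction,
                   d$target_um, d$measured_um)
}
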