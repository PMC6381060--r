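## Analytic closed-form trajectories used as integration oracles, a
## brute-force displacement estimator for image sequences, and a per-session
## cache for the expensive whole-protocol simulations shared by several
## acceptance checks.

## Shunting membrane under constant drives: linear ODE with rate
## (1 + i_ex + i_inh) / tau toward steady_state_membrane().
membrane_trajectory <- function(t, v0, i_ex, i_inh, tau) {
  v_star <- (i_ex - i_inh) / (1 + i_ex + i_inh)
  v_star + (v0 - v_star) * exp(-(1 + i_ex + i_inh) * t / tau)
}

## Vesicle gating under constant presynaptic activity v: rate
## (alpha + beta v) / tau_syn toward alpha / (alpha + beta v).
synapse_trajectory <- function(t, y0, alpha, beta, v, tau_syn) {
  y_star <- alpha / (alpha + beta * v)
  y_star + (y0 - y_star) * exp(-(alpha + beta * v) * t / tau_syn)
}

## Brute-force content-displacement oracle: the integer (dx, dy-up) shift
## maximizing the correlation between two frames (periodic).
oracle_displacement <- function(a, b, win = 4) {
  n <- nrow(a)
  best <- c(0, 0); best_v <- -Inf
  for (dx in -win:win) for (dy in -win:win) {
    ## content moving by (dx, dy-up): b[r, c] = a[r + dy, c - dx]
    pred <- a[(seq_len(n) - 1 + dy) %% n + 1, (seq_len(n) - 1 - dx) %% n + 1]
    v <- sum(b * pred)
    if (v > best_v) { best_v <- v; best <- c(dx, dy) }
  }
  best
}

## Session cache: the five-variant, three-experiment matrix and the
## variant-5 trial tables are reused by several acceptance checks.
.cache <- new.env(parent = emptyenv())

cached_matrix <- function(seed = 1L) {
  key <- paste0("matrix_", seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- run_variant_matrix(seed = seed)
  .cache[[key]]
}

cached_trials <- function(variant, experiment, seed = 1L) {
  key <- sprintf("trials_v%d_e%d_s%d", variant, experiment, seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- run_experiment(variant_params(variant),
                                    build_schedule(experiment, seed))
  .cache[[key]]
}
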