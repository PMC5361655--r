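# shared helpers: cached steady-gait snapshots so the disturbance tests
# re-use one settling run per speed within a test session

.fixture_env <- new.env(parent = emptyenv())

fixture_params <- function(speed, subject = "default") {
  walking_params(speed, subject)
}

fixture_snapshot <- function(speed = 0.97, subject = "default") {
  key <- paste0("snap_", subject, "_", speed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  model <- if (subject == "mmr") scale_anthropometry(1.75, 64)
           else if (speed == 1.20) scale_anthropometry(1.8, 75)
           else scale_anthropometry(1.8, 80)
  sn <- steady_snapshot(fixture_params(speed, subject), model = model,
                        v0 = speed, settle = 5)
  sn$model <- model
  .fixture_env[[key]] <- sn
  sn
}

.sol_pair <- function(disturbed, undisturbed, muscle = "sol", leg = "r") {
  n <- min(nrow(disturbed$trajectory), nrow(undisturbed$trajectory))
  col <- paste(muscle, leg, "act", sep = "_")
  tibble::tibble(time = disturbed$trajectory$time[seq_len(n)],
                 disturbed = disturbed$trajectory[[col]][seq_len(n)],
                 undisturbed = undisturbed$trajectory[[col]][seq_len(n)])
}

# brute-force (dense grid) band-overlap maximizer, the independent oracle
# for the exact breakpoint algorithm
brute_force_overlap <- function(m, mu, sd, n_grid = 2e4, k_max = NULL) {
  act <- which(m != 0)
  base <- sum(m == 0 & abs(mu) <= sd)
  if (!length(act)) return(list(k = 0, count = base))
  bps <- c((mu[act] - sd[act]) / m[act], (mu[act] + sd[act]) / m[act])
  bps <- bps[is.finite(bps) & bps >= 0]
  if (is.null(k_max)) k_max <- if (length(bps)) max(bps) * 1.5 + 1 else 1
  ks <- c(seq(0, k_max, length.out = n_grid), bps)  # include exact breakpoints
  counts <- vapply(ks, function(k)
    sum(abs(k * m[act] - mu[act]) <= sd[act]), integer(1)) + base
  best <- max(counts)
  list(k = ks[which.max(counts)], count = best)
}
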