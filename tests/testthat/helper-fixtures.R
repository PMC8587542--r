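# Shared fixtures. Trials are deterministic and moderately expensive to
# generate, so they are built once per session on demand and cached.

default_subject <- function() subject_record(1.77, 78.9, "male")

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  sub <- default_subject()
  val <- switch(name,
    stand_quiet = generate_stand(sub, duration = 2, sway_amplitude = 0),
    stand_sway = generate_stand(sub, duration = 3, sway_amplitude = 0.03),
    gait = generate_gait(sub),
    lift = generate_lift(sub),
    lift_impact = generate_lift(sub, impact_transient = TRUE),
    weight_shift = generate_weight_shift(sub),
    stop("unknown fixture: ", name))
  .fixture_cache[[name]] <- val
  val
}

# run the full pipeline on a trial via its on-disk fixture form (exercises
# BVH + CSV I/O); cached alongside
get_run <- function(name, flavor = "dynamic") {
  key <- paste0("run_", name, "_", flavor)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  trial <- get_fixture(name)
  dir <- tempfile(paste0("wbid_fix_", name))
  write_trial_fixture(trial, dir)
  fx <- read_trial_fixture(dir)
  run <- run_pipeline(fx$motion, fx$sensors, fx$subject, loads = fx$loads,
                      v_th = fx$v_th, flavor = flavor)
  .fixture_cache[[key]] <- run
  run
}

max_joint_moment_err <- function(run_loads, truth_loads) {
  err <- 0
  for (j in names(run_loads$joints))
    err <- max(err, max(abs(run_loads$joints[[j]]$moment -
                              truth_loads$joints[[j]]$moment)))
  err
}

rn <- function(m) sqrt(rowSums(m * m))
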