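# Shared fixtures: built once per test run, in code.

default_sched <- function(seed = 1L) generate_schedule(task_config(), seed = seed)

# a small schedule for fast fitting tests
small_sched <- function(n = 40L, seed = 3L) {
  generate_schedule(task_config(n_trials = n), seed = seed)
}

ref_params <- function() group_mean_params()

# simulate one reference subject on a schedule
ref_subject <- function(schedule, seed = 5L,
                        model = model_spec("three_level", "arbitrated")) {
  gp <- ref_params()
  simulate_agent(schedule, gp$perceptual, gp$response, model, seed = seed)
}
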