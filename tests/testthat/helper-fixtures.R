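# shared fixtures built in code

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# the deterministic two-tripling genealogy: everything survives, 9 leaves
deterministic_33 <- function() {
  sched <- event_schedule(c(3, 3))
  params <- survival_params(sched, surv2 = c(0, 0), surv3 = c(1, 1))
  g <- enumerate_genealogies(sched, params)
  g[g$weight > 0.999, ]
}

# two-component synthetic similarities, fixed seed
two_component_sample <- function(n1 = 5000, n2 = 5000, mu = c(70, 90),
                                 sd = c(3, 3), seed = 101) {
  withr::with_seed(seed, c(stats::rnorm(n1, mu[1], sd[1]),
                           stats::rnorm(n2, mu[2], sd[2])))
}

# grid of survival parameter settings for a schedule (squared and free u')
param_grid <- function(schedule, values = seq(0.1, 0.5, length.out = 5),
                       squared = TRUE) {
  sched <- event_schedule(schedule)
  m <- length(sched)
  grid <- expand.grid(rep(list(values), m))
  lapply(seq_len(nrow(grid)), function(i) {
    s2 <- as.numeric(grid[i, ])
    if (squared) {
      survival_params(sched, s2, squared = TRUE)
    } else {
      s3 <- ifelse(unclass(sched) == 3L, pmin(0.3, 1 - s2 - 0.05), NA_real_)
      survival_params(sched, s2, s3)
    }
  })
}
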