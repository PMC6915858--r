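# Closed-form expected triplet counts per root, transcribed model by model
# from the published two- and three-event tables.  u, u2 = P(2 of 3 survive)
# and P(3 of 3 survive) at event 1 (u2 is u' in the usual notation; for a
# doubling u = P(both survive) and u2 is unused); likewise v, v2 and w, w2.
# Unrealizable types (oldest divergence occurring once) are structural
# zeros and omitted here; new_profile() fills them with 0.

closed_form_two <- function(model, u, u2, v, v2) {
  switch(model,
    "3,3" = c(
      "t1,t1,t1" = u2 * (1 + 2 * v2 + v)^3,
      "t1,t1,t2" = 2 * (3 * u2 + u) * (3 * v2 + v) * (1 + 2 * v2 + v),
      "t2,t2,t2" = (1 + 2 * u2 + u) * v2
    ),
    "3,2" = c(
      "t1,t1,t1" = u2 * (1 + v)^3,
      "t1,t1,t2" = 2 * (3 * u2 + u) * v * (1 + v)
    ),
    "2,3" = c(
      "t1,t1,t2" = 2 * u * (3 * v2 + v) * (1 + 2 * v2 + v),
      "t2,t2,t2" = (1 + u) * v2
    ),
    "2,2" = c(
      "t1,t1,t2" = 2 * u * v * (1 + v)
    ),
    rlang::abort(paste0("no closed form for model (", model, ")"))
  )
}

closed_form_three <- function(model, u, u2, v, v2, w, w2) {
  switch(model,
    "2,2,2" = c(
      "t1,t1,t2" = 2 * u * v * (1 + v) * (1 + w)^3,
      "t2,t2,t3" = 2 * (1 + u) * v * w * (1 + w),
      "t1,t1,t3" = 2 * u * (1 + v)^2 * w * (1 + w)
    ),
    "3,2,2" = c(
      "t1,t1,t1" = u2 * (1 + v)^3 * (1 + w)^3,
      "t1,t1,t2" = 2 * (3 * u2 + u) * v * (1 + v) * (1 + w)^3,
      "t2,t2,t3" = 2 * (1 + 2 * u2 + u) * v * w * (1 + w),
      "t1,t1,t3" = 2 * (3 * u2 + u) * (1 + v)^2 * w * (1 + w)
    ),
    "2,3,2" = c(
      "t1,t1,t2" = 2 * u * (3 * v2 + v) * (1 + 2 * v2 + v) * (1 + w)^3,
      "t2,t2,t2" = (1 + u) * v2 * (1 + w)^3,
      "t2,t2,t3" = 2 * (1 + u) * (3 * v2 + v) * w * (1 + w),
      "t1,t1,t3" = 2 * u * (1 + 2 * v2 + v)^2 * w * (1 + w)
    ),
    "2,2,3" = c(
      "t1,t1,t2" = 2 * u * v * (1 + v) * (1 + 2 * w2 + w)^3,
      "t2,t2,t3" = 2 * (1 + u) * v * (3 * w2 + w) * (1 + 2 * w2 + w),
      "t3,t3,t3" = (1 + u) * (1 + v) * w2,
      "t1,t1,t3" = 2 * u * (1 + v)^2 * (3 * w2 + w) * (1 + 2 * w2 + w)
    ),
    "2,3,3" = c(
      "t1,t1,t2" = 2 * u * (3 * v2 + v) * (1 + 2 * v2 + v) * (1 + 2 * w2 + w)^3,
      "t2,t2,t2" = (1 + u) * v2 * (1 + 2 * w2 + w)^3,
      "t2,t2,t3" = 2 * (1 + u) * (3 * v2 + v) * (3 * w2 + w) * (1 + 2 * w2 + w),
      "t3,t3,t3" = (1 + u) * (1 + 2 * v2 + v) * w2,
      "t1,t1,t3" = 2 * u * (1 + 2 * v2 + v)^2 * (3 * w2 + w) * (1 + 2 * w2 + w)
    ),
    "3,2,3" = c(
      "t1,t1,t1" = u2 * (1 + v)^3 * (1 + 2 * w2 + w)^3,
      "t1,t1,t2" = 2 * (3 * u2 + u) * v * (1 + v) * (1 + 2 * w2 + w)^3,
      "t2,t2,t3" = 2 * (1 + 2 * u2 + u) * v * (3 * w2 + w) * (1 + 2 * w2 + w),
      "t3,t3,t3" = (1 + 2 * u2 + u) * (1 + v) * w2,
      "t1,t1,t3" = 2 * (3 * u2 + u) * (1 + v)^2 * (3 * w2 + w) * (1 + 2 * w2 + w)
    ),
    "3,3,2" = c(
      "t1,t1,t1" = u2 * (1 + 2 * v2 + v)^3 * (1 + w)^3,
      "t1,t1,t2" = 2 * (3 * u2 + u) * (3 * v2 + v) * (1 + 2 * v2 + v) * (1 + w)^3,
      "t2,t2,t2" = (1 + 2 * u2 + u) * v2 * (1 + w)^3,
      "t2,t2,t3" = 2 * (1 + 2 * u2 + u) * (3 * v2 + v) * w * (1 + w),
      "t1,t1,t3" = 2 * (3 * u2 + u) * (1 + 2 * v2 + v)^2 * w * (1 + w)
    ),
    "3,3,3" = c(
      "t1,t1,t1" = u2 * (1 + 2 * v2 + v)^3 * (1 + 2 * w2 + w)^3,
      "t1,t1,t2" = 2 * (3 * u2 + u) * (3 * v2 + v) * (1 + 2 * v2 + v) * (1 + 2 * w2 + w)^3,
      "t2,t2,t2" = (1 + 2 * u2 + u) * v2 * (1 + 2 * w2 + w)^3,
      "t2,t2,t3" = 2 * (1 + 2 * u2 + u) * (3 * v2 + v) * (3 * w2 + w) * (1 + 2 * w2 + w),
      "t3,t3,t3" = (1 + 2 * u2 + u) * (1 + 2 * v2 + v) * w2,
      "t1,t1,t3" = 2 * (3 * u2 + u) * (1 + 2 * v2 + v)^2 * (3 * w2 + w) * (1 + 2 * w2 + w)
    ),
    rlang::abort(paste0("no closed form for model (", model, ")"))
  )
}

closed_form_profile <- function(schedule, params) {
  schedule <- check_consistent(schedule, params)
  m <- length(schedule)
  if (!m %in% c(2L, 3L)) {
    rlang::abort("closed forms are tabulated for 2 or 3 events only; use method = \"enumeration\" or \"product\"")
  }
  model <- paste(unclass(schedule), collapse = ",")
  s2 <- params$surv2
  s3 <- ifelse(is.na(params$surv3), 0, params$surv3)
  vals <- if (m == 2L) {
    closed_form_two(model, s2[1], s3[1], s2[2], s3[2])
  } else {
    closed_form_three(model, s2[1], s3[1], s2[2], s3[2], s2[3], s3[3])
  }
  new_profile(vals, m, "underlying")
}
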