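# Independent brute-force oracles: straightforward loops that never touch
# the package's closed-form evaluation path.

# 2x2 expected counts by direct multiplication
oracle_2x2 <- function(n, prev, se, sp) {
  list(tp = n * prev * se,
       fp = n * (1 - prev) * (1 - sp),
       fn = n * prev * (1 - se),
       tn = n * (1 - prev) * sp)
}

# discounted stage accrual by explicit per-cycle loop
oracle_stage <- function(utility, median_survival, cost, horizon = 5,
                         rate = 0.035,
                         reward = c("start", "end", "half_cycle"),
                         dstart = c("cycle1", "cycle0"),
                         ctime = c("lump_sum", "spread"),
                         round_p = 2) {
  reward <- match.arg(reward); dstart <- match.arg(dstart)
  ctime <- match.arg(ctime)
  p <- 1 - 0.5^(1 / median_survival)
  if (!is.null(round_p)) p <- round(p, round_p)
  s <- 1 - p
  ly <- q <- cst <- 0
  occ_sum <- sum(s^(0:(horizon - 1)))
  for (t in 0:(horizon - 1)) {
    d <- (1 + rate)^(-(t + if (dstart == "cycle0") 1 else 0))
    occ <- switch(reward, start = s^t, end = s^(t + 1),
                  half_cycle = (s^t + s^(t + 1)) / 2)
    ly <- ly + occ * d
    q <- q + utility * occ * d
    if (ctime == "spread") cst <- cst + cost * s^t / occ_sum * d
    if (ctime == "lump_sum" && t == 0) cst <- cst + cost * d
  }
  list(ly = ly, qalys = q, cost = cst)
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_equal(object, expected, tolerance = tol)
}

base_params <- function() default_parameters()
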