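# Shared fixtures: tiny hand-checkable IPD sets and an exhaustive-search
# oracle for the pseudo-IPD reconstruction.

ipd_df <- function(time, event) {
  data.frame(subject_id = seq_along(time), arm = "control", endpoint = "PFS",
             time_months = time, event = as.integer(event))
}

# five subjects, all events at 1..5
ipd_five_events <- function() ipd_df(1:5, rep(1, 5))

# Exponential survival law as a parsurv object
exp_law <- function(rate) parsurv("exponential", c(rate = rate))

# Brute-force reconstruction oracle for small instances: enumerate all
# per-interval (events-at-click, censor-count) assignments consistent with
# the published at-risk numbers and return the minimal achievable maximum
# survival deviation at the coordinates. Censors are placed at interval
# midpoints, like the algorithm under test.
guyot_oracle_best_dev <- function(curve, risk) {
  t <- curve$time_months; S <- curve$survival
  rt <- risk$time_months; nr <- risk$n_at_risk
  I <- length(rt)
  iv <- findInterval(t, rt)
  best <- Inf
  # recursive enumeration over intervals
  recurse <- function(i, n_enter, events_so_far, cens_so_far) {
    if (i > I) {
      # assemble ipd: remaining n_enter censored at tail
      tail_t <- max(t[length(t)], rt[I])
      times <- c(events_so_far$t, cens_so_far$t, rep(tail_t, n_enter))
      ev <- c(rep(1L, length(events_so_far$t)),
              rep(0L, length(cens_so_far$t) + n_enter))
      if (length(times) == 0) return()
      km <- kaplan_meier(data.frame(time_months = times, event = ev))
      dev <- max(abs(km_survival_at(km, t) - S))
      if (dev < best) best <<- dev
      return()
    }
    idx <- which(iv == i)
    end_i <- if (i < I) rt[i + 1] else max(t[length(t)], rt[I])
    target <- if (i < I) nr[i + 1] else NA
    # enumerate total events d_i (split over clicks) and censors c_i
    max_exit <- n_enter
    for (ci in 0:max_exit) {
      di_total <- if (i < I) n_enter - ci - target else NA
      di_range <- if (i < I) {
        if (is.na(di_total) || di_total < 0) next
        di_total
      } else NA
      totals <- if (i < I) di_range else 0:(max_exit - ci)
      for (di in totals) {
        if (di + ci > n_enter) next
        # split di events over the clicks of the interval
        splits <- if (length(idx) == 0) {
          if (di == 0) list(integer(0)) else list()
        } else event_splits(di, length(idx))
        cts <- if (ci > 0) rt[i] + seq_len(ci) * (end_i - rt[i]) / (ci + 1)
               else numeric(0)
        for (sp in splits) {
          recurse(i + 1, n_enter - di - ci,
                  list(t = c(events_so_far$t, rep(t[idx], sp))),
                  list(t = c(cens_so_far$t, cts)))
        }
      }
    }
  }
  recurse(1, nr[1], list(t = numeric(0)), list(t = numeric(0)))
  best
}

# all compositions of total into k non-negative parts
event_splits <- function(total, k) {
  if (k == 1) return(list(total))
  out <- list()
  for (first in 0:total)
    for (rest in event_splits(total - first, k - 1))
      out[[length(out) + 1L]] <- c(first, rest)
  out
}
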